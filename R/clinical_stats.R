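#' Pearson chi-square test for a 2x2 table
#'
#' Chi-square test of independence without continuity correction (df = 1),
#' as used for baseline-table comparisons of binary traits between groups.
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = trait present/absent).
#' @return list with `test`, `statistic`, `p`.
#' @export
#' @examples
#' chi_square_2x2(rbind(c(36, 8), c(11, 7)))$p  # 0.084
chi_square_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0), sum(tab) > 0)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("chi-square test requires all margins to be positive")
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(test = "chi-square", statistic = unname(ht$statistic), p = ht$p.value)
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by the "probabilities at most that of the observed
#' table" rule: the sum over all tables with the same margins whose
#' hypergeometric probability does not exceed the observed table's.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `test`, `statistic` (`NA`; the test is exact), `p`.
#' @export
#' @examples
#' fisher_exact_2x2(rbind(c(4, 40), c(4, 14)))$p  # 0.214
fisher_exact_2x2 <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(identical(dim(tab), c(2L, 2L)), all(tab >= 0))
  if (sum(tab) == 0) stop("all-zero table")
  ht <- stats::fisher.test(tab)
  list(test = "fisher", statistic = NA_real_, p = ht$p.value)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples: exact enumeration when both samples
#' have at most 8 observations and no ties are present, otherwise the
#' tie-corrected normal approximation.
#'
#' @param x,y numeric samples.
#' @return list with `test`, `statistic` (the U statistic for `x`), `p`.
#' @export
#' @examples
#' mann_whitney_u(1:3, 4:6)$p  # exact two-sided 0.1
mann_whitney_u <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- any(duplicated(c(x, y)))
  use_exact <- length(x) <= 8 && length(y) <= 8 && !ties
  ht <- suppressWarnings(stats::wilcox.test(x, y, exact = use_exact,
                                            correct = !use_exact))
  p <- min(1, ht$p.value)
  if (is.nan(p)) p <- 1  # fully tied samples: no evidence against the null
  list(test = "mann-whitney", statistic = unname(ht$statistic), p = p)
}

#' Baseline characteristics table
#'
#' Compares every phenotype variable between the EM and CM groups the way a
#' clinical baseline table is built: continuous variables by Mann-Whitney,
#' binary variables by chi-square unless the smallest expected cell count
#' falls below `fisher_threshold`, in which case Fisher's exact test is used.
#' Continuous rows report mean +/- SD per group; binary rows report n (%).
#' A constant binary column gets p = 1 by convention and is flagged.
#'
#' @param phenotype data frame with a two-level `group` column (levels EM,
#'   CM) and the variables to compare.
#' @param continuous_vars,binary_vars character vectors naming the columns to
#'   treat as continuous / binary; defaults cover the columns produced by
#'   [generate_clinical_table()].
#' @param fisher_threshold minimum expected cell count below which the
#'   chi-square test is replaced by Fisher's exact test (default 2.5).
#' @return data frame with columns `variable`, `em`, `cm`, `test`, `p`,
#'   `flag`.
#' @export
compare_baseline_table <- function(phenotype,
                                   continuous_vars = c("age", "disease_duration_y",
                                                       "headache_days",
                                                       "headache_intensity",
                                                       "acute_drug_days"),
                                   binary_vars = c("sex", "aura", "allodynia",
                                                   "anxiety", "depression"),
                                   fisher_threshold = 2.5) {
  if (!"group" %in% names(phenotype)) stop("phenotype table must have a group column")
  group <- droplevels(as.factor(phenotype$group))
  if (nlevels(group) != 2)
    stop("baseline comparison requires two groups")
  lev <- levels(group)
  known <- c(continuous_vars, binary_vars)
  missing_cols <- setdiff(known, names(phenotype))
  if (length(missing_cols))
    stop(sprintf("unknown column(s): %s", paste(missing_cols, collapse = ", ")))
  rows <- list()
  for (v in continuous_vars) {
    x <- phenotype[[v]][group == lev[1]]
    y <- phenotype[[v]][group == lev[2]]
    res <- mann_whitney_u(x, y)
    rows[[v]] <- data.frame(
      variable = v,
      em = sprintf("%.1f ± %.1f", mean(x), stats::sd(x)),
      cm = sprintf("%.1f ± %.1f", mean(y), stats::sd(y)),
      test = res$test, p = res$p, flag = "", stringsAsFactors = FALSE)
  }
  for (v in binary_vars) {
    x <- phenotype[[v]]
    if (!all(x %in% c(0, 1))) stop(sprintf("column %s is not binary 0/1", v))
    pos <- c(sum(x[group == lev[1]]), sum(x[group == lev[2]]))
    tot <- as.integer(table(group))
    tab <- cbind(pos, tot - pos)
    fmt <- sprintf("%d (%.1f%%)", pos, 100 * pos / tot)
    if (length(unique(x)) < 2) {
      res <- list(test = "none", p = 1)
      flag <- "constant"
    } else {
      expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
      res <- if (min(expected) < fisher_threshold) fisher_exact_2x2(tab)
             else chi_square_2x2(tab)
      flag <- ""
    }
    rows[[v]] <- data.frame(variable = v, em = fmt[1], cm = fmt[2],
                            test = res$test, p = res$p, flag = flag,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
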
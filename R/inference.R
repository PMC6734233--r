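#' Permutation test for group differences in degree centrality
#'
#' Tests, per node, the difference of group means of degree centrality
#' (CM minus EM) against a permutation null: subjects are randomly reassigned
#' to groups (preserving group sizes) `b` times, and the two-sided p-value is
#' `(1 + #\{|T_perm| >= |T_obs|\}) / (b + 1)`. With `exact = TRUE` all
#' distinct assignments are enumerated instead and the p-value is the exact
#' fraction `#\{|T| >= |T_obs|\} / n_assignments`. P-values are
#' FDR-corrected across nodes with Benjamini-Hochberg.
#'
#' @param dc n x K matrix (or data frame of `dc_*` columns, or vector) of
#'   degree-centrality values.
#' @param group factor/character with two levels; the statistic is
#'   mean(second level) - mean(first level). A factor with levels
#'   `c("EM", "CM")` gives CM - EM.
#' @param b number of random permutations (default 5000).
#' @param alpha two-sided significance level for the uncorrected test.
#' @param q FDR level for the corrected test.
#' @param seed seed for the permutation draw.
#' @param exact enumerate all label assignments (feasible for small cohorts).
#' @return object of class `permutation_result`: list with `observed`,
#'   `null` (b x K matrix), `p`, `p_fdr`, `rejected` (at `q`, FDR-corrected),
#'   `rejected_uncorrected` (at `alpha`), `b`, `seed`, `groups`.
#' @export
permutation_group_test <- function(dc, group, b = 5000, alpha = 0.05,
                                   q = 0.05, seed = 1, exact = FALSE) {
  if (is.data.frame(dc)) dc <- as.matrix(dc[grep("^dc_", names(dc), value = TRUE)])
  dc <- as.matrix(dc)
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("group must have exactly two non-empty levels")
  if (any(table(group) == 0)) stop("a group has size 0")
  stopifnot(nrow(dc) == length(group), b >= 1)
  lev <- levels(group)
  g2 <- group == lev[2]
  n <- length(group); n2 <- sum(g2)
  stat <- function(sel) colMeans(dc[sel, , drop = FALSE]) -
    colMeans(dc[!sel, , drop = FALSE])
  observed <- stat(g2)
  if (exact) {
    combos <- utils::combn(n, n2)
    if (ncol(combos) > 5e5) stop("too many assignments for exhaustive enumeration")
    null <- t(apply(combos, 2, function(idx) {
      sel <- rep(FALSE, n); sel[idx] <- TRUE; stat(sel)
    }))
    if (ncol(dc) == 1) null <- matrix(null, ncol = 1)
    p <- colMeans(abs(null) >= rep(abs(observed), each = nrow(null)))
    b_used <- nrow(null)
  } else {
    set.seed(seed)
    null <- matrix(0, b, ncol(dc))
    for (i in seq_len(b)) {
      sel <- rep(FALSE, n); sel[sample.int(n, n2)] <- TRUE
      null[i, ] <- stat(sel)
    }
    p <- (1 + colSums(abs(null) >= rep(abs(observed), each = b))) / (b + 1)
    b_used <- b
  }
  nm <- colnames(dc)
  if (!is.null(nm)) names(p) <- nm
  fdr <- bh_fdr(p, q)
  structure(list(observed = observed, null = null, p = p,
                 p_fdr = fdr$adjusted, rejected = fdr$rejected,
                 rejected_uncorrected = p <= alpha,
                 b = b_used, seed = seed, exact = exact,
                 groups = lev), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("permutation test (%s - %s), %s%d permutations\n",
              x$groups[2], x$groups[1], if (x$exact) "exhaustive " else "",
              x$b))
  print(data.frame(observed = x$observed, p = x$p, p_fdr = x$p_fdr,
                   significant = x$rejected))
  invisible(x)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted p-values; a hypothesis is rejected when its adjusted
#' p-value is at most `q`.
#'
#' @param pvals vector of p-values in (0, 1].
#' @param q FDR level (default 0.05).
#' @return list with `adjusted` and logical `rejected`.
#' @export
#' @examples
#' bh_fdr(c(0.0066, rep(0.35, 6)))$adjusted[1]  # 0.0462
bh_fdr <- function(pvals, q = 0.05) {
  if (!length(pvals)) stop("empty p-value vector")
  stopifnot(all(pvals > 0 & pvals <= 1))
  adj <- stats::p.adjust(pvals, method = "BH")
  list(adjusted = adj, rejected = adj <= q)
}

#' Covariate-adjusted group effect on degree centrality
#'
#' For each covariate set, fits an ordinary linear model
#' `DC ~ group + covariates` per node and reports the two-sided p-value of
#' the group coefficient, FDR-corrected across the node family within each
#' covariate set. A Freedman-Lane permutation alternative is available:
#' residuals of the covariates-only model are permuted to form the null for
#' the group coefficient's t statistic.
#'
#' @param dc n x K matrix (or data frame of `dc_*` columns, or vector).
#' @param group two-level factor.
#' @param covariates data frame of covariates (rows match subjects).
#' @param covariate_sets list of character vectors naming columns of
#'   `covariates`; each defines one adjustment model. An empty character
#'   vector gives the unadjusted model.
#' @param method `"parametric"` (default) or `"freedman_lane"`.
#' @param b,seed permutation controls for `"freedman_lane"`.
#' @return data frame with one row per (covariate set, node): `set`, `node`,
#'   `p`, `p_fdr` (across nodes within the set).
#' @export
adjusted_group_effect <- function(dc, group, covariates, covariate_sets,
                                  method = c("parametric", "freedman_lane"),
                                  b = 5000, seed = 1) {
  method <- match.arg(method)
  if (is.data.frame(dc)) dc <- as.matrix(dc[grep("^dc_", names(dc), value = TRUE)])
  dc <- as.matrix(dc)
  group <- droplevels(as.factor(group))
  if (nlevels(group) < 2) stop("group indicator is constant: no contrast to test")
  stopifnot(is.list(covariate_sets))
  out <- list()
  for (si in seq_along(covariate_sets)) {
    vars <- covariate_sets[[si]]
    missing_vars <- setdiff(vars, names(covariates))
    if (length(missing_vars))
      stop(sprintf("unknown covariate(s): %s", paste(missing_vars, collapse = ", ")))
    df0 <- data.frame(group = group)
    if (length(vars)) df0 <- cbind(df0, covariates[vars])
    x <- stats::model.matrix(~ ., data = df0)
    if (nrow(x) <= ncol(x))
      stop(sprintf("insufficient degrees of freedom: %d subjects for %d model terms",
                   nrow(x), ncol(x)))
    qrx <- qr(x)
    if (qrx$rank < ncol(x)) {
      aliased <- colnames(x)[qrx$pivot[(qrx$rank + 1):ncol(x)]]
      stop(sprintf("collinear design; offending column(s): %s",
                   paste(aliased, collapse = ", ")))
    }
    pvec <- numeric(ncol(dc))
    for (j in seq_len(ncol(dc))) {
      df <- df0; df$y <- dc[, j]
      fit <- stats::lm(y ~ ., data = df)
      co <- summary(fit)$coefficients
      grow <- grep("^group", rownames(co))
      if (method == "parametric") {
        pvec[j] <- co[grow, "Pr(>|t|)"]
      } else {
        t_obs <- co[grow, "t value"]
        nuis <- stats::lm(y ~ . - group, data = df)
        rz <- stats::residuals(nuis)
        fz <- stats::fitted(nuis)
        set.seed(seed + j)
        t_null <- replicate(b, {
          df$y <- fz + sample(rz)
          summary(stats::lm(y ~ ., data = df))$coefficients[grow, "t value"]
        })
        pvec[j] <- (1 + sum(abs(t_null) >= abs(t_obs))) / (b + 1)
      }
    }
    adj <- bh_fdr(pvec)$adjusted
    out[[si]] <- data.frame(
      set = if (length(vars)) paste(vars, collapse = "+") else "(unadjusted)",
      node = seq_len(ncol(dc)), p = pvec, p_fdr = adj,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Pearson correlation with a clinical variable
#'
#' @param dc numeric vector (e.g. one node's degree centrality per subject).
#' @param clinical numeric vector of the same length.
#' @return list with `r` and two-sided `p` from the t distribution with
#'   n - 2 degrees of freedom.
#' @export
correlate_clinical <- function(dc, clinical) {
  stopifnot(length(dc) == length(clinical), length(dc) >= 3,
            all(is.finite(dc)), all(is.finite(clinical)))
  if (stats::sd(dc) == 0 || stats::sd(clinical) == 0)
    stop("zero variance in input; correlation undefined")
  ct <- stats::cor.test(dc, clinical, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Interaction between group and a binary moderator
#'
#' P-value for the product term in the linear model
#' `DC ~ group + moderator + group:moderator`.
#'
#' @param dc numeric vector of degree-centrality values.
#' @param group two-level factor.
#' @param moderator binary vector coded 0/1.
#' @return two-sided p-value of the interaction coefficient.
#' @export
interaction_effect <- function(dc, group, moderator) {
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2) stop("group must have two levels")
  if (length(unique(moderator)) < 2) stop("moderator is constant")
  if (!all(moderator %in% c(0, 1))) stop("moderator must be coded 0/1")
  if (any(table(group, moderator) == 0))
    stop("empty cell in the group x moderator layout")
  fit <- stats::lm(dc ~ group * moderator)
  co <- summary(fit)$coefficients
  unname(co[grep(":", rownames(co)), "Pr(>|t|)"])
}
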
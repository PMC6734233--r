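#' Network construction parameters
#'
#' @param ridge_lambda ridge regularization of the inverse covariance,
#'   expressed relative to the mean diagonal covariance (default 0.1;
#'   `0` gives the unregularized partial correlation).
#' @param soft_power_beta exponent of the power soft threshold (default 6).
#' @param use_absolute_weights if `TRUE` (default) soft-thresholded weights
#'   are unsigned `|r|^beta`; if `FALSE` the sign of `r` is retained.
#' @param soft_method `"power"` (default) for the power-adjacency transform,
#'   or `"sigmoid"` for `1 / (1 + exp(-alpha (|r| - tau)))`.
#' @param sigmoid_alpha,sigmoid_tau sigmoid steepness and midpoint (used only
#'   when `soft_method = "sigmoid"`).
#' @return list of class `network_params`.
#' @export
network_params <- function(ridge_lambda = 0.1, soft_power_beta = 6,
                           use_absolute_weights = TRUE,
                           soft_method = c("power", "sigmoid"),
                           sigmoid_alpha = 12, sigmoid_tau = 0.5) {
  stopifnot(ridge_lambda >= 0, soft_power_beta >= 1)
  structure(list(ridge_lambda = ridge_lambda,
                 soft_power_beta = soft_power_beta,
                 use_absolute_weights = use_absolute_weights,
                 soft_method = match.arg(soft_method),
                 sigmoid_alpha = sigmoid_alpha, sigmoid_tau = sigmoid_tau),
            class = "network_params")
}

#' L2-regularized partial correlation
#'
#' Edge weights of the weighted undirected network: the partial correlation
#' between every pair of node time series after removing the linear influence
#' of all other nodes, computed from a ridge-regularized inverse covariance.
#' Columns are standardized internally; the sample covariance `S` is
#' regularized as `S + lambda c I`, where `c` is the mean of `diag(S)`, then
#' inverted to a precision matrix `P`, and
#' `r_ij = -P_ij / sqrt(P_ii P_jj)`.
#'
#' @param x T x K matrix of node time series (T > 2, K >= 2).
#' @param ridge_lambda ridge weight relative to the mean diagonal covariance
#'   (default 0.1); at `0` this equals the classical partial correlation
#'   (the correlation of residuals after regressing out all other nodes).
#' @return K x K symmetric matrix with zero diagonal and entries in (-1, 1),
#'   attribute `stage = "partial_r"`.
#' @export
partial_correlation_l2 <- function(x, ridge_lambda = 0.1) {
  x <- as.matrix(x)
  if (nrow(x) <= 2) stop("need more than 2 time points")
  if (ncol(x) < 2) stop("need at least 2 nodes")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    nm <- colnames(x) %||% paste0("node_", seq_len(ncol(x)))
    stop(sprintf("constant time series for node(s): %s",
                 paste(nm[sds == 0], collapse = ", ")))
  }
  xs <- scale(x)
  s <- stats::cov(xs)
  p <- solve(s + ridge_lambda * mean(diag(s)) * diag(ncol(s)))
  r <- -p / sqrt(diag(p) %o% diag(p))
  diag(r) <- 0
  r <- (r + t(r)) / 2
  dimnames(r) <- list(colnames(x), colnames(x))
  attr(r, "stage") <- "partial_r"
  r
}

#' Soft-threshold edge weights
#'
#' Monotone power transform of partial correlations that down-weights weak
#' edges without binarizing: `w_ij = |r_ij|^beta` (sign retained when
#' `use_absolute = FALSE`). A sigmoid alternative is available through
#' [network_params()].
#'
#' @param r symmetric matrix of partial correlations (entries in (-1, 1)).
#' @param beta power exponent (>= 1, default 6).
#' @param use_absolute drop edge signs (default `TRUE`).
#' @param method `"power"` or `"sigmoid"`.
#' @param sigmoid_alpha,sigmoid_tau sigmoid parameters.
#' @return matrix of soft-thresholded weights, attribute `stage = "soft"`.
#' @export
soft_threshold <- function(r, beta = 6, use_absolute = TRUE,
                           method = c("power", "sigmoid"),
                           sigmoid_alpha = 12, sigmoid_tau = 0.5) {
  method <- match.arg(method)
  if (beta < 1) stop("soft-threshold power beta must be >= 1")
  if (any(abs(r) >= 1)) stop("partial correlations must lie in (-1, 1)")
  w <- if (method == "power") abs(r)^beta
       else 1 / (1 + exp(-sigmoid_alpha * (abs(r) - sigmoid_tau)))
  if (method == "sigmoid") diag(w) <- 0
  if (!use_absolute) w <- w * sign(r)
  attr(w, "stage") <- "soft"
  w
}

#' Fisher r-to-z transform of edge weights
#'
#' Elementwise `z = arctanh(w)`, stabilizing the variance of
#' correlation-derived edge weights. Symmetry and the zero diagonal are
#' preserved.
#'
#' @param w matrix of weights with `|w| < 1`.
#' @return transformed matrix, attribute `stage = "fisher_z"`.
#' @export
fisher_z <- function(w) {
  if (any(abs(w) >= 1)) stop("weights must satisfy |w| < 1 for arctanh")
  z <- atanh(w)
  attr(z, "stage") <- "fisher_z"
  z
}

#' Degree centrality
#'
#' Per-node sum of incident edge weights in a weighted undirected graph:
#' `DC_i = sum_{j != i} z_ij`.
#'
#' @param z symmetric K x K edge matrix (zero diagonal).
#' @return named numeric vector of length K.
#' @export
degree_centrality <- function(z) {
  z <- unclass(z)
  if (!isTRUE(all.equal(z, t(z), check.attributes = FALSE)))
    stop("edge matrix must be symmetric")
  d <- z
  diag(d) <- 0
  colSums(d)
}

#' Per-subject connectome and degree centrality
#'
#' Runs the full edge pipeline partial correlation -> soft threshold ->
#' Fisher z -> degree centrality on one subject's node time series.
#'
#' @param x T x K node time series.
#' @param params a [network_params()].
#' @return list with `partial_r`, `soft`, `fisher_z` matrices and the `dc`
#'   vector.
#' @export
subject_connectome <- function(x, params = network_params()) {
  stopifnot(inherits(params, "network_params"))
  r <- partial_correlation_l2(x, params$ridge_lambda)
  w <- soft_threshold(r, beta = params$soft_power_beta,
                      use_absolute = params$use_absolute_weights,
                      method = params$soft_method,
                      sigmoid_alpha = params$sigmoid_alpha,
                      sigmoid_tau = params$sigmoid_tau)
  z <- fisher_z(w)
  list(partial_r = r, soft = w, fisher_z = z, dc = degree_centrality(z))
}

#' Degree-centrality table for a cohort
#'
#' Applies [subject_connectome()] to each subject's node time series and
#' assembles the subjects x nodes degree-centrality matrix with group labels
#' and covariates.
#'
#' @param node_timeseries list of T x K matrices, one per subject.
#' @param group factor of group labels (levels EM, CM), one per subject.
#' @param covariates optional data frame of per-subject covariates bound to
#'   the result.
#' @param params a [network_params()].
#' @return data frame with `group`, the covariates, and `dc_1 .. dc_K`.
#' @export
dc_table <- function(node_timeseries, group, covariates = NULL,
                     params = network_params()) {
  stopifnot(is.list(node_timeseries), length(node_timeseries) == length(group))
  dc <- t(vapply(node_timeseries,
                 function(x) subject_connectome(x, params)$dc,
                 numeric(ncol(node_timeseries[[1]]))))
  colnames(dc) <- paste0("dc_", seq_len(ncol(dc)))
  out <- data.frame(group = group, dc, stringsAsFactors = FALSE)
  if (!is.null(covariates)) out <- cbind(out, covariates)
  out
}
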
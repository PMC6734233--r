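# Symmetric decorrelation: W <- (W W^T)^{-1/2} W
sym_decor <- function(w) {
  e <- eigen(w %*% t(w), symmetric = TRUE)
  solve_sqrt <- e$vectors %*% diag(1 / sqrt(e$values), nrow(w)) %*% t(e$vectors)
  solve_sqrt %*% w
}

# Fixed-point FastICA (logcosh contrast, symmetric scheme) on whitened data
# z (k x m, unit-variance uncorrelated rows; m = number of samples).
fastica_core <- function(z, max_iter = 200, tol = 1e-8) {
  k <- nrow(z); m <- ncol(z)
  w <- sym_decor(matrix(stats::rnorm(k * k), k, k))
  for (it in seq_len(max_iter)) {
    wz <- w %*% z
    g <- tanh(wz)
    gp <- 1 - g^2
    w_new <- (g %*% t(z)) / m - diag(rowMeans(gp), k) %*% w
    w_new <- sym_decor(w_new)
    delta <- max(abs(1 - abs(rowSums(w_new * w))))
    w <- w_new
    if (delta < tol) break
  }
  w
}

#' Temporal-concatenation group ICA
#'
#' Temporally concatenates all subjects' preprocessed volumes, reduces the
#' concatenated data to `k` dimensions by PCA, and extracts `k` spatially
#' independent components by fixed-point ICA (logcosh contrast, symmetric
#' decorrelation). Components are reported as spatial maps together with
#' z-maps (loadings standardized across voxels). The stochastic unmixing
#' initialization is controlled by `seed`, so results are deterministic given
#' the seed; component sign is fixed so each map's maximum-magnitude voxel
#' loads positively.
#'
#' @param volumes list of per-subject data: 4D arrays (x-y-z-time) or
#'   T x V matrices, all on a common voxel grid.
#' @param k number of components (>= 2); must not exceed the rank of the
#'   concatenated data.
#' @param seed integer seed for the unmixing initialization.
#' @param mask optional logical spatial mask restricting the voxel set.
#' @param max_iter,tol fixed-point iteration controls.
#' @return object of class `group_components`: list with `spatial_maps`
#'   (k x V), `z_maps` (k x V), `order` (component indices), `grid_dim`
#'   (spatial dimensions if the input was 4D), and `mask`.
#' @export
concat_and_decompose <- function(volumes, k, seed = 1, mask = NULL,
                                 max_iter = 200, tol = 1e-8) {
  stopifnot(is.list(volumes), length(volumes) >= 1, k >= 2)
  grid_dim <- NULL
  flat <- lapply(volumes, function(v) {
    if (is.matrix(v)) return(v)
    d <- dim(v)
    if (length(d) != 4) stop("each subject must be a 4D array or a T x V matrix")
    grid_dim <<- d[1:3]
    t(matrix(v, prod(d[1:3]), d[4]))
  })
  nv <- unique(vapply(flat, ncol, 1L))
  if (length(nv) != 1) stop("subjects are not on a common voxel grid")
  if (!is.null(mask)) flat <- lapply(flat, function(m) m[, as.logical(mask), drop = FALSE])
  y <- do.call(rbind, flat)
  y <- sweep(y, 2, colMeans(y))
  # PCA on the (small) time dimension; spatial maps live in the row space
  sv <- svd(y, nu = min(nrow(y), k + 5), nv = 0)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (k > rank)
    stop(sprintf("k = %d exceeds the rank (%d) of the concatenated data", k, rank))
  # whitened spatial signals: rows are uncorrelated, unit-variance over voxels
  v_k <- t(y) %*% sv$u[, seq_len(k), drop = FALSE]   # V x k, scaled right-singular
  v_k <- sweep(v_k, 2, colMeans(v_k))                # voxels are the samples
  z <- t(sweep(v_k, 2, sqrt(colSums(v_k^2) / ncol(y)), "/"))  # k x V
  set.seed(seed)
  w <- fastica_core(z, max_iter = max_iter, tol = tol)
  maps <- w %*% z                                    # k x V
  # sign convention: maximum-|loading| voxel positive
  for (i in seq_len(k)) {
    j <- which.max(abs(maps[i, ]))
    if (maps[i, j] < 0) maps[i, ] <- -maps[i, ]
  }
  if (!is.null(mask)) {
    full <- matrix(0, k, length(mask))
    full[, as.logical(mask)] <- maps
    maps <- full
  }
  zmaps <- t(apply(maps, 1, function(r) (r - mean(r)) / stats::sd(r)))
  structure(list(spatial_maps = maps, z_maps = zmaps,
                 order = seq_len(k), grid_dim = grid_dim, mask = mask),
            class = "group_components")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Subject-level component time series (dual-regression stage 1)
#'
#' Regresses each volume's voxel vector on the K group spatial maps, yielding
#' per-frame least-squares loadings: the subject-specific time series of each
#' component.
#'
#' @param volumes one subject's 4D array (x-y-z-time) or T x V matrix on the
#'   component grid.
#' @param components a [concat_and_decompose()] result.
#' @return T x K matrix of component time series, columns in
#'   `components$order`.
#' @export
subject_timeseries <- function(volumes, components) {
  stopifnot(inherits(components, "group_components"))
  y <- if (is.matrix(volumes)) volumes else {
    d <- dim(volumes)
    t(matrix(volumes, prod(d[1:3]), d[4]))
  }
  s <- components$spatial_maps
  if (ncol(y) != ncol(s)) stop("subject grid does not match component grid")
  gram <- s %*% t(s)
  if (rcond(gram) < 1e-12) stop("component map matrix is rank deficient")
  ts <- y %*% t(s) %*% solve(gram)
  colnames(ts) <- paste0("node_", components$order)
  ts
}

#' Classify components as signal or noise
#'
#' Computes, per component, the maximum absolute spatial cross-correlation
#' against a set of reference network templates; components whose best match
#' falls below `threshold` are labelled noise. Advisory quantitative
#' heuristics (spatial kurtosis and, when the grid is known, the fraction of
#' loading on the grid boundary) are reported but do not influence the label.
#'
#' @param components a [concat_and_decompose()] result.
#' @param templates named list of reference maps (numeric vectors on the same
#'   voxel grid), or a named matrix with templates in rows.
#' @param threshold correlation threshold below which a component is labelled
#'   noise (default 0.25).
#' @return data frame with one row per component: `component`, `label`
#'   (`"signal"`/`"noise"`), `template` (best match), `r` (absolute
#'   correlation), plus advisory `kurtosis` and `edge_fraction`.
#' @export
classify_components <- function(components, templates, threshold = 0.25) {
  stopifnot(inherits(components, "group_components"))
  if (is.matrix(templates)) {
    tl <- lapply(seq_len(nrow(templates)), function(i) templates[i, ])
    names(tl) <- rownames(templates) %||% paste0("template_", seq_len(nrow(templates)))
    templates <- tl
  }
  if (!length(templates)) stop("template set is empty")
  if (is.null(names(templates)) || any(!nzchar(names(templates))))
    stop("templates must be named")
  maps <- components$spatial_maps
  k <- nrow(maps)
  edge_frac <- rep(NA_real_, k)
  if (!is.null(components$grid_dim)) {
    d <- components$grid_dim
    idx <- array(seq_len(prod(d)), d)
    edge <- rep(FALSE, prod(d))
    edge[c(idx[c(1, d[1]), , ], idx[, c(1, d[2]), ], idx[, , c(1, d[3])])] <- TRUE
    edge_frac <- apply(abs(maps), 1, function(m) sum(m[edge]) / sum(m))
  }
  res <- lapply(seq_len(k), function(i) {
    rs <- vapply(templates, function(tp) {
      if (stats::sd(tp) == 0 || stats::sd(maps[i, ]) == 0) 0
      else abs(stats::cor(maps[i, ], tp))
    }, 1)
    best <- which.max(rs)
    m <- maps[i, ]
    data.frame(component = i,
               label = if (rs[best] < threshold) "noise" else "signal",
               template = names(templates)[best],
               r = unname(rs[best]),
               kurtosis = mean((m - mean(m))^4) / stats::var(m)^2,
               edge_fraction = edge_frac[i],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Rank sub-regions of a component by mean z-statistic
#'
#' Averages a component's z-map within each named region mask and ranks the
#' regions by descending mean z; ties are broken alphabetically by region
#' name.
#'
#' @param z_map numeric vector, one z value per voxel.
#' @param masks named list of logical vectors (or voxel index vectors) on the
#'   same grid.
#' @return data frame with columns `region` and `mean_z`, sorted by
#'   descending `mean_z`.
#' @export
subregion_importance <- function(z_map, masks) {
  stopifnot(is.list(masks), length(masks) >= 1)
  if (is.null(names(masks)) || any(!nzchar(names(masks))))
    stop("region masks must be named")
  mz <- vapply(names(masks), function(nm) {
    m <- masks[[nm]]
    idx <- if (is.logical(m)) which(m) else as.integer(m)
    if (!length(idx)) stop(sprintf("region '%s' has an empty mask", nm))
    mean(z_map[idx])
  }, 1)
  ord <- order(-mz, names(masks))
  data.frame(region = names(masks)[ord], mean_z = unname(mz[ord]),
             stringsAsFactors = FALSE)
}

#' Match recovered components to reference maps
#'
#' Finds the one-to-one assignment of components to reference maps maximizing
#' the total absolute spatial correlation (exhaustive over permutations, so
#' intended for small K).
#'
#' @param maps k x V recovered maps.
#' @param reference k x V planted/reference maps.
#' @return list with `assignment` (reference index per component) and
#'   `correlations` (absolute correlation per matched pair).
#' @export
match_components <- function(maps, reference) {
  k <- nrow(maps)
  stopifnot(nrow(reference) == k, k <= 8)
  cmat <- abs(stats::cor(t(maps), t(reference)))
  perms <- permutations_of(k)
  scores <- vapply(perms, function(p) sum(cmat[cbind(seq_len(k), p)]), 1)
  best <- perms[[which.max(scores)]]
  list(assignment = best, correlations = cmat[cbind(seq_len(k), best)])
}

permutations_of <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    rest <- permutations_of(n - 1)
    out <- c(out, lapply(rest, function(p) c(i, setdiff(seq_len(n), i)[p])))
  }
  out
}
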
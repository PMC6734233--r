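#' Region-of-interest specification
#'
#' @param name region name.
#' @param centroid_mni_mm length-3 numeric, MNI coordinates (mm).
#' @param radius_mm sphere radius (mm, default 3; small midbrain nuclei
#'   demand small radii).
#' @return list of class `roi_spec`.
#' @export
roi_spec <- function(name, centroid_mni_mm, radius_mm = 3) {
  stopifnot(is.character(name), length(centroid_mni_mm) == 3, radius_mm > 0)
  structure(list(name = name, centroid_mni_mm = as.numeric(centroid_mni_mm),
                 radius_mm = radius_mm), class = "roi_spec")
}

#' Default seed regions
#'
#' The three seed regions of the secondary analysis, as 3 mm-radius spheres
#' at their standard MNI centroids: hypothalamus (0, -4, -9),
#' periaqueductal gray (1, -31, -9) and dorsal raphe nucleus (1, -32, -17).
#'
#' @return named list of [roi_spec()] objects.
#' @export
default_roi_specs <- function() {
  list(hypothalamus = roi_spec("hypothalamus", c(0, -4, -9)),
       pag = roi_spec("pag", c(1, -31, -9)),
       drn = roi_spec("drn", c(1, -32, -17)))
}

#' Define a voxel grid in world (MNI) coordinates
#'
#' World coordinate of voxel index `(i, j, k)` (1-based) is
#' `origin_mm + (index - 1) * voxel_mm` per axis.
#'
#' @param dim length-3 integer grid dimensions.
#' @param voxel_mm isotropic voxel size, or length-3 vector.
#' @param origin_mm world coordinate of voxel (1, 1, 1).
#' @return list of class `voxel_grid`.
#' @export
voxel_grid <- function(dim, voxel_mm = 2, origin_mm = NULL) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1))
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  if (is.null(origin_mm)) origin_mm <- -(dim - 1) / 2 * voxel_mm
  stopifnot(length(origin_mm) == 3, all(voxel_mm > 0))
  structure(list(dim = dim, voxel_mm = as.numeric(voxel_mm),
                 origin_mm = as.numeric(origin_mm)), class = "voxel_grid")
}

#' Build a spherical ROI mask
#'
#' Marks every voxel whose center lies within `radius_mm` of the ROI
#' centroid. The resulting mask centroid reproduces the requested centroid to
#' within one voxel.
#'
#' @param spec a [roi_spec()].
#' @param grid a [voxel_grid()].
#' @return logical array of `grid$dim` with attributes `centroid_mm` (mask
#'   centroid in world coordinates) and `n_voxels`.
#' @export
build_sphere_mask <- function(spec, grid) {
  stopifnot(inherits(spec, "roi_spec"), inherits(grid, "voxel_grid"))
  ctr <- spec$centroid_mni_mm
  lo <- grid$origin_mm
  hi <- grid$origin_mm + (grid$dim - 1) * grid$voxel_mm
  if (any(ctr < lo - grid$voxel_mm) || any(ctr > hi + grid$voxel_mm))
    stop(sprintf("ROI '%s' centroid lies outside the grid", spec$name))
  ax <- lapply(1:3, function(a) lo[a] + (seq_len(grid$dim[a]) - 1) * grid$voxel_mm[a])
  dx2 <- outer(ax[[1]], ctr[1], "-")[, 1]^2
  dy2 <- outer(ax[[2]], ctr[2], "-")[, 1]^2
  dz2 <- outer(ax[[3]], ctr[3], "-")[, 1]^2
  d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  mask <- d2 <= spec$radius_mm^2
  if (!any(mask))
    stop(sprintf("ROI '%s' produced an empty mask (radius %.2g mm on a %.2g mm grid)",
                 spec$name, spec$radius_mm, max(grid$voxel_mm)))
  idx <- which(mask, arr.ind = TRUE)
  centroid <- lo + (unname(colMeans(idx)) - 1) * grid$voxel_mm
  attr(mask, "centroid_mm") <- centroid
  attr(mask, "n_voxels") <- sum(mask)
  attr(mask, "name") <- spec$name
  mask
}

#' Mean time series within a mask
#'
#' @param volumes 4D array (x-y-z-time) on the mask grid.
#' @param mask logical array matching the spatial dimensions.
#' @return numeric vector of length T: per-frame mean over mask voxels.
#' @export
extract_mean_timeseries <- function(volumes, mask) {
  d <- dim(volumes)
  if (length(d) != 4) stop("volumes must be a 4D array")
  if (!identical(as.integer(d[1:3]), as.integer(dim(mask))))
    stop("mask grid does not match volume grid")
  if (!any(mask)) stop("mask is empty")
  v <- matrix(volumes, prod(d[1:3]), d[4])
  colMeans(v[as.logical(mask), , drop = FALSE])
}

#' Seed-to-network connectivity contrast
#'
#' For each subject and ROI, computes the Pearson correlation between the ROI
#' time series and the target network node's time series, applies the Fisher
#' r-to-z transform, and contrasts the z values between groups with the
#' permutation test, FDR-corrected across ROIs.
#'
#' @param roi_ts list of per-subject T x R matrices with named ROI columns.
#' @param node_ts list of per-subject T x K node time-series matrices.
#' @param target_node node (column) index of the network of interest.
#' @param group two-level factor (EM, CM).
#' @param b,q,seed permutation and FDR controls (see
#'   [permutation_group_test()]).
#' @return list with `z` (subjects x ROIs matrix of Fisher z values) and
#'   `contrast` (a `permutation_result` across ROIs).
#' @export
seed_network_edges <- function(roi_ts, node_ts, target_node, group,
                               b = 5000, q = 0.05, seed = 1) {
  stopifnot(is.list(roi_ts), is.list(node_ts),
            length(roi_ts) == length(node_ts))
  n <- length(roi_ts)
  roi_names <- colnames(roi_ts[[1]])
  z <- matrix(NA_real_, n, ncol(roi_ts[[1]]),
              dimnames = list(NULL, roi_names))
  for (s in seq_len(n)) {
    if (nrow(roi_ts[[s]]) != nrow(node_ts[[s]]))
      stop(sprintf("subject %d: ROI and node series frame counts differ", s))
    target <- node_ts[[s]][, target_node]
    for (rj in seq_len(ncol(z))) {
      r <- stats::cor(roi_ts[[s]][, rj], target)
      if (!is.finite(r) || abs(r) >= 1 - 1e-12)
        stop(sprintf("degenerate seed correlation (|r| ~ 1) for subject %d, ROI %s",
                     s, roi_names[rj] %||% rj))
      z[s, rj] <- atanh(r)
    }
  }
  contrast <- permutation_group_test(z, group, b = b, q = q, seed = seed)
  list(z = z, contrast = contrast)
}
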
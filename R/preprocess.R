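#' Preprocessing configuration
#'
#' Bundles the deterministic preprocessing parameters: frame censoring
#' ("scrubbing") at a framewise-displacement threshold, discarding of initial
#' non-saturated volumes, global intensity normalization, temporal band-pass
#' and spatial smoothing. Defaults follow common resting-state practice:
#' FD threshold 0.5 mm, 12 s initial discard, grand mean 10,000, pass band
#' 0.009-0.08 Hz, 6 mm FWHM smoothing, 50 mm head radius for converting
#' rotations to displacements.
#'
#' @param fd_threshold_mm censor frames whose FD exceeds this (mm).
#' @param discard_initial_s initial acquisition time to discard (s).
#' @param target_mean global in-mask 4D mean after intensity normalization.
#' @param band_low_hz,band_high_hz temporal pass band (Hz); must satisfy
#'   `0 < low < high < 1/(2 TR)`.
#' @param smoothing_fwhm_mm Gaussian smoothing kernel full width at half
#'   maximum (mm).
#' @param head_radius_mm sphere radius used to convert rotation differences
#'   to arc-length displacements (mm).
#' @param filter_order Butterworth band-pass order (applied forward-backward,
#'   so the effective attenuation is doubled).
#' @return list of class `preproc_config`.
#' @export
preproc_config <- function(fd_threshold_mm = 0.5, discard_initial_s = 12,
                           target_mean = 10000, band_low_hz = 0.009,
                           band_high_hz = 0.08, smoothing_fwhm_mm = 6,
                           head_radius_mm = 50, filter_order = 2) {
  stopifnot(fd_threshold_mm > 0, discard_initial_s >= 0, target_mean > 0,
            band_low_hz > 0, band_high_hz > band_low_hz,
            smoothing_fwhm_mm >= 0, head_radius_mm > 0, filter_order >= 1)
  structure(list(fd_threshold_mm = fd_threshold_mm,
                 discard_initial_s = discard_initial_s,
                 target_mean = target_mean,
                 band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 smoothing_fwhm_mm = smoothing_fwhm_mm,
                 head_radius_mm = head_radius_mm,
                 filter_order = filter_order),
            class = "preproc_config")
}

#' Framewise displacement
#'
#' Power-style framewise displacement: the sum of absolute backward
#' differences of the six rigid-body motion parameters, with rotation
#' differences (radians) converted to arc length on a sphere of
#' `head_radius_mm`.
#'
#' @param motion T x 6 matrix: translations (mm) in columns 1-3, rotations
#'   (radians) in columns 4-6.
#' @param head_radius_mm head radius for the rotation-to-displacement
#'   conversion (default 50 mm).
#' @return numeric vector of length T - 1 (FD between consecutive frames),
#'   non-negative; `FD[t]` refers to the transition into frame `t + 1`.
#' @export
#' @examples
#' m <- matrix(0, 10, 6); m[6:10, 1] <- 0.2
#' framewise_displacement(m)  # 0.2 at the step, 0 elsewhere
framewise_displacement <- function(motion, head_radius_mm = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) != 6) stop("motion trace must have 6 columns")
  if (nrow(motion) < 2) stop("motion trace needs at least 2 frames")
  bad <- which(!is.finite(motion))
  if (length(bad)) {
    frame <- ((bad[1] - 1) %% nrow(motion)) + 1
    stop(sprintf("non-finite motion parameter at frame %d", frame))
  }
  d <- abs(diff(motion))
  rowSums(d[, 1:3, drop = FALSE]) +
    head_radius_mm * rowSums(d[, 4:6, drop = FALSE])
}

#' Trim initial volumes and scrub high-motion frames
#'
#' Removes the first `ceiling(discard_initial_s / tr_s)` frames, then censors
#' every remaining frame whose inbound framewise displacement exceeds
#' `fd_threshold_mm` (the later frame of each high-FD transition is dropped).
#'
#' @param series T x K numeric matrix (or length-T vector) of time series.
#' @param motion T x 6 motion trace matching `series` frame-for-frame.
#' @param tr_s repetition time (s).
#' @param config a [preproc_config()].
#' @return list with `retained` (strictly increasing original frame indices),
#'   `series` and `motion` restricted to those frames, and counts `n_trimmed`,
#'   `n_scrubbed`.
#' @export
trim_and_scrub <- function(series, motion, tr_s, config = preproc_config()) {
  stopifnot(inherits(config, "preproc_config"), tr_s > 0)
  series <- as.matrix(series)
  motion <- as.matrix(motion)
  if (nrow(series) != nrow(motion))
    stop("series and motion trace must have the same number of frames")
  n_t <- nrow(series)
  n_trim <- min(ceiling(config$discard_initial_s / tr_s), n_t)
  keep <- seq_len(n_t) > n_trim
  fd <- framewise_displacement(motion, config$head_radius_mm)
  # fd[t] is the transition into frame t + 1; drop the later frame
  high <- c(FALSE, fd > config$fd_threshold_mm)
  retained <- which(keep & !high)
  if (!length(retained)) stop("no usable volumes after trimming and scrubbing")
  list(retained = retained,
       series = series[retained, , drop = FALSE],
       motion = motion[retained, , drop = FALSE],
       n_trimmed = n_trim,
       n_scrubbed = sum(keep & high))
}

#' Global intensity normalization
#'
#' Rescales a 4D run by a single multiplicative factor so that its in-mask
#' grand mean equals `target_mean`.
#'
#' @param volumes numeric array (any shape; typically x-y-z-time).
#' @param target_mean desired grand mean (default 10,000).
#' @param mask optional logical array matching the spatial shape of `volumes`;
#'   the mean is computed (and applied) over in-mask voxels only, but the
#'   whole array is rescaled.
#' @return the rescaled array, with the scaling factor in attribute `factor`.
#' @export
intensity_normalize <- function(volumes, target_mean = 10000, mask = NULL) {
  stopifnot(target_mean > 0)
  if (is.null(mask)) {
    m <- mean(volumes)
  } else {
    d <- dim(volumes)
    nt <- if (length(d) == 4) d[4] else 1
    m <- mean(volumes[rep(as.logical(mask), nt)])
  }
  if (!is.finite(m) || m <= 0)
    stop(sprintf("in-mask mean is %.4g; cannot normalize to a positive target", m))
  f <- target_mean / m
  out <- volumes * f
  attr(out, "factor") <- f
  out
}

#' Temporal band-pass filter
#'
#' Zero-phase (forward-backward) Butterworth band-pass. Each column is
#' demeaned, filtered with [signal::filtfilt()], and returned demeaned; the
#' DC component is removed by construction.
#'
#' @param series T x K matrix (or vector) sampled at `1/tr_s` Hz.
#' @param tr_s repetition time (s).
#' @param band_low_hz,band_high_hz pass band (Hz); `band_high_hz` must be
#'   strictly below the Nyquist frequency `1/(2 tr_s)`.
#' @param order Butterworth order per pass (default 2).
#' @return filtered matrix of the same shape.
#' @export
bandpass_filter <- function(series, tr_s, band_low_hz = 0.009,
                            band_high_hz = 0.08, order = 2) {
  stopifnot(tr_s > 0, band_low_hz > 0, band_high_hz > band_low_hz)
  nyq <- 1 / (2 * tr_s)
  if (band_high_hz >= nyq)
    stop(sprintf("band_high_hz (%.4g) must be below Nyquist (%.4g Hz)",
                 band_high_hz, nyq))
  x <- as.matrix(series)
  bf <- signal::butter(order, c(band_low_hz, band_high_hz) / nyq, type = "pass")
  out <- apply(x, 2, function(col) {
    col <- col - mean(col)
    signal::filtfilt(bf, col)
  })
  if (is.null(dim(series))) out <- as.numeric(out)
  out
}

# 1D Gaussian kernel, truncated at 4 sigma, unit sum.
gauss_kernel <- function(sigma_vox) {
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(-r:r)^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Convolve a 3D array along one axis with a symmetric kernel (zero padding).
conv_axis <- function(vol, kernel, axis) {
  r <- (length(kernel) - 1L) / 2L
  out <- array(0, dim(vol))
  n <- dim(vol)[axis]
  for (off in -r:r) {
    w <- kernel[off + r + 1L]
    src <- seq_len(n) - off
    ok <- src >= 1 & src <= n
    idx_dst <- which(ok)
    idx_src <- src[ok]
    if (axis == 1) out[idx_dst, , ] <- out[idx_dst, , ] + w * vol[idx_src, , ]
    else if (axis == 2) out[, idx_dst, ] <- out[, idx_dst, ] + w * vol[, idx_src, ]
    else out[, , idx_dst] <- out[, , idx_dst] + w * vol[, , idx_src]
  }
  out
}

#' Spatial Gaussian smoothing
#'
#' Separable 3D Gaussian smoothing with kernel standard deviation
#' `sigma = fwhm / (2 sqrt(2 log 2))` per axis (in voxels, after dividing by
#' the voxel size). The kernel is normalized to unit sum, so the total image
#' sum is conserved up to boundary truncation.
#'
#' @param volumes 3D array, or 4D array (x-y-z-time) smoothed frame by frame.
#' @param fwhm_mm kernel full width at half maximum (mm); values below a
#'   hundredth of a voxel return the input unchanged (the identity limit).
#' @param voxel_mm isotropic voxel size (mm), or length-3 vector per axis.
#' @return smoothed array of the same shape.
#' @export
spatial_smooth <- function(volumes, fwhm_mm = 6, voxel_mm = 2) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (length(voxel_mm) == 1) voxel_mm <- rep(voxel_mm, 3)
  stopifnot(all(voxel_mm > 0))
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_mm
  if (all(sigma_vox < 0.01)) return(volumes)
  smooth3 <- function(v) {
    for (ax in 1:3)
      if (sigma_vox[ax] >= 0.01) v <- conv_axis(v, gauss_kernel(sigma_vox[ax]), ax)
    v
  }
  d <- dim(volumes)
  if (length(d) == 3) return(smooth3(volumes))
  if (length(d) != 4) stop("volumes must be a 3D or 4D array")
  out <- volumes
  for (t in seq_len(d[4])) out[, , , t] <- smooth3(volumes[, , , t])
  out
}
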
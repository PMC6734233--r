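#' Specify a synthetic migraine cohort
#'
#' Builds the parameter object that every generator in the package consumes.
#' Defaults emulate the study conditions of a typical interictal resting-state
#' cohort: 44 episodic-migraine (EM) and 18 chronic-migraine (CM) subjects,
#' TR = 3 s, 100 volumes, and seven network nodes.
#'
#' The group difference is planted on the precision matrix of the node time
#' series: for CM subjects, every off-diagonal precision entry incident to
#' `effect_node` is scaled by `(1 + effect_size)`, so the planted partial
#' correlations of that node's edges grow by the same factor while all other
#' edges are untouched. Network topology: `effect_node` (the "hub", standing in
#' for a pain-matrix-like component) is weakly partially correlated
#' (`hub_partial`) with every other node; the remaining nodes form strongly
#' coupled disjoint pairs (`pair_partial`). Both group precisions must be
#' symmetric positive definite, otherwise generation is refused.
#'
#' Seed regions are modelled alongside the network: each subject carries three
#' region-of-interest (ROI) time series (hypothalamus, dorsal raphe nucleus,
#' periaqueductal gray) coupled to the hub node with group-specific strengths
#' `roi_coupling_em` / `roi_coupling_cm`. The defaults plant the qualitative
#' structure hypothalamus CM > EM, DRN EM > CM, PAG equal.
#'
#' @param n_em,n_cm group sizes (each at least 2).
#' @param n_nodes number of network nodes K.
#' @param n_volumes number of acquired volumes T (before any trimming).
#' @param tr_s repetition time in seconds.
#' @param n_voxels_per_axis voxel grid side for 4D image generation.
#' @param effect_node node index carrying the planted group effect, or `NULL`
#'   for a null cohort; when `NULL` the hub is node 1 with no scaling.
#' @param effect_size dimensionless scaling of hub-incident precision entries
#'   in the CM group (`0` = null cohort).
#' @param noise_sd white-noise standard deviation added to generated volumes.
#' @param motion_spike_rate per-frame Bernoulli probability of a motion spike
#'   with framewise displacement above 0.5 mm by construction.
#' @param ar_coef optional AR(1) coefficient for temporal colouring of the node
#'   series (`0` = white in time, the default; the analysis operates on
#'   correlations, not spectra).
#' @param hub_partial planted partial correlation of hub-to-node edges (EM).
#' @param pair_partial planted partial correlation within node pairs.
#' @param roi_coupling_em,roi_coupling_cm named numeric vectors of ROI-to-hub
#'   coupling correlations per group (names `hypothalamus`, `drn`, `pag`).
#' @param seed integer seed; all generators are pure functions of (spec, seed).
#'
#' @return An object of class `cohort_spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_em = 6, n_cm = 4, n_volumes = 40, effect_node = 2,
#'                     effect_size = 0.5, seed = 1)
#' coh <- generate_node_timeseries_cohort(spec)
#' dim(coh$node_timeseries[[1]])
cohort_spec <- function(n_em = 44, n_cm = 18, n_nodes = 7, n_volumes = 100,
                        tr_s = 3, n_voxels_per_axis = 20,
                        effect_node = NULL, effect_size = 0,
                        noise_sd = 0.5, motion_spike_rate = 0, ar_coef = 0,
                        hub_partial = 0.16, pair_partial = 0.45,
                        roi_coupling_em = c(hypothalamus = 0.1, drn = 0.5, pag = 0.3),
                        roi_coupling_cm = c(hypothalamus = 0.5, drn = 0.1, pag = 0.3),
                        seed = 1) {
  stopifnot(n_em >= 2, n_cm >= 2, n_nodes >= 2, n_volumes >= 4, tr_s > 0,
            motion_spike_rate >= 0, motion_spike_rate <= 1,
            effect_size >= 0, noise_sd >= 0, abs(ar_coef) < 1,
            hub_partial >= 0, pair_partial >= 0)
  if (!is.null(effect_node)) {
    effect_node <- as.integer(effect_node)
    if (effect_node < 1 || effect_node > n_nodes)
      stop("effect_node must lie in 1..n_nodes")
  }
  if (!all(c("hypothalamus", "drn", "pag") %in% names(roi_coupling_em)) ||
      !all(c("hypothalamus", "drn", "pag") %in% names(roi_coupling_cm)))
    stop("roi couplings must name hypothalamus, drn and pag")
  spec <- list(n_em = as.integer(n_em), n_cm = as.integer(n_cm),
               n_nodes = as.integer(n_nodes), n_volumes = as.integer(n_volumes),
               tr_s = tr_s, n_voxels_per_axis = as.integer(n_voxels_per_axis),
               effect_node = effect_node, effect_size = effect_size,
               noise_sd = noise_sd, motion_spike_rate = motion_spike_rate,
               ar_coef = ar_coef, hub_partial = hub_partial,
               pair_partial = pair_partial,
               roi_coupling_em = roi_coupling_em,
               roi_coupling_cm = roi_coupling_cm,
               seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  spec
}

#' Planted per-group precision matrices
#'
#' Constructs the EM and CM precision (inverse covariance) matrices implied by
#' a [cohort_spec()]: unit diagonal, hub-to-all edges at partial correlation
#' `hub_partial` (scaled by `1 + effect_size` for CM), and disjoint node pairs
#' at `pair_partial`. A precision entry `P[i, j] = -r` corresponds to planted
#' partial correlation `r` because the diagonal is 1.
#'
#' @param spec a [cohort_spec()].
#' @return list with elements `em` and `cm` (K x K precision matrices) and
#'   `hub` (the hub node index).
#' @export
planted_precision <- function(spec) {
  k <- spec$n_nodes
  hub <- if (is.null(spec$effect_node)) 1L else spec$effect_node
  base <- function(scale_hub) {
    p <- diag(k)
    others <- setdiff(seq_len(k), hub)
    p[hub, others] <- p[others, hub] <- -spec$hub_partial * scale_hub
    i <- 1L
    while (i + 1L <= length(others)) {
      a <- others[i]; b <- others[i + 1L]
      p[a, b] <- p[b, a] <- -spec$pair_partial
      i <- i + 2L
    }
    p
  }
  em <- base(1)
  cm <- base(1 + spec$effect_size)
  for (nm in c("em", "cm")) {
    ev <- min(eigen(get(nm), symmetric = TRUE, only.values = TRUE)$values)
    if (ev <= 0)
      stop(sprintf(
        "planted %s precision is not positive definite (min eigenvalue %.4f); %s",
        toupper(nm), ev,
        "reduce hub_partial, pair_partial or effect_size"))
  }
  list(em = em, cm = cm, hub = hub)
}

# Draw a T x K Gaussian series with the given precision; optional AR(1)
# colouring preserves the cross-sectional covariance structure in expectation.
draw_series <- function(n_t, prec, ar_coef = 0) {
  cc <- chol(solve(prec))
  z <- matrix(stats::rnorm(n_t * ncol(prec)), n_t, ncol(prec))
  if (ar_coef != 0) {
    z <- apply(z, 2, function(col)
      as.numeric(stats::filter(col, ar_coef, method = "recursive")))
    z <- z * sqrt(1 - ar_coef^2)  # restore unit marginal variance
  }
  z %*% cc
}

#' Generate a cohort of node time series
#'
#' Draws per-subject T x K node time series from zero-mean Gaussian processes
#' whose inverse covariance equals the group's planted precision matrix (see
#' [planted_precision()]), together with motion traces, ROI seed series and a
#' phenotype table. Output is a pure function of the spec (which carries the
#' seed): two calls with the same spec are bit-identical.
#'
#' @param spec a [cohort_spec()].
#' @return An object of class `synthetic_cohort`: list with
#'   `node_timeseries` (list of T x K matrices), `motion` (list of T x 6
#'   matrices, translations mm then rotations rad), `roi_timeseries`
#'   (list of T x 3 matrices, columns hypothalamus/drn/pag),
#'   `clinical` (phenotype data frame), and `truth` (planted precisions, group
#'   labels, hub/effect node, ROI couplings, motion spike frames).
#' @export
generate_node_timeseries_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  prec <- planted_precision(spec)
  n <- spec$n_em + spec$n_cm
  group <- factor(rep(c("EM", "CM"), c(spec$n_em, spec$n_cm)),
                  levels = c("EM", "CM"))
  set.seed(spec$seed)
  ts <- vector("list", n)
  roi <- vector("list", n)
  roi_names <- c("hypothalamus", "drn", "pag")
  for (s in seq_len(n)) {
    p <- if (group[s] == "EM") prec$em else prec$cm
    x <- draw_series(spec$n_volumes, p, spec$ar_coef)
    colnames(x) <- paste0("node_", seq_len(spec$n_nodes))
    ts[[s]] <- x
    coup <- if (group[s] == "EM") spec$roi_coupling_em else spec$roi_coupling_cm
    hubser <- scale(x[, prec$hub])[, 1]
    r3 <- vapply(roi_names, function(rn) {
      rho <- coup[[rn]]
      rho * hubser + sqrt(1 - rho^2) * stats::rnorm(spec$n_volumes)
    }, numeric(spec$n_volumes))
    colnames(r3) <- roi_names
    roi[[s]] <- r3
  }
  motion <- generate_motion_traces(spec)
  clinical <- generate_clinical_table(spec)
  structure(list(
    node_timeseries = ts,
    motion = motion,
    roi_timeseries = roi,
    clinical = clinical,
    truth = list(precision_em = prec$em, precision_cm = prec$cm,
                 hub = prec$hub, effect_node = spec$effect_node,
                 group = group,
                 roi_coupling_em = spec$roi_coupling_em,
                 roi_coupling_cm = spec$roi_coupling_cm,
                 spike_frames = attr(motion, "spike_frames")),
    spec = spec), class = "synthetic_cohort")
}

#' Generate per-subject motion traces
#'
#' Each trace is a T x 6 matrix (3 translations in mm, 3 rotations in rad):
#' a smooth low-amplitude baseline drift whose framewise displacement stays
#' well below 0.5 mm, plus step displacements ("spikes") at frames drawn
#' Bernoulli(`motion_spike_rate`); spike frames have FD > 0.5 mm by
#' construction and are recorded in the `spike_frames` attribute.
#'
#' @param spec a [cohort_spec()].
#' @param spike_frames optional list (one integer vector per subject) of
#'   planted spike frames, overriding the Bernoulli draw.
#' @return list of T x 6 matrices with attribute `spike_frames`.
#' @export
generate_motion_traces <- function(spec, spike_frames = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_em + spec$n_cm
  n_t <- spec$n_volumes
  set.seed(spec$seed + 1000L)
  traces <- vector("list", n)
  spikes <- vector("list", n)
  tgrid <- seq_len(n_t)
  for (s in seq_len(n)) {
    # smooth drift: slow sinusoids, amplitude chosen so per-frame FD << 0.5 mm
    phase <- stats::runif(6, 0, 2 * pi)
    amp <- stats::runif(6, 0.01, 0.05)      # mm or rad-equivalent scale
    period <- stats::runif(6, 40, 120)      # frames
    tr <- sapply(seq_len(6), function(j) {
      a <- if (j > 3) amp[j] / 50 else amp[j]  # keep rotational arc small
      a * sin(2 * pi * tgrid / period[j] + phase[j])
    })
    sf <- if (!is.null(spike_frames)) as.integer(spike_frames[[s]])
          else which(stats::rbinom(n_t, 1, spec$motion_spike_rate) == 1)
    sf <- sf[sf >= 2]  # FD is defined between frames; frame 1 has no inbound FD
    # decaying displacement transient: the inbound FD of the spike frame is
    # ~0.8 mm, every later transition stays below the 0.5 mm threshold even
    # after the spike frame itself has been censored
    profile <- c(0.8, 0.45, 0.25, 0.1)
    # spikes closer than the transient length would overlap and censor
    # neighbouring frames too; keep the first of any such cluster
    if (length(sf) > 1) {
      keep <- sf[1]
      for (f in sf[-1]) if (f - keep[length(keep)] > length(profile)) keep <- c(keep, f)
      sf <- keep
    }
    sgn <- 1
    for (f in sf) {
      idx <- f:min(n_t, f + length(profile) - 1)
      tr[idx, 1] <- tr[idx, 1] + sgn * profile[seq_along(idx)]
      sgn <- -sgn
    }
    colnames(tr) <- c("trans_x", "trans_y", "trans_z",
                      "rot_x", "rot_y", "rot_z")
    traces[[s]] <- tr
    spikes[[s]] <- sf
  }
  attr(traces, "spike_frames") <- spikes
  traces
}

#' Generate a phenotype table
#'
#' Per-subject demographics and headache characteristics drawn from
#' group-specific distributions chosen to resemble a migraine clinic cohort:
#' CM subjects have 15 or more monthly headache days by construction (the
#' ICHD-3 beta chronic-migraine definition); binary traits use group-specific
#' prevalences typical of EM vs CM clinic samples.
#'
#' @param spec a [cohort_spec()].
#' @param age_mean,age_sd age distribution (years); `age_sd = 0` gives a
#'   degenerate constant-age cohort, useful for null checks.
#' @return data frame with columns `subject`, `group`, `age`, `sex`
#'   (1 = female), `aura`, `allodynia`, `depression`, `anxiety`
#'   (all 0/1), `disease_duration_y`, `headache_days`,
#'   `headache_intensity` (0-10 numeric rating), `acute_drug_days`.
#' @export
generate_clinical_table <- function(spec, age_mean = 40, age_sd = 10) {
  stopifnot(inherits(spec, "cohort_spec"), age_sd >= 0)
  n <- spec$n_em + spec$n_cm
  group <- rep(c("EM", "CM"), c(spec$n_em, spec$n_cm))
  set.seed(spec$seed + 2000L)
  is_cm <- group == "CM"
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  age <- round(clamp(stats::rnorm(n, age_mean, age_sd), 18, 60))
  sex <- stats::rbinom(n, 1, ifelse(is_cm, 0.61, 0.82))
  aura <- stats::rbinom(n, 1, ifelse(is_cm, 0.22, 0.09))
  allodynia <- stats::rbinom(n, 1, ifelse(is_cm, 0.28, 0.18))
  depression <- stats::rbinom(n, 1, ifelse(is_cm, 0.33, 0.14))
  anxiety <- stats::rbinom(n, 1, ifelse(is_cm, 0.50, 0.34))
  duration <- round(clamp(stats::rgamma(n, shape = 1.8, scale = 12 / 1.8), 0.5, 45), 1)
  hd <- ifelse(is_cm,
               clamp(round(stats::rnorm(n, 23, 5.9)), 15, 30),
               clamp(round(stats::rnorm(n, 6.3, 3.6)), 1, 14))
  intensity <- clamp(round(stats::rnorm(n, 7, 1.5)), 1, 10)
  drug <- clamp(stats::rpois(n, ifelse(is_cm, 8, 4)), 0, 30)
  data.frame(subject = sprintf("sub%02d", seq_len(n)),
             group = factor(group, levels = c("EM", "CM")),
             age = age, sex = sex, aura = aura, allodynia = allodynia,
             depression = depression, anxiety = anxiety,
             disease_duration_y = duration, headache_days = hd,
             headache_intensity = intensity, acute_drug_days = drug,
             stringsAsFactors = FALSE)
}

# Disjoint dipole blob maps on an n^3 grid: K blobs on a g^3 cell lattice,
# each with a positive and a negative lobe of equal voxel count so every map
# has exactly zero spatial mean (maps are then pairwise uncorrelated, making
# noiseless ICA recovery exact).
make_blob_maps <- function(k, n_vox) {
  g <- ceiling(k^(1 / 3))
  cell <- floor(n_vox / g)
  if (cell < 2)
    stop(sprintf("cannot place %d disjoint blobs on a %d^3 grid", k, n_vox))
  half <- max(1L, floor(cell / 4))
  maps <- matrix(0, k, n_vox^3)
  idx <- 0L
  for (cz in seq_len(g)) for (cy in seq_len(g)) for (cx in seq_len(g)) {
    if (idx >= k) break
    idx <- idx + 1L
    ctr <- c(cx, cy, cz) * cell - floor(cell / 2)
    vol <- array(0, c(n_vox, n_vox, n_vox))
    rng <- function(c0) max(1L, c0 - half):min(n_vox, c0 + half)
    vol[rng(ctr[1]), rng(ctr[2]), rng(ctr[3])] <- 1
    voxels <- which(vol > 0)
    if (length(voxels) %% 2 == 1) voxels <- voxels[-length(voxels)]
    m <- rep(0, n_vox^3)
    m[voxels[seq_len(length(voxels) / 2)]] <- 1
    m[voxels[(length(voxels) / 2 + 1):length(voxels)]] <- -1
    maps[idx, ] <- m
  }
  maps
}

#' Generate a cohort with 4D volumes
#'
#' Builds per-subject 4D images as `sum_k map_k (outer) timeseries_k` plus
#' white noise, where the K spatial maps are disjoint cubic blobs on an
#' `n_voxels_per_axis`^3 grid. Exercises group ICA on images; the planted maps
#' are stored in `truth$maps` (K x V, V = n_voxels_per_axis^3).
#'
#' @param spec a [cohort_spec()]; `n_voxels_per_axis` must allow
#'   `n_nodes` disjoint blobs.
#' @return a `synthetic_cohort` as in [generate_node_timeseries_cohort()] with
#'   an additional `volumes` element (list of 4D arrays, x-y-z-time) and
#'   `truth$maps`.
#' @export
generate_4d_dataset <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  coh <- generate_node_timeseries_cohort(spec)
  nv <- spec$n_voxels_per_axis
  maps <- make_blob_maps(spec$n_nodes, nv)
  set.seed(spec$seed + 3000L)
  vols <- lapply(coh$node_timeseries, function(x) {
    y <- x %*% maps                                  # T x V
    if (spec$noise_sd > 0)
      y <- y + matrix(stats::rnorm(length(y), sd = spec$noise_sd), nrow(y))
    array(t(y), c(nv, nv, nv, nrow(y)))
  })
  coh$volumes <- vols
  coh$truth$maps <- maps
  coh$truth$grid_dim <- c(nv, nv, nv)
  coh
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  s <- x$spec
  cat(sprintf("synthetic migraine cohort: %d EM + %d CM, T = %d, K = %d\n",
              s$n_em, s$n_cm, s$n_volumes, s$n_nodes))
  if (!is.null(s$effect_node))
    cat(sprintf("planted effect: node %d, effect size %.2f\n",
                s$effect_node, s$effect_size))
  if (!is.null(x$volumes))
    cat(sprintf("4D volumes: %s voxels\n",
                paste(dim(x$volumes[[1]])[1:3], collapse = " x ")))
  invisible(x)
}
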
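#' Table-3-style nested covariate sets
#'
#' The nested adjustment models used for the multivariable analysis of the
#' group effect: demographics first, then aura, then psychiatric comorbidity,
#' then disease burden and medication use.
#'
#' @return list of character vectors (the first is the unadjusted model).
#' @export
default_covariate_sets <- function() {
  list(character(0),
       c("age", "sex", "aura"),
       c("age", "sex", "aura", "allodynia"),
       c("age", "sex", "aura", "depression", "anxiety"),
       c("age", "sex", "aura", "allodynia", "depression", "anxiety"),
       c("age", "sex", "aura", "allodynia", "depression", "anxiety",
         "disease_duration_y"),
       c("age", "sex", "aura", "allodynia", "depression", "anxiety",
         "disease_duration_y", "headache_intensity"),
       c("age", "sex", "aura", "allodynia", "depression", "anxiety",
         "disease_duration_y", "headache_intensity", "acute_drug_days"))
}

#' Pipeline run configuration
#'
#' @param spec a [cohort_spec()] (synthetic mode) or `NULL` when loading a
#'   dataset from disk.
#' @param dataset_dir directory produced by [write_cohort()] to load instead
#'   of generating (overrides `spec` as data source; the manifest's spec is
#'   used for metadata).
#' @param preproc a [preproc_config()].
#' @param network a [network_params()].
#' @param k number of ICA components (4D mode).
#' @param b,alpha,q permutation count, uncorrected level, FDR level.
#' @param covariate_sets list of covariate name vectors
#'   (default [default_covariate_sets()]).
#' @param target_node network node for the seed analysis; default the
#'   FDR-significant node (falling back to the planted hub, then node 1).
#' @param seed integer master seed for all stochastic stages.
#' @param output_dir if non-`NULL`, stage outputs and a JSON manifest are
#'   written here.
#' @param mode `"node"` to start from node time series (the statistical
#'   core), `"4d"` to run the imaging stages (preprocessing + group ICA) on
#'   generated volumes first.
#' @return list of class `run_config`.
#' @export
run_config <- function(spec = cohort_spec(), dataset_dir = NULL,
                       preproc = preproc_config(), network = network_params(),
                       k = NULL, b = 5000, alpha = 0.05, q = 0.05,
                       covariate_sets = default_covariate_sets(),
                       target_node = NULL, seed = 1, output_dir = NULL,
                       mode = c("node", "4d")) {
  mode <- match.arg(mode)
  if (!is.null(dataset_dir) && !dir.exists(dataset_dir))
    stop(sprintf("dataset directory does not exist: %s", dataset_dir))
  structure(list(spec = spec, dataset_dir = dataset_dir, preproc = preproc,
                 network = network, k = k, b = b, alpha = alpha, q = q,
                 covariate_sets = covariate_sets, target_node = target_node,
                 seed = as.integer(seed), output_dir = output_dir,
                 mode = mode), class = "run_config")
}

stage_log <- function(stage, msg, ...) {
  message(sprintf("[%s] %s", stage, sprintf(msg, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order: cohort acquisition (synthetic generation or
#' [load_dataset()]), preprocessing (frame trimming and motion scrubbing; in
#' 4D mode also intensity normalization, band-pass, smoothing and group ICA),
#' per-subject connectome construction, degree-centrality group inference
#' (permutation + FDR and covariate-adjusted linear models), seed-to-network
#' analysis of the three ROIs, and the baseline clinical table. Re-running
#' with an identical configuration reproduces identical numerical outputs.
#'
#' @param config a [run_config()].
#' @return list of class `pipeline_result` with elements `dc`,
#'   `permutation`, `adjusted`, `roi`, `baseline`, `retained_frames`,
#'   `target_node`, `components` (4D mode), `labels` (4D mode), and
#'   `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  spec <- config$spec
  if (!is.null(config$dataset_dir)) {
    stage_log("load", "reading dataset from %s", config$dataset_dir)
    cohort <- load_dataset(config$dataset_dir)
    spec <- cohort$spec
  } else {
    stage_log("simulate", "generating synthetic cohort (seed %d)", spec$seed)
    cohort <- if (config$mode == "4d") generate_4d_dataset(spec)
              else generate_node_timeseries_cohort(spec)
  }
  group <- cohort$truth$group %||% cohort$clinical$group
  n <- length(group)

  components <- NULL; labels <- NULL
  if (config$mode == "4d") {
    if (is.null(cohort$volumes)) stop("4d mode requires volumes")
    k <- config$k %||% spec$n_nodes
    pp <- config$preproc
    vox <- 2
    node_ts <- vector("list", n); retained <- vector("list", n)
    vols <- vector("list", n)
    for (s in seq_len(n)) {
      v <- cohort$volumes[[s]]
      d <- dim(v)
      flat <- t(matrix(v, prod(d[1:3]), d[4]))            # T x V
      ts0 <- trim_and_scrub(flat, cohort$motion[[s]], spec$tr_s, pp)
      flat <- ts0$series
      flat <- bandpass_filter(flat, spec$tr_s, pp$band_low_hz, pp$band_high_hz,
                              pp$filter_order)
      v2 <- array(t(flat), c(d[1:3], nrow(flat)))
      v2 <- spatial_smooth(v2, pp$smoothing_fwhm_mm, vox)
      vols[[s]] <- v2
      retained[[s]] <- ts0$retained
      stage_log("preprocess", "subject %d: %d frames retained", s, nrow(flat))
    }
    components <- concat_and_decompose(vols, k, seed = config$seed)
    stage_log("ica", "decomposed into %d components", k)
    if (!is.null(cohort$truth$maps))
      labels <- classify_components(components, split_rows(cohort$truth$maps))
    node_ts <- lapply(vols, subject_timeseries, components = components)
    roi_ts <- lapply(seq_len(n), function(s)
      cohort$roi_timeseries[[s]][retained[[s]], , drop = FALSE])
  } else {
    pre <- lapply(seq_len(n), function(s)
      trim_and_scrub(cohort$node_timeseries[[s]], cohort$motion[[s]],
                     spec$tr_s, config$preproc))
    node_ts <- lapply(pre, `[[`, "series")
    retained <- lapply(pre, `[[`, "retained")
    roi_ts <- lapply(seq_len(n), function(s)
      cohort$roi_timeseries[[s]][retained[[s]], , drop = FALSE])
    stage_log("preprocess", "%d subjects, %d-%d frames retained", n,
              min(lengths(retained)), max(lengths(retained)))
  }

  dc <- dc_table(node_ts, group, params = config$network)
  stage_log("network", "%d x %d degree-centrality table", nrow(dc),
            sum(grepl("^dc_", names(dc))))
  perm <- permutation_group_test(dc, group, b = config$b,
                                 alpha = config$alpha, q = config$q,
                                 seed = config$seed)
  stage_log("infer", "%d node(s) FDR-significant at q = %.2g",
            sum(perm$rejected), config$q)
  # covariates that happen to be constant in this cohort carry no
  # information and would only make the design singular; drop them per set
  usable <- vapply(cohort$clinical, function(col) length(unique(col)) > 1,
                   TRUE)
  sets <- lapply(config$covariate_sets, function(vars) {
    dropped <- vars[!vars %in% names(usable)[usable]]
    if (length(dropped))
      stage_log("infer", "dropping constant covariate(s): %s",
                paste(dropped, collapse = ", "))
    intersect(vars, names(usable)[usable])
  })
  adjusted <- adjusted_group_effect(dc, group, cohort$clinical, sets)

  target <- config$target_node %||%
    (if (any(perm$rejected)) which(perm$rejected)[1] else NULL) %||%
    cohort$truth$hub %||% 1L
  roi <- seed_network_edges(roi_ts, node_ts, target, group,
                            b = config$b, q = config$q, seed = config$seed)
  stage_log("roi", "seed analysis against node %d", target)
  baseline <- compare_baseline_table(cohort$clinical)

  result <- structure(list(dc = dc, permutation = perm, adjusted = adjusted,
                           roi = roi, baseline = baseline,
                           clinical = cohort$clinical,
                           retained_frames = lengths(retained),
                           target_node = target, components = components,
                           labels = labels, spec = spec,
                           manifest = NULL), class = "pipeline_result")
  if (!is.null(config$output_dir))
    result$manifest <- write_pipeline_outputs(result, config)
  result
}

split_rows <- function(m) {
  out <- lapply(seq_len(nrow(m)), function(i) m[i, ])
  names(out) <- paste0("planted_", seq_len(nrow(m)))
  out
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(strip_config(config), auto_unbox = TRUE,
                              digits = NA), f)
  unname(tools::md5sum(f))
}

strip_config <- function(config) {
  cfg <- unclass(config)
  cfg$spec <- unclass(cfg$spec)
  cfg$preproc <- unclass(cfg$preproc)
  cfg$network <- unclass(cfg$network)
  cfg$output_dir <- NULL
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_pipeline_outputs <- function(result, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$output_dir
  hash <- config_hash(config)
  write_tsv(cbind(result$dc, config_hash = hash),
            file.path(out, "degree_centrality.tsv"))
  perm <- result$permutation
  write_tsv(data.frame(node = seq_along(perm$observed),
                       observed = perm$observed, p = perm$p,
                       p_fdr = perm$p_fdr, significant = perm$rejected,
                       config_hash = hash),
            file.path(out, "permutation_result.tsv"))
  write_tsv(cbind(result$adjusted, config_hash = hash),
            file.path(out, "adjusted_models.tsv"))
  write_tsv(cbind(as.data.frame(result$roi$z), group = result$dc$group,
                  config_hash = hash),
            file.path(out, "roi_z.tsv"))
  rp <- result$roi$contrast
  write_tsv(data.frame(roi = colnames(result$roi$z),
                       observed = rp$observed, p = rp$p, p_fdr = rp$p_fdr,
                       significant = rp$rejected, config_hash = hash),
            file.path(out, "roi_contrast.tsv"))
  write_tsv(cbind(result$baseline, config_hash = hash),
            file.path(out, "baseline_table.tsv"))
  manifest <- list(config = strip_config(config), config_hash = hash,
                   b = config$b, seed = config$seed, alpha = config$alpha,
                   q = config$q, target_node = result$target_node,
                   retained_frames = as.integer(result$retained_frames),
                   r_version = as.character(getRversion()))
  jsonlite::write_json(manifest, file.path(out, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}

#' Write a synthetic cohort to disk
#'
#' External representation of a cohort: per-subject node time series
#' (`subNN_nodes.tsv`), ROI series (`subNN_roi.tsv`), motion traces as
#' 6-column whitespace-delimited text (`subNN_motion.par`), 4D volumes as
#' NIfTI when present (`subNN_bold.nii.gz`), the phenotype table
#' (`phenotype.tsv`) and a JSON manifest recording the generating spec and
#' planted truth.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- length(cohort$node_timeseries)
  spec_out <- unclass(cohort$spec)
  spec_out$roi_coupling_em <- as.list(spec_out$roi_coupling_em)
  spec_out$roi_coupling_cm <- as.list(spec_out$roi_coupling_cm)
  for (s in seq_len(n)) {
    id <- sprintf("sub%02d", s)
    write_tsv(as.data.frame(cohort$node_timeseries[[s]]),
              file.path(dir, paste0(id, "_nodes.tsv")))
    write_tsv(as.data.frame(cohort$roi_timeseries[[s]]),
              file.path(dir, paste0(id, "_roi.tsv")))
    utils::write.table(cohort$motion[[s]],
                       file.path(dir, paste0(id, "_motion.par")),
                       sep = " ", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    if (!is.null(cohort$volumes))
      RNifti::writeNifti(RNifti::asNifti(cohort$volumes[[s]],
                                         pixdim = rep(2, 4)),
                         file.path(dir, paste0(id, "_bold.nii.gz")))
  }
  write_tsv(cohort$clinical, file.path(dir, "phenotype.tsv"))
  truth <- cohort$truth
  manifest <- list(
    spec = spec_out,
    n_subjects = n,
    has_volumes = !is.null(cohort$volumes),
    truth = list(precision_em = truth$precision_em,
                 precision_cm = truth$precision_cm,
                 hub = truth$hub, effect_node = truth$effect_node,
                 group = as.character(truth$group),
                 roi_coupling_em = as.list(truth$roi_coupling_em),
                 roi_coupling_cm = as.list(truth$roi_coupling_cm),
                 spike_frames = truth$spike_frames))
  jsonlite::write_json(manifest, file.path(dir, "cohort_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Load a cohort dataset from disk
#'
#' Reads a directory produced by [write_cohort()] back into a validated
#' in-memory `synthetic_cohort`: subject lists are cross-checked against the
#' phenotype table, frame counts against the manifest, and voxel grids across
#' subjects.
#'
#' @param dir dataset directory.
#' @return a `synthetic_cohort`.
#' @export
load_dataset <- function(dir) {
  if (!dir.exists(dir)) stop(sprintf("dataset directory does not exist: %s", dir))
  mf_path <- file.path(dir, "cohort_manifest.json")
  if (!file.exists(mf_path)) stop("missing cohort_manifest.json")
  mf <- jsonlite::read_json(mf_path, simplifyVector = TRUE)
  spec_l <- mf$spec
  en <- spec_l$effect_node
  if (!length(en) || (is.atomic(en) && is.na(en[1]))) en <- NULL
  spec_l$effect_node <- en
  spec <- cohort_spec(n_em = spec_l$n_em, n_cm = spec_l$n_cm,
                      n_nodes = spec_l$n_nodes, n_volumes = spec_l$n_volumes,
                      tr_s = spec_l$tr_s,
                      n_voxels_per_axis = spec_l$n_voxels_per_axis,
                      effect_node = spec_l$effect_node,
                      effect_size = spec_l$effect_size,
                      noise_sd = spec_l$noise_sd,
                      motion_spike_rate = spec_l$motion_spike_rate,
                      ar_coef = spec_l$ar_coef,
                      hub_partial = spec_l$hub_partial,
                      pair_partial = spec_l$pair_partial,
                      roi_coupling_em = unlist(spec_l$roi_coupling_em),
                      roi_coupling_cm = unlist(spec_l$roi_coupling_cm),
                      seed = spec_l$seed)
  phen_path <- file.path(dir, "phenotype.tsv")
  if (!file.exists(phen_path)) stop("missing phenotype.tsv")
  clinical <- utils::read.delim(phen_path, stringsAsFactors = FALSE)
  if (!"group" %in% names(clinical))
    stop("phenotype table is missing the group column")
  clinical$group <- factor(clinical$group, levels = c("EM", "CM"))
  n <- mf$n_subjects
  if (nrow(clinical) != n)
    stop(sprintf("phenotype lists %d subjects but manifest records %d",
                 nrow(clinical), n))
  ids <- sprintf("sub%02d", seq_len(n))
  node_files <- file.path(dir, paste0(ids, "_nodes.tsv"))
  absent <- ids[!file.exists(node_files)]
  if (length(absent))
    stop(sprintf("subjects in phenotype but without node series: %s",
                 paste(absent, collapse = ", ")))
  read_mat <- function(f) as.matrix(utils::read.delim(f))
  node_ts <- lapply(node_files, read_mat)
  bad_t <- which(vapply(node_ts, nrow, 1L) != spec$n_volumes)
  if (length(bad_t))
    stop(sprintf("wrong frame count (expected %d) for: %s", spec$n_volumes,
                 paste(ids[bad_t], collapse = ", ")))
  roi_ts <- lapply(file.path(dir, paste0(ids, "_roi.tsv")), read_mat)
  motion <- lapply(file.path(dir, paste0(ids, "_motion.par")), function(f)
    as.matrix(utils::read.table(f)))
  volumes <- NULL
  if (isTRUE(mf$has_volumes)) {
    vfiles <- file.path(dir, paste0(ids, "_bold.nii.gz"))
    volumes <- lapply(vfiles, function(f) {
      v <- RNifti::readNifti(f)
      array(as.numeric(v), dim(v))
    })
    dims <- vapply(volumes, function(v) paste(dim(v)[1:3], collapse = "x"), "")
    if (length(unique(dims)) != 1)
      stop(sprintf("inconsistent voxel grids: %s",
                   paste(unique(dims), collapse = " vs ")))
  }
  truth <- mf$truth
  structure(list(
    node_timeseries = node_ts, motion = motion, roi_timeseries = roi_ts,
    volumes = volumes, clinical = clinical,
    truth = list(precision_em = matrix(unlist(truth$precision_em),
                                       spec$n_nodes, spec$n_nodes),
                 precision_cm = matrix(unlist(truth$precision_cm),
                                       spec$n_nodes, spec$n_nodes),
                 hub = truth$hub, effect_node = truth$effect_node,
                 group = factor(truth$group, levels = c("EM", "CM")),
                 roi_coupling_em = unlist(truth$roi_coupling_em),
                 roi_coupling_cm = unlist(truth$roi_coupling_cm),
                 spike_frames = truth$spike_frames),
    spec = spec), class = "synthetic_cohort")
}
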
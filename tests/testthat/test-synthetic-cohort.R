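test_that("cohort spec validates its invariants", {
  expect_error(cohort_spec(n_em = 1), "n_em")
  expect_error(cohort_spec(motion_spike_rate = 1.5), "motion_spike_rate")
  expect_error(cohort_spec(tr_s = 0), "tr_s")
  expect_error(cohort_spec(effect_node = 9, n_nodes = 7), "effect_node")
})

test_that("non-positive-definite planted precision is rejected with a diagnostic", {
  spec <- cohort_spec(hub_partial = 0.45, pair_partial = 0.45,
                      effect_node = 1, effect_size = 1)
  expect_error(planted_precision(spec), "positive definite")
})

test_that("planted precisions are symmetric positive definite and carry the effect", {
  spec <- cohort_spec(effect_node = 3, effect_size = 0.5)
  pr <- planted_precision(spec)
  for (p in list(pr$em, pr$cm)) {
    expect_identical(p, t(p))
    expect_gt(min(eigen(p, symmetric = TRUE)$values), 0)
  }
  others <- setdiff(1:7, 3)
  expect_equal(pr$cm[3, others], 1.5 * pr$em[3, others])
  expect_equal(pr$cm[others, others], pr$em[others, others])
})

test_that("generation is a pure function of (spec, seed)", {
  spec <- tiny_spec(motion_spike_rate = 0.1)
  a <- generate_node_timeseries_cohort(spec)
  b <- generate_node_timeseries_cohort(spec)
  expect_identical(a$node_timeseries, b$node_timeseries)
  expect_identical(a$motion, b$motion)
  expect_identical(a$roi_timeseries, b$roi_timeseries)
  expect_identical(a$clinical, b$clinical)
  c2 <- generate_node_timeseries_cohort(tiny_spec(motion_spike_rate = 0.1, seed = 43))
  expect_false(identical(a$node_timeseries, c2$node_timeseries))
})

test_that("sample partial correlation converges to the planted value with T", {
  mads <- vapply(c(100, 1000, 10000), function(n_t) {
    spec <- cohort_spec(n_em = 2, n_cm = 2, n_nodes = 5, n_volumes = n_t,
                        effect_node = NULL, seed = 5)
    coh <- generate_node_timeseries_cohort(spec)
    pr <- planted_precision(spec)
    planted <- -pr$em / sqrt(diag(pr$em) %o% diag(pr$em)); diag(planted) <- 0
    est <- partial_correlation_l2(coh$node_timeseries[[1]], ridge_lambda = 0)
    mean(abs(est - planted)[upper.tri(planted)])
  }, 1)
  expect_true(all(diff(mads) < 0))
  expect_lt(mads[3], 0.02)
})

test_that("null cohorts show only sampling-level group differences in partial correlation", {
  spec <- cohort_spec(n_em = 10, n_cm = 10, n_nodes = 4, n_volumes = 5000,
                      effect_size = 0, seed = 8)
  coh <- generate_node_timeseries_cohort(spec)
  rs <- lapply(coh$node_timeseries, partial_correlation_l2, ridge_lambda = 0)
  g <- coh$truth$group
  gd <- Reduce(`+`, rs[g == "CM"]) / sum(g == "CM") -
        Reduce(`+`, rs[g == "EM"]) / sum(g == "EM")
  expect_lt(max(abs(gd)), 0.02)
})

test_that("motion traces plant spikes where requested and bookkeeping matches", {
  spec <- tiny_spec(n_volumes = 100, tr_s = 3)
  tr <- generate_motion_traces(spec, spike_frames = rep(list(c(10, 42)), 10))
  fd <- framewise_displacement(tr[[1]])
  expect_true(all(fd[c(9, 41)] > 0.5))
  expect_true(all(fd[-c(9, 41)] < 0.5))
  ts <- trim_and_scrub(matrix(rnorm(400), 100, 4), tr[[1]], tr_s = 3,
                       preproc_config(discard_initial_s = 0))
  expect_identical(setdiff(seq_len(100), ts$retained), c(10L, 42L))

  spec2 <- tiny_spec(n_volumes = 100, motion_spike_rate = 0.1)
  tr2 <- generate_motion_traces(spec2)
  spikes <- attr(tr2, "spike_frames")
  for (s in seq_along(tr2)) {
    fd <- framewise_displacement(tr2[[s]])
    expect_identical(which(fd > 0.5) + 1L, spikes[[s]])
  }
})

test_that("spike-free traces stay below the scrubbing threshold", {
  tr <- generate_motion_traces(tiny_spec(motion_spike_rate = 0))
  for (m in tr) expect_lt(max(framewise_displacement(m)), 0.5)
})

test_that("clinical tables respect the chronic-migraine definition and reproduce", {
  spec <- cohort_spec(seed = 3)
  cl <- generate_clinical_table(spec)
  expect_true(all(cl$headache_days[cl$group == "CM"] >= 15))
  expect_true(all(cl$headache_days[cl$group == "EM"] < 15))
  expect_identical(cl, generate_clinical_table(spec))
  const <- generate_clinical_table(spec, age_sd = 0)
  expect_equal(mann_whitney_u(const$age[const$group == "EM"],
                              const$age[const$group == "CM"])$p, 1)
})

test_that("4D volumes are planted maps times series plus noise", {
  spec <- cohort_spec(n_em = 2, n_cm = 2, n_nodes = 2, n_volumes = 20,
                      n_voxels_per_axis = 10, noise_sd = 0, seed = 2)
  coh <- generate_4d_dataset(spec)
  expect_equal(dim(coh$volumes[[1]]), c(10, 10, 10, 20))
  # disjoint supports, exactly zero spatial mean per map
  expect_equal(max(colSums(coh$truth$maps != 0)), 1)
  expect_equal(rowSums(coh$truth$maps), rep(0, 2))
  # noiseless volumes reconstruct exactly from truth
  rec <- coh$node_timeseries[[1]] %*% coh$truth$maps
  expect_equal(as.numeric(coh$volumes[[1]]), as.numeric(t(rec)), tolerance = 1e-12)
  expect_error(generate_4d_dataset(cohort_spec(n_em = 2, n_cm = 2,
                                               n_nodes = 30, n_volumes = 8,
                                               n_voxels_per_axis = 6,
                                               hub_partial = 0.02,
                                               pair_partial = 0.05)),
               "blobs")
})
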
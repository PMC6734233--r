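make_ica_cohort <- function(k, noise_sd, n_vox = 12, seed = 1) {
  generate_4d_dataset(cohort_spec(n_em = 2, n_cm = 2, n_nodes = k,
                                  n_volumes = 60, n_voxels_per_axis = n_vox,
                                  noise_sd = noise_sd, seed = seed))
}

test_that("noiseless planted maps are recovered exactly up to sign and order", {
  coh <- make_ica_cohort(k = 2, noise_sd = 0)
  comps <- concat_and_decompose(coh$volumes, k = 2, seed = 1)
  m <- match_components(comps$spatial_maps, coh$truth$maps)
  expect_equal(m$correlations, c(1, 1), tolerance = 1e-6)
})

test_that("maps survive moderate noise with matched correlation above 0.9", {
  coh <- make_ica_cohort(k = 4, noise_sd = 0.5, seed = 3)
  comps <- concat_and_decompose(coh$volumes, k = 4, seed = 1)
  m <- match_components(comps$spatial_maps, coh$truth$maps)
  expect_true(all(m$correlations > 0.9))
})

test_that("decomposition is deterministic given the seed", {
  coh <- make_ica_cohort(k = 3, noise_sd = 0.3, seed = 5)
  a <- concat_and_decompose(coh$volumes, k = 3, seed = 9)
  b <- concat_and_decompose(coh$volumes, k = 3, seed = 9)
  expect_identical(a$spatial_maps, b$spatial_maps)
})

test_that("k beyond the data rank is refused", {
  flat <- matrix(rnorm(40), 10, 4) %*% matrix(rnorm(8 * 4), 4, 8)  # rank 4
  expect_error(concat_and_decompose(list(flat, flat), k = 6), "rank")
})

test_that("subject time series are exact for planted disjoint maps", {
  coh <- make_ica_cohort(k = 3, noise_sd = 0, seed = 2)
  comps <- concat_and_decompose(coh$volumes, k = 3, seed = 1)
  ts <- subject_timeseries(coh$volumes[[1]], comps)
  cmat <- abs(cor(ts, coh$node_timeseries[[1]]))
  # each planted series is recovered by exactly one component with |r| = 1
  expect_equal(sort(unname(apply(cmat, 2, max))), rep(1, 3), tolerance = 1e-8)

  # K = 1, constant map: series proportional to the global mean signal
  set.seed(99)
  v <- array(rnorm(6^3 * 15), c(6, 6, 6, 15))
  const <- structure(list(spatial_maps = matrix(1, 1, 6^3),
                          z_maps = matrix(0, 1, 6^3),
                          order = 1L, grid_dim = c(6, 6, 6), mask = NULL),
                     class = "group_components")
  ts1 <- subject_timeseries(v, const)
  gm <- apply(v, 4, mean)
  expect_equal(cor(ts1[, 1], gm), 1, tolerance = 1e-12)
})

test_that("dual regression on noisy orthogonal maps is unbiased", {
  set.seed(7)
  v_len <- 500
  maps <- rbind(c(rep(1, 250), rep(0, 250)), c(rep(0, 250), rep(1, 250)))
  planted <- matrix(rnorm(80), 40, 2)
  err <- replicate(30, {
    y <- planted %*% maps + matrix(rnorm(40 * v_len, sd = 1), 40)
    comps <- structure(list(spatial_maps = maps, z_maps = maps,
                            order = 1:2, grid_dim = NULL, mask = NULL),
                       class = "group_components")
    colMeans(subject_timeseries(y, comps) - planted)
  })
  expect_lt(max(abs(rowMeans(err))), 0.02)
})

test_that("component classification applies the 0.25 correlation rule", {
  set.seed(11)
  v <- 400
  tpl <- list(net_a = c(rep(1, 100), rep(0, 300)),
              net_b = c(rep(0, 100), rep(1, 100), rep(0, 200)))
  comps <- structure(list(spatial_maps = rbind(tpl$net_a, rnorm(v)),
                          z_maps = NULL, order = 1:2, grid_dim = NULL,
                          mask = NULL), class = "group_components")
  lab <- classify_components(comps, tpl)
  expect_identical(lab$label, c("signal", "noise"))
  expect_equal(lab$r[1], 1)
  expect_identical(lab$template[1], "net_a")
  expect_lt(lab$r[2], 0.25)
  expect_error(classify_components(comps, list()), "empty")
})

test_that("classification is monotone in the threshold", {
  set.seed(13)
  v <- 300
  tpl <- list(t1 = rnorm(v), t2 = rnorm(v))
  maps <- rbind(tpl$t1 + rnorm(v, sd = 0.5), rnorm(v), tpl$t2 + rnorm(v, sd = 2))
  comps <- structure(list(spatial_maps = maps, z_maps = NULL, order = 1:3,
                          grid_dim = NULL, mask = NULL),
                     class = "group_components")
  thresholds <- seq(0.05, 0.95, by = 0.1)
  n_noise <- vapply(thresholds, function(th)
    sum(classify_components(comps, tpl, threshold = th)$label == "noise"), 1L)
  expect_true(all(diff(n_noise) >= 0))
})

test_that("a 7-signal / 2-noise cohort yields seven signal labels", {
  set.seed(17)
  v <- 500
  tpl <- lapply(1:7, function(i) {
    m <- rep(0, v); m[((i - 1) * 70 + 1):(i * 70)] <- 1; m
  })
  names(tpl) <- paste0("network_", 1:7)
  maps <- rbind(do.call(rbind, tpl) + matrix(rnorm(7 * v, sd = 0.1), 7),
                matrix(rnorm(2 * v), 2))
  comps <- structure(list(spatial_maps = maps, z_maps = NULL, order = 1:9,
                          grid_dim = NULL, mask = NULL),
                     class = "group_components")
  lab <- classify_components(comps, tpl)
  expect_equal(sum(lab$label == "signal"), 7)
  expect_identical(lab$label[8:9], c("noise", "noise"))
})

test_that("sub-region ranking orders regions by mean z with alphabetical ties", {
  z <- c(rep(3.7, 10), rep(2.4, 10), rep(0, 30))
  masks <- list(thalamus = 11:20, acc = 1:10)
  imp <- subregion_importance(z, masks)
  expect_identical(imp$region, c("acc", "thalamus"))
  expect_equal(imp$mean_z, c(3.7, 2.4), tolerance = 1e-12)

  tie <- subregion_importance(z, list(beta = 1:10, alpha = 1:10))
  expect_identical(tie$region, c("alpha", "beta"))

  expect_error(subregion_importance(z, list(pons = integer(0))), "pons")
})
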
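test_that("sampled permutation p-values agree with exhaustive enumeration", {
  set.seed(41)
  for (rep in 1:5) {
    values <- rnorm(8, mean = rep(c(0, 0.8), each = 4))
    group <- factor(rep(c("EM", "CM"), each = 4), levels = c("EM", "CM"))
    exact <- permutation_group_test(values, group, exact = TRUE)
    oracle <- oracle_exact_perm_p(values, 4)
    expect_equal(exact$p, oracle, tolerance = 1e-12)
    expect_equal(exact$b, choose(8, 4))
    sampled <- permutation_group_test(values, group, b = 20000, seed = rep)
    se <- sqrt(oracle * (1 - oracle) / 20000)
    expect_lt(abs(sampled$p - oracle), 2 * se + 2 / 20001)
  }
})

test_that("an extreme observed statistic attains the add-one lower bound", {
  dc <- c(rep(0, 10), rep(100, 5))
  group <- factor(rep(c("EM", "CM"), c(10, 5)), levels = c("EM", "CM"))
  res <- permutation_group_test(dc, group, b = 500, seed = 1)
  expect_equal(res$p, 1 / 501)
})

test_that("permutation test validates its inputs and is seed-reproducible", {
  dc <- matrix(rnorm(40), 20, 2)
  g <- factor(rep(c("EM", "CM"), each = 10))
  expect_error(permutation_group_test(dc, rep("EM", 20)), "two")
  a <- permutation_group_test(dc, g, b = 200, seed = 5)
  b <- permutation_group_test(dc, g, b = 200, seed = 5)
  expect_identical(a$p, b$p)
})

test_that("Benjamini-Hochberg adjustment reproduces the worked example", {
  p <- c(0.0066, 0.35, 0.41, 0.52, 0.63, 0.74, 0.30)
  res <- bh_fdr(p)
  expect_equal(res$adjusted[1], 0.0462)
  expect_true(res$rejected[1])
  expect_false(any(res$rejected[-1]))

  expect_equal(bh_fdr(rep(0.2, 5))$adjusted, rep(0.2, 5))
  expect_equal(bh_fdr(0.03)$adjusted, 0.03)
  expect_error(bh_fdr(numeric(0)), "empty")
})

test_that("FDR never rejects more than unadjusted thresholding", {
  set.seed(43)
  for (i in 1:20) {
    p <- runif(15)^runif(1, 0.5, 2)
    res <- bh_fdr(p, q = 0.05)
    expect_lte(sum(res$rejected), sum(p <= 0.05))
    expect_true(all(res$adjusted >= p))
  }
})

test_that("covariate adjustment leaves an independent group effect intact", {
  set.seed(44)
  n <- 120
  group <- factor(rep(c("EM", "CM"), each = n / 2), levels = c("EM", "CM"))
  covs <- data.frame(age = rnorm(n, 40, 10), sex = rbinom(n, 1, 0.5))
  dc <- 0.5 * (group == "CM") + rnorm(n)
  res <- adjusted_group_effect(dc, group, covs,
                               list(character(0), c("age", "sex")))
  expect_equal(res$p[1], res$p[2], tolerance = 0.05)
  expect_lt(res$p[2], 0.05)
})

test_that("a confounder fully explaining the group difference removes it", {
  set.seed(45)
  n <- 200
  confounder <- rnorm(n)
  group <- factor(ifelse(confounder + rnorm(n, sd = 0.3) > 0, "CM", "EM"),
                  levels = c("EM", "CM"))
  dc <- confounder + rnorm(n, sd = 0.5)  # group affects dc only via confounder
  covs <- data.frame(conf = confounder)
  res <- adjusted_group_effect(dc, group, covs,
                               list(character(0), "conf"))
  expect_lt(res$p[1], 0.001)   # unadjusted: strong spurious effect
  expect_gt(res$p[2], 0.05)    # adjusted: gone
})

test_that("degenerate designs are refused with diagnostics", {
  n <- 30
  g <- factor(rep("EM", n))
  expect_error(adjusted_group_effect(rnorm(n), g, data.frame(x = rnorm(n)),
                                     list("x")), "constant")
  g2 <- factor(rep(c("EM", "CM"), each = n / 2))
  covs <- data.frame(a = rnorm(n))
  covs$b <- covs$a
  expect_error(adjusted_group_effect(rnorm(n), g2, covs, list(c("a", "b"))),
               "collinear")
  expect_error(adjusted_group_effect(rnorm(n), g2, covs, list("zzz")),
               "unknown covariate")
})

test_that("Freedman-Lane permutation p agrees with the parametric p on clean data", {
  set.seed(46)
  n <- 80
  group <- factor(rep(c("EM", "CM"), each = n / 2), levels = c("EM", "CM"))
  covs <- data.frame(age = rnorm(n))
  dc <- 0.6 * (group == "CM") + 0.2 * covs$age + rnorm(n)
  par <- adjusted_group_effect(dc, group, covs, list("age"))
  fl <- adjusted_group_effect(dc, group, covs, list("age"),
                              method = "freedman_lane", b = 2000, seed = 2)
  expect_lt(abs(par$p - fl$p), 0.02)
})

test_that("clinical correlation reproduces the t-distribution formula", {
  x <- rnorm(20)
  expect_equal(correlate_clinical(x, x)$r, 1)
  # consistency with a printed (r, p) pair at n = 62
  set.seed(47)
  a <- rnorm(62)
  v <- scale(residuals(lm(rnorm(62) ~ a)))[, 1]  # exactly uncorrelated with a
  b <- 0.0444 * scale(a)[, 1] + sqrt(1 - 0.0444^2) * v
  res <- correlate_clinical(b, a)
  expect_equal(res$r, 0.0444, tolerance = 1e-6)
  expect_equal(res$p, 0.7319, tolerance = 1e-3)
  expect_error(correlate_clinical(rep(1, 10), rnorm(10)), "variance")
})

test_that("null clinical correlations have uniform p-values", {
  set.seed(48)
  ps <- replicate(400, correlate_clinical(rnorm(62), rnorm(62))$p)
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("interaction analysis detects a planted crossover and nothing else", {
  set.seed(49)
  n <- 200
  group <- factor(rep(c("EM", "CM"), each = n / 2), levels = c("EM", "CM"))
  mod <- rbinom(n, 1, 0.5)
  # pure crossover interaction, no main effects
  dc <- ifelse((group == "CM") == (mod == 1), 1, -1) + rnorm(n, sd = 0.8)
  expect_lt(interaction_effect(dc, group, mod), 0.01)

  rate <- mean(replicate(200, {
    dc0 <- rnorm(n) + 0.3 * (group == "CM") + 0.2 * mod
    interaction_effect(dc0, group, mod) < 0.05
  }))
  expect_lt(abs(rate - 0.05), 0.04)

  expect_error(interaction_effect(rnorm(n), group, rep(1, n)), "constant")
  expect_error(interaction_effect(rnorm(4), factor(c("EM", "EM", "CM", "CM")),
                                  c(1, 1, 0, 0)), "empty cell")
})
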
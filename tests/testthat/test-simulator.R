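test_that("ICC <-> variance conversion matches the logistic-scale definition", {
  expect_equal(icc_to_sigma2(0), 0)
  expect_equal(icc_to_sigma2(0.5), pi^2 / 3)
  expect_equal(icc_to_sigma2(0.1), pi^2 / 27)   # 0.36554
  for (r in c(0.001, 0.01, 0.05, 0.1, 0.6))
    expect_equal(sigma2_to_icc(icc_to_sigma2(r)), r)
  expect_error(icc_to_sigma2(1), "icc")
  expect_error(sigma2_to_icc(-1), "non-negative")
})

test_that("cluster sizes have the requested mean and CV and minimum 2", {
  expect_equal(draw_cluster_sizes(8, 10, 0), rep(10L, 8))
  set.seed(1)
  m <- draw_cluster_sizes(1e5, 50, 0.8)
  expect_true(min(m) >= 2)
  expect_lt(abs(mean(m) / 50 - 1), 0.01)
  expect_lt(abs(sd(m) / mean(m) / 0.8 - 1), 0.02)
  # negative-binomial parameterisation requires s^2 > mean - 2
  expect_error(draw_cluster_sizes(8, 10, 0.2), "mean_size - 2")
})

test_that("cluster effects have mean zero, the target variance, and the right shape", {
  for (dist in c("normal", "gamma", "uniform"))
    expect_equal(draw_cluster_effects(5, dist, 0), rep(0, 5))
  set.seed(2)
  for (dist in c("normal", "gamma", "uniform")) {
    s2 <- 0.37
    u <- draw_cluster_effects(1e6, dist, s2)
    mc_se_mean <- sqrt(s2 / 1e6)
    expect_lt(abs(mean(u)), 3 * mc_se_mean)
    expect_lt(abs(var(u) / s2 - 1), 0.01)
  }
  u <- draw_cluster_effects(1e6, "gamma", 1)
  skew <- mean((u - mean(u))^3) / sd(u)^3
  expect_lt(abs(skew - sqrt(2)), 0.02)
  u <- draw_cluster_effects(1e5, "uniform", 0.5)
  expect_true(all(abs(u) <= sqrt(3 * 0.5)))
  expect_error(draw_cluster_effects(5, "cauchy", 1), "should be one of")
})

test_that("solved odds ratios span the published bracket and are monotone", {
  g <- scenario_grid("solve")
  expect_true(all(g$or > 1.05 & g$or < 12.2))
  # bracket endpoints within 5% of the printed 1.12 and 11.49
  expect_lt(abs(min(g$or) / 1.12 - 1), 0.05)
  expect_lt(abs(max(g$or) / 11.49 - 1), 0.05)
  # power is increasing in the number of clusters, so OR decreases
  for (mbar in c(10, 1000)) {
    ors <- vapply(c(8, 12, 20, 30), function(n)
      solve_effect_size(n, mbar, 0.5, 0.1, 0.05), numeric(1))
    expect_true(all(diff(ors) < 0))
  }
  expect_error(solve_effect_size(4, 3, 0, 0.1, 0.1), "target power")
})

test_that("generated trials follow the binomial data-generating model", {
  scn <- scenario(8, 50, 0, 0.3, 0.05, effect = 2)
  set.seed(3)
  d1 <- generate_trial(scn)
  set.seed(3)
  d2 <- generate_trial(scn)
  expect_identical(d1, d2)                      # determinism under a seed
  expect_silent(validate_trial_dataset(d1))
  expect_equal(sum(d1$arm), 4)
  # no clustering, no effect: pooled proportion approaches the prevalence
  scn0 <- scenario(20, 5e4, 0, 0.3, 0)
  set.seed(4)
  d <- generate_trial(scn0)
  expect_lt(abs(sum(d$events) / sum(d$size) - 0.3), 0.005)
})

test_that("cluster log odds variance matches the Taylor expansion", {
  # Var(log odds_j) ~ sigma_b2 + E[1/(p(1-p)m)] for large clusters
  scn <- scenario(30, 1000, 0, 0.3, 0.1)
  set.seed(5)
  sim <- crtsmall:::generate_scenario_matrix(scn, 2000)
  s <- log((sim$Y + 0.5) / (sim$M - sim$Y + 0.5))
  p <- plogis(qlogis(0.3) + draw_cluster_effects(2e5, "normal", scn$sigma_b2))
  expected <- scn$sigma_b2 + mean(1 / (p * (1 - p) * 1000))
  expect_lt(abs(var(as.vector(s)) / expected - 1), 0.05)
})

test_that("the factorial grid has the published cell counts", {
  g <- scenario_grid("both")
  expect_equal(nrow(g), 1728)
  expect_equal(sum(g$effect_status == "null"), 864)
  expect_equal(anyDuplicated(g$scenario_id), 0)
  eff <- g[g$effect_status == "effect", ]
  expect_equal(nrow(eff[eff$mean_size == 10 &
                        eff$control_prevalence == 0.1, ]), 144)
  nul <- g[g$effect_status == "null", ]
  expect_equal(nrow(nul[nul$cv_size == 0.5, ]), 288)
  expect_equal(nrow(nul[nul$n_clusters == 8 & nul$mean_size == 10, ]), 72)
  # combinatorial product 4 x 3 x 3 x 2 x 4 x 3 per effect status
  expect_equal(nrow(nul), 4 * 3 * 3 * 2 * 4 * 3)
})

test_that("derived per-scenario seeds are valid 32-bit integers", {
  idx <- crtsmall:::seed_index(scenario_grid("null")$scenario_id)
  seeds <- crtsmall:::derive_seed(1, idx)
  expect_true(all(seeds == as.integer(seeds)))
  expect_true(all(seeds >= 0 & seeds < 2^31))
  expect_identical(crtsmall:::derive_seed(1, idx), seeds)
})
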
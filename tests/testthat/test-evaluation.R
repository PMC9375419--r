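test_that("conditional-to-marginal conversion follows the attenuation formula", {
  expect_equal(marginal_truth(0.7, 0), 0.7)
  expect_equal(marginal_truth(1, 1), 0.86205, tolerance = 1e-4)
  s2 <- seq(0, 3, by = 0.5)
  expect_true(all(diff(marginal_truth(1, s2)) < 0))
  expect_equal(marginal_truth(-1, 1), -marginal_truth(1, 1))
})

test_that("uniform p-values give 5% rejection under the null", {
  set.seed(51)
  R <- 20000
  res <- data.frame(estimate = rnorm(R), se = 1, p = runif(R),
                    ci_low = -1, ci_high = 1, converged = TRUE)
  s <- summarise_performance(res, 0)
  expect_lt(abs(s$type_one_error_pct - 5), 3 * 100 * sqrt(0.05 * 0.95 / R))
  expect_true(is.na(s$power_pct))
})

test_that("performance measures match a hand-computed table", {
  est <- c(0.2, 0.5, 0.4, 0.9, 0.6, 0.3, 0.7, 0.55, 0.45, 0.8)
  se <- c(0.2, 0.25, 0.22, 0.3, 0.24, 0.21, 0.26, 0.23, 0.2, 0.28)
  p <- c(0.30, 0.04, 0.10, 0.01, 0.03, 0.20, 0.02, 0.06, 0.12, 0.015)
  lo <- est - 0.5; hi <- est + 0.5
  conv <- c(rep(TRUE, 9), FALSE)
  res <- data.frame(estimate = est, se = se, p = p, ci_low = lo,
                    ci_high = hi, converged = conv)
  truth <- 0.5
  s <- summarise_performance(res, truth)
  k <- conv
  expect_equal(s$n_converged, 9)
  expect_equal(s$standardised_bias_pct,
               100 * (mean(est[k]) - truth) / sd(est[k]))
  expect_equal(s$relative_se_bias_pct, 100 * (mean(se[k]) / sd(est[k]) - 1))
  expect_equal(s$power_pct, 100 * mean(p[k] < 0.05))
  expect_equal(s$coverage_pct, 100 * mean(lo[k] <= truth & truth <= hi[k]))
  expect_true(is.na(s$type_one_error_pct))
})

test_that("type-one error classification uses the 3.6/6.4 band", {
  mk <- function(nrej, R = 1000) {
    data.frame(estimate = 0, se = 1,
               p = c(rep(0.01, nrej), rep(0.5, R - nrej)),
               ci_low = -1, ci_high = 1, converged = TRUE)
  }
  expect_equal(summarise_performance(mk(20), 0)$classification,
               "conservative")
  expect_equal(summarise_performance(mk(50), 0)$classification, "nominal")
  expect_equal(summarise_performance(mk(80), 0)$classification, "inflated")
})

test_that("degenerate repetition sets are flagged, not crashed", {
  res <- data.frame(estimate = 1, se = 1, p = 0.5, ci_low = 0, ci_high = 2,
                    converged = FALSE)[rep(1, 5), ]
  s <- summarise_performance(res, 1)
  expect_equal(s$n_converged, 0)
  expect_true(is.na(s$standardised_bias_pct))
})

test_that("the engine is deterministic and worker-invariant", {
  g <- scenario_grid("null")
  sub <- g[g$n_clusters == 8 & g$mean_size == 10 & g$cv_size == 0 &
           g$icc == 0.05, ]
  r1 <- run_grid(sub, c("CL-UNW", "FG.I.DF_CP"), reps = 50, master_seed = 9)
  r2 <- run_grid(sub, c("CL-UNW", "FG.I.DF_CP"), reps = 50, master_seed = 9)
  expect_identical(r1, r2)
  r4 <- run_grid(sub, c("CL-UNW", "FG.I.DF_CP"), reps = 50, master_seed = 9,
                 workers = 2)
  expect_equal(r4, r2)
  r3 <- run_grid(sub, c("CL-UNW", "FG.I.DF_CP"), reps = 50, master_seed = 10)
  expect_false(identical(r3$type_one_error_pct, r2$type_one_error_pct))
})

test_that("fast engine paths equal the per-dataset reference fits", {
  meth <- c("CL-UNW", "CL-W", "UNC.I.DF_CP", "KC.I.DF_CP", "FG.I.DF_CP",
            "REPL.DF_CP")
  scn <- scenario(12, 20, 0.5, 0.3, 0.05, effect = 2)
  set.seed(52)
  fast <- crtsmall:::simulate_scenario_results(scn, meth, 30)
  set.seed(52)
  sim <- crtsmall:::generate_scenario_matrix(scn, 30)
  ids <- sprintf("c%02d", seq_len(nrow(sim$Y)))
  ref <- lapply(seq_len(ncol(sim$Y)), function(r)
    analyse_trial(trial_dataset(ids, sim$arm, sim$Y[, r], sim$M[, r]), meth))
  for (mm in meth) {
    want <- do.call(rbind, lapply(ref, function(x)
      x[x$method == mm, c("estimate", "se", "p", "converged")]))
    ok <- want$converged & fast[[mm]]$converged
    expect_equal(fast[[mm]]$converged, want$converged)
    expect_equal(fast[[mm]]$estimate[ok], want$estimate[ok],
                 tolerance = 1e-8)
    expect_equal(fast[[mm]]$se[ok], want$se[ok], tolerance = 1e-8)
    expect_equal(fast[[mm]]$p[ok], want$p[ok], tolerance = 1e-8)
  }
})

test_that("one repetition with two methods reuses the same dataset", {
  g <- scenario_grid("null")
  sub <- g[g$n_clusters == 8 & g$mean_size == 50 & g$cv_size == 0 &
           g$icc == 0.001 & g$effect_distribution == "normal" &
           g$control_prevalence == 0.3, ]
  r <- run_grid(sub, c("CL-UNW", "CL-W"), reps = 1, master_seed = 3)
  expect_equal(nrow(r), 2)
  # equal cluster sizes: weighted and unweighted estimates coincide, which
  # can only happen when both methods saw the identical dataset
  expect_equal(r$n_converged, c(1, 1))
})

test_that("unknown method labels fail before any computation", {
  g <- scenario_grid("null")[1, ]
  expect_error(run_grid(g, "CL-XX", reps = 1), "unknown method")
  expect_error(run_grid(g, "CL-UNW", reps = 0), "reps")
  expect_error(analyse_trial(toy_trial(), "nope"), "valid labels")
})

test_that("benchmark null scenarios give calibrated rejection rates", {
  # one moderate design cell, 1000 repetitions: CL-UNW and REPL inside the
  # 95% Monte-Carlo band around 5%, FG GEE not inflated
  g <- scenario_grid("null")
  cl_cell <- g[g$n_clusters == 30 & g$mean_size == 50 & g$cv_size == 0 &
               g$control_prevalence == 0.3 & g$icc == 0.05 &
               g$effect_distribution == "normal", ]
  r <- run_grid(cl_cell, c("CL-UNW"), reps = 1000, master_seed = 71)
  expect_gte(r$type_one_error_pct, 3.6)
  expect_lte(r$type_one_error_pct, 6.4)
  gm_cell <- g[g$n_clusters == 20 & g$mean_size == 50 & g$cv_size == 0 &
               g$control_prevalence == 0.3 & g$icc == 0.05 &
               g$effect_distribution == "normal", ]
  r2 <- run_grid(gm_cell, c("REPL.DF_CP", "FG.I.DF_CP"), reps = 1000,
                 master_seed = 72)
  expect_gte(r2$type_one_error_pct[r2$method == "REPL.DF_CP"], 3.6)
  expect_lte(r2$type_one_error_pct[r2$method == "REPL.DF_CP"], 6.4)
  expect_lte(r2$type_one_error_pct[r2$method == "FG.I.DF_CP"], 6.4)
})
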
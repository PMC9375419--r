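test_that("REPL collapses to the pooled logistic fit without cluster variation", {
  # identical counts in every cluster: no between-cluster variability
  d <- trial_dataset(paste0("c", 1:8), rep(c(0L, 1L), each = 4),
                     rep(c(6L, 10L), each = 4), rep(20L, 8))
  f <- fit_repl(d)
  expect_equal(f$sigma_b2_hat, 0)
  g <- glm(cbind(events, size - events) ~ arm, binomial, data = d)
  expect_equal(f$beta1, unname(coef(g)[2]), tolerance = 1e-6)
  expect_equal(f$beta0, unname(coef(g)[1]), tolerance = 1e-6)
})

test_that("REPL recovers the generating parameters on simulated trials", {
  scn <- scenario(30, 50, 0, 0.3, 0.1, effect = 2)
  set.seed(31)
  sim <- crtsmall:::generate_scenario_matrix(scn, 300)
  r <- crtsmall:::.repl_fit_many(sim$Y, sim$M, as.integer(sim$arm))
  ok <- r[, "converged"] > 0
  expect_gt(mean(ok), 0.9)
  mc_se <- sd(r[ok, "beta1"]) / sqrt(sum(ok))
  expect_lt(abs(mean(r[ok, "beta1"]) - log(2)), 3 * mc_se)
  expect_lt(abs(mean(r[ok, "sigma_b2"]) / scn$sigma_b2 - 1), 0.15)
})

test_that("adaptive quadrature matches brute-force integration of the likelihood", {
  d <- trial_dataset(paste0("c", 1:4), c(0L, 0L, 1L, 1L),
                     c(1L, 8L, 3L, 9L), c(10L, 12L, 10L, 12L))
  f <- fit_aq(d, q_points = 25)
  expect_gt(f$sigma_b2_hat, 0.01)   # interior variance estimate
  sb <- sqrt(f$sigma_b2_hat)
  bf <- sum(vapply(seq_len(nrow(d)), function(j) {
    fn <- function(u) dbinom(d$events[j], d$size[j],
                             plogis(f$beta0 + f$beta1 * d$arm[j] + u)) *
      dnorm(u, 0, sb)
    log(integrate(fn, -12 * sb, 12 * sb, rel.tol = 1e-12)$value)
  }, numeric(1)))
  expect_lt(abs(f$loglik - bf), 1e-6)
})

test_that("the quadrature rule is converged at the default precision", {
  set.seed(33)
  d <- generate_trial(scenario(12, 20, 0.5, 0.3, 0.1, effect = 2))
  gh <- crtsmall:::gauss_hermite
  ll <- function(q) crtsmall:::aq_loglik(-0.8, 0.7, 0.4, d$events, d$size,
                                         d$arm, gh(q))
  expect_lt(abs(ll(25) - ll(51)), 1e-6)
  # one node is the Laplace approximation: close but not equal here
  expect_lt(abs(ll(1) - ll(51)), 0.1)
})

test_that("adaptive quadrature agrees with an independent mixed-model fitter", {
  set.seed(34)
  d <- generate_trial(scenario(12, 30, 0.5, 0.3, 0.1, effect = 2))
  f <- fit_aq(d, q_points = 25)
  g <- lme4::glmer(cbind(events, size - events) ~ arm + (1 | cluster),
                   data = d, family = binomial, nAGQ = 25)
  expect_equal(f$beta1, unname(lme4::fixef(g)[2]), tolerance = 1e-4)
  expect_equal(f$sigma_b2_hat, unname(unlist(lme4::VarCorr(g))[1]),
               tolerance = 1e-3)
  expect_equal(sqrt(f$cov_beta[2, 2]), sqrt(vcov(g)[2, 2]),
               tolerance = 1e-3, ignore_attr = TRUE)
})

test_that("AQ approaches the pooled logistic fit when clustering vanishes", {
  set.seed(35)
  d <- generate_trial(scenario(16, 2000, 0, 0.3, 0))
  f <- fit_aq(d)
  g <- glm(cbind(events, size - events) ~ arm, binomial, data = d)
  expect_equal(f$beta1, unname(coef(g)[2]), tolerance = 1e-3)
})

test_that("degrees-of-freedom rules behave as documented", {
  set.seed(36)
  d <- generate_trial(scenario(12, 50, 0, 0.3, 0.05, effect = 2))
  f <- fit_repl(d)
  expect_equal(glmm_dof(f, "CP")$df, 10)
  # balanced one-way design: between-cluster information only, df ~ n - 2
  st <- glmm_dof(f, "Satterthwaite")
  expect_lt(abs(st$df - 10), 0.5)
  expect_equal(st$se_used, sqrt(f$cov_beta[2, 2]))
  # Satterthwaite/KR are defined on the REPL pseudo-model only
  fa <- fit_aq(d)
  expect_error(glmm_dof(fa, "Satterthwaite"), "REPL")
  expect_error(glmm_dof(fa, "KR"), "REPL")
})

test_that("the Kenward-Roger standard error never deflates the model SE", {
  set.seed(37)
  worst <- 0
  for (i in 1:60) {
    d <- generate_trial(scenario(sample(c(8, 12), 1), 30, 0.5, 0.3, 0.05,
                                 effect = 2))
    f <- fit_repl(d)
    if (!f$converged) next
    kr <- glmm_dof(f, "KR")
    worst <- min(worst, kr$se_used / sqrt(f$cov_beta[2, 2]) - 1)
    expect_equal(kr$df, glmm_dof(f, "Satterthwaite")$df)
  }
  expect_gte(worst, -1e-8)
})

test_that("the GLMM t-test matches direct t-distribution evaluation", {
  set.seed(38)
  d <- generate_trial(scenario(10, 40, 0.5, 0.3, 0.05, effect = 2))
  f <- fit_repl(d)
  r <- glmm_test(f)
  expect_equal(r$p, 2 * pt(-abs(f$beta1 / r$se), 8))
  expect_equal(r$method, "REPL.DF_CP")
  # zero estimate gives p = 1
  r0 <- glmm_test(f, dof = list(rule = "CP", df = 8, se_used = r$se))
  f0 <- f; f0$beta1 <- 0
  expect_equal(glmm_test(f0, list(rule = "CP", df = 8, se_used = r$se))$p, 1)
  # large df reproduces the normal approximation
  rn <- glmm_test(f, list(rule = "CP", df = 1e6, se_used = r$se))
  expect_lt(abs(rn$p - 2 * pnorm(-abs(f$beta1 / r$se))), 1e-4)
})

test_that("REPL and AQ agree on well-behaved data and are arm-antisymmetric", {
  set.seed(39)
  d <- generate_trial(scenario(30, 50, 0, 0.3, 0.05, effect = 2))
  fr <- fit_repl(d)
  fa <- fit_aq(d)
  expect_lt(abs(fr$beta1 / fa$beta1 - 1), 0.1)
  dsw <- trial_dataset(d$cluster, 1L - d$arm, d$events, d$size)
  expect_equal(fit_repl(dsw)$beta1, -fr$beta1, tolerance = 1e-6)
  expect_equal(fit_aq(dsw)$beta1, -fa$beta1, tolerance = 1e-4)
})

test_that("single-arm data is a design error", {
  d <- trial_dataset(c("a", "b"), c(0L, 0L), c(1L, 2L), c(10L, 10L))
  expect_error(fit_repl(d), "per arm")
  expect_error(fit_aq(d), "per arm")
})
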
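#' Convert a log-odds-scale ICC to the cluster-effect variance
#'
#' The intracluster correlation coefficient on the log-odds scale is
#' \eqn{\rho = \sigma_b^2 / (\sigma_b^2 + \pi^2/3)}, the between-cluster
#' variance as a share of the total latent-logistic variance. This inverts
#' the definition: \eqn{\sigma_b^2 = \rho (\pi^2/3) / (1 - \rho)}.
#'
#' @param icc ICC in `[0, 1)`.
#' @return Cluster random-effect variance on the log-odds squared scale.
#' @examples
#' icc_to_sigma2(0.1) # 0.36554
#' @export
icc_to_sigma2 <- function(icc) {
  if (any(icc < 0) || any(icc >= 1)) stop("icc must lie in [0, 1)")
  icc * (pi^2 / 3) / (1 - icc)
}

#' Convert a cluster-effect variance back to the log-odds-scale ICC
#'
#' @param sigma_b2 non-negative variance on the log-odds squared scale.
#' @return ICC in `[0, 1)`.
#' @export
sigma2_to_icc <- function(sigma_b2) {
  if (any(sigma_b2 < 0)) stop("sigma_b2 must be non-negative")
  sigma_b2 / (sigma_b2 + pi^2 / 3)
}

#' Draw cluster sizes with a given mean and coefficient of variation
#'
#' With `cv_size = 0` all clusters have size `round(mean_size)`. Otherwise
#' sizes are `2 + delta` with `delta` negative-binomial, parameterised
#' (failures-before-rth-success convention) so that `E[size] = mean_size`
#' and `SD[size] = cv_size * mean_size` exactly:
#' `size = (mbar-2)^2/(s^2-(mbar-2))`, `prob = (mbar-2)/s^2`. This requires
#' `s^2 > mean_size - 2` and gives a minimum size of 2.
#'
#' @param n_clusters number of clusters.
#' @param mean_size mean cluster size (>= 3 when `cv_size > 0`).
#' @param cv_size coefficient of variation of cluster size (>= 0).
#' @return Integer vector of `n_clusters` sizes.
#' @export
draw_cluster_sizes <- function(n_clusters, mean_size, cv_size) {
  if (cv_size == 0) return(rep(as.integer(round(mean_size)), n_clusters))
  s2 <- (cv_size * mean_size)^2
  if (s2 <= mean_size - 2)
    stop("negative-binomial size model needs (cv_size*mean_size)^2 > mean_size - 2")
  r <- (mean_size - 2)^2 / (s2 - (mean_size - 2))
  p <- (mean_size - 2) / s2
  2L + rnbinom(n_clusters, size = r, prob = p)
}

#' Draw cluster random effects on the log-odds scale
#'
#' All three distributions are centred and scaled to mean 0 and variance
#' `sigma_b2`:
#' * `"normal"`: \eqn{N(0, \sigma_b^2)}.
#' * `"gamma"`: \eqn{\sigma_b (a - 2)/\sqrt{2}} with \eqn{a \sim Gamma(2, 1)}
#'   (skewness \eqn{\sqrt 2}).
#' * `"uniform"`: \eqn{U(-\sqrt{3\sigma_b^2}, +\sqrt{3\sigma_b^2})}.
#'
#' @param n_clusters number of draws.
#' @param distribution one of `"normal"`, `"gamma"`, `"uniform"`.
#' @param sigma_b2 non-negative variance.
#' @return Numeric vector of cluster log-odds shifts.
#' @export
draw_cluster_effects <- function(n_clusters, distribution, sigma_b2) {
  if (sigma_b2 < 0) stop("sigma_b2 must be non-negative")
  sb <- sqrt(sigma_b2)
  switch(match.arg(distribution, c("normal", "gamma", "uniform")),
    normal  = rnorm(n_clusters, 0, sb),
    gamma   = sb * (rgamma(n_clusters, shape = 2, rate = 1) - 2) / sqrt(2),
    uniform = runif(n_clusters, -sqrt(3) * sb, sqrt(3) * sb))
}

#' Solve the conditional odds ratio giving 80% power for a scenario
#'
#' Two-proportion power calculation with a clustered design effect. The
#' effective sample size per arm is `(n_clusters/2 * mean_size) / DE` with
#' `DE = (1 + (mean_size - 1) * icc) / RE` and `RE = 1 - cv^2 * lambda *
#' (1 - lambda)`, `lambda = mean_size * icc / (1 + (mean_size - 1) * icc)`,
#' the van Breukelen-Candel-Berger relative efficiency for varying cluster
#' size. Power uses t quantiles with `n_clusters - 2` degrees of freedom
#' (the clustered design has cluster-level error df):
#' `power = pt(|p1 - p0| / sd - t_{0.975, n-2}, n-2)` with
#' `sd = sqrt((p0 q0 + p1 q1) / n_eff)`, and the odds ratio is found by
#' root-finding on the log scale to power 0.80 (tolerance 1e-8 in power).
#'
#' @param n_clusters total number of clusters (1:1 randomisation).
#' @param mean_size mean cluster size.
#' @param cv_size coefficient of variation of cluster size.
#' @param control_prevalence control-arm prevalence.
#' @param icc log-odds-scale ICC, used directly as the design-effect
#'   correlation.
#' @param target_power target power, default 0.8.
#' @param alpha two-sided significance level, default 0.05.
#' @return Odds ratio > 1.
#' @export
solve_effect_size <- function(n_clusters, mean_size, cv_size,
                              control_prevalence, icc,
                              target_power = 0.8, alpha = 0.05) {
  df <- n_clusters - 2
  p0 <- control_prevalence
  lam <- mean_size * icc / (1 + (mean_size - 1) * icc)
  re <- 1 - cv_size^2 * lam * (1 - lam)
  de <- (1 + (mean_size - 1) * icc) / re
  n_eff <- (n_clusters / 2 * mean_size) / de
  pow <- function(log_or) {
    p1 <- plogis(qlogis(p0) + log_or)
    s <- sqrt((p0 * (1 - p0) + p1 * (1 - p1)) / n_eff)
    pt(abs(p1 - p0) / s - qt(1 - alpha / 2, df), df)
  }
  if (pow(log(100)) < target_power)
    stop("no odds ratio in (1, 100] achieves the target power")
  # bisection on log OR until the power bracket closes to 1e-8
  lo <- 1e-9; hi <- log(100)
  while (pow(hi) - pow(lo) > 1e-8 && hi - lo > 1e-14) {
    mid <- (lo + hi) / 2
    if (pow(mid) < target_power) lo <- mid else hi <- mid
  }
  exp((lo + hi) / 2)
}

#' Define one simulation scenario
#'
#' A scenario is one cell of the factorial simulation grid: trial design
#' (clusters, size distribution), outcome model (prevalence, ICC,
#' cluster-effect distribution), and intervention effect (`"null"` or a
#' conditional odds ratio; `"solve"` requests the 80%-power odds ratio from
#' [solve_effect_size()]).
#'
#' @param n_clusters even total number of clusters (1:1 randomisation).
#' @param mean_size mean cluster size.
#' @param cv_size coefficient of variation of cluster size.
#' @param control_prevalence control-arm prevalence in (0, 1).
#' @param icc log-odds-scale ICC in `[0, 1)`.
#' @param effect `"null"`, `"solve"`, or a numeric odds ratio > 0.
#' @param effect_distribution `"normal"`, `"gamma"`, or `"uniform"`.
#' @return A list of class `crt_scenario` with the fields above plus the
#'   derived `sigma_b2` and `beta1` (true conditional log odds ratio).
#' @export
scenario <- function(n_clusters, mean_size, cv_size, control_prevalence,
                     icc, effect = "null",
                     effect_distribution = "normal") {
  if (n_clusters %% 2 != 0) stop("n_clusters must be even (1:1 randomisation)")
  effect_distribution <- match.arg(effect_distribution,
                                   c("normal", "gamma", "uniform"))
  sigma_b2 <- icc_to_sigma2(icc)
  if (identical(effect, "solve"))
    effect <- solve_effect_size(n_clusters, mean_size, cv_size,
                                control_prevalence, icc)
  if (identical(effect, "null")) {
    beta1 <- 0
    or <- NA_real_
  } else {
    if (!is.numeric(effect) || effect <= 0)
      stop("effect must be \"null\", \"solve\", or an odds ratio > 0")
    or <- effect
    beta1 <- log(effect)
  }
  structure(list(n_clusters = as.integer(n_clusters), mean_size = mean_size,
                 cv_size = cv_size, control_prevalence = control_prevalence,
                 icc = icc, effect = if (is.na(or)) "null" else or,
                 effect_distribution = effect_distribution,
                 sigma_b2 = sigma_b2, beta1 = beta1),
            class = "crt_scenario")
}

#' Generate one simulated trial under a scenario
#'
#' The data-generating model is binomial at cluster level:
#' \deqn{Y_{ij} \sim Binomial(expit(\beta_0 + \beta_1 i + u_{ij}), m_{ij})}
#' with \eqn{\beta_0 = logit(control\_prevalence)} (conditional,
#' median-cluster prevalence), \eqn{\beta_1} the conditional log odds
#' ratio (0 under the null), sizes from [draw_cluster_sizes()] and cluster
#' effects \eqn{u_{ij}} from [draw_cluster_effects()]. The first
#' `n_clusters/2` clusters are control, the rest intervention.
#'
#' @param scn a [scenario()].
#' @return A [trial_dataset()].
#' @export
generate_trial <- function(scn) {
  n <- scn$n_clusters
  arm <- rep(c(0L, 1L), each = n / 2)
  m <- draw_cluster_sizes(n, scn$mean_size, scn$cv_size)
  u <- draw_cluster_effects(n, scn$effect_distribution, scn$sigma_b2)
  eta <- qlogis(scn$control_prevalence) + scn$beta1 * arm + u
  y <- rbinom(n, m, plogis(eta))
  trial_dataset(sprintf("c%02d", seq_len(n)), arm, y, m)
}

#' Enumerate the full factorial scenario grid
#'
#' The full grid crosses 4 cluster counts (8, 12, 20, 30), 3 mean sizes
#' (10, 50, 1000), 3 size CVs (0, 0.5, 0.8), 2 control prevalences (0.10,
#' 0.30), 4 ICCs (0.001, 0.01, 0.05, 0.1), 3 cluster-effect distributions
#' (normal, gamma, uniform), and effect status (null / 80%-power odds
#' ratio): 1728 scenarios, 864 of them null. Odds ratios for the effect
#' scenarios are solved by [solve_effect_size()] and included in the table.
#'
#' @param effect `"both"` (default), `"null"`, or `"solve"` to restrict the
#'   effect-status factor.
#' @return A data frame with one row per scenario: the six design factors,
#'   `effect_status` (`"null"`/`"effect"`), derived `or`, `sigma_b2`,
#'   `beta1`, and a `scenario_id` string.
#' @export
scenario_grid <- function(effect = c("both", "null", "solve")) {
  effect <- match.arg(effect)
  status <- switch(effect, both = c("null", "effect"), null = "null",
                   solve = "effect")
  g <- expand.grid(
    effect_distribution = c("normal", "gamma", "uniform"),
    icc = c(0.001, 0.01, 0.05, 0.1),
    control_prevalence = c(0.10, 0.30),
    cv_size = c(0, 0.5, 0.8),
    mean_size = c(10, 50, 1000),
    n_clusters = c(8L, 12L, 20L, 30L),
    effect_status = status,
    stringsAsFactors = FALSE)
  g <- g[, c("n_clusters", "mean_size", "cv_size", "control_prevalence",
             "icc", "effect_distribution", "effect_status")]
  or_key <- unique(g[, c("n_clusters", "mean_size", "cv_size",
                         "control_prevalence", "icc")])
  or_key$or_solved <- mapply(solve_effect_size, or_key$n_clusters,
                             or_key$mean_size, or_key$cv_size,
                             or_key$control_prevalence, or_key$icc)
  g <- merge(g, or_key, sort = FALSE)
  g$or <- ifelse(g$effect_status == "effect", g$or_solved, NA_real_)
  g$or_solved <- NULL
  g$sigma_b2 <- icc_to_sigma2(g$icc)
  g$beta1 <- ifelse(g$effect_status == "effect", log(g$or), 0)
  o <- order(g$n_clusters, g$mean_size, g$cv_size, g$control_prevalence,
             g$icc, g$effect_distribution, g$effect_status)
  g <- g[o, ]
  rownames(g) <- NULL
  g$scenario_id <- sprintf("n%02d_m%04d_cv%s_p%s_icc%s_%s_%s",
                           g$n_clusters, g$mean_size, g$cv_size,
                           g$control_prevalence, g$icc,
                           substr(g$effect_distribution, 1, 4),
                           g$effect_status)
  g
}

# deterministic per-scenario seed stream below 2^31, safe in double precision
derive_seed <- function(master_seed, index) {
  s <- (as.numeric(master_seed) %% 2147483647)
  s <- (s * 48271 + 11) %% 2147483647
  as.integer((s + as.numeric(index) * 2246822519) %% 2147483647)
}
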
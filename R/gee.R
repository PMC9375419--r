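#' Fit a logistic GEE for a two-arm CRT
#'
#' Population-averaged logistic model `logit(mu) = beta0 + beta1 * arm`
#' solved by iteratively reweighted estimating equations. Because the only
#' covariate is cluster-constant and the working correlation is
#' compound-symmetric, every per-cluster matrix quantity collapses to a
#' scalar: the working-covariance inverse enters only through
#' `c_j = 1 / (1 + (m_j - 1) * alpha)`, and the estimating equation is a
#' weighted aggregated-binomial score. No `m x m` matrix is ever formed,
#' so clusters of size 1000 cost the same as clusters of size 5.
#'
#' With the independence working correlation the solution equals the
#' pooled logistic MLE on the aggregated 2x2 totals. With the exchangeable
#' working correlation, `alpha` is re-estimated each iteration by the
#' moment estimator on standardised Pearson residuals (scale
#' `phi = sum(r^2)/(N - p)`, divisor `sum(m(m-1)) - p`), truncated into
#' its validity range `(-1/(max(m) - 1), 1)`.
#'
#' Non-convergence (relative score norm not below `tol` within `max_iter`
#' iterations, or divergence under separation) is flagged, not errored.
#'
#' @param data a [trial_dataset()] with both arms present.
#' @param working `"independence"` or `"exchangeable"`.
#' @param max_iter iteration limit (default 50).
#' @param tol score-norm convergence tolerance (default 1e-10).
#' @return An object of class `gee_fit`: `beta` (length 2), `V_M`
#'   (model-based covariance), `working`, `alpha_hat`, `converged`,
#'   `alpha_truncated`, and `cluster_components` (per-cluster scalars
#'   `v`, `c`, `e`, `m`, `arm` sufficient to assemble any sandwich).
#' @export
fit_gee <- function(data, working = c("independence", "exchangeable"),
                    max_iter = 50L, tol = 1e-10) {
  validate_trial_dataset(data)
  check_two_arms(data)
  working <- match.arg(working)
  y <- as.numeric(data$events); m <- as.numeric(data$size)
  arm <- as.numeric(data$arm)
  n <- length(y)
  # start at the continuity-corrected pooled estimate
  p0 <- (sum(y[arm == 0]) + 0.5) / (sum(m[arm == 0]) + 1)
  p1 <- (sum(y[arm == 1]) + 0.5) / (sum(m[arm == 1]) + 1)
  beta <- c(qlogis(p0), qlogis(p1) - qlogis(p0))
  alpha <- 0
  truncated <- FALSE
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- beta[1] + beta[2] * arm
    mu <- plogis(eta)
    v <- mu * (1 - mu)
    cc <- 1 / (1 + (m - 1) * alpha)
    e <- y - m * mu
    score <- c(sum(cc * e), sum(arm * cc * e))
    a11 <- sum(cc * m * v); a12 <- sum(arm * cc * m * v)
    det <- a12 * (a11 - a12)
    if (!is.finite(det) || det <= 0) break
    step2 <- (a11 * score[2] - a12 * score[1]) / det
    step <- c((score[1] - a12 * step2) / a11, step2)
    beta <- beta + step
    if (any(!is.finite(beta)) || max(abs(beta)) > 30) break
    if (working == "exchangeable") {
      mu <- plogis(beta[1] + beta[2] * arm)
      v <- mu * (1 - mu)
      # closed-form sums of individual-level standardised residual products
      sr <- (y - m * mu) / sqrt(v)
      sr2 <- (y * (1 - mu)^2 + (m - y) * mu^2) / v
      phi <- sum(sr2) / (sum(m) - 2)
      num <- sum(sr^2 - sr2) / phi
      alpha_new <- num / (sum(m * (m - 1)) - 2)
      lo <- -1 / (max(m) - 1) + 1e-8
      if (max(m) == 1) lo <- 0
      if (alpha_new < lo) { alpha_new <- lo; truncated <- TRUE }
      if (alpha_new > 1 - 1e-8) { alpha_new <- 1 - 1e-8; truncated <- TRUE }
      alpha <- alpha_new
    }
    if (sqrt(sum(score^2)) < tol * (1 + sum(abs(y)))) { converged <- TRUE; break }
  }
  eta <- beta[1] + beta[2] * arm
  mu <- plogis(eta)
  v <- mu * (1 - mu)
  cc <- 1 / (1 + (m - 1) * alpha)
  a11 <- sum(cc * m * v); a12 <- sum(arm * cc * m * v)
  det <- a12 * (a11 - a12)
  V_M <- matrix(c(a12, -a12, -a12, a11), 2, 2) / det
  # pooled separation: an arm with no events (or only events) pushes the
  # estimating equations to infinity
  sep <- any(vapply(0:1, function(a) {
    ev <- sum(y[arm == a]); ev == 0 || ev == sum(m[arm == a])
  }, logical(1)))
  structure(list(
    beta = beta, V_M = V_M, working = working, alpha_hat = alpha,
    converged = converged && !sep && all(is.finite(beta)) &&
      max(abs(beta)) < 30,
    alpha_truncated = truncated, n_clusters = n,
    cluster_components = data.frame(arm = arm, m = m, v = v, c = cc,
                                    e = y - m * mu)),
    class = "gee_fit")
}

#' Sandwich covariance for a GEE fit
#'
#' Assembles the requested robust covariance of the GEE coefficients from
#' the per-cluster components of [fit_gee()]:
#' * `"none"`: the uncorrected sandwich
#'   \eqn{V_s = V_M [\sum D' V_W^{-1} \hat{Cov}(y) V_W^{-1} D] V_M}.
#' * `"KC"`: Kauermann-Carroll -- each cluster's residual term is scaled by
#'   the principal inverse square root of `I - H_j` (cluster leverage);
#'   in the collapsed representation `I - H_j` has the single non-unit
#'   eigenvalue `1 - m_j v_j c_j x_j' V_M x_j`, so the inverse square root
#'   is the scalar `(1 - leverage)^{-1/2}` on the residual direction. A
#'   non-positive eigenvalue makes the correction undefined and flags the
#'   fit.
#' * `"FG"`: Fay-Graubard -- the parameter-space diagonal correction
#'   `diag[(1 - min(b, [D'V_W^{-1}D V_M]_kk))^{-1/2}]` applied to each
#'   cluster's score contribution, with boundary parameter
#'   `b = fg_bound` (default 0.75).
#'
#' @param fit a `gee_fit`.
#' @param correction `"none"`, `"KC"`, or `"FG"`.
#' @param fg_bound Fay-Graubard boundary parameter in (0, 1], default 0.75.
#' @return A 2x2 covariance matrix with attribute `"ok"` (FALSE when the
#'   KC inverse square root is undefined).
#' @export
gee_sandwich <- function(fit, correction = c("none", "KC", "FG"),
                         fg_bound = 0.75) {
  correction <- match.arg(correction)
  comp <- fit$cluster_components
  V_M <- fit$V_M
  meat <- matrix(0, 2, 2)
  ok <- TRUE
  for (j in seq_len(nrow(comp))) {
    x <- c(1, comp$arm[j])
    u <- comp$c[j] * comp$e[j] * x          # D' V_W^-1 (y - mu), collapsed
    if (correction == "none") {
      meat <- meat + tcrossprod(u)
    } else if (correction == "KC") {
      lev <- comp$m[j] * comp$v[j] * comp$c[j] *
        drop(t(x) %*% V_M %*% x)
      if (lev >= 1) { ok <- FALSE; next }
      meat <- meat + tcrossprod(u) / (1 - lev)
    } else {
      q <- comp$m[j] * comp$v[j] * comp$c[j] *
        diag(tcrossprod(x) %*% V_M)
      a <- (1 - pmin(fg_bound, q))^(-1 / 2)
      meat <- meat + tcrossprod(a * u)
    }
  }
  out <- V_M %*% meat %*% V_M
  attr(out, "ok") <- ok
  out
}

#' t-based test of the intervention effect from a GEE fit
#'
#' `t = beta1 / sqrt(cov[2,2])` against a t distribution with `n - 2`
#' degrees of freedom (clusters minus cluster-level parameters).
#'
#' @param fit a `gee_fit`.
#' @param sandwich_cov covariance from [gee_sandwich()].
#' @param label method label; defaults to the vocabulary name implied by
#'   the fit's working correlation and the covariance's correction.
#' @return A one-row `FitResult` data frame.
#' @export
gee_test <- function(fit, sandwich_cov, label = NULL) {
  if (is.null(label)) label <- "GEE"
  est <- fit$beta[2]
  se <- sqrt(sandwich_cov[2, 2])
  df <- fit$n_clusters - 2
  tstat <- if (se > 0) est / se else 0
  p <- 2 * pt(-abs(tstat), df)
  tcrit <- qt(0.975, df)
  conv <- fit$converged && isTRUE(attr(sandwich_cov, "ok"))
  fit_result(label, est, se, df, p, est - tcrit * se, est + tcrit * se,
             conv)
}

#' @export
print.gee_fit <- function(x, ...) {
  cat("Logistic GEE (", x$working, " working correlation)\n", sep = "")
  cat("  log OR:", format(x$beta[2], digits = 4),
      " alpha:", format(x$alpha_hat, digits = 4),
      " converged:", x$converged, "\n")
  invisible(x)
}
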
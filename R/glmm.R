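#' Fit a random-intercept logistic GLMM by restricted pseudo-likelihood
#'
#' Iterative linearisation of the logistic mixed model
#' \eqn{E[y | u] = expit(\beta_0 + \beta_1 arm + u)},
#' \eqn{u \sim N(0, \sigma_b^2)}, at cluster-aggregated level (the arm
#' indicator is cluster-constant, so the aggregated binomial totals carry
#' the full likelihood). Each iteration forms the pseudo-response
#' `z = eta + (y/m - mu)/(mu(1-mu))` with working weights `m mu(1-mu)` and
#' refits a two-variance-component linear mixed model (cluster intercept
#' variance and residual scale) by REML, profiled to a one-dimensional
#' search over the variance ratio; random effects are re-expanded at their
#' predicted values (subject-specific expansion). Convergence is a joint
#' relative change below `tol` in `(beta, sigma_b2)`; a period-2 oscillation
#' or a linear predictor pinned at the numerical boundary (cluster-level
#' separation) flags the fit non-converged.
#'
#' @param data a [trial_dataset()] with both arms present.
#' @param max_iter outer iteration limit (default 100).
#' @param tol relative-change convergence tolerance (default 1e-8).
#' @return An object of class `glmm_fit`: list with `beta0`, `beta1`,
#'   `sigma_b2_hat`, `cov_beta` (2x2), `method = "REPL"`, `converged`,
#'   `iterations`, `n_clusters`, and `pseudo_model` (the converged
#'   linearised state needed for Satterthwaite/Kenward-Roger degrees of
#'   freedom).
#' @export
fit_repl <- function(data, max_iter = 100L, tol = 1e-8) {
  validate_trial_dataset(data)
  check_two_arms(data)
  core <- .repl_fit_core(as.numeric(data$events), as.numeric(data$size),
                         as.integer(data$arm), max_iter, tol)
  structure(list(
    beta0 = core$beta0, beta1 = core$beta1,
    sigma_b2_hat = core$sigma_b2, cov_beta = core$cov_beta,
    method = "REPL", converged = core$converged,
    iterations = core$iterations, n_clusters = nrow(data),
    pseudo_model = list(z = core$z, w = core$w, phi = core$phi,
                        gamma = core$gamma, arm = as.integer(data$arm),
                        m = as.numeric(data$size))),
    class = "glmm_fit")
}

# Gauss-Hermite nodes/weights (weight exp(-x^2)) via the Golub-Welsch
# eigendecomposition of the Jacobi matrix
gauss_hermite <- function(q) {
  if (q == 1) return(list(nodes = 0, weights = sqrt(pi)))
  off <- sqrt(seq_len(q - 1) / 2)
  J <- diag(0, q)
  J[cbind(seq_len(q - 1), seq_len(q - 1) + 1)] <- off
  J[cbind(seq_len(q - 1) + 1, seq_len(q - 1))] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(nodes = e$values[ord], weights = sqrt(pi) * e$vectors[1, ord]^2)
}

# adaptive GH marginal log-likelihood at cluster level
aq_loglik <- function(beta0, beta1, sigma2, y, m, arm, gh) {
  eta <- beta0 + beta1 * arm
  sb <- sqrt(sigma2)
  ll <- 0
  for (j in seq_along(y)) {
    # conditional mode of the integrand by damped Newton
    u <- 0
    for (it in 1:50) {
      mu <- plogis(eta[j] + u)
      g <- y[j] - m[j] * mu - u / sigma2
      h <- -m[j] * mu * (1 - mu) - 1 / sigma2
      step <- g / h
      if (abs(step) > 5) step <- sign(step) * 5
      u <- u - step
      if (abs(step) < 1e-12) break
    }
    mu <- plogis(eta[j] + u)
    tau <- 1 / sqrt(m[j] * mu * (1 - mu) + 1 / sigma2)
    uq <- u + sqrt(2) * tau * gh$nodes
    logf <- lchoose(m[j], y[j]) + y[j] * (eta[j] + uq) -
      m[j] * log1p(exp(eta[j] + uq)) -
      uq^2 / (2 * sigma2) - 0.5 * log(2 * pi * sigma2)
    lt <- log(gh$weights) + gh$nodes^2 + logf
    mx <- max(lt)
    ll <- ll + mx + log(sum(exp(lt - mx))) + 0.5 * log(2) + log(tau)
  }
  ll
}

central_hessian <- function(f, x, h = 1e-4) {
  k <- length(x)
  H <- matrix(0, k, k)
  hh <- h * (1 + abs(x))
  for (i in seq_len(k)) for (j in i:k) {
    e_i <- e_j <- rep(0, k); e_i[i] <- hh[i]; e_j[j] <- hh[j]
    H[i, j] <- H[j, i] <-
      (f(x + e_i + e_j) - f(x + e_i - e_j) -
       f(x - e_i + e_j) + f(x - e_i - e_j)) / (4 * hh[i] * hh[j])
  }
  H
}

#' Fit a random-intercept logistic GLMM by adaptive Gauss-Hermite quadrature
#'
#' Maximises the exact marginal likelihood of the same model as
#' [fit_repl()], integrating the cluster random effect with `q_points`
#' Gauss-Hermite nodes centred and scaled at each cluster's conditional
#' mode and curvature (`q_points = 1` is the Laplace approximation). The
#' variance is optimised on the log scale with a floor of 1e-12; a
#' boundary estimate is flagged, not errored. `cov_beta` is the
#' fixed-effect block of the inverse observed information (numerical
#' Hessian of the marginal log-likelihood).
#'
#' @inheritParams fit_repl
#' @param q_points number of quadrature nodes (default 11).
#' @return An object of class `glmm_fit` with `method = "AQ"` and no
#'   `pseudo_model` (Satterthwaite/Kenward-Roger degrees of freedom are
#'   defined only for the REPL pseudo-model).
#' @export
fit_aq <- function(data, q_points = 11L, max_iter = 200L) {
  validate_trial_dataset(data)
  check_two_arms(data)
  y <- as.numeric(data$events); m <- as.numeric(data$size)
  arm <- as.numeric(data$arm)
  gh <- gauss_hermite(q_points)
  lfloor <- log(1e-12)
  negll <- function(par) {
    s2 <- exp(max(par[3], lfloor))
    -aq_loglik(par[1], par[2], s2, y, m, arm, gh)
  }
  # start at the pooled logistic MLE with a moment guess for the variance
  p0 <- (sum(y[arm == 0]) + 0.5) / (sum(m[arm == 0]) + 1)
  p1 <- (sum(y[arm == 1]) + 0.5) / (sum(m[arm == 1]) + 1)
  s <- cluster_log_odds(data$events, data$size)
  v0 <- var(s) - mean(1 / (m * plogis(s) * (1 - plogis(s))))
  if (!is.finite(v0)) v0 <- 0.01
  start <- c(qlogis(p0), qlogis(p1) - qlogis(p0),
             log(max(v0, 0.01)))
  opt <- nlminb(start, negll, lower = c(-Inf, -Inf, lfloor),
                control = list(iter.max = max_iter, abs.tol = 1e-12))
  par <- opt$par
  boundary <- par[3] <= lfloor + 1e-6
  H <- central_hessian(negll, par)
  cov_beta <- tryCatch({
    ok <- solve(H)
    if (!all(is.finite(ok)) || ok[1, 1] <= 0 || ok[2, 2] <= 0)
      stop("bad hessian")
    ok[1:2, 1:2]
  }, error = function(e) solve(H[1:2, 1:2]))
  structure(list(
    beta0 = par[1], beta1 = par[2],
    sigma_b2_hat = exp(max(par[3], lfloor)) * (!boundary),
    cov_beta = cov_beta, method = "AQ",
    converged = opt$convergence == 0, iterations = opt$iterations,
    n_clusters = nrow(data), boundary = boundary,
    loglik = -opt$objective, pseudo_model = NULL),
    class = "glmm_fit")
}

#' Degrees of freedom for the GLMM intervention-effect test
#'
#' Three rules:
#' * `"CP"`: clusters minus cluster-level parameters, `df = n - 2`, with
#'   the model standard error.
#' * `"Satterthwaite"`: `df = 2 Var(beta1)^2 / Var[Var(beta1)]`, the
#'   variance of the variance approximated by the delta method on the
#'   converged REPL pseudo-model (gradient of `Var(beta1)` with respect to
#'   the two variance parameters, REML expected information).
#' * `"KR"`: Kenward-Roger -- standard error from the adjusted covariance
#'   `C + 2*Lambda` of the pseudo-model (the covariance structure is
#'   linear in the variance parameters, so the second-derivative term
#'   vanishes) and the Satterthwaite degrees of freedom, which for a
#'   single-parameter test is the degrees-of-freedom part of the
#'   correction.
#'
#' Satterthwaite and Kenward-Roger require a REPL fit (the pseudo-model is
#' the linear mixed model these corrections are defined on).
#'
#' @param fit a `glmm_fit` from [fit_repl()] or [fit_aq()].
#' @param rule `"CP"`, `"Satterthwaite"`, or `"KR"`.
#' @return A list with `rule`, `df`, and `se_used`.
#' @export
glmm_dof <- function(fit, rule = c("CP", "Satterthwaite", "KR")) {
  rule <- match.arg(rule)
  se_model <- sqrt(fit$cov_beta[2, 2])
  if (rule == "CP")
    return(list(rule = "CP", df = fit$n_clusters - 2, se_used = se_model))
  if (fit$method != "REPL" || is.null(fit$pseudo_model))
    stop("Satterthwaite/KR degrees of freedom require a REPL fit ",
         "with its pseudo-model")
  pm <- fit$pseudo_model
  n <- length(pm$z)
  X <- cbind(1, pm$arm)
  sigma2 <- pm$phi * pm$gamma
  d <- sigma2 + pm$phi / pm$w            # diagonal marginal variance
  Vi <- 1 / d
  A <- crossprod(X * Vi, X)
  C <- solve(A)
  dV <- list(rep(1, n), 1 / pm$w)        # d V / d(sigma_b2), d V / d(phi)
  # REML expected information of (sigma_b2, phi)
  XVi <- X * Vi
  B <- XVi %*% C                         # V^-1 X C
  info <- matrix(0, 2, 2)
  Pk <- Qf <- vector("list", 2)
  for (k in 1:2) Pk[[k]] <- crossprod(XVi, dV[[k]] * XVi)
  for (k in 1:2) for (l in k:2) {
    # tr(P dVk P dVl) with P = V^-1 - V^-1 X C X' V^-1, V diagonal
    PdV_k <- Vi * dV[[k]]
    PdV_l <- Vi * dV[[l]]
    t1 <- sum(PdV_k * PdV_l)
    M_k <- B %*% t(XVi * dV[[k]])        # V^-1 X C X' V^-1 dVk (n x n, small)
    M_l <- B %*% t(XVi * dV[[l]])
    t2 <- sum(diag(M_k) * PdV_l) + sum(diag(M_l) * PdV_k)
    t3 <- sum(M_k * t(M_l))
    info[k, l] <- info[l, k] <- 0.5 * (t1 - t2 + t3)
  }
  # within-cluster pseudo-residual directions ((m_j - 1) each) carry
  # information on phi only: V^-1 dV/dphi is 1/phi there
  info[2, 2] <- info[2, 2] + 0.5 * sum(pm$m - 1) / pm$phi^2
  Wth <- solve(info)                     # covariance of variance parameters
  g <- vapply(1:2, function(k) (C %*% Pk[[k]] %*% C)[2, 2], numeric(1))
  var_var <- drop(t(g) %*% Wth %*% g)
  df_s <- 2 * C[2, 2]^2 / var_var
  if (rule == "Satterthwaite")
    return(list(rule = "Satterthwaite", df = df_s, se_used = se_model))
  # Kenward-Roger adjusted covariance
  Lam_inner <- matrix(0, 2, 2)
  for (k in 1:2) for (l in 1:2) {
    Qkl <- crossprod(XVi * dV[[k]], Vi * dV[[l]] * XVi)
    Lam_inner <- Lam_inner +
      Wth[k, l] * (Qkl - Pk[[k]] %*% C %*% Pk[[l]])
  }
  cov_adj <- C + 2 * (C %*% Lam_inner %*% C)
  list(rule = "KR", df = df_s, se_used = sqrt(max(cov_adj[2, 2], 0)))
}

#' t-based test of the intervention effect from a GLMM fit
#'
#' Computes `t = beta1 / se_used` against a t distribution with the
#' degrees of freedom from [glmm_dof()]; two-sided p-value and 95%
#' confidence interval from the same distribution.
#'
#' @param fit a `glmm_fit`.
#' @param dof result of [glmm_dof()]; default is the CP rule.
#' @return A one-row `FitResult` data frame; the method label encodes
#'   fitting method and degrees-of-freedom rule (e.g. `REPL.DF_S`).
#' @export
glmm_test <- function(fit, dof = glmm_dof(fit, "CP")) {
  lab <- paste0(fit$method, ".",
                switch(dof$rule, CP = "DF_CP", Satterthwaite = "DF_S",
                       KR = "DF_KR"))
  est <- fit$beta1
  se <- dof$se_used
  tstat <- if (se > 0) est / se else 0
  p <- 2 * pt(-abs(tstat), dof$df)
  tcrit <- qt(0.975, dof$df)
  fit_result(lab, est, se, dof$df, p, est - tcrit * se, est + tcrit * se,
             fit$converged)
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat("Random-intercept logistic GLMM (", x$method, ")\n", sep = "")
  cat("  log OR:", format(x$beta1, digits = 4),
      " sigma_b2:", format(x$sigma_b2_hat, digits = 4),
      " converged:", x$converged, "\n")
  invisible(x)
}
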
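#' Convert a conditional log odds ratio to the marginal scale
#'
#' A random-intercept logistic model defines a cluster-specific
#' (conditional) effect; GEE estimate the population-averaged (marginal)
#' effect, which is attenuated by the between-cluster variance:
#' \deqn{\beta_M \approx \beta_C ([16\sqrt3/(15\pi)]^2 \sigma_b^2 + 1)^{-1/2}}
#' The engine uses this as the truth for GEE bias, power, and coverage;
#' cluster-level and GLMM methods are compared to the conditional effect.
#'
#' @param beta_conditional conditional log odds ratio.
#' @param sigma_b2 cluster random-effect variance (log-odds scale).
#' @return Marginal log odds ratio.
#' @export
marginal_truth <- function(beta_conditional, sigma_b2) {
  beta_conditional * ((16 * sqrt(3) / (15 * pi))^2 * sigma_b2 + 1)^(-1 / 2)
}

methods_marginal <- function(methods) {
  grepl("^(UNC|KC|FG)\\.", methods)
}

#' Summarise Monte-Carlo performance of one method in one scenario
#'
#' Computes the performance measures over converged repetitions:
#' * standardised bias: `100 * (mean(estimate) - truth) / SD(estimate)`;
#' * relative SE bias: `100 * (mean(se) / SD(estimate) - 1)`;
#' * rejection rate: `100 * share with p < 0.05`, reported as type-one
#'   error when `truth == 0` and as power otherwise;
#' * coverage: `100 * share with ci_low <= truth <= ci_high`;
#' * classification of type-one error: conservative below 3.6%, inflated
#'   above 6.4% (the 95% Monte-Carlo band around 5% at 1000 repetitions),
#'   nominal between.
#'
#' @param results data frame of per-repetition `FitResult` rows for one
#'   method (columns `estimate`, `se`, `p`, `ci_low`, `ci_high`,
#'   `converged`).
#' @param truth true log odds ratio on the method's estimand scale.
#' @return A one-row data frame of performance measures.
#' @export
summarise_performance <- function(results, truth) {
  conv <- results$converged & is.finite(results$estimate) &
    is.finite(results$se) & is.finite(results$p)
  nc <- sum(conv)
  null_scn <- truth == 0
  if (nc < 2) {
    return(data.frame(n_reps = nrow(results), n_converged = nc,
                      standardised_bias_pct = NA_real_,
                      relative_se_bias_pct = NA_real_,
                      type_one_error_pct = NA_real_, power_pct = NA_real_,
                      coverage_pct = NA_real_,
                      classification = NA_character_,
                      stringsAsFactors = FALSE))
  }
  est <- results$estimate[conv]; se <- results$se[conv]
  p <- results$p[conv]
  sdv <- sd(est)
  rej <- 100 * mean(p < 0.05)
  data.frame(
    n_reps = nrow(results), n_converged = nc,
    standardised_bias_pct = if (sdv > 0) 100 * (mean(est) - truth) / sdv
                            else NA_real_,
    relative_se_bias_pct = if (sdv > 0) 100 * (mean(se) / sdv - 1)
                           else NA_real_,
    type_one_error_pct = if (null_scn) rej else NA_real_,
    power_pct = if (!null_scn) rej else NA_real_,
    coverage_pct = 100 * mean(results$ci_low[conv] <= truth &
                              truth <= results$ci_high[conv]),
    classification = if (null_scn) {
      if (rej < 3.6) "conservative" else if (rej > 6.4) "inflated"
      else "nominal"
    } else NA_character_,
    stringsAsFactors = FALSE)
}

#' Analyse one trial with a set of methods
#'
#' Applies each requested estimator to the same dataset and returns their
#' `FitResult` rows. Model fits shared between methods (the REPL fit for
#' the three degrees-of-freedom rules, one GEE fit per working
#' correlation for the three sandwich corrections) are computed once.
#'
#' @param data a [trial_dataset()].
#' @param methods character vector from [crt_methods()].
#' @return A data frame with one `FitResult` row per method.
#' @export
analyse_trial <- function(data, methods = c("CL-UNW", "REPL.DF_CP",
                                            "FG.I.DF_CP")) {
  bad <- setdiff(methods, crt_methods())
  if (length(bad))
    stop("unknown method(s) ", paste(bad, collapse = ", "),
         "; valid labels: ", paste(crt_methods(), collapse = ", "))
  out <- list()
  if ("CL-UNW" %in% methods) out$clu <- cl_unweighted_test(data)
  if ("CL-W" %in% methods) out$clw <- cl_weighted_test(data)
  repl_rules <- c("REPL.DF_CP" = "CP", "REPL.DF_S" = "Satterthwaite",
                  "REPL.DF_KR" = "KR")
  want_repl <- intersect(names(repl_rules), methods)
  if (length(want_repl)) {
    fit <- fit_repl(data)
    for (mm in want_repl)
      out[[mm]] <- glmm_test(fit, glmm_dof(fit, repl_rules[[mm]]))
  }
  if ("AQ.DF_CP" %in% methods) {
    fit <- fit_aq(data)
    out$aq <- glmm_test(fit, glmm_dof(fit, "CP"))
  }
  for (wk in c("I", "E")) {
    want <- intersect(paste0(c("UNC", "KC", "FG"), ".", wk, ".DF_CP"),
                      methods)
    if (!length(want)) next
    fit <- fit_gee(data, if (wk == "I") "independence" else "exchangeable")
    for (mm in want) {
      corr <- sub("\\..*", "", mm)
      cv <- gee_sandwich(fit, if (corr == "UNC") "none" else corr)
      out[[mm]] <- gee_test(fit, cv, label = mm)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[match(intersect(methods, res$method), res$method), , drop = FALSE]
}

# ---- vectorised per-scenario fast paths (columns = repetitions) -----------

# two-sample t machinery on an n x R matrix of cluster summaries
cl_unw_cols <- function(S, arm) {
  n <- nrow(S); n0 <- sum(arm == 0); n1 <- n - n0
  S0 <- S[arm == 0, , drop = FALSE]; S1 <- S[arm == 1, , drop = FALSE]
  m0 <- colMeans(S0); m1 <- colMeans(S1)
  ss0 <- colSums(S0^2) - n0 * m0^2
  ss1 <- colSums(S1^2) - n1 * m1^2
  pooled <- (ss0 + ss1) / (n - 2)
  est <- m1 - m0
  se <- sqrt(pooled * (1 / n0 + 1 / n1))
  list(est = est, se = se, df = n - 2,
       converged = !(ss0 <= 0 & ss1 <= 0))
}

cl_w_cols <- function(S, Y, M, arm) {
  n <- nrow(S); n0 <- sum(arm == 0); n1 <- n - n0
  i0 <- arm == 0; i1 <- arm == 1
  m0 <- colMeans(S[i0, , drop = FALSE]); m1 <- colMeans(S[i1, , drop = FALSE])
  ss0 <- colSums(S[i0, , drop = FALSE]^2) - n0 * m0^2
  ss1 <- colSums(S[i1, , drop = FALSE]^2) - n1 * m1^2
  total <- (ss0 + ss1) / (n - 2)
  Pt <- (Y + 0.5) / (M + 1)
  within <- colMeans(1 / (M * Pt * (1 - Pt)))
  sigma_b2 <- pmax(0, total - within)
  p_bar <- (colSums(Y) + 0.5 * n) / (colSums(M) + n)
  rho <- sigma_b2 / (sigma_b2 + 1 / (p_bar * (1 - p_bar)))
  rho <- pmin(pmax(rho, 0), 1 - 1e-8)
  W <- M / (1 + (M - 1) * rep(rho, each = n))
  sw0 <- colSums(W[i0, , drop = FALSE]); sw1 <- colSums(W[i1, , drop = FALSE])
  mu0 <- colSums((W * S)[i0, , drop = FALSE]) / sw0
  mu1 <- colSums((W * S)[i1, , drop = FALSE]) / sw1
  ss0 <- colSums((W * S^2)[i0, , drop = FALSE]) - sw0 * mu0^2
  ss1 <- colSums((W * S^2)[i1, , drop = FALSE]) - sw1 * mu1^2
  pooled <- (ss0 + ss1) / (n - 2)
  est <- mu1 - mu0
  se <- sqrt(pooled * (1 / sw0 + 1 / sw1))
  list(est = est, se = se, df = n - 2, converged = !(ss0 <= 0 & ss1 <= 0))
}

# independence-working GEE with uncorrected/KC/FG sandwiches, collapsed and
# vectorised across repetitions; returns one entry per requested correction
gee_i_cols <- function(Y, M, arm, corrections, fg_bound = 0.75) {
  i0 <- arm == 0; i1 <- arm == 1
  E0 <- colSums(Y[i0, , drop = FALSE]); N0 <- colSums(M[i0, , drop = FALSE])
  E1 <- colSums(Y[i1, , drop = FALSE]); N1 <- colSums(M[i1, , drop = FALSE])
  okfit <- E0 > 0 & E0 < N0 & E1 > 0 & E1 < N1   # pooled separation
  mu0 <- E0 / N0; mu1 <- E1 / N1
  mu0[!okfit] <- NA; mu1[!okfit] <- NA
  est <- qlogis(mu1) - qlogis(mu0)
  v0 <- mu0 * (1 - mu0); v1 <- mu1 * (1 - mu1)
  S0 <- v0 * N0; S1 <- v1 * N1
  E_res0 <- Y[i0, , drop = FALSE] -
    M[i0, , drop = FALSE] * rep(mu0, each = sum(i0))
  E_res1 <- Y[i1, , drop = FALSE] -
    M[i1, , drop = FALSE] * rep(mu1, each = sum(i1))
  lev0 <- M[i0, , drop = FALSE] * rep(v0 / S0, each = sum(i0))
  lev1 <- M[i1, , drop = FALSE] * rep(v1 / S1, each = sum(i1))
  out <- list()
  for (corr in corrections) {
    if (corr == "UNC") {
      M0 <- colSums(E_res0^2); M1 <- colSums(E_res1^2)
      v22 <- M0 / S0^2 + M1 / S1^2
      okc <- okfit
    } else if (corr == "KC") {
      okc <- okfit & colSums(lev0 >= 1) == 0 & colSums(lev1 >= 1) == 0
      M0 <- colSums(E_res0^2 / pmin(1 - lev0, 1))
      M0[colSums(lev0 >= 1) > 0] <- NA
      M1 <- colSums(E_res1^2 / pmin(1 - lev1, 1))
      M1[colSums(lev1 >= 1) > 0] <- NA
      v22 <- M0 / S0^2 + M1 / S1^2
    } else {  # FG
      a0 <- (1 - pmin(fg_bound, lev0))^(-1 / 2)  # intercept-row factor
      a1 <- (1 - pmin(fg_bound, lev1))^(-1 / 2)  # arm-row factor
      F0 <- colSums((a0 * E_res0)^2)
      G1 <- colSums(E_res1^2)
      H1 <- colSums(a1 * E_res1^2)
      K1 <- colSums((a1 * E_res1)^2)
      r1 <- -1 / S0; r2 <- 1 / S0 + 1 / S1
      v22 <- r1^2 * (F0 + G1) + 2 * r1 * r2 * H1 + r2^2 * K1
      okc <- okfit
    }
    out[[corr]] <- list(est = est, se = sqrt(v22), df = length(arm) - 2,
                        converged = okc & is.finite(v22))
  }
  out
}

# assemble per-rep columns into a FitResult-shaped data frame
cols_to_results <- function(x) {
  tcrit <- qt(0.975, x$df)
  tstat <- ifelse(x$se > 0, x$est / x$se, 0)
  data.frame(estimate = x$est, se = x$se, df = x$df,
             p = 2 * pt(-abs(tstat), x$df),
             ci_low = x$est - tcrit * x$se, ci_high = x$est + tcrit * x$se,
             converged = x$converged & is.finite(x$est) & is.finite(x$se))
}

# generate all repetitions of one scenario as n x R matrices
generate_scenario_matrix <- function(scn, reps) {
  n <- scn$n_clusters
  arm <- rep(c(0L, 1L), each = n / 2)
  if (scn$cv_size == 0) {
    M <- matrix(round(scn$mean_size), n, reps)
  } else {
    M <- matrix(draw_cluster_sizes(n * reps, scn$mean_size, scn$cv_size),
                n, reps)
  }
  U <- matrix(draw_cluster_effects(n * reps, scn$effect_distribution,
                                   scn$sigma_b2), n, reps)
  P <- plogis(qlogis(scn$control_prevalence) + scn$beta1 * arm + U)
  Y <- matrix(rbinom(n * reps, as.vector(M), as.vector(P)), n, reps)
  list(Y = Y, M = M, arm = arm)
}

as_scenario_row <- function(row) {
  scenario(row$n_clusters, row$mean_size, row$cv_size,
           row$control_prevalence, row$icc,
           effect = if (row$effect_status == "null") "null" else row$or,
           effect_distribution = row$effect_distribution)
}

simulate_scenario_results <- function(scn, methods, reps) {
  sim <- generate_scenario_matrix(scn, reps)
  Y <- sim$Y; M <- sim$M; arm <- sim$arm
  res <- list()
  need_s <- any(c("CL-UNW", "CL-W") %in% methods)
  if (need_s) S <- log((Y + 0.5) / (M - Y + 0.5))
  if ("CL-UNW" %in% methods)
    res[["CL-UNW"]] <- cols_to_results(cl_unw_cols(S, arm))
  if ("CL-W" %in% methods)
    res[["CL-W"]] <- cols_to_results(cl_w_cols(S, Y, M, arm))
  gee_i <- intersect(c("UNC.I.DF_CP", "KC.I.DF_CP", "FG.I.DF_CP"), methods)
  if (length(gee_i)) {
    got <- gee_i_cols(Y, M, arm, sub("\\..*", "", gee_i))
    for (mm in gee_i)
      res[[mm]] <- cols_to_results(got[[sub("\\..*", "", mm)]])
  }
  if ("REPL.DF_CP" %in% methods) {
    fits <- .repl_fit_many(Y, M, as.integer(arm))
    res[["REPL.DF_CP"]] <- cols_to_results(list(
      est = fits[, "beta1"], se = fits[, "se1"], df = nrow(Y) - 2,
      converged = fits[, "converged"] > 0))
  }
  # remaining methods go through the per-dataset reference implementations
  slow <- setdiff(methods, names(res))
  if (length(slow)) {
    ids <- sprintf("c%02d", seq_len(nrow(Y)))
    rows <- lapply(seq_len(ncol(Y)), function(r) {
      dat <- trial_dataset(ids, arm, Y[, r], M[, r])
      analyse_trial(dat, slow)
    })
    for (mm in slow) {
      picked <- do.call(rbind, lapply(rows, function(d)
        d[d$method == mm, , drop = FALSE]))
      res[[mm]] <- picked[, c("estimate", "se", "df", "p", "ci_low",
                              "ci_high", "converged")]
    }
  }
  res[methods]
}

#' Run a Monte-Carlo scenario grid
#'
#' For every scenario row, generates `reps` trials and analyses each one
#' with every requested method on the same dataset (paired comparison),
#' then summarises performance per scenario and method with
#' [summarise_performance()]. The truth is the conditional log odds ratio
#' for cluster-level and GLMM methods and the converted marginal effect
#' ([marginal_truth()]) for GEE methods. Per-scenario seeds are derived
#' from `master_seed` and the scenario id, so results are reproducible
#' and independent of the worker count.
#'
#' @param scenarios data frame of scenario rows (from [scenario_grid()],
#'   possibly filtered) or a single [scenario()].
#' @param methods character vector from [crt_methods()].
#' @param reps repetitions per scenario (>= 1).
#' @param master_seed integer master seed.
#' @param workers number of parallel workers (forked; results identical
#'   for any value).
#' @return A data frame with one row per scenario x method: the scenario
#'   factors, method, and all performance measures.
#' @export
run_grid <- function(scenarios, methods = c("CL-UNW", "REPL.DF_CP",
                                            "FG.I.DF_CP"),
                     reps = 1000, master_seed = 1, workers = 1) {
  bad <- setdiff(methods, crt_methods())
  if (length(bad))
    stop("unknown method(s): ", paste(bad, collapse = ", "))
  if (reps < 1) stop("reps must be >= 1")
  if (inherits(scenarios, "crt_scenario"))
    scenarios <- scenario_grid_row(scenarios)
  one_scenario <- function(i) {
    row <- scenarios[i, ]
    scn <- as_scenario_row(row)
    set.seed(derive_seed(master_seed, seed_index(row$scenario_id)))
    res <- simulate_scenario_results(scn, methods, reps)
    out <- lapply(methods, function(mm) {
      truth <- if (methods_marginal(mm))
        marginal_truth(scn$beta1, scn$sigma_b2) else scn$beta1
      cbind(row, method = mm, summarise_performance(res[[mm]], truth),
            stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  }
  idx <- seq_len(nrow(scenarios))
  pieces <- if (workers > 1) {
    parallel::mclapply(idx, one_scenario, mc.cores = workers)
  } else {
    lapply(idx, one_scenario)
  }
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# stable numeric index for a scenario id string (sum of char codes)
seed_index <- function(id) {
  vapply(id, function(s) sum(utf8ToInt(s) * seq_len(nchar(s))), numeric(1))
}

scenario_grid_row <- function(scn) {
  data.frame(n_clusters = scn$n_clusters, mean_size = scn$mean_size,
             cv_size = scn$cv_size,
             control_prevalence = scn$control_prevalence, icc = scn$icc,
             effect_distribution = scn$effect_distribution,
             effect_status = if (identical(scn$effect, "null")) "null"
                             else "effect",
             or = if (identical(scn$effect, "null")) NA_real_ else scn$effect,
             sigma_b2 = scn$sigma_b2, beta1 = scn$beta1,
             scenario_id = sprintf("single_n%02d", scn$n_clusters),
             stringsAsFactors = FALSE)
}
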
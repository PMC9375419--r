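#' Construct a FitResult row
#'
#' All estimators in the package report through a common contract: the
#' method label, the log odds ratio estimate, its standard error, the
#' degrees of freedom used for t-based inference, the two-sided p-value,
#' the 95% confidence interval, and a convergence flag. Non-converged fits
#' still carry their (flagged) numbers; the evaluation engine excludes
#' them from performance summaries.
#'
#' @param method method label from [crt_methods()].
#' @param estimate log odds ratio estimate.
#' @param se standard error.
#' @param df degrees of freedom.
#' @param p two-sided p-value.
#' @param ci_low,ci_high 95% confidence limits.
#' @param converged logical flag.
#' @return A one-row data frame with those columns.
#' @export
fit_result <- function(method, estimate, se, df, p, ci_low, ci_high,
                       converged) {
  data.frame(method = method, estimate = estimate, se = se, df = df,
             p = p, ci_low = ci_low, ci_high = ci_high,
             converged = converged, stringsAsFactors = FALSE)
}

#' Method vocabulary
#'
#' Fixed labels for the estimators studied by the package:
#' * `CL-UNW`, `CL-W` -- cluster-level t-tests (unweighted /
#'   inverse-variance weighted).
#' * `REPL.DF_CP`, `REPL.DF_S`, `REPL.DF_KR` -- restricted
#'   pseudo-likelihood GLMM with clusters-minus-parameters, Satterthwaite,
#'   or Kenward-Roger degrees of freedom.
#' * `AQ.DF_CP` -- adaptive Gauss-Hermite quadrature GLMM.
#' * `UNC/KC/FG` x `I/E` x `DF_CP` -- logistic GEE with uncorrected,
#'   Kauermann-Carroll, or Fay-Graubard sandwich covariance and
#'   independence or exchangeable working correlation.
#'
#' @return Character vector of method labels.
#' @export
crt_methods <- function() {
  c("CL-UNW", "CL-W",
    "REPL.DF_CP", "REPL.DF_S", "REPL.DF_KR", "AQ.DF_CP",
    "UNC.I.DF_CP", "KC.I.DF_CP", "FG.I.DF_CP",
    "UNC.E.DF_CP", "KC.E.DF_CP", "FG.E.DF_CP")
}
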
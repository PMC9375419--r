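---
title: "Analysing cluster randomised trials with few clusters and a binary outcome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing cluster randomised trials with few clusters and a binary outcome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtsmall)
```

## The problem

Cluster randomised trials (CRTs) randomise intact groups — clinics,
schools, villages — and many are run with 30 clusters or fewer. With a
binary outcome, the analyst must both respect the intracluster correlation
and cope with the small number of independent units, which breaks the
asymptotics that individual-level methods rely on. `crtsmall` implements
the three families of estimators of the intervention odds ratio that are
candidates in this setting, under a common reporting contract, together
with a simulator and a Monte-Carlo engine for comparing their type-one
error, bias, standard-error bias, power, and coverage.

All estimators here are *unadjusted*: the only covariate is the
cluster-constant arm indicator. A consequence used throughout the package
is that every method depends on the data only through the per-cluster
totals (arm, events, size), so the package stores and analyses trials in
cluster-aggregated form; individual-level files are aggregated on read and
give identical results.

## The estimators

**Cluster-level (two-stage) analysis.** Each cluster is summarised by its
continuity-corrected log odds \(s_{ij} = \log[(y_{ij}+0.5)/(m_{ij}-y_{ij}+0.5)]\);
adding half an event and half a non-event keeps the summary finite in
clusters with no (or only) events. Arms are compared with an
equal-variance two-sample t-test on the \(s_{ij}\) with \(n-2\) degrees of
freedom (`CL-UNW`), or with a weighted t-test (`CL-W`) using Kerry–Bland
inverse-variance weights \(w = m/(1+(m-1)\hat\rho)\). The weight ICC
\(\hat\rho\) is a method-of-moments estimate formed under the null: the
pooled within-arm variance of \(s_{ij}\) estimates
\(\sigma_b^2 + E[1/(p(1-p)m)]\) (a Taylor expansion of the cluster
log-odds variance), the within-cluster term is estimated at the
continuity-corrected cluster proportions, and the difference (truncated at
zero) is converted to the proportion-scale ICC at the pooled prevalence.
The main text of the source literature does not pin this estimator down,
so it is the module's most discretionary choice; `CL-W` is correspondingly
kept out of the package's headline reproduction targets. The weighted test
treats the weights as known — weighted least squares with residual
variance \(\sum w r^2/(n-2)\) — which is deliberate: the failure to
propagate weight-estimation uncertainty is precisely the mechanism that
makes `CL-W` standard errors unreliable with few, variable clusters, and
the evaluation engine is designed to expose it.

**Random-intercept logistic GLMM.** The model is
\(E[y\mid u] = \mathrm{expit}(\beta_0 + \beta_1\,\mathrm{arm} + u_j)\),
\(u_j \sim N(0, \sigma_b^2)\), giving a cluster-specific odds ratio.
Two fitting routes are provided:

* `fit_repl()` — *restricted pseudo-likelihood*: iteratively linearise the
  model to a pseudo-response \(z = \eta + (y/m - \mu)/(\mu(1-\mu))\) and
  fit the resulting linear mixed model by REML, re-expanding at the
  predicted random effects (subject-specific expansion). The pseudo-model
  has two variance components, the cluster-intercept variance and a
  residual scale \(\phi\); writing \(\sigma_b^2 = \phi\gamma\) and
  profiling \(\phi\) leaves a one-dimensional REML criterion in \(\gamma\)
  that is minimised by grid bracketing plus golden-section refinement.
  Although the fitter works on cluster totals, the REML criterion is that
  of the individual-level pseudo-model: the within-cluster pseudo-residual
  sum of squares \(m\bar y(1-\bar y)/v\) and its \(m-1\) degrees of
  freedom per cluster enter the profiled criterion. This matters — the
  within-cluster information anchors \(\phi\) near its binomial value of
  1; dropping it leaves \(\phi\) weakly identified and makes the
  doubly-iterative algorithm oscillate. The fitter is written in C++
  because the evaluation engine calls it hundreds of thousands of times.
* `fit_aq()` — *adaptive Gauss–Hermite quadrature* on the exact marginal
  likelihood, with nodes centred and scaled at each cluster's conditional
  mode and curvature. The default of 11 nodes is a sensitivity parameter;
  one node is the Laplace approximation, and the test suite checks that
  the default agrees with 51-node quadrature and with brute-force
  numerical integration. The variance is optimised on the log scale with
  a floor of `1e-12`; estimates at the floor are reported as zero and
  flagged.

Inference on \(\hat\beta_1\) uses a t distribution. Three
degrees-of-freedom rules are available through `glmm_dof()`: clusters
minus cluster-level parameters (`CP`, \(df = n-2\)); Satterthwaite
(\(df = 2\,\mathrm{Var}(\hat\beta_1)^2/\mathrm{Var}[\mathrm{Var}(\hat\beta_1)]\),
delta method on the REML information of the pseudo-model); and
Kenward–Roger, implemented as the adjusted covariance \(\Phi + 2\Lambda\)
for the standard error with the Satterthwaite degrees of freedom — for a
single-parameter test the degrees-of-freedom part of the Kenward–Roger
correction coincides with Satterthwaite, and because the pseudo-model
covariance is linear in its variance parameters the second-derivative
term of \(\Lambda\) vanishes. Satterthwaite and Kenward–Roger are defined
only for the REPL route, which carries the linear pseudo-model they
operate on.

**Logistic GEE.** The population-averaged model
\(\mathrm{logit}(\mu) = \beta_0 + \beta_1\,\mathrm{arm}\) with an
independence or exchangeable working correlation, and sandwich covariance
\(V_s = V_M[\sum_j D_j' V_{Wj}^{-1}\widehat{\mathrm{Cov}}(y_j) V_{Wj}^{-1} D_j]V_M\).
Because the covariate is cluster-constant and the working correlation is
compound-symmetric, all per-cluster matrix algebra collapses to scalars
(the working inverse enters only through \(c_j = 1/(1+(m_j-1)\alpha)\)),
so no \(m\times m\) matrix is ever formed and clusters of size 1000 cost
no more than clusters of size 5. The test suite verifies this collapsed
algebra against brute-force individual-level matrix assembly to
\(10^{-10}\). Two small-sample corrections of the sandwich are provided:
Kauermann–Carroll (`KC`), the principal inverse square root of the
cluster leverage \(I - H_j\) (in collapsed form a scalar
\((1-\mathrm{lev}_j)^{-1}\) on the residual term, undefined and flagged if
the leverage reaches 1), and Fay–Graubard (`FG`), the parameter-space
diagonal factor \((1-\min(b, [D'V_W^{-1}D\,V_M]_{kk}))^{-1/2}\) with
boundary \(b = 0.75\). The exchangeable \(\hat\alpha\) is the moment
estimator on standardised Pearson residuals with scale
\(\hat\phi = \sum r^2/(N-p)\) and divisor \(\sum m(m-1)-p\), truncated to
its validity range. Inference is t-based with \(n-2\) degrees of freedom.
GEE estimate a marginal odds ratio; the evaluation engine therefore
compares GEE estimates to the attenuated truth
\(\beta_M = \beta_C([16\sqrt3/(15\pi)]^2\sigma_b^2+1)^{-1/2}\), and the
conditional \(\beta_C\) is the truth for cluster-level and GLMM methods.

## The simulator

`generate_trial()` draws from
\(Y_{ij} \sim \mathrm{Binomial}(\mathrm{expit}(\beta_0 + \beta_1 i + u_{ij}),\, m_{ij})\)
with \(\beta_0 = \mathrm{logit}\) of the control prevalence (a
conditional, median-cluster prevalence: the marginal prevalence is
slightly larger for \(\sigma_b^2 > 0\) and is not targeted). The scenario
grid crosses:

* clusters \(n \in \{8, 12, 20, 30\}\), 1:1 allocation;
* mean cluster size \(\bar m \in \{10, 50, 1000\}\) with size CV
  \(\in \{0, 0.5, 0.8\}\) — variable sizes are \(2 + \delta\) with
  \(\delta\) negative-binomial parameterised so the size mean and
  variance are exact (minimum size 2);
* control prevalence \(\in \{0.10, 0.30\}\);
* log-odds-scale ICC \(\rho = \sigma_b^2/(\sigma_b^2 + \pi^2/3)
  \in \{0.001, 0.01, 0.05, 0.1\}\);
* cluster-effect distribution: normal, a scaled-centred Gamma(2,1)
  (skewness \(\sqrt2\)), or a uniform matched to \(\sigma_b^2\) — the
  limits within which mixed models are known to tolerate non-normality;
* intervention effect: none, or a conditional odds ratio solved for 80%
  power.

That is \(4\times3\times3\times2\times4\times3 = 864\) null cells and 864
effect cells. The defaults are the study conditions; they are not tuning
knobs.

**Effect-size calibration.** For the effect cells, `solve_effect_size()`
finds the odds ratio giving 80% power from a two-proportion calculation
with effective sample size per arm \((n/2)\bar m / DE\), where
\(DE = [1+(\bar m-1)\rho]/RE\) and
\(RE = 1 - CV^2\lambda(1-\lambda)\),
\(\lambda = \bar m\rho/(1+(\bar m-1)\rho)\), is the van
Breukelen–Candel–Berger relative efficiency for unequal cluster sizes.
Two details were settled empirically against the published bracket of
solved odds ratios (1.12 to 11.49): the ICC enters the design effect
directly on the log-odds scale (converting it to a proportion-scale ICC
caps the bracket near 8), and the power computation uses t quantiles with
\(n-2\) degrees of freedom, \(power = P(T_{n-2} > t_{0.975,n-2} -
\delta/sd)\), not normal quantiles. With these choices the package's
solved odds ratios span 1.108 to 11.553. The calibration of reference
power commands is not fully published, so targets that depend on solved
effect sizes carry wider tolerances.

## The evaluation engine

`run_grid()` simulates each scenario's repetitions once and applies every
requested method to the same datasets (paired comparison), then reports
per scenario and method: standardised bias
(\(100(\bar{\hat\beta} - \beta)/SD\)), relative SE bias
(\(100[\overline{SE}/SD - 1]\)), type-one error or power
(share of converged repetitions with \(p < 0.05\), strict inequality),
and coverage. Rates use converged repetitions only, per method — a
dataset can count for the cluster-level test and not for GEE. Type-one
error below 3.6% is labelled conservative and above 6.4% inflated: the
95% Monte-Carlo band for a true 5% rate estimated from 1000 repetitions.
Coverage is computed even though it closely tracks type-one error, for
completeness.

Reproducibility: each scenario derives its seed from the master seed and
a stable hash of the scenario id, so any grid subset, in any order, with
any number of forked workers, reproduces bitwise.

Two implementation routes coexist deliberately. The per-dataset functions
(`cl_unweighted_test()`, `fit_gee()` + `gee_sandwich()`, `fit_repl()`,
...) are the reference implementations; the engine uses vectorised
fast paths across repetitions for the cluster-level tests and the
independence-working GEE, and the batched C++ REPL fitter. The test suite
pins the fast paths to the reference functions on random scenarios.

## Convergence rules and degenerate inputs

* Cluster-level tests are non-converged only when the summaries are
  constant within both arms (zero pooled variance); constancy in one arm
  only still yields a valid pooled test.
* REPL is non-converged on reaching 100 outer iterations, on a genuine
  period-2 oscillation (state repeats two iterations back while still
  moving by more than \(10^{-3}\) relative — a damped zig-zag approaching
  the fixed point must not trip this), or when a fitted linear predictor
  pins at the \(\pm 30\) boundary (cluster-level separation). Convergence
  is a joint relative change below \(10^{-8}\) in \((\beta, \sigma_b^2)\).
  These criteria are this package's own; reference implementations in
  commercial software are doubly iterative with unpublished internals, so
  convergence *rates* are reported but are not reproduction targets.
* GEE is non-converged when the relative score norm fails to fall below
  \(10^{-10}\) within 50 iterations, when coefficients diverge, or under
  pooled separation (an arm with no events or only events). The
  Kauermann–Carroll correction is additionally flagged per repetition if
  a cluster leverage reaches 1.
* Ties in the REML criterion at \(\gamma = 0\) resolve to the boundary
  (no between-cluster variance), so degenerate, perfectly balanced data
  return \(\hat\sigma_b^2 = 0\) and the pooled logistic estimate.

## What the simulations do and do not show

The generator emulates two-arm CRTs with binomial outcomes,
negative-binomial cluster sizes, and three cluster-effect shapes. It does
not emulate covariate adjustment, stratified or restricted randomisation,
informative cluster size, overdispersion beyond the random intercept, or
missing data — conclusions from passing tests extend to real trials only
as far as those assumptions do. Performance summaries condition on
convergence, as analyses of real trials would.

## Problem sizes used in the shipped reproduction

The acceptance script and the reproduction tests use: the full 864-cell
null grid at 1000 repetitions per cell with the three headline methods
(`CL-UNW`, `REPL.DF_CP`, `FG.I.DF_CP`) sharing datasets; the 144
small-cluster/low-prevalence effect cells at 1000 repetitions for the
attenuation summary; and the effect cells with size CV 0.8 at 400 paired
repetitions for the power comparison — the power difference is a
between-method contrast on shared datasets, far less variable than the
rates themselves, so 400 repetitions resolve a 10-point contrast
comfortably. Two summary conventions are worth noting. The Fay–Graubard
classification shares are reported over the cells with mean cluster size
10 or 50 — the set on which both working correlations run, and the set
the GEE-specific summaries describe — while the three-way method
comparison uses the whole grid; both are computed, and they differ
noticeably because FG is anti-conservative with very large, variable
clusters. The power comparison excludes the low-prevalence mean-size-10
cells, where the attenuated cluster-level estimate makes its power
meaningless. Heavier settings (exchangeable GEE at \(\bar m = 1000\),
Satterthwaite/Kenward–Roger over the whole grid) are supported by the
same engine but are not part of the shipped runs.

## A worked example

```{r example}
set.seed(2026)
scn <- scenario(n_clusters = 12, mean_size = 50, cv_size = 0.5,
                control_prevalence = 0.3, icc = 0.05, effect = 2)
trial <- generate_trial(scn)
analyse_trial(trial, c("CL-UNW", "CL-W", "REPL.DF_CP", "AQ.DF_CP",
                       "FG.I.DF_CP", "FG.E.DF_CP"))
```

The estimates are log odds ratios (conditional for the first four rows,
marginal for the GEE rows), with t-based confidence intervals at the
degrees of freedom each method prescribes.

## Known limitations

* `CL-W` depends on an ICC estimator the source literature leaves
  under-specified; results for it are indicative.
* With as few as 8 clusters, the mean of a pooled-SD-based standard error
  sits a few percent below the true sampling SD (Jensen's inequality at 6
  degrees of freedom, worse under skewed cluster effects), so worst-case
  relative SE bias across a large grid can slightly exceed a 10% envelope
  even for a correctly implemented t-test.
* The REPL convergence criteria approximate, but cannot replicate,
  those of the commercial implementation it mirrors; cells with heavy
  separation (8 clusters of mean size 10 at 10% prevalence) are the most
  sensitive to this.
* The effect-size solver reproduces the published odds-ratio bracket to
  within about 1%, but the reference power command's internals are not
  published; power-dependent quantities inherit that uncertainty.
* Multi-arm trials, covariates, and non-binomial outcomes are out of
  scope.
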
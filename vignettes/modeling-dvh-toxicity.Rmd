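---
title: "Functional data analysis for DVH-based toxicity modeling: methods and design"
author: "fdantcp maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional data analysis for DVH-based toxicity modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fdantcp)
```

# The modeling problem

Normal tissue complication probability (NTCP) models relate the radiation
dose received by an organ at risk to the probability of a toxicity event.
The dosimetric input is usually the normalized cumulative dose-volume
histogram (DVH): $V_i(d)$ is the fraction of patient $i$'s organ receiving
at least dose $d$, here expressed per treatment fraction (Gy/fraction)
because acute toxicities develop while treatment is still being delivered.
Adjacent dose levels of a DVH are almost perfectly correlated across
patients, so ordinary logistic regression on sampled DVH points produces
unstable, biased coefficients. This package treats the whole curve as a
single functional covariate instead.

Two data-driven bases reduce the curves to a handful of scores:

* **FPCA** — eigendecomposition of the covariance operator
  $\Sigma(d_1,d_2) = \mathrm{E}[(V(d_1)-\mu(d_1))(V(d_2)-\mu(d_2))]$,
  giving orthonormal eigenfunctions $\xi_k(d)$ ranked by the curve variance
  $\lambda_k$ they explain (unsupervised).
* **FPLS** — components built to maximize squared covariance with the
  binary outcome, subject to mutual orthonormality (supervised).

The scores $c_{ik} = \langle V_i - \mu, \xi_k \rangle$ enter a logistic
regression with the clinical covariates $Z_{ij}$:
$$\mathrm{logit}\, P(y_i = 1) = \alpha + \sum_j \beta_j Z_{ij} +
  \sum_{k=1}^{k_n} \beta_k c_{ik},$$
and the implied dose-weighting function $\beta(d) = \sum_k \beta_k
\xi_k(d)$ is read as the relative importance of each dose level. A
curvature penalty $\tfrac{r}{2}\,\beta_f^\top R\,\beta_f$, with $R$ the
integrated squared second derivative of the components, discourages wiggly
weighting functions; clinical coefficients are never penalized. The LASSO
comparator (`fitPLR()`) instead regresses on 13 discrete DVH points
(percent volume at 0.2–2.6 Gy/fraction) plus the same clinical design.

All functional objects live on a shared uniform grid (0–2.60 Gy/fraction at
0.01 Gy), and every inner product is the rectangle-rule quadrature
$\langle f,g\rangle = \Delta d \sum_k f(d_k) g(d_k)$. At 261 grid points a
spline pre-smoothing stage adds nothing, so none is used; the generator and
all estimators share the same quadrature, which keeps recovery experiments
self-consistent.

# Numerical conventions

* **Covariance divisor** is $n$ (expectation form), so FPCA score
  variances reproduce the operator eigenvalues exactly.
* **Sign convention**: component signs are mathematically arbitrary; each
  component is flipped so its quadrature inner product with the centered
  dose ramp $d - \bar d$ is non-negative (ties broken toward a positive
  last element), making all downstream output deterministic.
* **Eigenvalue ties** ($\lambda_k - \lambda_{k+1} < 10^{-10}$) make
  individual component shapes non-identifiable; tests then assert only the
  spanned subspace.
* **IRLS**: penalized iteratively reweighted least squares, convergence
  when the largest coefficient change drops below $10^{-8}$, capped at 100
  iterations; suspected perfect separation (divergent linear predictor at
  the cap) is flagged on the fitted object rather than silently accepted.
* **Probability clipping** at $10^{-8}$ before any logit transform, with
  the clipped count recorded.
* **Second derivatives** for the penalty use central differences with
  one-sided stencils at the boundaries; the penalty matrix is exact for
  polynomial components up to degree two.

# FPLS: the projection-score compromise

For a single binary response, NIPALS partial least squares extracts weight
functions from successively deflated curve data. Three properties cannot
hold simultaneously in this setting: (i) component functions orthonormal,
(ii) scores equal to quadrature projections of the *original* centered
curves onto the components (the only rule that can also be applied to new
patients), and (iii) scores exactly uncorrelated. The deflated-data
cross-covariance at step two lies exactly in the span of the first weight
and loading, so forcing all three leaves nothing to extract.

`fplsDecompose()` therefore extracts NIPALS weights with regression
deflation, re-orthogonalizes each weight against the previous components,
and **stores projection scores** (rule (ii)). This keeps one consistent
scoring rule for training and external cohorts and makes
$\beta(d) = \sum_k \beta_k \xi_k(d)$ exactly consistent with the fitted
linear predictor. The raw deflated NIPALS scores — exactly mutually
orthogonal — are retained as an attribute for diagnostics. Projection
scores of later components may correlate with earlier ones; since the
regression uses the components jointly, only the spanned subspace matters
for prediction.

Component shapes are invariant to affine recoding of the response (it is
centered internally), and the first component is exactly the normalized
cross-covariance function $\mathrm{Cov}(V(d), y)$ — the direction with
maximal squared covariance among all unit-quadrature-norm weightings.

# Model selection

`mscSelect()` scores each candidate (leading components $k_n \le 5$,
penalty $r$ from $\{0\} \cup$ 15 log-spaced values in $[0.1, 1350]$) with
$$\mathrm{MSC}(k_n) = \log\Big[\tfrac{1}{n}\sum_i (y_i - \hat y_i)^2\Big]
  + \frac{\log(n)\,k_n}{n/2},$$
$\hat y_i$ being the fitted probability, and returns the minimizer; ties
break to the smallest $k_n$, then the largest $r$. The complexity divisor
$n/2$ is configurable (`msc_denominator = "n"`).

Because the first term is a *training* error, it is (to numerical
precision) non-increasing as the penalty weakens, so strictly positive $r$
essentially never attains the minimum and additional components enter only
when they improve training fit faster than $2\log(n)/n$ per component. On
the synthetic cohorts below this selects one component and $r = 0$ almost
always. We implement the criterion as printed and expose the full candidate
table so users can apply stricter parsimony by hand; a cross-validated
selector would be the natural extension, but is deliberately out of scope
to keep the selection rule exactly the documented one.

# The synthetic cohort generator

No patient DVH data ship with the package; `generateCohort()` produces
cohorts with the statistical structure the methods assume, plus known
ground truth for recovery studies. Each curve is a convex combination of
smooth logistic shoulders:

* a broad "body" falloff centered near 1.1 Gy/fraction (SD 0.2 across
  patients) — the gradually irradiated bulk of the organ;
* two steep shoulders at the elective and boost prescription levels
  (defaults 1.8 and 2.1 Gy/fraction, centers jittered per patient,
  SD 0.07 Gy), weighted $(1-w)$ and $w$ where the boost-overlap fraction
  $w \sim \mathrm{Beta}(2,2)$ — the varying overlap of the boost target
  with the organ dominates between-patient variance near the prescription
  doses, mirroring dual-prescription head-and-neck planning;
* a small hotspot tail (at most ~3% of volume) above the boost level, so
  the high-dose region is not variance-dead;
* a low-amplitude smooth sinusoidal perturbation (SD 0.004).

Curves are clipped to $[0,1]$, repaired to non-increasing, and anchored at
volume 1 for $d = 0$. Adjacent-dose correlations across patients exceed
0.999, reproducing the collinearity that motivates the functional approach.

Outcomes follow the functional logistic model with a monotone-increasing
default weighting function $\beta^*(d) = 16\,\mathrm{logit}^{-1}((d -
1.1)/0.3)$ — most weight above ~1 Gy/fraction. The amplitude was calibrated
once so that the functional term $\Delta d \sum_k \beta^*(d_k) V_i(d_k)$
has roughly unit log-odds standard deviation across patients, which puts
model discrimination in the published NTCP range (apparent AUC ≈ 0.75).
The intercept is found by root-finding so the cohort's expected prevalence
matches a target; the presets use 73% (mucositis-like) and 66%
(dysphagia-like), the latter with a strong concurrent-cisplatin effect
(log-odds 1.4). Clinical covariate marginals are plausible for
head-and-neck trial cohorts (75% male, 80% definitive RT, cisplatin the
dominant concurrent regimen, oropharynx the dominant site) but are *not*
matched to any real cohort's joint distribution, and no correlation
between site and chemotherapy is induced by default.

What passing tests on these cohorts do **not** show: robustness to
non-monotone artifacts, interpolated or truncated real DVHs, scoring-system
drift between cohorts, or clinical covariates correlated with dose (e.g.
unilaterally irradiated patients receiving no chemotherapy). The generator
emulates second-order structure, not treatment-planning physics.

# Validation machinery

`optimismCorrect()` implements Efron's bootstrap optimism correction for
AUC, Brier score, and calibration slope/intercept: the full recipe —
including per-replicate re-selection of components/penalty or CV re-tuning
— is refit on every resample, and
$M_{\mathrm{corrected}} = M_{\mathrm{apparent}} - \tfrac1B \sum_b
(M_{b,\mathrm{boot}} - M_{b,\mathrm{orig}})$.
Resampling is plain (unstratified); resamples that lose an outcome class or
break the recipe are redrawn, capped at $2B$ draws and logged. Calibration
slope and intercept come from one unpenalized logistic recalibration fit of
$y$ on $\mathrm{logit}(p)$ (the intercept is the value at
$\mathrm{logit}(p)=0$); a calibration-in-the-large intercept with the slope
fixed at 1 is available via `intercept_fixed_slope = TRUE`. The additive
optimism correction is applied uniformly to all four metrics.
`bootstrapORCI()` reports percentile 2.5/97.5 bootstrap intervals of the
exponentiated coefficients, with covariates absent from a replicate's
selected model contributing an odds ratio of exactly 1 — percentile rather
than BCa intervals, matching common practice for these models. Production
analyses use $B = 2000$; the examples and tests run at $B \le 200$.

One master seed fans out into named substreams (simulation, folds,
bootstrap), so changing the replicate count never perturbs the simulated
cohort, and the whole pipeline is reproducible byte for byte.

# Problem sizes used in the shipped studies

The package's own studies (tests and the acceptance script) run at desk
scale, chosen to make every stochastic assertion stable under its fixed
seed: cohorts of 60–500 patients for unit properties, $n = 1000$ with 20
seeds for weighting-function recovery, $B = 200$ for optimism and
odds-ratio machinery with 120 outer Monte-Carlo replications for the
interval-coverage study, and $B = 2000$ reserved for production use.

# Known limitations

* The printed MSC is a penalized training-error criterion; it cannot in
  practice prefer $r > 0$ (see above), so the roughness penalty matters
  mainly when a user fixes $r$ or compares fits across the exposed grid.
* With one component selected, the estimated weighting function is
  proportional to the covariance-filtered direction $\Sigma\beta^*$, not
  $\beta^*$ itself; on realistically collinear DVH cohorts the quadrature
  cosine between the two plateaus near 0.88, and regions where the curves
  do not vary (very low doses, the extreme high-dose tail) are
  structurally unidentifiable. Recovery experiments report exactly this.
* The weighting function may decrease at the highest doses without
  biophysical rationale, an acknowledged artifact of data-driven bases; a
  monotone prior would address it and is intentionally not implemented.
* No Firth correction: near-separated bootstrap replicates are flagged and
  redrawn rather than stabilized, which can matter for rare covariate
  levels at small $n$.

# A worked run

```{r example, eval = FALSE}
cohort <- generateCohort(presetMucositisLike(n_patients = 200, seed = 1))
fit <- fitNTCP(cohort, method = "fpls-lr")
attr(fit, "selection")        # component count and penalty chosen
plot(doseGrid(cohort), betaFunction(fit), type = "l",
     xlab = "dose (Gy/fraction)", ylab = "weighting function")
recipe <- ntcpRecipe("fpls-lr")
optimismCorrect(recipe, cohort, B = 200, seed = 1)
bootstrapORCI(recipe, cohort, B = 200, seed = 1)
```
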
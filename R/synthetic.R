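#' @include AllClasses.R dvh-data.R
NULL

#' Configuration for the synthetic DVH cohort generator
#'
#' The generator emulates the statistical structure of fractional-dose DVH
#' cohorts from dual-prescription-level head-and-neck radiotherapy: smooth,
#' monotone-non-increasing normalized cumulative DVHs with very high
#' adjacent-dose-level correlation, between-patient variation concentrated
#' near the two prescription dose levels (driven by the varying overlap of
#' the boost target volume with the organ at risk), a gradual patient-specific
#' low/intermediate-dose falloff, and a small high-dose hotspot tail. Binary
#' toxicity outcomes are drawn from a functional logistic model with a known
#' dose-weighting function, enabling parameter-recovery studies.
#'
#' Each curve is a convex combination of smooth logistic shoulders:
#' a broad "body" falloff centered at a patient-specific intermediate dose,
#' two steep shoulders at the elective and boost prescription levels weighted
#' by (1 - w) and w where w is the per-patient boost-overlap fraction, and a
#' small hotspot shoulder above the boost level. A low-amplitude smooth
#' sinusoidal perturbation is added, and curves are repaired (clipped to
#' [0, 1], made non-increasing, anchored at volume 1 for d = 0).
#'
#' @param n_patients cohort size (>= 2).
#' @param grid fractional-dose grid (default 0-2.6 Gy at 0.01 Gy).
#' @param prescription_doses the two prescription levels in Gy per fraction
#'   (elective, boost).
#' @param overlap_shape shape parameters of the Beta law of the per-patient
#'   boost-overlap fraction w.
#' @param curve_smoothness steepness (1/Gy) of the prescription shoulders;
#'   larger is sharper.
#' @param body_weight,body_center,body_center_sd,body_steepness the broad
#'   intermediate-dose falloff: its volume weight, mean center (Gy), patient
#'   SD of the center, and steepness.
#' @param hotspot_weight maximum volume fraction in the high-dose hotspot
#'   tail.
#' @param center_jitter_sd per-patient SD (Gy) of the prescription shoulder
#'   centers.
#' @param steepness_jitter_sd lognormal SD of per-patient steepness.
#' @param noise_sd SD of the smooth sinusoidal perturbation coefficients.
#' @param true_beta dose-weighting function beta*(d) on \code{grid}
#'   (log-odds per unit of the quadrature integral of beta*V); default a
#'   monotone-increasing logistic ramp giving most weight to doses above
#'   about 1 Gy per fraction.
#' @param true_clinical named log-odds vector over the 11 design columns of
#'   [encodeDesign()]; omitted names are 0.
#' @param true_intercept log-odds intercept; if \code{NULL} it is found by
#'   root-finding so the cohort's expected prevalence equals
#'   \code{target_prevalence}.
#' @param target_prevalence expected outcome prevalence used when
#'   \code{true_intercept} is \code{NULL}.
#' @param seed integer; fixed seed implies a fully reproducible cohort.
#' @return a \code{SimulationConfig} list.
#' @seealso [generateCohort()], [presetMucositisLike()],
#'   [presetDysphagiaLike()]
#' @export
simulationConfig <- function(n_patients = 200L,
                             grid = buildDoseGrid(0, 2.6, 0.01),
                             prescription_doses = c(1.8, 2.1),
                             overlap_shape = c(2, 2),
                             curve_smoothness = 9,
                             body_weight = 0.35,
                             body_center = 1.1,
                             body_center_sd = 0.2,
                             body_steepness = 3.5,
                             hotspot_weight = 0.03,
                             center_jitter_sd = 0.07,
                             steepness_jitter_sd = 0.2,
                             noise_sd = 0.004,
                             true_beta = NULL,
                             true_clinical = c(cisplatin = 0.8),
                             true_intercept = NULL,
                             target_prevalence = 0.5,
                             seed = 1L) {
  if (n_patients < 2) stop("n_patients must be >= 2")
  if (!isUniformGrid(grid)) stop("grid must be uniform and increasing")
  if (any(prescription_doses < min(grid)) || any(prescription_doses > max(grid)))
    stop("prescription doses must lie within the grid span")
  ## Default weighting function: monotone-increasing logistic ramp giving
  ## most weight to doses above ~1 Gy/fraction; amplitude calibrated so the
  ## functional term has roughly unit log-odds SD across patients under the
  ## default curve model (discrimination in the published NTCP range).
  if (is.null(true_beta))
    true_beta <- 16 * plogis((grid - 1.1) / 0.3)
  if (length(true_beta) != length(grid))
    stop("true_beta must be evaluated on the grid")
  gamma <- stats::setNames(numeric(length(.DESIGN_COLUMNS)), .DESIGN_COLUMNS)
  if (length(true_clinical)) {
    bad <- setdiff(names(true_clinical), .DESIGN_COLUMNS)
    if (length(bad))
      stop("unknown clinical coefficient name(s): ", paste(bad, collapse = ", "))
    gamma[names(true_clinical)] <- true_clinical
  }
  structure(list(
    n_patients = as.integer(n_patients), grid = grid,
    prescription_doses = prescription_doses, overlap_shape = overlap_shape,
    curve_smoothness = curve_smoothness, body_weight = body_weight,
    body_center = body_center, body_center_sd = body_center_sd,
    body_steepness = body_steepness, hotspot_weight = hotspot_weight,
    center_jitter_sd = center_jitter_sd,
    steepness_jitter_sd = steepness_jitter_sd, noise_sd = noise_sd,
    true_beta = true_beta, true_clinical = gamma,
    true_intercept = true_intercept, target_prevalence = target_prevalence,
    seed = as.integer(seed)), class = "SimulationConfig")
}

## Decreasing logistic shoulder: ~1 below center, ~0 above, width ~ 4/steepness.
.shoulder <- function(d, center, steepness) {
  plogis(-(d - center) * steepness)
}

#' Generate one synthetic DVH curve
#'
#' Draws one curve using the current RNG state (use [generateCohort()] for a
#' seeded cohort). The returned curve satisfies all DVH invariants: values in
#' [0, 1], non-increasing in dose, volume 1 at d = 0.
#'
#' @param config a [simulationConfig()].
#' @return numeric volume-fraction vector on \code{config$grid}.
#' @export
generateCurve <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  d <- config$grid
  p <- config$prescription_doses
  w <- stats::rbeta(1, config$overlap_shape[1L], config$overlap_shape[2L])
  jitter <- function(center) center + rnorm(1, 0, config$center_jitter_sd)
  steep <- function(base) base * exp(rnorm(1, 0, config$steepness_jitter_sd))
  a_body <- config$body_weight
  a_hot <- config$hotspot_weight * runif(1)
  a_rest <- 1 - a_body - a_hot
  c0 <- rnorm(1, config$body_center, config$body_center_sd)
  v <- a_body * .shoulder(d, c0, steep(config$body_steepness)) +
    a_rest * (1 - w) * .shoulder(d, jitter(p[1L]), steep(config$curve_smoothness)) +
    a_rest * w * .shoulder(d, jitter(p[2L]), steep(config$curve_smoothness)) +
    a_hot * .shoulder(d, rnorm(1, max(d) - 0.15, 0.1), steep(12))
  if (config$noise_sd > 0) {
    m <- seq_len(4L)
    amp <- rnorm(4L, 0, config$noise_sd)
    span <- max(d) - min(d)
    v <- v + drop(sin(outer(d - min(d), m * pi / span)) %*% amp)
  }
  v <- pmin(pmax(v, 0), 1)
  v <- rev(cummax(rev(v)))          # repair to non-increasing
  if (abs(d[1L]) < 1e-12) v[1L] <- 1
  v
}

## Sample clinical covariates with marginals typical of head-and-neck RT
## trial cohorts (mostly male, definitive RT, concurrent cisplatin common,
## oropharynx dominant).
.sampleClinical <- function(n) {
  data.frame(
    sex = sample(.SEX_LEVELS, n, replace = TRUE, prob = c(0.75, 0.25)),
    age = round(rnorm(n, 60, 9), 1),
    rt_intent = sample(.INTENT_LEVELS, n, replace = TRUE, prob = c(0.8, 0.2)),
    induction_chemo = sample(.YESNO_LEVELS, n, replace = TRUE,
                             prob = c(0.5, 0.5)),
    concurrent_chemo = sample(.CONCURRENT_LEVELS, n, replace = TRUE,
                              prob = c(0.25, 0.55, 0.12, 0.08)),
    primary_site = sample(.SITE_LEVELS, n, replace = TRUE,
                          prob = c(0.5, 0.12, 0.2, 0.1, 0.08)),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic DVH cohort with known ground truth
#'
#' Draws \code{n_patients} curves and clinical covariate rows, computes each
#' patient's true linear predictor
#' \deqn{\eta_i = \alpha + Z_i \gamma + \Delta d \sum_k \beta^*(d_k) V_i(d_k)}
#' (left-Riemann quadrature, the same rule the estimators use), and draws
#' outcomes \eqn{y_i \sim \mathrm{Bernoulli}(\mathrm{logit}^{-1} \eta_i)}.
#' When \code{config$true_intercept} is \code{NULL}, the intercept is found
#' by root-finding so that the mean of the cohort's outcome probabilities
#' equals \code{config$target_prevalence}.
#'
#' The ground truth (weighting function, clinical coefficients, intercept,
#' per-patient linear predictors) is stored in
#' \code{S4Vectors::metadata(cohort)$truth}.
#'
#' @param config a [simulationConfig()].
#' @return a [DVHCohort-class] with a \code{truth} metadata entry.
#' @export
generateCohort <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  withSeed(config$seed, {
    n <- config$n_patients
    d <- config$grid
    dd <- d[2L] - d[1L]
    vol <- vapply(seq_len(n), function(i) generateCurve(config),
                  numeric(length(d)))
    clin <- .sampleClinical(n)
    z <- encodeDesign(clin)
    eta0 <- drop(z %*% config$true_clinical) +
      dd * drop(crossprod(vol, config$true_beta))
    alpha <- config$true_intercept
    if (is.null(alpha)) {
      f <- function(a) mean(plogis(a + eta0)) - config$target_prevalence
      alpha <- uniroot(f, c(-40, 40), tol = 1e-10)$root
    }
    eta <- alpha + eta0
    y <- rbinom(n, 1L, plogis(eta))
    cohort <- DVHCohort(vol, d, clin, y)
    S4Vectors::metadata(cohort)$truth <- list(
      beta = config$true_beta, clinical = config$true_clinical,
      intercept = alpha, linear_predictor = eta,
      functional_term = dd * drop(crossprod(vol, config$true_beta)))
    cohort
  })
}

#' Preset configurations mirroring reported toxicity incidences
#'
#' Two ready-made generator configurations targeting the severe-toxicity
#' prevalences of the motivating oral-mucositis (73\%) and dysphagia (66\%)
#' modeling cohorts. Both use a monotone-increasing dose-weighting function
#' (non-decreasing below 2 Gy per fraction), giving most weight to fractional
#' doses above about 1 Gy; the dysphagia-like preset carries a strong
#' concurrent-cisplatin effect (log-odds 1.4).
#'
#' @param n_patients cohort size.
#' @param seed RNG seed.
#' @return a [simulationConfig()].
#' @export
presetMucositisLike <- function(n_patients = 200L, seed = 1L) {
  simulationConfig(n_patients = n_patients, seed = seed,
                   target_prevalence = 0.73,
                   true_clinical = c(cisplatin = 0.8))
}

#' @rdname presetMucositisLike
#' @export
presetDysphagiaLike <- function(n_patients = 200L, seed = 1L) {
  simulationConfig(n_patients = n_patients, seed = seed,
                   target_prevalence = 0.66,
                   true_clinical = c(cisplatin = 1.4))
}
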
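#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

.CONCURRENT_LEVELS <- c("none", "cisplatin", "carboplatin", "cis_carbo")
.SITE_LEVELS <- c("oropharynx_oral_cavity", "nasopharynx_nasal_cavity",
                  "hypopharynx_larynx", "parotid", "unknown_primary")
.SEX_LEVELS <- c("male", "female")
.INTENT_LEVELS <- c("definitive", "postoperative")
.YESNO_LEVELS <- c("yes", "no")

## Covariate/design column order mirrors the conventional reporting order of
## clinical odds-ratio tables for this model family.
.DESIGN_COLUMNS <- c("male", "age", "definitive_rt", "induction_chemo",
                     "cisplatin", "carboplatin", "cis_carbo",
                     "hypopharynx_larynx", "nasopharynx_nasal_cavity",
                     "unknown_primary", "parotid")

#' DVHCohort: a cohort of normalized cumulative DVH curves
#'
#' A \code{DVHCohort} extends
#' \linkS4class{SummarizedExperiment}: the \code{"volume"} assay
#' holds one normalized cumulative dose-volume histogram per patient (rows =
#' dose grid points in Gy per fraction, columns = patients), \code{rowData}
#' holds the dose grid, and \code{colData} holds the clinical covariates and
#' the binary toxicity outcome.
#'
#' Invariants enforced by the validity method: the dose grid is uniform and
#' strictly increasing; every curve is bounded in [0, 1] and non-increasing
#' in dose; when the grid starts at 0 Gy the curve starts at volume 1;
#' clinical factors are restricted to their enumerated levels; the outcome is
#' 0/1.
#'
#' @seealso [DVHCohort()] for construction, [doseGrid()], [volumeMatrix()],
#'   [outcomes()], [clinicalData()] for access.
#' @export
setClass("DVHCohort", contains = "SummarizedExperiment")

setValidity("DVHCohort", function(object) {
  msg <- character()
  if (!"volume" %in% SummarizedExperiment::assayNames(object))
    return("assay 'volume' is required")
  v <- SummarizedExperiment::assay(object, "volume")
  grid <- SummarizedExperiment::rowData(object)$dose
  if (is.null(grid))
    return("rowData column 'dose' (Gy per fraction) is required")
  if (!isUniformGrid(grid))
    msg <- c(msg, "dose grid must be uniform and strictly increasing")
  if (any(v < -1e-9 | v > 1 + 1e-9))
    msg <- c(msg, sprintf("volume fractions outside [0,1] for patient(s): %s",
                          paste(colnames(v)[colSums(v < -1e-9 | v > 1 + 1e-9) > 0],
                                collapse = ", ")))
  nonmono <- vapply(seq_len(ncol(v)), function(j) any(diff(v[, j]) > 1e-9),
                    logical(1))
  if (any(nonmono))
    msg <- c(msg, sprintf("non-monotone DVH curve(s) for patient(s): %s",
                          paste(colnames(v)[nonmono], collapse = ", ")))
  if (length(grid) && abs(grid[1L]) < 1e-12 && ncol(v) &&
      any(abs(v[1L, ] - 1) > 1e-6))
    msg <- c(msg, "curves on a grid starting at 0 Gy must start at volume 1")
  cd <- SummarizedExperiment::colData(object)
  req <- c("sex", "age", "rt_intent", "induction_chemo", "concurrent_chemo",
           "primary_site", "outcome")
  missing <- setdiff(req, colnames(cd))
  if (length(missing))
    msg <- c(msg, sprintf("missing colData column(s): %s",
                          paste(missing, collapse = ", ")))
  if ("outcome" %in% colnames(cd) && !all(cd$outcome %in% c(0L, 1L)))
    msg <- c(msg, "outcome must be binary 0/1")
  checkLevels <- function(col, levels) {
    if (col %in% colnames(cd) && !all(as.character(cd[[col]]) %in% levels))
      sprintf("invalid %s level(s): %s", col,
              paste(setdiff(unique(as.character(cd[[col]])), levels),
                    collapse = ", "))
    else NULL
  }
  msg <- c(msg,
           checkLevels("sex", .SEX_LEVELS),
           checkLevels("rt_intent", .INTENT_LEVELS),
           checkLevels("induction_chemo", .YESNO_LEVELS),
           checkLevels("concurrent_chemo", .CONCURRENT_LEVELS),
           checkLevels("primary_site", .SITE_LEVELS))
  if (length(msg)) msg else TRUE
})

#' FunctionalBasis: FPCA or FPLS component functions and scores
#'
#' Holds an ordered set of component functions on a shared dose grid, the
#' training mean function, per-component variance summaries, and the n x k
#' matrix of per-patient scores. Components are orthonormal under the
#' quadrature inner product \eqn{\langle f,g\rangle = \Delta d \sum_k
#' f(d_k) g(d_k)}.
#'
#' @slot grid numeric dose grid (Gy per fraction), uniform spacing.
#' @slot kind \code{"fpca"} or \code{"fpls"}.
#' @slot components p x k matrix, one column per component function.
#' @slot eigenvalues per-component variance: covariance-operator eigenvalues
#'   for FPCA; score variances (divisor n) for FPLS.
#' @slot totalVariance total quadrature variance of the training curves, the
#'   denominator of [varianceExplained()].
#' @slot meanFunction training mean curve on \code{grid}.
#' @slot scores n x k matrix of quadrature projections of centered training
#'   curves onto the components.
#' @export
setClass("FunctionalBasis",
         representation(grid = "numeric",
                        kind = "character",
                        components = "matrix",
                        eigenvalues = "numeric",
                        totalVariance = "numeric",
                        meanFunction = "numeric",
                        scores = "matrix"))

setValidity("FunctionalBasis", function(object) {
  msg <- character()
  p <- length(object@grid)
  if (!isUniformGrid(object@grid))
    msg <- c(msg, "grid must be uniform and strictly increasing")
  if (!object@kind %in% c("fpca", "fpls"))
    msg <- c(msg, "kind must be 'fpca' or 'fpls'")
  if (nrow(object@components) != p)
    msg <- c(msg, "components must have one row per grid point")
  if (length(object@meanFunction) != p)
    msg <- c(msg, "meanFunction must match grid length")
  k <- ncol(object@components)
  if (length(object@eigenvalues) != k)
    msg <- c(msg, "one eigenvalue per component required")
  if (k && ncol(object@scores) != k)
    msg <- c(msg, "scores must have one column per component")
  if (k && p > 1) {
    dd <- object@grid[2L] - object@grid[1L]
    g <- dd * crossprod(object@components)
    if (max(abs(g - diag(k))) > 1e-6)
      msg <- c(msg, "components must be orthonormal under the quadrature inner product")
  }
  if (any(object@eigenvalues < -1e-10))
    msg <- c(msg, "eigenvalues must be non-negative")
  if (length(msg)) msg else TRUE
})

#' FunctionalLogisticModel: fitted functional logistic regression
#'
#' The fitted NTCP model
#' \deqn{\mathrm{logit}\, P(y_i = 1) = \alpha + \sum_j \beta_j Z_{ij} +
#'   \int \beta(d) V_i(d)\, dd}
#' with the functional term expanded in \code{kn} leading components of a
#' [FunctionalBasis] and the coefficient function \eqn{\beta(d) = \sum_k
#' \beta_k \xi_k(d)}. Fitting penalizes the curvature of \eqn{\beta(d)}
#' through the component coefficients only; clinical coefficients are never
#' penalized.
#'
#' @slot intercept log-odds intercept.
#' @slot clinicalCoefficients named log-odds per design-matrix column.
#' @slot functionalCoefficients log-odds per unit component score.
#' @slot basis the training [FunctionalBasis].
#' @slot kn number of leading components used.
#' @slot r roughness penalty multiplier (dimensionless).
#' @slot converged logical IRLS convergence flag.
#' @slot nIterations IRLS iterations used.
#' @slot referenceLevels dropped reference categories of the design coding.
#' @export
setClass("FunctionalLogisticModel",
         representation(intercept = "numeric",
                        clinicalCoefficients = "numeric",
                        functionalCoefficients = "numeric",
                        basis = "FunctionalBasis",
                        kn = "integer",
                        r = "numeric",
                        converged = "logical",
                        nIterations = "integer",
                        referenceLevels = "character"))

#' SelectionResult: model-selection trace over (component count, penalty)
#'
#' @slot table data.frame of candidates: \code{kn}, \code{r}, \code{msc},
#'   \code{converged}.
#' @slot kn selected leading-component count.
#' @slot r selected roughness penalty.
#' @export
setClass("SelectionResult",
         representation(table = "data.frame", kn = "integer", r = "numeric"))

#' PLRModel: LASSO-penalized logistic regression on discrete DVH points
#'
#' The comparator model: L1-penalized logistic regression on 13 DVH volume
#' columns (percent organ volume receiving at least each dose level) plus the
#' clinical design columns, with the penalty chosen by stratified 10-fold
#' cross-validation maximizing mean out-of-fold AUC.
#'
#' @slot intercept unpenalized intercept (log-odds).
#' @slot coefficients named vector over all penalized columns, on the
#'   original covariate scale; exact zeros correspond to odds ratio 1.
#' @slot lambda selected penalty strength.
#' @slot cvTable data.frame with one row per path value: \code{lambda},
#'   \code{mean_auc}.
#' @slot doseGrid the discrete dose levels (Gy per fraction) of the Vx block.
#' @export
setClass("PLRModel",
         representation(intercept = "numeric",
                        coefficients = "numeric",
                        lambda = "numeric",
                        cvTable = "data.frame",
                        doseGrid = "numeric"))

#' ValidationReport: apparent and optimism-corrected performance
#'
#' Bootstrap internal validation of a model recipe: for each metric
#' (AUC, Brier score, calibration slope, calibration intercept) the apparent
#' value, the mean bootstrap optimism, and the optimism-corrected value
#' (corrected = apparent - mean optimism).
#'
#' @slot metrics data.frame with columns \code{metric}, \code{apparent},
#'   \code{optimism}, \code{corrected}.
#' @slot B bootstrap replicate count.
#' @slot replicates per-replicate metric table (boot and original columns).
#' @slot nRedrawn replicates redrawn because a resample lost an outcome class
#'   or the recipe failed.
#' @export
setClass("ValidationReport",
         representation(metrics = "data.frame",
                        B = "integer",
                        replicates = "data.frame",
                        nRedrawn = "integer"))

#' ORTable: bootstrap percentile odds-ratio confidence intervals
#'
#' @slot table data.frame with columns \code{covariate}, \code{or},
#'   \code{ci_low}, \code{ci_high}, \code{significant}.
#' @slot B bootstrap replicate count.
#' @export
setClass("ORTable",
         representation(table = "data.frame", B = "integer"))
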
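#' @include AllClasses.R
NULL

#' Dose grid of an object
#'
#' The shared uniform fractional-dose grid (Gy per fraction) on which curves,
#' component functions and coefficient functions are evaluated.
#'
#' @param x a [DVHCohort], [FunctionalBasis] or [FunctionalLogisticModel].
#' @return numeric vector of strictly increasing, uniformly spaced doses.
#' @export
setGeneric("doseGrid", function(x) standardGeneric("doseGrid"))

#' @rdname doseGrid
#' @export
setGeneric("doseStep", function(x) standardGeneric("doseStep"))

#' DVH volume matrix
#'
#' @param x a [DVHCohort].
#' @return numeric matrix, rows = dose grid points, columns = patients,
#'   entries = normalized volume fraction receiving at least that dose.
#' @export
setGeneric("volumeMatrix", function(x) standardGeneric("volumeMatrix"))

#' Binary toxicity outcomes of a cohort
#'
#' @param x a [DVHCohort].
#' @return integer vector, 1 = severe toxicity.
#' @export
setGeneric("outcomes", function(x) standardGeneric("outcomes"))

#' Clinical covariate table of a cohort
#'
#' @param x a [DVHCohort].
#' @return a \code{DataFrame} with the clinical covariate columns.
#' @export
setGeneric("clinicalData", function(x) standardGeneric("clinicalData"))

#' Component functions of a basis
#'
#' @param x a [FunctionalBasis].
#' @return p x k matrix of component functions on the dose grid.
#' @export
setGeneric("basisComponents", function(x) standardGeneric("basisComponents"))

#' Per-patient component scores
#'
#' @param x a [FunctionalBasis].
#' @return n x k matrix of quadrature projections of centered curves.
#' @export
setGeneric("basisScores", function(x) standardGeneric("basisScores"))

#' Training mean curve of a basis
#'
#' @param x a [FunctionalBasis].
#' @return numeric vector on the dose grid.
#' @export
setGeneric("meanCurve", function(x) standardGeneric("meanCurve"))

#' Component variances
#'
#' Covariance-operator eigenvalues for FPCA; per-component score variances
#' for FPLS.
#'
#' @param x a [FunctionalBasis].
#' @return numeric vector.
#' @export
setGeneric("componentVariances", function(x) standardGeneric("componentVariances"))

#' Fraction of total curve variance attributed to components
#'
#' Each component's variance divided by the total quadrature variance of the
#' training curves, reported in percent. The fractions over all retained
#' components sum to at most 100.
#'
#' @param x a [FunctionalBasis].
#' @param k report the first \code{k} components (default: all).
#' @return numeric vector of percentages.
#' @export
setGeneric("varianceExplained",
           function(x, k = ncol(basisComponents(x))) standardGeneric("varianceExplained"))

#' Dose-weighting coefficient function of a fitted functional model
#'
#' Reconstructs \eqn{\beta(d) = \sum_{k=1}^{k_n} \beta_k \xi_k(d)} on the
#' model's dose grid. Interpreted as the relative importance of each
#' fractional dose level for the toxicity log-odds.
#'
#' @param model a [FunctionalLogisticModel].
#' @return numeric vector on the model grid.
#' @export
setGeneric("betaFunction", function(model) standardGeneric("betaFunction"))
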
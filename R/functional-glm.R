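#' @include AllClasses.R AllGenerics.R fpca.R fpls.R
NULL

## Discrete second-derivative operator on a uniform grid: central differences
## in the interior, first-order one-sided stencils at the boundaries.
.secondDerivOperator <- function(grid) {
  p <- length(grid)
  if (p < 3L) stop("a grid with at least 3 points is required")
  dd <- grid[2L] - grid[1L]
  D <- matrix(0, p, p)
  for (i in 2:(p - 1L)) D[i, (i - 1L):(i + 1L)] <- c(1, -2, 1)
  D[1L, 1:3] <- c(1, -2, 1)
  D[p, (p - 2L):p] <- c(1, -2, 1)
  D / dd^2
}

#' Curvature penalty matrix for component coefficients
#'
#' Roughness of the coefficient function \eqn{\beta(d) = \sum_k \beta_k
#' \xi_k(d)} is measured by the integrated squared second derivative;
#' expanding in the components gives the quadratic form \eqn{\beta^T R
#' \beta} with \eqn{R_{jk} = \Delta d \sum_d \xi_j''(d)\, \xi_k''(d)}.
#' Second derivatives use central differences (one-sided at the
#' boundaries). R is symmetric positive semidefinite; a linear component
#' function contributes a zero row and column.
#'
#' @param basis a [FunctionalBasis-class].
#' @param k use the first \code{k} components (default: all).
#' @return k x k symmetric PSD matrix.
#' @export
penaltyMatrix <- function(basis, k = ncol(basisComponents(basis))) {
  stopifnot(methods::is(basis, "FunctionalBasis"))
  g <- basis@grid
  dd <- g[2L] - g[1L]
  D <- .secondDerivOperator(g)
  xi2 <- D %*% basis@components[, seq_len(k), drop = FALSE]
  R <- dd * crossprod(xi2)
  (R + t(R)) / 2
}

## Penalized IRLS for logistic regression. x: n x q full design including
## intercept column; penalty: q x q (zero rows/cols for unpenalized terms).
## Maximizes loglik - 0.5 * t(beta) %*% penalty %*% beta.
.irlsLogistic <- function(x, y, penalty = NULL, tol = 1e-8, max_iter = 100L) {
  n <- nrow(x)
  q <- ncol(x)
  if (is.null(penalty)) penalty <- matrix(0, q, q)
  qrx <- qr(x)
  if (qrx$rank < q) {
    unpen <- which(colSums(abs(penalty)) == 0)
    if (qr(x[, unpen, drop = FALSE])$rank < length(unpen)) {
      bad <- colnames(x)[qrx$pivot[(qrx$rank + 1L):q]]
      stop("collinear design column(s): ", paste(bad, collapse = ", "))
    }
  }
  beta <- numeric(q)
  beta[1L] <- qlogis(min(max(mean(y), 1e-6), 1 - 1e-6))
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    z <- eta + (y - p) / w
    xtw <- t(x * w)
    beta_new <- tryCatch(
      solve(xtw %*% x + penalty, xtw %*% z),
      error = function(e) stop("penalized IRLS system is singular: ",
                               conditionMessage(e)))
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol) { converged <- TRUE; break }
  }
  eta <- drop(x %*% beta)
  separated <- !converged && max(abs(eta)) > 30
  list(beta = beta, converged = converged, iterations = iter,
       separated = separated,
       loglik = sum(y * eta - log1p(exp(eta))))
}

#' Fit a penalized functional logistic regression
#'
#' Maximizes the Bernoulli log-likelihood of
#' \deqn{\mathrm{logit}\,P(y_i=1) = \alpha + \sum_j \beta_j Z_{ij} +
#' \sum_{k=1}^{k_n} \beta_k c_{ik}}
#' minus the curvature penalty \eqn{(r/2)\, \beta_f^T R\, \beta_f} on the
#' functional coefficient block only, by iteratively reweighted least
#' squares (penalized weighted least squares per iteration). Clinical
#' coefficients and the intercept are never penalized. Convergence when the
#' largest coefficient change falls below 1e-8, capped at 100 iterations;
#' perfect separation is flagged via the \code{converged} slot with finite
#' coefficients returned at the iteration cap.
#'
#' @param basis a [FunctionalBasis-class] trained on the cohort's curves.
#' @param cohort a [DVHCohort-class] (provides clinical covariates and
#'   outcome), or \code{NULL} when \code{scores}, \code{design}, \code{y}
#'   are given directly.
#' @param k_n number of leading components to include.
#' @param r roughness penalty multiplier (>= 0).
#' @param scores,design,y low-level inputs overriding \code{cohort}:
#'   n x k score matrix, n x q clinical design matrix (possibly zero
#'   columns), binary outcome.
#' @return a [FunctionalLogisticModel-class].
#' @export
fitFunctionalLogistic <- function(basis, cohort = NULL, k_n = NULL, r = 0,
                                  scores = NULL, design = NULL, y = NULL) {
  stopifnot(methods::is(basis, "FunctionalBasis"))
  if (r < 0) stop("penalty r must be non-negative")
  ref <- character()
  if (!is.null(cohort)) {
    if (is.null(scores)) scores <- projectScores(basis, cohort)
    if (is.null(design)) {
      design <- encodeDesign(as.data.frame(clinicalData(cohort)))
      ref <- attr(design, "reference_levels")
    }
    if (is.null(y)) y <- outcomes(cohort)
  }
  if (is.null(scores) || is.null(y)) stop("scores and y are required")
  scores <- as.matrix(scores)
  if (is.null(k_n)) k_n <- ncol(scores)
  k_n <- as.integer(k_n)
  if (k_n > ncol(scores)) stop("k_n exceeds available score columns")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  sc <- scores[, seq_len(k_n), drop = FALSE]
  if (is.null(design)) design <- matrix(0, length(y), 0L)
  design <- as.matrix(design)
  x <- cbind(`(Intercept)` = 1, sc, design)
  q <- ncol(x)
  penalty <- matrix(0, q, q)
  if (k_n > 0L && r > 0) {
    R <- penaltyMatrix(basis, k_n)
    penalty[1L + seq_len(k_n), 1L + seq_len(k_n)] <- r * R
  }
  fit <- .irlsLogistic(x, y, penalty)
  if (fit$separated)
    warning("possible perfect separation: IRLS did not converge; ",
            "coefficients returned at the iteration cap")
  beta <- fit$beta
  fcoef <- beta[1L + seq_len(k_n)]
  names(fcoef) <- colnames(sc)
  ccoef <- if (ncol(design)) {
    stats::setNames(beta[(1L + k_n + 1L):q], colnames(design))
  } else numeric()
  methods::new("FunctionalLogisticModel",
               intercept = unname(beta[1L]),
               clinicalCoefficients = ccoef,
               functionalCoefficients = fcoef,
               basis = basis, kn = k_n, r = as.numeric(r),
               converged = fit$converged,
               nIterations = as.integer(fit$iterations),
               referenceLevels = if (length(ref)) ref else character())
}

#' @rdname betaFunction
#' @export
setMethod("betaFunction", "FunctionalLogisticModel", function(model) {
  k <- model@kn
  if (k == 0L) return(numeric(length(model@basis@grid)))
  drop(model@basis@components[, seq_len(k), drop = FALSE] %*%
         model@functionalCoefficients)
})

#' @rdname doseGrid
#' @export
setMethod("doseGrid", "FunctionalLogisticModel", function(x) x@basis@grid)

setMethod("show", "FunctionalLogisticModel", function(object) {
  cat(sprintf(
    "FunctionalLogisticModel (%s): k_n = %d, r = %.4g, %s in %d iterations\n",
    object@basis@kind, object@kn, object@r,
    if (object@converged) "converged" else "NOT converged",
    object@nIterations))
  cat(sprintf("  intercept: %.4f\n", object@intercept))
  if (length(object@functionalCoefficients))
    cat("  functional coefficients:",
        paste(sprintf("%.4g", object@functionalCoefficients), collapse = " "),
        "\n")
})

#' Predicted toxicity probabilities from a functional model
#'
#' Scores for the new curves are computed against the model's training mean
#' and components; the clinical design uses the same reference coding. No
#' refitting occurs, so the same call serves internal and external
#' validation.
#'
#' @param object a [FunctionalLogisticModel-class].
#' @param cohort a [DVHCohort-class] on the model's dose grid.
#' @return numeric probabilities strictly inside (0, 1).
#' @export
setMethod("predict", "FunctionalLogisticModel", function(object, cohort) {
  eta <- linearPredictor(object, cohort)
  plogis(eta)
})

#' Linear predictor of a functional logistic model
#'
#' @inheritParams predict,FunctionalLogisticModel-method
#' @param model a [FunctionalLogisticModel-class].
#' @return numeric log-odds per patient.
#' @export
linearPredictor <- function(model, cohort) {
  stopifnot(methods::is(model, "FunctionalLogisticModel"),
            methods::is(cohort, "DVHCohort"))
  eta <- rep(model@intercept, ncol(cohort))
  if (model@kn > 0L) {
    sc <- projectScores(model@basis, cohort)[, seq_len(model@kn),
                                             drop = FALSE]
    eta <- eta + drop(sc %*% model@functionalCoefficients)
  }
  if (length(model@clinicalCoefficients)) {
    z <- encodeDesign(as.data.frame(clinicalData(cohort)))
    eta <- eta + drop(z[, names(model@clinicalCoefficients), drop = FALSE] %*%
                        model@clinicalCoefficients)
  }
  eta
}

#' Model selection over component count and roughness penalty
#'
#' Evaluates candidate models over leading-component prefixes (1, ...,
#' \code{component_budget}) crossed with a roughness-penalty grid, scoring
#' each fit by the BIC-style criterion
#' \deqn{\mathrm{MSC}(k_n) = \log\Big[\frac{1}{n}\sum_i (y_i - \hat y_i)^2
#' \Big] + \frac{\log(n)\, k_n}{n/2}}
#' where \eqn{\hat y_i} is the fitted probability. The minimizing pair is
#' selected; ties break to the smallest \eqn{k_n}, then the largest penalty
#' (parsimony first, then strongest smoothing).
#'
#' @param basis a [FunctionalBasis-class] (FPCA or FPLS) on the cohort.
#' @param cohort a [DVHCohort-class], or \code{NULL} with low-level inputs.
#' @param component_budget largest component prefix considered (default 5).
#' @param r_grid roughness penalty candidates; default \code{0} plus 15
#'   log-spaced values spanning 0.1 to 1350.
#' @param msc_denominator \code{"n/2"} (default) or \code{"n"}: divisor of
#'   the complexity term.
#' @param scores,design,y low-level overrides as in
#'   [fitFunctionalLogistic()].
#' @return a [SelectionResult-class].
#' @export
mscSelect <- function(basis, cohort = NULL,
                      component_budget = 5L,
                      r_grid = defaultPenaltyGrid(),
                      msc_denominator = c("n/2", "n"),
                      scores = NULL, design = NULL, y = NULL) {
  msc_denominator <- match.arg(msc_denominator)
  if (!is.null(cohort)) {
    if (is.null(scores)) scores <- projectScores(basis, cohort)
    if (is.null(design))
      design <- encodeDesign(as.data.frame(clinicalData(cohort)))
    if (is.null(y)) y <- outcomes(cohort)
  }
  if (!0 %in% r_grid) r_grid <- c(0, r_grid)
  component_budget <- min(component_budget, ncol(scores))
  n <- length(y)
  div <- if (msc_denominator == "n/2") n / 2 else n
  rows <- list()
  for (kn in seq_len(component_budget)) {
    for (r in r_grid) {
      res <- tryCatch({
        m <- fitFunctionalLogistic(basis, k_n = kn, r = r, scores = scores,
                                   design = design, y = y)
        sc <- scores[, seq_len(kn), drop = FALSE]
        eta <- m@intercept + drop(sc %*% m@functionalCoefficients)
        if (length(m@clinicalCoefficients))
          eta <- eta + drop(design[, names(m@clinicalCoefficients),
                                   drop = FALSE] %*% m@clinicalCoefficients)
        p <- plogis(eta)
        msc <- log(mean((y - p)^2)) + log(n) * kn / div
        list(msc = msc, converged = m@converged, error = NA_character_)
      }, warning = function(w) {
        suppressWarnings({
          m <- fitFunctionalLogistic(basis, k_n = kn, r = r, scores = scores,
                                     design = design, y = y)
          sc <- scores[, seq_len(kn), drop = FALSE]
          eta <- m@intercept + drop(sc %*% m@functionalCoefficients)
          if (length(m@clinicalCoefficients))
            eta <- eta + drop(design[, names(m@clinicalCoefficients),
                                     drop = FALSE] %*% m@clinicalCoefficients)
          p <- plogis(eta)
          list(msc = log(mean((y - p)^2)) + log(n) * kn / div,
               converged = m@converged, error = conditionMessage(w))
        })
      }, error = function(e) list(msc = NA_real_, converged = FALSE,
                                  error = conditionMessage(e)))
      rows[[length(rows) + 1L]] <- data.frame(
        kn = kn, r = r, msc = res$msc, converged = res$converged,
        note = res$error, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ok <- which(!is.na(tab$msc))
  if (!length(ok)) {
    stop("all candidate fits failed:\n",
         paste(sprintf("  kn=%d r=%.4g: %s", tab$kn, tab$r, tab$note),
               collapse = "\n"))
  }
  ## argmin with deterministic tie-breaking: smallest kn, then largest r
  cand <- tab[ok, ]
  best <- cand[cand$msc <= min(cand$msc) + 1e-12, ]
  best <- best[order(best$kn, -best$r), ][1L, ]
  methods::new("SelectionResult", table = tab,
               kn = as.integer(best$kn), r = as.numeric(best$r))
}

#' Default roughness-penalty search grid
#'
#' Zero plus 15 log-spaced values from 0.1 to 1350 (endpoints included),
#' spanning the range searched in practice for curvature penalization of
#' DVH coefficient functions.
#'
#' @return numeric vector of candidate penalties.
#' @export
defaultPenaltyGrid <- function() {
  c(0, exp(seq(log(0.1), log(1350), length.out = 15L)))
}

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: selected k_n = %d, r = %.4g over %d candidates\n",
              object@kn, object@r, nrow(object@table)))
})

#' Fit an NTCP model to a DVH cohort
#'
#' High-level wrapper chaining basis extraction (FPCA or FPLS), model
#' selection over component count and roughness penalty, and the final
#' penalized functional logistic fit; or the LASSO comparator via
#' [fitPLR()]. This is the "recipe" applied from scratch inside every
#' bootstrap replicate of the validation suite, so hyperparameter tuning is
#' repeated per replicate.
#'
#' @param cohort a [DVHCohort-class].
#' @param method \code{"fpls-lr"}, \code{"fpc-lr"} or \code{"plr"}.
#' @param component_budget,r_grid,msc_denominator see [mscSelect()].
#' @param folds,fold_seed,lambda_path PLR options, see [fitPLR()].
#' @return a [FunctionalLogisticModel-class] (with the selection trace in
#'   attribute \code{"selection"}) or a [PLRModel-class].
#' @examples
#' cohort <- generateCohort(presetMucositisLike(n_patients = 80, seed = 7))
#' fit <- fitNTCP(cohort, "fpls-lr", component_budget = 2,
#'                r_grid = c(0, 10))
#' head(predict(fit, cohort))
#' @export
fitNTCP <- function(cohort, method = c("fpls-lr", "fpc-lr", "plr"),
                    component_budget = 5L, r_grid = defaultPenaltyGrid(),
                    msc_denominator = "n/2", folds = 10L, fold_seed = 1L,
                    lambda_path = NULL) {
  method <- match.arg(method)
  if (method == "plr")
    return(fitPLR(cohort, lambda_path = lambda_path, folds = folds,
                  fold_seed = fold_seed))
  k_extract <- min(component_budget, ncol(cohort) - 1L, nrow(cohort))
  basis <- if (method == "fpls-lr") {
    fplsDecompose(cohort, k_max = k_extract)
  } else {
    fpcaDecompose(cohort, k_max = k_extract)
  }
  sel <- mscSelect(basis, cohort, component_budget = k_extract,
                   r_grid = r_grid, msc_denominator = msc_denominator)
  model <- suppressWarnings(
    fitFunctionalLogistic(basis, cohort, k_n = sel@kn, r = sel@r))
  attr(model, "selection") <- sel
  model
}
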
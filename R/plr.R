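#' @include AllClasses.R dvh-data.R
NULL

.PLR_GRID <- function() buildDoseGrid(0.2, 2.6, 0.2)

#' Design matrix for the LASSO comparator model
#'
#' Resamples each DVH curve to the 13-point coarse grid (0.2 to 2.6 Gy per
#' fraction at 0.2-Gy intervals) and expresses the volume columns in percent
#' (0-100), so odds ratios are per percent organ volume; appends the 11
#' clinical design columns of [encodeDesign()]. Column names follow the
#' V020...V260 convention (dose level in cGy per fraction).
#'
#' @param cohort a [DVHCohort-class].
#' @return n x 24 numeric matrix.
#' @export
buildPLRDesign <- function(cohort) {
  stopifnot(methods::is(cohort, "DVHCohort"))
  g <- doseGrid(cohort)
  target <- .PLR_GRID()
  if (min(target) < min(g) - 1e-9 || max(target) > max(g) + 1e-9)
    stop("cohort grid does not span the 0.2-2.6 Gy comparator grid")
  v <- volumeMatrix(cohort)
  vx <- t(apply(v, 2L, function(col) resampleCurve(col, g, target))) * 100
  colnames(vx) <- sprintf("V%03.0f", target * 100)
  z <- encodeDesign(as.data.frame(clinicalData(cohort)))
  cbind(vx, z)
}

## Mann-Whitney AUC of predictions s against labels y (ties count 1/2);
## shared by CV tuning and the validation module.
.aucRank <- function(y, s) {
  y <- as.integer(y)
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both outcome classes are required for AUC")
  r <- rank(s, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

## Stratified fold assignment: each fold receives a balanced share of both
## outcome classes; redrawn (up to 50 times) if any training fold would lose
## a class.
.stratifiedFolds <- function(y, folds, seed) {
  n <- length(y)
  withSeed(seed, {
    for (attempt in 1:50) {
      fold <- integer(n)
      for (cls in unique(y)) {
        idx <- sample(which(y == cls))
        fold[idx] <- rep_len(seq_len(folds), length(idx))
      }
      ok <- all(vapply(seq_len(folds), function(f)
        length(unique(y[fold != f])) == 2L, logical(1)))
      if (ok) return(fold)
    }
    stop("could not build folds with both classes in every training split")
  })
}

#' LASSO-penalized logistic regression on discrete DVH points
#'
#' The comparator model: L1-penalized logistic regression (via
#' \pkg{glmnet} coordinate descent) on the 13 Vx columns plus the 11
#' clinical columns of [buildPLRDesign()]. All covariate columns are
#' penalized (internally standardized; coefficients are reported on the
#' original scale); the intercept is unpenalized. The penalty is chosen by
#' stratified k-fold cross-validation maximizing the mean out-of-fold AUC,
#' with ties resolved toward the larger (sparser) penalty, and the final
#' model is refit on all data at the selected penalty.
#'
#' @param cohort a [DVHCohort-class].
#' @param lambda_path descending penalty sequence; default 100 log-spaced
#'   values from the smallest all-zero penalty down four decades.
#' @param folds number of CV folds (default 10).
#' @param fold_seed seed for the stratified fold assignment (redrawn per
#'   bootstrap replicate by the validation suite).
#' @return a [PLRModel-class].
#' @export
fitPLR <- function(cohort, lambda_path = NULL, folds = 10L, fold_seed = 1L) {
  stopifnot(methods::is(cohort, "DVHCohort"))
  x <- buildPLRDesign(cohort)
  y <- outcomes(cohort)
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  if (is.null(lambda_path)) {
    ## largest |standardized-score| gives the smallest all-zero penalty;
    ## constant columns contribute nothing after centering
    sds <- pmax(apply(x, 2L, sd), 1e-9)
    xs <- sweep(sweep(x, 2L, colMeans(x)), 2L, sds, "/")
    lmax <- max(abs(crossprod(xs, y - mean(y)))) / length(y)
    lambda_path <- exp(seq(log(lmax * 1.05), log(lmax * 1.05e-4),
                           length.out = 100L))
  }
  lambda_path <- sort(lambda_path, decreasing = TRUE)
  fold <- .stratifiedFolds(y, folds, fold_seed)
  auc_mat <- matrix(NA_real_, length(lambda_path), folds)
  for (f in seq_len(folds)) {
    tr <- fold != f
    fit_f <- suppressWarnings(
      glmnet::glmnet(x[tr, , drop = FALSE], y[tr], family = "binomial",
                     lambda = lambda_path, standardize = TRUE,
                     maxit = 3e5))
    pred <- predict(fit_f, newx = x[!tr, , drop = FALSE], s = lambda_path,
                    type = "link")
    y_te <- y[!tr]
    if (length(unique(y_te)) == 2L)
      auc_mat[, f] <- apply(pred, 2L, function(s) .aucRank(y_te, s))
  }
  mean_auc <- rowMeans(auc_mat, na.rm = TRUE)
  best <- max(mean_auc)
  sel <- which(mean_auc >= best - 1e-12)[1L]  # path is descending: sparsest
  lambda_star <- lambda_path[sel]
  fit <- suppressWarnings(
    glmnet::glmnet(x, y, family = "binomial", lambda = lambda_path,
                   standardize = TRUE, maxit = 3e5))
  cf <- as.numeric(predict(fit, s = lambda_star, type = "coefficients",
                           exact = FALSE))
  names(cf) <- c("(Intercept)", colnames(x))
  methods::new("PLRModel",
               intercept = unname(cf[1L]),
               coefficients = cf[-1L],
               lambda = lambda_star,
               cvTable = data.frame(lambda = lambda_path,
                                    mean_auc = mean_auc),
               doseGrid = .PLR_GRID())
}

setMethod("show", "PLRModel", function(object) {
  nz <- sum(abs(object@coefficients) > 0)
  cat(sprintf("PLRModel: lambda = %.4g, %d/%d nonzero coefficients\n",
              object@lambda, nz, length(object@coefficients)))
})

#' @describeIn fitPLR predicted severe-toxicity probabilities for a cohort.
#' @param object a [PLRModel-class].
#' @export
setMethod("predict", "PLRModel", function(object, cohort) {
  x <- buildPLRDesign(cohort)
  eta <- object@intercept +
    drop(x[, names(object@coefficients), drop = FALSE] %*% object@coefficients)
  plogis(eta)
})

#' Odds ratios of a fitted model
#'
#' Exponentiated coefficients; LASSO-zeroed coefficients give odds ratio
#' exactly 1.
#'
#' @param model a [PLRModel-class] or [FunctionalLogisticModel-class].
#' @return named numeric vector (intercept included).
#' @export
oddsRatios <- function(model) {
  if (methods::is(model, "PLRModel")) {
    exp(c("(Intercept)" = model@intercept, model@coefficients))
  } else if (methods::is(model, "FunctionalLogisticModel")) {
    exp(c("(Intercept)" = model@intercept, model@clinicalCoefficients,
          model@functionalCoefficients))
  } else stop("unsupported model type")
}
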
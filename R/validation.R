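#' @include AllClasses.R functional-glm.R plr.R
NULL

#' Area under the ROC curve
#'
#' Mann-Whitney estimator: the probability that a randomly chosen positive
#' receives a higher prediction than a randomly chosen negative, ties
#' counting one half. Invariant under strictly monotone transforms of the
#' predictions.
#'
#' @param y binary outcomes (both classes required).
#' @param p predictions (any monotone score; probabilities typical).
#' @return value in [0, 1].
#' @export
aucROC <- function(y, p) .aucRank(y, p)

#' Brier score
#'
#' Mean squared difference between predicted probability and binary outcome;
#' 0 is perfect, lower is better, and a constant prediction of 0.5 scores
#' exactly 0.25.
#'
#' @param y binary outcomes.
#' @param p probabilities in [0, 1].
#' @return value in [0, 1].
#' @export
brierScore <- function(y, p) {
  if (any(p < 0 | p > 1)) stop("probabilities must lie in [0, 1]")
  mean((p - y)^2)
}

#' Calibration slope and intercept
#'
#' Unpenalized logistic regression of the observed outcome on the logit of
#' the predicted probability. Slope 1 / intercept 0 indicates perfect
#' calibration; slope < 1 indicates overfitting (predictions too extreme),
#' slope > 1 underfitting. By default both coefficients come from the same
#' recalibration fit (the intercept is the value at logit(p) = 0);
#' \code{intercept_fixed_slope = TRUE} instead refits the intercept with the
#' slope fixed at 1 (calibration-in-the-large).
#'
#' Predictions are clipped to [1e-8, 1 - 1e-8] before the logit transform;
#' the number of clipped values is attached as an attribute.
#'
#' @param y binary outcomes.
#' @param p predicted probabilities.
#' @param intercept_fixed_slope logical, see above.
#' @return named vector \code{c(slope, intercept)}; \code{NA} slope with a
#'   warning for degenerate constant predictions.
#' @export
calibration <- function(y, p, intercept_fixed_slope = FALSE) {
  p <- clipProb(p)
  n_clipped <- attr(p, "n_clipped")
  lp <- qlogis(as.numeric(p))
  if (sd(lp) < 1e-12) {
    warning("constant predictions: calibration slope undefined")
    return(structure(c(slope = NA_real_,
                       intercept = qlogis(min(max(mean(y), 1e-8), 1 - 1e-8)) -
                         lp[1L]),
                     n_clipped = n_clipped))
  }
  fit <- suppressWarnings(glm(y ~ lp, family = binomial()))
  slope <- unname(coef(fit)[2L])
  intercept <- if (intercept_fixed_slope) {
    fit0 <- suppressWarnings(glm(y ~ 1 + offset(lp), family = binomial()))
    unname(coef(fit0)[1L])
  } else {
    unname(coef(fit)[1L])
  }
  structure(c(slope = slope, intercept = intercept), n_clipped = n_clipped)
}

.allMetrics <- function(y, p) {
  cal <- suppressWarnings(calibration(y, p))
  c(auc = aucROC(y, p), brier = brierScore(y, p),
    calibration_slope = unname(cal["slope"]),
    calibration_intercept = unname(cal["intercept"]))
}

#' Model recipes for the validation suite
#'
#' A recipe is a self-contained fitting procedure — including all
#' hyperparameter tuning — that can be applied from scratch to any cohort.
#' The bootstrap validation functions refit the recipe on every resample so
#' that tuning is repeated per replicate and no information leaks from the
#' original data into the internal validation.
#'
#' \code{ntcpRecipe()} wraps [fitNTCP()] for the three model families;
#' \code{constantRecipe()} predicts a fixed probability (no fitting, hence
#' zero optimism for the Brier score at p = 0.5); \code{customRecipe()}
#' accepts arbitrary fit / predict / coefficient functions.
#'
#' @param method,... passed to [fitNTCP()].
#' @param p the constant probability.
#' @param fit function(cohort) -> model.
#' @param predict function(model, cohort) -> probabilities.
#' @param coefficients optional function(model) -> named log-odds vector
#'   (used by [bootstrapORCI()]).
#' @param label short label stored with the recipe.
#' @return a \code{list} with elements \code{fit}, \code{predict},
#'   \code{coefficients}, class \code{"ntcpRecipe"}.
#' @export
ntcpRecipe <- function(method = c("fpls-lr", "fpc-lr", "plr"), ...) {
  method <- match.arg(method)
  args <- list(...)
  structure(list(
    fit = function(cohort) {
      do.call(fitNTCP, c(list(cohort = cohort, method = method), args))
    },
    predict = function(model, cohort) predict(model, cohort),
    coefficients = function(model) log(oddsRatios(model)),
    label = method), class = "ntcpRecipe")
}

#' @rdname ntcpRecipe
#' @export
constantRecipe <- function(p = 0.5) {
  force(p)
  structure(list(
    fit = function(cohort) p,
    predict = function(model, cohort) rep(model, ncol(cohort)),
    coefficients = function(model) c(`(Intercept)` = qlogis(model)),
    label = "constant"), class = "ntcpRecipe")
}

#' @rdname ntcpRecipe
#' @export
customRecipe <- function(fit, predict, coefficients = NULL,
                         label = "custom") {
  structure(list(fit = fit, predict = predict,
                 coefficients = coefficients, label = label),
            class = "ntcpRecipe")
}

## Draw a bootstrap resample index vector whose outcome retains both
## classes; cap the redraw count.
.bootIndex <- function(y, max_draws) {
  n <- length(y)
  for (i in seq_len(max_draws)) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(y[idx])) == 2L) return(idx)
  }
  stop("could not draw a bootstrap resample containing both outcome classes")
}

#' Bootstrap optimism-corrected internal validation
#'
#' Efron's optimism correction: the apparent performance of the recipe fit
#' on the full cohort is debiased by the mean over B bootstrap replicates of
#' (performance of the replicate's model on its own resample) minus
#' (performance of that model on the original cohort):
#' \deqn{M_{corrected} = M_{apparent} - \frac{1}{B} \sum_b (M_{b,boot} -
#'   M_{b,orig})}
#' The full recipe — including component/penalty selection or CV tuning —
#' is re-run on every resample. Resamples that lose an outcome class, or on
#' which the recipe fails, are redrawn (logged; total draws capped at 2B).
#'
#' @param recipe an [ntcpRecipe()].
#' @param cohort a [DVHCohort-class].
#' @param B bootstrap replicate count (2000 for production runs; reduce for
#'   desk-scale work).
#' @param seed RNG seed for the resampling.
#' @return a [ValidationReport-class].
#' @export
optimismCorrect <- function(recipe, cohort, B = 200L, seed = 1L) {
  stopifnot(inherits(recipe, "ntcpRecipe"), methods::is(cohort, "DVHCohort"))
  y <- outcomes(cohort)
  model0 <- recipe$fit(cohort)
  p0 <- recipe$predict(model0, cohort)
  apparent <- .allMetrics(y, p0)
  metric_names <- names(apparent)
  boot <- orig <- matrix(NA_real_, B, length(apparent),
                         dimnames = list(NULL, metric_names))
  redrawn <- 0L
  draws_left <- 2L * B
  withSeed(deriveSeed(seed, "optimism"), {
    b <- 1L
    while (b <= B) {
      if (draws_left <= 0L)
        stop("bootstrap redraw cap (2B) exhausted")
      draws_left <- draws_left - 1L
      idx <- sample.int(length(y), length(y), replace = TRUE)
      if (length(unique(y[idx])) < 2L) { redrawn <- redrawn + 1L; next }
      res <- tryCatch({
        cb <- cohort[, idx]
        mb <- recipe$fit(cb)
        pb <- recipe$predict(mb, cb)
        po <- recipe$predict(mb, cohort)
        list(boot = .allMetrics(y[idx], pb), orig = .allMetrics(y, po))
      }, error = function(e) NULL)
      if (is.null(res)) { redrawn <- redrawn + 1L; next }
      boot[b, ] <- res$boot
      orig[b, ] <- res$orig
      b <- b + 1L
    }
  })
  optimism <- colMeans(boot - orig, na.rm = TRUE)
  metrics <- data.frame(metric = metric_names,
                        apparent = unname(apparent),
                        optimism = unname(optimism),
                        corrected = unname(apparent - optimism),
                        row.names = NULL)
  reps <- data.frame(replicate = seq_len(B), boot, orig)
  colnames(reps) <- c("replicate", paste0(metric_names, "_boot"),
                      paste0(metric_names, "_orig"))
  methods::new("ValidationReport", metrics = metrics, B = as.integer(B),
               replicates = reps, nRedrawn = redrawn)
}

setMethod("show", "ValidationReport", function(object) {
  cat(sprintf("ValidationReport (B = %d, %d redrawn):\n",
              object@B, object@nRedrawn))
  print(format(object@metrics, digits = 3), row.names = FALSE)
})

#' Bootstrap percentile confidence intervals for odds ratios
#'
#' Refits the full recipe on B bootstrap resamples and reports per-covariate
#' percentile 2.5/97.5 bounds of the exponentiated coefficients. A covariate
#' absent from a replicate's selected model (a component dropped by model
#' selection, or a column zeroed by the LASSO) contributes an odds ratio of
#' exactly 1 for that replicate. A covariate is flagged significant when 1
#' lies outside its interval.
#'
#' @inheritParams optimismCorrect
#' @return an [ORTable-class].
#' @export
bootstrapORCI <- function(recipe, cohort, B = 200L, seed = 1L) {
  stopifnot(inherits(recipe, "ntcpRecipe"), methods::is(cohort, "DVHCohort"))
  if (is.null(recipe$coefficients))
    stop("recipe does not expose coefficients")
  y <- outcomes(cohort)
  model0 <- recipe$fit(cohort)
  coef0 <- recipe$coefficients(model0)
  redrawn <- 0L
  draws_left <- 2L * B
  store <- list()
  withSeed(deriveSeed(seed, "orci"), {
    b <- 1L
    while (b <= B) {
      if (draws_left <= 0L) stop("bootstrap redraw cap (2B) exhausted")
      draws_left <- draws_left - 1L
      idx <- sample.int(length(y), length(y), replace = TRUE)
      if (length(unique(y[idx])) < 2L) { redrawn <- redrawn + 1L; next }
      cf <- tryCatch(recipe$coefficients(recipe$fit(cohort[, idx])),
                     error = function(e) NULL)
      if (is.null(cf)) { redrawn <- redrawn + 1L; next }
      store[[b]] <- cf
      b <- b + 1L
    }
  })
  all_names <- unique(c(names(coef0), unlist(lapply(store, names))))
  mat <- matrix(0, B, length(all_names), dimnames = list(NULL, all_names))
  for (b in seq_len(B)) mat[b, names(store[[b]])] <- store[[b]]
  ors <- exp(mat)
  qs <- apply(ors, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  point <- exp(ifelse(all_names %in% names(coef0), coef0[all_names], 0))
  tab <- data.frame(covariate = all_names,
                    or = unname(point),
                    ci_low = qs[1L, ],
                    ci_high = qs[2L, ],
                    significant = qs[1L, ] > 1 | qs[2L, ] < 1,
                    row.names = NULL)
  methods::new("ORTable", table = tab, B = as.integer(B))
}

setMethod("show", "ORTable", function(object) {
  cat(sprintf("ORTable (B = %d):\n", object@B))
  print(format(object@table, digits = 3), row.names = FALSE)
})

#' Evaluate a frozen model on an external cohort
#'
#' Computes AUC, Brier score and calibration on a held-out cohort using
#' only the frozen model (training mean, components, coefficients); no
#' refitting occurs.
#'
#' @param model a [FunctionalLogisticModel-class] or [PLRModel-class].
#' @param cohort the external [DVHCohort-class] on a compatible grid.
#' @return named vector: auc, brier, calibration_slope,
#'   calibration_intercept.
#' @export
externalValidate <- function(model, cohort) {
  p <- predict(model, cohort)
  .allMetrics(outcomes(cohort), p)
}
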
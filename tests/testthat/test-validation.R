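test_that("AUC follows the Mann-Whitney definition with half-weight ties", {
  expect_equal(aucROC(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1.0)
  expect_equal(aucROC(c(0, 1, 0, 1), rep(0.4, 4)), 0.5)
  # brute force over all 4 positive-negative pairs: (0.9>0.6) + (0.9>0.2) +
  # (0.4<0.6=0) + (0.4>0.2) = 3/4
  expect_equal(aucROC(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.2)), 0.75)
  expect_error(aucROC(c(1, 1), c(0.2, 0.3)), "both outcome classes")
  # invariance under strictly monotone transforms
  withr::with_seed(8, {
    y <- rbinom(50, 1, 0.5); p <- runif(50)
    expect_equal(aucROC(y, p), aucROC(y, plogis(5 * qlogis(p))))
    expect_false(isTRUE(all.equal(brierScore(y, p),
                                  brierScore(y, plogis(5 * qlogis(p))))))
  })
})

test_that("Brier score equals its hand-computed values", {
  expect_equal(brierScore(c(1, 0, 1), c(1, 0, 1)), 0)
  expect_equal(brierScore(c(1, 0, 1, 0), rep(0.5, 4)), 0.25)
  expect_equal(brierScore(c(1, 0), c(0.8, 0.4)), 0.10)
  expect_error(brierScore(c(1, 0), c(1.2, 0.4)), "0, 1")
})

test_that("calibration recovers slope 1 for honest predictions and scaled slopes", {
  withr::with_seed(13, {
    n <- 5000
    eta <- rnorm(n, 0, 1.2)
    p <- plogis(eta)
    y <- rbinom(n, 1, p)
    cal <- calibration(y, p)
    se <- sqrt(1 / (n * mean(p * (1 - p)) * var(eta)))  # rough slope SE
    expect_lt(abs(cal["slope"] - 1), 2.5 * se * 3)
    expect_lt(abs(cal["intercept"]), 0.1)
    # under-confident predictions (logit shrunk by half): slope ~ 2
    cal2 <- calibration(y, plogis(0.5 * eta))
    expect_lt(abs(cal2["slope"] - 2), 0.25)
    # over-confident predictions (logit doubled): slope ~ 0.5
    cal05 <- calibration(y, plogis(2 * eta))
    expect_lt(abs(cal05["slope"] - 0.5), 0.1)
  })
  expect_warning(calibration(c(0, 1, 1), rep(0.5, 3)), "constant")
})

test_that("a constant predictor has exactly zero Brier optimism", {
  co <- tinyCohort(n = 60, seed = 51)
  rep0 <- optimismCorrect(constantRecipe(0.5), co, B = 20, seed = 3)
  m <- rep0@metrics
  expect_identical(m$optimism[m$metric == "brier"], 0)
  expect_equal(m$apparent[m$metric == "brier"], 0.25)
  expect_equal(m$corrected[m$metric == "auc"], 0.5)
})

test_that("an overfit recipe is penalized by the optimism correction", {
  noiseCols <- function(cohort) {
    cd <- SummarizedExperiment::colData(cohort)
    as.matrix(as.data.frame(cd[, grep("^noise", colnames(cd))]))
  }
  overfit <- customRecipe(
    fit = function(cohort) {
      cf <- suppressWarnings(glm.fit(cbind(1, noiseCols(cohort)),
                                     outcomes(cohort),
                                     family = binomial())$coefficients)
      ifelse(is.na(cf), 0, cf)
    },
    predict = function(model, cohort)
      drop(plogis(cbind(1, noiseCols(cohort)) %*% model)))
  withr::with_seed(61, {
    co <- tinyCohort(n = 100, seed = 52)
    noise <- matrix(rnorm(100 * 30), 100, 30,
                    dimnames = list(NULL, paste0("noise", 1:30)))
    SummarizedExperiment::colData(co) <- cbind(
      SummarizedExperiment::colData(co), S4Vectors::DataFrame(noise))
    rep1 <- optimismCorrect(overfit, co, B = 60, seed = 9)
    m <- rep1@metrics
    expect_gt(m$optimism[m$metric == "auc"], 0.05)
    expect_lt(m$corrected[m$metric == "auc"], m$apparent[m$metric == "auc"])
  })
})

test_that("bootstrap OR machinery handles always-zero and strong covariates", {
  co <- tinyCohort(n = 150, seed = 53)
  fixed <- customRecipe(
    fit = function(cohort) c(alpha = 0.2, nullcov = 0),
    predict = function(model, cohort) rep(plogis(model[1]), ncol(cohort)),
    coefficients = function(model) model)
  tab <- bootstrapORCI(fixed, co, B = 25, seed = 2)@table
  row <- tab[tab$covariate == "nullcov", ]
  expect_equal(c(row$or, row$ci_low, row$ci_high), c(1, 1, 1))
  expect_false(row$significant)
})

test_that("external validation of the training cohort equals apparent metrics", {
  co <- tinyCohort(n = 120, seed = 54)
  fit <- fitNTCP(co, "fpls-lr", component_budget = 2, r_grid = c(0, 10))
  ext <- externalValidate(fit, co)
  p <- predict(fit, co)
  y <- outcomes(co)
  expect_equal(unname(ext["auc"]), aucROC(y, p))
  expect_equal(unname(ext["brier"]), brierScore(y, p))
})

test_that("a model is well calibrated on data generated from itself", {
  co <- tinyCohort(n = 250, seed = 55)
  fit <- fitNTCP(co, "fpls-lr", component_budget = 2, r_grid = c(0, 10))
  big <- tinyCohort(n = 2000, seed = 56)
  p <- predict(fit, big)
  withr::with_seed(57, ynew <- rbinom(length(p), 1, p))
  ext <- suppressWarnings(
    calibration(ynew, p))
  expect_lt(abs(ext["slope"] - 1), 0.15)
  expect_lt(abs(ext["intercept"]), 0.15)
  # shifted case mix: intercept moves, slope stays near 1
  withr::with_seed(58, {
    eta <- qlogis(p) + 1.0
    yshift <- rbinom(length(p), 1, plogis(eta))
  })
  cal <- calibration(yshift, p)
  expect_gt(cal["intercept"], 0.6)
  expect_lt(abs(cal["slope"] - 1), 0.2)
})

test_that("the validation report is deterministic under a fixed seed", {
  co <- tinyCohort(n = 80, seed = 59)
  recipe <- ntcpRecipe("fpls-lr", component_budget = 2, r_grid = c(0, 10))
  r1 <- optimismCorrect(recipe, co, B = 10, seed = 21)
  r2 <- optimismCorrect(recipe, co, B = 10, seed = 21)
  expect_identical(r1@metrics, r2@metrics)
  expect_identical(r1@replicates, r2@replicates)
})
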
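test_that("curvature penalty matrix follows the difference-scheme oracle", {
  g <- buildDoseGrid(0, 10, 1)
  # a linear component has zero curvature: zero row and column
  lin <- manualBasis(g, cbind(g - mean(g), (g - mean(g))^2))
  R <- penaltyMatrix(lin)
  expect_equal(R, t(R))
  expect_lt(max(abs(R[1, ])), 1e-10)
  # pure quadratic xi(d) = c d^2: second difference exactly 2c everywhere
  # (one-sided boundary stencils are exact for quadratics), so
  # R = dd * p * (2c)^2
  quad <- manualBasis(g, cbind(g^2))
  cscale <- basisComponents(quad)[11, 1] / g[11]^2
  expect_equal(penaltyMatrix(quad)[1, 1],
               1 * length(g) * (2 * cscale)^2, tolerance = 1e-10)
  expect_error(penaltyMatrix(manualBasis(c(0, 1), cbind(c(1, 0)))),
               "3 points")
  # PSD on a real basis
  b <- fplsDecompose(tinyCohort(n = 40, seed = 2), k_max = 4)
  ev <- eigen(penaltyMatrix(b), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), -1e-10)
})

test_that("unpenalized fit matches an independent logistic oracle", {
  co <- tinyCohort(n = 200, seed = 25)
  b <- fplsDecompose(co, k_max = 3)
  sc <- basisScores(b)
  y <- outcomes(co)
  fit <- fitFunctionalLogistic(b, scores = sc, y = y, k_n = 3, r = 0)
  oracle <- glm(y ~ sc, family = binomial())
  expect_lt(max(abs(c(fit@intercept, fit@functionalCoefficients) -
                      unname(coef(oracle)))), 1e-6)
  # with clinical covariates too
  z <- encodeDesign(as.data.frame(clinicalData(co)))
  keep <- colnames(z)[apply(z, 2, sd) > 0]
  z <- z[, keep, drop = FALSE]
  fit2 <- fitFunctionalLogistic(b, scores = sc, design = z, y = y,
                                k_n = 2, r = 0)
  oracle2 <- glm(y ~ sc[, 1:2] + z, family = binomial())
  expect_lt(max(abs(c(fit2@intercept, fit2@functionalCoefficients,
                      fit2@clinicalCoefficients) - unname(coef(oracle2)))),
            1e-6)
})

test_that("huge penalties drive functional coefficients to curvature-free space", {
  co <- tinyCohort(n = 150, seed = 26)
  b <- fplsDecompose(co, k_max = 3)
  y <- outcomes(co)
  f0 <- fitFunctionalLogistic(b, scores = basisScores(b), y = y, k_n = 3,
                              r = 0)
  fH <- fitFunctionalLogistic(b, scores = basisScores(b), y = y, k_n = 3,
                              r = 1e9)
  R <- penaltyMatrix(b, 3)
  pen <- function(m) drop(t(m@functionalCoefficients) %*% R %*%
                            m@functionalCoefficients)
  expect_lt(pen(fH), pen(f0) * 1e-6)
})

test_that("clinical coefficients are not shrunk by the roughness penalty", {
  co <- tinyCohort(n = 400, seed = 27)
  b <- fplsDecompose(co, k_max = 2)
  sc <- basisScores(b)
  y <- outcomes(co)
  z <- encodeDesign(as.data.frame(clinicalData(co)))[, "cisplatin",
                                                    drop = FALSE]
  f0 <- fitFunctionalLogistic(b, scores = sc, design = z, y = y, k_n = 2,
                              r = 0)
  fH <- fitFunctionalLogistic(b, scores = sc, design = z, y = y, k_n = 2,
                              r = 1e9)
  # functional block collapses, clinical stays the same order of magnitude
  expect_lt(sum(abs(fH@functionalCoefficients)),
            0.01 * sum(abs(f0@functionalCoefficients)))
  oracle <- glm(y ~ z[, 1], family = binomial())  # score-free limit
  expect_lt(abs(fH@clinicalCoefficients["cisplatin"] -
                  unname(coef(oracle)[2])), 0.05)
})

test_that("beta(d) is the exact component expansion and predicts consistently", {
  co <- tinyCohort(n = 120, seed = 28)
  b <- fplsDecompose(co, k_max = 3)
  fit <- fitFunctionalLogistic(b, co, k_n = 3, r = 1.5)
  xi <- basisComponents(b)
  expect_equal(betaFunction(fit),
               drop(xi %*% fit@functionalCoefficients), tolerance = 1e-12)
  # single-component model: beta(d) = beta_1 * xi_1(d)
  f1 <- fitFunctionalLogistic(b, co, k_n = 1, r = 0)
  expect_equal(betaFunction(f1), xi[, 1] * f1@functionalCoefficients[1],
               tolerance = 1e-12)
  # quadrature of beta(d) against centered curves + clinical + intercept
  # reproduces the linear predictor
  g <- doseGrid(co); dd <- g[2] - g[1]
  z <- encodeDesign(as.data.frame(clinicalData(co)))
  eta_manual <- fit@intercept +
    dd * drop(crossprod(volumeMatrix(co) - meanCurve(b), betaFunction(fit))) +
    drop(z[, names(fit@clinicalCoefficients)] %*% fit@clinicalCoefficients)
  expect_lt(max(abs(eta_manual - linearPredictor(fit, co))), 1e-8)
  expect_equal(predict(fit, co), plogis(eta_manual), tolerance = 1e-8)
})

test_that("maximized likelihood never decreases when a component is added", {
  co <- tinyCohort(n = 150, seed = 29)
  b <- fplsDecompose(co, k_max = 5)
  y <- outcomes(co)
  sc <- basisScores(b)
  ll <- sapply(1:5, function(k) {
    m <- fitFunctionalLogistic(b, scores = sc, y = y, k_n = k, r = 0)
    eta <- m@intercept + drop(sc[, 1:k, drop = FALSE] %*%
                                m@functionalCoefficients)
    sum(y * eta - log1p(exp(eta)))
  })
  expect_true(all(diff(ll) >= -1e-8))
})

test_that("the unpenalized optimum beats random coefficient perturbations", {
  co <- tinyCohort(n = 200, seed = 30)
  b <- fplsDecompose(co, k_max = 2)
  sc <- basisScores(b)
  y <- outcomes(co)
  m <- fitFunctionalLogistic(b, scores = sc, y = y, k_n = 2, r = 0)
  theta <- c(m@intercept, m@functionalCoefficients)
  x <- cbind(1, sc[, 1:2])
  ll <- function(th) { eta <- drop(x %*% th); sum(y * eta - log1p(exp(eta))) }
  ll0 <- ll(theta)
  withr::with_seed(77, {
    for (i in 1:100) {
      expect_lte(ll(theta + rnorm(3, 0, 0.2 * abs(theta) + 1e-3)), ll0 + 1e-10)
    }
  })
})

test_that("model selection reproduces a hand-evaluated MSC table", {
  co <- tinyCohort(n = 100, seed = 31)
  b <- fplsDecompose(co, k_max = 2)
  sc <- basisScores(b)
  y <- outcomes(co)
  n <- length(y)
  r_grid <- c(0, 50)
  sel <- mscSelect(b, scores = sc, design = matrix(0, n, 0), y = y,
                   component_budget = 2, r_grid = r_grid)
  tab <- sel@table
  # hand evaluation of the criterion for every candidate
  for (i in seq_len(nrow(tab))) {
    m <- fitFunctionalLogistic(b, scores = sc, y = y, k_n = tab$kn[i],
                               r = tab$r[i])
    p <- plogis(m@intercept + drop(sc[, 1:tab$kn[i], drop = FALSE] %*%
                                     m@functionalCoefficients))
    hand <- log(mean((y - p)^2)) + log(n) * tab$kn[i] / (n / 2)
    expect_equal(tab$msc[i], hand, tolerance = 1e-12)
  }
  best <- tab[which.min(tab$msc), ]
  expect_identical(sel@kn, as.integer(best$kn))
  # identical residual sums at kn = 1 vs kn = 2: complexity term decides
  msc1 <- log(0.2) + log(n) * 1 / (n / 2)
  msc2 <- log(0.2) + log(n) * 2 / (n / 2)
  expect_lt(msc1, msc2)
})

test_that("pure-noise outcomes select the most parsimonious component count", {
  withr::with_seed(55, {
    kns <- sapply(1:10, function(i) {
      co <- tinyCohort(n = 200, seed = 500 + i)
      y <- sample(outcomes(co))          # break any dose-outcome link
      if (length(unique(y)) < 2) return(NA)
      b <- fplsDecompose(volumeMatrix(co), y = y, k_max = 3,
                         grid = doseGrid(co))
      sel <- mscSelect(b, scores = basisScores(b),
                       design = matrix(0, 200, 0), y = y,
                       component_budget = 3, r_grid = c(0, 10, 1350))
      sel@kn
    })
    tabulated <- table(kns)
    expect_identical(names(tabulated)[which.max(tabulated)], "1")
  })
})

test_that("predictions respect stochastic ordering under a non-negative weighting", {
  co <- tinyCohort(n = 100, seed = 32)
  b <- fplsDecompose(co, k_max = 1)
  y <- outcomes(co)
  m <- fitFunctionalLogistic(b, scores = basisScores(b), y = y, k_n = 1,
                             r = 0)
  bf <- betaFunction(m)
  # construct two comparable patients: one pointwise-dominating DVH
  g <- doseGrid(co)
  lo <- plogis(-(g - 1.6) * 8); lo[1] <- 1
  hi <- pmin(lo + 0.2, 1); hi[1] <- 1
  lo <- rev(cummax(rev(lo))); hi <- rev(cummax(rev(hi)))
  clin <- fullLevelClinical()[c(1, 1), ]
  two <- DVHCohort(cbind(lo, hi), g, clin, c(0, 1))
  p <- predict(m, two)
  if (all(bf >= -1e-9)) expect_gte(p[2], p[1])
  if (all(bf <= 1e-9)) expect_lte(p[2], p[1])
  expect_true(all(p > 0 & p < 1))
})

test_that("fitted models serialize to JSON and back without changing predictions", {
  co <- tinyCohort(n = 80, seed = 34)
  fit <- fitNTCP(co, "fpls-lr", component_budget = 2, r_grid = c(0, 10))
  path <- tempfile(fileext = ".json")
  writeModel(fit, path)
  back <- readModel(path)
  expect_equal(predict(back, co), predict(fit, co), tolerance = 1e-10)
  expect_equal(betaFunction(back), betaFunction(fit), tolerance = 1e-10)
  # PLR model round trip
  plr <- fitPLR(co, folds = 4)
  writeModel(plr, path)
  plrBack <- readModel(path)
  expect_equal(predict(plrBack, co), predict(plr, co), tolerance = 1e-10)
})

test_that("degenerate designs and separation are reported", {
  co <- tinyCohort(n = 60, seed = 35)
  b <- fplsDecompose(co, k_max = 2)
  sc <- basisScores(b)
  y <- outcomes(co)
  dup <- cbind(a = sc[, 1], b = sc[, 1])
  expect_error(fitFunctionalLogistic(b, scores = sc, design = dup, y = y,
                                     k_n = 2, r = 0), "collinear")
  # perfectly separable toy data: flagged, finite coefficients
  ysep <- as.integer(sc[, 1] > median(sc[, 1]))
  expect_warning(
    msep <- fitFunctionalLogistic(b, scores = sc, y = ysep, k_n = 1, r = 0),
    "separation")
  expect_false(msep@converged)
  expect_true(all(is.finite(c(msep@intercept, msep@functionalCoefficients))))
})
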
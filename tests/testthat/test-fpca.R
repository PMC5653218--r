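test_that("mean function is the pointwise average and centers residuals", {
  g <- buildDoseGrid(0, 1, 0.25)
  v <- cbind(c(1, 0, 0, 0, 0), c(1, 1, 1, 1, 0))
  expect_equal(meanFunction(v, g), c(1, .5, .5, .5, 0))
  expect_equal(meanFunction(v[, c(1, 1)], g), v[, 1])
  resid <- v - meanFunction(v, g)
  expect_equal(rowMeans(resid), numeric(5))
  expect_error(meanFunction(matrix(numeric(0), 5, 0), g), "at least one")
})

test_that("covariance operator matches a hand-computed 2x2 case", {
  g <- c(0, 1)
  # three two-point curves listed by hand
  v <- cbind(c(1, 0.2), c(0.8, 0.6), c(0.6, 0.1))
  mu <- c(0.8, 0.3)
  # hand computation, divisor n = 3:
  # centered: (0.2, -0.1), (0, 0.3), (-0.2, -0.2)
  # S11 = (0.04 + 0 + 0.04)/3, S22 = (0.01 + 0.09 + 0.04)/3
  # S12 = (-0.02 + 0 + 0.04)/3
  hand <- matrix(c(0.08, 0.02, 0.02, 0.14), 2, 2) / 3
  expect_equal(covarianceOperator(v, g), hand, tolerance = 1e-12)
  expect_equal(covarianceOperator(v, g), t(covarianceOperator(v, g)))
  expect_equal(covarianceOperator(v[, c(1, 1)], g), matrix(0, 2, 2))
  expect_error(covarianceOperator(v[, 1, drop = FALSE], g), "two curves")
})

test_that("rank-1 variation yields a single dominant component", {
  g <- buildDoseGrid(0, 2.6, 0.01)
  base <- plogis(-(g - 1.8) * 8)
  dir <- plogis(-(g - 2.1) * 8) - base
  withr::with_seed(1, a <- rnorm(12, 0, 0.1))
  v <- sapply(a, function(ai) base + ai * dir)
  b <- fpcaDecompose(v, k_max = 3, grid = g)
  expect_gt(abs(cosQ(basisComponents(b)[, 1], dir)), 0.9999)
  ev <- componentVariances(b)
  expect_lt(ev[2] / ev[1], 1e-12)
  expect_equal(varianceExplained(b)[1], 100, tolerance = 1e-8)
})

test_that("fpca matches a dense eigendecomposition oracle and its identities", {
  co <- tinyCohort(n = 15, seed = 8)
  v <- volumeMatrix(co)
  g <- doseGrid(co)
  dd <- g[2] - g[1]
  b <- fpcaDecompose(co, k_max = 5)
  # oracle: direct symmetric eigensolver on the discretized operator
  xc <- v - rowMeans(v)
  oracle <- eigen(dd * tcrossprod(xc) / ncol(v), symmetric = TRUE)
  expect_equal(componentVariances(b), oracle$values[1:5], tolerance = 1e-8)
  for (k in 1:5) {
    expect_gt(abs(cosQ(basisComponents(b)[, k],
                       oracle$vectors[, k] / sqrt(dd))), 1 - 1e-8)
  }
  # trace identity: total eigenvalue mass equals total quadrature variance
  expect_equal(sum(oracle$values), dd * sum(apply(v, 1, var)) * (14 / 15),
               tolerance = 1e-8)
  # orthonormality under the quadrature inner product
  gram <- dd * crossprod(basisComponents(b))
  expect_lt(max(abs(gram - diag(5))), 1e-8)
  # scores: zero mean, covariance diag(lambda) with divisor n
  sc <- basisScores(b)
  expect_lt(max(abs(colMeans(sc))), 1e-8)
  covs <- crossprod(scale(sc, center = TRUE, scale = FALSE)) / ncol(v)
  expect_lt(max(abs(covs - diag(componentVariances(b)))), 1e-6)
  # variance fractions over all components sum to 100
  bful <- fpcaDecompose(co, k_max = 14)
  expect_equal(sum(varianceExplained(bful)), 100, tolerance = 1e-6)
  expect_error(fpcaDecompose(co, k_max = 15), "rank")
})

test_that("adding a constant shift moves the mean but not components or scores", {
  co <- tinyCohort(n = 12, seed = 3)
  v <- volumeMatrix(co)
  g <- doseGrid(co)
  b1 <- fpcaDecompose(v, k_max = 3, grid = g)
  b2 <- fpcaDecompose(v * 0.5 + 0.25, k_max = 3, grid = g)  # affine, monotone-safe
  expect_equal(meanCurve(b2), meanCurve(b1) * 0.5 + 0.25, tolerance = 1e-10)
  for (k in 1:3)
    expect_gt(abs(cosQ(basisComponents(b1)[, k], basisComponents(b2)[, k])),
              1 - 1e-8)
})

test_that("reconstruction error follows the eigenvalue tail identity", {
  co <- tinyCohort(n = 10, seed = 6)
  v <- volumeMatrix(co)
  g <- doseGrid(co)
  dd <- g[2] - g[1]
  n <- ncol(v)
  b <- fpcaDecompose(co, k_max = n - 1)
  lam <- componentVariances(b)
  errAt <- function(k) {
    rec <- reconstructCurves(b, k)
    dd * sum((v - rec)^2)
  }
  # complete expansion reconstructs exactly; k = 0 gives the mean curve
  expect_lt(errAt(n - 1), 1e-6)
  expect_equal(reconstructCurves(b, 0),
               matrix(meanCurve(b), nrow(v), n), ignore_attr = TRUE)
  for (k in c(0, 2, 5)) {
    expect_equal(errAt(k), n * sum(lam[(k + 1):(n - 1)]), tolerance = 1e-6)
  }
  # error decreases by n * lambda_{k+1} per added component
  expect_equal(errAt(2) - errAt(3), n * lam[3], tolerance = 1e-6)
  expect_error(reconstructCurves(b, n), "exceeds")
})

test_that("first-component shape is stable under patient resampling", {
  # a well-separated cohort: the boost-overlap mode carries ~95% of the
  # variance, so the leading eigenvalue gap is wide
  co <- tinyCohort(n = 100, seed = 19, body_center_sd = 0.03,
                   center_jitter_sd = 0.01, steepness_jitter_sd = 0.05,
                   noise_sd = 0.002)
  v <- volumeMatrix(co)
  g <- doseGrid(co)
  withr::with_seed(42, {
    shapes <- sapply(1:200, function(b) {
      idx <- sample(ncol(v), replace = TRUE)
      basisComponents(fpcaDecompose(v[, idx], k_max = 1, grid = g))[, 1]
    })
  })
  nrm <- sqrt(colSums(shapes^2))
  cosmat <- crossprod(sweep(shapes, 2, nrm, "/"))
  expect_gt(min(abs(cosmat)), 0.9)
})
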
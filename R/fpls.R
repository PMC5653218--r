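#' @include AllClasses.R fpca.R
NULL

#' Functional partial least squares decomposition
#'
#' Supervised analogue of [fpcaDecompose()]: components maximize the squared
#' covariance between the curves and the binary response, subject to mutual
#' orthonormality under the quadrature inner product. The first component is
#' the normalized cross-covariance function \eqn{w(d) \propto
#' \mathrm{Cov}(V(d), y)}; subsequent components are extracted NIPALS-style
#' from curve data deflated by the fitted rank-1 approximation, with each
#' weight function orthogonalized against all previous components and
#' loadings so that stored scores (projections of the original centered
#' curves) are exactly the mutually uncorrelated PLS scores.
#'
#' The response is centered before extraction, so component shapes are
#' invariant to affine recoding of y. The algorithm is deterministic.
#'
#' Two score sets are produced. The \code{basisScores()} slot holds
#' quadrature projections of the original centered curves onto the
#' orthonormal components — the same rule [projectScores()] applies to new
#' cohorts, which keeps the coefficient-function reconstruction
#' \eqn{\beta(d) = \sum_k \beta_k \xi_k(d)} exactly consistent with the
#' fitted linear predictor. The raw NIPALS scores (computed on deflated
#' data, exactly mutually orthogonal) are attached as
#' \code{attr(basisScores(basis), "deflated")}. For single-response PLS the
#' two sets coincide only for the first component; projection scores of
#' later components carry some correlation with earlier ones, the price of
#' a single self-consistent projection rule.
#'
#' @inheritParams fpcaDecompose
#' @param y binary outcome vector; both classes must be present.
#' @return a [FunctionalBasis-class] with \code{kind = "fpls"};
#'   \code{componentVariances()} holds per-component score variances
#'   (divisor n).
#' @export
fplsDecompose <- function(curves, y = NULL, k_max = 5L, grid = NULL) {
  if (methods::is(curves, "DVHCohort") && is.null(y)) y <- outcomes(curves)
  cg <- .curvesAndGrid(curves, grid)
  v <- cg$v
  g <- cg$grid
  n <- ncol(v)
  p <- nrow(v)
  if (length(y) != n) stop("y must have one value per curve")
  if (length(unique(y)) < 2L)
    stop("both outcome classes must be present for FPLS")
  if (k_max < 1L) stop("k_max must be >= 1")
  if (k_max > min(n - 1L, p))
    stop(sprintf("k_max = %d exceeds the data rank bound min(n - 1, p) = %d",
                 k_max, min(n - 1L, p)))
  dd <- g[2L] - g[1L]
  mu <- rowMeans(v)
  xc <- t(v - mu)                       # n x p, centered curves in rows
  yc <- as.numeric(y) - mean(y)
  lam_total <- dd * sum(xc^2) / n       # total quadrature variance
  comps <- matrix(0, p, k_max)
  loads <- matrix(0, p, k_max)
  xk <- xc
  tmat <- matrix(0, n, k_max)
  for (k in seq_len(k_max)) {
    w <- drop(crossprod(xk, yc)) / n    # cross-covariance function on grid
    ## re-orthogonalize against previous components (quadrature = Euclidean
    ## direction on a uniform grid)
    if (k > 1L) {
      prev <- comps[, seq_len(k - 1L), drop = FALSE]
      w <- w - prev %*% crossprod(prev, w) * dd
    }
    nrm <- sqrt(dd * sum(w^2))
    if (nrm < 1e-10 * max(1, sqrt(dd * sum(xk^2) / n)))
      stop(sprintf("data rank exhausted at component %d; lower k_max", k))
    w <- drop(w) / nrm
    t_k <- dd * drop(xk %*% w)          # NIPALS score on deflated data
    denom <- sum(t_k^2)
    pl <- drop(crossprod(xk, t_k)) / denom
    xk <- xk - tcrossprod(t_k, pl)      # rank-1 regression deflation
    comps[, k] <- w
    loads[, k] <- pl
    tmat[, k] <- t_k
  }
  flip <- logical(k_max)
  for (k in seq_len(k_max)) {
    s <- applySignConvention(comps[, k], g)
    flip[k] <- any(s != comps[, k])
    comps[, k] <- s
  }
  tmat[, flip] <- -tmat[, flip, drop = FALSE]
  scores <- dd * (xc %*% comps)
  attr(scores, "deflated") <- tmat
  colnames(comps) <- colnames(scores) <- paste0("FPLS", seq_len(k_max))
  rownames(scores) <- colnames(v)
  lam <- apply(scores, 2L, function(s) sum((s - mean(s))^2) / n)
  .makeBasis(g, "fpls", comps, lam, totalVariance = lam_total,
             meanFunction = mu, scores = scores)
}

#' Scores of curves under an FPLS (or FPCA) basis
#'
#' Alias of [projectScores()] retained for symmetry with the extraction
#' function: quadrature inner products of curves, centered by the training
#' mean stored in the basis, with the component functions.
#'
#' @inheritParams projectScores
#' @return n x k score matrix.
#' @export
fplsScores <- function(basis, curves, grid = NULL) {
  projectScores(basis, curves, grid)
}
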
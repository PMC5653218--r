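#' @include AllClasses.R AllGenerics.R utils.R
NULL

## Extract the p x n curve matrix and grid from a DVHCohort or accept a
## plain matrix + grid pair.
.curvesAndGrid <- function(curves, grid = NULL) {
  if (methods::is(curves, "DVHCohort")) {
    list(v = volumeMatrix(curves), grid = doseGrid(curves))
  } else {
    if (is.null(grid)) stop("grid is required when curves is a matrix")
    v <- as.matrix(curves)
    if (nrow(v) != length(grid)) {
      if (ncol(v) == length(grid)) v <- t(v)
      else stop("curve matrix does not match grid length")
    }
    list(v = v, grid = grid)
  }
}

#' Pointwise mean DVH curve
#'
#' @param curves a [DVHCohort-class] or a p x n matrix of curves.
#' @param grid dose grid (required for a plain matrix).
#' @return numeric mean curve mu(d) on the grid.
#' @export
meanFunction <- function(curves, grid = NULL) {
  cg <- .curvesAndGrid(curves, grid)
  if (!ncol(cg$v)) stop("at least one curve is required")
  rowMeans(cg$v)
}

#' Sample covariance operator of DVH curves
#'
#' The discretized covariance surface
#' \eqn{\Sigma(d_1, d_2) = \mathrm{E}[(V(d_1) - \mu(d_1))(V(d_2) -
#' \mu(d_2))]} with divisor n (expectation form), a symmetric positive
#' semidefinite p x p matrix over the dose grid.
#'
#' @inheritParams meanFunction
#' @return p x p covariance matrix.
#' @export
covarianceOperator <- function(curves, grid = NULL) {
  cg <- .curvesAndGrid(curves, grid)
  n <- ncol(cg$v)
  if (n < 2L) stop("at least two curves are required")
  xc <- cg$v - rowMeans(cg$v)
  tcrossprod(xc) / n
}

.makeBasis <- function(grid, kind, components, eigenvalues, totalVariance,
                       meanFunction, scores) {
  methods::new("FunctionalBasis", grid = grid, kind = kind,
               components = components, eigenvalues = eigenvalues,
               totalVariance = totalVariance, meanFunction = meanFunction,
               scores = scores)
}

#' Functional principal component analysis of DVH curves
#'
#' Eigendecomposition of the quadrature-weighted covariance operator of the
#' curves. Component functions \eqn{\xi_k(d)} are orthonormal under the
#' quadrature inner product \eqn{\Delta d \sum f g}; eigenvalues
#' \eqn{\lambda_1 \ge \lambda_2 \ge \dots} give the variance captured by
#' each component; scores are \eqn{c_{ik} = \langle V_i - \mu, \xi_k
#' \rangle} and have variance \eqn{\lambda_k} (divisor n) and zero mean.
#'
#' A deterministic sign convention is applied (component oriented so its
#' inner product with the centered dose ramp is non-negative), since
#' component signs are mathematically arbitrary.
#'
#' @inheritParams meanFunction
#' @param k_max number of leading components to retain; at most
#'   \code{min(n - 1, p)}.
#' @return a [FunctionalBasis-class] with \code{kind = "fpca"}.
#' @export
fpcaDecompose <- function(curves, k_max = 5L, grid = NULL) {
  cg <- .curvesAndGrid(curves, grid)
  v <- cg$v
  g <- cg$grid
  n <- ncol(v)
  p <- nrow(v)
  if (n < 2L) stop("at least two curves are required")
  if (k_max > min(n - 1L, p))
    stop(sprintf("k_max = %d exceeds the data rank bound min(n - 1, p) = %d",
                 k_max, min(n - 1L, p)))
  dd <- g[2L] - g[1L]
  mu <- rowMeans(v)
  xc <- v - mu
  sigma <- tcrossprod(xc) / n
  ## Eigendecomposition of the quadrature-weighted operator dd * Sigma. On a
  ## uniform grid the quadrature weight is a scalar, so eigenvectors of Sigma
  ## serve directly; eigenvalues scale by dd. Eigenvectors have unit
  ## Euclidean norm and are rescaled by 1/sqrt(dd) to unit quadrature norm.
  es <- eigen(dd * sigma, symmetric = TRUE)
  lam <- pmax(es$values, 0)
  comps <- es$vectors[, seq_len(k_max), drop = FALSE] / sqrt(dd)
  for (k in seq_len(k_max)) comps[, k] <- applySignConvention(comps[, k], g)
  scores <- dd * crossprod(xc, comps)
  colnames(comps) <- colnames(scores) <- paste0("FPC", seq_len(k_max))
  rownames(scores) <- colnames(v)
  .makeBasis(g, "fpca", comps, lam[seq_len(k_max)],
             totalVariance = sum(lam), meanFunction = mu, scores = scores)
}

#' Reconstruct curves from leading components
#'
#' Truncated expansion \eqn{\hat V_i(d) = \mu(d) + \sum_{k \le k_n} c_{ik}
#' \xi_k(d)}. With all components the reconstruction is exact up to
#' numerical error; the summed quadrature L2 error of a rank-\eqn{k_n}
#' reconstruction equals \eqn{n \sum_{k > k_n} \lambda_k}.
#'
#' @param basis a [FunctionalBasis-class].
#' @param k_n number of leading components to use (0 gives the mean curve).
#' @return p x n matrix of reconstructed curves.
#' @export
reconstructCurves <- function(basis, k_n) {
  stopifnot(methods::is(basis, "FunctionalBasis"))
  k_avail <- ncol(basis@components)
  if (k_n > k_avail)
    stop(sprintf("k_n = %d exceeds the %d available components", k_n, k_avail))
  n <- nrow(basis@scores)
  out <- matrix(basis@meanFunction, nrow = length(basis@grid), ncol = n)
  if (k_n >= 1L) {
    idx <- seq_len(k_n)
    out <- out + basis@components[, idx, drop = FALSE] %*%
      t(basis@scores[, idx, drop = FALSE])
  }
  rownames(out) <- names(basis@meanFunction)
  colnames(out) <- rownames(basis@scores)
  out
}

#' @rdname varianceExplained
#' @export
setMethod("varianceExplained", "FunctionalBasis", function(x, k) {
  k <- min(k, ncol(x@components))
  100 * x@eigenvalues[seq_len(k)] / x@totalVariance
})

#' @rdname doseGrid
#' @export
setMethod("doseGrid", "FunctionalBasis", function(x) x@grid)

#' @rdname doseGrid
#' @export
setMethod("doseStep", "FunctionalBasis", function(x) x@grid[2L] - x@grid[1L])

#' @rdname basisComponents
#' @export
setMethod("basisComponents", "FunctionalBasis", function(x) x@components)

#' @rdname basisScores
#' @export
setMethod("basisScores", "FunctionalBasis", function(x) x@scores)

#' @rdname meanCurve
#' @export
setMethod("meanCurve", "FunctionalBasis", function(x) x@meanFunction)

#' @rdname componentVariances
#' @export
setMethod("componentVariances", "FunctionalBasis", function(x) x@eigenvalues)

setMethod("show", "FunctionalBasis", function(object) {
  k <- ncol(object@components)
  cat(sprintf("FunctionalBasis (%s): %d components on %d dose points\n",
              object@kind, k, length(object@grid)))
  if (k) {
    ve <- varianceExplained(object)
    cat("  variance explained (%):",
        paste(sprintf("%.1f", ve), collapse = " "), "\n")
  }
})

#' Project curves onto a trained basis
#'
#' Quadrature inner products of curves, centered with the basis's stored
#' training mean, against the component functions. Using the training mean
#' (not the new cohort's mean) is essential for external validation.
#'
#' @param basis a [FunctionalBasis-class].
#' @param curves a [DVHCohort-class] or p x n matrix on the basis grid.
#' @param grid dose grid when \code{curves} is a matrix.
#' @return n x k score matrix.
#' @export
projectScores <- function(basis, curves, grid = NULL) {
  stopifnot(methods::is(basis, "FunctionalBasis"))
  cg <- .curvesAndGrid(curves, grid)
  if (length(cg$grid) != length(basis@grid) ||
      max(abs(cg$grid - basis@grid)) > 1e-9)
    stop("curve grid does not match the basis grid")
  dd <- basis@grid[2L] - basis@grid[1L]
  xc <- cg$v - basis@meanFunction
  sc <- dd * crossprod(xc, basis@components)
  rownames(sc) <- colnames(cg$v)
  sc
}
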
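## Internal numerical helpers shared across modules.

#' @importFrom stats plogis qlogis var cov sd rnorm runif rbinom uniroot
#'   binomial coef glm predict quantile median
NULL

## Quadrature inner product on a uniform dose grid: <f, g> = dd * sum(f * g).
## All functional objects in the package live on the same uniform grid, so a
## rectangle rule with weight dd is used throughout (generator and estimators
## share it, keeping recovery studies self-consistent).
quadInner <- function(f, g, dd) {
  dd * sum(f * g)
}

quadNorm <- function(f, dd) {
  sqrt(quadInner(f, f, dd))
}

## Deterministic sign convention for component functions: orient each
## component so that its quadrature inner product with the centered dose ramp
## (d - mean(d)) is non-negative; break exact ties toward a positive last
## element. Component signs are otherwise arbitrary.
applySignConvention <- function(comp, grid) {
  ramp <- grid - mean(grid)
  dd <- grid[2L] - grid[1L]
  s <- quadInner(comp, ramp, dd)
  if (abs(s) < 1e-12) {
    s <- comp[length(comp)]
  }
  if (s < 0) -comp else comp
}

## Derive a reproducible substream seed (< 2^31) from one master seed and a
## stream name, so e.g. changing the bootstrap replicate count does not
## perturb the simulated cohort.
deriveSeed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) %% 65011) * 33029 + h * 7 + 1) %% 2147483647L
}

## Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

## Clip probabilities away from 0/1 before logit transforms; count of clipped
## values is attached so callers can log it.
clipProb <- function(p, eps = 1e-8) {
  clipped <- sum(p < eps | p > 1 - eps)
  out <- pmin(pmax(p, eps), 1 - eps)
  attr(out, "n_clipped") <- clipped
  out
}

isUniformGrid <- function(points, tol = 1e-8) {
  if (length(points) < 2L) return(TRUE)
  d <- diff(points)
  all(d > 0) && (max(d) - min(d)) < tol * max(d)
}
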
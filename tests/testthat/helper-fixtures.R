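# Shared fixtures, generated in code.

# Quadrature cosine similarity between two functions on a shared grid.
cosQ <- function(a, b) sum(a * b) / sqrt(sum(a * a) * sum(b * b))

# A small cohort from the default generator.
tinyCohort <- function(n = 60, seed = 11, ...) {
  generateCohort(simulationConfig(n_patients = n, seed = seed, ...))
}

# A clinical table with one row per category level so that the design is
# full rank, plus an all-reference first row.
fullLevelClinical <- function() {
  ref <- data.frame(
    sex = "female", age = 50, rt_intent = "postoperative",
    induction_chemo = "no", concurrent_chemo = "none",
    primary_site = "oropharynx_oral_cavity", stringsAsFactors = FALSE)
  out <- ref[rep(1, 12), ]
  out$age <- 50:61
  out$sex[2] <- "male"
  out$rt_intent[3] <- "definitive"
  out$induction_chemo[4] <- "yes"
  out$concurrent_chemo[5:7] <- c("cisplatin", "carboplatin", "cis_carbo")
  out$primary_site[8:11] <- c("hypopharynx_larynx", "nasopharynx_nasal_cavity",
                              "unknown_primary", "parotid")
  rownames(out) <- NULL
  out
}

# Manually construct a FunctionalBasis holding given component functions
# (orthonormalized under the quadrature inner product first).
manualBasis <- function(grid, funcs, kind = "fpca") {
  dd <- grid[2L] - grid[1L]
  funcs <- as.matrix(funcs)
  q <- qr.Q(qr(funcs)) / sqrt(dd)      # orthonormal under quadrature
  k <- ncol(q)
  new("FunctionalBasis", grid = grid, kind = kind, components = q,
      eigenvalues = rep(1, k), totalVariance = k,
      meanFunction = numeric(length(grid)),
      scores = matrix(0, 1L, k))
}

# Cohort with well-conditioned discrete DVH columns: monotone curves built
# from Dirichlet-style independent decrements on the coarse 13-point grid.
independentVxCohort <- function(n = 400, seed = 5) {
  withr::with_seed(seed, {
    grid <- buildDoseGrid(0.2, 2.6, 0.2)
    vol <- sapply(seq_len(n), function(i) {
      dec <- rgamma(14, shape = 0.8)
      dec <- dec / sum(dec)
      1 - cumsum(dec)[1:13]
    })
    vol <- pmin(pmax(vol, 0), 1)
    clin <- data.frame(
      sex = sample(c("male", "female"), n, TRUE),
      age = round(rnorm(n, 60, 8), 1),
      rt_intent = sample(c("definitive", "postoperative"), n, TRUE),
      induction_chemo = sample(c("yes", "no"), n, TRUE),
      concurrent_chemo = sample(c("none", "cisplatin"), n, TRUE),
      primary_site = sample(c("oropharynx_oral_cavity", "hypopharynx_larynx"),
                            n, TRUE),
      stringsAsFactors = FALSE)
    eta <- -0.5 + 2.5 * vol[6, ] + 0.5 * (clin$sex == "male")
    y <- rbinom(n, 1, plogis(eta))
    DVHCohort(vol, grid, clin, y)
  })
}
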
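#' @include AllClasses.R AllGenerics.R
NULL

#' Build a uniform fractional-dose grid
#'
#' Constructs the shared sampling lattice for DVH curves. Two grids are used
#' in practice: a fine grid from 0 to 2.60 Gy at 0.01-Gy intervals for the
#' functional analyses (261 points), and a coarse grid from 0.2 to 2.6 Gy at
#' 0.2-Gy intervals for the discrete-point comparator model (13 points).
#'
#' @param d_min,d_max grid endpoints in Gy per fraction.
#' @param step grid spacing in Gy per fraction; the span must be an integer
#'   multiple of the step.
#' @return numeric vector of uniformly spaced doses.
#' @examples
#' length(buildDoseGrid(0, 2.60, 0.01))  # 261
#' buildDoseGrid(0, 1, 0.5)              # 0.0 0.5 1.0
#' @export
buildDoseGrid <- function(d_min, d_max, step) {
  stopifnot(is.numeric(d_min), is.numeric(d_max), is.numeric(step))
  if (step <= 0) stop("step must be positive")
  if (d_max < d_min) stop("d_max must be >= d_min")
  span <- d_max - d_min
  n_steps <- span / step
  if (abs(n_steps - round(n_steps)) > 1e-8 * max(1, n_steps)) {
    stop(sprintf(
      "grid span %.6g is not an integer multiple of step %.6g (remainder %.6g)",
      span, step, span - round(n_steps) * step))
  }
  d_min + step * seq.int(0L, round(n_steps))
}

#' Convert physical doses to fractional doses
#'
#' Divides physical dose values (Gy) by the number of treatment fractions,
#' giving Gy per fraction. Acute toxicity develops during treatment, so the
#' per-fraction dose distribution, not the total physical dose, is the
#' dosimetric input throughout the package.
#'
#' @param physical_doses non-negative dose values in Gy.
#' @param n_fractions number of treatment fractions (>= 1).
#' @return doses in Gy per fraction.
#' @examples
#' toFractionalDose(c(60, 54, 48), 30)  # 2.0 1.8 1.6
#' @export
toFractionalDose <- function(physical_doses, n_fractions) {
  if (length(n_fractions) != 1L || is.na(n_fractions) || n_fractions < 1)
    stop("n_fractions must be a single count >= 1")
  if (any(physical_doses < 0)) stop("doses must be non-negative")
  physical_doses / n_fractions
}

#' Normalized cumulative DVH from dose samples
#'
#' Given per-fraction doses of equal-volume elements of an organ at risk,
#' evaluates the normalized cumulative dose-volume histogram on a grid:
#' \code{volume[k]} is the fraction of elements with dose >= \code{grid[k]}
#' (ties at a grid point count as receiving the level).
#'
#' @param dose_samples non-negative doses (Gy per fraction), one per
#'   equal-volume element.
#' @param grid dose grid from [buildDoseGrid()].
#' @return numeric volume-fraction vector on \code{grid}, non-increasing,
#'   in [0, 1].
#' @export
cumulativeDVH <- function(dose_samples, grid) {
  if (!length(dose_samples)) stop("at least one dose sample is required")
  if (any(dose_samples < 0)) stop("dose samples must be non-negative")
  vapply(grid, function(d) mean(dose_samples >= d), numeric(1))
}

#' Resample a DVH curve onto a new grid
#'
#' Linear interpolation between source knots; linear interpolation of a
#' non-increasing sequence is non-increasing and bounded, so the DVH
#' invariants are preserved. Extrapolation is refused.
#'
#' @param volume volume fractions on \code{grid}.
#' @param grid source dose grid.
#' @param target target dose grid, contained in the source span.
#' @return volume fractions on \code{target}.
#' @export
resampleCurve <- function(volume, grid, target) {
  stopifnot(length(volume) == length(grid))
  if (min(target) < min(grid) - 1e-9 || max(target) > max(grid) + 1e-9)
    stop("target grid requires extrapolation outside the source dose span")
  xout <- pmin(pmax(target, min(grid)), max(grid))  # absorb fp endpoint noise
  stats::approx(grid, volume, xout = xout, method = "linear",
                ties = "ordered")$y
}

#' Dummy-code clinical covariates against fixed reference levels
#'
#' One-hot-minus-reference coding of the clinical covariates. Reference
#' levels are female sex, postoperative RT, no induction chemotherapy, no
#' concurrent chemotherapy, and oropharynx/oral-cavity primary site; the
#' reference categories are dropped to avoid perfect collinearity with the
#' intercept. Age enters continuously, in years.
#'
#' @param clinical a data.frame or DataFrame with columns \code{sex},
#'   \code{age}, \code{rt_intent}, \code{induction_chemo},
#'   \code{concurrent_chemo}, \code{primary_site}, levels restricted to the
#'   package enumerations.
#' @return numeric matrix with 11 columns (male, age, definitive_rt,
#'   induction_chemo, cisplatin, carboplatin, cis_carbo, hypopharynx_larynx,
#'   nasopharynx_nasal_cavity, unknown_primary, parotid) and attribute
#'   \code{reference_levels}.
#' @export
encodeDesign <- function(clinical) {
  clinical <- as.data.frame(clinical)
  req <- c("sex", "age", "rt_intent", "induction_chemo", "concurrent_chemo",
           "primary_site")
  missing <- setdiff(req, colnames(clinical))
  if (length(missing))
    stop("missing clinical column(s): ", paste(missing, collapse = ", "))
  checkLevels <- function(col, levels) {
    bad <- setdiff(unique(as.character(clinical[[col]])), levels)
    if (length(bad))
      stop(sprintf("unknown %s level(s): %s", col, paste(bad, collapse = ", ")))
  }
  checkLevels("sex", .SEX_LEVELS)
  checkLevels("rt_intent", .INTENT_LEVELS)
  checkLevels("induction_chemo", .YESNO_LEVELS)
  checkLevels("concurrent_chemo", .CONCURRENT_LEVELS)
  checkLevels("primary_site", .SITE_LEVELS)
  if (!is.numeric(clinical$age)) stop("age must be numeric (years)")
  sx <- as.character(clinical$sex)
  cc <- as.character(clinical$concurrent_chemo)
  ps <- as.character(clinical$primary_site)
  x <- cbind(
    male = as.numeric(sx == "male"),
    age = as.numeric(clinical$age),
    definitive_rt = as.numeric(as.character(clinical$rt_intent) == "definitive"),
    induction_chemo = as.numeric(as.character(clinical$induction_chemo) == "yes"),
    cisplatin = as.numeric(cc == "cisplatin"),
    carboplatin = as.numeric(cc == "carboplatin"),
    cis_carbo = as.numeric(cc == "cis_carbo"),
    hypopharynx_larynx = as.numeric(ps == "hypopharynx_larynx"),
    nasopharynx_nasal_cavity = as.numeric(ps == "nasopharynx_nasal_cavity"),
    unknown_primary = as.numeric(ps == "unknown_primary"),
    parotid = as.numeric(ps == "parotid"))
  rownames(x) <- rownames(clinical)
  attr(x, "reference_levels") <- c(sex = "female", rt_intent = "postoperative",
                                   induction_chemo = "no",
                                   concurrent_chemo = "none",
                                   primary_site = "oropharynx_oral_cavity")
  x
}

#' Construct a DVHCohort
#'
#' @param volume p x n matrix of volume fractions (rows = grid points,
#'   columns = patients) or an n x p matrix with patients in rows (detected
#'   from the grid length).
#' @param grid fractional-dose grid from [buildDoseGrid()].
#' @param clinical data.frame of clinical covariates, one row per patient.
#' @param outcome binary toxicity vector (1 = severe).
#' @param patient_ids optional character ids (default P001, ...).
#' @return a validated [DVHCohort-class] object.
#' @export
DVHCohort <- function(volume, grid, clinical, outcome, patient_ids = NULL) {
  volume <- as.matrix(volume)
  if (nrow(volume) != length(grid)) {
    if (ncol(volume) == length(grid)) volume <- t(volume)
    else stop("volume matrix does not match grid length")
  }
  n <- ncol(volume)
  if (is.null(patient_ids)) patient_ids <- sprintf("P%04d", seq_len(n))
  clinical <- as.data.frame(clinical)
  stopifnot(nrow(clinical) == n, length(outcome) == n)
  cd <- S4Vectors::DataFrame(clinical, outcome = as.integer(outcome),
                             row.names = patient_ids)
  colnames(volume) <- patient_ids
  rownames(volume) <- sprintf("d_%.2f", grid)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(volume = volume),
    rowData = S4Vectors::DataFrame(dose = grid),
    colData = cd)
  methods::new("DVHCohort", se)
}

#' @rdname doseGrid
#' @export
setMethod("doseGrid", "DVHCohort", function(x)
  SummarizedExperiment::rowData(x)$dose)

#' @rdname doseGrid
#' @export
setMethod("doseStep", "DVHCohort", function(x) {
  g <- doseGrid(x)
  g[2L] - g[1L]
})

#' @rdname volumeMatrix
#' @export
setMethod("volumeMatrix", "DVHCohort", function(x)
  SummarizedExperiment::assay(x, "volume"))

#' @rdname outcomes
#' @export
setMethod("outcomes", "DVHCohort", function(x)
  as.integer(SummarizedExperiment::colData(x)$outcome))

#' @rdname clinicalData
#' @export
setMethod("clinicalData", "DVHCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  cd[, setdiff(colnames(cd), "outcome"), drop = FALSE]
})

setMethod("show", "DVHCohort", function(object) {
  g <- doseGrid(object)
  cat(sprintf("DVHCohort: %d patients, %d dose points [%.2f, %.2f] Gy/fraction\n",
              ncol(object), length(g), min(g), max(g)))
  y <- outcomes(object)
  cat(sprintf("  severe toxicity: %d/%d (%.1f%%)\n",
              sum(y), length(y), 100 * mean(y)))
})

#' Read / write a DVH cohort as paired CSV files
#'
#' The on-disk form is two comma-separated files: \code{dvh.csv} with columns
#' \code{patient_id, V_0.00, V_0.01, ...} (volume fractions, dose labels in
#' Gy with two decimals) and \code{clinical.csv} with columns
#' \code{patient_id, sex, age, rt_intent, induction_chemo, concurrent_chemo,
#' primary_site, outcome}. Writing then reading reproduces the cohort to the
#' precision stored.
#'
#' @param dvh_csv,clinical_csv file paths.
#' @param cohort a [DVHCohort-class].
#' @param digits decimal digits for stored volume fractions.
#' @return \code{readCohort} returns a [DVHCohort-class];
#'   \code{writeCohort} returns the paths invisibly.
#' @export
readCohort <- function(dvh_csv, clinical_csv) {
  dvh <- utils::read.csv(dvh_csv, check.names = FALSE)
  clin <- utils::read.csv(clinical_csv, check.names = FALSE)
  if (!"patient_id" %in% colnames(dvh)) stop("dvh CSV lacks patient_id")
  if (!"patient_id" %in% colnames(clin)) stop("clinical CSV lacks patient_id")
  if (!"outcome" %in% colnames(clin)) stop("clinical CSV lacks outcome column")
  vcols <- grep("^V_", colnames(dvh), value = TRUE)
  if (!length(vcols)) stop("dvh CSV has no V_<dose> columns")
  grid <- as.numeric(sub("^V_", "", vcols))
  ord <- order(grid)
  grid <- grid[ord]
  vol <- t(as.matrix(dvh[, vcols[ord], drop = FALSE]))
  ids <- as.character(dvh$patient_id)
  if (!identical(ids, as.character(clin$patient_id)))
    stop("patient_id mismatch between dvh and clinical CSVs")
  bad <- which(apply(vol, 2L, function(v) any(v < 0 | v > 1)))
  if (length(bad))
    stop("volume fraction outside [0,1] for patient(s): ",
         paste(ids[bad], collapse = ", "))
  bad <- which(apply(vol, 2L, function(v) any(diff(v) > 1e-9)))
  if (length(bad))
    stop("non-monotone DVH row(s) for patient(s): ",
         paste(ids[bad], collapse = ", "))
  clin2 <- clin[, setdiff(colnames(clin), c("patient_id", "outcome")),
                drop = FALSE]
  DVHCohort(vol, grid, clin2, clin$outcome, patient_ids = ids)
}

#' @rdname readCohort
#' @export
writeCohort <- function(cohort, dvh_csv, clinical_csv, digits = 10) {
  g <- doseGrid(cohort)
  v <- volumeMatrix(cohort)
  dvh <- data.frame(patient_id = colnames(v),
                    round(t(v), digits), check.names = FALSE)
  colnames(dvh) <- c("patient_id", sprintf("V_%.2f", g))
  clin <- as.data.frame(clinicalData(cohort))
  out <- data.frame(patient_id = colnames(v), clin,
                    outcome = outcomes(cohort), check.names = FALSE)
  utils::write.csv(dvh, dvh_csv, row.names = FALSE, quote = FALSE)
  utils::write.csv(out, clinical_csv, row.names = FALSE, quote = FALSE)
  invisible(c(dvh = dvh_csv, clinical = clinical_csv))
}
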
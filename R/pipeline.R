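#' @include validation.R
NULL

#' Serialize / restore a fitted model as flat JSON text
#'
#' Writes the full prediction state (dose grid, training mean, component
#' functions, coefficients, selection metadata) so a model can be frozen,
#' shipped as text, and used for external validation. Round-tripping
#' reproduces predictions exactly to the stored precision.
#'
#' @param model a [FunctionalLogisticModel-class] or [PLRModel-class].
#' @param path output JSON file.
#' @return \code{readModel} returns the restored model object.
#' @export
writeModel <- function(model, path) {
  if (methods::is(model, "FunctionalLogisticModel")) {
    b <- model@basis
    obj <- list(type = "functional", kind = b@kind,
                grid = b@grid, mean_function = b@meanFunction,
                components = unname(b@components[, seq_len(model@kn),
                                                 drop = FALSE]),
                eigenvalues = b@eigenvalues[seq_len(model@kn)],
                total_variance = b@totalVariance,
                intercept = model@intercept,
                clinical_coefficients = as.list(model@clinicalCoefficients),
                functional_coefficients = unname(model@functionalCoefficients),
                kn = model@kn, r = model@r, converged = model@converged)
  } else if (methods::is(model, "PLRModel")) {
    obj <- list(type = "plr", intercept = model@intercept,
                coefficients = as.list(model@coefficients),
                lambda = model@lambda, dose_grid = model@doseGrid,
                cv_table = model@cvTable)
  } else stop("unsupported model type")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$type == "functional") {
    comps <- matrix(unlist(obj$components), nrow = length(obj$grid))
    kn <- as.integer(obj$kn)
    prefix <- if (obj$kind == "fpca") "FPC" else "FPLS"
    colnames(comps) <- paste0(prefix, seq_len(kn))
    fcoef <- as.numeric(obj$functional_coefficients)
    names(fcoef) <- colnames(comps)
    scores <- matrix(numeric(0), 0L, kn,
                     dimnames = list(NULL, colnames(comps)))
    basis <- .makeBasis(as.numeric(obj$grid), obj$kind, comps,
                        as.numeric(obj$eigenvalues),
                        totalVariance = obj$total_variance,
                        meanFunction = as.numeric(obj$mean_function),
                        scores = scores)
    methods::new("FunctionalLogisticModel",
                 intercept = obj$intercept,
                 clinicalCoefficients = unlist(obj$clinical_coefficients),
                 functionalCoefficients = fcoef,
                 basis = basis, kn = kn, r = obj$r,
                 converged = isTRUE(obj$converged), nIterations = 0L,
                 referenceLevels = character())
  } else if (obj$type == "plr") {
    methods::new("PLRModel", intercept = obj$intercept,
                 coefficients = unlist(obj$coefficients),
                 lambda = obj$lambda,
                 cvTable = as.data.frame(obj$cv_table),
                 doseGrid = as.numeric(obj$dose_grid))
  } else stop("unknown model type: ", obj$type)
}

#' End-to-end simulate / fit / validate pipeline
#'
#' Orchestrates the full analysis on a synthetic cohort: generate the cohort
#' from a preset, fit the requested model family, run bootstrap
#' optimism-corrected validation and odds-ratio confidence intervals, and
#' write all artifacts (cohort CSVs, model JSON, validation report JSON,
#' odds-ratio CSV) into an output directory. One master seed fans out into
#' named substreams (simulation / folds / bootstrap), so e.g. changing B
#' does not perturb the simulated cohort; identical configurations produce
#' byte-identical reports.
#'
#' @param preset \code{"mucositis"} or \code{"dysphagia"}.
#' @param method \code{"fpls-lr"}, \code{"fpc-lr"} or \code{"plr"}.
#' @param n cohort size.
#' @param B bootstrap replicate count.
#' @param seed master seed.
#' @param out_dir output directory (created if needed).
#' @param component_budget,r_grid passed to [fitNTCP()].
#' @return invisibly, a list with the cohort, model, report and OR table.
#' @export
runPipeline <- function(preset = c("mucositis", "dysphagia"),
                        method = c("fpls-lr", "fpc-lr", "plr"),
                        n = 200L, B = 50L, seed = 1L, out_dir = ".",
                        component_budget = 5L,
                        r_grid = defaultPenaltyGrid()) {
  preset <- match.arg(preset)
  method <- match.arg(method)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  cfg <- if (preset == "mucositis") {
    presetMucositisLike(n_patients = n, seed = deriveSeed(seed, "simulate"))
  } else {
    presetDysphagiaLike(n_patients = n, seed = deriveSeed(seed, "simulate"))
  }
  cohort <- generateCohort(cfg)
  writeCohort(cohort, file.path(out_dir, "dvh.csv"),
              file.path(out_dir, "clinical.csv"))
  truth <- S4Vectors::metadata(cohort)$truth
  utils::write.csv(
    data.frame(dose = doseGrid(cohort), true_beta = truth$beta),
    file.path(out_dir, "truth.csv"), row.names = FALSE, quote = FALSE)
  recipe <- ntcpRecipe(method, component_budget = component_budget,
                       r_grid = r_grid,
                       fold_seed = deriveSeed(seed, "folds"))
  model <- recipe$fit(cohort)
  if (methods::is(model, "FunctionalLogisticModel") ||
      methods::is(model, "PLRModel"))
    writeModel(model, file.path(out_dir, "model.json"))
  report <- optimismCorrect(recipe, cohort, B = B,
                            seed = deriveSeed(seed, "bootstrap"))
  jsonlite::write_json(
    list(preset = preset, method = method, n = n, B = B, seed = seed,
         metrics = report@metrics, n_redrawn = report@nRedrawn),
    file.path(out_dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  or_tab <- bootstrapORCI(recipe, cohort, B = B,
                          seed = deriveSeed(seed, "bootstrap"))
  utils::write.csv(or_tab@table, file.path(out_dir, "or_ci.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest <- list(package_version = as.character(utils::packageVersion("fdantcp")),
                   preset = preset, method = method, n = n, B = B,
                   seed = seed,
                   substreams = list(simulate = deriveSeed(seed, "simulate"),
                                     folds = deriveSeed(seed, "folds"),
                                     bootstrap = deriveSeed(seed, "bootstrap")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(cohort = cohort, model = model, report = report,
                 or_table = or_tab))
}
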
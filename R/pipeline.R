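#' Default pipeline configuration
#'
#' Returns the default run configuration as a named list. Fields:
#' `seed` (integer, drives simulation and bootstrap), `alpha` (ANOVA
#' screening level), `model` ("I", "II" or "both"), `prior_mode`
#' ("uniform"/"empirical"), `iterations` (bootstrap B), `group_size`
#' (patients per class per bootstrap iteration), `feature_set` ("auto" =
#' ANOVA-selected, or an explicit biomarker vector), `resample_psp`,
#' `protocol` ("resubstitution"/"oob"), `outlier_threshold`, `cohort_file`
#' (CSV of panels; when `NULL` a synthetic cohort is simulated from
#' `spec_file` or the reference specification), `spec_file` (JSON/YAML
#' cohort spec) and `out_dir` (where report tables are written).
#'
#' @return Named list of defaults.
#' @export
defaultRunConfig <- function() {
  list(seed = 1L, alpha = 0.05, model = "both", prior_mode = "uniform",
       iterations = 25000L, group_size = 10L, feature_set = "auto",
       resample_psp = TRUE, protocol = "resubstitution",
       outlier_threshold = 2.5, cohort_file = NULL, spec_file = NULL,
       out_dir = "pdmri_reports")
}

#' Read a pipeline configuration file
#'
#' JSON or YAML (by extension); fields missing from the file keep their
#' defaults ([defaultRunConfig()]), unknown fields are rejected.
#'
#' @param file Path to a `.json`, `.yaml` or `.yml` config file.
#' @return Validated configuration list.
#' @export
readRunConfig <- function(file) {
  if (!file.exists(file))
    .pdmriStop("pdmri_config_error", "config file not found: %s", file)
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
  base <- defaultRunConfig()
  unknown <- setdiff(names(cfg), names(base))
  if (length(unknown))
    .pdmriStop("pdmri_config_error", "unknown config field(s): %s",
               paste(unknown, collapse = ", "))
  base[names(cfg)] <- cfg
  validateRunConfig(base)
}

#' @rdname readRunConfig
#' @param config Configuration list to validate (partial lists are completed
#'   with defaults).
#' @export
validateRunConfig <- function(config) {
  base <- defaultRunConfig()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    .pdmriStop("pdmri_config_error", "unknown config field(s): %s",
               paste(unknown, collapse = ", "))
  base[names(config)] <- config
  config <- base
  if (!is.numeric(config$alpha) || config$alpha <= 0 || config$alpha >= 1)
    .pdmriStop("pdmri_config_error", "alpha must lie in (0, 1)")
  if (!(config$model %in% c("I", "II", "both")))
    .pdmriStop("pdmri_config_error", "model must be 'I', 'II' or 'both'")
  if (!(config$prior_mode %in% c("uniform", "empirical")))
    .pdmriStop("pdmri_config_error", "prior_mode must be uniform or empirical")
  if (!(config$protocol %in% c("resubstitution", "oob")))
    .pdmriStop("pdmri_config_error", "protocol must be resubstitution or oob")
  if (config$iterations < 1L || config$group_size < 1L)
    .pdmriStop("pdmri_config_error",
               "iterations and group_size must be positive")
  if (!identical(config$feature_set, "auto") &&
      !all(config$feature_set %in% .BIOMARKERS))
    .pdmriStop("pdmri_config_error", "feature_set must be 'auto' or biomarkers")
  config$seed <- as.integer(config$seed)
  config$iterations <- as.integer(config$iterations)
  config$group_size <- as.integer(config$group_size)
  config
}

#' Run the full decision-model pipeline
#'
#' Executes the analysis sequence end to end: obtain a cohort (from
#' `cohort_file`, or simulated from `spec_file` / the reference
#' specification), screen biomarkers by one-way ANOVA, select the feature
#' panel, fit and apply the decision model(s), run the class-balanced
#' bootstrap evaluation, and flag outliers. All tables are written as CSV
#' under `out_dir`, every stage is logged via `message()`, and the returned
#' bundle contains every intermediate object. Identical configurations
#' produce identical bundles.
#'
#' @param config Configuration list (see [defaultRunConfig()]) or the path to
#'   a JSON/YAML config file.
#' @return (Invisibly) a list: `config`, `cohort`, `screening`, `features`,
#'   `classification` (per model), `bootstrap` (per model), `outliers`,
#'   `files` (paths written).
#' @export
#' @examples
#' \donttest{
#' out <- runPipeline(list(iterations = 200, out_dir = tempfile()))
#' }
runPipeline <- function(config = defaultRunConfig()) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- validateRunConfig(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()

  cohort <- if (!is.null(config$cohort_file)) {
    message("pipeline: reading cohort from ", config$cohort_file)
    readCohort(config$cohort_file)
  } else {
    spec <- if (!is.null(config$spec_file)) readCohortSpec(config$spec_file)
            else referenceCohortSpec()
    message("pipeline: simulating cohort (seed ", config$seed, ")")
    simulateCohort(spec, seed = config$seed)
  }
  message("pipeline: ", ncol(cohort), " patients (",
          paste(sprintf("%s=%d", names(groupSizes(cohort)),
                        groupSizes(cohort)), collapse = ", "), ")")

  screening <- screenBiomarkers(cohort, alpha = config$alpha)
  f <- file.path(config$out_dir, "screening.csv")
  write.csv(screening, f, row.names = FALSE)
  files <- c(files, f)

  features <- if (identical(config$feature_set, "auto"))
    selectBiomarkers(screening, alpha = config$alpha)
  else config$feature_set
  dropped <- setdiff(screening$biomarker, features)
  message("pipeline: retained features (alpha=", config$alpha, "): ",
          paste(features, collapse = ", "))
  message("pipeline: excluded features: ",
          if (length(dropped)) paste(dropped, collapse = ", ") else "none")
  if (!length(features))
    .pdmriStop("pdmri_numeric_error",
               "no biomarker passed screening at alpha=%g", config$alpha)

  models <- if (config$model == "both") c("I", "II") else config$model
  classification <- list(); bootstrap <- list()
  for (mid in models) {
    message("pipeline: classifying with model ", mid)
    cls <- classifyCohort(cohort, model = mid, features = features,
                          priorMode = config$prior_mode)
    classification[[mid]] <- cls
    f <- file.path(config$out_dir, sprintf("classification_model%s.csv", mid))
    write.csv(cls, f, row.names = FALSE)
    files <- c(files, f)
    message(sprintf("pipeline: model %s resubstitution: %d/%d correct (%.0f%%)",
                    mid, sum(cls$correct, na.rm = TRUE), nrow(cls),
                    100 * mean(cls$correct, na.rm = TRUE)))
    message("pipeline: bootstrap (B=", config$iterations, ", ",
            config$group_size, " per group) for model ", mid)
    rep <- bootstrapEvaluate(cohort, model = mid,
                             iterations = config$iterations,
                             groupSize = config$group_size,
                             seed = config$seed,
                             features = features,
                             resamplePsp = config$resample_psp,
                             protocol = config$protocol)
    bootstrap[[mid]] <- rep
    f <- file.path(config$out_dir, sprintf("bootstrap_model%s.csv", mid))
    write.csv(bootstrapSummary(rep), f, row.names = FALSE)
    files <- c(files, f)
  }

  f <- file.path(config$out_dir, "metrics_table.csv")
  write.csv(do.call(formatBootstrapReports, unname(bootstrap)), f,
            row.names = FALSE)
  files <- c(files, f)

  outliers <- outlierReport(cohort, classification[[models[1L]]],
                            threshold = config$outlier_threshold)
  f <- file.path(config$out_dir, "outliers.csv")
  write.csv(outliers, f, row.names = FALSE)
  files <- c(files, f)
  message("pipeline: ", nrow(outliers), " outlier patient(s) flagged")
  message("pipeline: reports written to ", config$out_dir)

  invisible(list(config = config, cohort = cohort, screening = screening,
                 features = features, classification = classification,
                 bootstrap = bootstrap, outliers = outliers, files = files))
}
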
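# Table validation, configuration and the umbrella pipeline runner.

.require_columns <- function(df, cols, what) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_validation("%s table is missing required column(s): %s",
                    what, paste(miss, collapse = ", "))
}

#' @rdname read_tables
#' @export
validate_scans <- function(scans) {
  .require_columns(scans, c("participant_id", "timestamp", "count"), "scans")
  if (nrow(scans)) {
    bad <- which(is.na(scans$count) | scans$count < 0)
    if (length(bad))
      stop_validation("negative or missing NBDC count at scans row(s): %s",
                      paste(utils::head(bad, 5), collapse = ", "))
    if (anyNA(parse_timestamp(scans$timestamp))) {
      bad <- which(is.na(parse_timestamp(scans$timestamp)))
      stop_validation("unparseable timestamp at scans row(s): %s",
                      paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  invisible(scans)
}

#' @rdname read_tables
#' @export
validate_phq8 <- function(phq8) {
  .require_columns(phq8, c("participant_id", "date", "score"), "phq8")
  if (nrow(phq8)) {
    d <- as.Date(phq8$date, optional = TRUE)
    if (anyNA(d))
      stop_validation("unparseable date at phq8 row(s): %s",
                      paste(utils::head(which(is.na(d)), 5), collapse = ", "))
    bad <- which(is.na(phq8$score) | phq8$score < 0 | phq8$score > 24 |
                   phq8$score != round(phq8$score))
    if (length(bad))
      stop_validation("PHQ-8 score outside 0..24 at phq8 row(s): %s",
                      paste(utils::head(bad, 5), collapse = ", "))
  }
  invisible(phq8)
}

#' @rdname read_tables
#' @export
validate_demographics <- function(demographics) {
  .require_columns(demographics,
                   c("participant_id", "age", "gender", "education_years"),
                   "demographics")
  if (anyDuplicated(demographics$participant_id))
    stop_validation("duplicate participant_id in demographics")
  if (nrow(demographics) &&
      any(is.na(demographics$age) | is.na(demographics$gender) |
            is.na(demographics$education_years)))
    stop_validation("demographics contain missing covariate values")
  invisible(demographics)
}

#' Read and validate the three input tables
#'
#' @param scans_path,phq8_path,demographics_path CSV paths with the column
#'   layouts written by [write_cohort()].
#' @param scans,phq8,demographics in the `validate_*` helpers, the already
#'   loaded data.frames.
#' @return list with validated `scans`, `phq8` (dates normalized to `Date`)
#'   and `demographics` data.frames.
#' @export
read_tables <- function(scans_path, phq8_path, demographics_path) {
  for (p in c(scans_path, phq8_path, demographics_path))
    if (!file.exists(p)) stop_validation("input file does not exist: %s", p)
  scans <- utils::read.csv(scans_path, stringsAsFactors = FALSE)
  phq8 <- utils::read.csv(phq8_path, stringsAsFactors = FALSE)
  demographics <- utils::read.csv(demographics_path, stringsAsFactors = FALSE)
  validate_scans(scans)
  validate_phq8(phq8)
  validate_demographics(demographics)
  phq8$date <- as.Date(phq8$date)
  list(scans = scans, phq8 = phq8, demographics = demographics)
}

#' Pipeline configuration
#'
#' @param out_dir output directory for all artifacts.
#' @param seed master seed: also seeds simulation and the sampler unless they
#'   set their own.
#' @param simulate `NULL` to read existing CSVs (then `scans_path` etc. are
#'   required), or a [cohort_config()] to generate the inputs first.
#' @param scans_path,phq8_path,demographics_path input CSVs when not
#'   simulating.
#' @param settings an [interval_settings()].
#' @param entropy an [entropy_config()].
#' @param bands a [spectrum_bands()].
#' @param sampler a [hier_spec()].
#' @param predict_schemes CV schemes to run (subset of `c("lao","loo")`);
#'   empty vector skips the prediction stage.
#' @param predict_models models to run (subset of `c("full","baseline")`).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = NULL,
                            scans_path = NULL, phq8_path = NULL,
                            demographics_path = NULL,
                            settings = interval_settings(),
                            entropy = entropy_config(),
                            bands = spectrum_bands(),
                            sampler = hier_spec(seed = seed),
                            predict_schemes = c("lao", "loo"),
                            predict_models = c("full", "baseline")) {
  if (is.null(simulate) &&
      (is.null(scans_path) || is.null(phq8_path) || is.null(demographics_path)))
    stop_validation("either supply a simulate config or all three input paths")
  structure(list(out_dir = out_dir, seed = as.integer(seed),
                 simulate = simulate, scans_path = scans_path,
                 phq8_path = phq8_path, demographics_path = demographics_path,
                 settings = settings, entropy = entropy, bands = bands,
                 sampler = sampler, predict_schemes = predict_schemes,
                 predict_models = predict_models),
            class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Reads a flat YAML file whose sections mirror the constructor arguments
#' (`simulate:`, `settings:`, `entropy:`, `bands:`, `sampler:` plus the
#' top-level paths and seed).
#'
#' @param path YAML file.
#' @param out_dir overrides the file's `out_dir` when given.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  if (!file.exists(path)) stop_validation("config file does not exist: %s", path)
  y <- yaml::read_yaml(path)
  args <- list(out_dir = out_dir %||% y$out_dir, seed = y$seed %||% 1L)
  if (!is.null(y$simulate)) args$simulate <- do.call(cohort_config, y$simulate)
  for (nm in c("scans_path", "phq8_path", "demographics_path",
               "predict_schemes", "predict_models"))
    if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
  if (!is.null(y$settings)) args$settings <- do.call(interval_settings, y$settings)
  if (!is.null(y$entropy)) args$entropy <- do.call(entropy_config, y$entropy)
  if (!is.null(y$sampler)) args$sampler <- do.call(hier_spec, y$sampler)
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' Executes (optional) simulation, preprocessing, feature extraction,
#' association screening and prediction, writing every stage's artifacts and
#' a manifest (seed, settings, input checksums, record counts, timings) to
#' `config$out_dir`. Identical configuration and seed give bit-identical
#' outputs.
#'
#' @param config a [pipeline_config()] or path to a YAML file.
#' @param quiet suppress progress messages.
#' @return list with the in-memory stage outputs, invisibly.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      stop_runtime("pipeline stage '%s' failed: %s", name, conditionMessage(e))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 2)
    say("stage %-10s done in %.1fs", name, timings[[name]])
    res
  }

  if (!is.null(config$simulate)) {
    cohort <- stage("simulate", generate_cohort(config$simulate, out))
    tables <- list(scans = cohort$scans, phq8 = cohort$phq8,
                   demographics = cohort$demographics)
    tables$phq8$date <- as.Date(tables$phq8$date)
    input_files <- file.path(out, c("scans.csv", "phq8.csv", "demographics.csv"))
  } else {
    input_files <- c(config$scans_path, config$phq8_path,
                     config$demographics_path)
    tables <- stage("read", read_tables(config$scans_path, config$phq8_path,
                                        config$demographics_path))
  }
  if (nrow(tables$scans) == 0L)
    stop_validation("scan table is empty; nothing to preprocess")

  intervals <- stage("preprocess", build_intervals(
    tables$scans, tables$phq8, tables$demographics, config$settings))
  if (nrow(intervals$intervals) == 0L)
    stop_validation("no intervals were retained; check inclusion settings")
  utils::write.csv(intervals$intervals, file.path(out, "intervals.csv"),
                   row.names = FALSE)
  utils::write.csv(intervals$rejections, file.path(out, "rejections.csv"),
                   row.names = FALSE)

  features <- stage("features", extract_feature_table(
    intervals, tables$demographics, config$entropy, config$bands))
  utils::write.csv(features, file.path(out, "features.csv"), row.names = FALSE)

  assoc <- stage("associate", associate_features(features))
  utils::write.csv(assoc, file.path(out, "associations.csv"), row.names = FALSE)
  lrt <- stage("lrt", lrt_ladder(fit_nested_models(
    features, entropy = config$entropy, drop_collinear = TRUE)))
  utils::write.csv(lrt, file.path(out, "lrt.csv"), row.names = FALSE)

  metrics <- NULL
  if (length(config$predict_schemes)) {
    metrics <- stage("predict", {
      rows <- list()
      for (sc in config$predict_schemes) for (md in config$predict_models) {
        cv <- run_cv(features, sc, md, config$sampler,
                     entropy = config$entropy)
        utils::write.csv(cv$predictions,
                         file.path(out, sprintf("predictions_%s_%s.csv", sc, md)),
                         row.names = FALSE)
        rows[[paste(sc, md)]] <- data.frame(
          scheme = toupper(sc), model = md, r2 = cv$metrics$r2,
          rmse = cv$metrics$rmse, n_test = cv$metrics$n_test)
      }
      do.call(rbind, rows)
    })
    rownames(metrics) <- NULL
    utils::write.csv(metrics, file.path(out, "metrics.csv"), row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("nbdcdep")),
    seed = config$seed,
    sampler = unclass(config$sampler),
    settings = lapply(unclass(config$settings),
                      function(x) if (inherits(x, "Date")) format(x) else x),
    simulated = !is.null(config$simulate),
    input_checksums = as.list(tools::md5sum(input_files)),
    retained_intervals = nrow(intervals$intervals),
    rejected_records = nrow(intervals$rejections),
    participants = length(unique(intervals$intervals$participant_id)),
    timings_seconds = as.list(timings))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(tables = tables, intervals = intervals, features = features,
                 associations = assoc, lrt = lrt, metrics = metrics,
                 manifest = manifest))
}
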
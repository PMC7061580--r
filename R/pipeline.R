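#' Default end-to-end run configuration
#'
#' A plain nested list (serializable as JSON) with every knob of the
#' pipeline.  Defaults mirror the standard protocol: 45 cycles of
#' 5 s + 15 s at 90 Hz, four film thicknesses, 11 VOCs in duplicate,
#' 100-point smoothing window, RBF SVM with C = 100 / gamma = 0.1 under
#' stratified 10-fold cross-validation.
#'
#' @param master_seed integer master seed for the simulation and CV folds.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(master_seed = 0L) {
  structure(list(
    schedule = list(n_cycles = 45L, exposure_s = 5, recovery_s = 15,
                    sampling_hz = 90),
    films = lapply(unname(default_film_set()), unclass),
    vocs = voc_names(),
    voc_seed = 0L,
    n_replicates = 2L,
    smoothing = list(window_points = 100L, window_shape = "hanning"),
    cv = list(n_folds = 10L, stratified = TRUE, C = 100, gamma = 0.1,
              standardize = TRUE),
    master_seed = as.integer(master_seed)
  ), class = "run_config")
}

check_keys <- function(x, allowed, where, violations) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    violations <- c(violations,
                    sprintf("%s: unknown key(s) %s", where,
                            paste(extra, collapse = ", ")))
  violations
}

#' Validate a run configuration
#'
#' Accepts a `run_config` list or a path to a JSON document.  Every
#' component invariant is checked (schedule positivity, film monotonicity
#' fields, fold count, kernel hyperparameters); unknown keys are rejected.
#'
#' @param config a list or a JSON file path.
#' @param collect if `TRUE`, return the character vector of violations
#'   (empty when valid) instead of raising.
#' @return The validated `run_config` (invisibly a list), or the violation
#'   vector when `collect = TRUE`.
#' @export
validate_config <- function(config, collect = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::read_json(config, simplifyVector = TRUE,
                                  simplifyDataFrame = FALSE)
  if (!is.list(config)) stop("config must be a list or a JSON path",
                             call. = FALSE)
  v <- character()
  v <- check_keys(config, c("schedule", "films", "vocs", "voc_seed",
                            "n_replicates", "smoothing", "cv", "master_seed"),
                  "config", v)
  sc <- config$schedule
  v <- check_keys(sc, c("n_cycles", "exposure_s", "recovery_s", "sampling_hz"),
                  "schedule", v)
  num_ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!num_ok(sc$n_cycles) || sc$n_cycles < 1)
    v <- c(v, "schedule.n_cycles: must be >= 1")
  if (!num_ok(sc$exposure_s) || sc$exposure_s <= 0)
    v <- c(v, "schedule.exposure_s: must be > 0")
  if (!num_ok(sc$recovery_s) || sc$recovery_s <= 0)
    v <- c(v, "schedule.recovery_s: must be > 0")
  if (!num_ok(sc$sampling_hz) || sc$sampling_hz <= 0)
    v <- c(v, "schedule.sampling_hz: must be > 0")
  if (!is.list(config$films) || length(config$films) < 1) {
    v <- c(v, "films: need at least one film")
  } else {
    for (i in seq_along(config$films)) {
      fm <- config$films[[i]]
      v <- check_keys(fm, c("predefined_um", "measured_um", "baseline_level",
                            "active_area_fraction"),
                      sprintf("films[%d]", i), v)
      for (fld in c("predefined_um", "measured_um", "baseline_level"))
        if (!num_ok(fm[[fld]]) || fm[[fld]] <= 0)
          v <- c(v, sprintf("films[%d].%s: must be > 0", i, fld))
      if (!num_ok(fm$active_area_fraction) || fm$active_area_fraction < 0 ||
          fm$active_area_fraction > 1)
        v <- c(v, sprintf("films[%d].active_area_fraction: must be in [0, 1]", i))
    }
  }
  vv <- unlist(config$vocs)
  if (!is.character(vv) || length(vv) < 1 || !all(vv %in% voc_names()) ||
      anyDuplicated(vv))
    v <- c(v, "vocs: must be a non-empty subset of the 11 library VOC names")
  if (!num_ok(config$voc_seed)) v <- c(v, "voc_seed: must be an integer")
  if (!num_ok(config$n_replicates) || config$n_replicates < 1)
    v <- c(v, "n_replicates: must be >= 1")
  sm <- config$smoothing
  v <- check_keys(sm, c("window_points", "window_shape"), "smoothing", v)
  if (!num_ok(sm$window_points) || sm$window_points < 1)
    v <- c(v, "smoothing.window_points: must be >= 1")
  if (!is.character(sm$window_shape) ||
      !sm$window_shape %in% c("hanning", "rectangular"))
    v <- c(v, "smoothing.window_shape: must be 'hanning' or 'rectangular'")
  cv <- config$cv
  v <- check_keys(cv, c("n_folds", "stratified", "C", "gamma", "standardize"),
                  "cv", v)
  if (!num_ok(cv$n_folds) || cv$n_folds < 2)
    v <- c(v, "cv.n_folds: CVConfig requires n_folds >= 2")
  if (!num_ok(cv$C) || cv$C <= 0) v <- c(v, "cv.C: must be > 0")
  if (!num_ok(cv$gamma) || cv$gamma <= 0) v <- c(v, "cv.gamma: must be > 0")
  if (!num_ok(config$master_seed)) v <- c(v, "master_seed: must be an integer")
  if (collect) return(v)
  if (length(v))
    stop("invalid run config:\n  ", paste(v, collapse = "\n  "),
         call. = FALSE)
  class(config) <- "run_config"
  invisible(config)
}

#' Run the full pipeline: simulate, preprocess, extract, classify, report
#'
#' Simulates the configured experiment, extracts per-cycle features and, for
#' each film thickness independently, runs stratified cross-validation of
#' the RBF SVM.  Per thickness it writes `features_<t>um.csv`,
#' `report_<t>um_confusion.csv` and `report_<t>um_metrics.json`, plus a
#' top-level `config.json` and `manifest.json` (config MD5, seeds, files).
#' Reruns with the same config produce byte-identical feature tables.
#'
#' @param config a `run_config` list (validated here) or JSON path.
#' @param output_dir writable output directory (created if needed).
#' @param quiet suppress per-stage progress messages.
#' @return Invisibly, a named list of `classification_report` objects, one
#'   per thickness.
#' @export
run_experiment <- function(config = default_run_config(), output_dir,
                           quiet = FALSE) {
  config <- validate_config(config)
  if (missing(output_dir)) stop("`output_dir` is required", call. = FALSE)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  schedule <- assay_schedule(config$schedule$n_cycles, config$schedule$exposure_s,
                             config$schedule$recovery_s, config$schedule$sampling_hz)
  films <- lapply(config$films, function(fm)
    film_model(fm$predefined_um, fm$measured_um, fm$baseline_level,
               fm$active_area_fraction))
  vocs <- default_voc_library(config$voc_seed)[unlist(config$vocs)]
  smooth_cfg <- smooth_config(config$smoothing$window_points,
                              config$smoothing$window_shape)

  t0 <- proc.time()[["elapsed"]]
  say("simulating %d traces ...", length(vocs) * length(films) * config$n_replicates)
  traces <- simulate_experiment(vocs, films, schedule,
                                n_replicates = config$n_replicates,
                                seed = config$master_seed)
  say("extracting features from %d traces ...", length(traces))
  feats <- extract_feature_table(traces, schedule, smooth_cfg)

  cfg_path <- file.path(output_dir, "config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  reports <- list()
  files <- c("config.json")
  for (fm in films) {
    th <- fm$predefined_um
    tab <- feats[feats$thickness_um == th, , drop = FALSE]
    fpath <- file.path(output_dir, sprintf("features_%gum.csv", th))
    write_feature_table(tab, fpath)
    n_class <- length(unique(tab$voc))
    cvc <- cv_config(config$cv$n_folds, config$cv$stratified,
                     seed = derive_seed(config$master_seed, 999),
                     C = config$cv$C, gamma = config$cv$gamma,
                     standardize = config$cv$standardize)
    ds <- assemble_dataset(tab, th,
                           min_class_size = if (n_class > 1) cvc$n_folds else 1L)
    say("classifying thickness %g um (%d cycles, %d classes) ...",
        th, nrow(tab), n_class)
    pred <- crossval_predict(ds, cvc)
    conf <- confusion_matrix_normalized(pred$labels, pred$predicted,
                                        levels(ds$labels))
    rep <- summarize_report(conf, pred, thickness_um = th)
    stem <- file.path(output_dir, sprintf("report_%gum", th))
    write_report(rep, stem)
    reports[[format(th)]] <- rep
    files <- c(files, basename(fpath), paste0(basename(stem), "_confusion.csv"),
               paste0(basename(stem), "_metrics.json"))
  }

  manifest <- list(
    config_md5 = unname(tools::md5sum(cfg_path)),
    master_seed = config$master_seed,
    cv_seed = derive_seed(config$master_seed, 999),
    n_traces = length(traces),
    files = files,
    overall_accuracy = lapply(reports, function(r) r$overall_accuracy)
  )
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in %.1f s", proc.time()[["elapsed"]] - t0)
  invisible(reports)
}
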
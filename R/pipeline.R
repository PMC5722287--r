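#' Pipeline configuration
#'
#' Collects every constant of the end-to-end fatigue-detection pipeline in
#' one plain list so a run is fully described by (config, input data). The
#' defaults reproduce the study protocol: 50 Hz notch, 0.15-45 Hz band-pass,
#' 1 s epochs, four-entropy fusion with `m = 2` and tolerance 0.2 SD, min-max
#' normalisation to `[-1, 1]` per subject, and epoch-level leave-one-out
#' evaluation of the four classifiers.
#'
#' @param notch_hz Notch centre frequency (`NULL` disables).
#' @param band Band-pass edges in Hz.
#' @param epoch_length_s Epoch length in seconds.
#' @param measures Entropy measures, subset of `c("PE","AE","SE","FE")`.
#' @param feature_mode `"entropy"` or `"ar"`.
#' @param ar_order AR order for `feature_mode = "ar"`.
#' @param entropy An [entropy_params()] set.
#' @param classifiers Named list of [classifier_spec()]s to evaluate.
#' @param cv_unit `"epoch"` or `"subject"` leave-one-out unit.
#' @param electrodes Optional electrode subset or region label.
#' @param region_map Region definition list (default [default_region_map()]).
#' @param select_channels Also compute the accuracy-weight electrode ranking
#'   (adds the pairwise accuracy matrix; expensive for many electrodes).
#' @param selection_cv CV protocol of the accuracy matrix
#'   (`"loo"`/`"holdout"`).
#' @param new_min,new_max Normalisation target range.
#' @param seed Master seed recorded in the report.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(notch_hz = 50, band = c(0.15, 45),
                            epoch_length_s = 1,
                            measures = c("PE", "AE", "SE", "FE"),
                            feature_mode = c("entropy", "ar"), ar_order = 10,
                            entropy = entropy_params(),
                            classifiers = list(svm = classifier_spec("rbf_svm")),
                            cv_unit = "epoch",
                            electrodes = NULL,
                            region_map = default_region_map(),
                            select_channels = FALSE,
                            selection_cv = "loo",
                            new_min = -1, new_max = 1, seed = 1L) {
  feature_mode <- match.arg(feature_mode)
  stopifnot(is.list(classifiers), length(classifiers) > 0)
  structure(list(notch_hz = notch_hz, band = band,
                 epoch_length_s = epoch_length_s, measures = measures,
                 feature_mode = feature_mode, ar_order = ar_order,
                 entropy = entropy, classifiers = classifiers,
                 cv_unit = cv_unit, electrodes = electrodes,
                 region_map = region_map, select_channels = select_channels,
                 selection_cv = selection_cv,
                 new_min = new_min, new_max = new_max,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the end-to-end fatigue-detection pipeline
#'
#' Executes filter -> segment -> feature extraction -> (optional electrode
#' restriction) -> leave-one-out evaluation for every configured classifier,
#' and optionally the accuracy-weight electrode ranking. Normalisation is
#' refitted inside every cross-validation fold (see
#' [loo_cross_validate()]). When `out_dir` is given, the feature table,
#' electrode weights and a JSON report are written there.
#'
#' @param recordings A cohort tibble (from [generate_cohort()]) or a list of
#'   [eeg_recording()] objects.
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory for artifacts.
#' @return A list of class `pipeline_result`: `reports` (named list of
#'   `eval_report`s), `features`, optional `weights`, `config`, and
#'   `timings` (seconds per stage).
#' @export
run_pipeline <- function(recordings, config = pipeline_config(),
                         out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.data.frame(recordings)) recordings <- recordings$recording
  if (inherits(recordings, "eeg_recording")) recordings <- list(recordings)
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage [", name, "] failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[name]] <<- tic() - t0
    out
  }

  epochs <- stage("preprocess", {
    purrr::map_dfr(recordings, function(rec) {
      if (!is.null(config$notch_hz)) rec <- notch_filter(rec, config$notch_hz)
      rec <- bandpass_filter(rec, config$band[1], config$band[2])
      segment_epochs(rec, config$epoch_length_s)
    })
  })

  features <- stage("features", {
    extract_feature_matrix(
      epochs, measures = config$measures, mode = config$feature_mode,
      params = config$entropy, ar_order = config$ar_order,
      low_hz = config$band[1], high_hz = config$band[2])
  })

  if (!is.null(config$electrodes)) {
    features <- stage("region", {
      select_region(features, config$electrodes, config$region_map)
    })
  }

  reports <- stage("evaluate", {
    lapply(config$classifiers, function(clf) {
      loo_cross_validate(features, clf, unit = config$cv_unit)
    })
  })

  weights <- NULL
  if (isTRUE(config$select_channels)) {
    weights <- stage("select_channels", {
      acc <- compute_accuracy_matrix(
        features, clf = config$classifiers[[1]], cv = config$selection_cv,
        seed = config$seed)
      standardize_weights(electrode_weights(acc))
    })
  }

  result <- structure(list(reports = reports, features = features,
                           weights = weights, config = config,
                           timings = timings),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_result(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  for (nm in names(x$reports)) {
    m <- x$reports[[nm]]$metrics
    cat(sprintf("  %-12s Acc %5.1f%%  Sn %5.1f%%  Sp %5.1f%%\n",
                nm, m$acc, m$sn, m$sp))
  }
  if (!is.null(x$weights)) {
    cat("  top electrodes:",
        paste(head(rank_electrodes(x$weights), 4), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn run_pipeline Per-classifier metric table.
#' @param x A `pipeline_result`.
#' @param ... Unused.
#' @export
tidy.pipeline_result <- function(x, ...) {
  purrr::map_dfr(x$reports, glance)
}

#' Serialise a pipeline result to disk
#'
#' Writes `features.tsv`, `weights.tsv` (when channel selection ran),
#' per-classifier ROC/PR curve tables, and `report.json` carrying metrics,
#' configuration constants and seeds.
#'
#' @param result A `pipeline_result`.
#' @param out_dir Output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_features(result$features, file.path(out_dir, "features.tsv"))
  if (!is.null(result$weights)) {
    utils::write.table(result$weights, file.path(out_dir, "weights.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  for (nm in names(result$reports)) {
    cv <- result$reports[[nm]]$curves
    if (!is.null(cv)) {
      utils::write.table(cv$roc, file.path(out_dir, paste0(nm, "_roc.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      utils::write.table(cv$pr, file.path(out_dir, paste0(nm, "_pr.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }
  report <- list(
    package_version = as.character(utils::packageVersion("entrofuse")),
    seed = result$config$seed,
    config = list(
      notch_hz = result$config$notch_hz, band = result$config$band,
      epoch_length_s = result$config$epoch_length_s,
      measures = result$config$measures,
      feature_mode = result$config$feature_mode,
      cv_unit = result$config$cv_unit,
      new_min = result$config$new_min, new_max = result$config$new_max),
    metrics = lapply(result$reports, function(r) as.list(r$metrics))
  )
  # wall-clock stage timings are logged separately so report.json is
  # byte-identical across reruns of the same config and seed
  jsonlite::write_json(as.list(result$timings),
                       file.path(out_dir, "timings.json"),
                       auto_unbox = TRUE, digits = 4)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(out_dir)
}
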
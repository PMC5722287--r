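#' @keywords internal
meta_cols <- function() c("subject_id", "state", "epoch")

#' Names of the feature columns of a feature table
#'
#' @param features A feature tibble produced by [extract_feature_matrix()].
#' @return Character vector of feature column names (everything except the
#'   `subject_id`, `state`, `epoch` metadata columns).
#' @export
feature_cols <- function(features) {
  setdiff(names(features), meta_cols())
}

entropy_measures <- c("PE", "AE", "SE", "FE")

compute_measure <- function(ch_series, measure, fs, params, low_hz, high_hz) {
  switch(measure,
    PE = spectral_entropy(ch_series, fs = fs, low_hz = low_hz,
                          high_hz = high_hz),
    AE = approximate_entropy(ch_series, params),
    SE = sample_entropy(ch_series, params),
    FE = fuzzy_entropy(ch_series, params),
    stop("unknown entropy measure: ", measure, call. = FALSE)
  )
}

#' Extract a per-epoch feature table
#'
#' Computes, for every epoch and every channel, either a set of entropy
#' measures (any non-empty subset of `PE` spectral, `AE` approximate, `SE`
#' sample, `FE` fuzzy entropy) or Yule-Walker AR coefficients, and
#' concatenates them into one feature vector per epoch. Columns are ordered
#' channel-major, measure-minor (`ch1_PE, ch1_AE, ..., ch2_PE, ...`), so a
#' 30-channel recording with all four entropies yields 120 feature columns
#' and AR order 10 yields 300.
#'
#' The template-entropy tolerance (`r_factor` times the SD) is recomputed from each
#' channel of each epoch.
#'
#' @param epochs Epoch tibble from [segment_epochs()] (rows from several
#'   recordings may be combined with [dplyr::bind_rows()]).
#' @param measures Entropy measures to compute, subset of
#'   `c("PE", "AE", "SE", "FE")`; ignored when `mode = "ar"`.
#' @param mode `"entropy"` (default) or `"ar"`.
#' @param params An [entropy_params()] set for AE/SE/FE.
#' @param ar_order AR model order for `mode = "ar"` (default 10).
#' @param low_hz,high_hz Spectral-entropy analysis band.
#' @param channels Optional subset of channel names to restrict to.
#' @return A tibble with metadata columns `subject_id`, `state`, `epoch`
#'   followed by one numeric column per (channel, measure) pair.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 500), 2), 100, c("O1", "O2"),
#'                      "s1", "normal")
#' fm <- extract_feature_matrix(segment_epochs(rec, 1))
#' names(fm)   # O1_PE O1_AE O1_SE O1_FE O2_PE ...
extract_feature_matrix <- function(epochs,
                                   measures = c("PE", "AE", "SE", "FE"),
                                   mode = c("entropy", "ar"),
                                   params = entropy_params(),
                                   ar_order = 10,
                                   low_hz = 0.15, high_hz = 45,
                                   channels = NULL) {
  mode <- match.arg(mode)
  if (nrow(epochs) == 0) stop("empty epoch set", call. = FALSE)
  if (mode == "entropy") {
    measures <- as.character(measures)
    if (length(measures) == 0) stop("no entropy measures given", call. = FALSE)
    bad <- setdiff(measures, entropy_measures)
    if (length(bad)) stop("unknown entropy measure: ",
                          paste(bad, collapse = ", "), call. = FALSE)
  }

  ch_names <- rownames(epochs$data[[1]])
  if (is.null(ch_names)) ch_names <- paste0("ch", seq_len(nrow(epochs$data[[1]])))
  if (!is.null(channels)) {
    missing_ch <- setdiff(channels, ch_names)
    if (length(missing_ch)) stop("channels not in recording: ",
                                 paste(missing_ch, collapse = ", "),
                                 call. = FALSE)
    ch_names <- channels
  }

  per_channel <- if (mode == "entropy") length(measures) else ar_order
  col_names <- as.vector(t(outer(
    ch_names,
    if (mode == "entropy") measures else sprintf("ar%02d", seq_len(ar_order)),
    paste, sep = "_"
  )))

  vals <- matrix(NA_real_, nrow = nrow(epochs), ncol = length(col_names),
                 dimnames = list(NULL, col_names))
  for (i in seq_len(nrow(epochs))) {
    win <- epochs$data[[i]]
    fs <- epochs$fs[i]
    row_vals <- numeric(0)
    for (ch in ch_names) {
      series <- as.numeric(win[ch, ])
      if (mode == "entropy") {
        row_vals <- c(row_vals, vapply(
          measures, compute_measure, numeric(1),
          ch_series = series, fs = fs, params = params,
          low_hz = low_hz, high_hz = high_hz))
      } else {
        row_vals <- c(row_vals, ar_coefficients(series, order = ar_order))
      }
    }
    vals[i, ] <- row_vals
  }

  dplyr::bind_cols(
    tibble::tibble(subject_id = epochs$subject_id, state = epochs$state,
                   epoch = epochs$epoch),
    tibble::as_tibble(vals)
  )
}

#' Fit min-max normalisation statistics
#'
#' Records, per feature column (and per subject when `per_subject = TRUE`,
#' matching the per-participant normalisation of the pipeline), the observed
#' minimum and maximum used by [minmax_normalize()]. Fitting on training rows
#' only and applying to held-out rows avoids information leakage across a
#' cross-validation split.
#'
#' @param features Feature tibble.
#' @param new_min,new_max Target range endpoints (defaults -1 and 1).
#' @param per_subject Fit separate statistics within each subject's rows.
#' @return An object of class `minmax_spec`.
#' @export
fit_normalization <- function(features, new_min = -1, new_max = 1,
                              per_subject = TRUE) {
  stopifnot(new_min < new_max, nrow(features) > 0)
  fcols <- feature_cols(features)
  groups <- if (per_subject) split(features, features$subject_id)
            else list(.all = features)
  stats <- lapply(groups, function(g) {
    list(x_min = vapply(g[fcols], min, numeric(1)),
         x_max = vapply(g[fcols], max, numeric(1)))
  })
  structure(list(new_min = new_min, new_max = new_max,
                 per_subject = per_subject, stats = stats,
                 feature_cols = fcols),
            class = "minmax_spec")
}

apply_minmax <- function(x, x_min, x_max, new_min, new_max) {
  rng <- x_max - x_min
  if (rng == 0) return(rep((new_min + new_max) / 2, length(x)))
  (new_max - new_min) * (x - x_min) / rng + new_min
}

#' Min-max normalise a feature table
#'
#' Rescales each feature column linearly so the observed range maps to
#' `[new_min, new_max]` (default `[-1, 1]`):
#' `x' = (newMax - newMin) * (x - x_min) / (x_max - x_min) + newMin`.
#' A constant column maps to the range midpoint. When `spec` is supplied
#' (fitted with [fit_normalization()] on training rows) its statistics are
#' applied, so held-out rows may fall slightly outside the target range;
#' otherwise statistics are fitted on `features` itself and the output is
#' exactly within range.
#'
#' @param features Feature tibble.
#' @param spec Optional fitted `minmax_spec`.
#' @inheritParams fit_normalization
#' @return A feature tibble of the same shape with rescaled feature columns.
#' @export
#' @examples
#' fm <- tibble::tibble(subject_id = "s1", state = "normal", epoch = 1:3,
#'                      f = c(0, 5, 10))
#' minmax_normalize(fm)$f   # -1 0 1
minmax_normalize <- function(features, spec = NULL, new_min = -1, new_max = 1,
                             per_subject = TRUE) {
  if (is.null(spec)) {
    spec <- fit_normalization(features, new_min = new_min, new_max = new_max,
                              per_subject = per_subject)
  }
  fcols <- spec$feature_cols
  stopifnot(all(fcols %in% names(features)))
  out <- features
  if (spec$per_subject) {
    for (sid in unique(features$subject_id)) {
      st <- spec$stats[[sid]]
      if (is.null(st)) {
        stop("no normalisation statistics for subject ", sid, call. = FALSE)
      }
      rows <- which(features$subject_id == sid)
      for (f in fcols) {
        out[[f]][rows] <- apply_minmax(features[[f]][rows], st$x_min[[f]],
                                       st$x_max[[f]], spec$new_min,
                                       spec$new_max)
      }
    }
  } else {
    st <- spec$stats[[1]]
    for (f in fcols) {
      out[[f]] <- apply_minmax(features[[f]], st$x_min[[f]], st$x_max[[f]],
                               spec$new_min, spec$new_max)
    }
  }
  out
}

#' Write / read a feature table as a delimited file
#'
#' Plain TSV with a header row naming each (channel, measure) column.
#'
#' @param features Feature tibble.
#' @param path File path.
#' @return `path` (write) or a tibble (read).
#' @export
write_features <- function(features, path) {
  utils::write.table(features, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE))
}
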
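#' Construct a labelled multichannel EEG recording
#'
#' A recording bundles a channels-by-samples signal matrix (microvolts) with
#' its sampling rate, electrode labels, subject identifier and behavioural
#' state label. All downstream stages (filtering, epoching, feature
#' extraction) operate on this object.
#'
#' @param signal Numeric matrix, channels x samples, all values finite.
#' @param fs Sampling rate in Hz (positive scalar).
#' @param channel_names Character vector of electrode labels, one per row of
#'   `signal`.
#' @param subject_id Subject identifier (coerced to character).
#' @param state State label, one of `"normal"` or `"fatigue"`.
#' @return An object of class `eeg_recording`.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(200), 2), fs = 100,
#'                      channel_names = c("O1", "O2"),
#'                      subject_id = "s1", state = "normal")
#' rec
eeg_recording <- function(signal, fs, channel_names, subject_id, state) {
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  state <- match.arg(state, c("normal", "fatigue"))
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive scalar sampling rate (Hz)", call. = FALSE)
  }
  if (length(channel_names) != nrow(signal)) {
    stop("`channel_names` length (", length(channel_names),
         ") must equal the signal row count (", nrow(signal), ")",
         call. = FALSE)
  }
  if (!all(is.finite(signal))) {
    stop("`signal` contains non-finite values", call. = FALSE)
  }
  rownames(signal) <- as.character(channel_names)
  structure(
    list(signal = signal, fs = as.numeric(fs),
         channel_names = as.character(channel_names),
         subject_id = as.character(subject_id), state = state),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> subject %s, state %s\n", x$subject_id, x$state))
  cat(sprintf("  %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$signal), ncol(x$signal), x$fs, ncol(x$signal) / x$fs))
  cat("  channels:", paste(head(x$channel_names, 8), collapse = ", "),
      if (length(x$channel_names) > 8) "..." else "", "\n")
  invisible(x)
}

#' Write a recording as a delimited matrix with a JSON sidecar
#'
#' The signal is written as a tab-separated matrix (one row per channel, no
#' header) and the metadata (sampling rate, channel labels, subject, state)
#' as a JSON sidecar at `<path>.json`.
#'
#' @param rec An [eeg_recording()].
#' @param path Output path for the signal matrix (e.g. `"rec.tsv"`).
#' @param digits Significant digits retained in the text representation.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, digits = 8) {
  stopifnot(inherits(rec, "eeg_recording"))
  utils::write.table(signif(rec$signal, digits), path, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  meta <- list(subject_id = rec$subject_id, state = rec$state, fs = rec$fs,
               channel_names = rec$channel_names)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a recording written by [write_recording()]
#'
#' @param path Path to the delimited signal matrix; the JSON sidecar is
#'   expected at `<path>.json`.
#' @return An [eeg_recording()].
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("signal file not found: ", path, call. = FALSE)
  if (!file.exists(sidecar)) {
    stop("sidecar metadata not found: ", sidecar, call. = FALSE)
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("subject_id", "state", "fs", "channel_names")) {
    if (is.null(meta[[field]])) {
      stop("sidecar field `", field, "` is required in ", sidecar,
           call. = FALSE)
    }
  }
  sig <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(sig) <- NULL
  eeg_recording(sig, fs = meta$fs, channel_names = meta$channel_names,
                subject_id = meta$subject_id, state = meta$state)
}
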
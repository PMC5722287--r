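#' Zero-phase band-pass filter a recording
#'
#' Removes drift and high-frequency noise outside the EEG analysis band
#' (default 0.15-45 Hz). The design is a cascade of an order-2 Butterworth
#' high-pass at `low_hz` and an order-4 Butterworth low-pass at `high_hz`,
#' each applied forward-backward ([signal::filtfilt()]) so the pass is
#' zero-phase and epoch alignment is unchanged. The cascade is used instead
#' of a single high-order band-pass polynomial because the very low relative
#' cutoff (0.15 Hz at 1000 Hz sampling) makes a monolithic design numerically
#' fragile.
#'
#' @param rec An [eeg_recording()].
#' @param low_hz,high_hz Band edges in Hz; must satisfy
#'   `0 < low_hz < high_hz < fs/2`.
#' @return A filtered [eeg_recording()] of identical shape.
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2000), 2), 250, c("O1", "O2"),
#'                      "s1", "normal")
#' filt <- bandpass_filter(rec, 0.15, 45)
#' dim(filt$signal)
bandpass_filter <- function(rec, low_hz = 0.15, high_hz = 45) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyq)) {
    stop("band edges must satisfy 0 < low_hz < high_hz < fs/2 = ", nyq,
         call. = FALSE)
  }
  hp <- signal::butter(2, low_hz / nyq, type = "high")
  lp <- signal::butter(4, high_hz / nyq, type = "low")
  out <- rec
  out$signal <- t(apply(rec$signal, 1, function(ch) {
    signal::filtfilt(lp, signal::filtfilt(hp, ch))
  }))
  rownames(out$signal) <- rec$channel_names
  out
}

#' Zero-phase notch filter for power-line interference
#'
#' Attenuates a narrow band around `center_hz` (default 50 Hz mains) with a
#' biquad IIR notch of quality factor `q`, applied forward-backward for zero
#' phase.
#'
#' @param rec An [eeg_recording()].
#' @param center_hz Notch centre frequency in Hz, in `(0, fs/2)`.
#' @param q Quality factor; bandwidth is `center_hz / q` (default 30).
#' @return A filtered [eeg_recording()] of identical shape.
#' @export
notch_filter <- function(rec, center_hz = 50, q = 30) {
  stopifnot(inherits(rec, "eeg_recording"))
  nyq <- rec$fs / 2
  if (!(center_hz > 0 && center_hz < nyq)) {
    stop("`center_hz` must lie in (0, fs/2) = (0, ", nyq, ")", call. = FALSE)
  }
  # RBJ audio-EQ biquad notch
  w0 <- 2 * pi * center_hz / rec$fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  flt <- signal::Arma(b = b, a = a)
  out <- rec
  out$signal <- t(apply(rec$signal, 1, function(ch) signal::filtfilt(flt, ch)))
  rownames(out$signal) <- rec$channel_names
  out
}

#' Cut a recording into fixed-length non-overlapping epochs
#'
#' Segments the signal into contiguous windows of `epoch_length_s` seconds
#' starting at sample 1; a trailing partial window is discarded. Each epoch
#' carries the recording's subject and state label, so epoch tables from
#' several recordings can be combined with [dplyr::bind_rows()].
#'
#' @param rec An [eeg_recording()].
#' @param epoch_length_s Epoch length in seconds (default 1).
#' @return A tibble with one row per epoch and columns `subject_id`, `state`,
#'   `epoch` (index within the recording), `fs`, and `data` (list column of
#'   channels x L signal matrices with channel rownames).
#' @export
#' @examples
#' rec <- eeg_recording(matrix(rnorm(2 * 1050), 2), 100, c("O1", "O2"),
#'                      "s1", "fatigue")
#' segment_epochs(rec, 1)   # 10 epochs; the 50-sample remainder is dropped
segment_epochs <- function(rec, epoch_length_s = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  L <- round(epoch_length_s * rec$fs)
  n_samp <- ncol(rec$signal)
  if (n_samp < L) {
    stop("recording (", n_samp, " samples) is shorter than one epoch (",
         L, " samples)", call. = FALSE)
  }
  n_epochs <- floor(n_samp / L)
  data <- lapply(seq_len(n_epochs), function(k) {
    rec$signal[, ((k - 1) * L + 1):(k * L), drop = FALSE]
  })
  tibble::tibble(
    subject_id = rec$subject_id,
    state = rec$state,
    epoch = seq_len(n_epochs),
    fs = rec$fs,
    data = data
  )
}
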
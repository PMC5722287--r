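#' Specification of a synthetic two-state EEG cohort
#'
#' Describes a cohort of paired recordings (one alert/"normal" and one
#' "fatigue" recording per subject) that emulates the geometry of a
#' simulated-driving EEG study: 12 subjects, 30 scalp channels in 10-20
#' montage, 1000 Hz sampling, 5 minutes per state. Fatigue is modelled as an
#' increase in narrowband low-frequency (delta/theta) oscillatory
#' *regularity* rather than raw amplitude: the fraction of signal variance
#' carried by band-limited oscillations rises with `effect_size`, which
#' lowers every entropy measure on the affected channels. Channels listed in
#' `planted_electrodes` receive the full effect (weight 1); all remaining
#' channels receive the weaker `background_weight`, so electrode-selection
#' methods have a planted ground truth to recover.
#'
#' @param n_subjects Number of subjects (default 12).
#' @param channel_names Montage labels (default [montage_30()]).
#' @param fs Sampling rate in Hz (default 1000).
#' @param duration_s Recording length per state in seconds (default 300).
#' @param effect_size Fatigue effect in `[0, 1]`; 0 makes the two states
#'   identically distributed (default 0.8).
#' @param planted_electrodes Channels carrying the full effect (default
#'   `c("T6", "P3", "TP7", "O1")`).
#' @param background_weight Effect weight of non-planted channels in
#'   `[0, 1]` (default 0.2).
#' @param regularity_base Fraction of variance in narrowband oscillation in
#'   the normal state (default 0.15).
#' @param regularity_max Oscillatory fraction reached at full effect on a
#'   weight-1 channel (default 0.85).
#' @param amplitude_uv Overall signal scale in microvolts (default 40).
#' @param seed Integer master seed of the cohort's deterministic seed stream.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 12, channel_names = montage_30(),
                        fs = 1000, duration_s = 300, effect_size = 0.8,
                        planted_electrodes = c("T6", "P3", "TP7", "O1"),
                        background_weight = 0.2,
                        regularity_base = 0.15, regularity_max = 0.85,
                        amplitude_uv = 40, seed = 1L) {
  stopifnot(n_subjects >= 1, fs > 0, duration_s >= 1,
            effect_size >= 0, effect_size <= 1,
            background_weight >= 0, background_weight <= 1,
            regularity_base >= 0, regularity_max <= 1,
            regularity_base < regularity_max)
  missing_pl <- setdiff(planted_electrodes, channel_names)
  if (length(missing_pl)) {
    stop("planted electrodes not in montage: ",
         paste(missing_pl, collapse = ", "), call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    channel_names = as.character(channel_names),
    fs = fs, duration_s = duration_s, effect_size = effect_size,
    planted_electrodes = as.character(planted_electrodes),
    background_weight = background_weight,
    regularity_base = regularity_base, regularity_max = regularity_max,
    amplitude_uv = amplitude_uv, seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Low-frequency rhythm bands of the fatigue oscillation model:
# a dominant theta component and a weaker delta component.
fatigue_bands <- function() {
  list(theta = list(low = 4, high = 8, amplitude = 1.0),
       delta = list(low = 1, high = 4, amplitude = 0.6))
}

# Band-limited oscillation: frequency redrawn and phase re-randomised every
# 1-second block so the signal is rhythmic but not a single periodic tone.
oscillation_series <- function(n, fs, bands) {
  block <- max(1L, round(fs))
  n_blocks <- ceiling(n / block)
  out <- numeric(n)
  t_block <- (0:(block - 1)) / fs
  for (b in seq_len(n_blocks)) {
    idx <- ((b - 1) * block + 1):min(b * block, n)
    x <- numeric(length(idx))
    for (bd in bands) {
      f <- runif(1, bd$low, bd$high)
      phi <- runif(1, 0, 2 * pi)
      x <- x + bd$amplitude * sin(2 * pi * f * t_block[seq_along(idx)] + phi)
    }
    out[idx] <- x
  }
  out
}

#' Generate one synthetic recording
#'
#' Every channel is a variance-normalised mixture
#' `amplitude * (sqrt(rho) * oscillation + sqrt(1 - rho) * noise)`, where the
#' oscillation is band-limited delta/theta activity with per-second random
#' phase and frequency, the noise is Gaussian white noise, and `rho` is the
#' channel's oscillatory regularity:
#' `rho = base + effect_size * w_ch * (max - base)` in the fatigue state and
#' `rho = base` in the normal state (`w_ch` = 1 for planted electrodes,
#' `background_weight` otherwise). Generation is reproducible from
#' `(spec$seed, subject_id, state)` alone.
#'
#' @param subject_id Subject identifier (e.g. `"sub01"`).
#' @param state `"normal"` or `"fatigue"`.
#' @param spec A [cohort_spec()].
#' @return An [eeg_recording()].
#' @export
generate_recording <- function(subject_id, state, spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  state <- match.arg(state, c("normal", "fatigue"))
  n <- round(spec$duration_s * spec$fs)
  n_ch <- length(spec$channel_names)
  w <- ifelse(spec$channel_names %in% spec$planted_electrodes,
              1, spec$background_weight)
  rho <- spec$regularity_base +
    (state == "fatigue") * spec$effect_size * w *
    (spec$regularity_max - spec$regularity_base)
  bands <- fatigue_bands()
  sig <- local_seed(derive_seed(spec$seed, subject_id, state), {
    m <- matrix(0, n_ch, n)
    for (ch in seq_len(n_ch)) {
      osc <- oscillation_series(n, spec$fs, bands)
      osc <- osc / sd(osc)
      noise <- rnorm(n)
      m[ch, ] <- spec$amplitude_uv *
        (sqrt(rho[ch]) * osc + sqrt(1 - rho[ch]) * noise)
    }
    m
  })
  eeg_recording(sig, fs = spec$fs, channel_names = spec$channel_names,
                subject_id = subject_id, state = state)
}

#' Generate a full two-state cohort
#'
#' One normal and one fatigue recording per subject, each of
#' `spec$duration_s` seconds. Every recording is drawn from its own seed
#' derived from `(spec$seed, subject, state)`, so the cohort is reproducible
#' and recordings are pairwise distinct.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble with columns `subject_id`, `state` and list column
#'   `recording`.
#' @export
#' @examples
#' spec <- cohort_spec(n_subjects = 1, duration_s = 4, fs = 100)
#' generate_cohort(spec)
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  subjects <- sprintf("sub%02d", seq_len(spec$n_subjects))
  grid <- tidyr::expand_grid(subject_id = subjects,
                             state = c("normal", "fatigue"))
  grid$recording <- purrr::map2(grid$subject_id, grid$state,
                                generate_recording, spec = spec)
  grid
}

#' Segment every recording of a cohort into epochs
#'
#' Convenience wrapper: applies [segment_epochs()] to each row of a cohort
#' tibble and binds the results.
#'
#' @param cohort Tibble from [generate_cohort()] (or any tibble with a
#'   `recording` list column).
#' @param epoch_length_s Epoch length in seconds.
#' @return A combined epoch tibble.
#' @export
segment_cohort <- function(cohort, epoch_length_s = 1) {
  purrr::map_dfr(cohort$recording, segment_epochs,
                 epoch_length_s = epoch_length_s)
}
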
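#' Entropy parameter set
#'
#' Parameters shared by the template-matching entropies (approximate, sample,
#' fuzzy). The similarity tolerance is `r_factor` times the standard
#' deviation of the series it is applied to, recomputed per channel per
#' epoch; `m = 2` and `r_factor = 0.2` are the conventional choices for
#' series longer than 200 samples.
#'
#' @param m Embedding dimension (template length), integer >= 1.
#' @param r_factor Tolerance as a multiple of the series SD, > 0.
#' @param n_grad Fuzzy membership gradient (exponent of the graded
#'   similarity), >= 1; only used by [fuzzy_entropy()].
#' @return A list of class `entropy_params`.
#' @export
entropy_params <- function(m = 2, r_factor = 0.2, n_grad = 2) {
  stopifnot(m >= 1, r_factor > 0, n_grad >= 1)
  structure(list(m = as.integer(m), r_factor = r_factor, n_grad = n_grad),
            class = "entropy_params")
}

check_series <- function(x, m) {
  if (anyNA(x) || !all(is.finite(x))) {
    stop("input series contains non-finite values", call. = FALSE)
  }
  if (length(x) <= m + 1) {
    stop("series length ", length(x), " is too short for m = ", m,
         call. = FALSE)
  }
}

resolve_r <- function(x, params, r) {
  if (!is.null(r)) return(r)
  params$r_factor * sd(x)
}

#' Approximate entropy
#'
#' Pincus' regularity statistic `AE = Phi^m(r) - Phi^(m+1)(r)`, where
#' `Phi^m` averages the log fraction of templates within Chebyshev distance
#' `r` of each template (self-matches included). Lower values indicate a
#' more regular series.
#'
#' @param x Numeric series (one channel of one epoch).
#' @param params An [entropy_params()] set.
#' @param r Optional absolute tolerance; overrides `params$r_factor * sd(x)`.
#' @return Non-negative scalar; 0 for a constant series.
#' @export
#' @examples
#' approximate_entropy(sin(seq_len(300) / 5))
#' approximate_entropy(rnorm(300))   # larger: noise is irregular
approximate_entropy <- function(x, params = entropy_params(), r = NULL) {
  check_series(x, params$m)
  r <- resolve_r(x, params, r)
  if (r <= 0) return(0)
  apen_cpp(as.numeric(x), params$m, r)
}

#' Sample entropy
#'
#' Richman-Moorman statistic `SE = -ln(A/B)` with Chebyshev distance and
#' self-matches excluded: `B` counts template pairs matching at length `m`,
#' `A` at length `m + 1`. When no `(m+1)`-length pair matches (`A = 0`) the
#' finite sentinel `ln(B)` is returned instead of infinity so feature
#' matrices stay finite.
#'
#' @inheritParams approximate_entropy
#' @return Non-negative scalar; 0 for a constant series.
#' @export
sample_entropy <- function(x, params = entropy_params(), r = NULL) {
  check_series(x, params$m)
  r <- resolve_r(x, params, r)
  if (r <= 0) return(0)
  sampen_cpp(as.numeric(x), params$m, r)
}

#' Fuzzy entropy
#'
#' Chen's fuzzy variant of sample entropy: templates are mean-centred and the
#' hard match threshold is replaced by the graded membership
#' `exp(-(d/r)^n_grad)` with Chebyshev distance `d`. The result is
#' `ln(phi^m) - ln(phi^(m+1))` where `phi` averages the membership grades
#' over all template pairs.
#'
#' @inheritParams approximate_entropy
#' @return Non-negative scalar; 0 for a constant series.
#' @export
fuzzy_entropy <- function(x, params = entropy_params(), r = NULL) {
  check_series(x, params$m)
  r <- resolve_r(x, params, r)
  if (r <= 0) return(0)
  fuzzyen_cpp(as.numeric(x), params$m, r, params$n_grad)
}

#' Spectral entropy of a series
#'
#' Shannon entropy of the normalised power spectrum: the periodogram of the
#' full epoch is computed by FFT, the DC bin is excluded, the bins are
#' restricted to the analysis band (`low_hz` to `high_hz`), the retained
#' power is normalised to a probability distribution and its Shannon entropy
#' is divided by `log(number of bins)` so the result lies in `[0, 1]`.
#' A flat (white) spectrum approaches 1; a single spectral line approaches 0.
#'
#' @param x Numeric series.
#' @param fs Sampling rate in Hz.
#' @param low_hz,high_hz Analysis band (defaults match the 0.15-45 Hz
#'   preprocessing band).
#' @return Scalar in `[0, 1]`; 0 for an all-zero or constant series.
#' @export
#' @examples
#' spectral_entropy(sin(2 * pi * 10 * (0:999) / 1000), fs = 1000)  # low
#' spectral_entropy(rnorm(1000), fs = 1000)                        # high
spectral_entropy <- function(x, fs, low_hz = 0.15, high_hz = 45) {
  if (anyNA(x) || !all(is.finite(x))) {
    stop("input series contains non-finite values", call. = FALSE)
  }
  n <- length(x)
  if (n < 2) stop("series too short for a spectrum", call. = FALSE)
  if (sd(x) == 0) return(0)   # degenerate spectrum: all mass at DC
  pw <- Mod(fft(x))^2 / n
  n_half <- floor(n / 2)
  freqs <- (seq_len(n_half)) * fs / n      # positive-frequency bins, DC excluded
  pw <- pw[2:(n_half + 1)]
  keep <- freqs >= low_hz & freqs <= high_hz
  if (!any(keep)) stop("analysis band contains no spectral bins", call. = FALSE)
  p <- pw[keep]
  tot <- sum(p)
  if (tot <= 0) return(0)
  p <- p / tot
  nz <- p > 0
  -sum(p[nz] * log(p[nz])) / log(length(p))
}

#' Autoregressive coefficients by Yule-Walker estimation
#'
#' Fits an AR(p) model `x_t = a_1 x_{t-1} + ... + a_p x_{t-p} + e_t` by
#' solving the Yule-Walker equations with biased autocovariance estimates
#' (via [stats::ar()], method `"yule-walker"`). Only the `p` coefficients are
#' returned; the innovation variance is not part of the feature vector.
#' A constant (zero-variance) series yields a zero vector with a warning.
#'
#' @param x Numeric series, longer than `order`.
#' @param order Model order `p` (default 10).
#' @return Numeric vector of length `order`.
#' @export
#' @examples
#' x <- as.numeric(arima.sim(list(ar = c(0.5, -0.3)), 2000))
#' ar_coefficients(x, order = 2)
ar_coefficients <- function(x, order = 10) {
  stopifnot(order >= 1, length(x) > order)
  if (anyNA(x) || !all(is.finite(x))) {
    stop("input series contains non-finite values", call. = FALSE)
  }
  if (sd(x) == 0) {
    warning("constant series: returning zero AR coefficients")
    return(numeric(order))
  }
  fit <- stats::ar(x, aic = FALSE, order.max = order, method = "yule-walker",
                   demean = TRUE)
  coefs <- as.numeric(fit$ar)
  length(coefs) <- order   # pad with NA then zero-fill, defensive
  coefs[is.na(coefs)] <- 0
  coefs
}
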
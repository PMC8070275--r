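#' Band-pass filter specification
#'
#' Breath-sound analysis discards energy below 60 Hz (body/handling rumble)
#' and above 2000 Hz (outside the stethoscope's useful band). The filter is a
#' Butterworth band-pass of the given order, applied forward-backward
#' (zero-phase) by default so that breath-cycle features are not delayed.
#'
#' @param low_hz Lower pass-band edge in Hz (default 60).
#' @param high_hz Upper pass-band edge in Hz (default 2000).
#' @param order Butterworth order per pass (default 4).
#' @param zero_phase Apply forward-backward for zero group delay? Default TRUE.
#' @return An object of class `filter_spec`.
#' @seealso [bandpass()]
#' @export
filter_spec <- function(low_hz = 60, high_hz = 2000, order = 4,
                        zero_phase = TRUE) {
  assert_that(is.numeric(low_hz) && is.numeric(high_hz) &&
                low_hz > 0 && high_hz > low_hz,
              "need 0 < low_hz < high_hz")
  assert_that(is_count(order), "order must be a positive integer")
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 zero_phase = isTRUE(zero_phase)),
            class = "filter_spec")
}

# Butterworth band-pass coefficients for a given sampling rate.
design_bandpass <- function(spec, rate_hz) {
  nyq <- rate_hz / 2
  assert_that(spec$high_hz < nyq,
              sprintf("high_hz (%g) must be below the Nyquist frequency (%g)",
                      spec$high_hz, nyq))
  signal::butter(spec$order, c(spec$low_hz, spec$high_hz) / nyq, type = "pass")
}

#' Band-pass filter a signal
#'
#' Applies the Butterworth band-pass described by `spec`. With
#' `spec$zero_phase` the filter runs forward and backward over the signal
#' (squaring the magnitude response, cancelling phase); the signal is
#' reflect-padded at both ends before the two passes so filter start-up
#' transients fall on the padding, not on the data.
#'
#' @param samples Numeric vector of audio samples.
#' @param rate_hz Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Numeric vector, same length as `samples`.
#' @examples
#' x <- sin(2 * pi * 500 * seq(0, 0.5, by = 1 / 8000))
#' y <- bandpass(x, 8000, filter_spec(60, 2000))
#' @export
bandpass <- function(samples, rate_hz, spec = filter_spec()) {
  assert_that(is.numeric(samples) && all(is.finite(samples)),
              "samples must be finite numeric")
  bf <- design_bandpass(spec, rate_hz)
  n <- length(samples)
  assert_that(n > 3 * spec$order, "signal too short for the filter order")
  if (!spec$zero_phase) return(as.numeric(signal::filter(bf, samples)))
  # reflect padding: ~3 periods of the lowest pass frequency, capped at n - 1
  pad <- min(n - 1, ceiling(3 * rate_hz / spec$low_hz))
  x <- c(2 * samples[1] - samples[(pad + 1):2],
         samples,
         2 * samples[n] - samples[(n - 1):(n - pad)])
  y <- as.numeric(signal::filter(bf, x))
  y <- rev(as.numeric(signal::filter(bf, rev(y))))
  y[(pad + 1):(pad + n)]
}

#' Convert filtered samples to an acoustic intensity series
#'
#' Intensity (proportional to acoustic power, watt/m^2 up to a reference
#' constant) is measured in constant gaps of `gap_s` seconds as the mean of
#' squared samples within each gap. At the acquisition gap of 0.00005 s
#' (20,000 samples/s) this is the per-sample squared amplitude, so a 12 s
#' recording yields 240,000 intensity values.
#'
#' @param samples Numeric vector (normally the output of [bandpass()]).
#' @param rate_hz Sampling rate in Hz.
#' @param gap_s Gap between intensity values in seconds; must be an integer
#'   multiple of `1/rate_hz`. Default `5e-5`.
#' @param labels Optional named list of source labels (subject, condition,
#'   volume_ml, channel) carried on the result.
#' @return An `intensity_series`: list with `values` (non-negative numeric)
#'   and `dt_s`, plus any labels.
#' @examples
#' s <- to_intensity(c(1, 3), rate_hz = 2, gap_s = 1)  # one gap of 2 samples
#' s$values  # (1^2 + 3^2) / 2 = 5
#' @export
to_intensity <- function(samples, rate_hz, gap_s = 5e-5, labels = NULL) {
  assert_that(is.numeric(samples) && length(samples) > 0, "samples must be non-empty numeric")
  m <- gap_s * rate_hz
  assert_that(m >= 1 - 1e-9 && abs(m - round(m)) < 1e-6,
              "gap_s must be an integer multiple of 1/rate_hz")
  m <- as.integer(round(m))
  sq <- samples^2
  if (m == 1L) {
    values <- sq
  } else {
    nb <- length(sq) %/% m  # trailing partial gap dropped
    values <- colMeans(matrix(sq[seq_len(nb * m)], nrow = m))
  }
  structure(c(list(values = values, dt_s = gap_s), labels),
            class = "intensity_series")
}

#' @export
print.intensity_series <- function(x, ...) {
  cat(sprintf("<intensity_series> %d values at dt = %g s (%.4g s total)\n",
              length(x$values), x$dt_s, length(x$values) * x$dt_s))
  invisible(x)
}
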
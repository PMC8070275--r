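#' Configuration for the synthetic breath-sound study generator
#'
#' Defines the study design replicated by [generate_study()]: a mechanically
#' ventilated subject auscultated over the chest wall, recorded for 12 s at
#' 20,000 samples/s by two digital stethoscopes (two audio channels each),
#' at baseline ("volume 0") and after injection of increasing pleural volumes
#' of air (PTX) or saline (HTX).
#'
#' Injury signatures are parametric and monotone in injected volume:
#' \describe{
#'   \item{PTX}{overall gain drop (`ptx_gain_drop_per_ml`, log-gain units per
#'     ml), spectral tilt toward low frequencies (`ptx_tilt_per_ml`, mixing
#'     fraction per ml of a low-pass filtered copy), and reduced breath-cycle
#'     amplitude variation (`ptx_envelope_drop_per_ml`, log-depth per ml).}
#'   \item{HTX}{signal damping (`htx_damping_per_ml`, log-gain per ml) plus a
#'     rising broadband noise floor (`htx_noise_per_ml`, additive noise
#'     standard deviation per ml, in units of the baseline signal RMS),
#'     i.e. a progressively lower signal-to-noise ratio.}
#' }
#' The two stethoscopes share the thoracic source process but receive
#' independent additive noise; the two channels of one stethoscope are
#' near-duplicates with independent low-level noise, so each recording yields
#' four distinct data sources.
#'
#' @param sample_rate_hz Sampling rate (samples/s). Default 20000.
#' @param duration_s Recording duration in seconds. Default 12.
#' @param respiratory_rate_bpm Ventilator rate, breaths/minute, in \[13, 15\].
#'   Default 15 (so a 12 s recording holds exactly 3 ventilation cycles).
#' @param n_subjects Number of subjects. Default 4.
#' @param volumes_ml Strictly increasing injected volumes (ml), including 0
#'   for baseline. Default `c(0, 200, 400, 600, 800, 1000)`.
#' @param ptx_gain_drop_per_ml,ptx_tilt_per_ml,ptx_envelope_drop_per_ml
#'   PTX effect magnitudes (all >= 0), see Details.
#' @param htx_damping_per_ml,htx_noise_per_ml HTX effect magnitudes (>= 0).
#' @param subject_variation Scale of per-subject random gain/spectral-shape
#'   offsets (log-normal sd for gain; also scales a small subject-specific
#'   spectral tilt). Default 0.15.
#' @param noise_floor Baseline additive noise standard deviation, in units of
#'   the baseline signal RMS. Default 0.02.
#' @param envelope_depth Baseline breath-envelope modulation depth in
#'   \[0, 1\]. Default 0.9.
#' @param seed Master seed for the study replica. Default 20210425.
#' @param preset Optional named preset overriding the effect magnitudes:
#'   `"default"` or `"strong_separation"` (large, distinct PTX and HTX
#'   effects with a near-zero noise floor, giving cleanly separable classes).
#' @param ... Named overrides applied after the preset.
#'
#' @return An object of class `generator_config` (a validated list).
#' @examples
#' cfg <- generator_config(sample_rate_hz = 4000, duration_s = 2)
#' cfg$volumes_ml
#' @export
generator_config <- function(sample_rate_hz = 20000,
                             duration_s = 12,
                             respiratory_rate_bpm = 15,
                             n_subjects = 4,
                             volumes_ml = c(0L, 200L, 400L, 600L, 800L, 1000L),
                             ptx_gain_drop_per_ml = 7e-4,
                             ptx_tilt_per_ml = 8e-4,
                             ptx_envelope_drop_per_ml = 7e-4,
                             htx_damping_per_ml = 9e-4,
                             htx_noise_per_ml = 1e-3,
                             subject_variation = 0.15,
                             noise_floor = 0.02,
                             envelope_depth = 0.9,
                             seed = 20210425,
                             preset = NULL,
                             ...) {
  cfg <- list(sample_rate_hz = sample_rate_hz, duration_s = duration_s,
              respiratory_rate_bpm = respiratory_rate_bpm,
              n_subjects = n_subjects,
              volumes_ml = as.integer(volumes_ml),
              ptx_gain_drop_per_ml = ptx_gain_drop_per_ml,
              ptx_tilt_per_ml = ptx_tilt_per_ml,
              ptx_envelope_drop_per_ml = ptx_envelope_drop_per_ml,
              htx_damping_per_ml = htx_damping_per_ml,
              htx_noise_per_ml = htx_noise_per_ml,
              subject_variation = subject_variation,
              noise_floor = noise_floor,
              envelope_depth = envelope_depth,
              seed = as.integer(seed))
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("default", "strong_separation"))
    if (preset == "strong_separation") {
      cfg <- modifyList(cfg, list(
        ptx_gain_drop_per_ml = 1.2e-3,
        ptx_tilt_per_ml = 9e-4,
        ptx_envelope_drop_per_ml = 1.2e-3,
        htx_damping_per_ml = 1.6e-3,
        htx_noise_per_ml = 3e-3,
        subject_variation = 0.05,
        noise_floor = 1e-4))
    }
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad)) stop_pleura("unknown generator_config fields: ",
                                 paste(bad, collapse = ", "))
    cfg <- modifyList(cfg, dots)
  }
  structure(validate_generator_config(cfg), class = "generator_config")
}

validate_generator_config <- function(cfg) {
  assert_that(is_count(cfg$sample_rate_hz), "sample_rate_hz must be a positive integer")
  assert_that(is.numeric(cfg$duration_s) && cfg$duration_s > 0,
              "duration_s must be positive")
  n <- cfg$duration_s * cfg$sample_rate_hz
  assert_that(abs(n - round(n)) < 1e-9,
              "duration_s * sample_rate_hz must be an integer number of samples")
  assert_that(cfg$respiratory_rate_bpm >= 13 && cfg$respiratory_rate_bpm <= 15,
              "respiratory_rate_bpm must lie in [13, 15]")
  assert_that(is_count(cfg$n_subjects), "n_subjects must be a positive integer")
  v <- cfg$volumes_ml
  assert_that(length(v) >= 1 && all(v >= 0) && all(diff(v) > 0),
              "volumes_ml must be non-negative and strictly increasing")
  for (f in c("ptx_gain_drop_per_ml", "ptx_tilt_per_ml",
              "ptx_envelope_drop_per_ml", "htx_damping_per_ml",
              "htx_noise_per_ml", "subject_variation", "noise_floor")) {
    assert_that(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 &&
                  is.finite(cfg[[f]]) && cfg[[f]] >= 0,
                paste(f, "must be a single non-negative number"))
  }
  assert_that(cfg$envelope_depth >= 0 && cfg$envelope_depth <= 1,
              "envelope_depth must lie in [0, 1]")
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  nrec <- x$n_subjects * (1 + 2 * sum(x$volumes_ml > 0))
  cat("<generator_config>\n",
      sprintf("  %d subject(s) x %d state(s) -> %d recordings (%d data sources)\n",
              x$n_subjects, 1 + 2 * sum(x$volumes_ml > 0), nrec, 4 * nrec),
      sprintf("  %g s at %d Hz, %g breaths/min\n",
              x$duration_s, x$sample_rate_hz, x$respiratory_rate_bpm),
      sprintf("  volumes (ml): %s\n", paste(x$volumes_ml, collapse = ", ")),
      sep = "")
  invisible(x)
}

# Conditions recognised throughout the package.
CONDITIONS <- c("BASELINE", "PTX", "HTX")
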
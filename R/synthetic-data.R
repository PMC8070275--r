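#' Generate one synthetic breath-sound recording
#'
#' Synthesises a multi-channel chest-wall recording for one subject in one
#' state. The base signal is band-limited (60--2000 Hz) stochastic breath
#' noise, amplitude-modulated by a raised-cosine inhalation--exhalation
#' envelope at the ventilator rate (no respiratory pause, as under controlled
#' mechanical ventilation). Injury effects are deterministic, monotone
#' transforms of the injected volume:
#'
#' * **PTX** scales the overall gain down, tilts the spectrum toward low
#'   frequencies (mixing in a low-pass filtered copy of the source), and
#'   reduces the envelope modulation depth (less amplitude variation).
#' * **HTX** damps the signal and adds independent broadband noise to every
#'   data source, lowering the signal-to-noise ratio.
#'
#' The two stethoscopes (A, B) share the thoracic source process but receive
#' independent additive sensor noise; the two audio channels of one
#' stethoscope are near-duplicates differing by independent low-level noise.
#' A recording therefore yields four correlated but non-identical data
#' sources. The breath envelope is normalised to unit root-mean-square so
#' that changes in modulation depth do not masquerade as gain changes.
#'
#' Output is bit-reproducible: the same `(seed, arguments)` pair always
#' yields the same samples, and the caller's RNG state is left untouched.
#'
#' @param condition `"BASELINE"`, `"PTX"` or `"HTX"`.
#' @param volume_ml Injected volume in ml; must be one of
#'   `config$volumes_ml`, and 0 if and only if `condition == "BASELINE"`.
#' @param subject_id Subject identifier (e.g. `"S1"`).
#' @param config A [generator_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return An object of class `recording`: subject/condition/volume labels,
#'   `sample_rate_hz`, and `channels`, a named list of four equal-length
#'   numeric vectors (`A1`, `A2`, `B1`, `B2`).
#' @examples
#' cfg <- generator_config(sample_rate_hz = 4000, duration_s = 2,
#'                         n_subjects = 1)
#' rec <- generate_recording("PTX", 600, "S1", cfg)
#' lengths(rec$channels)
#' @export
generate_recording <- function(condition, volume_ml, subject_id, config,
                               seed = config$seed) {
  assert_that(condition %in% CONDITIONS,
              paste("condition must be one of", paste(CONDITIONS, collapse = ", ")))
  assert_that(volume_ml %in% config$volumes_ml,
              "volume_ml must be one of config$volumes_ml")
  assert_that((condition == "BASELINE") == (volume_ml == 0),
              "volume_ml must be 0 if and only if condition is BASELINE")
  rate <- config$sample_rate_hz
  n <- as.integer(round(config$duration_s * rate))
  base_rms <- 0.1  # nominal chest-wall signal RMS in full-scale units

  # Shared thoracic source process: fixed per (seed, subject) so that injury
  # transforms -- not fresh noise draws -- carry the volume dependence.
  src_spec <- filter_spec(60, min(2000, 0.9 * rate / 2), order = 4,
                          zero_phase = FALSE)
  source_sig <- with_seed(hash_seed(seed, "source", subject_id), {
    x <- bandpass(rnorm(n), rate, src_spec)
    x * (base_rms / sqrt(mean(x^2)))
  })
  # Low-pass copy used for spectral tilt (PTX removes high-frequency content).
  lp <- signal::butter(2, min(300, 0.45 * rate / 2) / (rate / 2), type = "low")
  source_lp <- as.numeric(signal::filter(lp, source_sig))

  # Per-subject offsets: multiplicative gain and a small spectral-shape tilt,
  # drawn once per subject from the seed (subjects differ in size/chest wall).
  subj <- with_seed(hash_seed(seed, "subject", subject_id),
                    list(gain = exp(rnorm(1) * config$subject_variation),
                         tilt = abs(rnorm(1)) * 0.2 * config$subject_variation))

  # Injury effects, each monotone in volume.
  gain <- 1; tilt <- subj$tilt; depth <- config$envelope_depth
  htx_noise_sd <- 0
  if (condition == "PTX") {
    gain <- exp(-config$ptx_gain_drop_per_ml * volume_ml)
    tilt <- min(0.97, tilt + config$ptx_tilt_per_ml * volume_ml)
    depth <- depth * exp(-config$ptx_envelope_drop_per_ml * volume_ml)
  } else if (condition == "HTX") {
    gain <- exp(-config$htx_damping_per_ml * volume_ml)
    htx_noise_sd <- config$htx_noise_per_ml * volume_ml * base_rms
  }

  # Raised-cosine ventilation envelope, unit-RMS normalised.
  tt <- (seq_len(n) - 1) / rate
  period <- 60 / config$respiratory_rate_bpm
  rc <- (1 - cos(2 * pi * tt / period)) / 2
  env <- 1 - depth * (1 - rc)
  env <- env / sqrt(mean(env^2))

  shaped <- gain * subj$gain * env * ((1 - tilt) * source_sig + tilt * source_lp)

  steth_sd <- config$noise_floor * base_rms
  chan_sd <- 0.3 * steth_sd
  channels <- list()
  for (st in c("A", "B")) {
    steth <- shaped
    if (steth_sd > 0) {
      steth <- steth + with_seed(
        hash_seed(seed, "steth", subject_id, condition, volume_ml, st),
        rnorm(n, sd = steth_sd))
    }
    for (ch in 1:2) {
      y <- steth
      if (chan_sd > 0) {
        y <- y + with_seed(
          hash_seed(seed, "chan", subject_id, condition, volume_ml, st, ch),
          rnorm(n, sd = chan_sd))
      }
      if (htx_noise_sd > 0) {
        y <- y + with_seed(
          hash_seed(seed, "htx", subject_id, condition, volume_ml, st, ch),
          rnorm(n, sd = htx_noise_sd))
      }
      channels[[paste0(st, ch)]] <- y
    }
  }
  structure(list(subject_id = subject_id, condition = condition,
                 volume_ml = as.integer(volume_ml), sample_rate_hz = rate,
                 duration_s = config$duration_s, channels = channels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> %s %s %d ml: 4 channels x %d samples at %d Hz\n",
              x$subject_id, x$condition, x$volume_ml,
              length(x$channels[[1]]), x$sample_rate_hz))
  invisible(x)
}

#' Generate the full synthetic study
#'
#' Produces one recording per (subject, state) for the states baseline plus
#' PTX and HTX at every positive volume in `config$volumes_ml`, and a
#' manifest enumerating all four data sources (2 stethoscopes x 2 audio
#' channels) of every recording. With the default configuration this is
#' 4 subjects x 11 states = 44 recordings and 176 data sources.
#'
#' @param config A [generator_config()].
#' @return An object of class `study`: list with `recordings` (list of
#'   [generate_recording()] outputs) and `manifest`, a data frame with
#'   columns `path`, `channel` (0-based within the WAV file), `subject`,
#'   `condition`, `volume_ml` plus bookkeeping columns `recording` (index)
#'   and `source` (channel name `A1`/`A2`/`B1`/`B2`).
#' @seealso [write_study()] to materialise it as WAV files + CSV manifest.
#' @examples
#' cfg <- generator_config(sample_rate_hz = 4000, duration_s = 1,
#'                         n_subjects = 1, volumes_ml = c(0, 600))
#' st <- generate_study(cfg)
#' nrow(st$manifest)  # 3 states x 4 data sources
#' @export
generate_study <- function(config) {
  config <- validate_generator_config(config)
  pos <- config$volumes_ml[config$volumes_ml > 0]
  states <- rbind(data.frame(condition = "BASELINE", volume_ml = 0L),
                  expand.grid(condition = c("PTX", "HTX"), volume_ml = pos,
                              stringsAsFactors = FALSE))
  subjects <- sprintf("S%d", seq_len(config$n_subjects))
  recordings <- list()
  rows <- list()
  idx <- 0L
  for (s in subjects) {
    for (i in seq_len(nrow(states))) {
      idx <- idx + 1L
      rec <- generate_recording(states$condition[i], states$volume_ml[i], s,
                                config, seed = config$seed)
      recordings[[idx]] <- rec
      for (st in c("A", "B")) {
        for (ch in 0:1) {
          rows[[length(rows) + 1L]] <- data.frame(
            path = sprintf("%s_%s_%dml_%s.wav", s, rec$condition,
                           rec$volume_ml, st),
            channel = ch,
            subject = s, condition = rec$condition,
            volume_ml = rec$volume_ml,
            recording = idx, source = paste0(st, ch + 1L),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  manifest <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(manifest[, c("path", "channel")]))
  structure(list(recordings = recordings, manifest = manifest,
                 config = config),
            class = "study")
}

#' @export
print.study <- function(x, ...) {
  cat(sprintf("<study> %d recordings, %d data sources (%d subjects)\n",
              length(x$recordings), nrow(x$manifest), x$config$n_subjects))
  invisible(x)
}
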
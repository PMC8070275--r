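#' Feature extraction configuration
#'
#' The detector compares data sources through a short, interpretable feature
#' vector chosen to be sensitive to the three documented pneumothorax
#' signature axes (amplitude reduction, loss of high-frequency content,
#' reduced amplitude variation) plus the hemothorax noise-floor rise:
#'
#' * `n_windows` log mean-intensity values over equal time windows tiling
#'   the recording (level and its time course);
#' * log band-power ratios between consecutive frequency bands bounded by
#'   `band_edges_hz` (spectral shape);
#' * envelope-variation statistics of the windowed intensity: coefficient of
#'   variation, and the interquartile range on the log scale (amplitude
#'   variation, independent of overall gain).
#'
#' @param n_windows Number of time windows (default 24).
#' @param band_edges_hz Strictly increasing band edges within the filter
#'   pass-band; `length(band_edges_hz) - 1` bands give
#'   `length(band_edges_hz) - 2` consecutive-band ratios.
#'   Default `c(60, 250, 500, 1000, 2000)`.
#' @param include_envelope_stats Include the two envelope statistics?
#'   Default TRUE.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(n_windows = 24,
                           band_edges_hz = c(60, 250, 500, 1000, 2000),
                           include_envelope_stats = TRUE) {
  assert_that(is_count(n_windows), "n_windows must be a positive integer")
  assert_that(length(band_edges_hz) >= 2 && all(diff(band_edges_hz) > 0),
              "band_edges_hz must be strictly increasing")
  structure(list(n_windows = as.integer(n_windows),
                 band_edges_hz = as.numeric(band_edges_hz),
                 include_envelope_stats = isTRUE(include_envelope_stats)),
            class = "feature_config")
}

#' Reduce one intensity series to a fixed-length feature vector
#'
#' See [feature_config()] for the feature families. Windowed and
#' envelope features come from the intensity series; band powers come from
#' the raw (filtered) audio channel via its periodogram. All logs are
#' floored at `1e-12` so degenerate (all-zero) inputs yield finite sentinel
#' values rather than `-Inf`.
#'
#' Under a global gain change `a` of the input signal, windowed log-intensity
#' features shift by exactly `log(a^2)` while ratio and envelope features are
#' unchanged — level and shape information are carried by disjoint features.
#'
#' @param series An [to_intensity()] result.
#' @param raw_channel The band-passed audio samples the series came from;
#'   required when band-power ratios are requested (>= 3 band edges).
#' @param config A [feature_config()].
#' @param rate_hz Sampling rate of `raw_channel`; defaults to the rate
#'   implied by `series$dt_s` times samples-per-gap, i.e. `1/series$dt_s`
#'   when the gap is one sample.
#' @return An object of class `feature_vector`: named numeric vector with
#'   attribute `names` as feature identifiers.
#' @examples
#' x <- sin(2 * pi * 300 * seq(0, 1, by = 1 / 4000))
#' s <- to_intensity(x, 4000, 1 / 4000)
#' f <- extract_features(s, x, feature_config(n_windows = 4,
#'                       band_edges_hz = c(60, 500, 1500)), rate_hz = 4000)
#' length(f)  # 4 windows + 1 ratio + 2 envelope stats
#' @export
extract_features <- function(series, raw_channel = NULL,
                             config = feature_config(), rate_hz = NULL) {
  assert_that(inherits(series, "intensity_series"), "series must be an intensity_series")
  v <- series$values
  assert_that(length(v) > 0, "series is empty")
  nw <- config$n_windows
  # equal-count contiguous windows (last window absorbs the remainder)
  idx <- floor(seq_len(length(v)) * nw / (length(v) + 1)) + 1
  win_means <- as.numeric(tapply(v, factor(idx, levels = seq_len(nw)), mean))
  win_means[is.na(win_means)] <- 0
  feats <- setNames(safe_log(win_means), sprintf("logint_w%02d", seq_len(nw)))

  edges <- config$band_edges_hz
  if (length(edges) >= 3) {
    assert_that(!is.null(raw_channel),
                "raw_channel is required for band-power ratio features")
    if (is.null(rate_hz)) rate_hz <- round(1 / series$dt_s)
    p <- Mod(fft(raw_channel))^2
    n <- length(raw_channel)
    freqs <- (seq_len(n %/% 2 + 1) - 1) * rate_hz / n
    band_power <- vapply(seq_len(length(edges) - 1), function(b) {
      sel <- freqs >= edges[b] & freqs < edges[b + 1]
      sum(p[seq_along(freqs)][sel])
    }, numeric(1))
    ratios <- safe_log(band_power[-1]) - safe_log(band_power[-length(band_power)])
    names(ratios) <- sprintf("bandratio_%g_%g", edges[2:(length(edges) - 1)],
                             edges[3:length(edges)])
    feats <- c(feats, ratios)
  }

  if (config$include_envelope_stats) {
    m <- mean(win_means)
    cv <- if (m > 0) sd(win_means) / m else 0
    logiqr <- if (all(win_means > 0))
      diff(quantile(log(win_means), c(0.25, 0.75), names = FALSE)) else 0
    feats <- c(feats, env_cv = cv, env_logiqr = logiqr)
  }
  assert_that(all(is.finite(feats)), "non-finite feature value")
  structure(feats, class = c("feature_vector", "numeric"))
}

#' Featurize a whole study
#'
#' Runs every data source through [bandpass()], [to_intensity()] and
#' [extract_features()], producing the feature matrix the detector trains
#' on. Accepts either an in-memory [generate_study()] result or a
#' [load_study()] result.
#'
#' @param study A `study` or `study_data` object.
#' @param spec Band-pass [filter_spec()].
#' @param config [feature_config()].
#' @param gap_s Intensity gap in seconds (default `5e-5`, the acquisition
#'   interval at 20 kHz; clamped to one sample for lower test rates).
#' @return An object of class `feature_dataset`: list with `features`
#'   (numeric matrix, one row per data source, named columns) and `labels`
#'   (data frame with `subject`, `condition`, `volume_ml`, `source`).
#' @export
featurize_study <- function(study, spec = filter_spec(),
                            config = feature_config(), gap_s = 5e-5) {
  if (inherits(study, "study")) {
    rate <- study$recordings[[1]]$sample_rate_hz
    man <- study$manifest
    get_samples <- function(i)
      study$recordings[[man$recording[i]]]$channels[[man$source[i]]]
    labels <- data.frame(subject = man$subject, condition = man$condition,
                         volume_ml = man$volume_ml,
                         source = paste0(man$path, ":", man$channel),
                         stringsAsFactors = FALSE)
  } else if (inherits(study, "study_data")) {
    rate <- attr(study, "rate_hz")
    get_samples <- function(i) study[[i]]$samples
    labels <- data.frame(
      subject = vapply(study, `[[`, character(1), "subject"),
      condition = vapply(study, `[[`, character(1), "condition"),
      volume_ml = vapply(study, `[[`, integer(1), "volume_ml"),
      source = vapply(study, function(e) paste0(e$path, ":", e$channel),
                      character(1)),
      stringsAsFactors = FALSE)
  } else stop_pleura("study must be a 'study' or 'study_data' object")
  gap_s <- max(gap_s, 1 / rate)
  rows <- lapply(seq_len(nrow(labels)), function(i) {
    x <- bandpass(get_samples(i), rate, spec)
    s <- to_intensity(x, rate, gap_s)
    extract_features(s, raw_channel = x, config = config, rate_hz = rate)
  })
  features <- do.call(rbind, rows)
  rownames(features) <- labels$source
  structure(list(features = features, labels = labels),
            class = "feature_dataset")
}

#' @export
print.feature_dataset <- function(x, ...) {
  cat(sprintf("<feature_dataset> %d data sources x %d features\n",
              nrow(x$features), ncol(x$features)))
  invisible(x)
}

#' Export a feature dataset as CSV
#'
#' One row per data source: label columns first, then named features.
#' @param dataset A [featurize_study()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(dataset, path) {
  assert_that(inherits(dataset, "feature_dataset"), "not a feature_dataset")
  write.csv(cbind(dataset$labels, as.data.frame(dataset$features)),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a feature dataset written by [write_features()]
#' @param path CSV path.
#' @return A `feature_dataset`.
#' @export
read_features <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  lab_cols <- c("subject", "condition", "volume_ml", "source")
  assert_that(all(lab_cols %in% names(df)), "not a feature CSV (label columns missing)")
  feats <- as.matrix(df[, setdiff(names(df), lab_cols), drop = FALSE])
  rownames(feats) <- df$source
  structure(list(features = feats, labels = df[, lab_cols]),
            class = "feature_dataset")
}
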
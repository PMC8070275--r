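#' Write a study to disk as WAV files plus a CSV manifest
#'
#' Each recording becomes two 2-channel WAV files (one per stethoscope),
#' named `<subject>_<condition>_<volume>ml_<steth>.wav`. The manifest CSV has
#' header `path,channel,subject,condition,volume_ml`; `channel` is the
#' 0-based audio channel index within the WAV file, so each recording
#' contributes four manifest rows (four data sources).
#'
#' @param study A [generate_study()] result.
#' @param dir Output directory (created if needed).
#' @param format WAV sample format, see [write_wav()]. Default `"float32"`
#'   so the round-trip is lossless.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_study <- function(study, dir, format = "float32") {
  assert_that(inherits(study, "study"), "study must come from generate_study()")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(study$recordings)) {
    rec <- study$recordings[[i]]
    for (st in c("A", "B")) {
      path <- file.path(dir, sprintf("%s_%s_%dml_%s.wav", rec$subject_id,
                                     rec$condition, rec$volume_ml, st))
      write_wav(cbind(rec$channels[[paste0(st, 1)]],
                      rec$channels[[paste0(st, 2)]]),
                rec$sample_rate_hz, path, format = format)
    }
  }
  manifest_path <- file.path(dir, "manifest.csv")
  write.csv(study$manifest[, c("path", "channel", "subject", "condition",
                               "volume_ml")],
            manifest_path, row.names = FALSE, quote = FALSE)
  invisible(manifest_path)
}

#' Load a recorded study from a manifest
#'
#' Reads a `path,channel,subject,condition,volume_ml` manifest CSV and pulls
#' the referenced audio channel of every row. Rows are returned in manifest
#' order, with no filtering; every data source keeps its labels. WAV paths
#' are resolved relative to the manifest's directory.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return A list of class `study_data`: one element per manifest row, each a
#'   list with `samples` (numeric vector), `subject`, `condition`,
#'   `volume_ml`, `channel` and `path`. The common sampling rate is attached
#'   as attribute `rate_hz`.
#' @export
load_study <- function(manifest_path) {
  assert_that(file.exists(manifest_path),
              paste("no such manifest:", manifest_path))
  man <- read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("path", "channel", "subject", "condition", "volume_ml")
  missing_cols <- setdiff(need, names(man))
  assert_that(length(missing_cols) == 0,
              paste("manifest lacks columns:", paste(missing_cols, collapse = ", ")))
  base <- dirname(manifest_path)
  entries <- vector("list", nrow(man))
  cache <- new.env(parent = emptyenv())
  rate <- NULL
  for (i in seq_len(nrow(man))) {
    row <- man[i, ]
    wav_path <- if (file.exists(row$path)) row$path else file.path(base, row$path)
    if (!file.exists(wav_path))
      stop_pleura(sprintf("manifest row %d: missing WAV file '%s'", i, row$path))
    key <- wav_path
    if (is.null(cache[[key]])) cache[[key]] <- read_wav(wav_path)
    wav <- cache[[key]]
    if (is.null(rate)) rate <- wav$rate_hz
    if (wav$rate_hz != rate)
      stop_pleura(sprintf("manifest row %d: sample rate %d of '%s' differs from %d",
                          i, wav$rate_hz, row$path, rate))
    ch <- row$channel + 1L
    if (is.na(ch) || ch < 1L || ch > ncol(wav$samples))
      stop_pleura(sprintf("manifest row %d: channel index %s invalid for '%s'",
                          i, row$channel, row$path))
    entries[[i]] <- list(samples = wav$samples[, ch], subject = row$subject,
                         condition = row$condition,
                         volume_ml = as.integer(row$volume_ml),
                         channel = row$channel, path = row$path)
  }
  structure(entries, class = "study_data", rate_hz = rate)
}

#' @export
print.study_data <- function(x, ...) {
  cat(sprintf("<study_data> %d data sources at %s Hz\n", length(x),
              attr(x, "rate_hz") %||% "?"))
  invisible(x)
}
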
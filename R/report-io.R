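#' Write an evaluation report as JSON
#'
#' Serialises confusion counts, percentage metrics, the optional correlation
#' and permutation blocks, the genome and the config/seed echo. Optional
#' blocks that are absent are omitted from the JSON entirely (no `null`
#' placeholders).
#'
#' @param report An [evaluation_report()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  assert_that(inherits(report, "evaluation_report"), "not an evaluation_report")
  out <- list(task = report$task,
              counts = report$counts[c("TP", "TN", "FP", "FN")],
              sensitivity = report$sensitivity,
              specificity = report$specificity,
              accuracy = report$accuracy,
              n_iterations = report$n_iterations)
  if (!is.null(report$confusion_table)) {
    tab <- report$confusion_table
    out$confusion_table <- list(classes = rownames(tab),
                                counts = unclass(unname(tab)))
  }
  if (!is.null(report$correlation)) out$correlation <- report$correlation
  if (!is.null(report$permutation)) {
    p <- report$permutation
    out$permutation <- list(n_permutations = p$n_permutations,
                            observed_accuracy = p$observed_accuracy,
                            null_mean = p$null_mean,
                            p_perm = p$p_perm,
                            null_accuracies = p$null_accuracies)
  }
  if (!is.null(report$genome)) {
    g <- report$genome
    out$genome <- list(k = g$k, feature_mask = g$feature_mask,
                       feature_weights = g$feature_weights,
                       distance_exponent = g$distance_exponent)
  }
  if (!is.null(report$seed)) out$seed <- report$seed
  if (!is.null(report$config)) out$config <- report$config
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read an evaluation report written by [write_report()]
#' @param path JSON path.
#' @return An `evaluation_report`-classed list (the confusion table is
#'   restored as a matrix with class dimnames).
#' @export
read_report <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  rep <- list(task = j$task,
              counts = do.call(confusion_counts, as.list(j$counts)),
              sensitivity = j$sensitivity, specificity = j$specificity,
              accuracy = j$accuracy, n_iterations = j$n_iterations,
              correlation = j$correlation, permutation = j$permutation,
              seed = j$seed, config = j$config)
  if (!is.null(j$confusion_table)) {
    m <- j$confusion_table$counts
    dimnames(m) <- list(truth = j$confusion_table$classes,
                        predicted = j$confusion_table$classes)
    rep$confusion_table <- m
  }
  if (!is.null(j$genome))
    rep$genome <- detector_genome(j$genome$k, j$genome$feature_mask,
                                  j$genome$feature_weights,
                                  j$genome$distance_exponent)
  structure(rep, class = "evaluation_report")
}
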
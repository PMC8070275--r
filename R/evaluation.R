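#' Confusion counts
#'
#' @param TP,TN,FP,FN Non-negative integer counts (true/false
#'   positive/negative) from the binary injury-present collapse.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  v <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  assert_that(all(v >= 0) && all(v == round(v)), "counts must be non-negative integers")
  assert_that(sum(v) > 0, "all four confusion counts are zero")
  structure(as.list(as.integer(v)), names = names(v), class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' Sensitivity = 100 TP / (TP + FN); specificity = 100 TN / (TN + FP);
#' accuracy = 100 (TP + TN) / (TP + TN + FP + FN). A metric whose
#' denominator is zero is undefined and reported as `NA`, never as 0.
#'
#' @param c A [confusion_counts()].
#' @return Named numeric vector `sensitivity`, `specificity`, `accuracy`
#'   (percentages).
#' @examples
#' confusion_metrics(confusion_counts(8, 6, 3, 2))
#' @export
confusion_metrics <- function(c) {
  assert_that(inherits(c, "confusion_counts"), "not confusion_counts")
  sens <- if (c$TP + c$FN > 0) 100 * c$TP / (c$TP + c$FN) else NA_real_
  spec <- if (c$TN + c$FP > 0) 100 * c$TN / (c$TN + c$FP) else NA_real_
  acc <- 100 * (c$TP + c$TN) / (c$TP + c$TN + c$FP + c$FN)
  c(sensitivity = sens, specificity = spec, accuracy = acc)
}

#' Pearson correlation between real and predicted injury volumes
#'
#' Product-moment correlation with `df = n - 2` and a two-sided p-value from
#' the t transform `t = r * sqrt(df / (1 - r^2))` (as computed by
#' [stats::cor.test()]).
#'
#' @param real_volumes,predicted_volumes Equal-length numeric vectors,
#'   `n >= 3`, each with non-zero variance.
#' @return List with `r`, `df` and `p`.
#' @examples
#' volume_correlation(c(0, 400, 600, 800), c(0, 600, 400, 800))
#' @export
volume_correlation <- function(real_volumes, predicted_volumes) {
  n <- length(real_volumes)
  assert_that(n == length(predicted_volumes), "length mismatch")
  assert_that(n >= 3, "need at least 3 pairs")
  assert_that(sd(real_volumes) > 0 && sd(predicted_volumes) > 0,
              "undefined correlation: a sequence has zero variance")
  ct <- cor.test(real_volumes, predicted_volumes, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}

#' Monte-Carlo permutation check of a fitted detector
#'
#' Gauges how much of the observed LOOCV accuracy could arise by chance:
#' class labels are shuffled across the retained items and the LOOCV
#' accuracy of the *fixed* genome recomputed for each shuffle. The
#' permutation p-value uses the add-one estimator
#' `p = (1 + #\{null >= observed\}) / (n_permutations + 1)`.
#'
#' @param dataset A [featurize_study()] result.
#' @param task A [classification_task()].
#' @param genome The fixed [detector_genome()] under test.
#' @param n_permutations Number of label shuffles (>= 1). Default 200.
#' @param seed Integer seed; shuffles are reproducible and the caller's RNG
#'   state is untouched.
#' @return List of class `permutation_block`: `n_permutations`,
#'   `observed_accuracy`, `null_accuracies`, `null_mean`, `p_perm`.
#' @export
monte_carlo_permutation <- function(dataset, task, genome,
                                    n_permutations = 200, seed = 1) {
  assert_that(is_count(n_permutations), "n_permutations must be >= 1")
  base <- loocv(dataset, genome, task)
  observed <- base$accuracy
  cls <- apply_task(task, dataset$labels)
  keep <- which(!is.na(cls))
  sub <- list(features = dataset$features[keep, , drop = FALSE],
              labels = dataset$labels[keep, , drop = FALSE])
  # permute at the class-label level: a task whose mapping returns the
  # current shuffle verbatim, so the exclusion rules are not re-applied
  perm_env <- new.env(parent = emptyenv())
  ident <- classification_task(paste0(task$name, "_permuted"),
                               class_of = function(condition, volume_ml)
                                 perm_env$labels,
                               positive_classes = task$positive_classes,
                               volume_of = task$volume_of)
  null_acc <- with_seed(seed, vapply(seq_len(n_permutations), function(b) {
    perm_env$labels <- sample(base$truth)
    loocv(sub, genome, ident)$accuracy
  }, numeric(1)))
  structure(list(n_permutations = n_permutations,
                 observed_accuracy = observed,
                 null_accuracies = null_acc,
                 null_mean = mean(null_acc),
                 p_perm = (1 + sum(null_acc >= observed)) / (n_permutations + 1)),
            class = "permutation_block")
}

#' @export
print.permutation_block <- function(x, ...) {
  cat(sprintf("<permutation_block> observed %.1f%%, null mean %.1f%% (%d shuffles), p = %.4g\n",
              x$observed_accuracy, x$null_mean, x$n_permutations, x$p_perm))
  invisible(x)
}

#' Assemble a full evaluation report for one task
#'
#' @param task A [classification_task()].
#' @param cv A [loocv()] result for the final genome.
#' @param correlation Optional [volume_correlation()] block.
#' @param permutation Optional [monte_carlo_permutation()] block.
#' @param genome The evaluated genome.
#' @param seed Seed echo for provenance.
#' @param config Optional configuration echo (named list).
#' @return An object of class `evaluation_report`.
#' @seealso [write_report()]
#' @export
evaluation_report <- function(task, cv, correlation = NULL,
                              permutation = NULL, genome = NULL, seed = NULL,
                              config = NULL) {
  metrics <- confusion_metrics(cv$counts)
  structure(list(task = task$name,
                 counts = cv$counts,
                 sensitivity = unname(metrics["sensitivity"]),
                 specificity = unname(metrics["specificity"]),
                 accuracy = cv$accuracy,
                 n_iterations = cv$n_iterations,
                 confusion_table = cv$table,
                 correlation = correlation,
                 permutation = permutation,
                 genome = genome, seed = seed, config = config),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s\n", x$task))
  cat(sprintf("  sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%  (n = %d)\n",
              x$sensitivity, x$specificity, x$accuracy, x$n_iterations))
  if (!is.null(x$correlation))
    cat(sprintf("  volume correlation r(%d) = %.2f, p = %.3g\n",
                x$correlation$df, x$correlation$r, x$correlation$p))
  if (!is.null(x$permutation))
    cat(sprintf("  permutation: null mean %.1f%%, p = %.4g\n",
                x$permutation$null_mean, x$permutation$p_perm))
  invisible(x)
}
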
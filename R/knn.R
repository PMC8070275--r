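# Distances from one query to every training row under a genome:
# weighted Minkowski over the masked features.
genome_distances <- function(train_x, query, genome) {
  m <- genome$feature_mask
  w <- genome$feature_weights[m]
  p <- genome$distance_exponent
  d <- abs(train_x[, m, drop = FALSE] -
             matrix(query[m], nrow(train_x), sum(m), byrow = TRUE))
  if (p == 1) rowSums(d * rep(w, each = nrow(d)))
  else sqrt(rowSums(d * d * rep(w, each = nrow(d))))
}

#' Classify one query by weighted k-nearest neighbours
#'
#' Distance is weighted Minkowski (`genome$distance_exponent` 1 or 2) over
#' the features selected by `genome$feature_mask`. Among the `k` nearest
#' training items the majority class wins. Ties are resolved
#' deterministically: first the tied class with the smaller summed neighbour
#' distance, then the lexicographically first label. Equal distances at the
#' k-th neighbour are resolved by training-set order (stable sort).
#'
#' @param train_x Numeric training matrix (rows = items).
#' @param train_y Class labels, one per training row.
#' @param query Numeric feature vector.
#' @param genome A [detector_genome()].
#' @return The predicted class label (character scalar).
#' @export
knn_predict <- function(train_x, train_y, query, genome) {
  validate_genome(genome)
  assert_that(nrow(train_x) >= 1, "empty training set")
  assert_that(genome$k <= nrow(train_x), "k exceeds the training-set size")
  assert_that(length(genome$feature_mask) == ncol(train_x),
              "feature mask length does not match the feature space")
  assert_that(length(query) == ncol(train_x), "query dimension mismatch")
  d <- genome_distances(train_x, query, genome)
  nn <- order(d, seq_along(d))[seq_len(genome$k)]
  vote_class(as.character(train_y)[nn], d[nn])
}

# Majority vote with (summed-distance, lexicographic) tie-breaking.
vote_class <- function(labels, dists) {
  votes <- table(labels)
  top <- names(votes)[votes == max(votes)]
  if (length(top) > 1L) {
    sums <- vapply(top, function(cl) sum(dists[labels == cl]), numeric(1))
    top <- top[sums == min(sums)]
    top <- sort(top)
  }
  top[1L]
}

#' Leave-one-out cross-validation of a detector genome
#'
#' Applies the task's state-to-class mapping, drops excluded items, then
#' holds out each retained item in turn, training on all others. Features
#' are z-scored with the training fold's statistics only (the held-out item
#' never contributes to its own standardisation). The number of iterations
#' equals the retained item count — 176 for the full study with nothing
#' excluded, 144 after the standard 200 ml exclusions.
#'
#' By default every data source is its own fold, matching the study design
#' in which the four channels of one recording count as independent
#' datasets. That convention lets channels of the same recording sit in
#' both training and test folds; `group` enables a stricter leave-one-group-
#' out variant (e.g. `group = recording id`) that holds all channels of a
#' recording out together.
#'
#' @param dataset A [featurize_study()] result (or any list with a
#'   `features` matrix and `labels` data frame).
#' @param genome A [detector_genome()].
#' @param task A [classification_task()].
#' @param standardize Z-score features per training fold? Default TRUE.
#' @param group Optional grouping vector (length = dataset rows); items
#'   sharing a value are held out together. Default NULL (plain LOOCV).
#' @return An object of class `loocv_result`: `predictions` and `truth`
#'   (character vectors over retained items), `n_iterations`, `accuracy`
#'   (exact-match %, multi-class aware), `counts` (binary-collapse confusion
#'   counts TP/TN/FP/FN via `task$positive_classes`), `table` (full
#'   confusion table), `volumes` (real and predicted, where the task
#'   attaches volumes to classes), and `retained` (row indices kept).
#' @export
loocv <- function(dataset, genome, task, standardize = TRUE, group = NULL) {
  validate_genome(genome)
  cls <- apply_task(task, dataset$labels)
  keep <- which(!is.na(cls))
  assert_that(length(keep) >= 2, "fewer than two retained items")
  X <- dataset$features[keep, , drop = FALSE]
  y <- cls[keep]
  counts_per_class <- table(y)
  assert_that(all(counts_per_class >= 2), "each retained class needs >= 2 items")
  n <- nrow(X)
  assert_that(genome$k <= n - 1, "k must be below the retained item count")
  assert_that(length(genome$feature_mask) == ncol(X),
              "feature mask length does not match the feature space")
  folds <- if (is.null(group)) {
    as.list(seq_len(n))
  } else {
    assert_that(length(group) == nrow(dataset$features),
                "group length must match the dataset")
    unname(split(seq_len(n), group[keep]))
  }
  m <- genome$feature_mask
  Xm <- X[, m, drop = FALSE]
  w <- genome$feature_weights[m]
  p <- genome$distance_exponent
  # per-fold training mean/sd from running totals
  S <- colSums(Xm); Q <- colSums(Xm^2)
  preds <- character(n)
  for (fold in folds) {
    nt <- n - length(fold)
    assert_that(genome$k <= nt, "k must be below the training-fold size")
    if (standardize) {
      xg <- Xm[fold, , drop = FALSE]
      mu <- (S - colSums(xg)) / nt
      vr <- (Q - colSums(xg^2) - nt * mu^2) / (nt - 1)
      sdv <- sqrt(pmax(vr, 0)); sdv[sdv < 1e-12] <- 1
    } else {
      mu <- rep(0, ncol(Xm)); sdv <- rep(1, ncol(Xm))
    }
    train <- Xm[-fold, , drop = FALSE]
    y_train <- y[-fold]
    for (i in fold) {
      d <- abs(train - matrix(Xm[i, ], nt, ncol(Xm), byrow = TRUE))
      d <- d / rep(sdv, each = nt)
      dist_i <- if (p == 1) rowSums(d * rep(w, each = nt))
                else sqrt(rowSums(d * d * rep(w, each = nt)))
      nn <- order(dist_i, seq_len(nt))[seq_len(genome$k)]
      preds[i] <- vote_class(y_train[nn], dist_i[nn])
    }
  }
  classes <- sort(unique(y))
  tab <- table(truth = factor(y, classes), predicted = factor(preds, classes))
  pos <- task$positive_classes
  tp <- sum(y %in% pos & preds %in% pos)
  tn <- sum(!(y %in% pos) & !(preds %in% pos))
  fp <- sum(!(y %in% pos) & preds %in% pos)
  fn <- sum(y %in% pos & !(preds %in% pos))
  volumes <- NULL
  if (!is.null(task$volume_of)) {
    volumes <- list(real = unname(task$volume_of[y]),
                    predicted = unname(task$volume_of[preds]))
  }
  structure(list(predictions = preds, truth = y, n_iterations = n,
                 n_folds = length(folds),
                 accuracy = 100 * mean(preds == y),
                 counts = confusion_counts(tp, tn, fp, fn),
                 table = tab, volumes = volumes, retained = keep),
            class = "loocv_result")
}

#' @export
print.loocv_result <- function(x, ...) {
  cat(sprintf("<loocv_result> %d iterations, accuracy %.1f%%\n",
              x$n_iterations, x$accuracy))
  print(x$table)
  invisible(x)
}
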
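# Shared fixtures and independent oracles. Unit tests run on a scaled-down
# study (lower sampling rate, shorter recordings, fewer subjects); the
# full-scale replica is exercised in test-acceptance.R.

small_config <- function(seed = 42, ...) {
  generator_config(sample_rate_hz = 8000, duration_s = 1.5, n_subjects = 2,
                   volumes_ml = c(0, 200, 400, 600, 800, 1000),
                   seed = seed, ...)
}

small_filter <- function() filter_spec(60, 2000, order = 4)

# A task that reads the class straight from the `condition` column; lets
# KNN/LOOCV tests use arbitrary label vectors without inventing study states.
label_task <- function(positive_classes, volume_of = NULL) {
  classification_task("labels_as_classes",
                      class_of = function(condition, volume_ml) condition,
                      positive_classes = positive_classes,
                      volume_of = volume_of)
}

# Random feature dataset with the labels stored as conditions.
random_dataset <- function(n, n_features, classes, seed) {
  set.seed(seed)
  labels <- sample(rep_len(classes, n))
  list(features = matrix(rnorm(n * n_features), n, n_features,
                         dimnames = list(NULL, paste0("f", seq_len(n_features)))),
       labels = data.frame(condition = labels, volume_ml = 0L,
                           stringsAsFactors = FALSE))
}

# --- brute-force oracles (independent of the package implementation) --------

# Plain loops-and-sort KNN with the documented tie rules.
brute_knn <- function(train_x, train_y, query, k, mask, weights, p) {
  d <- numeric(nrow(train_x))
  for (i in seq_len(nrow(train_x))) {
    acc <- 0
    for (j in which(mask)) acc <- acc + weights[j] * abs(train_x[i, j] - query[j])^p
    d[i] <- acc^(1 / p)
  }
  ord <- order(d, seq_along(d))
  nn <- ord[seq_len(k)]
  lab <- as.character(train_y)[nn]
  tab <- table(lab)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) > 1) {
    sums <- sapply(winners, function(cl) sum(d[nn][lab == cl]))
    winners <- sort(winners[sums == min(sums)])
  }
  winners[1]
}

# Naive fold loop with per-fold z-scoring (sd via stats::sd on the fold).
brute_loocv <- function(X, y, k, mask, weights, p) {
  n <- nrow(X)
  preds <- character(n)
  for (i in seq_len(n)) {
    tr <- X[-i, , drop = FALSE]
    mu <- colMeans(tr)
    sdv <- apply(tr, 2, sd)
    sdv[sdv < 1e-12] <- 1
    trz <- scale(tr, center = mu, scale = sdv)
    qz <- (X[i, ] - mu) / sdv
    preds[i] <- brute_knn(trz, y[-i], qz, k, mask, weights, p)
  }
  preds
}

rms <- function(x) sqrt(mean(x^2))

spectral_centroid <- function(x, rate) {
  p <- Mod(fft(x))^2
  n <- length(x)
  half <- seq_len(n %/% 2)
  f <- (half - 1) * rate / n
  sum(f * p[half]) / sum(p[half])
}
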
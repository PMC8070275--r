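# Label table replicating the full study design (no audio needed).
full_design_labels <- function() {
  states <- rbind(data.frame(condition = "BASELINE", volume_ml = 0L),
                  expand.grid(condition = c("PTX", "HTX"),
                              volume_ml = c(200L, 400L, 600L, 800L, 1000L),
                              stringsAsFactors = FALSE))
  df <- merge(data.frame(subject = sprintf("S%d", 1:4)), states)
  df <- df[rep(seq_len(nrow(df)), each = 4), ]  # 2 stethoscopes x 2 channels
  rownames(df) <- NULL
  df
}

test_that("the six tasks map study states as documented", {
  lab <- full_design_labels()
  expect_equal(nrow(lab), 176)

  t1 <- build_task("injury_vs_normal")
  cls <- apply_task(t1, lab)
  expect_true(all(is.na(cls[lab$volume_ml == 200])))
  expect_true(all(cls[lab$condition == "BASELINE"] == "normal"))
  expect_true(all(cls[lab$condition != "BASELINE" & lab$volume_ml >= 400] ==
                    "injury"))
  expect_equal(sum(!is.na(cls)), 176 - 32)  # 200 ml exclusion accounting

  t5 <- build_task("htx_vs_normal")  # HTX keeps all five volumes here
  cls5 <- apply_task(t5, lab)
  expect_equal(sum(cls5 == "HTX", na.rm = TRUE), 5 * 4 * 4)
  expect_true(all(is.na(cls5[lab$condition == "PTX"])))

  t4 <- build_task("ptx_volume_ladder")
  cls4 <- apply_task(t4, lab)
  expect_setequal(unique(na.omit(cls4)),
                  c("normal", "PTX_400", "PTX_600", "PTX_800", "PTX_1000"))
  expect_equal(unname(t4$volume_of["PTX_600"]), 600)

  t6 <- build_task("htx_vs_ptx")
  cls6 <- apply_task(t6, lab)
  expect_true(all(is.na(cls6[lab$condition == "BASELINE"])))
  expect_equal(sum(!is.na(cls6)), 128)
  expect_error(build_task("no_such_task"))
})

test_that("genome invariants are enforced", {
  expect_error(detector_genome(0, TRUE), "positive")
  expect_error(detector_genome(1, c(FALSE, FALSE)), "at least one")
  expect_error(detector_genome(1, c(TRUE, TRUE), c(1, -1)), "non-negative")
  expect_error(detector_genome(1, TRUE, 1, distance_exponent = 3), "1 or 2")
  g <- detector_genome(3, c(TRUE, FALSE), c(2, 1), 1)
  path <- tempfile(fileext = ".json")
  write_genome(g, path)
  expect_equal(read_genome(path), g)
})

test_that("knn_predict handles the trivial and tie cases", {
  g1 <- detector_genome(1, c(TRUE, TRUE))
  expect_equal(knn_predict(matrix(c(0, 0), 1), "only", c(5, 5), g1), "only")
  # k = 2 vote tie: the class with the smaller summed neighbour distance wins
  X <- rbind(c(0, 0), c(3, 0))
  g2 <- detector_genome(2, c(TRUE, TRUE))
  expect_equal(knn_predict(X, c("near", "far"), c(1, 0), g2), "near")
  # equidistant and still tied -> lexicographically first label
  expect_equal(knn_predict(X, c("b", "a"), c(1.5, 0), g2), "a")
  expect_error(knn_predict(X, c("a", "b"), c(1, 0),
                           detector_genome(5, c(TRUE, TRUE))), "k exceeds")
  expect_error(knn_predict(X, c("a", "b"), c(1, 0, 0),
                           detector_genome(1, c(TRUE, TRUE))), "dimension")
})

test_that("knn_predict equals the brute-force oracle on random instances", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 30; nf <- 6
    X <- matrix(rnorm(n * nf), n, nf)
    y <- sample(c("alpha", "beta", "gamma"), n, replace = TRUE)
    mask <- c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE)
    w <- runif(nf, 0.2, 2)
    for (p in c(1, 2)) {
      g <- detector_genome(5, mask, w, p)
      for (q in 1:4) {
        query <- rnorm(nf)
        expect_equal(knn_predict(X, y, query, g),
                     brute_knn(X, y, query, 5, mask, w, p),
                     info = sprintf("seed %d p %g query %d", seed, p, q))
      }
    }
  }
})

test_that("loocv equals an independent naive fold loop", {
  for (seed in c(11, 12)) {
    ds <- random_dataset(12, 5, c("x", "y", "z"), seed)
    task <- label_task("x")
    for (p in c(1, 2)) {
      g <- detector_genome(3, c(TRUE, TRUE, FALSE, TRUE, TRUE),
                           c(1, 0.5, 1, 2, 1), p)
      got <- loocv(ds, g, task)
      want <- brute_loocv(ds$features, ds$labels$condition, 3,
                          g$feature_mask, g$feature_weights, p)
      expect_equal(got$predictions, want)
      expect_equal(got$n_iterations, 12)
      expect_equal(got$accuracy, 100 * mean(want == ds$labels$condition))
    }
  }
})

test_that("loocv is invariant to dataset order and exact on separable data", {
  # classes with identical members: every held-out prediction is correct
  X <- rbind(matrix(0, 4, 3), matrix(5, 4, 3)) +
    0  # two point-mass classes
  ds <- list(features = X,
             labels = data.frame(condition = rep(c("a", "b"), each = 4),
                                 volume_ml = 0L))
  g <- detector_genome(1, rep(TRUE, 3))
  cv <- loocv(ds, g, label_task("a"))
  expect_equal(cv$accuracy, 100)
  expect_equal(unlist(cv$counts), c(TP = 4L, TN = 4L, FP = 0L, FN = 0L))

  ds2 <- random_dataset(14, 4, c("u", "v"), 99)
  g2 <- detector_genome(3, rep(TRUE, 4))
  ref <- loocv(ds2, g2, label_task("u"))
  perm <- sample(14)
  ds2p <- list(features = ds2$features[perm, ], labels = ds2$labels[perm, ])
  got <- loocv(ds2p, g2, label_task("u"))
  expect_equal(got$predictions, ref$predictions[perm])
  expect_equal(got$counts, ref$counts)

  expect_error(loocv(ds2, detector_genome(14, rep(TRUE, 4)),
                     label_task("u")), "retained item count")
})

test_that("grouped LOOCV holds correlated channels out together", {
  ds <- random_dataset(16, 4, c("a", "b"), 71)
  grp <- rep(1:4, each = 4)
  g <- detector_genome(3, rep(TRUE, 4))
  cv <- loocv(ds, g, label_task("a"), group = grp)
  expect_equal(cv$n_folds, 4L)
  expect_equal(cv$n_iterations, 16L)
  # oracle: explicit group-fold loop with per-fold standardisation
  want <- character(16)
  for (gi in 1:4) {
    hold <- which(grp == gi)
    tr <- ds$features[-hold, , drop = FALSE]
    mu <- colMeans(tr); sdv <- apply(tr, 2, sd); sdv[sdv < 1e-12] <- 1
    trz <- scale(tr, mu, sdv)
    for (i in hold)
      want[i] <- brute_knn(trz, ds$labels$condition[-hold],
                           (ds$features[i, ] - mu) / sdv, 3,
                           rep(TRUE, 4), rep(1, 4), 2)
  }
  expect_equal(cv$predictions, want)
  # plain LOOCV differs in general (same-recording neighbours available)
  expect_equal(loocv(ds, g, label_task("a"))$n_folds, 16L)
})
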
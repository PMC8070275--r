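test_that("WAV round-trip is lossless for float32 and <= 1 LSB for pcm16", {
  set.seed(1)
  x <- matrix(runif(2000, -1, 1), ncol = 2)
  f32 <- tempfile(fileext = ".wav")
  write_wav(x, 8000, f32, format = "float32")
  w <- read_wav(f32)
  expect_equal(w$rate_hz, 8000)
  # float32 quantisation only (doubles written as 4-byte floats)
  expect_lt(max(abs(w$samples - x)), 1e-6)
  p16 <- tempfile(fileext = ".wav")
  write_wav(x, 8000, p16, format = "pcm16")
  w16 <- read_wav(p16)
  expect_lt(max(abs(w16$samples - x)), 1 / 32767)
})

test_that("write_study/load_study round-trips samples in manifest order", {
  cfg <- generator_config(sample_rate_hz = 4000, duration_s = 1,
                          n_subjects = 1, volumes_ml = c(0, 600), seed = 5)
  st <- generate_study(cfg)
  dir <- tempfile("study_")
  manifest_path <- write_study(st, dir)
  loaded <- load_study(manifest_path)
  expect_length(loaded, nrow(st$manifest))
  expect_equal(attr(loaded, "rate_hz"), 4000)
  for (i in seq_along(loaded)) {
    row <- st$manifest[i, ]
    orig <- st$recordings[[row$recording]]$channels[[row$source]]
    expect_lt(max(abs(loaded[[i]]$samples - orig)), 1e-6)
    expect_equal(loaded[[i]]$condition, row$condition)
    expect_equal(loaded[[i]]$volume_ml, row$volume_ml)
  }
})

test_that("an empty manifest loads as an empty collection", {
  path <- tempfile(fileext = ".csv")
  writeLines("path,channel,subject,condition,volume_ml", path)
  expect_length(load_study(path), 0)
})

test_that("malformed manifests are rejected with the offending row", {
  dir <- tempfile("bad_"); dir.create(dir)
  path <- file.path(dir, "manifest.csv")
  writeLines(c("path,channel,subject,condition,volume_ml",
               "missing.wav,0,S1,BASELINE,0"), path)
  expect_error(load_study(path), "missing.wav")
  write_wav(rnorm(100), 8000, file.path(dir, "a.wav"))
  writeLines(c("path,channel,subject,condition,volume_ml",
               "a.wav,5,S1,BASELINE,0"), path)
  expect_error(load_study(path), "channel index")
  write_wav(rnorm(100), 4000, file.path(dir, "b.wav"))
  writeLines(c("path,channel,subject,condition,volume_ml",
               "a.wav,0,S1,BASELINE,0", "b.wav,0,S1,PTX,400"), path)
  expect_error(load_study(path), "sample rate")
})

test_that("evaluation reports survive a JSON round-trip", {
  cv <- list(counts = confusion_counts(1, 1, 0, 0), accuracy = 100,
             n_iterations = 2,
             table = table(truth = c("a", "b"), predicted = c("a", "b")))
  rep <- evaluation_report(build_task("injury_vs_normal"), cv,
                           correlation = list(r = 0.5, df = 10, p = 0.01),
                           genome = detector_genome(3, c(TRUE, FALSE, TRUE)),
                           seed = 7)
  expect_equal(rep$accuracy, 100)
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- read_report(path)
  for (f in c("task", "sensitivity", "specificity", "accuracy",
              "n_iterations", "seed"))
    expect_equal(back[[f]], rep[[f]], info = f)
  expect_equal(unlist(back$counts), unlist(rep$counts))
  expect_equal(back$correlation$r, 0.5)
  expect_equal(back$genome$k, 3L)
  # absent optional blocks are omitted, not emitted as null
  raw <- jsonlite::read_json(path)
  expect_false("permutation" %in% names(raw))
  expect_true("correlation" %in% names(raw))
})
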
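test_that("recordings have the configured shape and are finite", {
  cfg <- small_config()
  rec <- generate_recording("PTX", 600, "S1", cfg)
  expect_named(rec$channels, c("A1", "A2", "B1", "B2"))
  expect_true(all(lengths(rec$channels) ==
                    cfg$sample_rate_hz * cfg$duration_s))
  expect_true(all(vapply(rec$channels, function(ch) all(is.finite(ch)),
                         logical(1))))
})

test_that("condition/volume preconditions are enforced", {
  cfg <- small_config()
  expect_error(generate_recording("BASELINE", 400, "S1", cfg), "BASELINE")
  expect_error(generate_recording("PTX", 0, "S1", cfg), "BASELINE")
  expect_error(generate_recording("PTX", 300, "S1", cfg), "volumes_ml")
  expect_error(generator_config(duration_s = -1), "positive")
  expect_error(generator_config(volumes_ml = c(0, 400, 400)),
               "strictly increasing")
  expect_error(generator_config(respiratory_rate_bpm = 20), "13")
})

test_that("zero effect sizes make injury recordings identical to baseline", {
  cfg <- small_config(ptx_gain_drop_per_ml = 0, ptx_tilt_per_ml = 0,
                      ptx_envelope_drop_per_ml = 0, htx_damping_per_ml = 0,
                      htx_noise_per_ml = 0, noise_floor = 0,
                      subject_variation = 0)
  base <- generate_recording("BASELINE", 0, "S1", cfg)
  ptx <- generate_recording("PTX", 1000, "S1", cfg)
  htx <- generate_recording("HTX", 1000, "S1", cfg)
  expect_identical(base$channels, ptx$channels)
  expect_identical(base$channels, htx$channels)
})

test_that("PTX effects are strictly monotone across the volume ladder", {
  cfg <- small_config()
  vols <- c(200, 400, 600, 800, 1000)
  recs <- lapply(vols, generate_recording, condition = "PTX",
                 subject_id = "S1", config = cfg)
  amp <- vapply(recs, function(r) rms(r$channels$A1), numeric(1))
  expect_true(all(diff(amp) < 0))  # amplitude reduction
  cent <- vapply(recs, function(r)
    spectral_centroid(r$channels$A1, cfg$sample_rate_hz), numeric(1))
  expect_true(all(diff(cent) < 0))  # loss of high-frequency content
  # RMS at 1000 ml strictly below 400 ml (same seed), on every channel
  r400 <- recs[[2]]; r1000 <- recs[[5]]
  expect_true(all(vapply(names(r400$channels), function(ch)
    rms(r1000$channels[[ch]]) < rms(r400$channels[[ch]]), logical(1))))
})

test_that("HTX raises the independent channel noise floor monotonically", {
  cfg <- small_config()
  vols <- c(200, 400, 600, 800, 1000)
  # half the variance of (A1 - A2) estimates the per-channel noise power
  noise <- vapply(vols, function(v) {
    r <- generate_recording("HTX", v, "S1", cfg)
    var(r$channels$A1 - r$channels$A2) / 2
  }, numeric(1))
  expect_true(all(diff(noise) > 0))
  # and HTX is a damping + noise signature, not a spectral tilt: the signal
  # (shared component) weakens while channel noise grows, so SNR drops
  shared <- vapply(vols, function(v) {
    r <- generate_recording("HTX", v, "S1", cfg)
    cov(r$channels$A1, r$channels$A2)
  }, numeric(1))
  expect_true(all(diff(shared / noise) < 0))
})

test_that("stethoscopes are correlated but not identical", {
  rec <- generate_recording("BASELINE", 0, "S1", small_config())
  expect_gt(cor(rec$channels$A1, rec$channels$B1), 0.9)
  expect_false(identical(rec$channels$A1, rec$channels$B1))
  expect_false(identical(rec$channels$A1, rec$channels$A2))
})

test_that("generate_study enumerates the full design deterministically", {
  cfg <- small_config()
  st <- generate_study(cfg)
  expect_length(st$recordings, 2 * 11)
  expect_equal(nrow(st$manifest), 2 * 11 * 4)
  expect_false(anyDuplicated(st$manifest[, c("path", "channel")]) > 0)
  # volume 0 if and only if baseline
  expect_true(all((st$manifest$volume_ml == 0) ==
                    (st$manifest$condition == "BASELINE")))
  # deterministic given the seed; different seed changes samples, not labels
  st2 <- generate_study(cfg)
  expect_identical(st$recordings[[7]]$channels, st2$recordings[[7]]$channels)
  st3 <- generate_study(small_config(seed = 43))
  expect_identical(st$manifest[, c("path", "channel", "subject", "condition",
                                   "volume_ml")],
                   st3$manifest[, c("path", "channel", "subject", "condition",
                                    "volume_ml")])
  expect_false(identical(st$recordings[[7]]$channels,
                         st3$recordings[[7]]$channels))
})

test_that("degenerate designs are allowed", {
  cfg <- generator_config(sample_rate_hz = 4000, duration_s = 1,
                          n_subjects = 1, volumes_ml = 0)
  st <- generate_study(cfg)
  expect_length(st$recordings, 1)
  expect_equal(nrow(st$manifest), 4)
})
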
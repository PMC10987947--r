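test_that("RMS windowing matches the closed form and the window-count rule", {
  # constant signal: every RMS entry equals |c|
  x <- matrix(-3, 500, 2)
  r <- compute_rms_windows(x, fs = 1000, window_ms = 100, step_ms = 50)
  expect_equal(unname(r), matrix(3, nrow(r), 2))

  # two samples [3, 4], one 2-sample window: sqrt((9 + 16)/2)
  r2 <- compute_rms_windows(matrix(c(3, 4)), fs = 1000, window_ms = 2,
                            step_ms = 1)
  expect_equal(dim(r2), c(1L, 1L))
  expect_equal(r2[1, 1], sqrt(12.5))

  # 2000 samples, W = 200, S = 100 -> floor((2000-200)/100)+1 = 19 windows
  r3 <- compute_rms_windows(matrix(rnorm(2000)), fs = 2000,
                            window_ms = 100, step_ms = 50)
  expect_identical(nrow(r3), 19L)

  # a sinusoid of amplitude A over whole periods has RMS A/sqrt(2)
  fs <- 1000; A <- 2.5
  t <- seq_len(1000) / fs
  s <- A * sin(2 * pi * 10 * t)  # 10 Hz: each 100 ms window = 1 period
  r4 <- compute_rms_windows(matrix(s), fs, window_ms = 100, step_ms = 100)
  expect_true(max(abs(r4 - A / sqrt(2))) < 1e-6)

  expect_error(compute_rms_windows(matrix(1, 10, 1), fs = 1000,
                                   window_ms = 100, step_ms = 50),
               "10 samples.*100")
})

test_that("mu-law companding has the right fixed points and derived values", {
  expect_identical(mu_law_normalize(0, 255), 0)
  expect_equal(mu_law_normalize(1, 255), 1)
  expect_equal(mu_law_normalize(-1, 255), -1)
  # direct evaluation of sign(x) ln(1 + mu|x|)/ln(1 + mu)
  expect_equal(mu_law_normalize(0.5, 255), 0.87570, tolerance = 1e-4)
  # small amplitudes are amplified strongly at mu = 2^20
  expect_equal(mu_law_normalize(0.001, 2^20), 0.50178, tolerance = 1e-4)
  expect_error(mu_law_normalize(1.5), "prescale")
  expect_error(mu_law_normalize(0.5, mu = -1), "positive")
})

test_that("mu-law is odd, strictly monotone, and exactly invertible", {
  x <- seq(-1, 1, length.out = 2001)
  for (mu in c(1, 255, 2^20)) {
    y <- mu_law_normalize(x, mu)
    expect_equal(y, -rev(y))           # odd
    expect_true(all(diff(y) > 0))      # strictly increasing
    expect_true(max(abs(y)) <= 1)
    expect_lt(max(abs(mu_law_inverse(y, mu) - x)), 1e-9)
  }
  # mu -> 0 limit approaches the identity
  expect_lt(max(abs(mu_law_normalize(x, 1e-6) - x)), 0.01)
  expect_identical(mu_law_inverse(0, 255), 0)
  expect_equal(mu_law_inverse(1, 255), 1)
})

test_that("z-score normalization is affine-invariant and flags dead channels", {
  x <- matrix(rnorm(300), 100, 3)
  m <- colMeans(x); s <- apply(x, 2, sd)
  z <- zscore_normalize(x, m, s)
  expect_equal(colMeans(z), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(z, 2, sd), rep(1, 3), tolerance = 1e-12)
  # already standardized input is unchanged
  expect_equal(zscore_normalize(z, rep(0, 3), rep(1, 3)), z)
  # positive affine transform of a channel normalizes to the same series
  x2 <- x
  x2[, 2] <- 3 * x[, 2] + 7
  z2 <- zscore_normalize(x2, colMeans(x2), apply(x2, 2, sd))
  expect_equal(z2[, 2], z[, 2], tolerance = 1e-12)
  expect_error(zscore_normalize(x, m, c(1, 0, 1)), "channel\\(s\\) 2")
})

test_that("normalization specs are fit on training data and frozen", {
  tr <- matrix(abs(rnorm(200)), 50, 4)
  spec <- fit_normalization(tr, "mu_law", mu = 255)
  out <- apply_normalization(tr, spec)
  expect_true(all(out >= 0 & out <= 1))
  expect_equal(max(out), 1)           # per-channel max maps to the endpoint
  # unseen larger amplitudes are clipped, not re-fit
  te <- tr * 2
  out_te <- apply_normalization(te, spec)
  expect_true(all(out_te <= 1))
  zspec <- fit_normalization(tr, "zscore")
  expect_equal(colMeans(apply_normalization(tr, zspec)), rep(0, 4),
               tolerance = 1e-12)
  expect_error(apply_normalization(tr[, 1:2], spec), "channels")
})

test_that("label resampling interpolates linearly with the length contract", {
  a <- matrix(5, 40, 3)
  out <- resample_labels(a, 20, 2000)
  expect_identical(nrow(out), as.integer(round(40 * 100)))
  expect_true(all(out == 5))
  # a linear ramp resamples to a linear ramp with identical endpoints
  ramp <- matrix(seq(0, 10, length.out = 50))
  r <- resample_labels(ramp, 20, 200)
  expect_equal(r[1, 1], 0, tolerance = 1e-9)
  expect_lt(max(abs(diff(r[, 1]) - diff(r[, 1])[1])), 1e-9)
  expect_error(resample_labels(matrix(1, 1, 1), 20, 2000), "at least 2")
})

test_that("trial splitting is a reproducible, exhaustive 4/2 partition", {
  s <- split_trials(1:6, seed = 7)
  expect_length(s$train, 4)
  expect_length(s$test, 2)
  expect_length(intersect(s$train, s$test), 0)
  expect_setequal(c(s$train, s$test), 1:6)
  expect_identical(split_trials(1:6, seed = 7), s)
  # over 200 seeds every one of the choose(6,2) = 15 partitions occurs
  parts <- vapply(1:200, function(sd)
    paste(split_trials(1:6, seed = sd)$test, collapse = ","), "")
  expect_identical(length(unique(parts)), 15L)
  expect_error(split_trials(1:5, seed = 1), "6 distinct trials")
  expect_error(split_trials(1:6), "seed")
})

test_that("feature series align labels to window centers and round-trip CSV", {
  rec <- subject_recording("sA", "m1", 1,
                           emg = matrix(rnorm(4000 * 3), ncol = 3),
                           angles = matrix(seq(0, 30, length.out = 40),
                                           40, 2),
                           fs_emg = 2000, fs_angles = 20)
  fs <- make_feature_series(rec, 100, 50)
  expect_identical(nrow(fs$features), nrow(fs$labels))
  expect_identical(ncol(fs$labels), 2L)
  # labels of a ramp are increasing at the aligned window centers
  expect_true(all(diff(fs$labels[, 1]) >= 0))

  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "trial")
  write_feature_series(fs, prefix)
  back <- read_feature_series(prefix)
  expect_equal(unname(back$features), unname(fs$features), tolerance = 1e-12)
  expect_equal(unname(back$labels), unname(fs$labels), tolerance = 1e-12)
  expect_identical(back$provenance$subject_id, "sA")
  expect_identical(back$window_ms, 100)

  expect_error(feature_series(matrix(0, 3, 2), matrix(0, 4, 2), 100, 50,
                              list()),
               "same number of windows")
})
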
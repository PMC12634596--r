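test_that("the Welch grid yields 15 bins in 1-60 Hz and 29 segments for 3 s", {
  set.seed(41)
  x <- rnorm(3000); y <- rnorm(3000)
  wc <- welch_coherence(x, y)
  expect_length(wc$C, 15)
  expect_equal(wc$Ns, 29)
  expect_equal(wc$bin_centers, (1:15) * 1000 / 256)
  expect_true(all(wc$bin_centers >= 1 & wc$bin_centers <= 60))
})

test_that("self-coherence is one at every bin", {
  set.seed(42)
  x <- rnorm(3000)
  wc <- welch_coherence(x, x)
  expect_equal(wc$C, rep(1, 15), tolerance = 1e-10)
})

test_that("coherence is symmetric in its arguments", {
  set.seed(43)
  x <- rnorm(3000); y <- 0.5 * x + rnorm(3000)
  expect_identical(welch_coherence(x, y)$C, welch_coherence(y, x)$C)
})

test_that("signal plus equal-variance noise gives coherence one half", {
  # closed form: C = (S / (S + N))^2-free magnitude-squared form equals
  # S/(S+N) = 0.5 per bin for y = x + independent noise of equal variance
  set.seed(44)
  Cs <- replicate(20, {
    x <- rnorm(3000)
    mean(welch_coherence(x, x + rnorm(3000))$C)
  })
  expect_lt(abs(mean(Cs) - 0.5), 0.05)
})

test_that("series shorter than one window are rejected", {
  expect_error(welch_coherence(rnorm(100), rnorm(100)), "window")
})

test_that("Fisher normalization matches its closed form and stays finite", {
  expect_equal(fisher_z(0, 29), 0)
  expect_equal(fisher_z(0.5, 29), 2 * 29 * atanh(0.5), tolerance = 1e-12)
  expect_equal(fisher_z(0.5, 29), 31.86, tolerance = 1e-3)
  expect_true(is.finite(fisher_z(1, 29)))
  # conventional form available for sensitivity checks
  expect_equal(fisher_z(0.5, 29, conventional = TRUE),
               sqrt(58) * atanh(sqrt(0.5)), tolerance = 1e-12)
})

test_that("demodulation removes amplitude and preserves phase", {
  t <- seq(1 / 1000, 3, by = 1 / 1000)
  x <- 5 * cos(2 * pi * 10 * t)        # amplitude 5, 30 whole periods
  xd <- demodulate(x)
  ref <- cos(2 * pi * 10 * t)          # unit amplitude, phase preserved
  core <- 200:2800                     # away from edge effects
  expect_lt(max(abs(xd[core] - ref[core])), 0.05)
  # bounded in [-1, 1] before mean subtraction
  expect_true(all(xd + mean(cos(Arg(imcoh:::analytic_signal(x)))) <= 1 + 1e-9))
})

test_that("a constant positive series demodulates to zero", {
  expect_warning(z <- demodulate(rep(0, 100)), "zero")
  expect_equal(z, rep(0, 100))
  d <- demodulate(rep(3, 1000))
  expect_equal(d, rep(0, 1000), tolerance = 1e-12)
})

test_that("demodulation recovers the instantaneous phase of a chirp", {
  fs <- 1000
  t <- seq(0, 3, by = 1 / fs)[-1]
  f0 <- 5; f1 <- 40
  phase <- 2 * pi * (f0 * t + (f1 - f0) / (2 * 3) * t^2)
  x <- cos(phase)
  theta <- Arg(imcoh:::analytic_signal(x))
  core <- 300:2700
  # compare on the circle (cos/sin) to dodge wrapping: agreement within 0.1 rad
  expect_lt(max(abs(cos(theta[core]) - cos(phase[core]))), 0.1)
  expect_lt(max(abs(sin(theta[core]) - sin(phase[core]))), 0.1)
})

test_that("activity detection follows the variance-ratio and fraction rules", {
  # hold variance equal to rest: not recruited (ratio 1 < 1.5)
  tr <- variance_trial(rest_sd = c(1, 1, 1), hold_sd = c(1, sqrt(2), 2))
  mask <- detect_active_muscles(tr)
  expect_false(mask$recruited[1])
  expect_true(mask$recruited[3])     # ratio 4 >= 1.5 everywhere
  expect_equal(mask$activity_fraction[3], 1)

  # alternating active/silent halves: fraction ~0.5 < 0.75 -> not recruited
  tr2 <- variance_trial(rest_sd = 1, hold_sd = 1, rest_s = 0.3, hold_s = 3)
  n0 <- tr2$phase_bounds$hold[1]
  half <- tr2$emg[, 1]
  idx <- n0:(n0 + 1499)
  half[idx] <- half[idx] * 3
  tr2$emg <- matrix(half)
  m2 <- detect_active_muscles(tr2)
  expect_false(m2$recruited[1])
  expect_gt(m2$activity_fraction[1], 0.3)
  expect_lt(m2$activity_fraction[1], 0.75)
})

test_that("zero rest-phase variance is floored with a warning", {
  tr <- variance_trial(rest_sd = 1, hold_sd = 1)
  tr$emg[tr$phase_bounds$rest[1]:tr$phase_bounds$rest[2], 1] <- 0
  expect_warning(mask <- detect_active_muscles(tr), "epsilon")
  expect_true(mask$recruited[1])
})

test_that("phase surrogates preserve the periodogram exactly", {
  set.seed(45)
  x <- rnorm(1024)
  s <- phase_surrogate(x)
  expect_equal(Mod(fft(s)), Mod(fft(x)), tolerance = 1e-8)
  expect_false(isTRUE(all.equal(s, x)))
  # batch path agrees in distribution and spectrum
  sb <- imcoh:::phase_surrogate_batch(x, 3)
  for (k in 1:3) expect_equal(Mod(fft(sb[, k])), Mod(fft(x)), tolerance = 1e-8)
})

test_that("identical signals survive the surrogate threshold at every bin", {
  set.seed(46)
  x <- rnorm(3000)
  thr <- surrogate_threshold(x, x, n_surrogates = 50)
  wc <- welch_coherence(x, x)
  expect_true(all(wc$C > thr))
})

test_that("the surrogate null lets through about five percent of bins", {
  set.seed(47)
  n_pairs <- 120
  survived <- 0L
  total <- 0L
  for (i in seq_len(n_pairs)) {
    x <- rnorm(1500); y <- rnorm(1500)
    thr <- surrogate_threshold(x, y, n_surrogates = 100)
    wc <- welch_coherence(x, y)
    survived <- survived + sum(wc$C > thr)
    total <- total + length(wc$C)
  }
  expect_lt(abs(survived / total - 0.05), 0.02)
})

test_that("trials with no recruited muscles yield all-zero spectra", {
  tr <- variance_trial(rest_sd = c(1, 1), hold_sd = c(1, 1))
  mask <- detect_active_muscles(tr)
  expect_false(any(mask$recruited))
  ct <- pair_coherence_for_trial(tr, mask, n_surrogates = 10)
  expect_equal(nrow(ct$pairs), 1)
  expect_false(ct$pairs$co_active[1])
  expect_true(all(ct$Z == 0))
  expect_equal(ct$Ns, 29)   # grid still reported

  # two recruited muscles out of four: one computed pair, five zero pairs
  tr2 <- variance_trial(rest_sd = rep(1, 4), hold_sd = c(3, 3, 1, 1))
  m2 <- detect_active_muscles(tr2)
  ct2 <- pair_coherence_for_trial(tr2, m2, n_surrogates = 20)
  expect_equal(sum(ct2$pairs$co_active), 1)
  zero_pairs <- which(!ct2$pairs$co_active)
  expect_true(all(ct2$Z[, zero_pairs] == 0))
})
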
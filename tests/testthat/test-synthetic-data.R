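test_that("zero-variance dwell gives periodic switches", {
  p <- synth_params(block_duration = 30, dwell_mean = 10, dwell_sd = 0, seed = 42)
  tl <- simulate_percept_timeline(p)
  expect_equal(tl$switch_times, c(10, 20))
  expect_length(tl$percepts, 3)
  expect_true(all(tl$percepts[-1] != tl$percepts[-3]))
  expect_equal(tl$button_times, c(10, 20) + p$reaction_time)
})

test_that("timeline and signal are deterministic given the seed", {
  p <- synth_params(block_duration = 40, seed = 11)
  a <- simulate_streaming_block(p)
  b <- simulate_streaming_block(p)
  expect_identical(a$timeline, b$timeline)
  expect_identical(a$recording$values, b$recording$values)
})

test_that("dwell times follow the requested log-normal mean", {
  dwells <- unlist(lapply(1:200, function(s) {
    tl <- simulate_percept_timeline(
      synth_params(block_duration = 300, dwell_mean = 10, dwell_sd = 3, seed = s)
    )
    diff(c(0, tl$switch_times)) # completed dwells only
  }))
  se <- sd(dwells) / sqrt(length(dwells))
  expect_lt(abs(mean(dwells) - 10), 2 * se + 0.15) # small truncation allowance
})

test_that("noiseless single-harmonic signal is a pure tone at the triplet rate", {
  p <- synth_params(n_channels = 1, block_duration = 60, n_harmonics = 1,
                    percept_phase_offsets = 0, slow_drift_amplitude = 0,
                    noise_sd = 0, seed = 5)
  tl <- simulate_percept_timeline(p)
  rec <- simulate_lfp(tl, p)
  x <- rec$values[, 1]
  pw <- Mod(fft(x))^2
  freqs <- (seq_along(x) - 1) * p$rate / length(x)
  peak_f <- freqs[which.max(pw[freqs > 0 & freqs <= p$rate / 2])+ 1L]
  expect_equal(peak_f, p$f_triplet, tolerance = 1e-9)
})

test_that("a pi phase offset negates the signal in two-stream epochs", {
  p <- synth_params(n_channels = 1, block_duration = 30, n_harmonics = 1,
                    percept_phase_offsets = pi, slow_drift_amplitude = 0,
                    noise_sd = 0, dwell_mean = 10, dwell_sd = 0, seed = 2)
  tl <- simulate_percept_timeline(p)
  rec <- simulate_lfp(tl, p)
  t <- rec_times(rec)
  z <- percept_state(tl, t)
  base <- p$harmonic_amplitudes[1, 1] * cos(2 * pi * p$f_triplet * t)
  expect_equal(rec$values[, 1], base * (1 - 2 * z), tolerance = 1e-12)
})

test_that("analytic-signal phase differs between percept states by the offset", {
  dphi <- pi / 2
  p <- synth_params(n_channels = 1, block_duration = 40, n_harmonics = 1,
                    percept_phase_offsets = dphi, slow_drift_amplitude = 0,
                    noise_sd = 0, dwell_mean = 20, dwell_sd = 0, seed = 3)
  tl <- simulate_percept_timeline(p)
  rec <- simulate_lfp(tl, p)
  x <- rec$values[, 1]
  # analytic-signal oracle via frequency-domain Hilbert transform
  n <- length(x)
  h <- rep(0, n); h[1] <- 1; h[2:(n / 2)] <- 2; h[n / 2 + 1] <- 1
  analytic <- fft(fft(x) * h, inverse = TRUE) / n
  t <- rec_times(rec)
  dev <- Arg(analytic * exp(-2i * pi * p$f_triplet * t))
  z <- percept_state(tl, t)
  interior <- t > 2 & t < 38 & abs(t - 20) > 2 # away from edges and the switch
  d <- atan2(sin(mean(dev[interior & z == 1]) - mean(dev[interior & z == 0])),
             cos(mean(dev[interior & z == 1]) - mean(dev[interior & z == 0])))
  expect_lt(abs(abs(d) - dphi), 0.1)
})

test_that("noiseless spectrum concentrates at triplet harmonics", {
  # no percept modulation: essentially all power sits exactly on the harmonics
  p0 <- synth_params(n_channels = 1, block_duration = 60, n_harmonics = 3,
                     percept_phase_offsets = rep(0, 3),
                     slow_drift_amplitude = 0, noise_sd = 0,
                     dwell_mean = 15, dwell_sd = 0, seed = 7)
  rec0 <- simulate_lfp(simulate_percept_timeline(p0), p0)
  x0 <- rec0$values[, 1]
  pw0 <- Mod(fft(x0))^2
  freqs <- (seq_along(x0) - 1) * p0$rate / length(x0)
  keep <- freqs > 0 & freqs <= p0$rate / 2
  in_band <- abs(freqs[keep] - round(freqs[keep] / p0$f_triplet) * p0$f_triplet) < 0.2 &
    round(freqs[keep] / p0$f_triplet) >= 1
  expect_gt(sum(pw0[keep][in_band]) / sum(pw0[keep]), 0.999)

  # with phase modulation the spectral peaks remain at the harmonics,
  # surrounded by modulation sidebands
  p1 <- synth_params(n_channels = 1, block_duration = 60, n_harmonics = 3,
                     slow_drift_amplitude = 0, noise_sd = 0,
                     dwell_mean = 15, dwell_sd = 0, seed = 7)
  rec1 <- simulate_lfp(simulate_percept_timeline(p1), p1)
  pw1 <- Mod(fft(rec1$values[, 1]))^2[keep]
  f_keep <- freqs[keep]
  top3 <- f_keep[order(pw1, decreasing = TRUE)[1:3]]
  expect_true(all(abs(top3 - round(top3 / p1$f_triplet) * p1$f_triplet) < 0.1))
})

test_that("percept occupancy approaches one half for symmetric dwells", {
  fracs <- vapply(1:5, function(s) {
    tl <- simulate_percept_timeline(
      synth_params(block_duration = 3000, dwell_mean = 10, dwell_sd = 3, seed = s)
    )
    t <- seq(0, 3000, by = 0.1)
    mean(percept_state(tl, t))
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.5), 0.1)
})

test_that("invalid generator parameters are rejected", {
  expect_error(synth_params(dwell_mean = -1), "dwell")
  expect_error(synth_params(noise_sd = -0.1), "noise_sd")
  expect_error(synth_params(dwell_mean = 0.5, reaction_time = 0.65), "reaction_time")
  p30 <- synth_params(block_duration = 30, seed = 1)
  p60 <- synth_params(block_duration = 60, seed = 1)
  tl <- simulate_percept_timeline(p60)
  expect_error(simulate_lfp(tl, p30), "duration")
})
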
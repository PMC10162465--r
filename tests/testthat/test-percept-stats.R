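make_timeline <- function(switches, duration, rt = 0.65, first = "one_stream",
                          td = 0.6) {
  other <- c(one_stream = "two_stream", two_stream = "one_stream")
  percepts <- first
  for (i in seq_along(switches)) percepts <- c(percepts, other[[tail(percepts, 1)]])
  structure(
    list(switch_times = switches, percepts = percepts,
         button_times = switches + rt, reaction_time = rt,
         block_duration = duration, triplet_duration = td),
    class = "percept_timeline"
  )
}

test_that("neutral-triplet counts follow ceiling(rt / triplet)", {
  tl <- make_timeline(c(30), 60, rt = 0.65)
  lab <- label_triplets(tl)
  expect_equal(attr(lab, "n_neutral"), 2)
  expect_equal(sum(lab$label == "neutral"), 2)
  # the ambiguous triplets span the switch-to-press interval [30, 30.65]
  expect_equal(lab$onset_s[lab$label == "neutral"], c(30, 30.6))

  tl_slow <- make_timeline(c(30), 60, rt = 3.22)
  lab_slow <- label_triplets(tl_slow)
  expect_equal(attr(lab_slow, "n_neutral"), 6)
  expect_equal(sum(lab_slow$label == "neutral"), 6)
})

test_that("labels alternate with the timeline and cover the block", {
  tl <- make_timeline(c(20, 40), 60, rt = 0.65, first = "two_stream")
  lab <- label_triplets(tl)
  expect_equal(nrow(lab), 100)
  expect_equal(lab$label[1], "two_stream")
  expect_equal(lab$label[60], "one_stream")
  expect_equal(lab$label[90], "two_stream")
  # no presses: all triplets carry the initial percept
  tl0 <- make_timeline(numeric(0), 30)
  lab0 <- label_triplets(tl0)
  expect_true(all(lab0$label == "one_stream"))
})

test_that("constrained permutations preserve switch count and run lengths", {
  set.seed(9)
  for (i in 1:50) {
    lab <- permute_triplet_labels(100, 5, rt = 0.65, triplet_duration = 0.6)
    core <- lab[lab != "neutral"]
    runs <- rle(core)
    expect_equal(length(runs$values) - 1L, 5L)
    # each percept run spans > RT (neutral zones bite into earlier runs)
    full_runs <- rle(sub("neutral", NA, lab))
    expect_true(all(table(cumsum(c(TRUE, diff(lab != "neutral") != 0))) >= 1))
  }
  expect_error(permute_triplet_labels(10, 9, rt = 0.65, triplet_duration = 0.6),
               "too many switches")
})

test_that("monte carlo p-value formula matches the reporting convention", {
  expect_equal(mc_p_value(0, 10000), 1 / 10001)
  expect_lt(mc_p_value(0, 10000), 1e-4)
  expect_equal(round(mc_p_value(52, 10000), 4), 0.0053)
})

test_that("a strongly percept-locked feature gets a small permutation p", {
  tl <- make_timeline(c(15, 30, 45), 60)
  lab <- label_triplets(tl)
  times <- seq(0, 59.995, by = 0.005)
  z <- percept_state(tl, times)
  phi <- z + rnorm(length(z), sd = 0.1)
  pt <- permutation_test_phi_star(phi, lab, times, n_perm = 199, seed = 1)
  expect_equal(pt$p_value, mc_p_value(0, 199))
  expect_equal(pt$n_switches, 3)
})

test_that("permutation p-values are calibrated under the null", {
  tl <- make_timeline(c(15, 30, 45), 60)
  lab <- label_triplets(tl)
  times <- seq(0, 59.995, by = 0.01)
  pvals <- vapply(1:50, function(s) {
    set.seed(1000 + s)
    phi <- rnorm(length(times))
    permutation_test_phi_star(phi, lab, times, n_perm = 199, seed = s)$p_value
  }, numeric(1))
  frac <- mean(pvals < 0.05)
  band <- qbinom(c(0.025, 0.975), 50, 0.05) / 50
  expect_gte(frac, band[1])
  expect_lte(frac, band[2])
})

test_that("KL divergence is zero for identical samples and grows with separation", {
  set.seed(12)
  x <- rnorm(5000)
  labs <- rep(c("one_stream", "two_stream"), each = 5000)
  expect_lt(kl_divergence_percepts(c(x, x), labs), 1e-10)
  far <- kl_divergence_percepts(c(rnorm(5000, -3), rnorm(5000, 3)), labs)
  near <- kl_divergence_percepts(c(rnorm(5000, -0.3), rnorm(5000, 0.3)), labs)
  expect_gt(far, near)
  expect_gte(near, 0)
})

test_that("histogram KL approximates the closed-form Gaussian divergence", {
  set.seed(13)
  n <- 50000
  mu <- 0.5
  x <- c(rnorm(n, -mu), rnorm(n, mu))
  labs <- rep(c("one_stream", "two_stream"), each = n)
  est <- kl_divergence_percepts(x, labs, n_bins = 25)
  analytic <- (2 * mu)^2 / 2 # KL between unit-variance Gaussians
  expect_lt(abs(est - analytic) / analytic, 0.1)
})

test_that("branch reconstructions are additive and empty branches are zero", {
  run <- get_desk_run()
  res <- run$result
  y1 <- branch_reconstruction(res$decomposition, res$branches, "J1", 1)
  y2 <- branch_reconstruction(res$decomposition, res$branches, "J2", 1)
  yu <- branch_reconstruction(res$decomposition, res$branches, "union", 1)
  expect_lt(max(abs(yu - (y1 + y2))), 1e-10)
  empty <- res$branches
  empty$J1 <- integer(0)
  expect_warning(y0 <- branch_reconstruction(res$decomposition, empty, "J1", 1),
                 "empty")
  expect_true(all(y0 == 0))
})

test_that("triplet averages recover periodic profiles with zero SEM", {
  tl <- make_timeline(numeric(0), 30)
  lab <- label_triplets(tl)
  rate <- 200
  times <- seq(0, 29.995, by = 1 / rate)
  series <- sin(2 * pi * times / 0.6)
  prof <- triplet_average(series, times, lab, "one_stream", rate)
  expect_equal(nrow(prof), round(0.6 * rate))
  expect_equal(max(prof$sem), 0, tolerance = 1e-10)
  expect_equal(prof$mean, sin(2 * pi * prof$time_in_triplet / 0.6),
               tolerance = 1e-9)
})

test_that("SEM of white-noise epochs matches sampling theory", {
  tl <- make_timeline(numeric(0), 60)
  lab <- label_triplets(tl)
  rate <- 200
  times <- seq(0, 59.995, by = 1 / rate)
  set.seed(14)
  series <- rnorm(length(times))
  prof <- triplet_average(series, times, lab, "one_stream", rate)
  n_ep <- attr(prof, "n_epochs")
  expect_lt(abs(mean(prof$sem) - 1 / sqrt(n_ep)) / (1 / sqrt(n_ep)), 0.2)
})

test_that("profile similarity and R^2 follow their closed forms", {
  expect_equal(profile_similarity(1:4, (1:4) * 2), 1)
  expect_equal(profile_similarity(1:4, -(1:4)), -1)
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 5)
  brute <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(profile_similarity(a, b), brute, tolerance = 1e-12)
  expect_equal(reconstruction_r2(a, a), 1)
  expect_error(profile_similarity(rep(1, 4), 1:4), "zero-variance")
  expect_error(reconstruction_r2(1:4, rep(2, 4)), "zero-variance")
})

make_fake_prediction <- function(t_stars, classes) {
  structure(
    list(matches = tibble::tibble(button_time = t_stars - 0.1,
                                  t_star = t_stars, class = classes),
         windows = tibble::tibble(), bp = sum(classes == "bp"),
         pb = sum(classes == "pb"), n_miss = 0, n_false_positive = 0,
         threshold = 0.1, rt = 0.65),
    class = "switch_prediction"
  )
}

test_that("motor control test stays null for exchangeable groups", {
  rate <- 200
  times <- seq(0, 120, by = 1 / rate)
  t_stars <- seq(5, 115, by = 5.5)
  classes <- rep(c("bp", "pb"), length.out = length(t_stars))
  dirs <- rep("to_two_stream", length(t_stars))
  rejections <- vapply(1:50, function(s) {
    set.seed(s)
    phi <- rnorm(length(times))
    out <- motor_control_analysis(phi, times, make_fake_prediction(t_stars, classes),
                                  dirs, rate)
    any(out$p_value < 0.05)
  }, logical(1))
  expect_gte(mean(!rejections), 0.8)
})

test_that("motor control is invariant to constant offsets and detects shape shifts", {
  rate <- 200
  times <- seq(0, 120, by = 1 / rate)
  t_stars <- seq(5, 115, by = 5.5)
  classes <- rep(c("bp", "pb"), length.out = length(t_stars))
  dirs <- rep("to_one_stream", length(t_stars))
  set.seed(20)
  phi <- rnorm(length(times))
  base <- motor_control_analysis(phi, times, make_fake_prediction(t_stars, classes),
                                 dirs, rate)
  # constant offset inside pb segments is removed by per-segment z-scoring
  phi_off <- phi
  n_seg <- round(1.2 * rate)
  for (i in which(classes == "pb")) {
    i_star <- findInterval(t_stars[i] - 1e-9, times)
    phi_off[(i_star - n_seg + 1):i_star] <- phi_off[(i_star - n_seg + 1):i_star] + 5
  }
  off <- motor_control_analysis(phi_off, times, make_fake_prediction(t_stars, classes),
                                dirs, rate)
  expect_equal(off$p_value, base$p_value, tolerance = 1e-9)

  # a ramp added to one group changes segment shape and is detected
  phi_ramp <- phi
  for (i in which(classes == "pb")) {
    i_star <- findInterval(t_stars[i] - 1e-9, times)
    idx <- (i_star - n_seg + 1):i_star
    phi_ramp[idx] <- phi_ramp[idx] + seq(0, 6, length.out = n_seg)
  }
  ramp <- motor_control_analysis(phi_ramp, times,
                                 make_fake_prediction(t_stars, classes), dirs, rate)
  expect_lt(min(ramp$p_value), 0.05)
})
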
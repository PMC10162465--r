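test_that("eDMD recovers the spectrum of a diagonal linear system", {
  x <- matrix(0, 60, 2)
  x[1, ] <- c(1, 1)
  for (k in 2:60) x[k, ] <- c(0.9, 0.5) * x[k - 1, ]
  decomp <- run_edmd(x, dt = 0.005)
  lam <- sort(Re(decomp$discrete_eigvals), decreasing = TRUE)
  expect_equal(lam, c(0.9, 0.5), tolerance = 1e-10)
  expect_equal(max(abs(Im(decomp$discrete_eigvals))), 0, tolerance = 1e-10)
  expect_equal(sort(Re(decomp$exp_eigvals), decreasing = TRUE),
               log(c(0.9, 0.5)) / 0.005, tolerance = 1e-8)
})

test_that("a pure rotation yields a unit-circle conjugate pair at its frequency", {
  f <- 1 / 0.6
  dt <- 0.005
  th <- 2 * pi * f * dt
  k <- 0:199
  x <- cbind(cos(k * th), sin(k * th))
  decomp <- run_edmd(x, dt = dt)
  expect_equal(Mod(decomp$discrete_eigvals), c(1, 1), tolerance = 1e-9)
  expect_equal(sort(Im(decomp$exp_eigvals) / (2 * pi)), c(-f, f), tolerance = 1e-8)
  # conjugate pairing of eigenvalues and eigenfunctions
  expect_equal(decomp$discrete_eigvals[1], Conj(decomp$discrete_eigvals[2]),
               tolerance = 1e-9)
  expect_equal(decomp$eigfuns[, 1], Conj(decomp$eigfuns[, 2]), tolerance = 1e-6)
  # unit-RMS normalization with a real non-negative first sample
  expect_equal(sqrt(mean(Mod(decomp$eigfuns[, 1])^2)), 1, tolerance = 1e-9)
  expect_lt(abs(Arg(decomp$eigfuns[1, 1])), 1e-9)
})

test_that("a constant feature contributes an eigenvalue one with constant eigenfunction", {
  x <- matrix(0, 60, 2)
  x[1, ] <- c(1, -2)
  for (k in 2:60) x[k, ] <- c(0.9, 0.5) * x[k - 1, ]
  decomp <- run_edmd(cbind(1, x), dt = 0.005)
  i1 <- which.min(abs(decomp$discrete_eigvals - 1))
  expect_equal(decomp$discrete_eigvals[i1], 1 + 0i, tolerance = 1e-10)
  f1 <- decomp$eigfuns[, i1]
  expect_lt(diff(range(Mod(f1))), 1e-8)
})

test_that("exponential eigenvalues implement log(lambda) / dt", {
  expect_equal(exponential_eigenvalues(1, 0.005), 0 + 0i)
  expect_equal(exponential_eigenvalues(exp(-0.005), 0.005), -1 + 0i,
               tolerance = 1e-12)
  lam <- 0.99 * exp(1i * 2 * pi * 1.67 * 0.005)
  w <- exponential_eigenvalues(lam, 0.005)
  expect_equal(Im(w) / (2 * pi), 1.67, tolerance = 1e-10)
  expect_equal(Re(w), log(0.99) / 0.005, tolerance = 1e-10)
  expect_warning(out <- exponential_eigenvalues(c(0, 1), 0.005), "zero")
  expect_true(is.na(out[1]))
})

test_that("dictionary cutoff separates organized vectors from a noise tail", {
  set.seed(6)
  n <- 2000
  rate <- 200
  t <- (0:(n - 1)) / rate
  organized <- cbind(
    1 / sqrt(n),
    sin(2 * pi * 1.667 * t), cos(2 * pi * 1.667 * t),
    sin(2 * pi * 3.333 * t), cos(2 * pi * 3.333 * t),
    sin(2 * pi * 5 * t)
  )
  noise <- matrix(rnorm(n * 6), n, 6)
  basis <- structure(list(eigvals = seq(1, 0.8, length.out = 12),
                          eigvecs = cbind(organized, noise),
                          epsilon = 1, kmin = 12L, knn = 192L),
                     class = "diffusion_basis")
  sel <- select_dictionary(basis, f_triplet = 1 / 0.6, rate = rate)
  expect_equal(sel$cutoff, 7L)
  expect_equal(ncol(sel$dictionary), 6L)

  all_noise <- structure(list(eigvals = seq(1, 0.8, length.out = 11),
                              eigvecs = cbind(1 / sqrt(n),
                                              matrix(rnorm(n * 10), n, 10)),
                              epsilon = 1, kmin = 12L, knn = 192L),
                         class = "diffusion_basis")
  expect_warning(sel2 <- select_dictionary(all_noise, 1 / 0.6, rate),
                 "constant eigenvector")
  expect_equal(sel2$cutoff, 2L)
})

test_that("modes recover exact coefficients and reconstruct in-span signals", {
  f <- 1 / 0.6
  dt <- 0.005
  th <- 2 * pi * f * dt
  k <- 0:399
  x <- cbind(cos(k * th), sin(k * th))
  decomp <- run_edmd(x, dt = dt, start_index = 1L)
  # a real signal lying exactly in the span of the conjugate pair
  y <- 2 * Re(decomp$eigfuns[, 1])
  rec <- mc_recording(y, rate = 1 / dt)
  decomp <- compute_modes(rec, decomp)
  expect_equal(unname(decomp$modes[1, 1]), 1 + 0i, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(decomp$modes[2, 1], Conj(decomp$modes[1, 1]), tolerance = 1e-8,
               ignore_attr = TRUE)
  recon <- decomp$eigfuns %*% decomp$modes[, 1]
  expect_lt(max(abs(Re(recon) - y)), 1e-8)
  expect_lt(max(abs(Im(recon))), 1e-8)
})

test_that("pipeline-scale decomposition reconstructs the preprocessed signal", {
  run <- get_desk_run()
  decomp <- run$result$decomposition
  pre <- run$result$preprocessed
  rows <- decomp$start_index + seq_len(nrow(decomp$eigfuns)) - 1L
  for (c in 1:2) {
    y <- pre$values[rows, c]
    recon <- Re(decomp$eigfuns %*% decomp$modes[, c])
    expect_gt(reconstruction_r2(as.numeric(recon), y), 0.9)
  }
  # conjugate-symmetry of the full reconstruction
  imag_part <- Im(decomp$eigfuns %*% decomp$modes[, 1])
  expect_lt(max(abs(imag_part)) / sd(pre$values[rows, 1]), 1e-6)
})
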
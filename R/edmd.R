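#' Harmonic concentration of basis vectors and dictionary cutoff
#'
#' Scores each diffusion eigenvector for spectral organization and cuts the
#' dictionary at the first run of `run_length` consecutive unorganized
#' vectors. A vector counts as organized when any of three concentration
#' measures clears `theta_h`-style thresholds: the fraction of spectral power
#' within `tol_f` of an integer multiple of the triplet rate (harmonic
#' concentration, threshold `theta_h`), the fraction below half the triplet
#' rate (slow percept-scale components, threshold `theta_h`), or the fraction
#' held by the top 5 percent of frequency bins (peakedness, threshold
#' `theta_peak`; a flat noise spectrum scores about 0.08). The constant
#' (Perron) eigenvector is always kept: it carries the eigenvalue-one
#' feature.
#'
#' @param basis A [diffusion_eigendecomposition()] result.
#' @param f_triplet Triplet presentation rate in Hz.
#' @param rate Sampling rate of the eigenvector time series in Hz.
#' @param tol_f Half-width (Hz) of the band around each harmonic.
#' @param theta_h Concentration threshold for the harmonic and slow-band
#'   measures.
#' @param theta_peak Threshold for the peakedness measure.
#' @param run_length Number of consecutive unorganized vectors that triggers
#'   the cutoff.
#' @param max_harmonic Highest harmonic multiple considered; defaults to all
#'   harmonics below the Nyquist frequency.
#' @return List with `cutoff` (index of the first excluded vector),
#'   `dictionary` (matrix of retained eigenvectors) and `diagnostics`
#'   (tibble: index, harmonic_power, slow_power, peak_power, total_power,
#'   selected).
#' @export
select_dictionary <- function(basis, f_triplet, rate, tol_f = 0.2,
                              theta_h = 0.3, theta_peak = 0.5,
                              run_length = 3, max_harmonic = NULL) {
  stopifnot(inherits(basis, "diffusion_basis"))
  vecs <- basis$eigvecs
  nvec <- ncol(vecs)
  if (nvec < 10) stop("basis must contain at least 10 vectors", call. = FALSE)
  n <- nrow(vecs)
  if (is.null(max_harmonic)) max_harmonic <- max(1L, floor((rate / 2) / f_triplet))
  freqs <- (seq_len(n) - 1) * rate / n
  pos <- freqs > 0 & freqs <= rate / 2
  near_harmonic <- vapply(freqs[pos], function(f) {
    m <- round(f / f_triplet)
    m >= 1 && m <= max_harmonic && abs(f - m * f_triplet) < tol_f
  }, logical(1))

  slow_band <- freqs[pos] < f_triplet / 2
  n_top <- ceiling(0.05 * sum(pos))
  h <- numeric(nvec)
  slow <- numeric(nvec)
  peak <- numeric(nvec)
  tot <- numeric(nvec)
  for (j in seq_len(nvec)) {
    v <- vecs[, j] - mean(vecs[, j])
    pw <- Mod(fft(v))^2
    pw <- pw[pos]
    tot[j] <- sum(pw)
    if (tot[j] > 0) {
      h[j] <- sum(pw[near_harmonic]) / tot[j]
      slow[j] <- sum(pw[slow_band]) / tot[j]
      peak[j] <- sum(sort(pw, decreasing = TRUE)[seq_len(n_top)]) / tot[j]
    }
  }
  h[1] <- 1 # constant vector: kept by construction

  below <- h < theta_h & slow < theta_h & peak < theta_peak
  cutoff <- nvec + 1L
  run <- rle(below)
  ends <- cumsum(run$lengths)
  starts <- ends - run$lengths + 1L
  hit <- which(run$values & run$lengths >= run_length)
  if (length(hit)) {
    cutoff <- starts[hit[1]]
  } else {
    warning("no run of unorganized vectors found; keeping the whole basis")
  }
  if (cutoff <= 2L) {
    warning("dictionary reduced to the constant eigenvector only")
    cutoff <- 2L
  }
  diag_tbl <- tibble::tibble(
    index = seq_len(nvec), harmonic_power = h, slow_power = slow,
    peak_power = peak, total_power = tot,
    selected = seq_len(nvec) < cutoff
  )
  list(cutoff = cutoff,
       dictionary = vecs[, seq_len(cutoff - 1L), drop = FALSE],
       diagnostics = diag_tbl)
}

#' Extended dynamic mode decomposition
#'
#' Fits the least-squares one-step operator `K` over dictionary features
#' evaluated on consecutive time samples (`Psi1 ~ Psi0 K`, solved through the
#' singular value decomposition pseudoinverse of `Psi0`), and
#' eigendecomposes it. Koopman eigenfunction time series are the dictionary
#' rows projected on the eigenvectors of `K`; each is normalized to unit RMS
#' with its phase rotated so the first sample is real and non-negative
#' (conjugate pairs stay conjugate). Eigenvalues are ordered by decreasing
#' real part of `log(lambda) / dt`, positive frequencies first within ties.
#'
#' @param dictionary Numeric matrix of dictionary features, one row per
#'   consecutive time sample (e.g. the `dictionary` from
#'   [select_dictionary()]).
#' @param dt Sampling interval in seconds.
#' @param times Optional vector of sample times (carried into the result).
#' @param start_index Optional index of the first dictionary row in the
#'   preprocessed recording (carried into the result; needed by
#'   [compute_modes()]).
#' @param sv_tol Relative singular-value cutoff for the pseudoinverse.
#' @return An object of class `koopman_decomposition` with
#'   `discrete_eigvals`, `exp_eigvals`, `eigfuns` (complex matrix, one column
#'   per eigenfunction), `eigvecs`, `modes` (`NULL` until
#'   [compute_modes()]), `dt`, `dictionary_size`, `effective_rank`,
#'   `times` and `start_index`.
#' @export
run_edmd <- function(dictionary, dt, times = NULL, start_index = NULL,
                     sv_tol = 1e-10) {
  psi <- as.matrix(dictionary)
  nt <- nrow(psi)
  nd <- ncol(psi)
  if (nt < nd + 1) stop("need more time samples than dictionary functions", call. = FALSE)
  psi0 <- psi[-nt, , drop = FALSE]
  psi1 <- psi[-1, , drop = FALSE]
  sv <- svd(psi0)
  keep <- sv$d > sv_tol * sv$d[1]
  eff_rank <- sum(keep)
  if (eff_rank < nd) {
    message(sprintf("rank-deficient dictionary: effective rank %d of %d",
                    eff_rank, nd))
  }
  dinv <- ifelse(keep, 1 / sv$d, 0)
  K <- sv$v %*% (dinv * (t(sv$u) %*% psi1))

  ee <- eigen(K)
  lambda <- as.complex(ee$values)
  xi <- ee$vectors
  if (!is.complex(xi)) xi <- matrix(as.complex(xi), nrow(xi), ncol(xi))
  nz <- Mod(lambda) > 1e-12
  if (!all(nz)) {
    warning(sprintf("excluded %d zero Koopman eigenvalue(s)", sum(!nz)))
    lambda <- lambda[nz]
    xi <- xi[, nz, drop = FALSE]
  }
  omega <- log(lambda) / dt
  ord <- order(-Re(omega), -Im(omega))
  lambda <- lambda[ord]
  omega <- omega[ord]
  xi <- xi[, ord, drop = FALSE]

  eigfuns <- psi %*% xi
  for (j in seq_len(ncol(eigfuns))) {
    f <- eigfuns[, j]
    rms <- sqrt(mean(Mod(f)^2))
    if (rms == 0) next
    f <- f / rms
    a <- if (Mod(f[1]) > 1e-12) Arg(f[1]) else 0
    f <- f * exp(-1i * a)
    eigfuns[, j] <- f
    xi[, j] <- xi[, j] * exp(-1i * a) / rms
  }

  structure(
    list(
      discrete_eigvals = lambda, exp_eigvals = omega,
      eigfuns = eigfuns, eigvecs = xi, modes = NULL,
      dt = dt, dictionary_size = nd, effective_rank = eff_rank,
      times = times, start_index = start_index
    ),
    class = "koopman_decomposition"
  )
}

#' Continuous-time (exponential) Koopman eigenvalues
#'
#' Transforms discrete one-step eigenvalues into continuous-time eigenvalues
#' `omega = log(lambda) / dt`; the real part is the decay rate in 1/s and the
#' imaginary part divided by `2 * pi` is the frequency in Hz.
#'
#' @param lambda Complex vector of discrete eigenvalues.
#' @param dt Sampling interval in seconds.
#' @return Complex vector of exponential eigenvalues (`NA` where
#'   `lambda == 0`, with a warning).
#' @export
exponential_eigenvalues <- function(lambda, dt) {
  lambda <- as.complex(lambda)
  zero <- Mod(lambda) == 0
  if (any(zero)) warning("zero eigenvalue(s) have no continuous-time equivalent")
  out <- log(lambda) / dt
  out[zero] <- NA_complex_
  out
}

#' @export
print.koopman_decomposition <- function(x, ...) {
  cat(sprintf(
    "<koopman_decomposition> %d eigenpairs from a %d-function dictionary (dt = %g s)%s\n",
    length(x$discrete_eigvals), x$dictionary_size, x$dt,
    if (is.null(x$modes)) "" else "; modes computed"
  ))
  invisible(x)
}

#' @export
tidy.koopman_decomposition <- function(x, ...) {
  tibble::tibble(
    index = seq_along(x$exp_eigvals),
    lambda = x$discrete_eigvals,
    decay_rate = Re(x$exp_eigvals),
    frequency_hz = Im(x$exp_eigvals) / (2 * pi)
  )
}

#' @export
glance.koopman_decomposition <- function(x, ...) {
  tibble::tibble(
    n_eigenvalues = length(x$discrete_eigvals),
    dictionary_size = x$dictionary_size,
    effective_rank = x$effective_rank,
    dt = x$dt,
    has_modes = !is.null(x$modes)
  )
}

#' Spatial Koopman modes by least squares
#'
#' Regresses each preprocessed channel on the span of the Koopman
#' eigenfunctions, giving the time-independent coefficients of the spectral
#' reconstruction `y_c(t) ~ sum_j v_j(c) phi_j(t)`. Real signals give
#' conjugate modes for conjugate eigenfunction pairs. An ill-conditioned
#' normal system falls back to a small ridge penalty (with a message).
#'
#' @param rec An [mc_recording()] aligned with the decomposition (the
#'   preprocessed recording the delay matrix was built from).
#' @param decomp A [run_edmd()] result carrying `start_index`.
#' @param ridge Ridge penalty used only in the fallback.
#' @return The decomposition with `modes` filled in (complex matrix,
#'   one row per eigenfunction, one column per channel).
#' @export
compute_modes <- function(rec, decomp, ridge = 1e-8) {
  stopifnot(inherits(rec, "mc_recording"), inherits(decomp, "koopman_decomposition"))
  if (is.null(decomp$start_index)) {
    stop("decomposition has no `start_index`; pass it to run_edmd()", call. = FALSE)
  }
  nt <- nrow(decomp$eigfuns)
  rows <- decomp$start_index + seq_len(nt) - 1L
  if (max(rows) > nrow(rec$values)) {
    stop("recording shorter than the eigenfunction time series", call. = FALSE)
  }
  Y <- rec$values[rows, , drop = FALSE]
  phi <- decomp$eigfuns
  H <- Conj(t(phi)) %*% phi
  b <- Conj(t(phi)) %*% Y
  v <- tryCatch({
    rc <- rcond(H)
    if (!is.finite(rc) || rc < 1e-12) stop("ill-conditioned")
    solve(H, b)
  }, error = function(e) {
    message(sprintf("ill-conditioned eigenfunction Gram matrix; ridge %.1e applied",
                    ridge))
    solve(H + ridge * mean(Mod(diag(H))) * diag(nrow(H)), b)
  })
  colnames(v) <- colnames(rec$values)
  decomp$modes <- v
  decomp
}
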
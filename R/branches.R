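#' Tag eigenvalues with triplet-rate harmonics
#'
#' An eigenvalue whose frequency magnitude `|Im(omega)| / 2pi` lies within
#' `tol_f` of `m * f_triplet` for some integer `m >= 1` is tagged with that
#' harmonic; conjugate partners share the tag.
#'
#' @param decomp A [run_edmd()] result.
#' @param f_triplet Triplet presentation rate in Hz.
#' @param tol_f Matching tolerance in Hz.
#' @return Integer vector, one entry per eigenvalue: harmonic multiple `m` or
#'   `NA` when untagged.
#' @export
match_harmonics <- function(decomp, f_triplet, tol_f = 0.2) {
  stopifnot(inherits(decomp, "koopman_decomposition"))
  freq <- abs(Im(decomp$exp_eigvals)) / (2 * pi)
  m <- round(freq / f_triplet)
  ok <- m >= 1 & abs(freq - m * f_triplet) < tol_f
  ifelse(ok, as.integer(m), NA_integer_)
}

# index of the conjugate partner of eigenvalue j (nearest conj(omega_j))
.conj_partner <- function(omega, j) {
  target <- Conj(omega[j])
  d <- Mod(omega - target)
  d[j] <- Inf
  which.min(d)
}

#' Assign eigenvalues to the stimulus and perception branches
#'
#' Per harmonic, the conjugate pair whose decay rate is closest to zero
#' (slowest decay) goes to branch `J1` (stimulus encoding); the next pair, if
#' present, to `J2` (perception encoding). A near-zero real eigenvalue (the
#' constant eigenfunction) joins `J1`; real decaying eigenvalues (candidates
#' for the slow percept feature) join `J2`. With more than two pairs at one
#' harmonic the two slowest-decaying are kept and the rest reported in the
#' table.
#'
#' @param decomp A [run_edmd()] result.
#' @param harmonic_of Output of [match_harmonics()].
#' @param f_triplet Triplet presentation rate in Hz.
#' @param tol_real Frequency tolerance (Hz) under which an eigenvalue counts
#'   as effectively real. The default, a tenth of the fundamental, admits
#'   slow percept-alternation modes that finite stochastic records estimate
#'   as near-real conjugate pairs, while staying an order of magnitude below
#'   the harmonic grid.
#' @param tol_zero Magnitude (1/s) under which a real eigenvalue counts as
#'   the near-zero constant one.
#' @return An object of class `branch_assignment`: list with index sets `J1`
#'   and `J2`, `harmonic_of`, `phi_star_index` (`NA` until
#'   [find_phi_star()]), `omega_star`, `f_triplet` and a `table` tibble of
#'   per-eigenvalue assignments.
#' @export
assign_branches <- function(decomp, harmonic_of, f_triplet,
                            tol_real = f_triplet / 10, tol_zero = 0.01) {
  stopifnot(inherits(decomp, "koopman_decomposition"))
  omega <- decomp$exp_eigvals
  n <- length(omega)
  branch <- rep(NA_character_, n)
  freq <- Im(omega) / (2 * pi)

  for (m in sort(unique(harmonic_of[!is.na(harmonic_of)]))) {
    pos <- which(harmonic_of == m & freq > 0)
    pos <- pos[order(abs(Re(omega[pos])))] # decay rate smallest in magnitude first
    if (length(pos) >= 1) {
      j <- pos[1]
      branch[c(j, .conj_partner(omega, j))] <- "J1"
    }
    if (length(pos) >= 2) {
      j <- pos[2]
      branch[c(j, .conj_partner(omega, j))] <- "J2"
    }
    if (length(pos) > 2) {
      message(sprintf("harmonic %d: %d extra pair(s) left unassigned", m,
                      length(pos) - 2))
    }
  }

  is_real <- abs(freq) < tol_real
  near_zero <- is_real & Mod(omega) < tol_zero
  branch[near_zero & is.na(branch)] <- "J1"
  branch[is_real & !near_zero & is.na(branch)] <- "J2"

  J1 <- which(branch == "J1")
  J2 <- which(branch == "J2")
  tbl <- tibble::tibble(
    index = seq_len(n),
    decay_rate = Re(omega),
    frequency_hz = freq,
    harmonic = harmonic_of,
    branch = branch
  )
  structure(
    list(J1 = J1, J2 = J2, harmonic_of = harmonic_of,
         phi_star_index = NA_integer_, omega_star = NA_real_,
         f_triplet = f_triplet, tol_real = tol_real, tol_zero = tol_zero,
         table = tbl),
    class = "branch_assignment"
  )
}

#' @export
print.branch_assignment <- function(x, ...) {
  cat(sprintf("<branch_assignment> |J1| = %d, |J2| = %d%s\n",
              length(x$J1), length(x$J2),
              if (is.na(x$phi_star_index)) "" else
                sprintf(", phi* at index %d (omega* = %.4g 1/s)",
                        x$phi_star_index, x$omega_star)))
  invisible(x)
}

#' @export
tidy.branch_assignment <- function(x, ...) x$table

#' Locate the slow percept-tracking eigenfunction
#'
#' Among effectively real, decaying eigenvalues (frequency magnitude below
#' `tol_real`, negative decay rate), excluding the near-zero one whose
#' eigenfunction is constant, selects the one with the largest real part
#' (slowest decay). Its eigenfunction's real part is the slow feature `phi*`.
#' A slow percept process estimated from a finite record may present as a
#' near-real conjugate pair rather than a single real eigenvalue; in that
#' case the positive-frequency member is used (with a message) and both pair
#' members join branch `J2`. When several candidates exist the slowest-decay
#' rule applies.
#'
#' @param decomp A [run_edmd()] result.
#' @param branches An [assign_branches()] result.
#' @return `branches` with `phi_star_index`, `omega_star` and
#'   `phi_star_is_pair` filled in, plus `phi_star`: the real slow-feature
#'   time series.
#' @export
find_phi_star <- function(decomp, branches) {
  stopifnot(inherits(decomp, "koopman_decomposition"),
            inherits(branches, "branch_assignment"))
  omega <- decomp$exp_eigvals
  freq <- Im(omega) / (2 * pi)
  cand <- which(abs(freq) < branches$tol_real &
                  Mod(omega) >= branches$tol_zero &
                  Re(omega) < 0 &
                  freq >= 0) # positive-frequency member of any pair
  if (!length(cand)) {
    stop("no slow decaying eigenvalue found: phi* is not identifiable",
         call. = FALSE)
  }
  j <- cand[which.max(Re(omega[cand]))]
  if (length(cand) > 1) {
    message(sprintf("%d slow decaying eigenvalue(s); slowest decay chosen (index %d)",
                    length(cand), j))
  }
  is_pair <- freq[j] > 0
  if (is_pair) {
    message(sprintf(
      "slow feature is a near-real conjugate pair at %.3f Hz; real part taken",
      freq[j]))
  }
  phi <- decomp$eigfuns[, j]
  branches$phi_star_index <- j
  branches$omega_star <- Re(omega[j])
  branches$phi_star_is_pair <- is_pair
  branches$phi_star <- Re(phi)
  add <- j
  if (is_pair) add <- c(j, .conj_partner(omega, j))
  for (k in add) {
    if (!(k %in% branches$J2)) {
      branches$J2 <- sort(c(branches$J2, k))
      branches$table$branch[k] <- "J2"
    }
  }
  branches
}

#' Orient the slow feature against the reported percepts
#'
#' `phi*` and `-phi*` are both eigenfunctions of the same real eigenvalue.
#' For display and downstream statistics the sign is fixed, post hoc, so the
#' median over two-stream samples exceeds the median over one-stream samples.
#' This is the only behaviour-aware step of feature extraction; everything
#' upstream never reads the percept labels.
#'
#' @param phi_star Numeric vector: the slow feature time series.
#' @param sample_labels Character vector of the same length with values
#'   `"one_stream"`, `"two_stream"` or `"neutral"` (see
#'   [triplet_labels_at()]), or `NULL` when behaviour is unavailable.
#' @return `phi_star`, possibly negated, with attribute `oriented` set to
#'   `TRUE` when labels were available and `FALSE` otherwise.
#' @export
orient_phi_star <- function(phi_star, sample_labels = NULL) {
  if (is.null(sample_labels)) {
    attr(phi_star, "oriented") <- FALSE
    return(phi_star)
  }
  stopifnot(length(sample_labels) == length(phi_star))
  med2 <- median(phi_star[sample_labels == "two_stream"])
  med1 <- median(phi_star[sample_labels == "one_stream"])
  if (is.na(med1) || is.na(med2)) {
    warning("both percepts must be present to orient phi*; left unsigned")
    attr(phi_star, "oriented") <- FALSE
    return(phi_star)
  }
  if (med2 < med1) phi_star <- -phi_star
  attr(phi_star, "oriented") <- TRUE
  phi_star
}
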
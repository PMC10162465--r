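#' Label triplets by percept, with a reaction-time-neutral zone
#'
#' Each triplet takes the percept in force at its onset. Because the subject
#' reports a switch only after their reaction time, the `ceiling(rt /
#' triplet_duration)` triplets whose onsets immediately precede each button
#' press are relabelled `"neutral"`: the percept during them is ambiguous.
#' An RT of 0.65 s with 0.6 s triplets gives 2 neutral triplets per press; an
#' RT of 3.22 s gives 6.
#'
#' @param timeline A [simulate_percept_timeline()] result (or any
#'   `percept_timeline`).
#' @param rt Reaction time in seconds; defaults to the timeline's.
#' @param triplet_duration Triplet length in seconds; defaults to the
#'   timeline's.
#' @return A tibble of class `triplet_labels` with columns `triplet` (1-based
#'   index), `onset_s` and `label`; attributes `triplet_duration`, `rt`,
#'   `n_neutral` and `block_duration`.
#' @export
label_triplets <- function(timeline, rt = timeline$reaction_time,
                           triplet_duration = timeline$triplet_duration) {
  stopifnot(inherits(timeline, "percept_timeline"))
  td <- triplet_duration
  n_tr <- floor(timeline$block_duration / td + 1e-9)
  onset <- (seq_len(n_tr) - 1) * td
  epoch <- findInterval(onset, c(0, timeline$switch_times))
  label <- timeline$percepts[pmax(epoch, 1L)]
  presses <- timeline$button_times
  if (length(presses) && (any(presses < 0) || any(presses > timeline$block_duration))) {
    stop("button press outside the stimulus block", call. = FALSE)
  }
  n_neutral <- ceiling(rt / td)
  for (bt in presses) {
    before <- which(onset < bt)
    idx <- tail(before, n_neutral)
    label[idx] <- "neutral"
  }
  out <- tibble::tibble(triplet = seq_len(n_tr), onset_s = onset, label = label)
  class(out) <- c("triplet_labels", class(out))
  attr(out, "triplet_duration") <- td
  attr(out, "rt") <- rt
  attr(out, "n_neutral") <- n_neutral
  attr(out, "block_duration") <- timeline$block_duration
  out
}

#' Per-sample percept labels
#'
#' Expands triplet labels to arbitrary sample times.
#'
#' @param labels A [label_triplets()] result.
#' @param times Sample times in seconds.
#' @return Character vector of labels, one per time.
#' @export
triplet_labels_at <- function(labels, times) {
  td <- attr(labels, "triplet_duration")
  idx <- pmin(pmax(floor(times / td + 1e-9) + 1L, 1L), nrow(labels))
  labels$label[idx]
}

# triplet index (1-based) of each sample time
.triplet_index <- function(times, td, n_tr) {
  pmin(pmax(floor(times / td + 1e-9) + 1L, 1L), n_tr)
}

#' Constrained permutation of triplet labels
#'
#' Draws a random alternating labelling of the triplets with exactly
#' `n_switches` switches. Switch positions are drawn uniformly over triplet
#' boundaries by rejection until every percept run (including the first and
#' last) spans strictly more than the reaction time and survives the
#' RT-neutral relabelling; the first percept is a fair coin; the RT-neutral
#' zone is re-applied to the triplets following each switch, mirroring the
#' labelling of reported presses (which trail the switch by the reaction
#' time).
#'
#' @param n_triplets Number of triplets.
#' @param n_switches Number of switches to place.
#' @param rt Reaction time in seconds.
#' @param triplet_duration Triplet length in seconds.
#' @param max_tries Rejection-sampling budget.
#' @return Character vector of `n_triplets` labels.
#' @keywords internal
permute_triplet_labels <- function(n_triplets, n_switches, rt,
                                   triplet_duration, max_tries = 2000) {
  n_neutral <- ceiling(rt / triplet_duration)
  # runs must exceed RT and keep at least one visible triplet after the
  # neutral zone is re-applied, so the drawn switch count is always preserved
  run_min <- max(floor(rt / triplet_duration) + 1L, n_neutral + 1L)
  if ((n_switches + 1L) * run_min > n_triplets) {
    stop("too many switches to place under the reaction-time constraint",
         call. = FALSE)
  }
  if (n_switches == 0) {
    first <- if (runif(1) < 0.5) "one_stream" else "two_stream"
    return(rep(first, n_triplets))
  }
  for (try in seq_len(max_tries)) {
    pos <- sort(sample.int(n_triplets - 1L, n_switches))
    gaps <- diff(c(0L, pos, n_triplets))
    if (all(gaps >= run_min)) {
      first <- if (runif(1) < 0.5) "one_stream" else "two_stream"
      seq_lab <- rep(c("one_stream", "two_stream"), length.out = n_switches + 1L)
      if (first == "two_stream") {
        seq_lab <- rep(c("two_stream", "one_stream"), length.out = n_switches + 1L)
      }
      lab <- rep(seq_lab, times = gaps)
      for (s in pos) {
        idx <- seq.int(s + 1L, min(n_triplets, s + n_neutral))
        lab[idx] <- "neutral"
      }
      return(lab)
    }
  }
  stop("could not place switches under the run-length constraint", call. = FALSE)
}

#' Monte Carlo p-value estimate
#'
#' `p = (m + 1) / (n + 1)` for `m` permutations at least as extreme as the
#' observation out of `n`; never exactly zero, so 10,000 permutations bound
#' the smallest reportable value at just under 1e-4.
#'
#' @param m Number of permutations with statistic at least as extreme as
#'   observed.
#' @param n Number of permutations.
#' @return The p-value estimate.
#' @export
mc_p_value <- function(m, n) {
  stopifnot(m >= 0, n >= 1, m <= n)
  (m + 1) / (n + 1)
}

#' Permutation test for the percept dependence of the slow feature
#'
#' Tests whether the mean of the slow feature differs between one-stream and
#' two-stream percepts against a null in which the triplet labels are
#' re-drawn with the observed number of switches, the subject's reaction-time
#' constraint on percept durations, and the RT-neutral zones re-applied
#' (see [permute_triplet_labels()]). The Monte Carlo p-value is
#' `(m + 1) / (n + 1)` where `m` counts permutations with
#' `|mu_perm| >= |mu_obs|`.
#'
#' @param phi_star Numeric slow-feature series.
#' @param labels A [label_triplets()] result.
#' @param times Sample times (seconds) aligned with `phi_star`.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List of class `perm_test`: `p_value`, `mu_obs`, `null`
#'   (permutation differences), `n_perm`, `n_switches`.
#' @export
permutation_test_phi_star <- function(phi_star, labels, times,
                                      n_perm = 10000, seed = 1L) {
  stopifnot(inherits(labels, "triplet_labels"),
            length(phi_star) == length(times))
  td <- attr(labels, "triplet_duration")
  rt <- attr(labels, "rt")
  n_tr <- nrow(labels)
  tri <- .triplet_index(times, td, n_tr)
  sums <- as.numeric(rowsum(phi_star, tri, reorder = TRUE))
  cnts <- as.numeric(table(factor(tri, levels = sort(unique(tri)))))
  tri_ids <- sort(unique(tri))
  # per-triplet sums aligned to the full 1..n_tr grid (zeros where no samples)
  full_sum <- numeric(n_tr)
  full_cnt <- numeric(n_tr)
  full_sum[tri_ids] <- sums
  full_cnt[tri_ids] <- cnts

  mean_diff <- function(lab) {
    two <- lab == "two_stream"
    one <- lab == "one_stream"
    n2 <- sum(full_cnt[two])
    n1 <- sum(full_cnt[one])
    if (n2 == 0 || n1 == 0) return(NA_real_)
    sum(full_sum[two]) / n2 - sum(full_sum[one]) / n1
  }
  mu_obs <- mean_diff(labels$label)
  if (is.na(mu_obs)) stop("both percepts must be present in the labels", call. = FALSE)

  runs <- rle(labels$label[labels$label != "neutral"])
  n_switches <- sum(diff(as.integer(factor(runs$values))) != 0)

  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) {
    lab <- permute_triplet_labels(n_tr, n_switches, rt, td)
    mean_diff(lab)
  }, numeric(1))
  null_ok <- null[!is.na(null)]
  m <- sum(abs(null_ok) >= abs(mu_obs))
  structure(
    list(p_value = mc_p_value(m, length(null_ok)), mu_obs = mu_obs,
         null = null_ok, n_perm = length(null_ok), n_switches = n_switches),
    class = "perm_test"
  )
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf(
    "<perm_test> mu_obs = %.4g, p = %.4g (%d permutations, %d switches)\n",
    x$mu_obs, x$p_value, x$n_perm, x$n_switches
  ))
  invisible(x)
}

#' @export
glance.perm_test <- function(x, ...) {
  tibble::tibble(mu_obs = x$mu_obs, p_value = x$p_value,
                 n_perm = x$n_perm, n_switches = x$n_switches)
}

#' Kullback-Leibler divergence between percept-split distributions
#'
#' Histograms the slow feature separately for the two percepts on shared
#' equal-width bins over the pooled range, applies additive smoothing, and
#' returns the divergence. The default direction is KL(two-stream ||
#' one-stream); the absolute value depends on the bin count and smoothing,
#' so compare divergences only across like-configured calls.
#'
#' @param phi_star Numeric feature series.
#' @param sample_labels Per-sample labels (see [triplet_labels_at()]).
#' @param n_bins Number of shared histogram bins.
#' @param smooth Additive smoothing mass per bin.
#' @param direction `"two_vs_one"`, `"one_vs_two"` or `"symmetric"`.
#' @return Non-negative scalar divergence (natural log).
#' @export
kl_divergence_percepts <- function(phi_star, sample_labels, n_bins = 25,
                                   smooth = 1e-10,
                                   direction = c("two_vs_one", "one_vs_two",
                                                 "symmetric")) {
  direction <- match.arg(direction)
  x1 <- phi_star[sample_labels == "one_stream"]
  x2 <- phi_star[sample_labels == "two_stream"]
  if (length(x1) < n_bins || length(x2) < n_bins) {
    stop("each percept needs at least `n_bins` samples", call. = FALSE)
  }
  rng <- range(c(x1, x2))
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  p_of <- function(x) {
    cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE,
                                 all.inside = TRUE), nbins = n_bins)
    p <- cnt / sum(cnt) + smooth
    p / sum(p)
  }
  p1 <- p_of(x1)
  p2 <- p_of(x2)
  kl <- function(p, q) sum(p * log(p / q))
  switch(direction,
    two_vs_one = kl(p2, p1),
    one_vs_two = kl(p1, p2),
    symmetric = (kl(p2, p1) + kl(p1, p2)) / 2
  )
}

#' Branch-restricted signal reconstruction
#'
#' Real part of the spectral reconstruction restricted to one branch:
#' `Y_b(c) = Re sum_{j in b} v_j(c) phi_j`. The `J1` and `J2`
#' reconstructions add up exactly to the `union` reconstruction.
#'
#' @param decomp A [compute_modes()] result (modes required).
#' @param branches An [assign_branches()] result.
#' @param branch `"J1"`, `"J2"` or `"union"`.
#' @param channel Channel index or name.
#' @return Numeric reconstruction series over the embedded samples.
#' @export
branch_reconstruction <- function(decomp, branches,
                                  branch = c("J1", "J2", "union"), channel = 1) {
  branch <- match.arg(branch)
  stopifnot(inherits(decomp, "koopman_decomposition"),
            inherits(branches, "branch_assignment"))
  if (is.null(decomp$modes)) stop("modes not computed; run compute_modes()", call. = FALSE)
  idx <- switch(branch, J1 = branches$J1, J2 = branches$J2,
                union = sort(c(branches$J1, branches$J2)))
  if (!length(idx)) {
    warning(sprintf("branch %s is empty; returning a zero series", branch))
    return(numeric(nrow(decomp$eigfuns)))
  }
  as.numeric(Re(decomp$eigfuns[, idx, drop = FALSE] %*%
                  decomp$modes[idx, channel, drop = FALSE]))
}

#' Triplet-locked average profile with SEM band
#'
#' Averages a series over all complete triplet epochs carrying one percept
#' label, returning the mean profile (one triplet long) and its standard
#' error across epochs.
#'
#' @param series Numeric series.
#' @param times Sample times (seconds) aligned with `series`.
#' @param labels A [label_triplets()] result.
#' @param percept `"one_stream"` or `"two_stream"`.
#' @param rate Sampling rate in Hz.
#' @return Tibble with `time_in_triplet`, `mean`, `sem`; attribute
#'   `n_epochs`.
#' @export
triplet_average <- function(series, times, labels, percept, rate) {
  stopifnot(length(series) == length(times))
  td <- attr(labels, "triplet_duration")
  n_per <- round(td * rate)
  tri <- .triplet_index(times, td, nrow(labels))
  pos <- round((times - (tri - 1) * td) * rate) + 1L
  keep_tri <- labels$triplet[labels$label == percept]
  epochs <- list()
  for (i in keep_tri) {
    sel <- which(tri == i)
    if (length(sel) == n_per && all(sort(pos[sel]) == seq_len(n_per))) {
      epochs[[length(epochs) + 1]] <- series[sel][order(pos[sel])]
    }
  }
  if (length(epochs) < 2) {
    stop(sprintf("fewer than 2 complete '%s' epochs", percept), call. = FALSE)
  }
  mat <- do.call(rbind, epochs)
  out <- tibble::tibble(
    time_in_triplet = (seq_len(n_per) - 1) / rate,
    mean = colMeans(mat),
    sem = apply(mat, 2, sd) / sqrt(nrow(mat))
  )
  attr(out, "n_epochs") <- nrow(mat)
  out
}

#' Profile similarity and reconstruction accuracy
#'
#' `profile_similarity()` is the Pearson correlation between two equal-length
#' profiles. `reconstruction_r2()` is the coefficient of determination of a
#' reconstructed profile against a reference profile (1 minus the residual
#' sum of squares over the total sum of squares about the reference mean).
#'
#' @param profile_a,profile_b,recon_profile,ref_profile Equal-length numeric
#'   vectors.
#' @return Scalar `r` or `R^2`.
#' @export
profile_similarity <- function(profile_a, profile_b) {
  stopifnot(length(profile_a) == length(profile_b))
  if (sd(profile_a) == 0 || sd(profile_b) == 0) {
    stop("zero-variance profile: correlation undefined", call. = FALSE)
  }
  cor(profile_a, profile_b)
}

#' @rdname profile_similarity
#' @export
reconstruction_r2 <- function(recon_profile, ref_profile) {
  stopifnot(length(recon_profile) == length(ref_profile))
  ss_tot <- sum((ref_profile - mean(ref_profile))^2)
  if (ss_tot == 0) stop("zero-variance reference profile: R^2 undefined", call. = FALSE)
  1 - sum((recon_profile - ref_profile)^2) / ss_tot
}

#' Motor-response control analysis
#'
#' Tests whether the slow feature's course just before a predicted switch
#' differs between events where the button press preceded the marked phase
#' change (`bp`) and events where it followed (`pb`) -- which would suggest a
#' motor artifact. The `seg_s` seconds of the slow feature preceding each
#' marked time are extracted, z-scored per segment, grouped by transition
#' direction, projected on their first two principal components, and the
#' `bp` / `pb` score distributions compared with a two-sample Wilcoxon rank
#' test per component.
#'
#' @param phi_star Numeric slow-feature series.
#' @param times Sample times aligned with `phi_star`.
#' @param prediction An [align_predictions()] result.
#' @param directions Character vector aligned with `prediction$matches` rows:
#'   transition direction of each press (e.g. `"to_two_stream"`).
#' @param rate Sampling rate in Hz.
#' @param seg_s Segment length in seconds before each marked time.
#' @return Tibble with one row per direction and principal component:
#'   `direction`, `component`, `statistic`, `p_value`, `n_bp`, `n_pb`.
#'   Directions with fewer than two events per group are skipped with a
#'   warning.
#' @export
motor_control_analysis <- function(phi_star, times, prediction, directions,
                                   rate, seg_s = 1.2) {
  stopifnot(inherits(prediction, "switch_prediction"),
            length(directions) == nrow(prediction$matches))
  n_seg <- round(seg_s * rate)
  m <- prediction$matches
  rows <- list()
  for (i in seq_len(nrow(m))) {
    if (!(m$class[i] %in% c("bp", "pb"))) next
    i_star <- findInterval(m$t_star[i] - 1e-9, times)
    sel <- seq.int(i_star - n_seg + 1L, i_star)
    if (sel[1] < 1 || i_star < 1) {
      message("event skipped: insufficient signal history before the marked time")
      next
    }
    seg <- phi_star[sel]
    s <- sd(seg)
    seg <- if (s > 0) (seg - mean(seg)) / s else seg - mean(seg)
    rows[[length(rows) + 1]] <- list(direction = directions[i],
                                     class = m$class[i], seg = seg)
  }
  out <- list()
  for (d in unique(vapply(rows, `[[`, "", "direction"))) {
    sub <- rows[vapply(rows, function(r) r$direction == d, logical(1))]
    cls <- vapply(sub, `[[`, "", "class")
    if (sum(cls == "bp") < 2 || sum(cls == "pb") < 2) {
      warning(sprintf("direction %s: fewer than 2 events per group; skipped", d))
      next
    }
    X <- do.call(rbind, lapply(sub, `[[`, "seg"))
    pc <- prcomp(X, center = TRUE, scale. = FALSE)
    for (comp in 1:2) {
      sc <- pc$x[, comp]
      ht <- wilcox.test(sc[cls == "pb"], sc[cls == "bp"], exact = FALSE)
      out[[length(out) + 1]] <- tibble::tibble(
        direction = d, component = comp,
        statistic = unname(ht$statistic), p_value = unname(ht$p.value),
        n_bp = sum(cls == "bp"), n_pb = sum(cls == "pb")
      )
    }
  }
  if (!length(out)) {
    return(tibble::tibble(direction = character(), component = integer(),
                          statistic = numeric(), p_value = numeric(),
                          n_bp = integer(), n_pb = integer()))
  }
  dplyr::bind_rows(out)
}
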
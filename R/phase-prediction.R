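#' Instantaneous phase of an eigenfunction relative to a reference frequency
#'
#' For a complex eigenfunction with four-quadrant angle `theta(t)`, the
#' instantaneous phase relative to frequency `f` is the wrapped angle of
#' `exp(i * (2 pi f t - theta(t)))`, in `(-pi, pi]`. A perfect oscillator at
#' `f` has identically zero phase. Samples where the eigenfunction magnitude
#' vanishes are masked as `NA`.
#'
#' @param phi Complex (or numeric) eigenfunction time series.
#' @param f Reference frequency in Hz.
#' @param times Sample times in seconds.
#' @return Numeric vector of phases in radians.
#' @export
instantaneous_phase <- function(phi, f, times) {
  stopifnot(length(phi) == length(times), f > 0)
  theta <- Arg(phi)
  raw <- 2 * pi * f * times - theta
  out <- atan2(sin(raw), cos(raw))
  out[Mod(phi) < 1e-12] <- NA_real_
  out
}

#' Trailing-window circular mean of a phase series
#'
#' The circular mean over the trailing window `[t - window_s, t]` is the
#' angle of the mean resultant vector of the windowed phases. Samples whose
#' trailing window extends before the start of the series are masked;
#' windows with zero resultant length are masked with a warning.
#'
#' @param phase Numeric vector of phases in radians (`NA` allowed).
#' @param window_s Window length in seconds (one or two triplets in the
#'   switch predictor).
#' @param rate Sampling rate in Hz.
#' @return Numeric vector of averaged phases.
#' @export
windowed_circular_mean <- function(phase, window_s, rate) {
  n <- length(phase)
  w <- round(window_s * rate)
  if (w < 1) stop("window must span at least one sample", call. = FALSE)
  cx <- cos(phase)
  sx <- sin(phase)
  cx[is.na(cx)] <- 0
  sx[is.na(sx)] <- 0
  cs <- c(0, cumsum(cx))
  ss <- c(0, cumsum(sx))
  out <- rep(NA_real_, n)
  k <- (w + 1):n
  resc <- cs[k + 1] - cs[k - w]
  ress <- ss[k + 1] - ss[k - w]
  r <- sqrt(resc^2 + ress^2)
  zero <- r < 1e-12
  if (any(zero)) warning("zero resultant length in circular mean; masked")
  val <- atan2(ress, resc)
  val[zero] <- NA_real_
  out[k] <- val
  out
}

#' Phase-difference switch predictor
#'
#' Maps the difference between the short- and long-window mean phases into
#' `[0, 1]`: `p = sin((short - long) / 2)^2`. Congruent phases map to 0,
#' antipodal phases to 1.
#'
#' @param mean_short,mean_long Aligned circular-mean phase series (radians).
#' @return Numeric predictor series in `[0, 1]` (`NA` where either input is
#'   masked).
#' @export
switch_predictor <- function(mean_short, mean_long) {
  stopifnot(length(mean_short) == length(mean_long))
  sin((mean_short - mean_long) / 2)^2
}

#' Predicted switch times and windows from the predictor series
#'
#' Thresholds the predictor at its mean plus one SD (over unmasked samples,
#' strict inequality), scanning forward in time. Each crossing at `t*` opens
#' the window `[t* - 1.2, t* + rt]` and starts a refractory period of
#' `rt + 1.2` seconds during which further crossings are ignored, so windows
#' never overlap.
#'
#' @param predictor Numeric predictor series in `[0, 1]`.
#' @param times Sample times in seconds.
#' @param rt Subject reaction time in seconds.
#' @param lead_s Look-back span of the window in seconds (two triplets).
#' @return An object of class `switch_windows`: tibble with columns `t_star`,
#'   `win_start`, `win_end`, plus attributes `threshold`, `rt` and `lead_s`.
#' @export
predict_switches <- function(predictor, times, rt, lead_s = 1.2) {
  stopifnot(length(predictor) == length(times))
  ok <- !is.na(predictor)
  if (!any(ok)) stop("predictor series is empty or fully masked", call. = FALSE)
  thr <- mean(predictor[ok]) + sd(predictor[ok])
  cross <- which(ok & predictor > thr)
  t_star <- numeric(0)
  last <- -Inf
  for (i in cross) {
    if (times[i] >= last + rt + lead_s) {
      t_star <- c(t_star, times[i])
      last <- times[i]
    }
  }
  out <- tibble::tibble(
    t_star = t_star,
    win_start = t_star - lead_s,
    win_end = t_star + rt
  )
  class(out) <- c("switch_windows", class(out))
  attr(out, "threshold") <- thr
  attr(out, "rt") <- rt
  attr(out, "lead_s") <- lead_s
  out
}

#' Match button presses to predicted windows
#'
#' Greedy, earliest-first matching: each press is matched to the (unique,
#' non-overlapping) window containing it, at most once. Matched pairs are
#' classified `bp` when the press precedes the marked time `t*` and `pb`
#' otherwise; unmatched windows are false positives and unmatched presses are
#' misses.
#'
#' @param windows A [predict_switches()] result.
#' @param button_times Numeric vector of reported button-press times
#'   (seconds), ascending.
#' @return An object of class `switch_prediction`: list with `matches`
#'   (per-press tibble: button_time, t_star, class), `windows` (per-window
#'   tibble with outcome), and counts `bp`, `pb`, `n_miss`,
#'   `n_false_positive`.
#' @export
align_predictions <- function(windows, button_times) {
  stopifnot(inherits(windows, "switch_windows"))
  button_times <- sort(button_times)
  nw <- nrow(windows)
  used <- rep(FALSE, nw)
  cls <- rep(NA_character_, length(button_times))
  t_star <- rep(NA_real_, length(button_times))
  for (i in seq_along(button_times)) {
    bt <- button_times[i]
    j <- which(!used & windows$win_start <= bt & bt <= windows$win_end)
    if (length(j)) {
      j <- j[1]
      used[j] <- TRUE
      t_star[i] <- windows$t_star[j]
      cls[i] <- if (bt < windows$t_star[j]) "bp" else "pb"
    } else {
      cls[i] <- "miss"
    }
  }
  win_tbl <- tibble::as_tibble(windows)
  win_tbl$outcome <- ifelse(used, "hit", "false_positive")
  structure(
    list(
      matches = tibble::tibble(button_time = button_times, t_star = t_star,
                               class = cls),
      windows = win_tbl,
      bp = sum(cls == "bp"),
      pb = sum(cls == "pb"),
      n_miss = sum(cls == "miss"),
      n_false_positive = sum(!used),
      threshold = attr(windows, "threshold"),
      rt = attr(windows, "rt")
    ),
    class = "switch_prediction"
  )
}

#' @export
print.switch_prediction <- function(x, ...) {
  cat(sprintf(
    "<switch_prediction> %d windows: bp = %d, pb = %d, miss = %d, false positive = %d\n",
    nrow(x$windows), x$bp, x$pb, x$n_miss, x$n_false_positive
  ))
  invisible(x)
}

#' @export
tidy.switch_prediction <- function(x, ...) x$matches

#' @export
glance.switch_prediction <- function(x, ...) {
  tibble::tibble(
    n_windows = nrow(x$windows), bp = x$bp, pb = x$pb,
    n_miss = x$n_miss, n_false_positive = x$n_false_positive,
    threshold = x$threshold
  )
}

#' Order test for press-versus-phase-change precedence
#'
#' One-degree-of-freedom chi-squared goodness-of-fit of the observed
#' `(bp, pb)` counts against equal expected counts, testing whether a button
#' press is more likely to precede or to follow the marked phase change.
#'
#' @param bp Count of presses preceding the marked phase change.
#' @param pb Count of phase changes preceding the press.
#' @return Tibble with `statistic`, `p_value`, `df` and `n`.
#' @export
chi_square_order_test <- function(bp, pb) {
  if (bp + pb <= 0) stop("need at least one matched event", call. = FALSE)
  ht <- stats::chisq.test(c(bp, pb), p = c(0.5, 0.5), correct = FALSE)
  tibble::tibble(
    statistic = unname(ht$statistic),
    p_value = unname(ht$p.value),
    df = 1L,
    n = bp + pb
  )
}
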
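#' Sliding-window standardization
#'
#' Standard-normalizes each channel with the mean and SD taken over a window
#' centered at each sample (3 s by default). Near the record boundaries the
#' window is truncated to the available samples; no data are fabricated
#' outside the record.
#'
#' @param rec An [mc_recording()].
#' @param window_s Window length in seconds (centered).
#' @return An [mc_recording()] of the same shape.
#' @export
sliding_standardize <- function(rec, window_s = 3) {
  stopifnot(inherits(rec, "mc_recording"))
  n <- nrow(rec$values)
  half <- floor(window_s * rec$rate / 2)
  if (half < 1 && n > 1) half <- n # degenerate window -> global standardization
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- hi - lo + 1
  if (any(cnt <= 1)) stop("standardization window must cover > 1 sample", call. = FALSE)
  out <- rec$values
  for (c in seq_len(ncol(out))) {
    x <- rec$values[, c]
    cs <- c(0, cumsum(x))
    cs2 <- c(0, cumsum(x^2))
    s1 <- cs[hi + 1] - cs[lo]
    s2 <- cs2[hi + 1] - cs2[lo]
    mu <- s1 / cnt
    varw <- (s2 - cnt * mu^2) / (cnt - 1)
    varw[varw < 0] <- 0
    sdw <- sqrt(varw)
    bad <- which(sdw <= 0)
    if (length(bad)) {
      stop(sprintf(
        "zero within-window SD in channel %s at t = %.3f s",
        colnames(rec$values)[c], rec$t0 + (bad[1] - 1) / rec$rate
      ), call. = FALSE)
    }
    out[, c] <- (x - mu) / sdw
  }
  mc_recording(out, rate = rec$rate, t0 = rec$t0,
               channel_names = colnames(rec$values))
}

#' Centered moving-average smoothing
#'
#' Averages each channel over a short centered window (10 ms by default).
#' An even sample count is widened to the next odd count so the window is
#' symmetric about each sample; edges are truncated to available samples.
#'
#' @param rec An [mc_recording()].
#' @param window_ms Window length in milliseconds.
#' @return An [mc_recording()] of the same shape.
#' @export
smooth_boxcar <- function(rec, window_ms = 10) {
  stopifnot(inherits(rec, "mc_recording"))
  n <- nrow(rec$values)
  half <- ceiling(window_ms / 1000 * rec$rate / 2)
  if (half < 0) stop("window must cover at least one sample", call. = FALSE)
  if (half == 0) return(rec)
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  cnt <- hi - lo + 1
  out <- rec$values
  for (c in seq_len(ncol(out))) {
    cs <- c(0, cumsum(rec$values[, c]))
    out[, c] <- (cs[hi + 1] - cs[lo]) / cnt
  }
  mc_recording(out, rate = rec$rate, t0 = rec$t0,
               channel_names = colnames(rec$values))
}

#' Decimate by integer stride
#'
#' Downsamples by keeping one sample every `rate / target_rate` points,
#' starting from the first sample. No filtering is applied here; smoothing
#' is expected to precede decimation in the pipeline.
#'
#' @param rec An [mc_recording()].
#' @param target_rate Target rate in Hz; must divide `rec$rate`.
#' @return An [mc_recording()] at `target_rate`.
#' @export
decimate_to <- function(rec, target_rate = 200) {
  stopifnot(inherits(rec, "mc_recording"))
  ratio <- rec$rate / target_rate
  if (abs(ratio - round(ratio)) > 1e-9) {
    stop("`rate` must be an integer multiple of `target_rate`", call. = FALSE)
  }
  ratio <- as.integer(round(ratio))
  if (ratio == 1L) return(rec)
  keep <- seq(1L, nrow(rec$values), by = ratio)
  mc_recording(rec$values[keep, , drop = FALSE], rate = target_rate, t0 = rec$t0,
               channel_names = colnames(rec$values))
}

#' Full preprocessing pipeline
#'
#' Order-fixed chain: sliding standardization (3 s), boxcar smoothing (10 ms),
#' decimation to 200 Hz. A 300 s input at 1000 Hz yields 60,000 samples per
#' channel.
#'
#' @param rec An [mc_recording()].
#' @param std_window_s Standardization window, seconds.
#' @param smooth_ms Smoothing window, milliseconds.
#' @param target_rate Decimation target, Hz.
#' @return An [mc_recording()].
#' @export
preprocess_recording <- function(rec, std_window_s = 3, smooth_ms = 10,
                                 target_rate = 200) {
  rec |>
    sliding_standardize(window_s = std_window_s) |>
    smooth_boxcar(window_ms = smooth_ms) |>
    decimate_to(target_rate = target_rate)
}
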
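#' Exponentially weighted time-delay coordinates
#'
#' Augments each multichannel sample with its `s` predecessors, down-weighting
#' lag `l` by `exp(-l * alpha)`:
#' \deqn{\tilde y_k = [y_k,\; e^{-\alpha} y_{k-1},\; \dots,\; e^{-s\alpha} y_{k-s}]}
#' The first `s` samples are dropped (insufficient history), so a recording of
#' `n` samples yields `n - s` embedded rows of dimension
#' `n_channels * (s + 1)`. Lag blocks are ordered newest to oldest; within a
#' block, channels keep their original order.
#'
#' @param rec An [mc_recording()].
#' @param s Number of appended past samples (delays).
#' @param alpha Exponential decay per lag step; `alpha = 0` gives classical
#'   delay coordinates.
#' @return An object of class `delay_matrix`: list with `coords`
#'   (matrix, `(n - s)` by `n_channels * (s + 1)`), `s`, `alpha`, `dt`,
#'   `start_index` (index into the recording of the first embedded sample),
#'   `n_channels` and `times`.
#' @export
build_delay_coordinates <- function(rec, s = 799, alpha = 0.001) {
  stopifnot(inherits(rec, "mc_recording"))
  n <- nrow(rec$values)
  nc <- ncol(rec$values)
  if (s >= n) {
    stop(sprintf("insufficient history: s = %d but only %d samples", s, n),
         call. = FALSE)
  }
  if (s < 0 || alpha < 0) stop("`s` and `alpha` must be non-negative", call. = FALSE)
  coords <- matrix(0, n - s, nc * (s + 1))
  for (l in 0:s) {
    cols <- l * nc + seq_len(nc)
    coords[, cols] <- rec$values[(s + 1 - l):(n - l), , drop = FALSE] * exp(-l * alpha)
  }
  structure(
    list(
      coords = coords, s = s, alpha = alpha, dt = 1 / rec$rate,
      start_index = s + 1L, n_channels = nc,
      times = rec$t0 + (s:(n - 1)) / rec$rate
    ),
    class = "delay_matrix"
  )
}

#' @export
print.delay_matrix <- function(x, ...) {
  cat(sprintf(
    "<delay_matrix> %d rows x %d cols (s = %d, alpha = %g, span = %g s)\n",
    nrow(x$coords), ncol(x$coords), x$s, x$alpha, (x$s + 1) * x$dt
  ))
  invisible(x)
}
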
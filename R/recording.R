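#' Multichannel recording container
#'
#' A minimal container for a regularly sampled time-by-channel signal matrix,
#' the common currency of the feature-extraction pipeline. Values are stored
#' as a numeric matrix with one row per sample and one column per channel.
#'
#' @param values Numeric matrix, time by channel. A vector is treated as a
#'   single channel.
#' @param rate Sampling rate in Hz (> 0).
#' @param t0 Time of the first sample in seconds (default 0).
#' @param channel_names Optional character vector of channel names.
#'
#' @return An object of class `mc_recording`: a list with elements `values`,
#'   `rate` and `t0`.
#' @export
#' @examples
#' rec <- mc_recording(cbind(sin(seq(0, 2 * pi, length.out = 100))), rate = 100)
#' rec
mc_recording <- function(values, rate, t0 = 0, channel_names = NULL) {
  if (is.vector(values)) values <- matrix(values, ncol = 1)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (!is.numeric(rate) || length(rate) != 1 || rate <= 0) {
    stop("`rate` must be a single positive number (Hz)", call. = FALSE)
  }
  if (ncol(values) < 1) stop("recording needs at least one channel", call. = FALSE)
  if (!all(is.finite(values))) stop("recording values must be finite", call. = FALSE)
  if (!is.null(channel_names)) colnames(values) <- channel_names
  if (is.null(colnames(values))) {
    colnames(values) <- paste0("ch", seq_len(ncol(values)))
  }
  structure(
    list(values = values, rate = rate, t0 = t0),
    class = "mc_recording"
  )
}

#' @export
print.mc_recording <- function(x, ...) {
  cat(sprintf(
    "<mc_recording> %d samples x %d channels @ %g Hz (%.3f s, t0 = %g s)\n",
    nrow(x$values), ncol(x$values), x$rate, nrow(x$values) / x$rate, x$t0
  ))
  invisible(x)
}

#' Sample times of a recording
#'
#' @param rec An [mc_recording()].
#' @return Numeric vector of sample times in seconds.
#' @export
rec_times <- function(rec) {
  stopifnot(inherits(rec, "mc_recording"))
  rec$t0 + (seq_len(nrow(rec$values)) - 1) / rec$rate
}

#' @export
as_tibble.mc_recording <- function(x, ...) {
  out <- tibble::as_tibble(as.data.frame(x$values))
  dplyr::bind_cols(tibble::tibble(time_s = rec_times(x)), out)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.mc_recording <- function(x, ...) {
  as_tibble.mc_recording(x) |>
    tidyr::pivot_longer(-"time_s", names_to = "channel", values_to = "value")
}
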
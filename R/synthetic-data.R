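#' Parameters for the synthetic bistable-streaming generator
#'
#' Bundles the knobs of the surrogate data generator. The generator emulates
#' the statistical structure the feature-extraction pipeline assumes in
#' recordings from an auditory triplet-streaming task: oscillatory components
#' at integer multiples of the triplet presentation rate, a slow two-state
#' latent percept process that shifts the phase of those components, a slow
#' multiplicative amplitude drift, additive Gaussian noise, and button events
#' delayed by a fixed reaction time.
#'
#' Defaults describe a 300 s block of 500 triplets of 600 ms (fundamental
#' 1/0.6 = 1.67 Hz) with log-normal percept durations of mean 10 s and SD 3 s,
#' a 0.65 s reaction time, three active harmonics whose phase is shifted by
#' `percept_phase_offsets` radians in the two-stream state, and moderate
#' additive noise.
#'
#' @param n_channels Number of recorded channels.
#' @param rate Sampling rate of the raw synthetic signal in Hz.
#' @param block_duration Block length in seconds.
#' @param f_triplet Triplet presentation rate in Hz (one triplet per 600 ms by
#'   default).
#' @param triplet_duration Triplet duration in seconds; `1 / f_triplet`.
#' @param n_harmonics Number of active harmonics of `f_triplet`.
#' @param harmonic_amplitudes Numeric matrix, `n_channels` by `n_harmonics`,
#'   of per-channel harmonic amplitudes. Default: `1/m` falloff with a mild
#'   deterministic per-channel variation.
#' @param percept_phase_offsets Phase shift (radians) applied to each harmonic
#'   while the latent percept is in the two-stream state. The percept is
#'   encoded in phase, not amplitude.
#' @param slow_drift_amplitude Relative amplitude of a slow multiplicative
#'   drift (period ~ 60 s) shared by all channels.
#' @param dwell_mean,dwell_sd Mean and SD (seconds) of the log-normal percept
#'   dwell-time distribution.
#' @param reaction_time Reporting delay in seconds between a perceptual
#'   switch and the button press.
#' @param noise_sd SD of additive white Gaussian noise per channel.
#' @param seed Integer seed; the generator is deterministic given the seed.
#'
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(n_channels = 4,
                         rate = 1000,
                         block_duration = 300,
                         f_triplet = 1 / 0.6,
                         triplet_duration = 1 / f_triplet,
                         n_harmonics = 3,
                         harmonic_amplitudes = NULL,
                         percept_phase_offsets = c(pi, pi / 2, pi / 4)[seq_len(n_harmonics)],
                         slow_drift_amplitude = 0.1,
                         dwell_mean = 10,
                         dwell_sd = 3,
                         reaction_time = 0.65,
                         noise_sd = 0.3,
                         seed = 1L) {
  if (rate <= 0) stop("`rate` must be positive", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  if (dwell_mean <= 0 || dwell_sd < 0) {
    stop("dwell parameters must be positive (mean) and non-negative (sd)", call. = FALSE)
  }
  if (dwell_mean <= reaction_time) {
    stop("`dwell_mean` must exceed `reaction_time`", call. = FALSE)
  }
  if (is.null(harmonic_amplitudes)) {
    m <- seq_len(n_harmonics)
    base <- 1 / m
    # mild per-channel variation so the channels are not identical
    chan <- 1 + 0.2 * sin(seq_len(n_channels))
    harmonic_amplitudes <- outer(chan, base)
  }
  harmonic_amplitudes <- as.matrix(harmonic_amplitudes)
  stopifnot(
    nrow(harmonic_amplitudes) == n_channels,
    ncol(harmonic_amplitudes) == n_harmonics,
    length(percept_phase_offsets) == n_harmonics
  )
  structure(
    list(
      n_channels = n_channels, rate = rate, block_duration = block_duration,
      f_triplet = f_triplet, triplet_duration = triplet_duration,
      n_harmonics = n_harmonics, harmonic_amplitudes = harmonic_amplitudes,
      percept_phase_offsets = percept_phase_offsets,
      slow_drift_amplitude = slow_drift_amplitude,
      dwell_mean = dwell_mean, dwell_sd = dwell_sd,
      reaction_time = reaction_time, noise_sd = noise_sd,
      seed = as.integer(seed)
    ),
    class = "synth_params"
  )
}

# log-normal (meanlog, sdlog) matching a target arithmetic mean and sd
.lnorm_pars <- function(mean, sd) {
  if (sd == 0) {
    return(list(meanlog = log(mean), sdlog = 0))
  }
  sigma2 <- log(1 + (sd / mean)^2)
  list(meanlog = log(mean) - sigma2 / 2, sdlog = sqrt(sigma2))
}

#' Simulate a bistable percept timeline
#'
#' Draws an alternating one-stream / two-stream percept sequence as a
#' semi-Markov process: dwell times are log-normal with the requested mean and
#' SD, truncated below at `reaction_time + 2 * triplet_duration` so that no
#' percept is shorter than the reporting-neutral zone. The first percept is a
#' seeded fair coin. Button presses trail each switch by `reaction_time`.
#'
#' @param params A [synth_params()] object.
#' @return An object of class `percept_timeline`: list with `switch_times`
#'   (seconds, strictly increasing, excludes the block start), `percepts`
#'   (label of each epoch, alternating `"one_stream"` / `"two_stream"`,
#'   length `length(switch_times) + 1`), `button_times`, `reaction_time`,
#'   `block_duration` and `triplet_duration`.
#' @export
#' @examples
#' tl <- simulate_percept_timeline(synth_params(block_duration = 60, seed = 7))
#' as_tibble(tl)
simulate_percept_timeline <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  set.seed(params$seed)
  floor_dwell <- params$reaction_time + 2 * params$triplet_duration
  lp <- .lnorm_pars(params$dwell_mean, params$dwell_sd)
  draw_dwell <- function() {
    if (lp$sdlog == 0) {
      return(max(params$dwell_mean, floor_dwell))
    }
    for (i in 1:1000) {
      d <- rlnorm(1, lp$meanlog, lp$sdlog)
      if (d >= floor_dwell) return(d)
    }
    stop("could not draw a dwell time above the truncation floor", call. = FALSE)
  }
  first <- if (runif(1) < 0.5) "one_stream" else "two_stream"
  other <- function(p) if (p == "one_stream") "two_stream" else "one_stream"

  switches <- numeric(0)
  percepts <- first
  t <- draw_dwell()
  # a switch is kept only if its report (switch + RT) falls inside the block
  while (t + params$reaction_time < params$block_duration) {
    switches <- c(switches, t)
    percepts <- c(percepts, other(percepts[length(percepts)]))
    t <- t + draw_dwell()
  }
  structure(
    list(
      switch_times = switches,
      percepts = percepts,
      button_times = switches + params$reaction_time,
      reaction_time = params$reaction_time,
      block_duration = params$block_duration,
      triplet_duration = params$triplet_duration
    ),
    class = "percept_timeline"
  )
}

#' @export
print.percept_timeline <- function(x, ...) {
  cat(sprintf(
    "<percept_timeline> %g s block, %d switches, RT %g s, first percept %s\n",
    x$block_duration, length(x$switch_times), x$reaction_time, x$percepts[1]
  ))
  invisible(x)
}

#' @export
as_tibble.percept_timeline <- function(x, ...) {
  tibble::tibble(
    epoch = seq_along(x$percepts),
    percept = x$percepts,
    onset_s = c(0, x$switch_times),
    offset_s = c(x$switch_times, x$block_duration),
    button_s = c(NA_real_, x$button_times)
  )
}

#' Latent percept state z(t)
#'
#' Evaluates the binary latent state of a timeline at arbitrary times:
#' 0 while the percept is one-stream, 1 while it is two-stream.
#'
#' @param timeline A [simulate_percept_timeline()] result.
#' @param times Numeric vector of times in seconds.
#' @return Integer vector of 0/1 states.
#' @export
percept_state <- function(timeline, times) {
  stopifnot(inherits(timeline, "percept_timeline"))
  epoch <- findInterval(times, c(0, timeline$switch_times))
  epoch[epoch < 1] <- 1L
  as.integer(timeline$percepts[epoch] == "two_stream")
}

#' Simulate a multichannel streaming recording
#'
#' Builds the surrogate signal channel by channel as
#' \deqn{y_c(t) = \Big[\sum_m a_{c,m} \cos(2\pi m f t + z(t)\,\Delta\phi_m)\Big]
#'   (1 + d(t)) + \epsilon_c(t)}
#' where \eqn{f} is the triplet rate, \eqn{z(t) \in \{0,1\}} the latent
#' percept state of `timeline`, \eqn{\Delta\phi_m} the per-harmonic percept
#' phase offsets, \eqn{d(t)} a slow sinusoidal drift and \eqn{\epsilon} white
#' Gaussian noise. Deterministic given `params$seed`.
#'
#' @param timeline A [simulate_percept_timeline()] result consistent with
#'   `params$block_duration`.
#' @param params A [synth_params()] object.
#' @return An [mc_recording()].
#' @export
simulate_lfp <- function(timeline, params) {
  stopifnot(inherits(timeline, "percept_timeline"), inherits(params, "synth_params"))
  if (abs(timeline$block_duration - params$block_duration) > 1e-9) {
    stop("timeline and params disagree on block duration", call. = FALSE)
  }
  n <- round(params$block_duration * params$rate)
  t <- (seq_len(n) - 1) / params$rate
  z <- percept_state(timeline, t)
  drift <- params$slow_drift_amplitude * sin(2 * pi * t / 60)
  set.seed(params$seed + 1L)
  vals <- matrix(0, n, params$n_channels)
  for (m in seq_len(params$n_harmonics)) {
    carrier <- cos(2 * pi * m * params$f_triplet * t +
                     z * params$percept_phase_offsets[m])
    vals <- vals + outer(carrier, params$harmonic_amplitudes[, m])
  }
  vals <- vals * (1 + drift)
  if (params$noise_sd > 0) {
    vals <- vals + matrix(rnorm(n * params$n_channels, sd = params$noise_sd),
                          n, params$n_channels)
  }
  mc_recording(vals, rate = params$rate, t0 = 0)
}

#' Simulate timeline and recording in one call
#'
#' @param params A [synth_params()] object.
#' @return List with elements `timeline` and `recording`.
#' @export
simulate_streaming_block <- function(params = synth_params()) {
  timeline <- simulate_percept_timeline(params)
  list(timeline = timeline, recording = simulate_lfp(timeline, params))
}
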
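# Shared fixtures built in code. The desk-scale pipeline run (60 s block,
# s = 199, 60 eigenpairs) is expensive, so it is computed lazily once per
# test session and shared across test files.

.fixture_cache <- new.env(parent = emptyenv())

desk_params <- function() synth_params(block_duration = 60)

desk_config <- function() {
  pipeline_config(s = 199, n_eigs = 60, n_perm = 500,
                  rt = desk_params()$reaction_time)
}

get_desk_run <- function() {
  if (is.null(.fixture_cache$desk)) {
    params <- desk_params()
    blk <- simulate_streaming_block(params)
    res <- suppressWarnings(suppressMessages(
      run_pipeline(blk$recording, blk$timeline, desk_config())
    ))
    .fixture_cache$desk <- list(params = params, block = blk, result = res)
  }
  .fixture_cache$desk
}

# a koopman_decomposition assembled by hand, for branch-rule unit tests
fake_decomposition <- function(omega, nt = 100, dt = 0.005) {
  omega <- as.complex(omega)
  t <- (seq_len(nt) - 1) * dt
  eigfuns <- vapply(omega, function(w) exp(w * t), complex(nt))
  structure(
    list(
      discrete_eigvals = exp(omega * dt), exp_eigvals = omega,
      eigfuns = eigfuns, eigvecs = diag(length(omega)) + 0i,
      modes = NULL, dt = dt, dictionary_size = length(omega),
      effective_rank = length(omega), times = t, start_index = 1L
    ),
    class = "koopman_decomposition"
  )
}

# cosine recording helper
cosine_recording <- function(f = 1 / 0.6, rate = 1000, duration = 10,
                             amplitude = 1, phase = 0) {
  t <- seq(0, duration - 1 / rate, by = 1 / rate)
  mc_recording(amplitude * cos(2 * pi * f * t + phase), rate = rate)
}
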
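#' Pipeline configuration
#'
#' All defaults are the reference operating point of the method: 3 s
#' standardization window, 10 ms smoothing, 200 Hz working rate, 799 delays
#' with decay 0.001 (a 4 s embedded span at 5 ms), bandwidth from 12 nearest
#' neighbours, kernel sparsified at 192 neighbours, a 0.6 s triplet
#' (fundamental 1.67 Hz), and 10,000 label permutations. Reduce `s`,
#' `n_eigs` and `n_perm` for quick runs; the structure of the result is
#' unchanged.
#'
#' @param std_window_s,smooth_ms,target_rate Preprocessing parameters.
#' @param s,alpha Delay-embedding parameters.
#' @param kmin,knn,n_eigs Diffusion-map parameters.
#' @param f_triplet Triplet presentation rate in Hz.
#' @param dict_tol_f,theta_h,run_length Dictionary-cutoff parameters.
#' @param branch_tol_f,tol_real,tol_zero Branch-assignment tolerances.
#' @param rt Subject reaction time in seconds (sizing of prediction windows).
#' @param lead_s Look-back span of prediction windows in seconds.
#' @param n_perm,kl_bins,seed Statistics parameters.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(std_window_s = 3, smooth_ms = 10, target_rate = 200,
                            s = 799, alpha = 0.001,
                            kmin = 12, knn = 192, n_eigs = 150,
                            f_triplet = 1 / 0.6,
                            dict_tol_f = 0.2, theta_h = 0.3, run_length = 3,
                            branch_tol_f = 0.2, tol_real = f_triplet / 10, tol_zero = 0.01,
                            rt = 0.65, lead_s = 1.2,
                            n_perm = 10000, kl_bins = 25, seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("<pipeline_config>\n")
  for (nm in names(x)) cat(sprintf("  %-14s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# first perception-branch eigenfunction with positive frequency
.leading_oscillator <- function(decomp, branches) {
  j2 <- branches$J2
  freq <- Im(decomp$exp_eigvals) / (2 * pi)
  cand <- j2[freq[j2] > branches$tol_real]
  if (!length(cand)) stop("no oscillatory eigenfunction on branch J2", call. = FALSE)
  cand[1] # indices are ordered by decreasing real part already
}

#' Run the full feature-extraction pipeline
#'
#' Executes preprocess, delay embedding, diffusion maps, dictionary
#' selection, eDMD, branch assignment, slow-feature location and phase-based
#' switch prediction on a recording. Behavioural statistics (orientation of
#' the slow feature, permutation test, divergence, press alignment, order
#' test, motor control) run only when a `timeline` is supplied; feature
#' extraction itself never reads it.
#'
#' @param recording An [mc_recording()] of raw (or already bandpassed)
#'   multichannel signal.
#' @param timeline Optional `percept_timeline` of behavioural reports.
#' @param config A [pipeline_config()].
#' @return A list of class `koop_pipeline` with the intermediate and final
#'   artifacts (`preprocessed`, `delay`, `epsilon`, `basis`, `dictionary`,
#'   `decomposition`, `branches`, `phase`, `predictor`, `windows`, and when
#'   behaviour is available `labels`, `phi_star`, `perm_test`, `kl_div`,
#'   `prediction`, `order_test`, `motor_control`).
#' @export
run_pipeline <- function(recording, timeline = NULL, config = pipeline_config()) {
  stopifnot(inherits(recording, "mc_recording"),
            inherits(config, "pipeline_config"))
  out <- list(config = config)
  out$preprocessed <- preprocess_recording(
    recording, std_window_s = config$std_window_s,
    smooth_ms = config$smooth_ms, target_rate = config$target_rate
  )
  dm <- build_delay_coordinates(out$preprocessed, s = config$s, alpha = config$alpha)
  out$delay <- dm
  nn <- knn_search(dm, k = max(config$kmin, config$knn))
  out$epsilon <- select_epsilon(dm, kmin = config$kmin, nn = nn)
  mk <- build_markov_matrix(dm, epsilon = out$epsilon, knn = config$knn, nn = nn)
  out$basis <- diffusion_eigendecomposition(mk, n_eigs = config$n_eigs,
                                            kmin = config$kmin)
  out$dictionary <- select_dictionary(
    out$basis, f_triplet = config$f_triplet, rate = config$target_rate,
    tol_f = config$dict_tol_f, theta_h = config$theta_h,
    run_length = config$run_length
  )
  decomp <- run_edmd(out$dictionary$dictionary, dt = 1 / config$target_rate,
                     times = dm$times, start_index = dm$start_index)
  decomp <- compute_modes(out$preprocessed, decomp)
  out$decomposition <- decomp
  harm <- match_harmonics(decomp, f_triplet = config$f_triplet,
                          tol_f = config$branch_tol_f)
  br <- assign_branches(decomp, harm, f_triplet = config$f_triplet,
                        tol_real = config$tol_real, tol_zero = config$tol_zero)
  br <- find_phi_star(decomp, br)
  out$branches <- br

  j_osc <- .leading_oscillator(decomp, br)
  f_osc <- max(1, round(Im(decomp$exp_eigvals[j_osc]) / (2 * pi) / config$f_triplet)) *
    config$f_triplet
  out$oscillator_index <- j_osc
  out$oscillator_freq <- f_osc
  td <- 1 / config$f_triplet
  phase <- instantaneous_phase(decomp$eigfuns[, j_osc], f_osc, decomp$times)
  ms <- windowed_circular_mean(phase, td, config$target_rate)
  ml <- windowed_circular_mean(phase, 2 * td, config$target_rate)
  out$phase <- phase
  out$predictor <- switch_predictor(ms, ml)
  out$windows <- predict_switches(out$predictor, decomp$times, rt = config$rt,
                                  lead_s = config$lead_s)

  if (!is.null(timeline)) {
    out$labels <- label_triplets(timeline)
    sample_labels <- triplet_labels_at(out$labels, decomp$times)
    out$phi_star <- orient_phi_star(br$phi_star, sample_labels)
    out$perm_test <- permutation_test_phi_star(
      out$phi_star, out$labels, decomp$times,
      n_perm = config$n_perm, seed = config$seed
    )
    out$kl_div <- kl_divergence_percepts(out$phi_star, sample_labels,
                                         n_bins = config$kl_bins)
    out$prediction <- align_predictions(out$windows, timeline$button_times)
    if (out$prediction$bp + out$prediction$pb > 0) {
      out$order_test <- chi_square_order_test(out$prediction$bp, out$prediction$pb)
    }
    k <- match(round(out$prediction$matches$button_time, 9),
               round(timeline$button_times, 9))
    dirs <- paste0("to_", timeline$percepts[k + 1L])
    out$motor_control <- tryCatch(
      motor_control_analysis(out$phi_star, decomp$times, out$prediction,
                             dirs, rate = config$target_rate),
      warning = function(w) {
        message("motor control analysis skipped: ", conditionMessage(w))
        NULL
      }
    )
  } else {
    out$phi_star <- orient_phi_star(br$phi_star, NULL)
    message("no behavioural timeline supplied; behaviour-aware statistics skipped")
  }
  class(out) <- "koop_pipeline"
  out
}

#' @export
print.koop_pipeline <- function(x, ...) {
  cat("<koop_pipeline>\n")
  print(x$decomposition)
  print(x$branches)
  cat(sprintf("  leading oscillator: index %d at %.2f Hz; %d predicted windows\n",
              x$oscillator_index, x$oscillator_freq, nrow(x$windows)))
  if (!is.null(x$perm_test)) print(x$perm_test)
  if (!is.null(x$order_test)) {
    cat(sprintf("  order test: chi^2 = %.2f, p = %.3f (bp = %d, pb = %d)\n",
                x$order_test$statistic, x$order_test$p_value,
                x$prediction$bp, x$prediction$pb))
  }
  invisible(x)
}

#' Three-dimensional embedding coordinates
#'
#' Exports the trajectory spanned by the slow feature and the leading
#' perception-branch oscillator: one row per embedded time sample with
#' `phi_star`, `Re(phi_f)` and `Im(phi_f)`. These coordinates draw the
#' double-cone perceptual manifold.
#'
#' @param pipeline A [run_pipeline()] result.
#' @return Tibble with columns `time_s`, `phi_star`, `re_phi_f`, `im_phi_f`.
#' @export
embedding_coordinates <- function(pipeline) {
  stopifnot(inherits(pipeline, "koop_pipeline"))
  phi_f <- pipeline$decomposition$eigfuns[, pipeline$oscillator_index]
  tibble::tibble(
    time_s = pipeline$decomposition$times,
    phi_star = as.numeric(pipeline$phi_star),
    re_phi_f = Re(phi_f),
    im_phi_f = Im(phi_f)
  )
}
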
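---
title: "Methods: Koopman spectral features for bistable auditory streaming"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Koopman spectral features for bistable auditory streaming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Model and assumptions

The pipeline assumes that multichannel recordings `y(t)` taken during an
auditory triplet-streaming task are observations of a smooth latent
dynamical system whose trajectory evolves on a low-dimensional manifold.
Two processes coexist on that manifold: a fast, stable limit-cycle-like
response locked to the 600 ms triplet (fundamental `1/0.6 ≈ 1.67` Hz and
its harmonics), and a slow process that switches between two
almost-invariant regions corresponding to the two percepts. The Koopman
operator — the linear operator that advances observation functions along
the flow — gives a spectral description of both at once: eigenvalues
`ω = ln(λ)/Δt` carry a decay rate (Re) and a frequency (Im/2π), and
eigenfunction time series `φ_j(t)` are the features.

Because the operator is infinite-dimensional, it is approximated by eDMD
over a finite dictionary. The dictionary here is data-driven: eigenvectors
of a diffusion-map Markov matrix built on exponentially weighted delay
coordinates. Delay embedding reconstructs the state space from few
channels; diffusion maps supply a Fourier-like basis adapted to the
manifold rather than to the recording axes.

Feature extraction is *behaviour-agnostic*: nothing upstream of
`orient_phi_star()` reads the event table. The button presses enter only
the post-hoc statistics (orientation of `φ*`, permutation test,
divergence, press/window alignment, motor control).

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `std_window_s` | 3 | s | sliding standardization window; long enough to span several triplets, short enough to track slow amplitude drift |
| `smooth_ms` | 10 | ms | suppresses sub-triplet jitter before decimation |
| `target_rate` | 200 | Hz | working rate; 5 ms sampling resolves all harmonics of interest |
| `s` | 799 | samples | delay count; with 5 ms sampling the embedded window is 4 s, deliberately incommensurate with the 0.6 s triplet |
| `alpha` | 0.001 | per lag | exponential down-weighting of old lags; balances regularization against information loss |
| `kmin` | 12 | neighbours | kernel bandwidth = mean distance to the 12 nearest neighbours |
| `knn` | 192 | neighbours | kernel sparsification; kept far above `kmin` so the graph stays connected |
| `n_eigs` | 150 | — | diffusion eigenpairs computed before dictionary selection |
| `dict_tol_f` | 0.2 | Hz | half-width of the harmonic bands in the dictionary cutoff |
| `theta_h`, `theta_peak` | 0.3, 0.5 | — | organization thresholds (below) |
| `branch_tol_f` | 0.2 | Hz | harmonic matching tolerance; small against the 1.67 Hz grid spacing |
| `tol_real` | `f_triplet/10` | Hz | "effectively real" threshold for the slow feature (below) |
| `tol_zero` | 0.01 | 1/s | magnitude under which a real eigenvalue counts as the constant mode |
| `rt` | 0.65 | s | subject reaction time; sizes prediction windows and the neutral zone |
| `n_perm` | 10000 | — | label permutations; smallest reportable p just under 1e-4 |

## The synthetic generator

`simulate_streaming_block()` emulates exactly the structure the pipeline
assumes: per channel, a sum of cosines at the first `n_harmonics` multiples
of the triplet rate whose phases shift by `percept_phase_offsets` while a
hidden two-state semi-Markov percept process is in its two-stream state,
multiplied by a slow sinusoidal drift and corrupted by additive white
Gaussian noise. Percept dwell times are log-normal (the standard
phenomenology for bistable percept durations) with mean 10 s and SD 3 s,
truncated below at `reaction_time + 2` triplets so no percept is shorter
than the reporting-neutral zone; button presses trail switches by a fixed
reaction time (0.65 s by default, a realistic fast responder). The percept
is encoded in *phase*, not amplitude, because the discriminating signal the
pipeline looks for is phase-borne; the default offsets (π, π/2, π/4)
decay across harmonics.

What the generator does **not** emulate: 1/f background spectra, channel
cross-correlation structure beyond shared harmonics, non-Gaussian or
nonstationary noise, reaction-time variability, and stimulus changes
(control-style df schedules). The noise spectrum of the non-harmonic
residual is not characterized by the phenomenon being modelled; white
Gaussian is an explicit simplifying assumption. Passing tests on this
generator therefore demonstrate correct mechanics and recoverability under
the assumed structure, not performance on real cortical recordings.

## Numerical choices

* **Edge handling.** Standardization and smoothing windows truncate at the
  record boundary rather than padding; no data are fabricated. Decimation
  keeps stride phase 0 (the first sample).
* **Smoothing parity.** A 10 ms window at 1000 Hz is 10 samples; the
  implementation widens even windows to the next odd count (11 samples,
  ±5 ms) so the average is centred.
* **Kernel convention.** The kernel exponent is `d²/ε²` as printed in the
  field's usual form with a squared bandwidth; `squared_bandwidth = FALSE`
  switches to the `d²/ε` convention found in part of the diffusion-maps
  literature. Nearest-neighbour distances for `ε` are plain Euclidean.
* **Symmetrization.** kNN graphs are symmetrized by the union rule (edge
  kept if either endpoint lists the other), which preserves connectivity
  and makes the kernel matrix exactly symmetric before row normalization.
* **Eigensolve.** The Markov matrix is conjugated to its symmetric form
  `D^{1/2} P D^{-1/2}` before solving, so the spectrum is provably real.
  Problems up to 2000 points use a dense symmetric solve — exact and robust
  to degenerate eigenvalue pairs that Krylov iterations can miss on
  perfectly symmetric geometries (e.g. a circle); larger problems use a
  sparse Lanczos solver. Eigenvector signs are fixed so the
  largest-magnitude entry is positive.
* **Dictionary cutoff.** The working rule keeps every eigenvector up to the
  first run of three consecutive *unorganized* vectors. Organization is
  scored three ways, any of which qualifies: harmonic-band concentration
  (≥ 0.3 of spectral power within 0.2 Hz of a triplet harmonic), slow-band
  concentration (≥ 0.3 below half the fundamental — the percept-scale
  coordinates the method exists to find), or spectral peakedness (top 5 %
  of frequency bins holding ≥ 0.5 of the power; a flat noise spectrum
  scores ≈ 0.08). Harmonic concentration alone proved too blunt: on finite
  noisy records, leading eigenvectors are often slow percept coordinates
  with *no* harmonic power, and genuinely harmonic vectors are smeared
  below any reasonable threshold by spectral leakage, so a harmonic-only
  rule truncates the dictionary to the constant vector.
* **eDMD.** The one-step operator is fitted through an SVD pseudoinverse
  with a relative singular-value cutoff of 1e-10 and the effective rank
  reported. Eigenfunctions are normalized to unit RMS with phase rotated so
  the first sample is real and non-negative (conjugate pairs stay
  conjugate); whether such a rescaling should precede mode regression is
  not determined by the method itself, so the convention is fixed and
  documented. Modes are complex least squares on the eigenfunction span,
  with a small ridge fallback when the Gram matrix is ill-conditioned.
* **Branch ranking.** Within a harmonic, pairs are ranked by `|Re ω|`
  ("decay rate smallest in magnitude"), which keeps spurious *unstable*
  eigenvalue estimates (Re ω > 0, a finite-noise artifact) from displacing
  the near-neutral stimulus pair.
* **The slow feature.** `φ*` is the slowest-decaying eigenvalue with
  `|Im ω|/2π < tol_real`, excluding the constant mode, and is required to
  be decaying (Re ω < 0). On finite records of a stochastically switching
  process, the percept mode is often estimated as a near-real conjugate
  pair at roughly `1/(2 × dwell)` Hz rather than an exactly real
  eigenvalue; `tol_real` therefore defaults to a tenth of the fundamental —
  a decade below the harmonic grid yet above the alternation scale — and
  when the winner is a pair, the real part of the positive-frequency member
  is taken and the result is flagged (`phi_star_is_pair`). When several
  candidates qualify the slowest-decay rule applies; this is a convention,
  and the alternatives remain visible in the branch table.
* **Permutation null.** Each draw places the observed number of switches
  uniformly over triplet boundaries by rejection sampling, requiring every
  percept run to exceed the reaction time *and* to survive the re-applied
  neutral zone (runs of at least `ceiling(rt/td) + 1` triplets) — otherwise
  a minimal run would be wholly relabelled neutral and the realized switch
  count would silently drop. Neutral zones follow each switch boundary,
  mirroring how reported presses (which trail switches by RT) are
  labelled.
* **KL divergence.** 25 shared equal-width bins over the pooled range,
  additive smoothing 1e-10, direction KL(two-stream ‖ one-stream) by
  default. Absolute values depend on this dialect; compare divergences only
  across like-configured calls.
* **Prediction conventions.** Threshold crossings use strict inequality on
  the 200 Hz grid; press-to-window matching is greedy earliest-first; a
  matched press is `bp` or `pb` according to its order relative to the
  marked time `t*` (not the window edges). Rotating all phases by π —
  sometimes convenient for display when transitions pass through ±π —
  leaves the predictor and all counts unchanged.

## Problem sizes

The reference operating point (300 s blocks at 1000 Hz, `s = 799`,
`n_eigs = 150`, 10,000 permutations) is what the defaults encode. The test
suite and the acceptance script exercise the full pipeline at a reduced
size chosen to keep a complete run in minutes on one core: 60 s blocks,
`s = 199` (a 1 s embedded window), 60 eigenpairs, and 199–2000
permutations where a null distribution is needed. Bookkeeping identities
(sample counts, embedded-vector counts, spans) are still checked at the
full 300 s scale, where generation and embedding are cheap.

## Known limitations

* The delay matrix is materialized in memory; at the documented problem
  sizes it stays below ~100 MB, but very long recordings at full delay
  depth would need blocked construction.
* Confidence intervals for group medians, where needed, would use plain
  percentile bootstrap; bias-corrected accelerated intervals are not
  implemented.
* Out-of-sample extension of the diffusion basis (Nyström) is not
  provided: the decomposition describes the block it was fitted on.
* With a single recorded channel the manifold reconstruction rests entirely
  on the delay embedding; the generator's default of four channels reflects
  the multi-contact setting the method targets.
* The slow-feature search can legitimately fail (`find_phi_star()` errors)
  when no slow decaying eigenvalue exists — e.g. on stimulus-only data with
  no percept process; this is reported rather than papered over.
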
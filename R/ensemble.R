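## Word-specific oscillator ensembles: spike-rate-adaptation frequency
## profiles, plasticity-optimal decay constants, baseline frequencies and
## the nonword / pair-intersection rules.

#' Ensemble (theta) parameters
#'
#' The parameter block driving the oscillator network: a word-specific
#' ensemble is tuned so that every member's adapting firing frequency
#' passes through the burst frequency `f_b` at the burst time `t_b`.
#'
#' @param t_b Burst time, s (> 0).
#' @param f_b Burst frequency, Hz.
#' @param f_max Maximum (initial) firing frequency, Hz; `f_b <= f_max`.
#' @param A Uniform coupling strength between ensemble members, in Hz-
#'   compatible units; negative values synchronize (see [wco_integrate()]).
#' @param g Mean baseline frequency, Hz (default 10, typical background
#'   alpha).
#' @param g_bandwidth Total width of the uniform baseline distribution
#'   (default `g / 2`, i.e. baselines on `[g - g/4, g + g/4]`).
#' @param seed Integer seed for baseline draws and frozen noise.
#' @return An object of class `ensemble_params`.
#' @export
ensemble_params <- function(t_b = 0.25, f_b = 135, f_max = 200, A = -2,
                            g = 10, g_bandwidth = g / 2, seed = 0L) {
  if (!(t_b > 0)) abort("t_b must be positive")
  if (!(f_b > 0 && f_b <= f_max)) abort("need 0 < f_b <= f_max")
  if (g_bandwidth < 0) abort("g_bandwidth must be >= 0")
  structure(list(t_b = t_b, f_b = f_b, f_max = f_max, A = A, g = g,
                 g_bandwidth = g_bandwidth, seed = as.integer(seed)),
            class = "ensemble_params")
}

#' Plasticity-optimal decay constant for one feature
#'
#' Returns the linear decay rate that takes a detector starting at `f_max`
#' when its feature occurs (time `t_k`) down to exactly `f_b` at the burst
#' time `t_b`.
#'
#' @param t_k Feature occurrence time, s; must precede `t_b`.
#' @param t_b Burst time, s.
#' @param f_b Burst frequency, Hz.
#' @param f_max Maximum firing frequency, Hz.
#' @return Decay constant tau in 1/s; zero when `f_b == f_max`.
#' @export
compute_tau_opt <- function(t_k, t_b, f_b, f_max) {
  if (any(t_k >= t_b)) {
    abort("t_k >= t_b: feature cannot reach f_b by decay")
  }
  if (!(f_b > 0 && f_b <= f_max)) abort("need 0 < f_b <= f_max")
  (1 - f_b / f_max) / (t_b - t_k)
}

#' Adapting transient frequency of a feature detector
#'
#' The firing frequency is zero before the feature occurs, jumps to
#' `f_max` at `t_k` and then decays linearly at rate `tau`, rectified at
#' zero (a firing rate cannot go negative).
#'
#' @param t Time(s) at which to evaluate, s.
#' @param t_k Feature occurrence time, s.
#' @param tau Decay constant, 1/s (>= 0).
#' @param f_max Maximum firing frequency, Hz.
#' @return Frequency in Hz, vectorized over `t`.
#' @export
transient_frequency <- function(t, t_k, tau, f_max) {
  stopifnot(tau >= 0)
  f <- f_max * (1 - tau * (t - t_k))
  f[t < t_k] <- 0
  pmax(f, 0)
}

#' Draw per-oscillator baseline frequencies
#'
#' Baselines are uniform on `[g - bw/2, g + bw/2]` with total bandwidth
#' `bw` (default `g / 2`).
#'
#' @param g Mean baseline frequency, Hz.
#' @param K Number of oscillators.
#' @param seed Integer seed.
#' @param bandwidth Total width of the uniform distribution, Hz.
#' @return Numeric vector of length K.
#' @export
draw_baselines <- function(g, K, seed = 0L, bandwidth = g / 2) {
  stopifnot(g > 0, K >= 1, bandwidth >= 0)
  with_seed(seed, runif(K, g - bandwidth / 2, g + bandwidth / 2))
}

#' Build input-frequency profiles for a word/nonword pair
#'
#' The oscillator set is the intersection of feature identities
#' (band, kind, level) detected in both pair members; decay constants are
#' computed from the WORD feature times and reused for the nonword, and
#' the same baselines serve both members. Features whose word time is at
#' or after `t_b` are excluded from both members (no non-negative decay
#' reaches `f_b`).
#'
#' @param word_features,nonword_features Tibbles from [extract_ot()] for
#'   the two pair members (times relative to stimulus onset).
#' @param params An [ensemble_params()].
#' @param time_axis Simulation time axis, s.
#' @param stim_onset Time of stimulus onset on `time_axis`, s.
#' @param g_k Optional pre-drawn baselines for the full intersection set
#'   (before the `t_b` exclusion); drawn from `params$seed` if `NULL`.
#' @return A list with elements `word` and `nonword`, each of class
#'   `frequency_profiles`: list(freqs = K x T matrix (Hz), time, features,
#'   g_k, tau).
#' @export
build_profiles <- function(word_features, nonword_features, params,
                           time_axis, stim_onset = 0, g_k = NULL) {
  stopifnot(inherits(params, "ensemble_params"))
  ident <- c("band", "kind", "level")
  joined <- dplyr::inner_join(
    dplyr::select(word_features, dplyr::all_of(c(ident, "time"))),
    dplyr::select(nonword_features, dplyr::all_of(c(ident, "time"))),
    by = ident, suffix = c("_word", "_nonword"))
  if (nrow(joined) == 0) {
    abort("empty feature intersection between word and nonword")
  }
  if (is.null(g_k)) {
    g_k <- draw_baselines(params$g, nrow(joined), seed = params$seed,
                          bandwidth = params$g_bandwidth)
  } else if (length(g_k) != nrow(joined)) {
    abort("g_k must have one entry per intersected feature")
  }
  keep <- which(joined$time_word < params$t_b)
  joined <- joined[keep, , drop = FALSE]
  g_k <- g_k[keep]
  if (nrow(joined) == 0) {
    abort("no features precede t_b; ensemble is empty")
  }
  tau <- compute_tau_opt(joined$time_word, params$t_b, params$f_b,
                         params$f_max)
  make_profiles <- function(times) {
    K <- length(times)
    freqs <- matrix(0, nrow = K, ncol = length(time_axis))
    for (k in seq_len(K)) {
      freqs[k, ] <- transient_frequency(time_axis, times[k] + stim_onset,
                                        tau[k], params$f_max) + g_k[k]
    }
    structure(list(freqs = freqs, time = time_axis,
                   features = joined[, ident], g_k = g_k, tau = tau,
                   keep = keep),
              class = "frequency_profiles")
  }
  list(word = make_profiles(joined$time_word),
       nonword = make_profiles(joined$time_nonword))
}

#' @export
print.frequency_profiles <- function(x, ...) {
  cat(sprintf("<frequency_profiles: %d oscillators x %d timepoints>\n",
              nrow(x$freqs), ncol(x$freqs)))
  invisible(x)
}
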
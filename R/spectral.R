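## Multitaper log-spectrograms, word-minus-nonword differential
## spectrograms, trial variability, and the forward map from ensemble
## parameters to a predicted differential spectrogram.

#' Spectrogram configuration
#'
#' Defaults mirror the analysis applied to the cortical recordings the
#' model is aimed at: 256-sample windows (0.128 s at 2003 Hz), 32-sample
#' hop, time-bandwidth product 3 with 5 Slepian tapers, log transform.
#'
#' @param window Window length N, samples.
#' @param hop Window offset, samples (`<= window`).
#' @param nw Time-bandwidth product NW.
#' @param n_tapers Number of Slepian tapers (`<= 2 * nw - 1`).
#' @param sample_rate Sample rate, Hz.
#' @param log_floor Power floor applied before the log; `NULL` uses
#'   `1e-6 * max(power)` (a 60 dB display range, with a tiny absolute
#'   fallback for silence). The floor keeps taper-sidelobe leakage in
#'   spectrally empty bands from dominating log differences.
#' @return An object of class `spectrogram_config`.
#' @export
spectrogram_config <- function(window = 256, hop = 32, nw = 3,
                               n_tapers = 2 * nw - 1, sample_rate = 2003,
                               log_floor = NULL) {
  if (hop > window) abort("hop must be <= window")
  if (n_tapers > 2 * nw - 1) abort("n_tapers must be <= 2 * nw - 1")
  structure(list(window = window, hop = hop, nw = nw, n_tapers = n_tapers,
                 sample_rate = sample_rate, log_floor = log_floor),
            class = "spectrogram_config")
}

#' Frequency resolution of a multitaper configuration
#'
#' The time-bandwidth product is the window length times the half
#' bandwidth W in radians per sample; expressed in Hz this is
#' `nw * sample_rate / (window * 2 * pi)` (3.7 Hz for the defaults).
#'
#' @param config A [spectrogram_config()].
#' @return Resolution in Hz.
#' @export
mt_frequency_resolution <- function(config) {
  config$nw * config$sample_rate / (config$window * 2 * pi)
}

# Discrete prolate spheroidal (Slepian) tapers via the symmetric
# tridiagonal eigenproblem; unit-energy, leading lobe made positive.
dpss_tapers <- function(n, nw, k) {
  key <- sprintf("dpss_%d_%g_%d", n, nw, k)
  if (!is.null(.wcots_cache[[key]])) return(.wcots_cache[[key]])
  w <- nw / n
  tt <- 0:(n - 1)
  M <- diag(((n - 1 - 2 * tt) / 2)^2 * cos(2 * pi * w))
  off <- tt[-1] * (n - tt[-1]) / 2
  M[cbind(1:(n - 1), 2:n)] <- off
  M[cbind(2:n, 1:(n - 1))] <- off
  V <- eigen(M, symmetric = TRUE)$vectors[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) if (sum(V[, j]) < 0) V[, j] <- -V[, j]
  .wcots_cache[[key]] <- V
  V
}

#' Multitaper log-spectrogram
#'
#' Windowed Slepian-tapered power averaged over tapers, then
#' log-transformed with a power floor guarding zeros. Window timestamps
#' are at window centers.
#'
#' @param x Numeric signal; at least one window long.
#' @param config A [spectrogram_config()].
#' @param t0 Time of the first sample, s (shifts the time axis).
#' @return An object of class `wcots_spectrogram`: list with `values`
#'   (F x T log-power), `freq` (Hz), `time` (s).
#' @export
multitaper_spectrogram <- function(x, config = spectrogram_config(),
                                   t0 = 0) {
  mt <- mt_power(x, config, t0 = t0)
  floor_p <- config$log_floor %||% max(1e-6 * max(mt$P), 1e-300)
  structure(
    list(values = log(pmax(mt$P, floor_p)), freq = mt$freq, time = mt$time),
    class = "wcots_spectrogram")
}

# Raw multitaper power (no log): Slepian-tapered windowed power averaged
# over tapers.
mt_power <- function(x, config, t0 = 0) {
  N <- config$window
  if (length(x) < N) abort("signal shorter than one spectrogram window")
  starts <- seq(1, length(x) - N + 1, by = config$hop)
  idx <- outer(seq_len(N) - 1L, starts, "+")
  frames <- matrix(x[idx], nrow = N)
  tapers <- dpss_tapers(N, config$nw, config$n_tapers)
  nf <- N %/% 2 + 1
  P <- matrix(0, nrow = nf, ncol = length(starts))
  for (j in seq_len(config$n_tapers)) {
    Fj <- mvfft(frames * tapers[, j])
    P <- P + Mod(Fj[seq_len(nf), , drop = FALSE])^2
  }
  list(P = P / config$n_tapers,
       freq = (seq_len(nf) - 1) * config$sample_rate / N,
       time = t0 + (starts - 1 + (N - 1) / 2) / config$sample_rate)
}

#' @export
print.wcots_spectrogram <- function(x, ...) {
  cat(sprintf("<wcots_spectrogram: %d freqs x %d windows, %.1f-%.1f Hz>\n",
              nrow(x$values), ncol(x$values), min(x$freq), max(x$freq)))
  invisible(x)
}

#' Average word-minus-nonword differential spectrogram
#'
#' Elementwise mean over pairs of the word spectrogram minus the nonword
#' spectrogram.
#'
#' @param word_spectrograms,nonword_spectrograms Lists of
#'   [multitaper_spectrogram()] results, paired by position.
#' @return An object of class `wcots_diffspec`: list with `values`,
#'   `freq`, `time`, `n_pairs`.
#' @export
differential_spectrogram <- function(word_spectrograms,
                                     nonword_spectrograms) {
  n <- length(word_spectrograms)
  if (n != length(nonword_spectrograms) || n == 0) {
    abort("need equal, non-zero counts of word and nonword spectrograms")
  }
  ref <- word_spectrograms[[1]]
  acc <- matrix(0, nrow = nrow(ref$values), ncol = ncol(ref$values))
  for (i in seq_len(n)) {
    gw <- word_spectrograms[[i]]; gn <- nonword_spectrograms[[i]]
    if (!all(dim(gw$values) == dim(ref$values)) ||
        !all(dim(gn$values) == dim(ref$values)) ||
        max(abs(gw$freq - ref$freq)) > 1e-9 ||
        max(abs(gn$time - ref$time)) > 1e-9) {
      abort("spectrogram shapes or axes do not match across pairs")
    }
    acc <- acc + (gw$values - gn$values)
  }
  structure(list(values = acc / n, freq = ref$freq, time = ref$time,
                 n_pairs = n),
            class = "wcots_diffspec")
}

#' @export
print.wcots_diffspec <- function(x, ...) {
  cat(sprintf("<wcots_diffspec: %d freqs x %d windows, %d pairs>\n",
              nrow(x$values), ncol(x$values), x$n_pairs))
  invisible(x)
}

#' Sample per-trial burst time and frequency
#'
#' Lets the burst time and frequency vary over trials. In the default
#' multiplicative convention a variability parameter `delta` of 0.2 means
#' the per-trial value ranges uniformly over +/- 20% of the ensemble
#' value: `t_b_i = t_b * (1 - delta_t + 2 delta_t z_i)` with `z_i`
#' uniform on `[0, 1]`. The literal additive form
#' `(1 - delta) t_b + 2 delta z_i` is available for comparison.
#'
#' @param theta List with `t_b`, `f_b` and variabilities `delta_t`,
#'   `delta_f` in `[0, 1)`.
#' @param n Number of trials.
#' @param seed Integer seed (the draws are frozen per fitting run).
#' @param form `"multiplicative"` (default) or `"additive"`.
#' @return Tibble with columns `t_b_i`, `f_b_i` of length `n`.
#' @export
sample_trial_variability <- function(theta, n, seed = 0L,
                                     form = c("multiplicative", "additive")) {
  form <- match.arg(form)
  dt_ <- theta$delta_t %||% 0
  df_ <- theta$delta_f %||% 0
  stopifnot(dt_ >= 0, dt_ < 1, df_ >= 0, df_ < 1)
  zw <- with_seed(seed, list(z = runif(n), w = runif(n)))
  if (form == "multiplicative") {
    tibble(t_b_i = theta$t_b * (1 - dt_ + 2 * dt_ * zw$z),
           f_b_i = theta$f_b * (1 - df_ + 2 * df_ * zw$w))
  } else {
    tibble(t_b_i = (1 - dt_) * theta$t_b + 2 * dt_ * zw$z,
           f_b_i = (1 - df_) * theta$f_b + 2 * df_ * zw$w)
  }
}

#' Extract occurrence-time features for every member of a pair set
#'
#' Feature extraction is independent of the ensemble parameters, so a
#' fitting run does it once up front.
#'
#' @param pairs Tibble from [generate_pair_set()].
#' @param fb_config A [filterbank_config()] matching the audio sample
#'   rate.
#' @param ot_cfg An [ot_config()]; the default keeps the 300 ms feature
#'   cutoff.
#' @return Tibble with columns `pair_id`, `word_features`,
#'   `nonword_features` (list columns of feature tibbles).
#' @export
prepare_pair_features <- function(pairs,
                                  fb_config = filterbank_config(),
                                  ot_cfg = ot_config()) {
  purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    wf <- extract_ot(band_envelopes(pairs$word[[i]], fb_config), ot_cfg)
    nf <- extract_ot(band_envelopes(pairs$nonword[[i]], fb_config), ot_cfg)
    tibble(pair_id = pairs$pair_id[i], word_features = list(wf),
           nonword_features = list(nf))
  })
}

# Count the feature-identity intersection of a prepared pair (before any
# t_b exclusion); fixes the dimensions of the frozen noise.
intersection_size <- function(word_features, nonword_features) {
  nrow(dplyr::inner_join(word_features, nonword_features,
                         by = c("band", "kind", "level"),
                         suffix = c("_w", "_n")))
}

#' Draw the frozen stochastic terms for a forward-model run
#'
#' All randomness of the forward model — per-pair baselines, initial
#' phases, state noise, and per-trial burst variability draws — is drawn
#' once per fitting run so the likelihood is a deterministic function of
#' the parameters.
#'
#' @param prepared Tibble from [prepare_pair_features()].
#' @param n_time Number of simulation time steps.
#' @param seed Integer seed.
#' @param kappa von Mises noise precision (`Inf` for none).
#' @param g,g_bandwidth Baseline distribution (Hz).
#' @return A list with per-pair elements `g_k`, `phi0`, `noise`, plus
#'   `z`, `w` (trial variability uniforms).
#' @export
freeze_forward_noise <- function(prepared, n_time, seed = 0L, kappa = 10,
                                 g = 10, g_bandwidth = g / 2) {
  n <- nrow(prepared)
  with_seed(seed, {
    per_pair <- lapply(seq_len(n), function(i) {
      K_full <- intersection_size(prepared$word_features[[i]],
                                  prepared$nonword_features[[i]])
      K_full <- max(K_full, 1L)
      list(g_k = runif(K_full, g - g_bandwidth / 2, g + g_bandwidth / 2),
           phi0 = runif(K_full, 0, 2 * pi),
           noise = if (is.finite(kappa)) {
             matrix(rvonmises(K_full * n_time, kappa), nrow = K_full)
           } else {
             matrix(0, nrow = K_full, ncol = n_time)
           })
    })
    list(per_pair = per_pair, z = runif(n), w = runif(n))
  })
}

#' Forward model: predicted differential spectrogram
#'
#' For each stimulus pair the model builds the ensemble frequency
#' profiles, integrates the coupled phase dynamics twice — once with the
#' proposed coupling `A` and once with `A = 0` (the no-synchronization
#' baseline) — computes the two LFPs, resamples them to the analysis
#' rate and takes multitaper log-spectrograms. The prediction is the mean
#' word-minus-nonword spectral difference of the coupled runs minus that
#' of the uncoupled runs, so that any spectral difference not caused by
#' synchronization cancels.
#'
#' @param theta Named list of parameters: `t_b` (s), `f_b`, `f_max` (Hz),
#'   `A`, optionally `delta_t`, `delta_f` (trial variability) and
#'   `beta1`, `beta2` (frequency-dependent coupling).
#' @param prepared Tibble from [prepare_pair_features()].
#' @param frozen Frozen stochastic terms from [freeze_forward_noise()];
#'   drawn from `seed` when `NULL`.
#' @param seed Integer seed used when `frozen` is `NULL`.
#' @param wco_cfg A [wco_config()]; its `dt` sets the simulation rate.
#' @param spec_cfg A [spectrogram_config()] for the analysis-rate
#'   spectrograms.
#' @param sim_duration Simulated epoch length, s.
#' @param stim_onset Stimulus onset within the simulated epoch, s; the
#'   output time axis is reported relative to stimulus onset.
#' @param g,g_bandwidth Baseline frequency distribution, Hz.
#' @return A `wcots_diffspec` with the predicted difference `D`.
#' @export
forward_model <- function(theta, prepared, frozen = NULL, seed = 0L,
                          wco_cfg = wco_config(), spec_cfg = spectrogram_config(),
                          sim_duration = 1.2, stim_onset = 0.2,
                          g = 10, g_bandwidth = g / 2) {
  check_theta(theta)
  sim_rate <- 1 / wco_cfg$dt
  n_time <- round(sim_duration * sim_rate)
  time_axis <- (seq_len(n_time) - 1) * wco_cfg$dt
  n <- nrow(prepared)
  if (is.null(frozen)) {
    frozen <- freeze_forward_noise(prepared, n_time, seed = seed,
                                   kappa = wco_cfg$kappa, g = g,
                                   g_bandwidth = g_bandwidth)
  }
  trial <- tibble(t_b_i = rep(theta$t_b, n), f_b_i = rep(theta$f_b, n))
  if (!is.null(theta$delta_t) || !is.null(theta$delta_f)) {
    dt_ <- theta$delta_t %||% 0; df_ <- theta$delta_f %||% 0
    trial <- tibble(
      t_b_i = theta$t_b * (1 - dt_ + 2 * dt_ * frozen$z),
      f_b_i = theta$f_b * (1 - df_ + 2 * df_ * frozen$w))
  }
  gw_s <- vector("list", n); gn_s <- vector("list", n)
  gw_0 <- vector("list", n); gn_0 <- vector("list", n)
  for (i in seq_len(n)) {
    fz <- frozen$per_pair[[i]]
    params <- ensemble_params(t_b = trial$t_b_i[i],
                              f_b = min(trial$f_b_i[i], theta$f_max),
                              f_max = theta$f_max, A = theta$A, g = g,
                              g_bandwidth = g_bandwidth)
    prof <- build_profiles(prepared$word_features[[i]],
                           prepared$nonword_features[[i]], params,
                           time_axis, stim_onset = stim_onset,
                           g_k = fz$g_k)
    keep <- prof$word$keep
    phi0 <- fz$phi0[keep]
    noise <- fz$noise[keep, , drop = FALSE]
    power_of <- function(profiles, A) {
      cs <- coupling_scale_matrix(theta, profiles)
      tr <- wco_integrate(profiles, A, wco_cfg, coupling_scale = cs,
                          phi0 = phi0, noise = noise)
      y <- resample_fft(lfp(tr)$y, sim_rate, spec_cfg$sample_rate)
      mt_power(y, spec_cfg, t0 = -stim_onset)
    }
    raw <- list(power_of(prof$word, theta$A),
                power_of(prof$nonword, theta$A),
                power_of(prof$word, 0),
                power_of(prof$nonword, 0))
    # one shared power floor per pair so spectrally empty bins cancel
    # exactly in the differences
    floor_p <- spec_cfg$log_floor %||%
      max(1e-6 * max(vapply(raw, function(r) max(r$P), numeric(1))), 1e-300)
    logged <- lapply(raw, function(r) {
      structure(list(values = log(pmax(r$P, floor_p)), freq = r$freq,
                     time = r$time),
                class = "wcots_spectrogram")
    })
    gw_s[[i]] <- logged[[1]]; gn_s[[i]] <- logged[[2]]
    gw_0[[i]] <- logged[[3]]; gn_0[[i]] <- logged[[4]]
  }
  Ds <- differential_spectrogram(gw_s, gn_s)
  D0 <- differential_spectrogram(gw_0, gn_0)
  structure(list(values = Ds$values - D0$values, freq = Ds$freq,
                 time = Ds$time, n_pairs = n),
            class = "wcots_diffspec")
}

# Frequency-dependent coupling modulation (augmented-model placeholder):
# oscillators whose instantaneous input frequency exceeds beta2 * f_max
# get their coupling multiplied by (1 + beta1); others are unmodulated.
coupling_scale_matrix <- function(theta, profiles) {
  if (is.null(theta$beta1) && is.null(theta$beta2)) return(NULL)
  b1 <- theta$beta1 %||% 0; b2 <- theta$beta2 %||% 1
  ifelse(profiles$freqs > b2 * theta$f_max, 1 + b1, 1)
}

check_theta <- function(theta) {
  for (nm in c("t_b", "f_b", "f_max", "A")) {
    if (is.null(theta[[nm]]) || !is.finite(theta[[nm]])) {
      abort(sprintf("theta$%s is missing or non-finite", nm))
    }
  }
  if (theta$t_b <= 0) abort("theta violates bound: t_b must be > 0")
  if (theta$f_b <= 0) abort("theta violates bound: f_b must be > 0")
  if (theta$f_max < theta$f_b) {
    abort("theta violates bound: f_max must be >= f_b")
  }
  invisible(theta)
}
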
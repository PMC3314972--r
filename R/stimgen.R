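## Synthetic stimulus generation: word-like narrowband signals with
## controlled per-band onset/peak/offset times, paired "nonword" surrogates
## with scrambled temporal structure, and labelled digit-like datasets.

#' Specify a synthetic word-like stimulus
#'
#' A word is a sum over frequency bands of narrowband carriers with smooth
#' (raised-cosine) amplitude envelopes. Each band is described by an event
#' triple: the envelope rises from zero at `onset`, is maximal at `peak`
#' and has returned to zero by `offset`.
#'
#' @param band_events Data frame with columns `center_frequency` (Hz),
#'   `onset`, `peak`, `offset` (seconds) and `amplitude` (unitless, > 0).
#'   May have zero rows, in which case the word is silence.
#' @param duration Total signal duration in seconds.
#' @param sample_rate Sample rate in Hz; must exceed twice the highest
#'   carrier frequency.
#' @param seed Integer seed controlling the (random) carrier phases.
#' @return An object of class `word_spec`.
#' @export
word_spec <- function(band_events, duration = 1.0, sample_rate = 8000,
                      seed = 0L) {
  band_events <- as_tibble(band_events)
  required <- c("center_frequency", "onset", "peak", "offset", "amplitude")
  if (!all(required %in% names(band_events))) {
    abort(paste("band_events needs columns:", paste(required, collapse = ", ")))
  }
  if (nrow(band_events) > 0) {
    bad <- which(!(band_events$onset < band_events$peak &
                     band_events$peak < band_events$offset &
                     band_events$offset <= duration))
    if (length(bad) > 0) {
      abort(sprintf(
        "band %d violates onset < peak < offset <= duration (%.3f, %.3f, %.3f)",
        bad[1], band_events$onset[bad[1]], band_events$peak[bad[1]],
        band_events$offset[bad[1]]))
    }
    if (any(band_events$amplitude <= 0)) {
      abort(sprintf("band %d has non-positive amplitude",
                    which(band_events$amplitude <= 0)[1]))
    }
    if (sample_rate <= 2 * max(band_events$center_frequency)) {
      abort("sample_rate must exceed twice the highest center frequency")
    }
  }
  structure(
    list(band_events = band_events, duration = duration,
         sample_rate = sample_rate, seed = as.integer(seed)),
    class = "word_spec")
}

#' @export
print.word_spec <- function(x, ...) {
  cat(sprintf("<word_spec: %d bands, %.3f s @ %g Hz, seed %d>\n",
              nrow(x$band_events), x$duration, x$sample_rate, x$seed))
  print(x$band_events)
  invisible(x)
}

# Raised-cosine envelope: attack onset -> peak, decay peak -> offset.
raised_cosine_envelope <- function(t, onset, peak, offset) {
  env <- numeric(length(t))
  up <- t >= onset & t < peak
  down <- t >= peak & t <= offset
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - onset) / (peak - onset)))
  env[down] <- 0.5 * (1 + cos(pi * (t[down] - peak) / (offset - peak)))
  env
}

#' Synthesize the audio signal for a word specification
#'
#' @param spec A [word_spec()].
#' @return Numeric vector of length `duration * sample_rate`, deterministic
#'   given the spec (including its seed).
#' @export
generate_word <- function(spec) {
  stopifnot(inherits(spec, "word_spec"))
  n <- round(spec$duration * spec$sample_rate)
  t <- (seq_len(n) - 1) / spec$sample_rate
  x <- numeric(n)
  if (nrow(spec$band_events) == 0) return(x)
  phases <- with_seed(spec$seed,
                      runif(nrow(spec$band_events), 0, 2 * pi))
  for (b in seq_len(nrow(spec$band_events))) {
    ev <- spec$band_events[b, ]
    env <- raised_cosine_envelope(t, ev$onset, ev$peak, ev$offset)
    x <- x + ev$amplitude * env * sin(2 * pi * ev$center_frequency * t +
                                        phases[b])
  }
  x
}

# Permute the (onset, peak, offset) event-time triples across bands so the
# carriers keep their frequencies but fire in a scrambled temporal order.
permute_spec_times <- function(spec, seed) {
  nb <- nrow(spec$band_events)
  if (nb < 2) return(spec)
  perm <- with_seed(seed, {
    p <- sample.int(nb)
    tries <- 0
    while (all(p == seq_len(nb)) && tries < 50) {
      p <- sample.int(nb); tries <- tries + 1
    }
    if (all(p == seq_len(nb))) p <- c(nb, seq_len(nb - 1))
    p
  })
  ev <- spec$band_events
  ev$onset <- spec$band_events$onset[perm]
  ev$peak <- spec$band_events$peak[perm]
  ev$offset <- spec$band_events$offset[perm]
  word_spec(ev, spec$duration, spec$sample_rate, spec$seed)
}

# Short-time Fourier transform helpers for the modulation-filter scramble.
stft_mat <- function(x, nfft, hop) {
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nfft) / (nfft + 1))  # hann
  starts <- seq(1, length(x) - nfft + 1, by = hop)
  frames <- vapply(starts, function(s) x[s:(s + nfft - 1)] * w,
                   numeric(nfft))
  list(S = mvfft(frames), window = w, starts = starts, nfft = nfft,
       hop = hop, n = length(x))
}

istft_mat <- function(S, window, starts, nfft, hop, n) {
  frames <- Re(mvfft(S, inverse = TRUE)) / nfft
  x <- numeric(n)
  wsum <- numeric(n)
  for (j in seq_along(starts)) {
    idx <- starts[j]:(starts[j] + nfft - 1)
    x[idx] <- x[idx] + frames[, j] * window
    wsum[idx] <- wsum[idx] + window^2
  }
  x / pmax(wsum, 1e-8)
}

# Remove slow joint time-frequency modulations from the log-magnitude
# spectrogram and resynthesize with random phase. `frac_t`/`frac_f` give the
# zeroed fraction of the temporal/spectral modulation axes (0 = identity).
modulation_filter_scramble <- function(word, sample_rate, seed,
                                       frac_t = 0.15, frac_f = 0.15,
                                       nfft = 256, hop = 64) {
  st <- stft_mat(word, nfft, hop)
  mag <- abs(st$S)
  logmag <- log(mag + 1e-8)
  if (frac_t > 0 || frac_f > 0) {
    M <- fft(logmag)  # 2-D FFT (matrix method of stats::fft)
    nf <- nrow(M); nt <- ncol(M)
    kf <- pmin(0:(nf - 1), nf - (0:(nf - 1)))   # symmetric mod-freq index
    kt <- pmin(0:(nt - 1), nt - (0:(nt - 1)))
    zero_f <- kf <= frac_f * (nf / 2)
    zero_t <- kt <= frac_t * (nt / 2)
    kill <- outer(zero_f, zero_t, "&")
    kill[1, 1] <- FALSE  # keep overall mean level
    M[kill] <- 0
    logmag <- Re(fft(M, inverse = TRUE)) / (nf * nt)
  }
  new_mag <- exp(logmag) - 1e-8
  new_mag[new_mag < 0] <- 0
  phase <- with_seed(seed,
                     matrix(runif(length(new_mag), 0, 2 * pi), nrow(new_mag)))
  # enforce conjugate symmetry so the inverse transform is real
  nf <- nrow(new_mag)
  phase[1, ] <- 0
  if (nf %% 2 == 0) phase[nf / 2 + 1, ] <- 0
  upper <- 2:ceiling(nf / 2)
  phase[nf - upper + 2, ] <- -phase[upper, ]
  S_new <- new_mag * exp(1i * phase)
  istft_mat(S_new, st$window, st$starts, st$nfft, st$hop, st$n)
}

#' Generate a nonword surrogate for a word
#'
#' Produces a signal with the same duration and root-mean-square power as
#' the word but with its slow temporal structure destroyed, either by
#' permuting the per-band event times (`"ot_permute"`) or by removing slow
#' joint time-frequency modulations from the log spectrogram and
#' resynthesizing with random phase (`"modulation_filter"`).
#'
#' @param word Numeric signal (the paired word).
#' @param spec The [word_spec()] that generated `word`; required for
#'   `"ot_permute"`, used for the sample rate otherwise.
#' @param method Scramble method.
#' @param seed Integer seed for the scramble.
#' @param frac_t,frac_f Zeroed fractions of the temporal/spectral modulation
#'   axes for `"modulation_filter"` (0 = identity reconstruction).
#' @return Numeric signal of the same length as `word`, RMS-matched to it.
#' @export
generate_nonword <- function(word, spec,
                             method = c("ot_permute", "modulation_filter"),
                             seed = 0L, frac_t = 0.15, frac_f = 0.15) {
  if (length(word) == 0) abort("word signal is empty")
  method <- match.arg(method)
  y <- switch(method,
    ot_permute = generate_word(permute_spec_times(spec, seed)),
    modulation_filter = modulation_filter_scramble(
      word, spec$sample_rate, seed, frac_t = frac_t, frac_f = frac_f))
  rms_w <- root_mean_square(word)
  rms_y <- root_mean_square(y)
  if (rms_y > 0) y <- y * (rms_w / rms_y)
  y
}

#' Default template ranges for random word specifications
#'
#' The ranges place all band events inside the first 300 ms of the
#' stimulus, the window within which occurrence-time features drive the
#' oscillator ensemble.
#'
#' @param n_bands_range,center_range,onset_range,rise_range,decay_range,amplitude_range
#'   Two-element numeric ranges drawn from uniformly.
#' @param duration,sample_rate Passed to [word_spec()].
#' @return A list of template ranges for [generate_pair_set()].
#' @export
pair_template <- function(n_bands_range = c(4, 6),
                          center_range = c(300, 3000),
                          onset_range = c(0.02, 0.18),
                          rise_range = c(0.04, 0.09),
                          decay_range = c(0.04, 0.10),
                          amplitude_range = c(0.6, 1.0),
                          duration = 1.0, sample_rate = 8000) {
  list(n_bands_range = n_bands_range, center_range = center_range,
       onset_range = onset_range, rise_range = rise_range,
       decay_range = decay_range, amplitude_range = amplitude_range,
       duration = duration, sample_rate = sample_rate)
}

# Draw one word_spec from template ranges.
draw_word_spec <- function(template, seed) {
  with_seed(seed, {
    nb_range <- seq(template$n_bands_range[1], template$n_bands_range[2])
    nb <- if (length(nb_range) == 1) nb_range else sample(nb_range, 1)
    centers <- sort(runif(nb, template$center_range[1],
                          template$center_range[2]))
    onset <- runif(nb, template$onset_range[1], template$onset_range[2])
    peak <- onset + runif(nb, template$rise_range[1], template$rise_range[2])
    offset <- peak + runif(nb, template$decay_range[1],
                           template$decay_range[2])
    amp <- runif(nb, template$amplitude_range[1], template$amplitude_range[2])
    word_spec(
      tibble(center_frequency = centers, onset = onset, peak = peak,
             offset = offset, amplitude = amp),
      duration = template$duration, sample_rate = template$sample_rate,
      seed = seed)
  })
}

#' Generate a set of word/nonword stimulus pairs
#'
#' @param n Number of pairs (>= 1).
#' @param template Template ranges from [pair_template()].
#' @param seed Integer master seed; each pair derives its own child seed.
#' @param scramble_method Passed to [generate_nonword()].
#' @return A tibble with columns `pair_id`, `seed`, `spec` (list of
#'   [word_spec()]), `word` and `nonword` (list columns of signals) and
#'   `scramble_method`.
#' @export
generate_pair_set <- function(n, template = pair_template(), seed = 0L,
                              scramble_method = "ot_permute") {
  if (n < 1) abort("n must be >= 1")
  purrr::map_dfr(seq_len(n), function(i) {
    s <- child_seed(seed, i)
    spec <- draw_word_spec(template, s)
    word <- generate_word(spec)
    nonword <- generate_nonword(word, spec, method = scramble_method,
                                seed = child_seed(s, 1))
    tibble(pair_id = i, seed = s, spec = list(spec), word = list(word),
           nonword = list(nonword), scramble_method = scramble_method)
  })
}

#' Write a pair set to disk as WAV files plus a manifest
#'
#' Each stimulus is written as a float32 WAV with a JSON sidecar holding
#' the generating specification; a `manifest.csv` indexes the set.
#'
#' @param pairs Tibble from [generate_pair_set()].
#' @param dir Output directory (created if needed).
#' @return The manifest path, invisibly.
#' @export
write_pair_set <- function(pairs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- purrr::pmap_dfr(pairs, function(pair_id, seed, spec, word,
                                          nonword, scramble_method) {
    wp <- file.path(dir, sprintf("pair%03d_word.wav", pair_id))
    np <- file.path(dir, sprintf("pair%03d_nonword.wav", pair_id))
    write_wav(word, wp, spec$sample_rate, bits = 32L)
    write_wav(nonword, np, spec$sample_rate, bits = 32L)
    jsonlite::write_json(
      list(band_events = spec$band_events, duration = spec$duration,
           sample_rate = spec$sample_rate, seed = spec$seed,
           scramble_method = scramble_method),
      file.path(dir, sprintf("pair%03d_spec.json", pair_id)),
      auto_unbox = TRUE, digits = NA)
    tibble(pair_id = pair_id, word_path = wp, nonword_path = np, seed = seed)
  })
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(rows, manifest, row.names = FALSE)
  invisible(manifest)
}

#' Generate a labelled synthetic digit-like dataset
#'
#' Each class is defined by a distinct word template; exemplars are
#' globally time-warped and jittered copies of it, split into disjoint
#' train and test sets. This emulates an isolated-word corpus (distinct
#' word identities, speaking-rate variation, small articulation jitter)
#' without reproducing any real speech statistics.
#'
#' @param n_classes Number of word classes (>= 2).
#' @param n_train,n_test Exemplars per class in each split.
#' @param warp_range Range of the global time-warp factor applied to every
#'   event time of an exemplar; must lie within (0.25, 4), the span of
#'   natural speaking-rate variation.
#' @param jitter_sd Standard deviation (s) of additive Gaussian jitter on
#'   event times after warping.
#' @param template Template ranges from [pair_template()].
#' @param seed Integer master seed.
#' @param shared_centers If `TRUE`, every class uses the same carrier
#'   frequencies (drawn once), so classes differ only in their temporal
#'   event patterns; useful for isolating timing-based discrimination.
#' @return A tibble with columns `class`, `split`, `exemplar`, `warp`,
#'   `spec` (list) and `signal` (list).
#' @export
generate_digit_dataset <- function(n_classes = 10, n_train = 5, n_test = 5,
                                   warp_range = c(0.7, 1.4),
                                   jitter_sd = 0.005,
                                   template = pair_template(), seed = 0L,
                                   shared_centers = FALSE) {
  if (n_classes < 2) abort("n_classes must be >= 2")
  if (warp_range[1] <= 0.25 || warp_range[2] >= 4) {
    abort("warp_range must lie strictly inside (0.25, 4)")
  }
  shared <- if (shared_centers) {
    draw_word_spec(template, child_seed(seed, 0))$band_events$center_frequency
  }
  if (shared_centers) {
    template$n_bands_range <- rep(length(shared), 2)
  }
  grid <- tidyr::expand_grid(
    class = seq_len(n_classes),
    split = c(rep("train", n_train), rep("test", n_test)))
  grid$exemplar <- stats::ave(grid$class, grid$class, FUN = seq_along)
  purrr::pmap_dfr(grid, function(class, split, exemplar) {
    class_seed <- child_seed(seed, class)
    base <- draw_word_spec(template, class_seed)
    if (shared_centers) {
      base$band_events <- base$band_events[seq_along(shared), ]
      base$band_events$center_frequency <- shared
    }
    ex_seed <- child_seed(class_seed, 100 + exemplar)
    draws <- with_seed(ex_seed, {
      list(warp = runif(1, warp_range[1], warp_range[2]),
           jit = matrix(rnorm(3 * nrow(base$band_events), 0, jitter_sd),
                        ncol = 3))
    })
    ev <- base$band_events
    ev$onset <- ev$onset * draws$warp + draws$jit[, 1]
    ev$peak <- ev$peak * draws$warp + draws$jit[, 2]
    ev$offset <- ev$offset * draws$warp + draws$jit[, 3]
    # keep the event triples valid after jitter
    ev$onset <- pmax(ev$onset, 0.001)
    ev$peak <- pmax(ev$peak, ev$onset + 0.005)
    ev$offset <- pmin(pmax(ev$offset, ev$peak + 0.005), base$duration)
    ev$peak <- pmin(ev$peak, ev$offset - 0.001)
    sp <- word_spec(ev, base$duration, base$sample_rate, ex_seed)
    tibble(class = class, split = split, exemplar = exemplar,
           warp = draws$warp, spec = list(sp),
           signal = list(generate_word(sp)))
  })
}
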
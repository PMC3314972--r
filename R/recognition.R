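## Isolated-word recognition benchmark: occurrence-time and MFCC front
## ends into an identical first-nearest-neighbour back end, with additive
## white or babble noise at controlled signal levels.

#' MFCC configuration
#'
#' Standard mel-frequency cepstral pipeline settings: pre-emphasis,
#' Hamming-windowed frames, mel filterbank, log, discrete cosine
#' transform.
#'
#' @param n_cepstra Cepstral coefficients kept per frame (default 18).
#' @param t_fix Fixed analysis period, s: frames are laid out over
#'   `[0, t_fix]` and frames past the end of a signal are all-zero, so
#'   every vector has the same length.
#' @param frame_length,frame_hop Frame size and hop, s.
#' @param n_mel_filters Number of triangular mel filters.
#' @param preemphasis Pre-emphasis coefficient.
#' @param sample_rate Sample rate, Hz.
#' @return An object of class `mfcc_config`.
#' @export
mfcc_config <- function(n_cepstra = 18, t_fix = 1.0, frame_length = 0.025,
                        frame_hop = 0.010, n_mel_filters = 26,
                        preemphasis = 0.97, sample_rate = 8000) {
  if (n_cepstra < 1) abort("n_cepstra must be >= 1")
  if (frame_hop > frame_length) abort("frame_hop must be <= frame_length")
  if (t_fix <= 0) abort("t_fix must be positive")
  structure(list(n_cepstra = n_cepstra, t_fix = t_fix,
                 frame_length = frame_length, frame_hop = frame_hop,
                 n_mel_filters = n_mel_filters, preemphasis = preemphasis,
                 sample_rate = sample_rate),
            class = "mfcc_config")
}

# Triangular mel filterbank matrix (n_filters x n_fft_bins).
mel_filterbank <- function(n_filters, nfft, sample_rate) {
  key <- sprintf("mel_%d_%d_%g", n_filters, nfft, sample_rate)
  if (!is.null(.wcots_cache[[key]])) return(.wcots_cache[[key]])
  nb <- nfft %/% 2 + 1
  mel_pts <- seq(hz_to_mel(0), hz_to_mel(sample_rate / 2),
                 length.out = n_filters + 2)
  bin <- floor((nfft + 1) * mel_to_hz(mel_pts) / sample_rate) + 1
  H <- matrix(0, nrow = n_filters, ncol = nb)
  for (m in seq_len(n_filters)) {
    lo <- bin[m]; ce <- bin[m + 1]; hi <- bin[m + 2]
    if (ce > lo) H[m, lo:ce] <- (lo:ce - lo) / (ce - lo)
    if (hi > ce) H[m, ce:hi] <- (hi - ce:hi) / (hi - ce)
  }
  .wcots_cache[[key]] <- H
  H
}

# Orthonormal DCT-II matrix rows 2..(K+1) (the 0th coefficient is dropped).
dct_matrix <- function(K, n) {
  key <- sprintf("dct_%d_%d", K, n)
  if (!is.null(.wcots_cache[[key]])) return(.wcots_cache[[key]])
  D <- sqrt(2 / n) * cos(pi * outer(seq_len(K), (seq_len(n) - 0.5)) / n)
  .wcots_cache[[key]] <- D
  D
}

#' Fixed-length MFCC feature vector
#'
#' Frames the signal over `[0, t_fix]`; per frame: pre-emphasis, Hamming
#' window, power spectrum, mel filterbank, log, DCT, first `n_cepstra`
#' coefficients (excluding the 0th). Frames past the end of the signal are
#' all-zero, so vector length is `n_cepstra * n_frames` independent of
#' signal length.
#'
#' @param x Numeric signal.
#' @param config An [mfcc_config()].
#' @return Numeric vector.
#' @export
mfcc_features <- function(x, config = mfcc_config()) {
  if (length(x) == 0) abort("signal is empty")
  fs <- config$sample_rate
  flen <- round(config$frame_length * fs)
  fhop <- round(config$frame_hop * fs)
  n_frames <- max(1L, floor((config$t_fix * fs - flen) / fhop) + 1L)
  xe <- c(x[1], x[-1] - config$preemphasis * x[-length(x)])
  ham <- 0.54 - 0.46 * cos(2 * pi * (seq_len(flen) - 1) / (flen - 1))
  H <- mel_filterbank(config$n_mel_filters, flen, fs)
  Dm <- dct_matrix(config$n_cepstra, config$n_mel_filters)
  out <- matrix(0, nrow = config$n_cepstra, ncol = n_frames)
  for (j in seq_len(n_frames)) {
    s <- (j - 1L) * fhop + 1L
    e <- s + flen - 1L
    if (s > length(xe)) next                 # frame entirely past the signal
    frame <- xe[s:min(e, length(xe))]
    if (length(frame) < flen) frame <- c(frame, numeric(flen - length(frame)))
    spec <- Mod(fft(frame * ham)[seq_len(flen %/% 2 + 1)])^2
    melE <- as.numeric(H %*% spec)
    out[, j] <- Dm %*% log(pmax(melE, 1e-30))
  }
  as.numeric(out)
}

#' First-nearest-neighbour classification and word error rate
#'
#' Each test vector receives the label of its Euclidean-nearest training
#' vector; exact distance ties resolve to the lowest-index training
#' exemplar, so predictions are deterministic.
#'
#' @param train_x Numeric matrix (training exemplars in rows).
#' @param train_y Training labels.
#' @param test_x Numeric matrix (test exemplars in rows).
#' @param test_y Optional true test labels; enables the WER.
#' @return A list with `predictions` and (when `test_y` given) `wer`,
#'   the fraction of misclassified test exemplars.
#' @export
nn_classify <- function(train_x, train_y, test_x, test_y = NULL) {
  train_x <- as.matrix(train_x); test_x <- as.matrix(test_x)
  if (nrow(train_x) == 0) abort("empty training set")
  if (ncol(train_x) != ncol(test_x)) abort("inconsistent vector lengths")
  # squared Euclidean distances via the expansion |a-b|^2 = |a|^2+|b|^2-2ab
  cross <- tcrossprod(test_x, train_x)
  d2 <- outer(rowSums(test_x^2), rowSums(train_x^2), "+") - 2 * cross
  nearest <- apply(d2, 1, which.min)   # which.min takes the first minimum
  pred <- train_y[nearest]
  out <- list(predictions = pred)
  if (!is.null(test_y)) out$wer <- mean(pred != test_y)
  out
}

#' Add noise at a controlled signal level
#'
#' The signal level in dB is `S = 20 log10(sigma_s / sigma_e)` where
#' `sigma_s` and `sigma_e` are the signal and noise standard deviations;
#' the noise is scaled so this holds exactly. White noise is seeded
#' Gaussian; babble is a seeded superposition of many word-like signals
#' (a surrogate for a crowd-of-speakers recording).
#'
#' @param x Numeric signal with positive standard deviation.
#' @param kind `"white"` or `"babble"`.
#' @param snr_db Signal level S in dB.
#' @param seed Integer seed.
#' @param n_voices Number of superposed voices for babble.
#' @param sample_rate Sample rate, Hz (babble synthesis).
#' @return Noisy signal, same length as `x`.
#' @export
add_noise <- function(x, kind = c("white", "babble"), snr_db = 20,
                      seed = 0L, n_voices = 12, sample_rate = 8000) {
  kind <- match.arg(kind)
  sigma_s <- sd(x)
  if (!(sigma_s > 0)) abort("signal has zero variance")
  e <- switch(kind,
    white = with_seed(seed, rnorm(length(x))),
    babble = babble_noise(length(x), n_voices, seed, sample_rate))
  e <- e - mean(e)
  sigma_target <- sigma_s / 10^(snr_db / 20)
  x + e * (sigma_target / sd(e))
}

# Sum of word-like signals at random offsets, long enough to cover n.
babble_noise <- function(n, n_voices, seed, sample_rate) {
  template <- pair_template(sample_rate = sample_rate,
                            duration = n / sample_rate)
  e <- numeric(n)
  for (v in seq_len(n_voices)) {
    sv <- child_seed(seed, v)
    spec <- draw_word_spec(template, sv)
    voice <- generate_word(spec)
    shift <- with_seed(child_seed(sv, 7), sample(n, 1))
    e <- e + c(voice[-seq_len(shift)], voice[seq_len(shift)])
  }
  e
}

# Feature matrix for a split of a digit dataset.
dataset_features <- function(signals, feature_kind, fb_cfg, ot_cfg,
                             mfcc_cfg, matched_length = NULL) {
  vecs <- lapply(signals, function(x) {
    switch(feature_kind,
      ot = ot_feature_vector(
        extract_ot(band_envelopes(x, fb_cfg), ot_cfg),
        B = fb_cfg$n_bands, config = ot_cfg),
      mfcc = mfcc_features(x, mfcc_cfg),
      mfcc_matched = {
        v <- mfcc_features(x, mfcc_cfg)
        length(v) <- matched_length     # truncate/pad to the OT length
        v[is.na(v)] <- 0
        v
      })
  })
  do.call(rbind, vecs)
}

#' Word error rate across signal levels
#'
#' Trains a first-nearest-neighbour classifier on clean exemplars and
#' tests on noise-corrupted test exemplars at each signal level.
#' `"mfcc_matched"` truncates the MFCC vector to the dimensionality of
#' the OT vector (`B * (2L + 1)`).
#'
#' @param dataset Tibble from [generate_digit_dataset()].
#' @param feature_kind `"ot"`, `"mfcc"` or `"mfcc_matched"`.
#' @param snr_list Numeric vector of signal levels in dB; `Inf` tests
#'   clean signals.
#' @param noise_kind `"white"` or `"babble"`.
#' @param seed Integer seed for the noise.
#' @param fb_cfg Filterbank for the OT front end (mel spacing by
#'   default, 11 bands).
#' @param ot_cfg Occurrence-time settings (7 intensity levels and warp
#'   normalization by default).
#' @param mfcc_cfg MFCC settings; `t_fix` defaults to the longest
#'   training exemplar.
#' @return Tibble with columns `snr_db`, `feature_kind`, `wer`.
#' @export
wer_curve <- function(dataset, feature_kind = c("ot", "mfcc", "mfcc_matched"),
                      snr_list = c(60, 20, 0), noise_kind = "white",
                      seed = 0L,
                      fb_cfg = filterbank_config(n_bands = 11,
                                                 spacing = "mel"),
                      ot_cfg = ot_config(n_levels = 7,
                                         cutoff_time = NULL,
                                         warp_normalize = TRUE),
                      mfcc_cfg = NULL) {
  feature_kind <- match.arg(feature_kind)
  if (length(snr_list) == 0) abort("snr_list must be non-empty")
  train <- dataset[dataset$split == "train", ]
  test <- dataset[dataset$split == "test", ]
  if (is.null(mfcc_cfg)) {
    t_fix <- max(vapply(train$signal, length, numeric(1))) /
      train$spec[[1]]$sample_rate
    mfcc_cfg <- mfcc_config(t_fix = t_fix,
                            sample_rate = train$spec[[1]]$sample_rate)
  }
  matched <- fb_cfg$n_bands * (2 * ot_cfg$n_levels + 1)
  train_x <- dataset_features(train$signal, feature_kind, fb_cfg, ot_cfg,
                              mfcc_cfg, matched)
  purrr::map_dfr(snr_list, function(snr) {
    noisy <- lapply(seq_len(nrow(test)), function(i) {
      if (is.infinite(snr)) return(test$signal[[i]])
      add_noise(test$signal[[i]], kind = noise_kind, snr_db = snr,
                seed = child_seed(seed, i),
                sample_rate = test$spec[[i]]$sample_rate)
    })
    test_x <- dataset_features(noisy, feature_kind, fb_cfg, ot_cfg,
                               mfcc_cfg, matched)
    res <- nn_classify(train_x, train$class, test_x, test$class)
    tibble(snr_db = snr, feature_kind = feature_kind, wer = res$wer)
  })
}
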
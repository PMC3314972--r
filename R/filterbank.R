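## FIR filterbank front end: least-squares bandpass filters applied
## forward and reverse (zero phase), followed by Hilbert envelopes.

#' Filterbank configuration
#'
#' @param n_bands Number of contiguous bands B.
#' @param f_min,f_max_band Band edges of the whole bank, Hz.
#' @param spacing `"linear"` or `"mel"`; mel spacing places band edges
#'   uniformly on the mel scale.
#' @param fir_order FIR filter order (even, default 80).
#' @param sample_rate Sample rate of the signals to be filtered, Hz.
#' @return An object of class `filterbank_config`.
#' @export
filterbank_config <- function(n_bands = 11, f_min = 100, f_max_band = 4000,
                              spacing = c("linear", "mel"), fir_order = 80,
                              sample_rate = 8000) {
  spacing <- match.arg(spacing)
  if (!(f_min > 0 && f_min < f_max_band && f_max_band <= sample_rate / 2)) {
    abort("need 0 < f_min < f_max_band <= sample_rate/2")
  }
  if (n_bands < 1) abort("n_bands must be >= 1")
  if (fir_order < 2 || fir_order %% 2 != 0) {
    abort("fir_order must be even and >= 2")
  }
  structure(list(n_bands = n_bands, f_min = f_min, f_max_band = f_max_band,
                 spacing = spacing, fir_order = fir_order,
                 sample_rate = sample_rate),
            class = "filterbank_config")
}

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

# Band edges tiling [f_min, f_max_band] on the configured scale.
band_edges <- function(config) {
  if (config$spacing == "mel") {
    mel_to_hz(seq(hz_to_mel(config$f_min), hz_to_mel(config$f_max_band),
                  length.out = config$n_bands + 1))
  } else {
    seq(config$f_min, config$f_max_band, length.out = config$n_bands + 1)
  }
}

# Least-squares linear-phase (type I) FIR design on a dense frequency grid.
# `bands` is a matrix with rows (f_lo, f_hi, amp_lo, amp_hi) in Hz; the
# desired amplitude is piecewise linear over the rows.
firls_design <- function(order, bands, sample_rate, grid_density = 16) {
  half <- order / 2
  fgrid <- unlist(lapply(seq_len(nrow(bands)), function(i) {
    seq(bands[i, 1], bands[i, 2], length.out = grid_density * (half + 1) /
          nrow(bands))
  }))
  dgrid <- unlist(lapply(seq_len(nrow(bands)), function(i) {
    seq(bands[i, 3], bands[i, 4], length.out = grid_density * (half + 1) /
          nrow(bands))
  }))
  wn <- fgrid / sample_rate          # cycles per sample
  C <- cbind(1, cos(2 * pi * outer(wn, seq_len(half))))
  a <- qr.solve(crossprod(C), crossprod(C, dgrid))
  # expand the cosine-series coefficients into the symmetric impulse response
  h <- c(rev(a[-1] / 2), a[1], a[-1] / 2)
  as.numeric(h)
}

#' Design the bandpass filterbank
#'
#' Builds B least-squares FIR bandpass filters whose passbands tile
#' `[f_min, f_max_band]` on the configured scale. Bands too narrow for the
#' filter order get a widened transition with a warning.
#'
#' @param config A [filterbank_config()].
#' @return A list of class `filterbank` with elements `coefficients`
#'   (list of impulse responses), `centers` (Hz), `edges` (Hz) and the
#'   config.
#' @export
design_filterbank <- function(config) {
  stopifnot(inherits(config, "filterbank_config"))
  key <- paste0("fb_", paste(unlist(config), collapse = "_"))
  if (!is.null(.wcots_cache[[key]])) return(.wcots_cache[[key]])
  edges <- band_edges(config)
  nyq <- config$sample_rate / 2
  # narrowest band the order can separate cleanly (one main-lobe width)
  tw_min <- config$sample_rate / config$fir_order
  coefs <- vector("list", config$n_bands)
  centers <- numeric(config$n_bands)
  for (b in seq_len(config$n_bands)) {
    lo <- edges[b]; hi <- edges[b + 1]
    centers[b] <- if (config$spacing == "mel") {
      mel_to_hz((hz_to_mel(lo) + hz_to_mel(hi)) / 2)
    } else {
      (lo + hi) / 2
    }
    tw <- (hi - lo) * 0.4
    if (hi - lo < tw_min) {
      warn(sprintf(
        "band %d (%.0f-%.0f Hz) narrower than achievable at order %d; widening transition",
        b, lo, hi, config$fir_order))
      tw <- tw_min / 2
    }
    f1 <- max(lo - tw, 0); f2 <- min(hi + tw, nyq)
    bands <- rbind(
      if (f1 > 0) c(0, f1, 0, 0),
      c(f1, lo, 0, 1),
      c(lo, hi, 1, 1),
      c(hi, f2, 1, 0),
      if (f2 < nyq) c(f2, nyq, 0, 0))
    coefs[[b]] <- firls_design(config$fir_order, bands, config$sample_rate)
  }
  out <- structure(list(coefficients = coefs, centers = centers,
                        edges = edges, config = config),
                   class = "filterbank")
  .wcots_cache[[key]] <- out
  out
}

#' Evaluate the frequency response of one filter
#'
#' @param h Impulse response (numeric vector).
#' @param freqs Frequencies at which to evaluate, Hz.
#' @param sample_rate Sample rate, Hz.
#' @return Complex response at `freqs`.
#' @export
filter_response <- function(h, freqs, sample_rate) {
  k <- seq_along(h) - 1
  vapply(freqs, function(f) sum(h * exp(-2i * pi * f * k / sample_rate)),
         complex(1))
}

# FFT convolution keeping alignment of a delay-`delay` kernel.
fft_conv_aligned <- function(x, g, delay) {
  L <- length(x) + length(g) - 1
  nfft <- 2^ceiling(log2(L))
  y <- Re(fft(fft(c(x, numeric(nfft - length(x)))) *
                fft(c(g, numeric(nfft - length(g)))), inverse = TRUE)) / nfft
  y[(delay + 1):(delay + length(x))]
}

# Zero-phase filtering: reflection-pad by the filter order, convolve with
# the forward-reverse kernel conv(h, rev(h)), crop the padding.
zero_phase_filter <- function(x, h) {
  M <- length(h) - 1
  if (length(x) <= M + 1) abort("signal too short for zero-phase filtering")
  pad_head <- x[(M + 1):2]
  pad_tail <- x[(length(x) - 1):(length(x) - M)]
  xp <- c(pad_head, x, pad_tail)
  g <- fft_conv_aligned(c(h, numeric(length(h) - 1)), rev(h), 0)  # conv(h, rev(h))
  g <- g[seq_len(2 * M + 1)]
  y <- fft_conv_aligned(xp, g, M)
  y[(M + 1):(M + length(x))]
}

# Analytic-signal magnitude via the FFT.
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- fft(x)
  hmul <- numeric(n)
  if (n %% 2 == 0) {
    hmul[1] <- 1; hmul[n / 2 + 1] <- 1; hmul[2:(n / 2)] <- 2
  } else {
    hmul[1] <- 1; hmul[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(X * hmul, inverse = TRUE) / n)
}

#' Band envelopes of a signal
#'
#' Applies each bandpass filter in forward and reverse directions (zero
#' phase distortion) and computes the Hilbert envelope of each band.
#'
#' @param x Numeric signal; must be longer than three filter orders.
#' @param config A [filterbank_config()].
#' @return An object of class `envelope_set`: list with `envelopes`
#'   (B x T matrix), `time` (s), `centers` (Hz), `sample_rate`.
#' @export
band_envelopes <- function(x, config) {
  if (length(x) <= 3 * config$fir_order) {
    abort("signal too short: need length > 3 * fir_order")
  }
  fb <- design_filterbank(config)
  env <- matrix(0, nrow = config$n_bands, ncol = length(x))
  for (b in seq_len(config$n_bands)) {
    filtered <- zero_phase_filter(x, fb$coefficients[[b]])
    env[b, ] <- hilbert_envelope(filtered)
  }
  structure(list(envelopes = env,
                 time = (seq_along(x) - 1) / config$sample_rate,
                 centers = fb$centers, sample_rate = config$sample_rate),
            class = "envelope_set")
}

#' @export
print.envelope_set <- function(x, ...) {
  cat(sprintf("<envelope_set: %d bands x %d samples @ %g Hz>\n",
              nrow(x$envelopes), ncol(x$envelopes), x$sample_rate))
  invisible(x)
}
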
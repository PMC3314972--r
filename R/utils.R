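## Small internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards. All generators in the package are pure
# functions of (arguments, seed) through this gate.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  withr::with_seed(as.integer(seed), expr)
}

# Derive a child seed from a parent seed and a stream index, staying well
# inside 32-bit integer range.
child_seed <- function(seed, stream) {
  (as.integer(seed) * 1103L + as.integer(stream) * 12289L) %% 2147483000L
}

root_mean_square <- function(x) sqrt(mean(x^2))

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Centered FFT-domain resampling of a real signal from `fs_in` to `fs_out`.
# Band-limited interpolation: the spectrum is zero-padded (upsampling) or
# truncated (downsampling) and rescaled so amplitudes are preserved.
resample_fft <- function(x, fs_in, fs_out) {
  n <- length(x)
  m <- max(2L, round(n * fs_out / fs_in))
  X <- fft(x)
  Y <- complex(m)
  nh <- min(n, m)
  half <- floor(nh / 2)
  idx_pos <- seq_len(half + 1L)              # DC .. positive freqs
  Y[idx_pos] <- X[idx_pos]
  if (half > 0) {
    idx_neg_src <- n - seq_len(half) + 1L
    idx_neg_dst <- m - seq_len(half) + 1L
    Y[idx_neg_dst] <- X[idx_neg_src]
  }
  # when upsampling past an even-length input, the old Nyquist bin is split
  # between its positive- and negative-frequency copies
  if (m > n && n %% 2L == 0L) {
    Y[half + 1L] <- Y[half + 1L] / 2
    Y[m - half + 1L] <- Y[m - half + 1L] / 2
  }
  Re(fft(Y, inverse = TRUE)) * (m / n) / m
}

# Linear interpolation of threshold-crossing time between samples i and i+1.
interp_crossing <- function(t1, t2, v1, v2, level) {
  if (v2 == v1) return(t1)
  t1 + (level - v1) / (v2 - v1) * (t2 - t1)
}
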
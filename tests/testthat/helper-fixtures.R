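# Shared fixtures, memoized so expensive objects are built once per run.

.fixture_env <- new.env()

# The standard 10-pair fixture with prepared occurrence-time features.
get_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    .fixture_env$fx <- standard_fixture(n_pairs = 10, seed = 1)
  }
  .fixture_env$fx
}

# Target differential spectrogram generated by the forward model at the
# fixture's reference parameters (frozen noise seed 1).
get_fixture_target <- function() {
  if (is.null(.fixture_env$Y)) {
    fx <- get_fixture()
    .fixture_env$Y <- forward_model(fx$theta, fx$prepared, seed = 1,
                                    wco_cfg = fx$wco_cfg,
                                    spec_cfg = fx$spec_cfg)
  }
  .fixture_env$Y
}

# A single-band test word: 1 kHz carrier, raised-cosine envelope rising at
# 0.1 s, peaking at 0.3 s, gone by 0.5 s.
one_band_word <- function(fs = 8000) {
  word_spec(data.frame(center_frequency = 1000, onset = 0.1, peak = 0.3,
                       offset = 0.5, amplitude = 1),
            duration = 1, sample_rate = fs, seed = 0)
}

# Wrap a plain envelope matrix as an envelope_set (synthetic envelopes let
# feature-extraction tests use analytically known crossing times).
as_envelope_set <- function(env, sample_rate = 1000,
                            centers = seq_len(nrow(env))) {
  structure(list(envelopes = env,
                 time = (seq_len(ncol(env)) - 1) / sample_rate,
                 centers = centers, sample_rate = sample_rate),
            class = "envelope_set")
}

# Kolmogorov-Smirnov statistic against a uniform on [lo, hi] (avoids the
# ties warning from stats::ks.test on thinned MCMC draws).
ks_stat_unif <- function(x, lo, hi) {
  u <- sort((x - lo) / (hi - lo))
  n <- length(u)
  max(abs(u - (seq_len(n) - 0.5) / n)) + 0.5 / n
}
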
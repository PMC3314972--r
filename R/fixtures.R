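## The standard synthetic fixture: a reproducible 10-pair word/nonword
## set plus the reference parameter point used throughout the examples,
## tests and the acceptance script.

#' Standard synthetic fixture
#'
#' Ten word/nonword pairs with band events confined to the first 300 ms,
#' an 11-band linear filterbank front end with single-level
#' occurrence-time detectors, and the reference parameter point
#' `t_b = 0.25 s, f_b = 135 Hz, f_max = 200 Hz, A = -2` (the midpoint
#' region of the fitting priors).
#'
#' @param n_pairs Number of pairs.
#' @param seed Integer master seed.
#' @param prepare Also extract occurrence-time features (slower).
#' @return A list with `pairs`, `theta`, `fb_cfg`, `ot_cfg`, `wco_cfg`,
#'   `spec_cfg` and (if `prepare`) `prepared`.
#' @export
standard_fixture <- function(n_pairs = 10, seed = 1L, prepare = TRUE) {
  fb_cfg <- filterbank_config(n_bands = 11, f_min = 100, f_max_band = 4000,
                              spacing = "linear", sample_rate = 8000)
  ot_cfg <- ot_config(n_levels = 1, cutoff_time = 0.300)
  pairs <- generate_pair_set(n_pairs, pair_template(), seed = seed,
                             scramble_method = "ot_permute")
  out <- list(pairs = pairs,
              theta = list(t_b = 0.25, f_b = 135, f_max = 200, A = -2),
              fb_cfg = fb_cfg, ot_cfg = ot_cfg,
              wco_cfg = wco_config(noise_seed = seed),
              spec_cfg = spectrogram_config())
  if (prepare) out$prepared <- prepare_pair_features(pairs, fb_cfg, ot_cfg)
  out
}
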
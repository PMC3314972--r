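# wcots

Transient synchronization modelling of auditory-cortex gamma activity with
weakly coupled oscillators, plus an occurrence-time speech-recognition
benchmark.

## The problem

When the brain recognizes a spoken word, electrocorticographic recordings
over superior temporal cortex show a brief burst of high-gamma (75–150 Hz)
power that is absent for acoustically matched nonwords. `wcots` implements
a dynamical model of that recognition event and everything needed to test
it end to end:

1. **Feature extraction.** Audio is bandpass-filtered into B channels
   (least-squares FIR filters applied forward and reverse, so zero phase
   distortion) and each channel's Hilbert envelope `s_b(t)` yields
   **Occurrence Times (OTs)**: the envelope's threshold onsets, offsets
   and peak per band, optionally at multiple intensity levels.
2. **Spike-rate adaptation.** Each detected feature `k` drives a neural
   oscillator that starts firing at `f_max` and decays linearly,
   `f_k(t) = f_max (1 − τ_k (t − t_k)) · h[t − t_k]`, rectified at zero.
   Plasticity is modelled by choosing `τ_k = (1 − f_b/f_max)/(t_b − t_k)`
   so that for the trained word *all* ensemble frequencies equal the burst
   frequency `f_b` at the burst time `t_b` (the "many-are-equal" code).
3. **Weakly coupled oscillators.** Phases follow
   `dφ_k/dt = 2π f_k(t) − Σ_k′ 2πA sin(φ_k′ − φ_k) + e_k`, integrated by
   Euler–Maruyama with frozen von Mises noise (κ = 10). When the
   frequencies coincide, negative coupling `A` locks the phases and the
   summed field `y(t) = Σ_k cos φ_k` — the model LFP — bursts with power
   up to `K²`. Scrambled (nonword) inputs never reach frequency equality
   and produce no burst: recognition is signalled by transient
   synchronization. A global time warp of the input moves the burst to
   `α·t_b` — warp invariance for free.
4. **Forward model and fitting.** Simulated LFPs are resampled to 2003 Hz
   and turned into multitaper log-spectrograms (N = 256, hop 32, NW = 3);
   the predicted word-minus-nonword differential spectrogram (with the
   zero-coupling baseline subtracted) is compared to a target by
   projecting onto the target's first singular vector, and the parameters
   `θ = (t_b, f_b, f_max, A)` are sampled by Metropolis–Hastings under
   uniform box priors, with posterior-harmonic-mean model evidence.
5. **Recognition benchmark.** OT feature vectors (11 mel bands × 15
   detectors = 165 features, warp-normalized) against standard MFCCs,
   both into an identical 1-nearest-neighbour back end, under additive
   white or babble noise at exact signal levels
   `S = 20 log10(σ_s/σ_e)` dB.

Everything runs on synthetic stimuli generated by the package (real
cortical recordings and licensed speech corpora are not distributable),
so every stage is testable.

## Worked example

```r
library(wcots)

fx <- standard_fixture(n_pairs = 10, seed = 1)   # words + scrambled nonwords
D  <- forward_model(fx$theta, fx$prepared, seed = 1,
                    wco_cfg = fx$wco_cfg, spec_cfg = fx$spec_cfg)
i  <- which(D$values == max(D$values), arr.ind = TRUE)
c(freq = D$freq[i[1]], time = D$time[i[2]])
#>       freq       time
#> 133.011719   0.215127
```

The predicted spectral difference peaks at 133 Hz, 0.215 s after stimulus
onset — a high-gamma burst at the trained burst time (`t_b` = 0.25 s,
`f_b` = 135 Hz), present for words and absent for their time-scrambled
pairs. Fitting the minimal model back to its own output recovers the
generating parameters:

```r
chain <- fit_wcots(D, fx$prepared, variant = "M0",
                   config = mh_config(n_iter = 500, n_burn = 250, seed = 1),
                   seed = 1, wco_cfg = fx$wco_cfg, spec_cfg = fx$spec_cfg)
glance(chain)
#> # A tibble: 1 x 5
#>   n_samples n_parameters acceptance_rate max_log_lik log_evidence
#> 1       250            4            0.6      -0.0802       -0.119
quantile(chain$samples$t_b, c(0.05, 0.95))   # 90% interval contains 0.25
#>     5%    95%
#>  0.214  0.294
```

`autoplot()` works on spectrograms, differential spectrograms, envelope
sets, LFP traces and chains; `tidy()` turns any of them into a tibble.

For the recognition benchmark:

```r
ds <- generate_digit_dataset(n_classes = 4, n_train = 4, n_test = 4, seed = 6)
wer_curve(ds, "ot", snr_list = c(60, 20, 0))
#> # A tibble: 3 x 3
#>   snr_db feature_kind   wer
#> 1     60 ot           0
#> 2     20 ot           0.5
#> 3      0 ot           0.875
```

A thin command-line launcher is installed at `cli/wcots.R` (subcommands
`synth`, `features`, `forward`, `fit`, `evidence`, `recognize`).

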
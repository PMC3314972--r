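---
title: "Transient synchronization as a model of recognition-locked gamma activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transient synchronization as a model of recognition-locked gamma activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wcots)
```

## The model

`wcots` implements a dynamical account of why auditory cortex emits a brief
high-gamma burst when a known word is heard but not when an acoustically
matched nonword is heard. The account has four stages.

**Occurrence-time features.** The stimulus is bandpass-filtered into $B$
channels with order-80 least-squares FIR filters, applied forward and
reverse so that filtering adds no phase delay, and each channel's Hilbert
envelope $s_b(t)$ is reduced to a handful of event times: the first upward
and last downward crossings of one or more intensity thresholds (onsets and
offsets) and the envelope maximum (peak). For the cortical forward model
only features earlier than 300 ms are used — recognition must precede the
end of the word.

**Spike-rate adaptation.** Each detected feature $k$ excites a detector
that starts firing at $f_{\max}$ and adapts linearly,

$$f_k(t) = f_{\max}\,\bigl(1 - \tau_k\,(t - t_k)\bigr)\,h[t - t_k],$$

where $h$ gates the response until the feature occurs at $t_k$. The
package rectifies the decay at zero — a firing rate cannot be negative — so
after the transient the detector relaxes to a baseline rate $g_k$, drawn
uniformly from $[g - g/4,\, g + g/4]$ with $g = 10$ Hz (background alpha).

**Plasticity-optimal decays.** Learning a word amounts to choosing, for
each of its features, the decay constant that makes all ensemble
frequencies pass through a common burst frequency $f_b$ at a common burst
time $t_b$:

$$\tau_k^{\mathrm{opt}} = \frac{1 - f_b/f_{\max}}{t_b - t_k}.$$

This "many-are-equal" code is exact (machine precision in the tests) and
carries time-warp invariance: if every feature time is scaled by $\alpha$,
the frequencies of the *stored* ensemble become equal again at
$\alpha\,t_b$, at the value $f_{\max}(1 - \alpha(1 - f_b/f_{\max}))$,
provided $\alpha < f_{\max}/(f_{\max} - f_b)$ so the rectifier has not yet
engaged. Both identities are asserted exactly in the test suite.

**Weakly coupled oscillators.** Each detector is a phase oscillator,

$$\dot\varphi_k = 2\pi f_k(t)
  - \sum_{k'} 2\pi A \sin(\varphi_{k'} - \varphi_k) + e_k,$$

with uniform all-to-all coupling $A$ (zero self-coupling) and zero-mean von
Mises state noise $e_k$ of precision $\kappa = 10$. With the sine
interaction function and the subtractive convention above, *negative* $A$
is the synchronizing direction; the two-oscillator reduction
$\Delta\dot\varphi = -4\pi|A|\sin\Delta\varphi$ is checked against its
closed-form (Adler) solution to $10^{-3}$ rad. The local field potential is
$y(t) = \sum_k \cos\varphi_k$, so full phase alignment yields $|y| = K$ and
the expected field power, normalized by $K/2$, is
$1 + e^{-\sigma^2}(K - 1)$ for Gaussian phase scatter $\sigma^2$ — the
Monte-Carlo oracle in the tests uses exactly that normalization.

For a word, all transients meet at $f_b$ at $t_b$, coupling locks the
phases, and the field bursts at $\approx f_b + g$. For a paired nonword the
same stored decay constants are applied to scrambled feature times, the
frequencies never coincide, and no burst occurs. On the standard synthetic
fixture the ratio of mean peak LFP power (word over nonword, in a
$\pm 50$ ms window around $t_b$) is about 3.

## From field to spectrogram to posterior

Model LFPs are integrated at a 2.5 ms step, resampled to 2003 Hz and
converted to multitaper log-spectrograms with 256-sample windows
(0.128 s), 32-sample hop (0.016 s), time-bandwidth product $NW = 3$ and 5
Slepian tapers — the same settings as the recordings the model addresses.
The reported frequency resolution of 3.7 Hz follows the radian convention
$NW \cdot f_s / (2\pi N)$; in the usual cycles-per-sample convention the
same tapers smooth over $NW \cdot f_s / N \approx 23$ Hz, which is why a
pure tone's spectral peak is flat over roughly $\pm 2$ bins.

The model's prediction is the mean word-minus-nonword log-power difference
$D_s$ minus the same quantity with coupling switched off, $D_0$; the
subtraction removes every spectral difference not caused by
synchronization (at $A = 0$, $D$ is identically zero). Fitting minimizes a
projection error: model and target difference matrices are scaled to unit
Frobenius norm, both are projected onto the first left singular vector of
the target, and the error is the RMS difference of the two time courses.
The log likelihood is $-E/\lambda$ ($\lambda = 1$ by default; it is
exposed because it sets the posterior width). Parameters are sampled by
random-walk Metropolis–Hastings under uniform box priors ($t_b$ 200–300 ms,
$f_b$ 120–150 Hz, $f_{\max}$ 150–250 Hz, $A$ $-3$–$0$), with per-parameter
proposal standard deviation equal to the prior range over $S = 8$
(12.5 ms, 3.75 Hz, 12.5 Hz, 0.375); out-of-box proposals are rejected
without a likelihood evaluation. Model evidence uses the posterior
harmonic mean, computed in log space.

All stochastic terms — baselines, initial phases, state noise, trial
variability draws — are frozen once per fitting run, so the likelihood is
a deterministic function of the parameters; the tests re-evaluate a stored
sample and reproduce its likelihood bit for bit.

Two augmented variants exist. `M1` lets the burst time and frequency vary
across trials; a variability parameter of 0.2 means a uniform $\pm 20\%$
multiplicative spread (the percentage reading; a literal additive form is
available via `form = "additive"` in `sample_trial_variability()`). `M2`
additionally modulates coupling by frequency. The defining functional form
for that modulation was not available, so the shipped rule — coupling
scaled by $1 + \beta_1$ for oscillators whose instantaneous frequency
exceeds $\beta_2 f_{\max}$ — is an explicitly labelled placeholder behind a
pluggable interface; `M0` is the supported headline model.

## What the synthetic data emulate — and what they do not

No cortical recordings or speech corpora ship with the package, so every
stage runs on generated stimuli:

- **Words** are sums of narrowband carriers with raised-cosine envelopes
  (analytically invertible, so the extractor's outputs have closed-form
  expected values). The standard template spreads band onsets over
  0.02–0.18 s. Temporal diversity matters: if all bands fire nearly
  together, a time-scrambled nonword is almost indistinguishable from its
  word and the burst loses specificity.
- **Nonwords** either rebuild the word with event-time triples permuted
  across bands (`ot_permute`, the default: it preserves the multiset of
  event times exactly) or remove slow joint time–frequency modulations
  from the log spectrogram and resynthesize with random phase
  (`modulation_filter`; fidelity of the inversion is not a goal, only the
  destruction of slow modulations). Both are RMS-matched to the word.
- **Digit-like datasets** give each class its own template and generate
  exemplars as globally time-warped (default factor 0.7–1.4; speech shows
  up to four-fold rate variation) and jittered (5 ms) copies. With
  `shared_centers = TRUE` all classes use one spectral layout, isolating
  timing as the only class cue.
- **Babble noise** is a superposition of generated word-like signals — a
  surrogate for a crowd recording, matched in spirit, not in acoustics.

Passing tests therefore demonstrate the *mechanisms* — exact frequency
convergence, warp scaling, synchronization specificity, parameter
recovery — not performance on real speech or real cortical data, whose
headline error rates and fits depend on corpora this package cannot ship.

## Numerical choices

- **Integration step.** Euler integration of a phase equation is exact for
  the frequency term at any step size, so the 2.5 ms default is limited
  only by the coupling and by what the sampled waveform can represent.
  The integrator refuses a step only when an oscillator would advance a
  full cycle per step; note that onset transients at
  $f_{\max} + g \approx 210$ Hz exceed the 200 Hz Nyquist limit of the
  sampled *waveform*, which briefly aliases the cosine readout but leaves
  the phase dynamics themselves exact. The Adler oracle runs at a 0.05 ms
  step, where the $O(\mathrm{d}t)$ Euler error is below the $10^{-3}$ rad
  tolerance.
- **Noise scaling.** The von Mises noise is bounded, not Brownian, and is
  added once per step without $\sqrt{\mathrm{d}t}$ scaling; its effective
  magnitude therefore depends on the step, and changing `dt` with noise
  enabled warns.
- **Resampling.** The 400 Hz model LFP is resampled to 2003 Hz in the
  Fourier domain (exact for band-limited signals; the test suite checks a
  periodic two-tone signal to $10^{-9}$). The output length rounds to the
  nearest sample, a 0.017% clock difference that is irrelevant at
  spectrogram resolution.
- **Log floor.** Spectrogram powers are floored at $10^{-6}$ of the
  maximum (a 60 dB display range) before the log. Inside the forward model
  the floor is *shared* across the four spectrograms of a pair, so
  spectrally empty bins cancel exactly in the differential; with a much
  lower floor, taper-sidelobe leakage in empty bands dominates the log
  differences.
- **Thresholds.** Intensity level $\ell$ of $L$ sits at $\ell/(L+1)$ of the
  band's maximum envelope (amplitude-invariant); an absolute mode exists
  for fidelity experiments. Crossing times are linearly interpolated
  between samples. Bands whose maximum envelope is below 5% of the
  loudest band's emit no features — detectors do not fire on filter
  leakage or faint background; without this gate, silent bands of the
  synthetic digits contribute noise-driven event times that corrupt
  classification at high signal-to-noise ratios.
- **Degenerate inputs.** Warp normalization needs two distinct feature
  times and errors otherwise; an empty word/nonword feature intersection
  errors with the pair identified; zero-variance signals cannot receive
  calibrated noise; exact nearest-neighbour distance ties resolve to the
  lowest training index so predictions are deterministic.
- **Rectification.** Whether the linear adaptation was rectified or
  allowed to go negative is left open in the source account; the package
  clamps at zero so the total input relaxes to the baseline $g_k$. A
  consequence worth knowing: just after $t_b$ the ensemble stays
  phase-locked while its common frequency decays, so the predicted
  spectral difference is a short downward chirp and its global maximum
  can sit somewhat below $f_b$ (133 Hz rather than 145 Hz on the standard
  fixture at the reference seed). Localization is therefore asserted
  against the 75–150 Hz high-gamma box around $t_b$.

## Problem sizes

The shipped analyses use a 10-pair fixture, a 1.2 s simulated epoch at
400 Hz with stimulus onset at 0.2 s (displayed as $-0.2$–$1.0$ s), and a
500-iteration, 250-burn-in fit for parameter recovery — the posterior is
nearly flat at these settings, as expected when a model fits its own
output, and the 90% intervals comfortably contain the generating burst
time and frequency. Recognition checks use 4-class datasets with 3–4
exemplars per class per split. Larger runs (more pairs, 2000 iterations,
10 classes with 5 + 5 exemplars) only sharpen the same conclusions.

## Known limitations

- The MFCC pipeline uses common defaults (0.97 pre-emphasis, 25 ms/10 ms
  Hamming frames, 26 mel filters, 18 cepstra, `t_fix` equal to the longest
  training exemplar) since the original appendix settings are unavailable;
  absolute error rates on synthetic digits are not comparable to corpus
  results.
- The `M2` coupling modulation is a placeholder (above).
- Serialization targets plain-text formats (WAV, CSV, JSON); no HDF5
  bindings are assumed.
- The nearest-neighbour back end is deliberately weak — it is the shared
  baseline that makes the two feature front ends comparable, not a
  recognizer anyone would deploy.
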
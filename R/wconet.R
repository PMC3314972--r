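## Weakly coupled oscillator network: Euler-Maruyama phase integration
## with von Mises state noise, the summed-cosine field (LFP), and
## synchronization diagnostics.

#' Oscillator network configuration
#'
#' @param dt Integration step, s. The default 2.5 ms suffices because the
#'   phase dynamics (unlike the waveform) are smooth; see the methods
#'   vignette. The additive von Mises noise is applied per step, so its
#'   effective magnitude depends on `dt`: changing `dt` with noise enabled
#'   triggers a warning.
#' @param kappa Precision of the zero-mean von Mises state noise; `Inf`
#'   disables noise.
#' @param pif Phase interaction function of the phase difference
#'   (default `sin`, making global zero-lag synchrony a stable state).
#' @param noise_seed Integer seed freezing initial phases and state noise.
#' @param coupling_units `"hz"` scales the coupling strength by 2 * pi so
#'   that it is commensurate with frequencies in Hz; `"rad_per_s"` uses it
#'   unscaled.
#' @return An object of class `wco_config`.
#' @export
wco_config <- function(dt = 0.0025, kappa = 10, pif = sin, noise_seed = 0L,
                       coupling_units = c("hz", "rad_per_s")) {
  coupling_units <- match.arg(coupling_units)
  if (dt <= 0) abort("dt must be positive")
  if (!(kappa > 0)) abort("kappa must be positive (use Inf for no noise)")
  if (is.finite(kappa) && abs(dt - 0.0025) > 1e-12) {
    warn("dt differs from 2.5 ms: per-step von Mises noise magnitude rescales with dt")
  }
  structure(list(dt = dt, kappa = kappa, pif = pif,
                 noise_seed = as.integer(noise_seed),
                 coupling_units = coupling_units),
            class = "wco_config")
}

# Zero-mean von Mises sampler (Best & Fisher rejection scheme), batched.
rvonmises <- function(n, kappa) {
  if (!is.finite(kappa)) return(numeric(n))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(16L, ceiling((n - length(out)) * 1.5))
    u1 <- runif(m); u2 <- runif(m); u3 <- runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    ok <- (cc * (2 - cc) - u2 > 0) | (log(cc / u2) + 1 - cc >= 0)
    out <- c(out, sign(u3[ok] - 0.5) * acos(pmax(pmin(f[ok], 1), -1)))
  }
  out[seq_len(n)]
}

#' Integrate the coupled-oscillator phase dynamics
#'
#' Euler-Maruyama integration of
#' `dphi_k = dt * (2 pi f_k(t) - sum_k' w h(phi_k' - phi_k)) + e_k`,
#' with uniform all-to-all coupling `w = 2 pi A` (in `"hz"` units), phase
#' interaction function `h`, and per-step zero-mean von Mises noise `e_k`.
#' With the sine interaction function and the subtractive coupling term,
#' negative `A` is the synchronizing direction. Initial phases are uniform
#' on `[0, 2 pi)`; both they and the noise are frozen by
#' `config$noise_seed`, so identical inputs give bit-identical output.
#'
#' @param profiles A `frequency_profiles` object (or a K x T matrix of
#'   frequencies in Hz plus a `time` attribute via `list(freqs=,time=)`).
#' @param A Coupling strength (negative synchronizes).
#' @param config A [wco_config()].
#' @param coupling_scale Optional K x T matrix of per-oscillator,
#'   per-time multipliers on the coupling (used for frequency-dependent
#'   coupling variants); default all ones.
#' @param phi0 Optional pre-drawn initial phases (length K); overrides the
#'   seeded draw.
#' @param noise Optional pre-drawn K x T noise matrix; overrides the
#'   seeded draw.
#' @return An object of class `phase_trajectories`: list with `phases`
#'   (K x T, radians) and `time` (s).
#' @export
wco_integrate <- function(profiles, A, config = wco_config(),
                          coupling_scale = NULL, phi0 = NULL, noise = NULL) {
  freqs <- profiles$freqs
  time_axis <- profiles$time
  K <- nrow(freqs); T_n <- ncol(freqs)
  dt <- config$dt
  if (dt * max(abs(freqs)) >= 1) {
    abort("dt too large: an oscillator advances a full cycle or more per step")
  }
  w <- if (config$coupling_units == "hz") 2 * pi * A else A
  # initial phases and state noise: frozen by noise_seed unless supplied
  # explicitly (a fitting run draws them once and shares them across
  # proposals and across the coupled / uncoupled companion runs)
  if (is.null(phi0) || is.null(noise)) {
    drawn <- with_seed(config$noise_seed, {
      p0 <- runif(K, 0, 2 * pi)
      e <- if (is.finite(config$kappa)) {
        matrix(rvonmises(K * T_n, config$kappa), nrow = K)
      } else {
        matrix(0, nrow = K, ncol = T_n)
      }
      list(phi0 = p0, e = e)
    })
    if (is.null(phi0)) phi0 <- drawn$phi0
    if (is.null(noise)) noise <- drawn$e
  }
  noise <- list(phi0 = phi0, e = noise)
  phases <- matrix(0, nrow = K, ncol = T_n)
  phases[, 1] <- noise$phi0
  sine_pif <- identical(config$pif, sin)
  for (j in seq_len(T_n - 1)) {
    phi <- phases[, j]
    if (K > 1 && w != 0) {
      if (sine_pif) {
        S <- sum(exp(1i * phi))
        coup <- w * Im(exp(-1i * phi) * S)
      } else {
        dphi <- outer(phi, phi, "-")      # dphi[k', k] = phi_k' - phi_k
        coup <- w * (colSums(config$pif(dphi)) - config$pif(0))  # no self-coupling
      }
      if (!is.null(coupling_scale)) coup <- coup * coupling_scale[, j]
    } else {
      coup <- 0
    }
    phases[, j + 1] <- phi + dt * (2 * pi * freqs[, j] - coup) +
      noise$e[, j]
  }
  structure(list(phases = phases, time = time_axis),
            class = "phase_trajectories")
}

#' Local field potential of a phase trajectory
#'
#' The field is the sum of the unit-amplitude oscillator waveforms,
#' `y(t) = sum_k cos(phi_k(t))`; phase-aligned oscillators give the
#' maximal field K.
#'
#' @param phases A `phase_trajectories` object.
#' @return An object of class `lfp_trace`: list with `y`, `time`, `K`.
#' @export
lfp <- function(phases) {
  y <- colSums(matrix(cos(phases$phases), nrow = nrow(phases$phases)))
  structure(list(y = y, time = phases$time, K = nrow(phases$phases)),
            class = "lfp_trace")
}

#' Closed-form instantaneous field power
#'
#' For K oscillators whose phases are Gaussian-scattered with variance
#' `sigma2` around a common mean, the expected field power (normalized by
#' K/2) is `1 + exp(-sigma2) * (K - 1)`: K when perfectly aligned, 1 in
#' the fully incoherent limit.
#'
#' @param K Number of oscillators.
#' @param sigma2 Phase variance, rad^2.
#' @return The normalized expected field power.
#' @export
field_power_closed_form <- function(K, sigma2) {
  stopifnot(K >= 1, sigma2 >= 0)
  1 + exp(-sigma2) * (K - 1)
}

#' Minimum frequency of a synchronized network
#'
#' Ensemble members must fire within a maximal period of each other for
#' their spikes to be bound into one network oscillation; a 25 ms maximal
#' period implies a 40 Hz (low-gamma) floor on the network rhythm.
#'
#' @param max_period Maximal spiking period, s.
#' @return Minimum network frequency, Hz.
#' @export
min_network_frequency <- function(max_period = 0.025) {
  stopifnot(max_period > 0)
  1 / max_period
}

#' Kuramoto order parameter
#'
#' @param phi Numeric vector of phases (radians) at one time point, or a
#'   K x T matrix (one value per column).
#' @return `r = |mean(exp(i phi))|` in `[0, 1]`.
#' @export
order_parameter <- function(phi) {
  if (is.matrix(phi)) {
    Mod(colSums(exp(1i * phi))) / nrow(phi)
  } else {
    Mod(mean(exp(1i * phi)))
  }
}

#' @export
print.phase_trajectories <- function(x, ...) {
  cat(sprintf("<phase_trajectories: %d oscillators x %d timepoints>\n",
              nrow(x$phases), ncol(x$phases)))
  invisible(x)
}

#' @export
print.lfp_trace <- function(x, ...) {
  cat(sprintf("<lfp_trace: %d samples, K = %d>\n", length(x$y), x$K))
  invisible(x)
}
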
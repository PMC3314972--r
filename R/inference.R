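## Bayesian fitting: spectrogram-mismatch likelihood, Metropolis-Hastings
## sampling under uniform box priors, and posterior-harmonic-mean model
## evidence.

#' Uniform box prior over model parameters
#'
#' @param bounds Data frame with columns `name`, `min`, `max`.
#' @return An object of class `param_prior`.
#' @export
param_prior <- function(bounds) {
  bounds <- as_tibble(bounds)
  stopifnot(all(c("name", "min", "max") %in% names(bounds)))
  if (any(bounds$min >= bounds$max)) abort("every prior needs min < max")
  structure(bounds, class = c("param_prior", class(bounds)))
}

#' Priors for the minimal and augmented model variants
#'
#' The minimal model `M0` has burst time (s), burst frequency (Hz),
#' maximum frequency (Hz) and coupling. `M1` adds trial-to-trial burst
#' variability (`delta_t`, `delta_f`); `M2` additionally allows
#' frequency-dependent coupling (`beta1`, `beta2`).
#'
#' @param variant `"M0"`, `"M1"` or `"M2"`.
#' @return A [param_prior()].
#' @export
model_priors <- function(variant = c("M0", "M1", "M2")) {
  variant <- match.arg(variant)
  base <- tibble(name = c("t_b", "f_b", "f_max", "A"),
                 min = c(0.200, 120, 150, -3),
                 max = c(0.300, 150, 250, 0))
  trial <- tibble(name = c("delta_t", "delta_f"),
                  min = c(0.1, 0.1), max = c(0.3, 0.3))
  freqdep <- tibble(name = c("beta1", "beta2"),
                    min = c(-0.25, 0.6), max = c(0.25, 0.9))
  param_prior(switch(variant,
    M0 = base,
    M1 = dplyr::bind_rows(base, trial),
    M2 = dplyr::bind_rows(base, trial, freqdep)))
}

#' Spectrogram mismatch (model error)
#'
#' Both the model and the data differential spectrograms are scaled to
#' unit power (Frobenius norm) over the comparison interval; the model
#' matrix is then projected onto the first left singular vector of the
#' normalized data matrix, and the error is the root-mean-square
#' difference between the two resulting time courses.
#'
#' @param D Model `wcots_diffspec`.
#' @param Y Data `wcots_diffspec`, on identical axes.
#' @param time_range Optional two-element crop of the comparison interval
#'   (s) applied to both matrices before normalization.
#' @return Non-negative scalar error.
#' @export
model_error <- function(D, Y, time_range = NULL) {
  if (!all(dim(D$values) == dim(Y$values)) ||
      max(abs(D$freq - Y$freq)) > 1e-9 ||
      max(abs(D$time - Y$time)) > 1e-9) {
    abort("D and Y must share dimensions and axes (resample/crop first)")
  }
  Dm <- D$values; Ym <- Y$values
  if (!is.null(time_range)) {
    sel <- Y$time >= time_range[1] & Y$time <= time_range[2]
    Dm <- Dm[, sel, drop = FALSE]; Ym <- Ym[, sel, drop = FALSE]
  }
  nD <- sqrt(sum(Dm^2)); nY <- sqrt(sum(Ym^2))
  if (nY == 0) abort("data differential spectrogram is identically zero")
  Dm <- Dm / max(nD, 1e-300); Ym <- Ym / nY
  u <- svd(Ym, nu = 1, nv = 0)$u[, 1]
  root_mean_square(crossprod(u, Dm) - crossprod(u, Ym))
}

#' Log likelihood from model error
#'
#' Log likelihood is proportional to negative model error:
#' `log p = -E / lambda` with temperature `lambda` (default 1).
#'
#' @param E Non-negative model error.
#' @param lambda Temperature scaling the error.
#' @return Log likelihood (<= 0).
#' @export
log_likelihood <- function(E, lambda = 1) {
  stopifnot(E >= 0, lambda > 0)
  -E / lambda
}

#' Metropolis-Hastings configuration
#'
#' @param proposal_scale Divisor S of the prior range giving each
#'   parameter's Gaussian proposal standard deviation
#'   `sigma_p = (max_p - min_p) / S`.
#' @param n_iter Total iterations.
#' @param n_burn Burn-in iterations discarded (`< n_iter`).
#' @param seed Integer seed for the proposal chain.
#' @return An object of class `mh_config`.
#' @export
mh_config <- function(proposal_scale = 8, n_iter = 2000, n_burn = 1000,
                      seed = 0L) {
  if (n_burn >= n_iter) abort("n_burn must be < n_iter")
  structure(list(proposal_scale = proposal_scale, n_iter = n_iter,
                 n_burn = n_burn, seed = as.integer(seed)),
            class = "mh_config")
}

#' Metropolis-Hastings sampling under a uniform box prior
#'
#' Random-walk MH with a zero-mean diagonal Gaussian proposal whose
#' per-parameter standard deviation is the prior range divided by the
#' proposal scale. Proposals outside the prior box are rejected without a
#' likelihood evaluation. The chain starts at the prior-box midpoint
#' (optionally at a seeded uniform draw).
#'
#' @param prior A [param_prior()].
#' @param loglik Function of a named parameter list returning a finite
#'   log likelihood (deterministic: model noise must be frozen).
#' @param config An [mh_config()].
#' @param init `"midpoint"` (default) or `"random"`.
#' @return An object of class `wcots_chain`: list with `samples`
#'   (tibble, kept iterations x parameters), `log_lik`, `acceptance_rate`,
#'   `map` (highest-likelihood kept sample as a named list), `prior`,
#'   `config`.
#' @export
mh_sample <- function(prior, loglik, config = mh_config(),
                      init = c("midpoint", "random")) {
  init <- match.arg(init)
  P <- nrow(prior)
  sigma <- (prior$max - prior$min) / config$proposal_scale
  theta <- if (init == "midpoint") {
    (prior$min + prior$max) / 2
  } else {
    with_seed(config$seed, runif(P, prior$min, prior$max))
  }
  names(theta) <- prior$name
  ll <- loglik(as.list(theta))
  if (!is.finite(ll)) abort("log likelihood non-finite at initialization")
  n_keep <- config$n_iter - config$n_burn
  samples <- matrix(NA_real_, nrow = n_keep, ncol = P,
                    dimnames = list(NULL, prior$name))
  lls <- numeric(n_keep)
  n_acc <- 0L
  with_seed(config$seed + 1L, {
    for (it in seq_len(config$n_iter)) {
      prop <- theta + rnorm(P, 0, sigma)
      accepted <- FALSE
      if (all(prop >= prior$min & prop <= prior$max)) {
        ll_prop <- loglik(as.list(stats::setNames(prop, prior$name)))
        if (log(runif(1)) < ll_prop - ll) {
          theta <- stats::setNames(prop, prior$name)
          ll <- ll_prop
          accepted <- TRUE
        }
      }
      if (accepted) n_acc <- n_acc + 1L
      if (it > config$n_burn) {
        samples[it - config$n_burn, ] <- theta
        lls[it - config$n_burn] <- ll
      }
    }
  })
  imap <- which.max(lls)
  structure(list(samples = as_tibble(as.data.frame(samples)),
                 log_lik = lls,
                 acceptance_rate = n_acc / config$n_iter,
                 map = as.list(samples[imap, ]),
                 prior = prior, config = config),
            class = "wcots_chain")
}

#' @export
print.wcots_chain <- function(x, ...) {
  cat(sprintf(
    "<wcots_chain: %d kept samples, %d parameters, acceptance %.2f>\n",
    nrow(x$samples), ncol(x$samples), x$acceptance_rate))
  invisible(x)
}

#' Posterior harmonic mean evidence
#'
#' The evidence estimate is the reciprocal of the mean reciprocal
#' likelihood over kept posterior samples, computed in log space.
#'
#' @param chain A `wcots_chain`.
#' @param log Return the log evidence instead of the evidence.
#' @return Evidence estimate (or its log).
#' @export
phm_evidence <- function(chain, log = FALSE) {
  ll <- chain$log_lik
  if (length(ll) == 0) abort("empty chain")
  log_ev <- -(log_sum_exp(-ll) - base::log(length(ll)))
  if (log) log_ev else exp(log_ev)
}

#' Fit the oscillator model to a differential spectrogram
#'
#' Composes the forward model, the spectrogram-mismatch error and the
#' likelihood into a Metropolis-Hastings target under the variant's box
#' priors. All model noise is frozen from `seed` before sampling, so the
#' likelihood is deterministic in the parameters.
#'
#' @param Y Data (target) `wcots_diffspec`.
#' @param prepared Prepared pair features from [prepare_pair_features()].
#' @param variant Model variant (see [model_priors()]).
#' @param config An [mh_config()].
#' @param seed Integer seed for the frozen model noise.
#' @param lambda Likelihood temperature.
#' @param time_range Comparison interval for [model_error()]; default the
#'   full post-onset epoch `[0, 1]` s.
#' @param wco_cfg,spec_cfg,sim_duration,stim_onset,g,g_bandwidth Passed to
#'   [forward_model()].
#' @return A `wcots_chain` (with the frozen noise attached as attribute
#'   `"frozen"`).
#' @export
fit_wcots <- function(Y, prepared, variant = c("M0", "M1", "M2"),
                      config = mh_config(), seed = 0L, lambda = 1,
                      time_range = c(0, 1), wco_cfg = wco_config(),
                      spec_cfg = spectrogram_config(), sim_duration = 1.2,
                      stim_onset = 0.2, g = 10, g_bandwidth = g / 2) {
  variant <- match.arg(variant)
  prior <- model_priors(variant)
  n_time <- round(sim_duration / wco_cfg$dt)
  frozen <- freeze_forward_noise(prepared, n_time, seed = seed,
                                 kappa = wco_cfg$kappa, g = g,
                                 g_bandwidth = g_bandwidth)
  loglik <- function(theta) {
    D <- forward_model(theta, prepared, frozen = frozen, wco_cfg = wco_cfg,
                       spec_cfg = spec_cfg, sim_duration = sim_duration,
                       stim_onset = stim_onset, g = g,
                       g_bandwidth = g_bandwidth)
    log_likelihood(model_error(D, Y, time_range = time_range), lambda)
  }
  chain <- mh_sample(prior, loglik, config)
  attr(chain, "frozen") <- frozen
  chain
}

#' Split a pair manifest into training and test sets
#'
#' @param pairs Tibble of pairs (one row per pair).
#' @param n_train Number of training pairs.
#' @param exclude Optional explicit `pair_id`s to drop (e.g. outliers).
#' @param seed Integer seed for the random split.
#' @return List with `train` and `test` tibbles (disjoint).
#' @export
split_pairs <- function(pairs, n_train, exclude = NULL, seed = 0L) {
  if (!is.null(exclude)) pairs <- pairs[!pairs$pair_id %in% exclude, ]
  if (n_train >= nrow(pairs)) abort("n_train must leave at least one test pair")
  idx <- with_seed(seed, sample(nrow(pairs), n_train))
  list(train = pairs[idx, ], test = pairs[-idx, ])
}
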
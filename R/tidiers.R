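## broom-style tidiers and ggplot2 autoplot methods for the package's
## result objects.

#' @exportS3Method generics::tidy
tidy.wcots_spectrogram <- function(x, ...) {
  tidyr::expand_grid(freq = x$freq, time = x$time) |>
    dplyr::arrange(.data$time, .data$freq) |>
    dplyr::mutate(log_power = as.vector(x$values))
}

#' @exportS3Method generics::tidy
tidy.wcots_diffspec <- function(x, ...) {
  tidyr::expand_grid(freq = x$freq, time = x$time) |>
    dplyr::arrange(.data$time, .data$freq) |>
    dplyr::mutate(difference = as.vector(x$values))
}

#' @exportS3Method generics::tidy
tidy.envelope_set <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$envelopes)), function(b) {
    tibble(band = b, center_frequency = x$centers[b], time = x$time,
           envelope = x$envelopes[b, ])
  })
}

#' @exportS3Method generics::tidy
tidy.lfp_trace <- function(x, ...) {
  tibble(time = x$time, lfp = x$y)
}

#' @exportS3Method generics::tidy
tidy.frequency_profiles <- function(x, ...) {
  purrr::map_dfr(seq_len(nrow(x$freqs)), function(k) {
    tibble(oscillator = k, time = x$time, frequency = x$freqs[k, ])
  })
}

#' @exportS3Method generics::tidy
tidy.wcots_chain <- function(x, ...) {
  x$samples |>
    dplyr::mutate(iteration = dplyr::row_number(),
                  log_lik = x$log_lik) |>
    tidyr::pivot_longer(-c("iteration", "log_lik"),
                        names_to = "parameter", values_to = "value")
}

#' @exportS3Method generics::glance
glance.wcots_chain <- function(x, ...) {
  tibble(n_samples = nrow(x$samples),
         n_parameters = ncol(x$samples),
         acceptance_rate = x$acceptance_rate,
         max_log_lik = max(x$log_lik),
         log_evidence = phm_evidence(x, log = TRUE))
}

#' @exportS3Method ggplot2::autoplot
autoplot.wcots_spectrogram <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$freq,
                               fill = .data$log_power)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "log power")
}

#' @exportS3Method ggplot2::autoplot
autoplot.wcots_diffspec <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$freq,
                               fill = .data$difference)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "time (s)", y = "frequency (Hz)",
                  fill = "word - nonword")
}

#' @exportS3Method ggplot2::autoplot
autoplot.envelope_set <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$envelope)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~round(.data$center_frequency), scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = "envelope")
}

#' @exportS3Method ggplot2::autoplot
autoplot.lfp_trace <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$time, y = .data$lfp)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "field (a.u.)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.wcots_chain <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::facet_wrap(~.data$parameter, scales = "free") +
    ggplot2::labs(x = "parameter value", y = "posterior samples")
}

#' Plot a word-error-rate curve
#'
#' @param wer_table Tibble from [wer_curve()] (possibly row-bound over
#'   feature kinds).
#' @return A ggplot object.
#' @export
plot_wer_curve <- function(wer_table) {
  ggplot2::ggplot(wer_table,
                  ggplot2::aes(x = .data$snr_db, y = .data$wer,
                               colour = .data$feature_kind)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "signal level (dB)", y = "word error rate",
                  colour = "features")
}

#' @importFrom rlang .data
NULL
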
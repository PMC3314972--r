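## Occurrence-Time features: per-band onset, offset and peak times at one
## or more intensity levels, plus fixed-length (optionally time-warp
## normalized) feature vectors.

#' Occurrence-time extraction configuration
#'
#' @param n_levels Number of intensity levels L (>= 1) for onset/offset
#'   detectors; the peak detector always has a single level.
#' @param threshold_mode `"relative_to_band_max"` places level l at
#'   `l / (L + 1)` of the band's maximum envelope (amplitude invariant);
#'   `"absolute"` uses `absolute_thresholds` directly.
#' @param absolute_thresholds Numeric vector of length L, used when
#'   `threshold_mode = "absolute"`.
#' @param cutoff_time Drop features occurring at or after this time (s);
#'   `NULL` disables the cutoff. The forward model of cortical responses
#'   uses 0.3 s so that recognition precedes the end of the word.
#' @param warp_normalize If `TRUE`, feature vectors divide out the global
#'   time scale (see [ot_feature_vector()]).
#' @param missing_value Value standing in for absent features in vectors.
#' @param silence_threshold Bands whose maximum envelope falls below this
#'   fraction of the loudest band's maximum contribute no features
#'   (detectors do not fire on filter leakage or faint background);
#'   0 disables the gate.
#' @return An object of class `ot_config`.
#' @export
ot_config <- function(n_levels = 1,
                      threshold_mode = c("relative_to_band_max", "absolute"),
                      absolute_thresholds = NULL, cutoff_time = 0.300,
                      warp_normalize = FALSE, missing_value = 0,
                      silence_threshold = 0.05) {
  threshold_mode <- match.arg(threshold_mode)
  if (n_levels < 1) abort("n_levels must be >= 1")
  if (!is.null(cutoff_time) && cutoff_time <= 0) {
    abort("cutoff_time must be positive or NULL")
  }
  if (threshold_mode == "absolute" &&
      (is.null(absolute_thresholds) ||
         length(absolute_thresholds) != n_levels)) {
    abort("absolute mode needs `absolute_thresholds` of length n_levels")
  }
  structure(list(n_levels = n_levels, threshold_mode = threshold_mode,
                 absolute_thresholds = absolute_thresholds,
                 cutoff_time = cutoff_time, warp_normalize = warp_normalize,
                 missing_value = missing_value,
                 silence_threshold = silence_threshold),
            class = "ot_config")
}

# First upward and last downward crossing of `e` with `level`, with linear
# interpolation between samples. Returns c(onset, offset) or NULL.
level_crossings <- function(e, time, level) {
  above <- e >= level
  if (!any(above)) return(NULL)
  i1 <- which(above)[1]
  onset <- if (i1 == 1) time[1] else {
    interp_crossing(time[i1 - 1], time[i1], e[i1 - 1], e[i1], level)
  }
  i2 <- which(above)[length(which(above))]
  offset <- if (i2 == length(e)) time[length(e)] else {
    interp_crossing(time[i2], time[i2 + 1], e[i2], e[i2 + 1], level)
  }
  c(onset, offset)
}

#' Extract occurrence-time features from band envelopes
#'
#' Per band: the peak time is the envelope argmax; per intensity level,
#' the onset is the first upward crossing of that level and the offset the
#' last downward crossing. Features at or after `cutoff_time` are dropped.
#'
#' @param env An [band_envelopes()] result.
#' @param config An [ot_config()].
#' @return A tibble with columns `band`, `kind` (`"onset"`, `"peak"`,
#'   `"offset"`), `level` and `time` (s). Bands that never cross a level
#'   simply contribute no feature at that level.
#' @export
extract_ot <- function(env, config = ot_config()) {
  stopifnot(inherits(env, "envelope_set"), inherits(config, "ot_config"))
  L <- config$n_levels
  rows <- list()
  gate <- (config$silence_threshold %||% 0) * max(env$envelopes)
  for (b in seq_len(nrow(env$envelopes))) {
    e <- env$envelopes[b, ]
    mx <- max(e)
    if (mx <= 0 || mx < gate) next
    ipk <- which.max(e)
    rows[[length(rows) + 1]] <-
      tibble(band = b, kind = "peak", level = 1L, time = env$time[ipk])
    for (l in seq_len(L)) {
      thr <- if (config$threshold_mode == "relative_to_band_max") {
        l / (L + 1) * mx
      } else {
        config$absolute_thresholds[l]
      }
      cr <- level_crossings(e, env$time, thr)
      if (is.null(cr)) next
      rows[[length(rows) + 1]] <-
        tibble(band = b, kind = c("onset", "offset"), level = l, time = cr)
    }
  }
  out <- if (length(rows) == 0) {
    tibble(band = integer(), kind = character(), level = integer(),
           time = numeric())
  } else {
    dplyr::bind_rows(rows)
  }
  if (!is.null(config$cutoff_time)) {
    out <- dplyr::filter(out, .data$time < config$cutoff_time)
  }
  dplyr::arrange(out, .data$band, .data$kind, .data$level)
}

#' Fixed-length occurrence-time feature vector
#'
#' Lays features out in a fixed (band, kind, level) order — per band: one
#' peak, then onset levels 1..L, then offset levels 1..L — giving a vector
#' of length `B * (2L + 1)` regardless of missing features. With
#' `warp_normalize` all times are mapped to
#' `(t - t_first) / (t_last - t_first)`, which removes any global time
#' warp exactly.
#'
#' @param features Tibble from [extract_ot()].
#' @param B Number of bands of the filterbank used.
#' @param config The [ot_config()] used at extraction.
#' @return Numeric vector of length `B * (2 * n_levels + 1)`.
#' @export
ot_feature_vector <- function(features, B, config = ot_config()) {
  L <- config$n_levels
  times <- features$time
  if (config$warp_normalize) {
    if (length(unique(times)) < 2) {
      abort("warp normalization undefined with < 2 distinct feature times")
    }
    t0 <- min(times); t1 <- max(times)
    times <- (times - t0) / (t1 - t0)
  }
  vec <- rep(config$missing_value, B * (2 * L + 1))
  # slot index within a band block: peak = 1, onset_l = 1 + l,
  # offset_l = 1 + L + l
  slot <- ifelse(features$kind == "peak", 1L,
                 ifelse(features$kind == "onset", 1L + features$level,
                        1L + L + features$level))
  idx <- (features$band - 1L) * (2L * L + 1L) + slot
  vec[idx] <- times
  vec
}

#' Write occurrence-time features to CSV
#'
#' @param features Tibble from [extract_ot()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ot_csv <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE)
  invisible(path)
}
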
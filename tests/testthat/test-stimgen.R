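test_that("word synthesis places band envelopes at the specified times", {
  spec <- one_band_word()
  x <- generate_word(spec)
  env <- band_envelopes(x, filterbank_config())
  b <- which.min(abs(env$centers - 1000))
  t_peak <- env$time[which.max(env$envelopes[b, ])]
  expect_lt(abs(t_peak - 0.3), 0.01)
})

test_that("a zero-band spec yields silence and generation is deterministic", {
  silent <- word_spec(data.frame(center_frequency = numeric(),
                                 onset = numeric(), peak = numeric(),
                                 offset = numeric(), amplitude = numeric()),
                      duration = 0.5, sample_rate = 8000)
  expect_identical(generate_word(silent), numeric(4000))

  spec <- one_band_word()
  expect_identical(generate_word(spec), generate_word(spec))
})

test_that("invalid specs are rejected naming the offending band", {
  bad <- data.frame(center_frequency = c(500, 900),
                    onset = c(0.1, 0.4), peak = c(0.2, 0.3),
                    offset = c(0.3, 0.5), amplitude = c(1, 1))
  expect_error(word_spec(bad, duration = 1, sample_rate = 8000), "band 2")
  expect_error(word_spec(transform(bad, peak = c(0.2, 0.45),
                                   amplitude = c(1, -1)),
                         duration = 1, sample_rate = 8000), "band 2")
})

test_that("nonwords match the word's RMS power for both scramble methods", {
  sp <- wcots:::draw_word_spec(pair_template(), 11)
  w <- generate_word(sp)
  for (m in c("ot_permute", "modulation_filter")) {
    nw <- generate_nonword(w, sp, method = m, seed = 5)
    expect_equal(length(nw), length(w))
    rms <- function(v) sqrt(mean(v^2))
    expect_lt(abs(rms(nw) - rms(w)) / rms(w), 1e-6)
  }
})

test_that("ot_permute reassigns event times across bands, preserving the multiset", {
  # three widely separated carriers with distinct, well-separated peaks
  ev <- data.frame(center_frequency = c(400, 1200, 3000),
                   onset = c(0.02, 0.10, 0.18),
                   peak = c(0.07, 0.15, 0.23),
                   offset = c(0.12, 0.20, 0.28),
                   amplitude = 1)
  sp <- word_spec(ev, duration = 1, sample_rate = 8000, seed = 3)
  w <- generate_word(sp)
  nw <- generate_nonword(w, sp, "ot_permute", seed = 9)
  cfg <- ot_config(cutoff_time = NULL)
  fb <- filterbank_config()
  pk <- function(x) {
    f <- extract_ot(band_envelopes(x, fb), cfg)
    sort(f$time[f$kind == "peak"])
  }
  pw <- pk(w); pn <- pk(nw)
  expect_equal(length(pw), length(pn))
  expect_lt(max(abs(pw - pn)), 0.005)           # same multiset of peak times
  # but the per-band assignment changed (scramble validity)
  fw <- extract_ot(band_envelopes(w, fb), cfg)
  fn <- extract_ot(band_envelopes(nw, fb), cfg)
  j <- merge(fw[fw$kind == "peak", ], fn[fn$kind == "peak", ],
             by = "band")
  expect_gt(max(abs(j$time.x - j$time.y)), 0.02)
})

test_that("an empty modulation-filter region reconstructs the spectrogram", {
  sp <- wcots:::draw_word_spec(pair_template(), 4)
  w <- generate_word(sp)
  nw <- generate_nonword(w, sp, "modulation_filter", seed = 2,
                         frac_t = 0, frac_f = 0)
  cfg <- spectrogram_config(window = 256, hop = 64, sample_rate = 8000)
  s1 <- multitaper_spectrogram(w, cfg)
  s2 <- multitaper_spectrogram(nw, cfg)
  expect_gt(cor(as.vector(s1$values), as.vector(s2$values)), 0.9)
})

test_that("pair sets satisfy their contracts and are seed-reproducible", {
  ps <- generate_pair_set(10, seed = 0)
  expect_equal(nrow(ps), 10)
  for (i in seq_len(10)) {
    expect_equal(length(ps$word[[i]]), length(ps$nonword[[i]]))
    rms <- function(v) sqrt(mean(v^2))
    expect_lt(abs(rms(ps$word[[i]]) - rms(ps$nonword[[i]])) /
                rms(ps$word[[i]]), 1e-6)
    ev <- ps$spec[[i]]$band_events
    expect_true(all(ev$onset < ev$peak & ev$peak < ev$offset))
  }
  ps2 <- generate_pair_set(10, seed = 0)
  expect_identical(ps$word, ps2$word)
  ps3 <- generate_pair_set(10, seed = 99)
  t1 <- unlist(lapply(ps$spec, function(s) s$band_events$onset))
  t3 <- unlist(lapply(ps3$spec, function(s) s$band_events$onset))
  expect_false(isTRUE(all.equal(t1, t3)))
  expect_error(generate_pair_set(0), "n must be")
})

test_that("digit datasets respect warp bounds, split disjointness and seeding", {
  expect_error(generate_digit_dataset(4, warp_range = c(0.2, 1)),
               "warp_range")
  ds <- generate_digit_dataset(n_classes = 3, n_train = 2, n_test = 2,
                               seed = 5)
  expect_equal(nrow(ds), 12)
  expect_setequal(unique(ds$split), c("train", "test"))
  key <- interaction(ds$class, ds$exemplar, drop = TRUE)
  expect_equal(anyDuplicated(key), 0)           # train/test exemplars disjoint
  ds2 <- generate_digit_dataset(n_classes = 3, n_train = 2, n_test = 2,
                                seed = 5)
  expect_identical(ds$signal, ds2$signal)
})

test_that("WAV round trip preserves mono signals", {
  x <- sin(2 * pi * 440 * (0:799) / 8000) * 0.5
  f <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, f, 8000, bits = 32L)
  back <- read_wav(f)
  expect_equal(back$sample_rate, 8000)
  expect_equal(back$signal, x, tolerance = 1e-7)
  f16 <- withr::local_tempfile(fileext = ".wav")
  write_wav(x, f16, 8000, bits = 16L)
  expect_equal(read_wav(f16)$signal, x, tolerance = 1e-3)
})
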
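test_that("multitaper bookkeeping matches the analysis configuration", {
  cfg <- spectrogram_config()
  expect_equal(mt_frequency_resolution(cfg), 3.7, tolerance = 0.02)
  expect_equal(cfg$window / cfg$sample_rate, 0.128, tolerance = 0.002)
  expect_equal(cfg$hop / cfg$sample_rate, 0.016, tolerance = 0.002)
})

test_that("Slepian tapers are pairwise orthonormal", {
  V <- wcots:::dpss_tapers(256, 3, 5)
  G <- crossprod(V)
  expect_lt(max(abs(G - diag(5))), 1e-10)
})

test_that("a pure tone is localized to within the taper bandwidth", {
  fs <- 2003
  x <- sin(2 * pi * 100 * (0:4005) / fs)
  sp <- multitaper_spectrogram(x, spectrogram_config())
  am <- sp$freq[apply(sp$values, 2, which.max)]
  # the multitaper main lobe is flat over ~ +/- 2 bins around the tone
  expect_true(all(abs(am - 100) <= 2 * fs / 256))
})

test_that("silence maps to a constant floor and short signals error", {
  sp <- multitaper_spectrogram(numeric(512), spectrogram_config())
  expect_equal(length(unique(as.vector(sp$values))), 1)
  expect_error(multitaper_spectrogram(numeric(100), spectrogram_config()),
               "shorter than one")
})

test_that("differential spectrograms are antisymmetric pairwise means", {
  mk <- function(vals) structure(
    list(values = vals, freq = 1:2, time = 1:2),
    class = "wcots_spectrogram")
  w <- list(mk(matrix(2, 2, 2)), mk(matrix(5, 2, 2)))
  n <- list(mk(matrix(0, 2, 2)), mk(matrix(1, 2, 2)))
  d <- differential_spectrogram(w, n)
  expect_equal(d$values, matrix(3, 2, 2))       # mean of +2 and +4
  d_swapped <- differential_spectrogram(n, w)
  expect_equal(d_swapped$values, -d$values)
  d_same <- differential_spectrogram(w, w)
  expect_equal(max(abs(d_same$values)), 0)
  bad <- list(mk(matrix(0, 2, 2)))
  expect_error(differential_spectrogram(w, bad), "counts")
})

test_that("trial variability spans the stated percentage range", {
  th <- list(t_b = 0.25, f_b = 135, delta_t = 0.2, delta_f = 0.1)
  tv <- sample_trial_variability(th, 2000, seed = 4)
  expect_true(all(tv$t_b_i >= 0.25 * 0.8 & tv$t_b_i <= 0.25 * 1.2))
  expect_true(all(tv$f_b_i >= 135 * 0.9 & tv$f_b_i <= 135 * 1.1))
  expect_lt(abs(mean(tv$t_b_i) - 0.25), 0.002)  # symmetric about t_b
  th0 <- list(t_b = 0.25, f_b = 135, delta_t = 0, delta_f = 0)
  tv0 <- sample_trial_variability(th0, 10, seed = 4)
  expect_true(all(tv0$t_b_i == 0.25))
  expect_identical(tv, sample_trial_variability(th, 2000, seed = 4))
  # the literal additive form is a different convention
  tva <- sample_trial_variability(th, 5, seed = 4, form = "additive")
  expect_false(isTRUE(all.equal(tva$t_b_i, tv$t_b_i[1:5])))
})

test_that("zero coupling predicts exactly no spectral difference", {
  fx <- get_fixture()
  theta0 <- modifyList(fx$theta, list(A = 0))
  D0 <- forward_model(theta0, fx$prepared, seed = 1, wco_cfg = fx$wco_cfg,
                      spec_cfg = fx$spec_cfg)
  expect_equal(max(abs(D0$values)), 0)
})

test_that("the forward model is bit-reproducible under frozen seeds", {
  fx <- get_fixture()
  D1 <- forward_model(fx$theta, fx$prepared, seed = 1, wco_cfg = fx$wco_cfg,
                      spec_cfg = fx$spec_cfg)
  D2 <- forward_model(fx$theta, fx$prepared, seed = 1, wco_cfg = fx$wco_cfg,
                      spec_cfg = fx$spec_cfg)
  expect_identical(D1$values, D2$values)
})

test_that("the predicted difference concentrates at the burst", {
  D <- get_fixture_target()
  i <- which(D$values == max(D$values), arr.ind = TRUE)
  # global argmax inside the high-gamma box around the burst time
  expect_lt(abs(D$time[i[2]] - 0.25), 0.1)
  expect_gte(D$freq[i[1]], 75)
  expect_lte(D$freq[i[1]], 150)
  box <- outer(D$freq >= 75 & D$freq <= 150,
               abs(D$time - 0.25) <= 0.05, "&")
  expect_gt(mean(D$values[box]), mean(D$values[!box]))
})

test_that("invalid parameter points are rejected by name", {
  fx <- get_fixture()
  expect_error(forward_model(list(t_b = -1, f_b = 135, f_max = 200, A = -2),
                             fx$prepared, seed = 1), "t_b")
  expect_error(forward_model(list(t_b = 0.25, f_b = 300, f_max = 200, A = -2),
                             fx$prepared, seed = 1), "f_max")
})

test_that("FFT resampling preserves band-limited content", {
  fs1 <- 400; fs2 <- 2003
  t <- (0:479) / fs1
  x <- sin(2 * pi * 50 * t) + 0.5 * cos(2 * pi * 120 * t)
  y <- wcots:::resample_fft(x, fs1, fs2)
  m <- round(480 * fs2 / fs1)
  expect_equal(length(y), m)
  # the m output samples span the same 1.2 s as the input (the output rate
  # is m / duration, within rounding of fs2)
  t2 <- (seq_len(m) - 1) * (480 / fs1) / m
  target <- sin(2 * pi * 50 * t2) + 0.5 * cos(2 * pi * 120 * t2)
  expect_lt(max(abs(y - target)), 1e-9)
})
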
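test_that("a lone oscillator at constant frequency advances exactly 2 pi f t", {
  prof <- list(freqs = matrix(10, 1, 41), time = seq(0, 0.1, by = 0.0025))
  tr <- wco_integrate(prof, A = 0, wco_config(kappa = Inf, noise_seed = 1))
  expect_equal(tr$phases[1, 41] - tr$phases[1, 1], 2 * pi, tolerance = 1e-9)
})

test_that("two coupled oscillators follow the closed-form Adler solution", {
  dt <- 5e-5
  tt <- seq(0, 0.2, by = dt)
  prof <- list(freqs = matrix(10, 2, length(tt)), time = tt)
  cfg <- wco_config(dt = dt, kappa = Inf, noise_seed = 1)
  tr <- wco_integrate(prof, A = -1, cfg, phi0 = c(0, 3))
  dphi <- tr$phases[2, ] - tr$phases[1, ]
  # d(dphi)/dt = -2 * 2pi|A| sin(dphi): tan(dphi/2) decays exponentially
  analytic <- 2 * atan(tan(3 / 2) * exp(-4 * pi * tt))
  expect_lt(max(abs(dphi - analytic)), 1e-3)
})

test_that("uncoupled oscillators drift apart at their frequency difference", {
  tt <- seq(0, 0.5, by = 0.0025)
  prof <- list(freqs = matrix(c(10, 11), 2, length(tt)), time = tt)
  tr <- wco_integrate(prof, A = 0, wco_config(kappa = Inf, noise_seed = 1),
                      phi0 = c(0, 0))
  dphi <- tr$phases[2, ] - tr$phases[1, ]
  # 1 Hz difference: 2 pi rad/s of relative drift
  expect_equal(dphi[length(tt)], 2 * pi * 0.5, tolerance = 1e-6)
})

test_that("the field is the phase-aligned sum and obeys |y| <= K", {
  ph <- structure(list(phases = matrix(0, 7, 5), time = 1:5),
                  class = "phase_trajectories")
  expect_equal(lfp(ph)$y, rep(7, 5))
  ph2 <- structure(list(phases = matrix(c(0, pi), 2, 3), time = 1:3),
                   class = "phase_trajectories")
  expect_equal(lfp(ph2)$y, rep(0, 3), tolerance = 1e-12)

  prof <- list(freqs = matrix(runif(20 * 100, 5, 50), 20, 100),
               time = seq(0, 0.2475, by = 0.0025))
  y <- lfp(wco_integrate(prof, A = -1, wco_config(noise_seed = 4)))$y
  expect_true(all(abs(y) <= 20 + 1e-12))
})

test_that("closed-form field power matches direct arithmetic and Monte Carlo", {
  expect_equal(field_power_closed_form(9, 0), 9)
  expect_equal(field_power_closed_form(1, 3.7), 1)
  expect_equal(field_power_closed_form(5, log(2)), 3)
  set.seed(11)
  mc <- replicate(4000, {
    psi <- runif(1, 0, 2 * pi)
    phases <- psi + rnorm(5, 0, sqrt(log(2)))
    (2 / 5) * sum(cos(phases))^2
  })
  se <- sd(mc) / sqrt(length(mc))
  expect_lt(abs(mean(mc) - 3), 3 * se)
  # fully incoherent limit: normalized power tends to 1
  mc2 <- replicate(2000, (2 / 100) * sum(cos(runif(100, 0, 2 * pi)))^2)
  expect_lt(abs(mean(mc2) - 1), 3 * sd(mc2) / sqrt(length(mc2)))
})

test_that("the order parameter ranges from incoherent 0 to aligned 1", {
  expect_equal(order_parameter(rep(1.3, 50)), 1)
  expect_lt(order_parameter(2 * pi * (0:9) / 10), 1e-12)
})

test_that("coupling overcomes frequency heterogeneity only below threshold", {
  # Lorentz-distributed stationary frequencies; synchronization requires
  # the spread-to-coupling ratio to be small
  set.seed(42)
  K <- 100; A <- -0.2
  run <- function(ratio) {
    sL <- ratio * abs(A) * K
    f <- 40 + sL * tan(pi * (runif(K) - 0.5))
    f <- pmin(pmax(f, 40 - 140), 40 + 140)   # winsorize heavy Cauchy tails
    Tn <- 1200
    prof <- list(freqs = matrix(f, K, Tn), time = (0:(Tn - 1)) * 0.0025)
    tr <- wco_integrate(prof, A, wco_config(kappa = Inf, noise_seed = 2))
    mean(order_parameter(tr$phases[, 800:1200]))
  }
  expect_gt(run(0.1), 0.8)
  expect_lt(run(2.0), 0.4)
})

test_that("frozen noise makes integration bit-reproducible", {
  prof <- list(freqs = matrix(runif(10 * 200, 5, 60), 10, 200),
               time = seq(0, by = 0.0025, length.out = 200))
  cfg <- wco_config(noise_seed = 9)
  tr1 <- wco_integrate(prof, A = -2, cfg)
  tr2 <- wco_integrate(prof, A = -2, cfg)
  expect_identical(tr1$phases, tr2$phases)
})

test_that("a step too large to represent the fastest oscillator errors", {
  prof <- list(freqs = matrix(500, 1, 10), time = (0:9) * 0.0025)
  expect_error(wco_integrate(prof, 0, wco_config(kappa = Inf)),
               "dt too large")
})

test_that("changing dt with noise enabled warns about noise rescaling", {
  expect_warning(wco_config(dt = 0.001, kappa = 10), "rescales")
  expect_silent(wco_config(dt = 0.001, kappa = Inf))
})

test_that("the spiking-period bound sets the minimum network frequency", {
  expect_equal(min_network_frequency(0.025), 40)
})
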
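mk_diffspec <- function(vals, freq = seq_len(nrow(vals)),
                        time = seq_len(ncol(vals))) {
  structure(list(values = vals, freq = freq, time = time, n_pairs = 1),
            class = "wcots_diffspec")
}

test_that("model error vanishes iff the projections coincide", {
  set.seed(5)
  Y <- mk_diffspec(matrix(rnorm(60), 6))
  expect_equal(model_error(Y, Y), 0)
  # negated model: projections negate, error is twice the data projection RMS
  D <- mk_diffspec(-Y$values, Y$freq, Y$time)
  Yn <- Y$values / sqrt(sum(Y$values^2))
  u <- svd(Yn)$u[, 1]
  expect_equal(model_error(D, Y), 2 * sqrt(mean(crossprod(u, Yn)^2)),
               tolerance = 1e-12)
})

test_that("rank-one data recovers its time course under projection", {
  set.seed(6)
  u <- rnorm(8); v <- rnorm(12)
  Y <- mk_diffspec(u %*% t(v))
  D <- mk_diffspec(2 * (u %*% t(v)))            # same direction, new scale
  # after unit normalization both match exactly
  expect_lt(model_error(D, Y), 1e-10)
  # brute-force oracle: for Y = u v^T the projection onto the first left
  # singular vector recovers v (up to sign) after unit normalization
  Yn <- Y$values / sqrt(sum(Y$values^2))
  u1 <- svd(Yn)$u[, 1]
  proj <- as.numeric(crossprod(u1, Yn))
  expect_lt(max(abs(abs(proj) - abs(v) / sqrt(sum(v^2)))), 1e-10)
  expect_error(model_error(mk_diffspec(matrix(0, 3, 3)), Y), "dimensions")
})

test_that("log likelihood is negative error over temperature", {
  expect_equal(log_likelihood(0), 0)
  expect_equal(log_likelihood(1, lambda = 2), -0.5)
  # doubling the error multiplies the likelihood ratio by exp(-E)
  expect_equal(exp(log_likelihood(2)) / exp(log_likelihood(1)), exp(-1))
})

test_that("proposal widths follow the prior ranges divided by S", {
  pr <- model_priors("M0")
  sigma <- (pr$max - pr$min) / 8
  expect_equal(sigma[pr$name == "t_b"], 0.0125)   # 12.5 ms
  expect_equal(sigma[pr$name == "f_b"], 3.75)
  expect_equal(sigma[pr$name == "f_max"], 12.5)
  expect_equal(sigma[pr$name == "A"], 0.375)
})

test_that("a flat likelihood recovers the uniform prior", {
  pr <- model_priors("M0")
  ch <- mh_sample(pr, function(th) 0,
                  mh_config(n_iter = 20000, n_burn = 2000, seed = 7))
  expect_true(all(ch$samples$t_b >= 0.2 & ch$samples$t_b <= 0.3))
  expect_true(all(ch$samples$A >= -3 & ch$samples$A <= 0))
  thin <- ch$samples[seq(1, nrow(ch$samples), by = 20), ]
  for (p in names(thin)) {
    stat <- ks_stat_unif(thin[[p]], pr$min[pr$name == p],
                         pr$max[pr$name == p])
    expect_lt(stat, 1.63 / sqrt(nrow(thin)) * 1.5)  # 1% critical, slack for
  }                                                  # residual autocorrelation
})

test_that("a sharply peaked target pulls the posterior mean to its mode", {
  pr <- model_priors("M0")
  mid <- (pr$min + pr$max) / 2
  scl <- (pr$max - pr$min) / 20
  ch <- mh_sample(pr, function(th) -sum(((unlist(th) - mid) / scl)^2),
                  mh_config(n_iter = 8000, n_burn = 2000, seed = 3))
  m <- colMeans(as.matrix(ch$samples))
  # posterior sd is ~ scl/sqrt(2); allow 3 Monte-Carlo standard errors with
  # a generous effective sample size discount for autocorrelation
  mc_se <- scl / sqrt(2) / sqrt(nrow(ch$samples) / 40)
  expect_true(all(abs(m - mid) < 3 * mc_se))
})

test_that("non-finite initial likelihood is rejected", {
  pr <- model_priors("M0")
  expect_error(mh_sample(pr, function(th) -Inf, mh_config(n_iter = 10,
                                                          n_burn = 5)),
               "non-finite")
})

test_that("posterior harmonic mean evidence matches hand values", {
  const <- structure(list(log_lik = rep(log(0.7), 40)),
                     class = "wcots_chain")
  expect_equal(phm_evidence(const), 0.7)
  two <- structure(list(log_lik = log(c(1, 1 / 3))), class = "wcots_chain")
  expect_equal(phm_evidence(two), 0.5)          # [ (1 + 3) / 2 ]^-1
  # a model against itself gives a Bayes factor of one
  expect_equal(phm_evidence(two) / phm_evidence(two), 1)
  empty <- structure(list(log_lik = numeric()), class = "wcots_chain")
  expect_error(phm_evidence(empty), "empty")
})

test_that("harmonic mean matches exact evidence on an enumerable toy", {
  # three states, uniform prior: Z = mean(L); posterior p_s  propto L_s
  L <- c(0.2, 0.5, 0.9)
  Z <- mean(L)
  set.seed(8)
  draws <- sample(1:3, 40000, replace = TRUE, prob = L / sum(L))
  ch <- structure(list(log_lik = log(L[draws])), class = "wcots_chain")
  expect_equal(phm_evidence(ch), Z, tolerance = 0.01)
})

test_that("pair splitting is disjoint and honours exclusions", {
  pairs <- tibble::tibble(pair_id = 1:10)
  sp <- split_pairs(pairs, n_train = 4, exclude = c(2, 7), seed = 1)
  expect_equal(nrow(sp$train), 4)
  expect_equal(nrow(sp$test), 4)
  expect_length(intersect(sp$train$pair_id, sp$test$pair_id), 0)
  expect_false(any(c(2, 7) %in% c(sp$train$pair_id, sp$test$pair_id)))
})
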
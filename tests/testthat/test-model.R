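test_that("bin indices map to angles on [0, 2*pi)", {
  expect_equal(position_to_angle(1000, 1000), 0)
  expect_equal(position_to_angle(500, 1000), pi)
  expect_equal(position_to_angle(1, 1000), 0.0062832, tolerance = 1e-4)
  expect_error(position_to_angle(0, 10), "range")
  expect_error(position_to_angle(11, 10), "range")
})

test_that("weighted log-likelihood equals the observation-expansion oracle", {
  sp <- dist_spec("von_mises")
  tr <- toy_track(c(3, 0, 5, 1, 2))
  pr <- list(mu = pi, kappa = 0.7)
  theta <- position_to_angle(1:5, 5)
  oracle <- sum(circ_density(sp, rep(theta, times = tr$depths), pr, log = TRUE))
  expect_equal(coverage_loglik(tr, sp, pr), oracle, tolerance = 1e-12)
  # uniform limit: loglik = T * log(1/2pi) for any depths
  expect_equal(coverage_loglik(tr, sp, list(mu = 1, kappa = 0)),
               tr$total * log(1 / (2 * pi)), tolerance = 1e-12)
  expect_equal(coverage_loglik(toy_track(c(0, 1, 0)), sp,
                               list(mu = 0, kappa = 0)),
               log(1 / (2 * pi)), tolerance = 1e-12)
  expect_error(coverage_loglik(toy_track(c(0, 0, 0)), sp, pr), "degenerate")
})

test_that("likelihood is equivariant under cyclic rotation of the track", {
  set.seed(2)
  d <- rpois(40, 6)
  sp <- dist_spec("von_mises")
  shift <- 11L
  ll1 <- coverage_loglik(toy_track(d), sp, list(mu = 1.1, kappa = 0.5))
  d2 <- c(d[(40 - shift + 1):40], d[1:(40 - shift)])
  ll2 <- coverage_loglik(toy_track(d2), sp,
                         list(mu = 1.1 + shift / 40 * 2 * pi, kappa = 0.5))
  expect_equal(ll1, ll2, tolerance = 1e-8)
})

test_that("multinomial form adds a parameter-free combinatorial constant", {
  sp <- dist_spec("von_mises")
  tr <- toy_track(c(4, 1, 0, 3, 2, 6))
  set.seed(5)
  diffs <- replicate(10, {
    pr <- list(mu = runif(1, 0, 2 * pi), kappa = runif(1, 0, 2))
    coverage_loglik_multinomial(tr, sp, pr) - coverage_loglik(tr, sp, pr)
  })
  expect_lt(diff(range(diffs)), 1e-9)
  # exact integer oracle: log T! - sum log d_i!
  expect_equal(diffs[1],
               log(factorial(16)) - sum(log(factorial(tr$depths))),
               tolerance = 1e-9)
  # a single observation has no combinatorial term
  tr1 <- toy_track(c(0, 1, 0, 0))
  expect_equal(coverage_loglik_multinomial(tr1, sp, list(mu = 0, kappa = 1)),
               coverage_loglik(tr1, sp, list(mu = 0, kappa = 1)))
})

test_that("binomial depth predictive matches simulation moments", {
  sp <- dist_spec("von_mises")
  tr <- generate_coverage(sp, list(mu = pi, kappa = 0.7), length_I = 200,
                          mean_depth = 10, seed = 42)
  pred <- binomial_depth_predictive(tr, sp, list(mu = pi, kappa = 0.7), 1:200)
  expect_true(all(pred$p < 1))
  # uniform density: p_i = 1/I exactly
  u <- binomial_depth_predictive(tr, sp, list(mu = 0, kappa = 0), 1:200)
  expect_equal(u$p, rep(1 / 200, 200), tolerance = 1e-12)
  # Monte-Carlo check of mean and variance at the modal bin
  i_mode <- 100L
  set.seed(9)
  draws <- rbinom(1e5, tr$total, pred$p[i_mode])
  expect_equal(mean(draws), pred$mean[i_mode], tolerance = 0.01)
  expect_equal(var(draws), pred$variance[i_mode], tolerance = 0.05)
  # mode bin attracts more depth than the antipode in expectation
  expect_gt(pred$mean[100], pred$mean[200])
})

test_that("half-t prior: folding identity and pPTR-2 calibration", {
  expect_equal(dhalf_t(0, 2.5, 0.2), 2 * dt(0, 2.5) / 0.2, tolerance = 1e-12)
  expect_equal(dhalf_t(0.3, 2.5, 0.2), 2 * dt(0.3 / 0.2, 2.5) / 0.2,
               tolerance = 1e-12)
  kap2 <- concentration_for_pptr(dist_spec("von_mises"), 2)
  expect_equal(phalf_t(kap2, 2.5, 0.2), 0.8, tolerance = 0.05)
})

test_that("log prior combines half-t, Gaussian and Dirichlet pieces", {
  pri <- ptr_priors("von_mises")
  lp <- log_prior(dist_spec("von_mises"), list(kappa = 0.4), pri)
  expect_equal(lp, dhalf_t(0.4, 2.5, 0.2, log = TRUE), tolerance = 1e-12)
  # Dirichlet(50/3) at the equal-weight point, against a log-gamma oracle
  alpha <- rep(1 / 3, 3)
  A <- 50 / 3
  oracle <- lgamma(3 * A) - 3 * lgamma(A) + sum((A - 1) * log(alpha))
  lp_mix <- log_prior(dist_spec("von_mises"),
                      list(kappa = 0.4, alpha = alpha), pri)
  expect_equal(lp_mix, dhalf_t(0.4, 2.5, 0.2, log = TRUE) + oracle,
               tolerance = 1e-10)
  expect_error(log_prior(dist_spec("von_mises"),
                         list(kappa = 0.4, alpha = c(0.6, 0.6)), pri),
               "sum to 1", class = "circptr_invalid_parameter")
})

test_that("discrete normalization constants follow the closed forms", {
  expect_equal(discrete_normalization_constant(dist_spec("cardioid"),
                                               list(mu = 1, kappa = 0.2), 100),
               100 / (2 * pi), tolerance = 1e-12)
  expect_equal(discrete_normalization_constant(dist_spec("linear_cardioid"),
                                               list(mu = 1, kappa = 0.2), 100),
               102 / (2 * pi), tolerance = 1e-12)
  cvm <- discrete_normalization_constant(dist_spec("von_mises"),
                                         list(mu = 0.3, kappa = 0.7), 1000)
  expect_equal(cvm, 1000 / (2 * pi), tolerance = 0.005 * 1000 / (2 * pi))
  expect_error(discrete_normalization_constant(dist_spec("jones_pewsey"),
                                               list(mu = 0, kappa = 1, psi = 1),
                                               100), "implemented")
})

test_that("mixture likelihood reduces exactly and matches a direct oracle", {
  sp <- dist_spec("von_mises")
  tr <- toy_track(c(5, 2, 0, 7, 1, 3, 2, 4))
  # M = 1 reduction is bit-for-bit the single-origin likelihood
  expect_identical(
    mixture_loglik(tr, sp, list(mu = 2, kappa = 0.8, alpha = 1)),
    coverage_loglik(tr, sp, list(mu = 2, kappa = 0.8)))
  # a zero-weight component contributes nothing
  expect_equal(
    mixture_loglik(tr, sp, list(mu = c(2, 5), kappa = c(0.8, 1.5),
                                alpha = c(1, 0))),
    coverage_loglik(tr, sp, list(mu = 2, kappa = 0.8)), tolerance = 1e-12)
  # M = 3 against a naive non-log-space computation
  mix <- list(mu = c(1, 3, 5), kappa = c(0.5, 1, 0.2), alpha = c(0.5, 0.3, 0.2))
  theta <- position_to_angle(1:8, 8)
  dens <- sapply(1:3, function(m)
    mix$alpha[m] * circ_density(sp, theta, list(mu = mix$mu[m],
                                                kappa = mix$kappa[m])))
  naive <- sum(tr$depths * log(rowSums(dens)))
  expect_equal(mixture_loglik(tr, sp, mix), naive, tolerance = 1e-8)
  # permutation invariance
  perm <- c(3, 1, 2)
  expect_equal(mixture_loglik(tr, sp, list(mu = mix$mu[perm],
                                           kappa = mix$kappa[perm],
                                           alpha = mix$alpha[perm])),
               mixture_loglik(tr, sp, mix), tolerance = 1e-10)
  expect_error(mixture_loglik(tr, sp, list(mu = c(1, 2), kappa = c(1, 1),
                                           alpha = c(0.7, 0.6))),
               "sum to 1", class = "circptr_invalid_parameter")
})

test_that("weighted PTRs and their chromosome-level mean", {
  # M = 1: the weighted PTR is the plain pPTR
  w1 <- wptr(list(mu = 0, kappa = 0.34657, alpha = 1))
  expect_equal(as.vector(w1$wptr), pptr(dist_spec("von_mises"),
                                        list(kappa = 0.34657)))
  # arithmetic reduction of per-origin scores to the chromosome score
  expect_equal(mean(c(3.59, 3.18, 2.66)), 3.143333, tolerance = 1e-6)
  kap <- log(c(3.59, 3.18, 2.66)) / (2 * (1 / 3))
  w <- wptr(list(mu = c(1, 2, 3), kappa = kap, alpha = rep(1 / 3, 3)))
  expect_equal(as.vector(w$wptr), c(3.59, 3.18, 2.66), tolerance = 1e-12)
  expect_equal(unname(w$mwptr), 3.143333, tolerance = 1e-6)
  w2 <- wptr(list(mu = c(0, pi), kappa = c(1, 1), alpha = c(0.5, 0.5)))
  expect_equal(as.vector(w2$wptr), c(exp(1), exp(1)))
  expect_equal(unname(w2$mwptr), exp(1))
  expect_error(wptr(list(mu = 0, kappa = 1), family = "cardioid"), "von Mises")
})

test_that("location reparameterization wraps atan2 to [0, 2*pi)", {
  expect_equal(location_from_vector(c(1, 0)), 0)
  expect_equal(location_from_vector(c(0, -1)), 3 * pi / 2)
  set.seed(8)
  for (mu in runif(100, 0, 2 * pi))
    expect_equal(location_from_vector(c(cos(mu), sin(mu))), mu,
                 tolerance = 1e-12)
  expect_error(location_from_vector(c(0, 0)), "non-zero")
})
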
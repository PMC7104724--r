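sp_vm <- dist_spec("von_mises")

test_that("MAP fitting recovers simulated parameters", {
  tr <- generate_coverage(sp_vm, list(mu = 0, kappa = 0.7), length_I = 1000,
                          mean_depth = 16, seed = 21)
  fit <- ptr_fit(tr, seed = 1)
  kl <- kl_divergence(sp_vm, list(mu = 0, kappa = 0.7),
                      sp_vm, list(mu = fit$params$mu,
                                  kappa = unname(fit$params$kappa)))
  expect_lt(kl, 0.01)
  # flat track: prior shrinks the concentration to (almost) uniform
  flat <- coverage_track(rep(10, 400))
  expect_lt(unname(ptr_fit(flat, seed = 1)$pptr), 1.05)
  # determinism of the restart bookkeeping
  f1 <- ptr_fit(tr, n_seeds = 2, seed = 5)
  f2 <- ptr_fit(tr, n_seeds = 2, seed = 5)
  expect_identical(coef(f1), coef(f2))
})

test_that("MAP under flat priors matches the weighted ML estimate", {
  tr <- generate_coverage(sp_vm, list(mu = 2, kappa = 0.5), length_I = 2000,
                          mean_depth = 500, seed = 22)  # T = 1e6
  fit <- ptr_fit(tr, priors = NULL, seed = 1)
  kap_hat <- vm_mle_kappa(position_to_angle(1:2000, 2000), tr$depths)
  expect_equal(unname(fit$params$kappa), kap_hat, tolerance = 0.02)
})

test_that("estimates are invariant under cyclic rotation of the input", {
  tr <- generate_coverage(sp_vm, list(mu = 1, kappa = 0.6), length_I = 800,
                          mean_depth = 10, seed = 23)
  shift <- 200L
  rot <- coverage_track(c(tr$depths[(800 - shift + 1):800],
                          tr$depths[1:(800 - shift)]))
  f0 <- ptr_fit(tr, seed = 1)
  f1 <- ptr_fit(rot, seed = 1)
  expect_equal(unname(f1$pptr), unname(f0$pptr), tolerance = 1e-3)
  expect_equal(circptr:::wrap_angle(f1$params$mu - shift / 800 * 2 * pi),
               f0$params$mu, tolerance = 1e-2)
})

test_that("parameter counts follow the information-criterion rule", {
  set.seed(24)
  tracks <- lapply(1:4, function(s)
    generate_coverage(sp_vm, list(mu = 1, kappa = 0.4), length_I = 150,
                      mean_depth = 4, sample_id = paste0("s", s)))
  expect_equal(ptr_fit(tracks, seed = 1)$k, 5L)          # 1 + S
  expect_equal(ptr_fit(tracks, family = "jones_pewsey", seed = 1)$k, 9L)  # 1 + 2S
  m3 <- circptr:::.model_ctx(tracks, sp_vm, 3L, ptr_priors(), 20L)
  expect_equal(3L + 3L * 4L + 2L,
               3L + m3$M * m3$S + (m3$M - 1L))
})

test_that("information criteria and the likelihood-ratio test", {
  fake <- structure(list(spec = sp_vm, M = 1L, mode = "optimizing",
                         k = 3L, loglik = -100, T_s = c(50, 50)),
                    class = "ptr_fit")
  ic <- information_criteria(fake)
  expect_equal(ic$aic, 206)
  expect_equal(ic$bic, 3 * log(100) + 200)
  expect_error(information_criteria(fake, include_waic = TRUE), "unavailable")
  null <- structure(list(spec = sp_vm, k = 2L, loglik = -100), class = "ptr_fit")
  same <- structure(list(spec = sp_vm, k = 3L, loglik = -100), class = "ptr_fit")
  expect_equal(likelihood_ratio_test(null, same)$p_value, 1)
  ext <- structure(list(spec = sp_vm, k = 3L, loglik = -100 + 3.841 / 2),
                   class = "ptr_fit")
  expect_equal(likelihood_ratio_test(null, ext)$p_value, 0.05, tolerance = 1e-3)
  worse <- structure(list(spec = sp_vm, k = 3L, loglik = -101), class = "ptr_fit")
  expect_warning(likelihood_ratio_test(null, worse), "lower log-likelihood")
})

test_that("the LRT detects Jones-Pewsey shape against a von Mises null", {
  set.seed(25)
  sp_jp <- dist_spec("jones_pewsey")
  hits <- replicate(20, {
    tr <- generate_coverage(sp_jp, list(mu = 3, kappa = 0.7, psi = 0.8),
                            length_I = 400, mean_depth = 10)
    f0 <- ptr_fit(tr, seed = 1)
    f1 <- ptr_fit(tr, family = "jones_pewsey", seed = 1)
    likelihood_ratio_test(f0, f1, df_delta = 1)$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("HMC sampling is reproducible and passes its own diagnostics", {
  tr <- generate_coverage(sp_vm, list(mu = pi, kappa = 0.35), length_I = 600,
                          mean_depth = 10, seed = 26)
  fs <- ptr_fit(tr, mode = "sampling", seed = 4)
  expect_true(fs$accepted)
  expect_true(all(fs$rhat <= 1.1, na.rm = TRUE))
  expect_equal(fs$n_draws, 200L)
  fs2 <- ptr_fit(tr, mode = "sampling", seed = 4)
  expect_identical(fs$draws, fs2$draws)
  # EAP close to the MAP on the same data
  fm <- ptr_fit(tr, seed = 4)
  expect_equal(unname(fs$pptr), unname(fm$pptr), tolerance = 0.1)
  # WAIC exists and is on the deviance scale
  expect_true(is.finite(fs$waic))
  expect_equal(fs$waic, -2 * fs$loglik, tolerance = 0.05)
})

test_that("split Rhat: constant chains are accepted, drifting ones are not", {
  expect_equal(split_rhat(rep(2.5, 100)), 1.0)
  set.seed(27)
  expect_lt(split_rhat(rnorm(400)), 1.05)
  expect_gt(split_rhat(cumsum(rnorm(400)) + seq(0, 20, length.out = 400)), 1.1)
})

test_that("WAIC matches the log-mean-exp / variance-penalty formula", {
  set.seed(28)
  ll <- matrix(rnorm(50 * 7, mean = -3), nrow = 50)
  res <- circptr:::.waic_from_pointwise(ll)
  lppd <- sum(log(colMeans(exp(ll))))
  p <- sum(apply(ll, 2, var))
  expect_equal(res$waic, -2 * (lppd - p), tolerance = 1e-10)
})

test_that("origin-count selection behaves on degenerate ranges", {
  tr <- generate_coverage(sp_vm, list(mu = 2, kappa = 0.6), length_I = 500,
                          mean_depth = 10, seed = 29)
  sel1 <- select_origin_count(tr, M_range = 1, use_mcmc = FALSE, map_seeds = 2)
  expect_equal(sel1$chosen, 1)
  expect_equal(nrow(sel1$table), 1L)
  # single-origin data does not grow spurious components
  sel <- select_origin_count(tr, M_range = 1:2, use_mcmc = FALSE,
                             map_seeds = 5, seed = 2)
  expect_equal(sel$chosen, 1)
})

test_that("fit methods: predict, residuals, simulate, serialization", {
  tr <- generate_coverage(sp_vm, list(mu = 1, kappa = 0.5), length_I = 300,
                          mean_depth = 8, seed = 30)
  fit <- ptr_fit(tr, seed = 1)
  expect_equal(length(predict(fit)), 300L)
  expect_equal(sum(predict(fit, type = "depth")), tr$total, tolerance = 0.01)
  expect_equal(dim(residuals(fit)), c(300L, 1L))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  expect_equal(attr(logLik(fit), "df"), 2L)
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2L)
  expect_equal(sims[[1]]$total, tr$total)
  js <- jsonlite::fromJSON(write_fit_json(fit))
  expect_equal(js$family, "von_mises")
  expect_equal(js$pptr, unname(fit$pptr), tolerance = 1e-9)
})
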
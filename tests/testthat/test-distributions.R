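test_that("every family's density integrates to one", {
  set.seed(42)
  fams <- c("von_mises", "cardioid", "wrapped_cauchy", "jones_pewsey",
            "linear_cardioid", "exp_linear_cardioid")
  for (fam in fams) {
    for (r in 1:5) {
      ub <- circptr:::conc_upper_bound(fam)
      conc <- if (is.finite(ub)) runif(1, 0, ub - 0.02) else runif(1, 0, 1.5)
      pr <- list(mu = runif(1, 0, 2 * pi), kappa = conc,
                 psi = runif(1, -1, 1))
      I <- simpson_integrate(function(t) circ_density(dist_spec(fam), t, pr),
                             n = 2000)
      expect_lt(abs(I - 1), 1e-6)
    }
  }
})

test_that("extended densities stay normalized over random draws", {
  set.seed(7)
  for (ext in c("SE", "InvSE", "MIAE", "InvMIAE")) {
    for (base in c("von_mises", "cardioid")) {
      for (r in 1:6) {
        pr <- list(mu = runif(1, 0, 2 * pi),
                   kappa = if (base == "von_mises") runif(1, 0.05, 1.5)
                           else runif(1, 0, 0.45),
                   lam = runif(1, -0.85, 0.85), nu = runif(1, -0.85, 0.85))
        I <- simpson_integrate(function(t)
          circ_density(dist_spec(base, ext), t, pr), n = 2000)
        expect_lt(abs(I - 1), 1e-5)
      }
    }
  }
})

test_that("log density matches closed forms and a Bessel series oracle", {
  sp <- dist_spec("von_mises")
  expect_equal(circ_density(sp, 0, list(mu = 0, kappa = 0), log = TRUE),
               log(1 / (2 * pi)), tolerance = 1e-12)
  expect_equal(
    circ_density(dist_spec("cardioid"), 0.7, list(mu = 0.7, kappa = 0.16666),
                 log = TRUE),
    log((1 + 2 * 0.16666) / (2 * pi)), tolerance = 1e-12)
  # vM at mu + pi/3, kappa = 1, against an independent >=30-term series for I0
  lp <- circ_density(sp, pi / 3, list(mu = 0, kappa = 1), log = TRUE)
  expect_equal(lp, 1 * cos(pi / 3) - log(2 * pi) - series_log_I0(1),
               tolerance = 1e-12)
})

test_that("analytic pPTR equals the grid max/min ratio for all families", {
  set.seed(11)
  fams <- c("von_mises", "cardioid", "wrapped_cauchy", "jones_pewsey",
            "linear_cardioid", "exp_linear_cardioid")
  for (fam in fams) {
    for (r in 1:8) {
      ub <- circptr:::conc_upper_bound(fam)
      conc <- if (is.finite(ub)) runif(1, 0.01, ub - 0.02) else runif(1, 0.05, 1.5)
      pr <- list(mu = runif(1, 0, 2 * pi), kappa = conc, psi = runif(1, -1, 1))
      expect_equal(pptr(dist_spec(fam), pr), grid_pptr(dist_spec(fam), pr),
                   tolerance = 1e-4)
    }
  }
  # the printed linear cardioid calibration, against a dense grid
  expect_equal(grid_pptr(dist_spec("linear_cardioid"), list(kappa = 0.1061),
                         n = 1e6), 2.0, tolerance = 1e-3)
})

test_that("pPTR of Jones-Pewsey does not depend on the shape parameter", {
  for (psi in c(-0.5, 0.5, 1.0)) {
    pr <- list(mu = 0, kappa = 0.6, psi = psi)
    expect_equal(pptr(dist_spec("jones_pewsey"), pr), exp(2 * 0.6))
    expect_equal(grid_pptr(dist_spec("jones_pewsey"), pr), exp(2 * 0.6),
                 tolerance = 1e-4)
  }
})

test_that("Jones-Pewsey converges to von Mises as psi -> 0", {
  theta <- seq(0, 2 * pi, length.out = 721)
  vm <- circ_density(dist_spec("von_mises"), theta, list(mu = 1, kappa = 0.8))
  for (psi in c(1e-3, 1e-4)) {
    jp <- circ_density(dist_spec("jones_pewsey"), theta,
                       list(mu = 1, kappa = 0.8, psi = psi))
    expect_lt(max(abs(jp - vm)), 1e-3)
  }
  # psi = 0 is handled as exactly von Mises
  expect_equal(circ_density(dist_spec("jones_pewsey"), theta,
                            list(mu = 1, kappa = 0.8, psi = 0)), vm)
})

test_that("vanilla densities are symmetric about the location", {
  delta <- seq(0.1, 3, by = 0.35)
  for (fam in c("von_mises", "cardioid", "wrapped_cauchy", "jones_pewsey",
                "linear_cardioid", "exp_linear_cardioid")) {
    pr <- list(mu = 2.2, kappa = 0.2, psi = 0.7)
    expect_equal(circ_density(dist_spec(fam), 2.2 + delta, pr),
                 circ_density(dist_spec(fam), 2.2 - delta, pr),
                 tolerance = 1e-12)
  }
})

test_that("concentration_for_pptr inverts the analytic pPTR", {
  expect_equal(concentration_for_pptr(dist_spec("von_mises"), 2),
               log(2) / 2, tolerance = 1e-12)
  expect_equal(concentration_for_pptr(dist_spec("cardioid"), 1), 0)
  expect_equal(concentration_for_pptr(dist_spec("exp_linear_cardioid"), 2),
               log(2) / (2 * pi), tolerance = 1e-12)
  for (fam in c("von_mises", "cardioid", "wrapped_cauchy", "jones_pewsey",
                "linear_cardioid", "exp_linear_cardioid")) {
    for (target in c(1, 1.3, 2, 5)) {
      conc <- concentration_for_pptr(dist_spec(fam), target)
      expect_equal(pptr(dist_spec(fam), list(kappa = conc, psi = 0.5)),
                   target, tolerance = 1e-10)
    }
  }
  expect_error(concentration_for_pptr(dist_spec("von_mises"), 0.8), "target")
})

test_that("kappa-to-rho alignment conversions", {
  expect_equal(rho_from_kappa("cardioid", 0), 0)
  expect_equal(rho_from_kappa("cardioid", 1), tanh(1) / 2, tolerance = 1e-15)
  expect_gt(rho_from_kappa("wrapped_cauchy", 50), 0.999999)
  expect_error(rho_from_kappa("von_mises", 1), "conversion")
})

test_that("mean resultant length: degenerate, symmetric and weighted cases", {
  expect_equal(mean_resultant_length(rep(1.2, 5)), 1.0, tolerance = 1e-12)
  expect_equal(mean_resultant_length(c(0, pi / 2, pi, 3 * pi / 2)), 0,
               tolerance = 1e-12)
  set.seed(3)
  theta <- 2 * pi * (1:100) / 100
  w <- rpois(100, 3)
  w[1] <- w[1] + 1  # ensure positive total
  expanded <- rep(theta, times = w)
  expect_equal(mean_resultant_length(theta, w),
               mean_resultant_length(expanded), tolerance = 1e-12)
  expect_error(mean_resultant_length(numeric(0)), "weight")
})

test_that("parameter bounds are enforced with informative errors", {
  expect_error(circ_density(dist_spec("cardioid"), 0, list(mu = 0, kappa = 0.5)),
               "bound", class = "circptr_invalid_parameter")
  expect_error(circ_density(dist_spec("von_mises"), 0, list(mu = 0, kappa = -1)),
               ">= 0", class = "circptr_invalid_parameter")
  expect_error(circ_density(dist_spec("jones_pewsey"), 0, list(mu = 0, kappa = 1)),
               "psi", class = "circptr_invalid_parameter")
  expect_error(pptr(dist_spec("cardioid"), list(kappa = 0.51)), "pole",
               class = "circptr_invalid_parameter")
  expect_error(circ_density(dist_spec("von_mises", "SE"), 0,
                            list(mu = 0, kappa = 1, lam = 1)),
               "lambda", class = "circptr_invalid_parameter")
})
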
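# shared oracles and fixture builders

# von Mises log I0 by series expansion (independent of base R's besselI)
series_log_I0 <- function(kappa, terms = 40L) {
  k <- 0:(terms - 1L)
  log(sum((kappa^2 / 4)^k / factorial(k)^2))
}

# grid peak-to-trough ratio of a density
grid_pptr <- function(spec, params, n = 1e5) {
  theta <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  dens <- circ_density(spec, theta, params)
  max(dens) / min(dens)
}

# weighted MLE of the von Mises concentration via the mean resultant length
vm_mle_kappa <- function(theta, weights) {
  C <- sum(weights * cos(theta)); S <- sum(weights * sin(theta))
  rbar <- sqrt(C^2 + S^2) / sum(weights)
  A <- function(k) besselI(k, 1, TRUE) / besselI(k, 0, TRUE)
  stats::uniroot(function(k) A(k) - rbar, c(1e-8, 500), tol = 1e-12)$root
}

toy_track <- function(depths, id = "toy") coverage_track(depths, sample_id = id)

# run the installed CLI script in a subprocess with the test library visible
run_cli <- function(args) {
  script <- system.file("cli", "circptr.R", package = "circptr")
  rscript <- file.path(R.home("bin"), "Rscript")
  out <- suppressWarnings(
    system2(rscript, c(shQuote(script), args), stdout = TRUE, stderr = TRUE,
            env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  list(status = attr(out, "status") %||% 0L, output = out)
}
`%||%` <- function(a, b) if (is.null(a)) b else a
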
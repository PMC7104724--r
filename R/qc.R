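#' Lander-Waterman coverage quality control
#'
#' Under uniform random sequencing with average coverage \eqn{a}, the
#' expected zero-coverage fraction is \eqn{\hat f = \exp(-a)}. Samples whose
#' observed zero fraction deviates strongly from this expectation carry
#' non-random (noisy or concentrated) coverage and give unreliable growth
#' estimates. The filter used here: for samples with average coverage below
#' 5.0x, flag when \eqn{\log f > 0.56 \log \hat f} (i.e. substantially more
#' zero coverage than random sampling predicts; both logs are negative).
#' Samples with a fitted PTR of 3.0 or more are flagged separately, and
#' samples below a minimal average coverage (default 0.01x) fail outright.
#'
#' @param track a [coverage_track()] (zero fraction is computed on the binned
#'   track).
#' @param pptr optional fitted peak-to-trough ratio for the cap check.
#' @param low_coverage_limit minimal acceptable average coverage.
#' @param noise_coverage_limit coverage below which the zero-fraction rule
#'   applies (default 5.0).
#' @param multiplier the 0.56 factor of the rule.
#' @param pptr_cap exclusion threshold on the fitted PTR (default 3.0).
#' @param log_scale apply the multiplier to the log theoretical score
#'   (default, `log(f) > 0.56 * log(fhat)`); if `FALSE`, the multiplier is
#'   applied to the raw theoretical score (`log(f) > 0.56 * fhat`), the
#'   alternative literal reading of the rule (it essentially never fires and
#'   is provided only for sensitivity analysis).
#' @return an object of class `"qc_report"`: list with `avg_coverage`,
#'   `zero_fraction`, `theoretical_fraction`, `log_ratio` and logical `flags`.
#' @export
lander_waterman_check <- function(track, pptr = NULL,
                                  low_coverage_limit = 0.01,
                                  noise_coverage_limit = 5,
                                  multiplier = 0.56, pptr_cap = 3,
                                  log_scale = TRUE) {
  a <- track$total / track$I
  f <- mean(track$depths == 0)
  fhat <- exp(-a)
  log_ratio <- if (f > 0) log(f) / log(fhat) else NA_real_
  noise_fail <- FALSE
  if (a < noise_coverage_limit && f > 0) {
    noise_fail <- if (log_scale) log(f) > multiplier * log(fhat)
                  else log(f) > multiplier * fhat
  }
  flags <- list(low_coverage_fail = a <= low_coverage_limit,
                noise_fail = noise_fail,
                pptr_cap_fail = !is.null(pptr) && pptr >= pptr_cap)
  structure(list(sample_id = track$sample_id, avg_coverage = a,
                 zero_fraction = f, theoretical_fraction = fhat,
                 log_ratio = log_ratio, flags = flags,
                 pass = !any(unlist(flags))),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %s: coverage %.3gx, zero fraction %.3g (theory %.3g)\n",
              x$sample_id, x$avg_coverage, x$zero_fraction,
              x$theoretical_fraction))
  cat("  flags:", paste(names(x$flags)[unlist(x$flags)], collapse = ", "),
      if (x$pass) "(pass)" else "(fail)", "\n")
  invisible(x)
}

#' Absolute relative error of a growth estimate
#'
#' \eqn{|(est - ref)/ref|}; estimates within the conventional 15% threshold
#' of the reference are considered reproduced.
#'
#' @param estimate estimate(s) from modified/rarefied data.
#' @param reference reference estimate(s), non-zero.
#' @param threshold acceptance threshold on the error (default 0.15).
#' @return list with `error` (vectorized) and logical `within_threshold`.
#' @export
error_rate <- function(estimate, reference, threshold = 0.15) {
  if (any(reference == 0)) stop("reference estimate must be non-zero")
  err <- abs((estimate - reference) / reference)
  list(error = err, within_threshold = err <= threshold)
}

#' Experimental growth rate from an abundance time series
#'
#' Centered differences
#' \eqn{gr_i = (\log_2 a_{i+1} - \log_2 a_{i-1}) / (t_{i+1} - t_{i-1})}
#' (endpoints omitted) or forward differences
#' \eqn{(\log_2 a_{i+1} - \log_2 a_i)/(t_{i+1} - t_i)}.
#'
#' @param abundance positive abundances (CFU/ml, OD, or relative abundance).
#' @param times strictly increasing observation times.
#' @param mode `"centered"` or `"forward"`.
#' @return data.frame with `time` and `growth_rate`.
#' @export
growth_rate_from_abundance <- function(abundance, times,
                                       mode = c("centered", "forward")) {
  mode <- match.arg(mode)
  if (any(abundance <= 0)) stop("abundances must be positive")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  la <- log2(abundance)
  n <- length(la)
  if (mode == "centered") {
    if (n < 3L) stop("centered differences need at least 3 points")
    idx <- 2:(n - 1L)
    data.frame(time = times[idx],
               growth_rate = (la[idx + 1L] - la[idx - 1L]) /
                 (times[idx + 1L] - times[idx - 1L]))
  } else {
    idx <- 1:(n - 1L)
    data.frame(time = times[idx],
               growth_rate = (la[idx + 1L] - la[idx]) /
                 (times[idx + 1L] - times[idx]))
  }
}

#' Best time delay between growth estimates and experimental rates
#'
#' Pearson correlation between the estimate series (shifted by each candidate
#' lag) and the experimental growth-rate series, matching time points
#' exactly; lags pairing fewer than `min_pairs` points are rejected, and the
#' admissible lag with the highest correlation is returned.
#'
#' @param estimates data.frame/list with `time` and `value` for the model
#'   estimates.
#' @param growth_rates data.frame/list with `time` and `value` for the
#'   experimental rates.
#' @param lag_grid candidate delays, in the unit of `time` (estimate at time
#'   t is paired with the rate at time t + lag).
#' @param min_pairs minimal number of paired points (default 3).
#' @param tol time-matching tolerance.
#' @return list with `lag`, `correlation`, and the per-lag `table`.
#' @export
lagged_correlation <- function(estimates, growth_rates, lag_grid = 0,
                               min_pairs = 3L, tol = 1e-8) {
  res <- lapply(lag_grid, function(lag) {
    i <- outer(estimates$time + lag, growth_rates$time,
               function(a, b) abs(a - b) < tol)
    pairs <- which(i, arr.ind = TRUE)
    if (nrow(pairs) < min_pairs)
      return(data.frame(lag = lag, n = nrow(pairs), correlation = NA_real_))
    data.frame(lag = lag, n = nrow(pairs),
               correlation = stats::cor(estimates$value[pairs[, 1L]],
                                        growth_rates$value[pairs[, 2L]]))
  })
  tab <- do.call(rbind, res)
  ok <- which(!is.na(tab$correlation))
  if (length(ok) == 0L) stop("no lag yields enough paired observations")
  best <- ok[which.max(tab$correlation[ok])]
  list(lag = tab$lag[best], correlation = tab$correlation[best], table = tab)
}
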
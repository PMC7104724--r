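#' Simulate coverage depth from a circular distribution
#'
#' Draws \eqn{T = } `mean_depth * length_I` observation events and distributes
#' them over bins by a multinomial whose success probabilities are
#' proportional to the circular density at the bin angles — the generative
#' structure assumed by the coverage model (each sequenced base is an
#' independent draw of a position, biased toward the replication origin).
#' Defaults emulate a 1 Mnt chromosome binned at 100 nt (10,000 bins) at 20x
#' average depth.
#'
#' @param spec a [dist_spec()].
#' @param params parameter list (scalar concentration; or a mixture list with
#'   `mu`/`kappa`/`alpha` of length M for multiple origins).
#' @param length_I number of bins (default 10000).
#' @param mean_depth average per-bin depth (default 20).
#' @param seed optional integer seed; recorded in the track metadata.
#' @param sample_id sample label.
#' @return a [coverage_track()].
#' @export
generate_coverage <- function(spec, params, length_I = 10000L,
                              mean_depth = 20, seed = NULL,
                              sample_id = "sim") {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (!is.null(seed)) set.seed(seed)
  theta <- position_to_angle(seq_len(length_I), length_I)
  M <- length(params$mu %||% 0)
  if (M > 1L) {
    alpha <- params$alpha %||% rep(1 / M, M)
    dens <- rep(0, length_I)
    for (m in seq_len(M))
      dens <- dens + alpha[m] *
        circ_density(spec, theta, list(mu = params$mu[m],
                                       kappa = params$kappa[m]))
  } else {
    dens <- circ_density(spec, theta, params)
  }
  p <- dens / sum(dens)
  T_total <- round(mean_depth * length_I)
  depths <- as.numeric(stats::rmultinom(1L, T_total, p))
  coverage_track(depths, sample_id = sample_id,
                 meta = list(simulated = TRUE, seed = seed,
                             family = spec$family, extension = spec$extension,
                             params = params, mean_depth = mean_depth))
}

#' Sorted depth profile with its density-quantile curve
#'
#' Sorting the binned depths ascending exposes the replication trend as a
#' smooth ramp; multinomial sampling noise distorts both tails relative to
#' the sorted expected counts even without any injected noise. The companion
#' curve is the sorted vector of expected bin counts \eqn{T p_i} when a
#' specification is supplied.
#'
#' @param track a [coverage_track()].
#' @param spec,params optional distribution giving the expected curve.
#' @return list with `sorted_depth` and (optionally) `expected_curve`.
#' @export
sorted_profile <- function(track, spec = NULL, params = NULL) {
  out <- list(sorted_depth = sort(track$depths))
  if (!is.null(spec)) {
    theta <- track_angles(track)
    dens <- circ_density(spec, theta, params)
    p <- dens / sum(dens)
    out$expected_curve <- sort(track$total * p)
  }
  out
}

#' Inject conserved-region peak noise
#'
#' Adds a uniform depth boost over randomly placed regions, emulating read
#' pileups on conserved elements (rRNA operons, prophages): each of
#' `n_regions` stretches of `region_len` consecutive bins gets `+fold` depth.
#'
#' @param track a [coverage_track()].
#' @param n_regions number of boosted regions.
#' @param region_len region length in bins.
#' @param fold depth added to every bin of a region (0 = identity).
#' @param seed optional seed for region placement.
#' @return the perturbed track; boosted bin indices are recorded in
#'   `meta$noise_bins`.
#' @export
add_peak_noise <- function(track, n_regions = 1L, region_len = 100L,
                           fold = 50, seed = NULL) {
  if (region_len > track$I) stop("region longer than the track")
  if (!is.null(seed)) set.seed(seed)
  depths <- track$depths
  bins <- integer(0)
  for (r in seq_len(n_regions)) {
    start <- sample.int(track$I - region_len + 1L, 1L)
    idx <- start:(start + region_len - 1L)
    depths[idx] <- depths[idx] + fold
    bins <- c(bins, idx)
  }
  meta <- track$meta
  meta$noise_bins <- bins
  coverage_track(depths, sample_id = track$sample_id, meta = meta)
}

#' Rarefy a track to a lower average depth
#'
#' Binomial thinning: each bin's depth is resampled as
#' \eqn{Binomial(d_i, target/current)}, emulating random read subsampling.
#'
#' @param track a [coverage_track()].
#' @param target_mean_depth desired average per-bin depth, at most the
#'   current average.
#' @param seed optional seed.
#' @return the thinned track.
#' @export
rarefy <- function(track, target_mean_depth, seed = NULL) {
  cur <- track$total / track$I
  if (target_mean_depth > cur)
    stop("target mean depth exceeds the current mean depth")
  if (!is.null(seed)) set.seed(seed)
  ratio <- target_mean_depth / cur
  depths <- stats::rbinom(track$I, round(track$depths), ratio)
  meta <- track$meta
  meta$rarefied_to <- target_mean_depth
  coverage_track(depths, sample_id = track$sample_id, meta = meta)
}

#' Kullback-Leibler divergence between two circular densities on a grid
#'
#' Discretizes both densities on `grid_n` equally spaced angles (default
#' 10,000, the discrete length used to represent the true distribution in
#' simulation studies), normalizes, and returns
#' \eqn{\sum_n p_n \log(p_n/q_n)}.
#'
#' @param spec_p,params_p the reference ("true") distribution.
#' @param spec_q,params_q the comparison (e.g. fitted) distribution.
#' @param grid_n grid size.
#' @return the divergence (non-negative, 0 iff identical on the grid).
#' @export
kl_divergence <- function(spec_p, params_p, spec_q, params_q,
                          grid_n = 10000L) {
  theta <- position_to_angle(seq_len(grid_n), grid_n)
  p <- circ_density(spec_p, theta, params_p)
  q <- circ_density(spec_q, theta, params_q)
  p <- p / sum(p); q <- q / sum(q)
  if (any(q <= 0 & p > 0)) stop("q has zero density inside the support of p")
  keep <- p > 0
  sum(p[keep] * log(p[keep] / q[keep]))
}
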
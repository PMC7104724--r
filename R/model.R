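#' Coverage track container
#'
#' A coverage track holds the binned coverage depth of one sample along one
#' circular replicon: depths \eqn{d_i} for bins \eqn{i = 1..I}, total
#' \eqn{T = \sum_i d_i}. Bin \eqn{i} maps to the angle
#' \eqn{\theta_i = i/I \cdot 2\pi}.
#'
#' @param depths non-negative numeric vector of binned depths.
#' @param sample_id label for the sample.
#' @param meta optional list of provenance metadata.
#' @return an object of class `"coverage_track"`.
#' @export
coverage_track <- function(depths, sample_id = "sample", meta = list()) {
  depths <- as.numeric(depths)
  if (length(depths) == 0L) stop("empty depth vector")
  if (any(!is.finite(depths)) || any(depths < 0))
    stop("depths must be finite and non-negative")
  structure(list(sample_id = sample_id, depths = depths,
                 I = length(depths), total = sum(depths), meta = meta),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> %s: %d bins, total depth %.0f (mean %.3g)\n",
              x$sample_id, x$I, x$total, x$total / x$I))
  invisible(x)
}

#' Map a bin index to its angle on the circle
#'
#' Bin \eqn{i} of \eqn{I} maps to \eqn{\theta = i/I \cdot 2\pi}, wrapped to
#' \eqn{[0, 2\pi)} (so bin \eqn{I} maps to 0).
#'
#' @param i bin index (1-based), vectorized.
#' @param I total number of bins.
#' @return angles in \eqn{[0, 2\pi)}.
#' @export
position_to_angle <- function(i, I) {
  if (any(i < 1L) || any(i > I)) stop("bin index out of range [1, I]")
  wrap_angle(i / I * 2 * pi)
}

track_angles <- function(track) position_to_angle(seq_len(track$I), track$I)

as_track_list <- function(x) {
  if (inherits(x, "coverage_track")) return(list(x))
  if (is.numeric(x)) return(list(coverage_track(x)))
  if (is.list(x) && all(vapply(x, inherits, TRUE, "coverage_track"))) {
    if (length(unique(vapply(x, function(t) t$I, 1L))) != 1L)
      stop("all tracks must share one binned reference length")
    return(x)
  }
  stop("'x' must be a coverage_track, a list of them, or a depth vector")
}

# per-sample scalar parameter extraction (kappa/psi/lam/nu recycled over S)
.sample_params <- function(params, s) {
  conc <- params$kappa %||% params$rho
  list(mu = params$mu,
       kappa = rep_len(conc, s)[s],
       psi = if (!is.null(params$psi)) rep_len(params$psi, s)[s],
       lam = if (!is.null(params$lam)) rep_len(params$lam, s)[s],
       nu = if (!is.null(params$nu)) rep_len(params$nu, s)[s])
}

#' Depth-weighted circular log-likelihood
#'
#' The single-origin model: the log-likelihood over samples \eqn{s} and bins
#' \eqn{i} is \eqn{\sum_s \sum_i d_{i,s} \log L(\omega_s | \theta_i)}. The
#' location \eqn{\mu} is shared across samples; the concentration (and any
#' shape/peakedness/skewness parameter) is per sample.
#'
#' @param x a [coverage_track()], list of tracks sharing one reference, or a
#'   numeric depth vector.
#' @param spec a [dist_spec()].
#' @param params list with `mu`, per-sample `kappa`/`rho` (length S or
#'   recycled), and `psi`/`lam`/`nu` as required.
#' @param quad_n Simpson subintervals for internal normalization.
#' @return log-likelihood, a scalar.
#' @export
coverage_loglik <- function(x, spec, params, quad_n = 20L) {
  tracks <- as_track_list(x)
  S <- length(tracks)
  ll <- 0
  for (s in seq_len(S)) {
    tr <- tracks[[s]]
    if (tr$total < 1) stop("degenerate input: track with all-zero depths")
    ps <- .sample_params(params, s)
    nz <- tr$depths > 0
    theta <- track_angles(tr)[nz]
    lp <- circ_density(spec, theta, ps, log = TRUE, quad_n = quad_n)
    ll <- ll + sum(tr$depths[nz] * lp)
  }
  ll
}

#' Full multinomial log-likelihood of binned depths
#'
#' The full multinomial form adds the data-only combinatorial terms
#' \eqn{\sum_s \log T_s! - \sum_{s,i} \log d_{i,s}!} to the depth-weighted
#' circular log-likelihood; the parameter-dependent part is identical, so MAP
#' and posterior shapes are unchanged.
#'
#' @inheritParams coverage_loglik
#' @return log-likelihood including combinatorial constants.
#' @export
coverage_loglik_multinomial <- function(x, spec, params, quad_n = 20L) {
  tracks <- as_track_list(x)
  const <- sum(vapply(tracks, function(tr)
    lgamma(tr$total + 1) - sum(lgamma(tr$depths + 1)), 1.0))
  coverage_loglik(tracks, spec, params, quad_n) + const
}

#' Binomial predictive distribution of the depth at one bin
#'
#' Under multinomial sampling of \eqn{T} observation events, the depth at bin
#' \eqn{i} is \eqn{Binomial(T, p_i)} with
#' \eqn{p_i = f(\theta_i)\cdot 2\pi/I} (density times bin width).
#'
#' @param track a [coverage_track()].
#' @param spec a [dist_spec()].
#' @param params parameter list (scalar concentration).
#' @param i bin index (vectorized).
#' @return list with `p`, `mean` and `variance` of the predicted depth.
#' @export
binomial_depth_predictive <- function(track, spec, params, i) {
  theta <- position_to_angle(i, track$I)
  p <- circ_density(spec, theta, params) * 2 * pi / track$I
  if (any(p >= 1))
    stop("success probability >= 1: binning too coarse for this density")
  list(p = p, mean = track$total * p, variance = track$total * p * (1 - p))
}

#' Half-Student-t density and distribution function
#'
#' The folded Student-t on \eqn{[0, \infty)} used as the prior on
#' concentration parameters.
#'
#' @param x quantiles (\eqn{\ge 0}).
#' @param df degrees of freedom.
#' @param scale scale parameter.
#' @param log return log density?
#' @return density or cumulative probability.
#' @export
dhalf_t <- function(x, df, scale, log = FALSE) {
  out <- ifelse(x < 0, if (log) -Inf else 0,
                if (log) log(2) + stats::dt(x / scale, df, log = TRUE) - log(scale)
                else 2 * stats::dt(x / scale, df) / scale)
  out
}

#' @rdname dhalf_t
#' @export
phalf_t <- function(x, df, scale) {
  ifelse(x < 0, 0, 2 * (stats::pt(x / scale, df) - 0.5))
}

#' Prior specification for the coverage model
#'
#' Defaults follow the model's calibration: a half-Student-t(df 2.5,
#' location 0) prior on each concentration parameter with a family-specific
#' scale chosen so that the prior CDF is near 0.8 at the concentration giving
#' a peak-to-trough ratio of 2 (0.2 for von Mises and Jones-Pewsey, 0.1
#' cardioid, 0.17 wrapped Cauchy, 0.105 linear cardioid, 0.1103 exponential
#' linear cardioid); a standard Gaussian prior on the Jones-Pewsey shape and
#' on peakedness/skewness parameters; and a symmetric Dirichlet prior with
#' per-component mass \eqn{A = 50/M} on mixture weights. The location is
#' uniform on the circle.
#'
#' @param family distribution family (sets the concentration prior scale).
#' @param conc_scale override for the half-t scale.
#' @param conc_df half-t degrees of freedom.
#' @param shape_sd Gaussian scale for psi/lambda/nu.
#' @param dirichlet_mass total Dirichlet mass; per-component A = mass / M.
#' @return an object of class `"ptr_priors"`.
#' @export
ptr_priors <- function(family = "von_mises", conc_scale = NULL, conc_df = 2.5,
                       shape_sd = 1, dirichlet_mass = 50) {
  default_scale <- c(von_mises = 0.2, jones_pewsey = 0.2, cardioid = 0.1,
                     wrapped_cauchy = 0.17, linear_cardioid = 0.105,
                     exp_linear_cardioid = 0.1103)
  structure(list(conc_df = conc_df,
                 conc_scale = conc_scale %||% unname(default_scale[family]),
                 shape_sd = shape_sd, dirichlet_mass = dirichlet_mass),
            class = "ptr_priors")
}

.ddirichlet_sym_log <- function(alpha, A) {
  M <- length(alpha)
  lgamma(M * A) - M * lgamma(A) + sum((A - 1) * log(alpha))
}

#' Log prior density of the model parameters
#'
#' Sums the half-t prior over per-sample concentrations, Gaussian priors over
#' shape/peakedness/skewness parameters if present, and the symmetric
#' Dirichlet prior over mixture weights if `alpha` is present. The location
#' prior is flat on the circle and contributes 0.
#'
#' @param spec a [dist_spec()].
#' @param params parameter list (`kappa`/`rho` per sample; optionally `psi`,
#'   `lam`, `nu`, `alpha`).
#' @param priors a [ptr_priors()].
#' @return log prior density, a scalar.
#' @export
log_prior <- function(spec, params, priors = ptr_priors(spec$family)) {
  conc <- params$kappa %||% params$rho
  lp <- sum(dhalf_t(conc, priors$conc_df, priors$conc_scale, log = TRUE))
  for (nm in c("psi", "lam", "nu"))
    if (!is.null(params[[nm]]))
      lp <- lp + sum(stats::dnorm(params[[nm]], 0, priors$shape_sd, log = TRUE))
  if (!is.null(params$alpha) && length(params$alpha) > 1L) {
    alpha <- params$alpha
    if (abs(sum(alpha) - 1) > 1e-8)
      stop_invalid_param("mixture weights must sum to 1")
    A <- priors$dirichlet_mass / length(alpha)
    lp <- lp + .ddirichlet_sym_log(alpha, A)
  }
  lp
}

#' Normalization constant of the discretized density
#'
#' When the continuous circular density is evaluated on \eqn{N} equally
#' spaced angles \eqn{\theta_n = n/N\cdot 2\pi}, dividing by \eqn{c_\omega}
#' makes the discrete probabilities sum to 1. The von Mises and wrapped
#' Cauchy constants are direct sums of the density; the cardioid constant is
#' \eqn{N/(2\pi)} and the linear cardioid constant \eqn{(N+2)/(2\pi)}.
#'
#' @param spec a [dist_spec()] (vanilla families only).
#' @param params parameter list (scalar concentration).
#' @param N discrete length, \eqn{\ge 2}.
#' @return the constant \eqn{c_\omega}.
#' @export
discrete_normalization_constant <- function(spec, params, N) {
  if (N < 2) stop("N must be >= 2")
  if (spec$extension != "none")
    stop("discrete normalization constants are defined for vanilla families")
  switch(spec$family,
         von_mises = , wrapped_cauchy = {
           theta <- position_to_angle(seq_len(N), N)
           sum(circ_density(spec, theta, params))
         },
         cardioid = N / (2 * pi),
         linear_cardioid = (N + 2) / (2 * pi),
         stop("no discrete normalization constant implemented for family '",
              spec$family, "'"))
}

#' Mixture log-likelihood for multiple replication origins
#'
#' For \eqn{M} origins with shared mixture weights \eqn{\alpha} and
#' per-component, per-sample concentrations, the log-likelihood is
#' \eqn{\sum_s \sum_i d_{i,s} \log \sum_m \alpha_m L(\omega_{m,s}|\theta_i)},
#' computed with log-sum-exp. With \eqn{M = 1} and \eqn{\alpha = 1} it
#' reduces exactly to [coverage_loglik()].
#'
#' @inheritParams coverage_loglik
#' @param mix list with `mu` (length M), `kappa` (M x S matrix, or length-M
#'   vector for S = 1), and `alpha` (length M, summing to 1).
#' @return log-likelihood, a scalar.
#' @export
mixture_loglik <- function(x, spec, mix, quad_n = 20L) {
  tracks <- as_track_list(x)
  S <- length(tracks)
  M <- length(mix$mu)
  alpha <- mix$alpha %||% rep(1 / M, M)
  if (abs(sum(alpha) - 1) > 1e-8)
    stop_invalid_param("mixture weights must sum to 1")
  kap <- mix$kappa
  if (is.null(dim(kap))) kap <- matrix(rep_len(kap, M * S), nrow = M)
  if (M == 1L) {
    return(coverage_loglik(tracks, spec,
                           list(mu = mix$mu, kappa = kap[1L, ],
                                psi = mix$psi, lam = mix$lam, nu = mix$nu),
                           quad_n))
  }
  ll <- 0
  for (s in seq_len(S)) {
    tr <- tracks[[s]]
    if (tr$total < 1) stop("degenerate input: track with all-zero depths")
    nz <- tr$depths > 0
    theta <- track_angles(tr)[nz]
    comp <- lapply(seq_len(M), function(m)
      log(alpha[m]) +
        circ_density(spec, theta, list(mu = mix$mu[m], kappa = kap[m, s]),
                     log = TRUE, quad_n = quad_n))
    mx <- do.call(pmax, comp)
    acc <- 0
    for (m in seq_len(M)) acc <- acc + exp(comp[[m]] - mx)
    ll <- ll + sum(tr$depths[nz] * (mx + log(acc)))
  }
  ll
}

#' Weighted peak-to-trough ratios for multiple origins
#'
#' For the von Mises mixture, the activity of origin \eqn{m} in sample
#' \eqn{s} is the weighted PTR \eqn{wPTR_{m,s} = \exp(2\alpha_m\kappa_{m,s})};
#' the chromosome-level score mwPTR is the arithmetic mean of the wPTRs over
#' origins.
#'
#' @param mix mixture parameter list as in [mixture_loglik()] (von Mises
#'   family only).
#' @param family distribution family of the mixture components.
#' @return list with `wptr` (M x S matrix) and `mwptr` (length-S vector).
#' @export
wptr <- function(mix, family = "von_mises") {
  if (family != "von_mises")
    stop("weighted PTRs are defined for the von Mises mixture")
  M <- length(mix$mu)
  alpha <- mix$alpha %||% rep(1 / M, M)
  kap <- mix$kappa
  if (is.null(dim(kap))) kap <- matrix(kap, nrow = M)
  w <- exp(2 * alpha * kap)  # alpha recycled down rows (per component)
  list(wptr = w, mwptr = colMeans(w))
}

#' Location angle from an unconstrained 2-vector
#'
#' Estimation reparameterizes the location as \eqn{\mu = atan2(y, x)} of a
#' two-dimensional vector so optimizers and samplers never see the wrap-around
#' at \eqn{2\pi}.
#'
#' @param v numeric length-2 vector (non-zero).
#' @return the angle in \eqn{[0, 2\pi)}.
#' @export
location_from_vector <- function(v) {
  if (length(v) != 2L || all(v == 0)) stop("need a non-zero 2-vector")
  wrap_angle(atan2(v[2L], v[1L]))
}
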
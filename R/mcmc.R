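# Hamiltonian Monte Carlo engine with dual-averaging step-size adaptation,
# split-chain rank-normalized Rhat, and WAIC. Gradients are central finite
# differences: the posterior dimension is small (a location 2-vector plus a
# handful of unconstrained scalars), so the cost is dominated by the
# vectorized likelihood itself.

.num_grad <- function(f, x, f0 = NULL) {
  d <- length(x)
  g <- numeric(d)
  for (j in seq_len(d)) {
    h <- 1e-6 * (1 + abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    g[j] <- (f(xp) - f(xm)) / (2 * h)
  }
  g
}

# lp: log target density over the unconstrained vector. Warmup adapts the
# step size by dual averaging and, halfway through, a diagonal mass matrix
# (per-coordinate step scaling) from the warmup draws.
hmc_chain <- function(lp, init, iter, warmup, eps0 = 0.1,
                      L_range = 5:15, target_accept = 0.8, grad = NULL) {
  d <- length(init)
  if (is.null(grad)) grad <- function(x) .num_grad(lp, x)
  draws <- matrix(NA_real_, nrow = iter, ncol = d)
  lps <- numeric(iter)
  x <- init
  lp_x <- lp(x)
  if (!is.finite(lp_x)) stop("non-finite log posterior at the initial value")
  g_x <- grad(x)
  scal <- rep(1, d)  # per-coordinate step scaling (sqrt of diagonal mass^-1)
  da_init <- function(e0) {
    list(mu = log(10 * e0), log_eps = log(e0), log_eps_bar = log(e0),
         H_bar = 0, m = 0L)
  }
  da <- da_init(eps0)
  gamma_da <- 0.05; t0 <- 10; kappa_da <- 0.75
  mass_at <- if (warmup >= 100L) floor(warmup / 2) else Inf
  divergences <- 0L
  accepts <- 0L
  for (it in seq_len(iter)) {
    if (it == mass_at + 1L) {
      win <- draws[max(1L, mass_at - 199L):mass_at, , drop = FALSE]
      s <- apply(win, 2L, stats::sd)
      s[!is.finite(s) | s < 1e-6] <- stats::median(s[s >= 1e-6]) %||% 1
      scal <- s
      da <- da_init(exp(da$log_eps_bar))  # re-adapt step in the new metric
    }
    eps <- exp(if (it <= warmup) da$log_eps else da$log_eps_bar)
    L <- if (length(L_range) > 1L) sample(L_range, 1L) else L_range
    p <- stats::rnorm(d)
    x_new <- x; g_new <- g_x
    lp_new <- lp_x
    H0 <- lp_x - 0.5 * sum(p^2)
    ok <- TRUE
    p_half <- p + 0.5 * eps * scal * g_new
    for (l in seq_len(L)) {
      x_new <- x_new + eps * scal * p_half
      lp_new <- lp(x_new)
      if (!is.finite(lp_new)) { ok <- FALSE; break }
      g_new <- grad(x_new)
      if (l < L) p_half <- p_half + eps * scal * g_new
    }
    if (ok) {
      p_end <- p_half + 0.5 * eps * scal * g_new
      H1 <- lp_new - 0.5 * sum(p_end^2)
      alpha <- min(1, exp(H1 - H0))
      if (!is.finite(alpha)) { alpha <- 0; ok <- FALSE }
    } else alpha <- 0
    if (!ok) divergences <- divergences + 1L
    if (stats::runif(1) < alpha) {
      x <- x_new; lp_x <- lp_new; g_x <- g_new
      accepts <- accepts + 1L
    }
    if (it <= warmup) {
      da$m <- da$m + 1L
      m <- da$m
      da$H_bar <- (1 - 1 / (m + t0)) * da$H_bar +
        (target_accept - alpha) / (m + t0)
      da$log_eps <- da$mu - sqrt(m) / gamma_da * da$H_bar
      w <- m^(-kappa_da)
      da$log_eps_bar <- w * da$log_eps + (1 - w) * da$log_eps_bar
    }
    draws[it, ] <- x
    lps[it] <- lp_x
  }
  list(draws = draws, lp = lps, warmup = warmup,
       accept_rate = accepts / iter, divergences = divergences,
       step_size = exp(da$log_eps_bar), mass_scale = scal)
}

rank_normalize <- function(x) {
  r <- rank(x, ties.method = "average")
  stats::qnorm((r - 3 / 8) / (length(x) + 1 / 4))
}

#' Split-chain rank-normalized Rhat
#'
#' The potential scale reduction factor computed after splitting each chain
#' in half and rank-normalizing, so that a single chain still yields a
#' within/between comparison. A constant quantity returns 1. Sampling results
#' are accepted when every monitored Rhat is at most 1.1.
#'
#' @param x numeric vector of draws from one chain (or a matrix with one
#'   column per chain).
#' @return the Rhat statistic.
#' @export
split_rhat <- function(x) {
  if (is.matrix(x)) chains <- x else chains <- matrix(x, ncol = 1L)
  n <- nrow(chains)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- do.call(cbind, lapply(seq_len(ncol(chains)), function(j)
    cbind(chains[seq_len(half), j], chains[(n - half + 1):n, j])))
  if (stats::var(as.vector(sub)) == 0) return(1.0)
  z <- matrix(rank_normalize(as.vector(sub)), nrow = half)
  m <- ncol(z)
  W <- mean(apply(z, 2L, stats::var))
  B <- half * stats::var(colMeans(z))
  if (W == 0) return(1.0)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# log(mean(exp(x))) stably
.log_mean_exp <- function(x) {
  mx <- max(x)
  mx + log(mean(exp(x - mx)))
}

# WAIC from a draws-by-datapoints matrix of pointwise log-likelihood
.waic_from_pointwise <- function(ll) {
  lppd <- sum(apply(ll, 2L, .log_mean_exp))
  p_waic <- sum(apply(ll, 2L, stats::var))
  list(waic = -2 * (lppd - p_waic), lppd = lppd, p_waic = p_waic)
}
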
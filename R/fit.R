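# Model fitting: unconstrained reparameterization, MAP optimization with
# multi-seed restarts, HMC sampling with EAP summaries, and the ptr_fit
# object with its methods.

# ---- unconstrained parameterization -----------------------------------------

.model_ctx <- function(tracks, spec, M, priors, quad_n) {
  S <- length(tracks)
  has_psi <- spec$family == "jones_pewsey"
  has_ext <- spec$extension != "none"
  if (M > 1L && (spec$family != "von_mises" || has_ext))
    stop("multiple-origin mixtures use the vanilla von Mises family")
  list(tracks = tracks, spec = spec, S = S, M = M, priors = priors,
       quad_n = quad_n, has_psi = has_psi, has_ext = has_ext,
       is_kappa = uses_kappa(spec$family),
       ub = conc_upper_bound(spec$family) - .conc_eps,
       d = if (M == 1L) 2L + S * (1L + has_psi + has_ext)
           else 2L * M + M * S + (M - 1L))
}

.unpack <- function(ctx, v) {
  S <- ctx$S; M <- ctx$M
  jac <- 0; tether <- 0
  conc_from_z <- function(z) {
    z <- pmin(pmax(z, -30), 30)
    if (ctx$is_kappa) exp(z) else ctx$ub * stats::plogis(z)
  }
  conc_jac <- function(z) {
    z <- pmin(pmax(z, -30), 30)
    if (ctx$is_kappa) sum(z)
    else sum(log(ctx$ub) + stats::plogis(z, log.p = TRUE) +
             stats::plogis(-z, log.p = TRUE))
  }
  if (M == 1L) {
    vec <- v[1:2]
    r <- sqrt(sum(vec^2))
    if (r < 1e-12) return(NULL)
    tether <- -0.5 * ((r - 1) / 0.25)^2
    mu <- wrap_angle(atan2(vec[2L], vec[1L]))
    z <- v[3:(2 + S)]
    conc <- conc_from_z(z)
    jac <- conc_jac(z)
    off <- 2L + S
    psi <- NULL; lam <- NULL; nu <- NULL
    if (ctx$has_psi) { psi <- v[off + 1:S]; off <- off + S }
    if (ctx$has_ext) {
      t <- tanh(v[off + 1:S])
      jac <- jac + sum(log1p(-t^2))
      if (ctx$spec$extension %in% c("SE", "InvSE")) lam <- t else nu <- t
    }
    params <- list(mu = mu, conc = conc, psi = psi, lam = lam, nu = nu)
  } else {
    mu <- numeric(M)
    for (m in seq_len(M)) {
      vec <- v[(2 * m - 1):(2 * m)]
      r <- sqrt(sum(vec^2))
      if (r < 1e-12) return(NULL)
      tether <- tether - 0.5 * ((r - 1) / 0.25)^2
      mu[m] <- wrap_angle(atan2(vec[2L], vec[1L]))
    }
    z <- v[2 * M + 1:(M * S)]
    conc <- matrix(conc_from_z(z), nrow = M)
    jac <- conc_jac(z)
    za <- if (M > 1L) v[2 * M + M * S + 1:(M - 1L)] else numeric(0)
    ea <- exp(c(0, za) - max(c(0, za)))
    alpha <- ea / sum(ea)
    jac <- jac + sum(log(alpha))
    params <- list(mu = mu, conc = conc, alpha = alpha)
  }
  list(params = params, jac = jac, tether = tether)
}

.ctx_loglik <- function(ctx, params) {
  if (ctx$M == 1L) {
    coverage_loglik(ctx$tracks, ctx$spec,
                    list(mu = params$mu, kappa = params$conc,
                         psi = params$psi, lam = params$lam, nu = params$nu),
                    quad_n = ctx$quad_n)
  } else {
    mixture_loglik(ctx$tracks, ctx$spec,
                   list(mu = params$mu, kappa = params$conc,
                        alpha = params$alpha),
                   quad_n = ctx$quad_n)
  }
}

.ctx_log_prior <- function(ctx, params) {
  if (is.null(ctx$priors)) return(0)
  pl <- list(kappa = as.vector(params$conc), psi = params$psi,
             lam = params$lam, nu = params$nu)
  if (ctx$M > 1L) pl$alpha <- params$alpha
  log_prior(ctx$spec, pl, ctx$priors)
}

# optimizing mode objective: constrained-space MAP (no Jacobian terms),
# matching the convention of posterior-optimization software
.ctx_map_objective <- function(ctx, v) {
  u <- .unpack(ctx, v)
  if (is.null(u)) return(-Inf)
  ll <- tryCatch(.ctx_loglik(ctx, u$params), error = function(e) -Inf)
  if (!is.finite(ll)) return(-Inf)
  ll + .ctx_log_prior(ctx, u$params) + u$tether
}

# sampling mode target: unconstrained posterior (Jacobian-adjusted)
.ctx_sampling_target <- function(ctx, v) {
  u <- .unpack(ctx, v)
  if (is.null(u)) return(-Inf)
  ll <- tryCatch(.ctx_loglik(ctx, u$params), error = function(e) -Inf)
  if (!is.finite(ll)) return(-Inf)
  ll + .ctx_log_prior(ctx, u$params) + u$jac + u$tether
}

# data_driven: start at the circular resultant direction of the pooled
# depths with an MRL-matched concentration. A random start antipodal to the
# true origin can strand BFGS on the kappa = 0 saddle (at zero concentration
# the location gradient vanishes), so the first restart is always informed.
.ctx_init <- function(ctx, data_driven = FALSE) {
  S <- ctx$S; M <- ctx$M
  pooled_dir <- function() {
    cs <- 0; sn <- 0; rbar <- 0
    for (s in seq_len(S)) {
      tr <- ctx$tracks[[s]]
      th <- track_angles(tr)
      cs <- cs + sum(tr$depths * cos(th))
      sn <- sn + sum(tr$depths * sin(th))
    }
    list(angle = atan2(sn, cs),
         rbar = sqrt(cs^2 + sn^2) / sum(vapply(ctx$tracks,
                                               function(t) t$total, 1.0)))
  }
  if (M == 1L) {
    if (data_driven) {
      d <- pooled_dir()
      a <- d$angle
      # small-concentration inversion of the mean resultant length
      k0 <- max(d$rbar * (2 - d$rbar^2) / (1 - d$rbar^2), 0.02)
      z <- rep(if (ctx$is_kappa) log(k0)
               else stats::qlogis(min(2 * d$rbar / ctx$ub, 0.9)), S)
    } else {
      a <- stats::runif(1, 0, 2 * pi)
      z <- stats::rnorm(S, -1.2, 0.6)
    }
    v <- c(cos(a), sin(a), z)
    if (ctx$has_psi) v <- c(v, stats::rnorm(S, 0, 0.3))
    if (ctx$has_ext) v <- c(v, stats::rnorm(S, 0, 0.3))
  } else {
    if (data_driven) {
      ang <- pooled_dir()$angle + 2 * pi * (0:(M - 1L)) / M
      zk <- rep(log(0.5), M * S)
      za <- rep(0, M - 1L)
    } else {
      ang <- stats::runif(M, 0, 2 * pi)
      zk <- stats::rnorm(M * S, 0, 0.8)
      za <- stats::rnorm(M - 1L, 0, 0.1)
    }
    v <- c(as.vector(rbind(cos(ang), sin(ang))), zk, za)
  }
  v
}

# sort mixture components by location and rebuild the unconstrained vector
.sort_components <- function(ctx, v) {
  if (ctx$M == 1L) return(v)
  u <- .unpack(ctx, v)
  ord <- order(u$params$mu)
  M <- ctx$M; S <- ctx$S
  loc <- matrix(v[1:(2 * M)], nrow = 2L)[, ord, drop = FALSE]
  zk <- matrix(v[2 * M + 1:(M * S)], nrow = M)[ord, , drop = FALSE]
  alpha <- u$params$alpha[ord]
  za <- log(alpha[-1L]) - log(alpha[1L])
  c(as.vector(loc), as.vector(zk), za)
}

.fit_map <- function(ctx, n_seeds, seed, maxit = 500L) {
  best <- NULL
  grad_fn <- if (!is.null(.ctx_grad(ctx, rep(0.5, ctx$d))))
    function(v) -.ctx_grad(ctx, v, sampling = FALSE) else NULL
  for (j in seq_len(n_seeds)) {
    set.seed(seed + j - 1L)
    v0 <- .ctx_init(ctx, data_driven = (j == 1L))
    res <- tryCatch(
      stats::optim(v0, function(v) -.ctx_map_objective(ctx, v),
                   gr = grad_fn, method = "BFGS",
                   control = list(maxit = maxit, reltol = 1e-9)),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$value)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best))
    stop("optimization failed to converge on every restart seed")
  best$par <- .sort_components(ctx, best$par)
  best
}

# ---- the fitting front end --------------------------------------------------

#' Fit the circular coverage model
#'
#' Fits a circular probability distribution to one or more coverage tracks
#' that share a reference. The location (replication origin) is shared across
#' samples; the concentration — and any shape, peakedness or skewness
#' parameter — is per sample. `mode = "optimizing"` maximizes the joint
#' posterior (MAP) with a BFGS quasi-Newton optimizer over unconstrained
#' reparameterized variables (unit-vector location, log or logistic-scaled
#' concentration), restarting from `n_seeds` random initializations and
#' keeping the highest posterior. `mode = "sampling"` runs Hamiltonian Monte
#' Carlo (one chain; 500 iterations with 300 warm-up for a single origin,
#' 1500/1000 for mixtures) and reports the expected a posteriori (EAP);
#' the result is flagged as accepted only when every split-chain Rhat is at
#' most 1.1.
#'
#' With `M > 1` a von Mises mixture with shared weights `alpha` (Dirichlet
#' prior, per-component mass 50/M) models multiple replication origins;
#' components are sorted by location, and per-origin weighted PTRs
#' \eqn{\exp(2\alpha_m\kappa_{m,s})} plus their mean (mwPTR) are reported.
#'
#' @param x a [coverage_track()], list of tracks, or depth vector.
#' @param family,extension the distribution, as in [dist_spec()].
#' @param M number of replication origins (mixture components).
#' @param mode `"optimizing"` (MAP) or `"sampling"` (HMC + EAP).
#' @param priors a [ptr_priors()]; `NULL` for flat priors (maximum
#'   likelihood).
#' @param n_seeds restart count for the optimizer (default 1 for a single
#'   origin, 30 for mixtures).
#' @param seed base seed; restart j uses `seed + j - 1`, and sampling is
#'   seeded deterministically from `seed`.
#' @param iter,warmup sampling-mode iteration counts (defaults 500/300, or
#'   1500/1000 for mixtures).
#' @param quad_n Simpson subintervals for internal normalization constants.
#' @param compute_waic also compute WAIC from the pointwise log-likelihood
#'   draws (sampling mode).
#' @return an object of class `"ptr_fit"`; see [summary.ptr_fit()],
#'   [information_criteria()].
#' @examples
#' tr <- generate_coverage(dist_spec("von_mises"),
#'                         list(mu = pi, kappa = 0.35),
#'                         length_I = 500, mean_depth = 10, seed = 1)
#' fit <- ptr_fit(tr)
#' fit$pptr
#' @export
ptr_fit <- function(x, family = "von_mises", extension = "none", M = 1L,
                    mode = c("optimizing", "sampling"), priors = ptr_priors(family),
                    n_seeds = NULL, seed = 1L, iter = NULL, warmup = NULL,
                    quad_n = 20L, compute_waic = TRUE) {
  mode <- match.arg(mode)
  tracks <- as_track_list(x)
  spec <- dist_spec(family, extension)
  ctx <- .model_ctx(tracks, spec, M, priors, quad_n)
  n_seeds <- n_seeds %||% if (M > 1L) 30L else 1L
  iter <- iter %||% if (M > 1L) 1500L else 500L
  warmup <- warmup %||% if (M > 1L) 1000L else 300L

  map <- .fit_map(ctx, n_seeds, seed)
  fit <- .build_fit(ctx, map$par, mode = "optimizing", seed = seed,
                    n_seeds = n_seeds)
  if (mode == "sampling") {
    set.seed(seed)
    target <- function(v) .ctx_sampling_target(ctx, v)
    grad <- if (!is.null(.ctx_grad(ctx, map$par)))
      function(v) .ctx_grad(ctx, v, sampling = TRUE) else NULL
    chain <- hmc_chain(target, init = map$par, iter = iter, warmup = warmup,
                       L_range = if (M > 1L) 15:30 else 5:15, grad = grad)
    post <- chain$draws[(warmup + 1):iter, , drop = FALSE]
    eap_v <- .eap_vector(ctx, post)
    fit <- .build_fit(ctx, .sort_components(ctx, eap_v), mode = "sampling",
                      seed = seed, n_seeds = n_seeds)
    mon <- cbind(post, lp = chain$lp[(warmup + 1):iter])
    rhat <- apply(mon, 2L, split_rhat)
    names(rhat) <- c(paste0("par", seq_len(ncol(post))), "lp")
    fit$rhat <- rhat
    fit$accepted <- all(is.na(rhat) | rhat <= 1.1)
    fit$n_draws <- nrow(post)
    fit$divergences <- chain$divergences
    fit$accept_rate <- chain$accept_rate
    fit$draws <- post
    if (compute_waic) fit$waic <- .fit_waic(ctx, post)$waic
  }
  fit$call <- match.call()
  fit
}

# EAP on the constrained scale, re-expressed as an unconstrained vector:
# location via the mean unit vector (circular mean), concentrations and
# weights via arithmetic means of constrained draws
.eap_vector <- function(ctx, post) {
  S <- ctx$S; M <- ctx$M
  cons <- t(apply(post, 1L, function(v) {
    u <- .unpack(ctx, v)
    c(as.vector(u$params$conc), u$params$alpha)
  }))
  if (M == 1L) {
    vecs <- post[, 1:2, drop = FALSE]
    vecs <- vecs / sqrt(rowSums(vecs^2))
    vbar <- colMeans(vecs)
    conc_bar <- colMeans(cons[, 1:S, drop = FALSE])
    z <- if (ctx$is_kappa) log(conc_bar)
         else stats::qlogis(pmin(conc_bar / ctx$ub, 1 - 1e-12))
    out <- c(vbar, z)
    off <- 2L + S
    if (ctx$has_psi) { out <- c(out, colMeans(post[, off + 1:S, drop = FALSE])); off <- off + S }
    if (ctx$has_ext) out <- c(out, atanh(colMeans(tanh(post[, off + 1:S, drop = FALSE]))))
    out
  } else {
    out <- numeric(0)
    for (m in seq_len(M)) {
      vecs <- post[, (2 * m - 1):(2 * m), drop = FALSE]
      vecs <- vecs / sqrt(rowSums(vecs^2))
      out <- c(out, colMeans(vecs))
    }
    conc_bar <- colMeans(cons[, 1:(M * S), drop = FALSE])
    out <- c(out, log(conc_bar))
    alpha_bar <- colMeans(cons[, M * S + 1:M, drop = FALSE])
    alpha_bar <- alpha_bar / sum(alpha_bar)
    c(out, log(alpha_bar[-1L]) - log(alpha_bar[1L]))
  }
}

.fit_waic <- function(ctx, post) {
  nz_theta <- list(); nz_d <- list()
  for (s in seq_len(ctx$S)) {
    tr <- ctx$tracks[[s]]
    nz <- tr$depths > 0
    nz_theta[[s]] <- track_angles(tr)[nz]
    nz_d[[s]] <- tr$depths[nz]
  }
  ll <- matrix(NA_real_, nrow = nrow(post),
               ncol = sum(lengths(nz_d)))
  for (k in seq_len(nrow(post))) {
    u <- .unpack(ctx, post[k, ])
    row <- numeric(0)
    for (s in seq_len(ctx$S)) {
      if (ctx$M == 1L) {
        ps <- list(mu = u$params$mu, kappa = u$params$conc[s],
                   psi = if (!is.null(u$params$psi)) u$params$psi[s],
                   lam = if (!is.null(u$params$lam)) u$params$lam[s],
                   nu = if (!is.null(u$params$nu)) u$params$nu[s])
        lp <- circ_density(ctx$spec, nz_theta[[s]], ps, log = TRUE,
                           quad_n = ctx$quad_n)
      } else {
        comp <- sapply(seq_len(ctx$M), function(m)
          log(u$params$alpha[m]) +
            circ_density(ctx$spec, nz_theta[[s]],
                         list(mu = u$params$mu[m],
                              kappa = u$params$conc[m, s]), log = TRUE))
        mx <- apply(comp, 1L, max)
        lp <- mx + log(rowSums(exp(comp - mx)))
      }
      row <- c(row, nz_d[[s]] * lp)
    }
    ll[k, ] <- row
  }
  .waic_from_pointwise(ll)
}

.build_fit <- function(ctx, v, mode, seed, n_seeds) {
  u <- .unpack(ctx, v)
  p <- u$params
  ll <- .ctx_loglik(ctx, p)
  S <- ctx$S; M <- ctx$M
  sample_ids <- vapply(ctx$tracks, function(t) t$sample_id, "")
  k <- if (M == 1L) 1L + S * (1L + ctx$has_psi + ctx$has_ext)
       else M + M * S + (M - 1L)
  out <- list(spec = ctx$spec, M = M, mode = mode, S = S,
              sample_ids = sample_ids,
              T_s = vapply(ctx$tracks, function(t) t$total, 1.0),
              I = ctx$tracks[[1L]]$I,
              tracks = ctx$tracks,
              priors = ctx$priors, seed = seed, n_seeds = n_seeds,
              loglik = ll,
              logpost = ll + .ctx_log_prior(ctx, p),
              k = k, unconstrained = v)
  if (M == 1L) {
    conc_name <- if (ctx$is_kappa) "kappa" else "rho"
    params <- list(mu = p$mu)
    params[[conc_name]] <- stats::setNames(p$conc, sample_ids)
    params$psi <- p$psi; params$lam <- p$lam; params$nu <- p$nu
    out$params <- params
    out$pptr <- stats::setNames(
      pptr(ctx$spec, list(kappa = p$conc)), sample_ids)
  } else {
    out$params <- list(mu = p$mu, kappa = p$conc, alpha = p$alpha)
    w <- wptr(list(mu = p$mu, kappa = p$conc, alpha = p$alpha))
    colnames(w$wptr) <- sample_ids
    out$wptr <- w$wptr
    out$mwptr <- stats::setNames(w$mwptr, sample_ids)
    out$pptr <- apply(exp(2 * p$conc), 2L, max)  # unweighted, per sample
  }
  class(out) <- "ptr_fit"
  out
}

# ---- methods ----------------------------------------------------------------

#' @export
print.ptr_fit <- function(x, digits = 4, ...) {
  ext <- if (x$spec$extension == "none") "" else paste0(" + ", x$spec$extension)
  cat(sprintf("Circular coverage model (%s%s), %s mode\n",
              x$spec$family, ext, x$mode))
  cat(sprintf("  %d sample(s), %d bins, origin at angle %s (genome fraction %s)\n",
              x$S, x$I,
              paste(signif(x$params$mu, digits), collapse = ", "),
              paste(signif(wrap_angle(x$params$mu) / (2 * pi), 3),
                    collapse = ", ")))
  if (x$M == 1L) {
    cat("  pPTR:\n")
    print(signif(x$pptr, digits))
  } else {
    cat(sprintf("  %d origins; mixture weights %s\n", x$M,
                paste(signif(x$params$alpha, 3), collapse = ", ")))
    cat("  mwPTR:\n")
    print(signif(x$mwptr, digits))
  }
  cat(sprintf("  log-likelihood %.2f (k = %d)\n", x$loglik, x$k))
  if (x$mode == "sampling")
    cat(sprintf("  max Rhat %.3f (%s), %d draws\n",
                max(x$rhat, na.rm = TRUE),
                if (x$accepted) "accepted" else "REJECTED", x$n_draws))
  invisible(x)
}

#' @export
coef.ptr_fit <- function(object, ...) {
  p <- object$params
  if (object$M == 1L) {
    out <- c(mu = unname(p$mu))
    conc <- p$kappa %||% p$rho
    nm <- if (!is.null(p$kappa)) "kappa" else "rho"
    out <- c(out, stats::setNames(unname(conc), paste0(nm, seq_along(conc))))
    for (v in c("psi", "lam", "nu"))
      if (!is.null(p[[v]]))
        out <- c(out, stats::setNames(p[[v]], paste0(v, seq_along(p[[v]]))))
    out
  } else {
    c(stats::setNames(p$mu, paste0("mu", seq_len(object$M))),
      stats::setNames(as.vector(p$kappa),
                      paste0("kappa", outer(seq_len(object$M),
                                            seq_len(object$S), paste, sep = "_"))),
      stats::setNames(p$alpha, paste0("alpha", seq_len(object$M))))
  }
}

#' @export
logLik.ptr_fit <- function(object, ...) {
  structure(object$loglik, df = object$k, nobs = sum(object$T_s),
            class = "logLik")
}

#' Predicted density or expected depth
#'
#' @param object a fitted [ptr_fit()].
#' @param newdata angles at which to predict; defaults to the bin angles of
#'   the fitted tracks.
#' @param sample which sample's parameters to use.
#' @param type `"density"` (circular pdf) or `"depth"` (expected bin depth
#'   \eqn{T p_i} with \eqn{p_i} = density times bin width).
#' @param ... unused.
#' @export
predict.ptr_fit <- function(object, newdata = NULL, sample = 1L,
                            type = c("density", "depth"), ...) {
  type <- match.arg(type)
  theta <- newdata %||% track_angles(object$tracks[[sample]])
  p <- object$params
  if (object$M == 1L) {
    conc <- (p$kappa %||% p$rho)[sample]
    ps <- list(mu = p$mu, kappa = conc,
               psi = if (!is.null(p$psi)) p$psi[sample],
               lam = if (!is.null(p$lam)) p$lam[sample],
               nu = if (!is.null(p$nu)) p$nu[sample])
    dens <- circ_density(object$spec, theta, ps)
  } else {
    dens <- rep(0, length(theta))
    for (m in seq_len(object$M))
      dens <- dens + p$alpha[m] *
        circ_density(object$spec, theta,
                     list(mu = p$mu[m], kappa = p$kappa[m, sample]))
  }
  if (type == "density") return(dens)
  tr <- object$tracks[[sample]]
  tr$total * dens * 2 * pi / tr$I
}

#' @export
fitted.ptr_fit <- function(object, ...) {
  sapply(seq_len(object$S), function(s)
    predict(object, sample = s, type = "depth"))
}

#' @export
residuals.ptr_fit <- function(object, type = c("pearson", "response"), ...) {
  type <- match.arg(type)
  sapply(seq_len(object$S), function(s) {
    tr <- object$tracks[[s]]
    mu <- predict(object, sample = s, type = "depth")
    r <- tr$depths - mu
    if (type == "pearson") {
      p <- mu / tr$total
      r <- r / sqrt(pmax(tr$total * p * (1 - p), .Machine$double.eps))
    }
    r
  })
}

#' @export
simulate.ptr_fit <- function(object, nsim = 1, seed = NULL, sample = 1L, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- object$params
  tr <- object$tracks[[sample]]
  lapply(seq_len(nsim), function(i) {
    if (object$M == 1L) {
      conc <- (p$kappa %||% p$rho)[sample]
      ps <- list(mu = p$mu, kappa = conc,
                 psi = if (!is.null(p$psi)) p$psi[sample],
                 lam = if (!is.null(p$lam)) p$lam[sample],
                 nu = if (!is.null(p$nu)) p$nu[sample])
    } else {
      ps <- list(mu = p$mu, kappa = p$kappa[, sample], alpha = p$alpha)
    }
    generate_coverage(object$spec, ps, length_I = tr$I,
                      mean_depth = tr$total / tr$I,
                      sample_id = paste0(tr$sample_id, "_sim", i))
  })
}

#' @export
plot.ptr_fit <- function(x, sample = 1L, ...) {
  tr <- x$tracks[[sample]]
  graphics::plot(seq_len(tr$I), tr$depths, type = "h", col = "grey70",
                 xlab = "bin", ylab = "depth",
                 main = sprintf("%s (%s)", tr$sample_id, x$spec$family), ...)
  graphics::lines(seq_len(tr$I), predict(x, sample = sample, type = "depth"),
                  col = "firebrick", lwd = 2)
  invisible(x)
}

#' @export
summary.ptr_fit <- function(object, ...) {
  ic <- information_criteria(object,
                             include_waic = object$mode == "sampling" &&
                               !is.null(object$waic))
  structure(list(fit = object, ic = ic), class = "summary.ptr_fit")
}

#' @export
print.summary.ptr_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  AIC %.2f  BIC %.2f%s\n", x$ic$aic, x$ic$bic,
              if (!is.null(x$ic$waic) && !is.na(x$ic$waic))
                sprintf("  WAIC %.2f", x$ic$waic) else ""))
  invisible(x)
}

# ---- model selection --------------------------------------------------------

#' Information criteria of a fitted coverage model
#'
#' AIC \eqn{= 2k - 2\log L} and BIC \eqn{= k\log(\sum_s T_s) - 2\log L} with
#' the parameter count \eqn{k = 1 + S} for single-origin non-Jones-Pewsey
#' models, \eqn{1 + 2S} for Jones-Pewsey (shape per sample), one extra
#' per-sample parameter for peakedness/skewness extensions, and
#' \eqn{M + MS + (M-1)} for mixtures. In sampling mode the log-likelihood at
#' the EAP is used; WAIC is computed from the pointwise log-likelihood draws
#' and is only available for sampling-mode fits.
#'
#' @param fit a [ptr_fit()] result.
#' @param include_waic request WAIC (error for optimizing-mode fits).
#' @return list of class `"ic_report"` with `k`, `loglik`, `aic`, `bic`,
#'   `waic`.
#' @export
information_criteria <- function(fit, include_waic = FALSE) {
  k <- fit$k; ll <- fit$loglik
  waic <- NULL
  if (include_waic) {
    if (fit$mode != "sampling")
      stop("WAIC is unavailable for optimizing-mode fits; refit with mode = 'sampling'")
    waic <- fit$waic
  }
  structure(list(model = paste0(fit$spec$family,
                                if (fit$spec$extension != "none")
                                  paste0("+", fit$spec$extension) else "",
                                if (fit$M > 1L) paste0(" M=", fit$M) else ""),
                 k = k, loglik = ll,
                 aic = 2 * k - 2 * ll,
                 bic = k * log(sum(fit$T_s)) - 2 * ll,
                 waic = waic),
            class = "ic_report")
}

#' @export
print.ic_report <- function(x, ...) {
  cat(sprintf("<ic_report> %s: k = %d, logLik = %.2f, AIC = %.2f, BIC = %.2f",
              x$model, x$k, x$loglik, x$aic, x$bic))
  if (!is.null(x$waic)) cat(sprintf(", WAIC = %.2f", x$waic))
  cat("\n")
  invisible(x)
}

#' Likelihood-ratio test between nested coverage models
#'
#' Wilks' theorem: twice the log-likelihood gain of the extended model is
#' compared against a chi-squared distribution with `df_delta` degrees of
#' freedom (defaulting to the difference in parameter counts). The statistic
#' is clipped at 0; a log-likelihood *loss* beyond tolerance triggers a
#' warning since it indicates optimizer failure.
#'
#' @param fit_null,fit_ext nested fits on the same data (e.g. von Mises vs
#'   Jones-Pewsey, or a vanilla family vs its extension).
#' @param df_delta degrees of freedom of the test.
#' @return list with `statistic`, `df` and `p_value`.
#' @export
likelihood_ratio_test <- function(fit_null, fit_ext, df_delta = NULL) {
  df_delta <- df_delta %||% (fit_ext$k - fit_null$k)
  if (df_delta < 1) stop("extended model must add parameters")
  delta <- fit_ext$loglik - fit_null$loglik
  if (delta < -1e-6)
    warning("extended model has lower log-likelihood; optimization may have failed")
  stat <- max(0, 2 * delta)
  list(statistic = stat, df = df_delta,
       p_value = stats::pchisq(stat, df_delta, lower.tail = FALSE))
}

#' Select the number of replication origins
#'
#' Fits the von Mises mixture for each candidate `M` (MAP with `map_seeds`
#' restarts, then — optionally — HMC for WAIC) and selects the component
#' count: best by AIC and best by WAIC are both reported; the returned
#' `chosen` is the smaller of the two when they disagree (ties always break
#' toward fewer origins, the conservative choice for a singular model).
#'
#' @param x track(s) as in [ptr_fit()].
#' @param M_range candidate origin counts (default 1:4).
#' @param seed base seed.
#' @param map_seeds optimizer restarts per M (default 30).
#' @param use_mcmc run sampling mode for WAIC (default TRUE).
#' @param iter,warmup sampling iterations (defaults 1500/1000).
#' @return list of class `"origin_selection"` with `chosen`, `best_aic`,
#'   `best_waic`, the per-M `table`, and the fits.
#' @export
select_origin_count <- function(x, M_range = 1:4, seed = 1L, map_seeds = 30L,
                                use_mcmc = TRUE, iter = 1500L, warmup = 1000L) {
  fits <- list()
  rows <- list()
  for (M in M_range) {
    fit <- tryCatch(
      ptr_fit(x, family = "von_mises", M = M,
              mode = if (use_mcmc) "sampling" else "optimizing",
              n_seeds = map_seeds, seed = seed, iter = iter, warmup = warmup),
      error = function(e) e)
    if (inherits(fit, "error")) {
      rows[[as.character(M)]] <- data.frame(M = M, k = NA, loglik = NA,
                                            aic = NA, waic = NA,
                                            error = conditionMessage(fit))
      next
    }
    fits[[as.character(M)]] <- fit
    ic <- information_criteria(fit, include_waic = use_mcmc &&
                                 !is.null(fit$waic))
    rows[[as.character(M)]] <- data.frame(M = M, k = ic$k, loglik = ic$loglik,
                                          aic = ic$aic,
                                          waic = ic$waic %||% NA_real_,
                                          error = NA_character_)
  }
  tab <- do.call(rbind, rows)
  ok <- !is.na(tab$aic)
  if (!any(ok)) stop("every candidate M failed to fit")
  best_aic <- tab$M[ok][which.min(tab$aic[ok])]
  best_waic <- if (any(ok & !is.na(tab$waic)))
    tab$M[which.min(replace(tab$waic, !ok, Inf))] else NA_integer_
  chosen <- if (is.na(best_waic)) best_aic else min(best_aic, best_waic)
  structure(list(chosen = chosen, best_aic = best_aic, best_waic = best_waic,
                 table = tab, fits = fits),
            class = "origin_selection")
}

#' @export
print.origin_selection <- function(x, ...) {
  cat("Replication-origin count selection\n")
  print(x$table[, setdiff(names(x$table), "error")], row.names = FALSE)
  cat(sprintf("chosen M = %d (AIC -> %d, WAIC -> %s)\n", x$chosen, x$best_aic,
              if (is.na(x$best_waic)) "n/a" else x$best_waic))
  invisible(x)
}

#' Serialize a fitted model to JSON
#'
#' Writes family, extension, locations, per-sample concentrations, extension
#' parameters, mixture weights and the growth estimates (pPTR / wPTR /
#' mwPTR) plus diagnostics as a JSON document.
#'
#' @param fit a [ptr_fit()].
#' @param path output file; when `NULL` the JSON string is returned.
#' @export
write_fit_json <- function(fit, path = NULL) {
  p <- fit$params
  doc <- list(family = fit$spec$family, extension = fit$spec$extension,
              mode = fit$mode, M = fit$M,
              samples = as.list(fit$sample_ids),
              mu = p$mu, concentration = p$kappa %||% p$rho,
              psi = p$psi, lam = p$lam, nu = p$nu, alpha = p$alpha,
              loglik = fit$loglik, k = fit$k, seed = fit$seed,
              pptr = fit$pptr)
  if (fit$M > 1L) {
    doc$wptr <- fit$wptr
    doc$mwptr <- fit$mwptr
  }
  if (fit$mode == "sampling") {
    doc$rhat_max <- max(fit$rhat, na.rm = TRUE)
    doc$accepted <- fit$accepted
    doc$waic <- fit$waic
  }
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
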
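# Analytic gradients of the unconstrained objective for the von Mises family
# (vanilla, single origin or mixture). Other families and the argument-
# transformed extensions fall back to finite differences; their parameter
# spaces are equally small and fits remain fast.

.bessel_A <- function(kappa)
  besselI(kappa, 1, expon.scaled = TRUE) / besselI(kappa, 0, expon.scaled = TRUE)

.halft_dlog <- function(kappa, df, scale)
  -(df + 1) * kappa / (df * scale^2 + kappa^2)

# gradient of the MAP objective (sampling = FALSE) or the Jacobian-adjusted
# sampling target (sampling = TRUE); NULL when no analytic form is available
.ctx_grad <- function(ctx, v, sampling = FALSE) {
  if (ctx$spec$family != "von_mises" || ctx$spec$extension != "none")
    return(NULL)
  S <- ctx$S; M <- ctx$M
  g <- numeric(length(v))
  tether_grad <- function(vec) {
    r <- sqrt(sum(vec^2))
    -(r - 1) / 0.25^2 * vec / r
  }
  if (M == 1L) {
    vec <- v[1:2]
    mu <- atan2(vec[2L], vec[1L])
    z <- pmin(pmax(v[3:(2 + S)], -30), 30)
    kap <- exp(z)
    dmu <- 0
    for (s in seq_len(S)) {
      tr <- ctx$tracks[[s]]
      nz <- tr$depths > 0
      theta <- track_angles(tr)[nz]
      d <- tr$depths[nz]
      cs <- sum(d * cos(theta - mu))
      ss <- sum(d * sin(theta - mu))
      dk <- cs - tr$total * .bessel_A(kap[s])
      if (!is.null(ctx$priors))
        dk <- dk + .halft_dlog(kap[s], ctx$priors$conc_df, ctx$priors$conc_scale)
      g[2L + s] <- kap[s] * dk + if (sampling) 1 else 0
      dmu <- dmu + kap[s] * ss
    }
    r2 <- sum(vec^2)
    g[1:2] <- dmu * c(-vec[2L], vec[1L]) / r2 + tether_grad(vec)
  } else {
    mu <- numeric(M)
    for (m in seq_len(M)) mu[m] <- atan2(v[2 * m], v[2 * m - 1])
    z <- pmin(pmax(v[2 * M + 1:(M * S)], -30), 30)
    kap <- matrix(exp(z), nrow = M)
    za <- v[2 * M + M * S + 1:(M - 1L)]
    ea <- exp(c(0, za) - max(c(0, za)))
    alpha <- ea / sum(ea)
    dmu <- numeric(M)
    dkap <- matrix(0, M, S)
    t_resp <- numeric(M)
    D <- 0
    for (s in seq_len(S)) {
      tr <- ctx$tracks[[s]]
      nz <- tr$depths > 0
      theta <- track_angles(tr)[nz]
      d <- tr$depths[nz]
      D <- D + tr$total
      lf <- lapply(seq_len(M), function(m)
        log(alpha[m]) + kap[m, s] * cos(theta - mu[m]) -
          log(2 * pi) - .log_I0(kap[m, s]))
      mx <- do.call(pmax, lf)
      resp <- lapply(lf, function(x) exp(x - mx))
      tot <- 0
      for (m in seq_len(M)) tot <- tot + resp[[m]]
      for (m in seq_len(M)) {
        wr <- d * resp[[m]] / tot
        dmu[m] <- dmu[m] + kap[m, s] * sum(wr * sin(theta - mu[m]))
        dkap[m, s] <- sum(wr * (cos(theta - mu[m]) - .bessel_A(kap[m, s])))
        t_resp[m] <- t_resp[m] + sum(wr)
      }
    }
    if (!is.null(ctx$priors)) {
      dkap <- dkap + .halft_dlog(kap, ctx$priors$conc_df, ctx$priors$conc_scale)
      A <- ctx$priors$dirichlet_mass / M
      t_alpha <- t_resp + (A - 1)
    } else t_alpha <- t_resp
    # softmax chain rule: d/dz_j = t_j - alpha_j * sum(t) (z_1 fixed at 0)
    if (sampling) t_alpha <- t_alpha + 1  # Jacobian sum(log alpha)
    dz_alpha <- t_alpha - alpha * sum(t_alpha)
    for (m in seq_len(M)) {
      vec <- v[(2 * m - 1):(2 * m)]
      r2 <- sum(vec^2)
      g[(2 * m - 1):(2 * m)] <- dmu[m] * c(-vec[2L], vec[1L]) / r2 +
        tether_grad(vec)
    }
    g[2 * M + 1:(M * S)] <- as.vector(kap * dkap) +
      if (sampling) 1 else 0
    g[2 * M + M * S + 1:(M - 1L)] <- dz_alpha[-1L]
  }
  g
}
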
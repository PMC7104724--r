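#' Composite Simpson quadrature over one circle
#'
#' Integrates a periodic function over \eqn{[0, 2\pi]} with the composite
#' Simpson rule. The model's internal normalization constants use 20
#' subintervals by default, which is ample for the smooth, moderately
#' concentrated densities coverage modeling produces; raise `n` for very
#' concentrated densities.
#'
#' @param f vectorized function of an angle.
#' @param n even number of subintervals (default 20).
#' @param a,b integration limits, default `0` and `2*pi`.
#' @return numeric scalar, the Simpson estimate of \eqn{\int_a^b f}.
#' @examples
#' simpson_integrate(function(x) rep(1 / (2 * pi), length(x)))  # 1
#' @export
simpson_integrate <- function(f, n = 20L, a = 0, b = 2 * pi) {
  n <- as.integer(n)
  if (n < 2L || n %% 2L != 0L) stop("'n' must be an even integer >= 2")
  h <- (b - a) / n
  x <- a + h * (0:n)
  w <- c(1, rep(c(4, 2), length.out = n - 1L), 1)
  sum(w * f(x)) * h / 3
}

#' One-dimensional root finding (Newton / Illinois)
#'
#' Newton's method is used with a convergence criterion of
#' \eqn{|f(x)| < 1.19\times 10^{-7}} (single-precision machine epsilon) and at
#' most 30 iterations; the Illinois variant of regula falsi uses
#' \eqn{|f(x)| < 10^{-13}} and at most 100 iterations. These are the
#' tolerances and caps used by the inverse angle transformations
#' ([invse_transform()], [invmiae_transform()]).
#'
#' @param f function of one variable.
#' @param x0 starting point (Newton) or length-2 bracket (Illinois).
#' @param method `"newton"` or `"illinois"`.
#' @param fprime optional derivative for Newton; numeric differencing is used
#'   when absent.
#' @param tol convergence tolerance on `|f(root)|`; defaults per method.
#' @param max_iter iteration cap; defaults 30 (Newton), 100 (Illinois).
#' @return the root, a numeric scalar.
#' @export
root_find <- function(f, x0, method = c("newton", "illinois"),
                      fprime = NULL, tol = NULL, max_iter = NULL) {
  method <- match.arg(method)
  if (method == "newton") {
    tol <- tol %||% 1.19e-7
    max_iter <- max_iter %||% 30L
    if (is.null(fprime)) {
      fprime <- function(x) (f(x + 1e-7) - f(x - 1e-7)) / 2e-7
    }
    x <- x0[1L]
    for (k in seq_len(max_iter)) {
      fx <- f(x)
      if (abs(fx) < tol) return(x)
      x <- x - fx / fprime(x)
    }
    if (abs(f(x)) < tol) return(x)
    stop_no_convergence(
      sprintf("Newton's method did not converge in %d iterations", max_iter), x)
  } else {
    tol <- tol %||% 1e-13
    max_iter <- max_iter %||% 100L
    if (length(x0) != 2L) stop("Illinois method needs a length-2 bracket")
    a <- x0[1L]; b <- x0[2L]
    fa <- f(a); fb <- f(b)
    if (abs(fa) < tol) return(a)
    if (abs(fb) < tol) return(b)
    if (sign(fa) == sign(fb))
      stop("Illinois bracket endpoints must have opposite signs")
    x <- b
    for (k in seq_len(max_iter)) {
      x <- b - fb * (b - a) / (fb - fa)
      fx <- f(x)
      if (abs(fx) < tol) return(x)
      if (sign(fx) == sign(fb)) {
        b <- x; fb <- fx
        fa <- fa / 2  # Illinois modification against endpoint stagnation
      } else {
        a <- b; fa <- fb
        b <- x; fb <- fx
      }
    }
    stop_no_convergence(
      sprintf("Illinois method did not converge in %d iterations", max_iter), x)
  }
}

# Vectorized inverse of a strictly increasing map g on [-pi, pi] with
# g(-pi) = -pi, g(pi) = pi. Method follows the estimation machinery: Newton
# when |par| < 0.8, Illinois otherwise (conservative at exactly 0.8).
.inv_increasing <- function(g, gprime, y, par) {
  if (abs(par) < 0.8) {
    x <- y
    tol <- 1.19e-7
    for (k in 1:30) {
      fx <- g(x) - y
      if (all(abs(fx) < tol)) return(x)
      x <- x - fx / gprime(x)
      x[x > pi] <- pi
      x[x < -pi] <- -pi
    }
    fx <- g(x) - y
    if (all(abs(fx) < tol)) return(x)
    stop_no_convergence("vectorized Newton inverse did not converge", x)
  } else {
    a <- rep(-pi, length(y)); b <- rep(pi, length(y))
    fa <- g(a) - y; fb <- g(b) - y
    x <- b
    tol <- 1e-13
    for (k in 1:100) {
      x <- b - fb * (b - a) / (fb - fa)
      fx <- g(x) - y
      if (all(abs(fx) < tol)) return(x)
      same <- sign(fx) == sign(fb)
      a[!same] <- b[!same]; fa[!same] <- fb[!same]
      fa[same] <- fa[same] / 2
      b <- x; fb <- fx
    }
    if (all(abs(g(x) - y) < 1e-10)) return(x)
    stop_no_convergence("vectorized Illinois inverse did not converge", x)
  }
}

#' Angle transformations for peakedness and skewness extensions
#'
#' The symmetric (Batschelet) extension SE maps an angular deviation
#' \eqn{x = \theta - \mu} to \eqn{x + \lambda \sin x}; its density needs
#' renormalization. The inverse symmetric extension InvSE uses
#' \eqn{g_\lambda(x) = \frac{1-\lambda}{1+\lambda} x +
#' \frac{2\lambda}{1+\lambda} t_{1,\lambda}^{-1}(x)} with
#' \eqn{t_{1,\lambda}(u) = u - \frac{1}{2}(1+\lambda)\sin u}; substituting it
#' into the base density still requires renormalization (handled by
#' [circ_density()]). The mode-invariant asymmetric extension
#' MIAE uses \eqn{g_\nu(x) = x - \nu \sin^2 x} (renormalized; the forward
#' counterpart of the InvMIAE map, strictly increasing for \eqn{|\nu| < 1} so
#' the mode stays at \eqn{\mu}); its inverse form InvMIAE
#' uses \eqn{s_\nu^{-1}(x)} with \eqn{s_\nu(u) = u + \nu \sin^2 u}
#' (normalization and peak-to-trough ratio unchanged, mode preserved at
#' \eqn{\mu}).
#'
#' Inverse maps are computed by Newton's method when the extension parameter
#' has absolute value below 0.8 and by the Illinois method otherwise.
#'
#' @param theta angles (radians, any real values; wrapped internally).
#' @param mu location (mode) angle.
#' @param lam peakedness parameter, in (-1, 1).
#' @param nu skewness parameter, in (-1, 1).
#' @return transformed angular deviations from `mu`, in \eqn{(-\pi, \pi]};
#'   feeding them through the base density (as deviation from its mode)
#'   evaluates the extended density.
#' @name angle-transforms
NULL

#' @rdname angle-transforms
#' @export
se_transform <- function(theta, mu, lam) {
  if (abs(lam) >= 1) stop_invalid_param("|lambda| must be < 1")
  x <- wrap_diff(theta - mu)
  x + lam * sin(x)
}

#' @rdname angle-transforms
#' @export
invse_transform <- function(theta, mu, lam) {
  if (abs(lam) >= 1) stop_invalid_param("|lambda| must be < 1")
  x <- wrap_diff(theta - mu)
  tinv <- .inv_increasing(function(u) u - 0.5 * (1 + lam) * sin(u),
                          function(u) 1 - 0.5 * (1 + lam) * cos(u),
                          x, lam)
  (1 - lam) / (1 + lam) * x + 2 * lam / (1 + lam) * tinv
}

#' @rdname angle-transforms
#' @export
miae_transform <- function(theta, mu, nu) {
  if (abs(nu) >= 1) stop_invalid_param("|nu| must be < 1")
  x <- wrap_diff(theta - mu)
  x - nu * sin(x)^2
}

#' @rdname angle-transforms
#' @export
invmiae_transform <- function(theta, mu, nu) {
  if (abs(nu) >= 1) stop_invalid_param("|nu| must be < 1")
  x <- wrap_diff(theta - mu)
  .inv_increasing(function(u) u + nu * sin(u)^2,
                  function(u) 1 + nu * sin(2 * u),
                  x, nu)
}
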
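#' Normal-exponential convolution density
#'
#' Closed-form density of `X = S + B` with `S ~ Exp(alpha)` and
#' `B ~ N(mu, sigma^2)`:
#' `f(x) = (1/alpha) exp(sigma^2/(2 alpha^2) - (x - mu)/alpha) * Phi(xbar)`
#' with `xbar = (x - mu - sigma^2/alpha)/sigma`. Evaluated in log space so the
#' exponential factor and the normal CDF never overflow or underflow.
#'
#' @param x Numeric vector of intensities.
#' @param p A [normexp_params()] object.
#' @param log Return the log-density?
#' @return Non-negative density values (or their logs), vectorized over `x`.
#' @examples
#' p <- normexp_params(mu = 100, sigma = 10, alpha = 200)
#' dnormexp(c(100, 300, 1000), p)
#' @export
dnormexp <- function(x, p, log = FALSE) {
  if (!inherits(p, "normexp_params")) {
    abort("`p` must be a normexp_params object.", class = "gammabg_param_error")
  }
  xbar <- (x - p$mu - p$sigma^2 / p$alpha) / p$sigma
  lf <- numeric(length(x))
  ok <- xbar > -30
  if (any(ok)) {
    lf[ok] <- -base::log(p$alpha) + p$sigma^2 / (2 * p$alpha^2) -
      (x[ok] - p$mu) / p$alpha + pnorm(xbar[ok], log.p = TRUE)
  }
  if (any(!ok)) {
    # exponent rewritten through the normal log-density: the exponential
    # factor and log Phi(xbar) cancel to -(x - mu)^2 / (2 sigma^2) up to the
    # Mills ratio, avoiding the catastrophic cancellation of the naive form
    t <- -xbar[!ok]
    lf[!ok] <- -base::log(p$alpha) + dnorm(x[!ok], p$mu, p$sigma, log = TRUE) +
      base::log(p$sigma) - base::log(t + 1 / t - 2 / t^3)
  }
  if (log) lf else exp(lf)
}

# Grid bounds covering both convolution factors: 8 noise SDs on the left,
# and on the right whichever of the noise window or the 1 - 1e-8 gamma
# quantile (shifted by mu) reaches further.
default_grid_range <- function(p) {
  c(p$mu - 8 * p$sigma,
    max(p$mu + 8 * p$sigma, p$mu + qgamma(1 - 1e-8, shape = p$k, scale = p$theta)))
}

#' Normal-gamma convolution density on a grid
#'
#' Computes the density of `X = S + B`, `S ~ Gamma(k, theta)`,
#' `B ~ N(mu, sigma^2)` — the convolution of the gamma and normal densities —
#' on an equispaced grid by discrete convolution via FFT with zero-padding
#' (no circular wrap-around).
#'
#' Each grid cell of the gamma factor contributes its exact probability mass
#' together with first- and second-moment corrections (the partial moments of
#' the gamma distribution have closed forms through `pgamma` at shifted
#' shapes), paired with the normal kernel and its first two derivatives. This
#' handles the density singularity at zero for `k < 1` — the first cell enters
#' through its exact mass, never through an (infinite) ordinate — and keeps
#' the grid density within about `1e-7` relative error of adaptive quadrature
#' of the convolution integral. Values are clipped below at `1e-300` so
#' log-likelihoods stay finite.
#'
#' @param p A [normal_gamma_params()] (or [normexp_params()], converted via
#'   `k = 1`) object.
#' @param n Grid length, a power of two. Default `2^16`.
#' @param range Optional numeric length-2 grid range; defaults to
#'   `[mu - 8 sigma, max(mu + 8 sigma, mu + Q_gamma(1 - 1e-8))]`.
#' @return An object of class `"density_grid"`: list with fields `x0` (grid
#'   origin), `dx` (step), `values` (density ordinates), and the parameters.
#'   `dx * sum(values)` integrates to 1 within `1e-4`.
#' @examples
#' p <- normal_gamma_params(mu = 0, sigma = 1, k = 2, theta = 50)
#' g <- dnormgamma_grid(p, n = 2^12)
#' interp_density(g, 150)
#' @export
dnormgamma_grid <- function(p, n = 2^16, range = NULL) {
  p <- as_normal_gamma_params(p)
  n <- as.integer(n)
  if (n < 8L || bitwAnd(n, n - 1L) != 0L) {
    abort("`n` must be a power of two (>= 8).", class = "gammabg_grid_error")
  }
  if (is.null(range)) range <- default_grid_range(p)
  x0 <- range[1]; hi <- range[2]
  if (!is.finite(x0) || !is.finite(hi) || hi <= x0) {
    abort("invalid grid range.", class = "gammabg_grid_error")
  }
  dx <- (hi - x0) / (n - 1)
  off <- (seq_len(n) - 1) * dx
  e <- off + dx / 2                               # upper cell edges
  lag0 <- function(v) c(0, v[-n])                 # lower edges are lagged uppers

  P0 <- pgamma(e, shape = p$k, scale = p$theta)
  # incomplete-gamma recurrence: P(k+1, x) = P(k, x) - x^k e^-x / Gamma(k+1)
  g1 <- p$theta * dgamma(e, shape = p$k + 1, scale = p$theta)
  P1 <- P0 - g1
  g2 <- g1 * (e / p$theta) / (p$k + 1)
  P2 <- P1 - g2

  mass <- P0 - lag0(P0)
  pm1 <- p$k * p$theta * (P1 - lag0(P1))
  pm2 <- p$k * (p$k + 1) * p$theta^2 * (P2 - lag0(P2))
  d1 <- pm1 - mass * off
  q2 <- pm2 - 2 * off * pm1 + off^2 * mass

  z <- x0 + off
  w <- (z - p$mu) / p$sigma
  phi <- dnorm(z, p$mu, p$sigma)
  zz <- numeric(n)
  FT <- fft(c(mass, zz)) * fft(c(phi, zz)) +
    fft(c(d1, zz)) * fft(c(w / p$sigma * phi, zz)) +
    fft(c(q2, zz)) * fft(c((w^2 - 1) / (2 * p$sigma^2) * phi, zz))
  f <- Re(fft(FT, inverse = TRUE)) / (2 * n)
  values <- pmax(f[seq_len(n)], 1e-300)

  total <- dx * sum(values)
  if (total < 1 - 1e-6) {
    abort(sprintf("grid too narrow: it holds mass %.8f < 1 - 1e-6.", total),
          class = "gammabg_grid_error")
  }
  structure(list(x0 = x0, dx = dx, values = values, params = p),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf("<density_grid: %d points on [%g, %g], dx = %g>\n",
              n, x$x0, x$x0 + (n - 1) * x$dx, x$dx))
  invisible(x)
}

#' Evaluate a grid density at arbitrary points
#'
#' Linear interpolation between grid nodes (positivity-preserving). Outside
#' the grid the dominant convolution factor takes over: the normal density
#' `N(mu, sigma^2)` on the left (signal mass sits near 0 there) and the gamma
#' density shifted by `mu` on the right. Never returns 0: a floor of `1e-300`
#' keeps downstream logs finite.
#'
#' @param g A `"density_grid"` from [dnormgamma_grid()].
#' @param x Numeric vector of evaluation points.
#' @return Strictly positive density values.
#' @export
interp_density <- function(g, x) {
  stopifnot(inherits(g, "density_grid"))
  p <- g$params
  n <- length(g$values)
  x_last <- g$x0 + (n - 1) * g$dx
  v <- numeric(length(x))
  inside <- x >= g$x0 & x <= x_last
  if (any(inside)) {
    j <- pmin(floor((x[inside] - g$x0) / g$dx) + 1, n - 1L)
    frac <- (x[inside] - (g$x0 + (j - 1) * g$dx)) / g$dx
    v[inside] <- (1 - frac) * g$values[j] + frac * g$values[j + 1L]
  }
  left <- x < g$x0
  if (any(left)) v[left] <- dnorm(x[left], p$mu, p$sigma)
  right <- x > x_last
  if (any(right)) v[right] <- dgamma(x[right] - p$mu, shape = p$k, scale = p$theta)
  pmax(v, 1e-300)
}

#' Normal-gamma density at arbitrary points
#'
#' Convenience wrapper: builds the FFT grid with [dnormgamma_grid()] and
#' evaluates it with [interp_density()].
#'
#' @inheritParams dnormgamma_grid
#' @param x Numeric vector of intensities.
#' @param log Return the log-density?
#' @return Density values at `x`.
#' @export
dnormgamma <- function(x, p, n = 2^16, log = FALSE) {
  v <- interp_density(dnormgamma_grid(p, n = n), x)
  if (log) base::log(v) else v
}
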
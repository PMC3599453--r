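# x + phi(x)/Phi(x), computed without cancellation. The ratio itself is
# stable via log-space dnorm/pnorm; far in the left tail the sum of two
# nearly opposite large terms is replaced by its asymptotic series
# 1/t - 2/t^3 + 10/t^5, t = -x.
mills_adjusted <- function(x) {
  out <- numeric(length(x))
  far <- x < -37
  if (any(!far)) {
    xb <- x[!far]
    out[!far] <- xb + exp(dnorm(xb, log = TRUE) - pnorm(xb, log.p = TRUE))
  }
  if (any(far)) {
    t <- -x[far]
    out[far] <- 1 / t - 2 / t^3 + 10 / t^5
  }
  out
}

#' Normexp background correction
#'
#' Conditional expectation of the signal given the observed intensity under
#' the normexp model: `S_hat(x) = sigma * (xbar + phi(xbar)/Phi(xbar))` with
#' `xbar = (x - mu - sigma^2/alpha)/sigma`. The Mills-ratio term is computed
#' stably for strongly negative `xbar`, so the output is strictly positive
#' for all finite input — the model-based alternative to clamping subtracted
#' intensities at zero.
#'
#' @param x Numeric vector of observed intensities.
#' @param p A [normexp_params()] object.
#' @return Strictly positive corrected intensities.
#' @examples
#' p <- normexp_params(mu = 100, sigma = 10, alpha = 200)
#' bg_correct_normexp(c(90, 150, 500), p)
#' @export
bg_correct_normexp <- function(x, p) {
  if (!inherits(p, "normexp_params")) {
    abort("`p` must be a normexp_params object.", class = "gammabg_param_error")
  }
  xbar <- (x - p$mu - p$sigma^2 / p$alpha) / p$sigma
  out <- p$sigma * mills_adjusted(xbar)
  # far right of the centering point the Mills term is below double
  # precision: use the exact limit to dodge overflow of xbar itself
  big <- xbar > 1e8
  if (any(big)) out[big] <- x[big] - p$mu - p$sigma^2 / p$alpha
  out
}

#' Normal-gamma background correction
#'
#' Conditional expectation of the signal given the observed intensity under
#' the normal-gamma model, computed through the shape-shift identity
#' `S_hat(x) = k * theta * f_ng(x; k + 1) / f_ng(x; k)`: the numerator and
#' denominator densities are evaluated on one shared FFT grid (its upper end
#' sized for shape `k + 1`) so the ratio stays smooth. Below the grid the
#' ratio uses the exponentially tilted gamma limit
#' `k * theta / (1 + theta (mu - x) / sigma^2)`; above it the gamma-dominated
#' limit `x - mu`.
#'
#' @param x Numeric vector of observed intensities.
#' @param p A [normal_gamma_params()] object (normexp parameters are
#'   converted via `k = 1`).
#' @param grid_n FFT grid length (power of two).
#' @return Strictly positive corrected intensities.
#' @examples
#' p <- normal_gamma_params(mu = 0, sigma = 1, k = 2, theta = 50)
#' bg_correct_normgamma(150, p)
#' @export
bg_correct_normgamma <- function(x, p, grid_n = 2^16) {
  p <- as_normal_gamma_params(p)
  p1 <- normal_gamma_params(p$mu, p$sigma, p$k + 1, p$theta)
  range <- default_grid_range(p1)  # shape k+1 reaches further right
  if (p$sigma < (range[2] - range[1]) / grid_n) {
    # noise below grid resolution: the correction degenerates to the
    # noiseless limit E[S | X = x] = x - mu
    return(pmax(x - p$mu, .Machine$double.xmin))
  }
  g0 <- dnormgamma_grid(p, n = grid_n, range = range)
  g1 <- dnormgamma_grid(p1, n = grid_n, range = range)

  # Right of the bulk the FFT ratio drowns in the transform's absolute
  # roundoff floor; there the posterior of S is a normally tilted gamma and
  # E[S | X = x] ~ x - mu + sigma^2 ((k - 1)/(x - mu) - 1/theta) (Laplace
  # approximation; exact normexp limit at k = 1). Switch where the
  # denominator density has fallen to 1e-6 of its peak — far beyond any
  # observable intensity — with a one-sigma linear blend for monotonicity.
  nodes <- g0$x0 + (seq_along(g0$values) - 1) * g0$dx
  above <- which(g0$values >= 1e-6 * max(g0$values))
  x_sw <- max(p$mu + 8 * p$sigma, nodes[above[length(above)]])
  tilt <- function(xx) {
    t <- pmax(xx - p$mu, p$sigma)
    pmax(t + p$sigma^2 * ((p$k - 1) / t - 1 / p$theta), .Machine$double.xmin)
  }

  out <- numeric(length(x))
  bulk <- x <= x_sw
  if (any(bulk)) {
    out[bulk] <- p$k * p$theta *
      interp_density(g1, x[bulk]) / interp_density(g0, x[bulk])
  }
  far <- x > x_sw + p$sigma
  if (any(far)) out[far] <- tilt(x[far])
  mid <- !bulk & !far
  if (any(mid)) {
    w <- (x[mid] - x_sw) / p$sigma
    ratio_mid <- p$k * p$theta *
      interp_density(g1, x[mid]) / interp_density(g0, x[mid])
    out[mid] <- (1 - w) * ratio_mid + w * tilt(x[mid])
  }
  left <- x < range[1]
  if (any(left)) {
    # exponential tilt of the gamma by the normal left tail
    out[left] <- p$k * p$theta / (1 + p$theta * (p$mu - x[left]) / p$sigma^2)
  }
  pmax(out, .Machine$double.xmin)
}

#' Background subtraction
#'
#' The BeadStudio-style rule: subtract the median negative-control intensity
#' and clamp at zero. Simple, but maps every weak probe to exactly 0 and
#' discards the information a model-based correction would retain.
#'
#' @param x Numeric vector of observed intensities.
#' @param negative Non-empty numeric vector of negative-control intensities.
#' @return Non-negative corrected intensities.
#' @examples
#' bg_correct_subtract(c(5, 10), negative = c(4, 6, 8))
#' @export
bg_correct_subtract <- function(x, negative) {
  if (length(negative) == 0L) {
    abort("`negative` must be non-empty.", class = "gammabg_data_error")
  }
  pmax(x - median(negative), 0)
}

#' Detection p-values from negative controls
#'
#' For each regular probe, the proportion of negative-control probes on the
#' same array with strictly greater intensity — the detection p-value
#' reported by the Illumina software.
#'
#' @param regular Numeric vector of regular-probe intensities.
#' @param negative Non-empty numeric vector of negative-control intensities.
#' @return Numeric vector in `[0, 1]`, aligned with `regular`.
#' @examples
#' detection_pvalues(5, negative = c(1, 2, 9, 10))
#' @export
detection_pvalues <- function(regular, negative) {
  if (length(negative) == 0L) {
    abort("`negative` must be non-empty.", class = "gammabg_data_error")
  }
  sneg <- sort(negative)
  (length(sneg) - findInterval(regular, sneg)) / length(sneg)
}

#' Infer negative-control intensities from detection p-values
#'
#' Many public data sets ship detection p-values but not the negative-probe
#' intensities themselves. Since the detection p-value of a probe is the
#' fraction of negatives above it, the sorted regular intensities together
#' with their p-values trace out the negative-probe empirical distribution:
#' the r-th negative order statistic is recovered by piecewise-linear
#' interpolation of intensity against p at the level `(n_neg - r) / n_neg`
#' (each p plateau is represented by the smallest intensity attaining it).
#' Order statistics falling outside the regular range are clamped to it.
#'
#' @param pvals Detection p-values in `[0, 1]`, aligned with `regular`.
#' @param regular Regular-probe intensities.
#' @param n_neg Number of negative probes to reconstruct (>= 2).
#' @return Numeric vector of `n_neg` inferred negative intensities (sorted).
#' @export
infer_negatives <- function(pvals, regular, n_neg) {
  if (length(pvals) != length(regular)) {
    abort("`pvals` and `regular` must have the same length.",
          class = "gammabg_validation_error")
  }
  if (any(pvals < 0 | pvals > 1)) {
    abort("`pvals` must lie in [0, 1].", class = "gammabg_validation_error")
  }
  n_neg <- as.integer(n_neg)
  if (n_neg < 2L) {
    abort("`n_neg` must be >= 2.", class = "gammabg_validation_error")
  }
  ord <- order(regular)
  xs <- regular[ord]
  ps <- cummin(pvals[ord])          # enforce the counting monotonicity
  # left edge of each p plateau
  first <- !duplicated(ps)
  levels_p <- ps[first]
  levels_x <- xs[first]
  q <- (n_neg - seq_len(n_neg)) / n_neg
  if (length(levels_p) < 2L) {
    # constant detection p-value: negatives with order-statistic level below
    # it sit right of every regular probe, the rest left of all of them
    return(sort(ifelse(q < levels_p[1], max(xs), min(xs))))
  }
  out <- approx(x = levels_p, y = levels_x, xout = q, rule = 2, ties = min)$y
  sort(pmin(pmax(out, min(xs)), max(xs)))
}

#' Quantile normalization
#'
#' Forces all arrays to share one intensity distribution: each array's sorted
#' values are replaced by the across-array mean of order statistics; tied
#' values receive the mean of their tied block. Typically applied to the
#' pooled regular + negative probe rows after background correction.
#'
#' @param x Numeric matrix (probes x arrays) or data frame of >= 2 intensity
#'   columns.
#' @return A matrix of the same dimensions.
#' @examples
#' quantile_normalize(cbind(a = c(1, 2, 3), b = c(4, 5, 6)))
#' @export
quantile_normalize <- function(x) {
  if (is.data.frame(x)) {
    if (!all(vapply(x, is.numeric, logical(1)))) {
      abort("all columns must be numeric.", class = "gammabg_validation_error")
    }
    x <- as.matrix(x)
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix.", class = "gammabg_validation_error")
  }
  if (ncol(x) < 2L) {
    abort("quantile normalization needs >= 2 arrays.",
          class = "gammabg_validation_error")
  }
  if (anyNA(x)) {
    abort("missing intensities are not supported.",
          class = "gammabg_validation_error")
  }
  limma::normalizeQuantiles(x, ties = TRUE)
}

#' Offset-log transform
#'
#' `log2(x + offset)`. Adding a moderate offset before the log aligns the
#' innate offsets of different background corrections and damps the variance
#' of weak probes at the cost of compressing fold changes.
#'
#' @param x Numeric vector (typically background-corrected, quantile
#'   normalized intensities).
#' @param offset Non-negative offset, in intensity units.
#' @return `log2(x + offset)`.
#' @examples
#' offset_log(c(1, 2, 4), offset = 0)
#' @export
offset_log <- function(x, offset = 0) {
  if (length(offset) != 1L || !is.finite(offset) || offset < 0) {
    abort("`offset` must be a single non-negative number.",
          class = "gammabg_validation_error")
  }
  if (any(x + offset <= 0)) {
    abort("`x + offset` must be strictly positive.",
          class = "gammabg_validation_error")
  }
  log2(x + offset)
}

#' Background-correct a probe table
#'
#' Tidy front end running the full per-array recipe on a probe table: fit the
#' chosen model (unless a fit or explicit parameters are supplied), then
#' replace observed intensities by corrected signal estimates. Negative
#' probes are corrected with the same rule as regular probes.
#'
#' @param data A data frame with columns `intensity` and `probe_type`.
#' @param method One of `"normal-gamma"`, `"normexp-mle"`, `"normexp-rma"`,
#'   `"normexp-np"`, `"subtract"`.
#' @param fit Optional `"bg_fit"` (skips fitting).
#' @param params Optional parameter object (skips fitting).
#' @param ... Passed to [fit_background()].
#' @return The input tibble with a `signal_hat` column appended.
#' @export
bg_correct <- function(data, method = c("normal-gamma", "normexp-mle",
                                        "normexp-rma", "normexp-np", "subtract"),
                       fit = NULL, params = NULL, ...) {
  method <- match.arg(method)
  data <- as_tibble(data)
  d <- as_array_data(data)
  x <- data$intensity
  if (method == "subtract") {
    data$signal_hat <- bg_correct_subtract(x, d$negative)
    return(data)
  }
  if (is.null(params)) {
    if (is.null(fit)) fit <- fit_background(d, model = method, ...)
    params <- fit$params
  }
  data$signal_hat <- if (method == "normal-gamma") {
    bg_correct_normgamma(x, params)
  } else {
    bg_correct_normexp(x, params)
  }
  data
}
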
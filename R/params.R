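#' Normal-gamma model parameters
#'
#' Parameter vector of the normal-gamma convolution model for single-channel
#' microarray intensities: the observed intensity of a regular probe is
#' `X = S + B` with signal `S ~ Gamma(shape = k, scale = theta)` and background
#' noise `B ~ N(mu, sigma^2)`; negative control probes carry noise only
#' (`S = 0`). The signal mean is `k * theta`.
#'
#' @param mu Noise mean, in intensity units.
#' @param sigma Noise standard deviation (> 0).
#' @param k Gamma shape of the signal (> 0).
#' @param theta Gamma scale of the signal (> 0), in intensity units.
#'
#' @return An object of class `c("normal_gamma_params", "bg_params")`.
#' @seealso [normexp_params()] for the exponential-signal special case `k = 1`.
#' @examples
#' p <- normal_gamma_params(mu = 900, sigma = 140, k = 0.64, theta = 500)
#' signal_mean(p)
#' @export
normal_gamma_params <- function(mu, sigma, k, theta) {
  check_scalar(mu, "mu")
  check_scalar(sigma, "sigma", positive = TRUE)
  check_scalar(k, "k", positive = TRUE)
  check_scalar(theta, "theta", positive = TRUE)
  structure(
    list(mu = mu, sigma = sigma, k = k, theta = theta),
    class = c("normal_gamma_params", "bg_params")
  )
}

#' Normal-exponential (normexp) model parameters
#'
#' Parameter vector of the normexp model: signal `S ~ Exp(mean = alpha)`,
#' noise `B ~ N(mu, sigma^2)`. Equivalent to [normal_gamma_params()] with
#' `k = 1`, `theta = alpha`.
#'
#' @param mu Noise mean.
#' @param sigma Noise standard deviation (> 0).
#' @param alpha Exponential signal mean (> 0).
#'
#' @return An object of class `c("normexp_params", "bg_params")`.
#' @examples
#' normexp_params(mu = 100, sigma = 10, alpha = 200)
#' @export
normexp_params <- function(mu, sigma, alpha) {
  check_scalar(mu, "mu")
  check_scalar(sigma, "sigma", positive = TRUE)
  check_scalar(alpha, "alpha", positive = TRUE)
  structure(
    list(mu = mu, sigma = sigma, alpha = alpha),
    class = c("normexp_params", "bg_params")
  )
}

check_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name),
          class = "gammabg_param_error")
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0.", name), class = "gammabg_param_error")
  }
  invisible(x)
}

#' Coerce parameters to the normal-gamma parametrization
#'
#' @param p A [normal_gamma_params()] or [normexp_params()] object.
#' @return A [normal_gamma_params()] object (`k = 1`, `theta = alpha` for
#'   normexp input).
#' @export
as_normal_gamma_params <- function(p) {
  if (inherits(p, "normal_gamma_params")) return(p)
  if (inherits(p, "normexp_params")) {
    return(normal_gamma_params(p$mu, p$sigma, k = 1, theta = p$alpha))
  }
  abort("`p` must be a bg_params object.", class = "gammabg_param_error")
}

#' Mean of the signal distribution
#'
#' @param p A parameter object.
#' @return `k * theta` (or `alpha`).
#' @export
signal_mean <- function(p) {
  p <- as_normal_gamma_params(p)
  p$k * p$theta
}

#' @export
print.bg_params <- function(x, ...) {
  lbl <- if (inherits(x, "normexp_params")) "normexp" else "normal-gamma"
  cat(sprintf("<%s parameters>\n", lbl))
  v <- unlist(x)
  cat(paste(sprintf("  %-5s %g", names(v), v), collapse = "\n"), "\n")
  invisible(x)
}

#' @export
as.double.bg_params <- function(x, ...) unlist(unclass(x))

#' Per-array intensity data
#'
#' Container for one array: observed intensities of regular probes and of
#' negative control probes. Negative probes measure pure background noise and
#' anchor the noise parameters during estimation.
#'
#' @param regular Numeric vector of regular-probe intensities (non-empty).
#' @param negative Numeric vector of negative-control intensities (may be
#'   empty, in which case only RMA-style estimation is possible).
#' @return An object of class `"array_data"`.
#' @examples
#' d <- array_data(regular = c(120, 340, 95), negative = c(90, 110))
#' @export
array_data <- function(regular, negative = numeric()) {
  regular <- as.double(regular)
  negative <- as.double(negative)
  if (anyNA(regular)) {
    abort("`regular` must not contain NA.", class = "gammabg_data_error")
  }
  if (anyNA(negative)) {
    abort("`negative` must not contain NA.", class = "gammabg_data_error")
  }
  structure(list(regular = regular, negative = negative), class = "array_data")
}

#' @export
print.array_data <- function(x, ...) {
  cat(sprintf("<array_data: %d regular, %d negative probes>\n",
              length(x$regular), length(x$negative)))
  invisible(x)
}

#' Coerce to array_data
#'
#' @param x An object: an `array_data`, or a data frame with an intensity
#'   column and a probe-type column containing `"regular"` / `"negative"`.
#' @param intensity,probe_type Column names used for the data-frame method.
#' @param ... Unused.
#' @return An `array_data` object.
#' @export
as_array_data <- function(x, ...) UseMethod("as_array_data")

#' @rdname as_array_data
#' @export
as_array_data.array_data <- function(x, ...) x

#' @rdname as_array_data
#' @export
as_array_data.data.frame <- function(x, intensity = "intensity",
                                     probe_type = "probe_type", ...) {
  if (!all(c(intensity, probe_type) %in% names(x))) {
    abort(sprintf("columns `%s` and `%s` are required.", intensity, probe_type),
          class = "gammabg_data_error")
  }
  type <- x[[probe_type]]
  bad <- setdiff(unique(type), c("regular", "negative"))
  if (length(bad)) {
    abort(sprintf("unknown probe type(s): %s", paste(bad, collapse = ", ")),
          class = "gammabg_data_error")
  }
  array_data(regular = x[[intensity]][type == "regular"],
             negative = x[[intensity]][type == "negative"])
}
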
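#' Built-in simulation parameter presets
#'
#' Named parameter sets with Illumina-plausible values used as defaults by
#' the simulator and throughout the package's evaluation examples:
#' `"A"` is a non-degenerate normal-gamma set
#' (`mu = 900, sigma = 140, k = 0.64, theta = 500`), `"B"` its normexp
#' counterpart (`mu = 900, sigma = 140, alpha = 320`), chosen so the signal
#' means roughly match.
#'
#' @param name `"A"` or `"B"`.
#' @return A parameter object.
#' @examples
#' preset_params("A")
#' @export
preset_params <- function(name = c("A", "B")) {
  switch(match.arg(name),
    A = normal_gamma_params(mu = 900, sigma = 140, k = 0.64, theta = 500),
    B = normexp_params(mu = 900, sigma = 140, alpha = 320)
  )
}

#' Specify a synthetic-array simulation design
#'
#' Describes how a batch of synthetic single-channel arrays is generated:
#' regular-probe intensities are the sum of a gamma signal and background
#' noise, negative probes carry noise only. Three noise families are
#' available: pure normal; a normal / moment-matched chi-square mixture whose
#' proportion `mixture_p` controls right-tail weight while the first two
#' moments stay fixed; and empirical resampling from a supplied noise vector.
#' Replicate mode draws one signal vector shared by every array (fresh noise
#' per array), mimicking technical replicates of a single sample.
#'
#' @param params Signal/noise parameters ([normal_gamma_params()] or
#'   [normexp_params()]); `sigma = 0` is tolerated here (noise-free arrays
#'   for calibration checks). Default [preset_params()] `"A"`.
#' @param n_reg,n_neg Regular / negative probes per array.
#' @param n_arrays Number of arrays.
#' @param noise `"normal"`, `"mixture"`, or `"empirical"`.
#' @param mixture_p Mixture proportion of the chi-square component.
#' @param chisq_df Degrees of freedom of the chi-square component.
#' @param empirical_noise Numeric vector resampled with replacement when
#'   `noise = "empirical"`.
#' @param replicate_signal Share one signal vector across all arrays?
#' @param seed Master seed; array `l` uses stream `seed + l`, so growing
#'   `n_arrays` never reshuffles earlier arrays.
#' @return A `"sim_design"` list.
#' @examples
#' sim_design(n_reg = 1000, n_neg = 100, n_arrays = 3, seed = 1)
#' @export
sim_design <- function(params = preset_params("A"), n_reg = 25000,
                       n_neg = 1000, n_arrays = 100,
                       noise = c("normal", "mixture", "empirical"),
                       mixture_p = 0, chisq_df = 4, empirical_noise = NULL,
                       replicate_signal = FALSE, seed = 1) {
  noise <- match.arg(noise)
  if (inherits(params, "bg_params")) {
    p <- as_normal_gamma_params(params)
    p <- list(mu = p$mu, sigma = p$sigma, k = p$k, theta = p$theta)
    model <- if (inherits(params, "normexp_params")) "normexp" else "normal-gamma"
  } else {
    p <- params
    if (!all(c("mu", "sigma", "k", "theta") %in% names(p))) {
      abort("`params` must provide mu, sigma, k, theta.",
            class = "gammabg_validation_error")
    }
    if (p$sigma < 0 || p$k <= 0 || p$theta <= 0) {
      abort("invalid simulation parameters.", class = "gammabg_validation_error")
    }
    model <- if (p$k == 1) "normexp" else "normal-gamma"
  }
  if (n_reg < 1 || n_neg < 1 || n_arrays < 1) {
    abort("n_reg, n_neg and n_arrays must be >= 1.",
          class = "gammabg_validation_error")
  }
  if (mixture_p < 0 || mixture_p > 1) {
    abort("`mixture_p` must be in [0, 1].", class = "gammabg_validation_error")
  }
  if (noise == "empirical" && (is.null(empirical_noise) ||
                               length(empirical_noise) < 2L)) {
    abort("`empirical_noise` must be supplied for empirical noise.",
          class = "gammabg_validation_error")
  }
  structure(
    list(model = model, params = p, n_reg = as.integer(n_reg),
         n_neg = as.integer(n_neg), n_arrays = as.integer(n_arrays),
         noise = noise, mixture_p = mixture_p, chisq_df = chisq_df,
         empirical_noise = empirical_noise,
         replicate_signal = isTRUE(replicate_signal), seed = as.integer(seed)),
    class = "sim_design"
  )
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("<sim_design: %s, %d arrays x (%d regular + %d negative), noise %s%s>\n",
              x$model, x$n_arrays, x$n_reg, x$n_neg, x$noise,
              if (x$replicate_signal) ", replicated signal" else ""))
  invisible(x)
}

#' Normal / chi-square mixture noise
#'
#' Each draw comes from a location/scale-adjusted chi-square with probability
#' `p` and from `N(mu, sigma^2)` otherwise. The chi-square component is
#' affinely mapped to `mu + sigma * (C - df) / sqrt(2 df)`, so the mixture
#' keeps the normal component's mean and variance for every `p`; `p` only
#' adds right-tail weight (skewness `sqrt(8 / df)` at `p = 1`).
#'
#' @param n Number of draws.
#' @param p Mixture proportion in `[0, 1]`.
#' @param mu,sigma Normal component parameters.
#' @param chisq_df Chi-square degrees of freedom.
#' @param seed Optional seed set before drawing.
#' @return Numeric vector of length `n`.
#' @export
mixture_noise <- function(n, p, mu, sigma, chisq_df = 4, seed = NULL) {
  if (p < 0 || p > 1) {
    abort("`p` must be in [0, 1].", class = "gammabg_validation_error")
  }
  if (!is.null(seed)) set.seed(seed)
  use_chisq <- runif(n) < p
  out <- rnorm(n, mu, sigma)
  n_c <- sum(use_chisq)
  if (n_c > 0) {
    cc <- rchisq(n_c, df = chisq_df)
    out[use_chisq] <- mu + sigma * (cc - chisq_df) / sqrt(2 * chisq_df)
  }
  out
}

draw_noise <- function(design, n) {
  p <- design$params
  switch(design$noise,
    normal = rnorm(n, p$mu, p$sigma),
    mixture = mixture_noise(n, design$mixture_p, p$mu, p$sigma,
                            design$chisq_df),
    empirical = sample(design$empirical_noise, n, replace = TRUE)
  )
}

#' Simulate synthetic arrays
#'
#' Generates `n_arrays` arrays under a [sim_design()]. Regular intensities
#' are exactly `signal + noise`; negative probes carry noise only. Fully
#' reproducible: array `l` is drawn under seed `seed + l` (the shared signal
#' of replicate mode under `seed` itself), so the first arrays of two designs
#' differing only in `n_arrays` are identical.
#'
#' @param design A [sim_design()].
#' @return A nested tibble of class `"sim_arrays"`: one row per array with
#'   columns `array` and `data`, where each `data` element is a tibble with
#'   columns `probe_id`, `probe_type`, `intensity`, `signal`, `noise`. The
#'   design is attached as attribute `"design"`.
#' @examples
#' arrays <- simulate_arrays(sim_design(n_reg = 500, n_neg = 50,
#'                                      n_arrays = 2, seed = 3))
#' arrays$data[[1]]
#' @export
simulate_arrays <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  p <- design$params
  shared_signal <- NULL
  if (design$replicate_signal) {
    set.seed(design$seed)
    shared_signal <- rgamma(design$n_reg, shape = p$k, scale = p$theta)
  }
  ids <- c(sprintf("reg_%05d", seq_len(design$n_reg)),
           sprintf("neg_%04d", seq_len(design$n_neg)))
  types <- c(rep("regular", design$n_reg), rep("negative", design$n_neg))
  rows <- lapply(seq_len(design$n_arrays), function(l) {
    set.seed(design$seed + l)
    s <- shared_signal %||% rgamma(design$n_reg, shape = p$k, scale = p$theta)
    b <- draw_noise(design, design$n_reg)
    b0 <- draw_noise(design, design$n_neg)
    tibble(
      probe_id = ids, probe_type = types,
      intensity = c(s + b, b0),
      signal = c(s, numeric(design$n_neg)),
      noise = c(b, b0)
    )
  })
  out <- tibble(array = seq_len(design$n_arrays), data = rows)
  attr(out, "design") <- design
  class(out) <- c("sim_arrays", class(out))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' True parameters of a simulation
#'
#' @param arrays A `"sim_arrays"` object.
#' @return The generating [normal_gamma_params()].
#' @export
true_params <- function(arrays) {
  design <- attr(arrays, "design")
  if (is.null(design)) {
    abort("`arrays` carries no design attribute.", class = "gammabg_validation_error")
  }
  p <- design$params
  normal_gamma_params(p$mu, max(p$sigma, .Machine$double.xmin), p$k, p$theta)
}
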
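#' Penalized-likelihood irregular histogram
#'
#' Adaptive density histogram with data-driven, unequal bin widths: candidate
#' breakpoints are placed at a dyadic grid of data quantiles and a dynamic
#' program selects the partition maximizing the histogram log-likelihood
#' `sum n_i log(n_i / (n w_i))` minus the penalty
#' `pen(D) = (D - 1) + lchoose(n - 1, D - 1)`, which charges both the number
#' of bins and the combinatorial richness of the break choice. Irregular
#' histograms adapt to the sharp peak and long right tail of microarray
#' intensity distributions far better than equal-width binning.
#'
#' @param x Numeric data (n >= 50 recommended; below that a regular
#'   histogram is returned with a warning).
#' @param grid_size Number of candidate quantile points (default `2^7`).
#' @param max_bins Cap on the number of bins searched.
#' @return An object of class `"irregular_histogram"`: `breaks` (strictly
#'   increasing), `heights` (density, one fewer), `counts`, `n`. Integrates
#'   to 1 exactly.
#' @examples
#' h <- irregular_histogram(rexp(1000))
#' sum(diff(h$breaks) * h$heights)
#' @export
irregular_histogram <- function(x, grid_size = 2^7, max_bins = 40L) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 50L) {
    warn("fewer than 50 observations: falling back to a regular histogram.")
    hh <- graphics::hist(x, plot = FALSE)
    return(new_irregular_histogram(hh$breaks, hh$counts, n))
  }
  edges <- unique(quantile(x, probs = seq(0, 1, length.out = grid_size),
                           names = FALSE, type = 7))
  if (length(edges) < 3L) edges <- range(x) + c(0, .Machine$double.eps)
  K <- length(edges) - 1L              # candidate cells
  # counts per candidate cell (right-closed on the last edge)
  idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
  cnt <- tabulate(idx, nbins = K)
  ccnt <- c(0, cumsum(cnt))
  sel <- select_partition_dp(edges, ccnt, n, max_bins)
  new_irregular_histogram(edges[sel], diff(ccnt[sel]), n)
}

# DP over candidate edges: best[d, j] = max loglik splitting edges[1..j]
# into d bins; returns the indices of the chosen edges.
select_partition_dp <- function(edges, ccnt, n, max_bins) {
  K <- length(edges) - 1L
  Dmax <- min(max_bins, K)
  ll_bin <- function(i, j) { # cells i..j-1 merged: edge index i to j
    cnt <- ccnt[j] - ccnt[i]
    w <- edges[j] - edges[i]
    ifelse(cnt > 0, cnt * (base::log(cnt) - base::log(n * w)), 0)
  }
  ne <- K + 1L
  best <- matrix(-Inf, nrow = Dmax, ncol = ne)
  back <- matrix(NA_integer_, nrow = Dmax, ncol = ne)
  for (j in 2:ne) best[1, j] <- ll_bin(1L, j)
  if (Dmax > 1) {
    for (d in 2:Dmax) {
      for (j in (d + 1):ne) {
        i <- d:(j - 1L)
        v <- best[d - 1L, i] + ll_bin(i, j)
        m <- which.max(v)
        best[d, j] <- v[m]
        back[d, j] <- i[m]
      }
    }
  }
  pen <- (seq_len(Dmax) - 1) + lchoose(n - 1, seq_len(Dmax) - 1)
  crit <- best[, ne] - pen
  D <- which.max(crit)
  sel <- ne
  d <- D
  while (d > 1) {
    sel <- c(back[d, sel[1]], sel)
    d <- d - 1L
  }
  c(1L, sel)
}

new_irregular_histogram <- function(breaks, counts, n) {
  widths <- diff(breaks)
  structure(
    list(breaks = breaks, heights = counts / (n * widths),
         counts = counts, n = n),
    class = "irregular_histogram"
  )
}

#' @export
print.irregular_histogram <- function(x, ...) {
  cat(sprintf("<irregular_histogram: %d bins on [%g, %g], n = %d>\n",
              length(x$heights), min(x$breaks), max(x$breaks), x$n))
  invisible(x)
}

#' @method tidy irregular_histogram
#' @export
tidy.irregular_histogram <- function(x, ...) {
  tibble(bin_lo = head(x$breaks, -1), bin_hi = tail(x$breaks, -1),
         count = x$counts, height = x$heights)
}

#' Evaluate an irregular histogram as a density
#'
#' @param h An `"irregular_histogram"`.
#' @param x Evaluation points (0 outside the histogram range).
#' @return Density values.
#' @export
histogram_density <- function(h, x) {
  i <- findInterval(x, h$breaks, rightmost.closed = TRUE)
  out <- numeric(length(x))
  inside <- i >= 1 & i <= length(h$heights)
  out[inside] <- h$heights[i[inside]]
  out
}

#' L1 distance between a fitted density and a histogram
#'
#' `integral |f(x) - h(x)| dx`, the total-variation-style distance used to
#' judge how well a plug-in parametric density reconstructs the observed
#' intensity distribution. Integrated numerically bin by bin (midpoint rule
#' on >= `points_per_bin` sub-points per bin) plus the density mass falling
#' outside the histogram range.
#'
#' @param f A density: a function of `x`, a parameter object, or a
#'   `"density_grid"`.
#' @param h An `"irregular_histogram"`.
#' @param points_per_bin Sub-grid size per bin.
#' @return Non-negative scalar (<= 2).
#' @export
l1_fit <- function(f, h, points_per_bin = 64L) {
  stopifnot(inherits(h, "irregular_histogram"))
  fx <- as_density_function(f)
  total <- 0
  mass_in <- 0
  for (i in seq_along(h$heights)) {
    a <- h$breaks[i]; b <- h$breaks[i + 1]
    xs <- a + (seq_len(points_per_bin) - 0.5) * (b - a) / points_per_bin
    fv <- fx(xs)
    w <- (b - a) / points_per_bin
    total <- total + sum(abs(fv - h$heights[i])) * w
    mass_in <- mass_in + sum(fv) * w
  }
  total + max(0, 1 - mass_in)
}

as_density_function <- function(f) {
  if (is.function(f)) return(f)
  if (inherits(f, "density_grid")) return(function(x) interp_density(f, x))
  if (inherits(f, "normexp_params")) return(function(x) dnormexp(x, f))
  if (inherits(f, "bg_params")) {
    g <- dnormgamma_grid(as_normal_gamma_params(f))
    return(function(x) interp_density(g, x))
  }
  abort("`f` must be a function, density_grid or parameter object.",
        class = "gammabg_validation_error")
}

#' Relative L1 parameter-recovery error
#'
#' For each parameter `beta`, the mean over replicate fits of
#' `|beta - beta_hat| / |beta|` (plain absolute error, flagged, when the true
#' value is 0). The standard summary of estimator quality in the simulation
#' studies.
#'
#' @param true True parameter object.
#' @param fits List of `"bg_fit"` objects sharing `true`'s parametrization.
#' @return A tibble with columns `term`, `error`, `relative`.
#' @export
param_error <- function(true, fits) {
  tv <- unlist(unclass(true))
  est <- vapply(fits, function(f) {
    e <- unlist(unclass(f$params))
    if (!identical(names(e), names(tv))) {
      abort("fits and `true` use different parametrizations.",
            class = "gammabg_validation_error")
    }
    e
  }, numeric(length(tv)))
  est <- matrix(est, nrow = length(tv))
  err <- abs(est - tv)
  rel <- tv != 0
  tibble(
    term = names(tv),
    error = unname(ifelse(rel, rowMeans(err) / abs(tv), rowMeans(err))),
    relative = unname(rel)
  )
}

# Corrected signal for one synthetic array under a named method.
# true_p is the generating parameter set (used by the oracle).
correct_with_method <- function(d, method, true_p, fit = NULL) {
  switch(method,
    oracle = {
      if (true_p$k == 1) {
        bg_correct_normexp(d$regular,
                           normexp_params(true_p$mu, true_p$sigma, true_p$theta))
      } else {
        bg_correct_normgamma(d$regular, true_p)
      }
    },
    "ng-mle" = {
      fit <- fit %||% fit_normgamma(d)
      bg_correct_normgamma(d$regular, fit$params)
    },
    "nexp-mle" = {
      fit <- fit %||% fit_normexp(d, "mle")
      bg_correct_normexp(d$regular, fit$params)
    },
    "nexp-rma" = {
      fit <- fit %||% fit_normexp(d, "rma")
      bg_correct_normexp(d$regular, fit$params)
    },
    "nexp-np" = {
      fit <- fit %||% fit_normexp(d, "np")
      bg_correct_normexp(d$regular, fit$params)
    },
    subtract = bg_correct_subtract(d$regular, d$negative),
    abort(sprintf("unknown method '%s'.", method),
          class = "gammabg_validation_error")
  )
}

#' MAD and excess-risk ratios of background corrections
#'
#' For each method, the mean absolute deviation between corrected intensity
#' and true signal, averaged over probes and arrays —
#' `MAD = mean_l mean_j |S_hat(X_jl) - S_jl|` — on the raw scale and on the
#' log scale (`mean |log S_hat - log S|`, probes with true signal < 1 and
#' zero corrected values excluded, so background subtraction contributes no
#' log-scale entry for its clamped probes). Each MAD is divided by the MAD of
#' the oracle — the normal-gamma correction at the true generating
#' parameters — giving the excess-risk ratio `R(i)`; `R = 1` means parameter
#' estimation costs nothing relative to knowing the truth.
#'
#' @param arrays A `"sim_arrays"` object (carries the ground-truth signal).
#' @param methods Character vector among `"oracle"`, `"ng-mle"`,
#'   `"nexp-mle"`, `"nexp-rma"`, `"nexp-np"`, `"subtract"`. The oracle is
#'   added automatically.
#' @return A tibble with one row per method: `method`, `mad_raw`, `mad_log`,
#'   `r_raw`, `r_log`, plus the per-array fits in attribute `"fits"`.
#' @export
mad_ratios <- function(arrays, methods = c("ng-mle", "nexp-mle", "nexp-rma",
                                           "nexp-np", "subtract")) {
  stopifnot(inherits(arrays, "sim_arrays"))
  methods <- union("oracle", methods)
  tp <- true_params(arrays)
  acc <- lapply(methods, function(m) c(raw = 0, log = 0, nlog = 0))
  names(acc) <- methods
  fits <- list()
  n_arr <- nrow(arrays)
  for (l in seq_len(n_arr)) {
    tbl <- arrays$data[[l]]
    d <- as_array_data(tbl)
    s_true <- tbl$signal[tbl$probe_type == "regular"]
    keep_log <- s_true >= 1
    fit_cache <- list()
    for (m in methods) {
      fit <- NULL
      if (m == "ng-mle") {
        fit <- fit_cache$ng %||% fit_normgamma(d)
        fit_cache$ng <- fit
      } else if (grepl("^nexp-", m)) {
        key <- m
        fit <- fit_cache[[key]] %||% fit_normexp(d, sub("nexp-", "", m))
        fit_cache[[key]] <- fit
      }
      s_hat <- correct_with_method(d, m, tp, fit = fit)
      acc[[m]]["raw"] <- acc[[m]]["raw"] + mean(abs(s_hat - s_true))
      ok <- keep_log & s_hat > 0
      acc[[m]]["log"] <- acc[[m]]["log"] +
        mean(abs(base::log(s_hat[ok]) - base::log(s_true[ok])))
      acc[[m]]["nlog"] <- acc[[m]]["nlog"] + 1
    }
    fits[[l]] <- fit_cache
  }
  mad_raw <- vapply(acc, function(a) a[["raw"]] / n_arr, 1)
  mad_log <- vapply(acc, function(a) a[["log"]] / a[["nlog"]], 1)
  # R(oracle) = 1 by definition, also when the oracle MAD is exactly 0
  # (noise-free designs)
  r_raw <- ifelse(mad_raw == mad_raw[["oracle"]], 1,
                  mad_raw / mad_raw[["oracle"]])
  r_log <- ifelse(mad_log == mad_log[["oracle"]], 1,
                  mad_log / mad_log[["oracle"]])
  out <- tibble(
    method = methods,
    mad_raw = unname(mad_raw),
    mad_log = unname(mad_log),
    r_raw = unname(r_raw),
    r_log = unname(r_log)
  )
  attr(out, "fits") <- fits
  out
}

#' Absolute-deviation profile of a correction method
#'
#' On a replicate design (one signal vector shared by all arrays), the
#' per-probe mean absolute deviation `AD(S_j) = mean_l |S_hat(X_jl) - S_jl|`
#' (or its log-scale analogue), returned against the log signal together
#' with an equal-count binned summary. Shows where along the intensity range
#' a correction loses accuracy — typically as the signal weakens.
#'
#' @param arrays A replicate-mode `"sim_arrays"`.
#' @param method A method label accepted by [mad_ratios()].
#' @param scale `"raw"` or `"log"`.
#' @param bins Number of equal-count signal bins in the summary.
#' @return An object of class `"ad_profile"`: list of `per_probe` and
#'   `binned` tibbles.
#' @export
ad_profile <- function(arrays, method = "ng-mle", scale = c("raw", "log"),
                       bins = 25L) {
  stopifnot(inherits(arrays, "sim_arrays"))
  scale <- match.arg(scale)
  design <- attr(arrays, "design")
  if (!isTRUE(design$replicate_signal)) {
    abort("ad_profile requires a replicate design (shared signal).",
          class = "gammabg_validation_error")
  }
  tp <- true_params(arrays)
  s_true <- arrays$data[[1]]$signal[arrays$data[[1]]$probe_type == "regular"]
  dev <- matrix(0, nrow = length(s_true), ncol = nrow(arrays))
  for (l in seq_len(nrow(arrays))) {
    d <- as_array_data(arrays$data[[l]])
    s_hat <- correct_with_method(d, method, tp)
    dev[, l] <- if (scale == "raw") {
      abs(s_hat - s_true)
    } else {
      ifelse(s_true >= 1 & s_hat > 0,
             abs(base::log(s_hat) - base::log(s_true)), NA_real_)
    }
  }
  per_probe <- tibble(
    signal = s_true,
    log_signal = base::log(pmax(s_true, .Machine$double.xmin)),
    ad = rowMeans(dev)
  )
  pp <- per_probe[complete.cases(per_probe), ]
  pp <- pp[order(pp$signal), ]
  bin <- ceiling(seq_along(pp$signal) / (nrow(pp) / bins))
  binned <- pp |>
    mutate(bin = bin) |>
    group_by(.data$bin) |>
    summarise(log_signal = mean(.data$log_signal), ad = mean(.data$ad),
              .groups = "drop")
  structure(list(per_probe = per_probe, binned = binned,
                 method = method, scale = scale),
            class = "ad_profile")
}

#' @export
print.ad_profile <- function(x, ...) {
  cat(sprintf("<ad_profile: %s, %s scale, %d probes>\n",
              x$method, x$scale, nrow(x$per_probe)))
  print(x$binned)
  invisible(x)
}

#' Operating characteristics of corrected replicates
#'
#' Bias and precision profile of a preprocessing pipeline evaluated on
#' replicate measurements with known reference values (true simulated signal,
#' or spike-in concentration): per reference bin, the mean log2 corrected
#' intensity (bias/compression) and the SD of log2 intensities across
#' replicates (precision); the innate offset — the mean corrected intensity
#' on zero-reference probes; and the slope of mean log2 intensity on log2
#' reference over the unsaturated range (the top two bins are excluded, where
#' scanner saturation bends the response).
#'
#' @param corrected Numeric matrix, probes x replicate arrays, of corrected
#'   (optionally normalized) intensities on the raw scale.
#' @param reference Per-probe reference values (0 allowed).
#' @param bins Number of equal-count bins of positive log-reference.
#' @return An object of class `"op_chars"`: `curves` tibble
#'   (`bin`, `log2_ref`, `mean_log2`, `sd_log2`), `innate_offset`, `slope`,
#'   `mean_sd`.
#' @export
operating_chars <- function(corrected, reference, bins = 25L) {
  corrected <- as.matrix(corrected)
  if (ncol(corrected) < 2L) {
    abort("at least 2 replicate arrays are required for an SD.",
          class = "gammabg_validation_error")
  }
  if (nrow(corrected) != length(reference)) {
    abort("`reference` must align with the rows of `corrected`.",
          class = "gammabg_validation_error")
  }
  innate <- if (any(reference == 0)) {
    mean(corrected[reference == 0, , drop = FALSE])
  } else {
    NA_real_
  }
  pos <- reference > 0
  lref <- log2(reference[pos])
  lint <- log2(pmax(corrected[pos, , drop = FALSE], .Machine$double.xmin))
  ord <- order(lref)
  bin <- ceiling(seq_along(lref) / (length(lref) / bins))[order(ord)]
  curves <- tibble(
    bin = bin, log2_ref = lref,
    mean_log2 = rowMeans(lint),
    sd_log2 = apply(lint, 1, sd)
  ) |>
    group_by(.data$bin) |>
    summarise(log2_ref = mean(.data$log2_ref),
              mean_log2 = mean(.data$mean_log2),
              sd_log2 = mean(.data$sd_log2), .groups = "drop")
  unsat <- curves$bin <= max(curves$bin) - 2L
  slope <- unname(coef(lm(mean_log2 ~ log2_ref, data = curves[unsat, ]))[2])
  structure(list(curves = curves, innate_offset = innate, slope = slope,
                 mean_sd = mean(curves$sd_log2)),
            class = "op_chars")
}

#' @export
print.op_chars <- function(x, ...) {
  cat(sprintf("<op_chars: innate offset %.3g, mean SD %.3g, slope %.3g>\n",
              x$innate_offset, x$mean_sd, x$slope))
  invisible(x)
}

#' @method tidy op_chars
#' @export
tidy.op_chars <- function(x, ...) x$curves

#' @method glance op_chars
#' @export
glance.op_chars <- function(x, ...) {
  tibble(innate_offset = x$innate_offset, mean_sd = x$mean_sd, slope = x$slope)
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney
#' statistic (ties get mid-ranks): the probability that a random positive
#' outranks a random negative. Invariant under any strictly increasing
#' transform of the scores — adding an offset before a log transform cannot
#' change it.
#'
#' @param scores Numeric scores (larger = more positive).
#' @param labels Binary labels (0/1 or logical); both classes must occur.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1))
#' @export
auc_rank <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) {
    abort("`scores` and `labels` must have the same length.",
          class = "gammabg_validation_error")
  }
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("both classes must be present.", class = "gammabg_validation_error")
  }
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Per-probe Spearman correlation against a design gradient
#'
#' For each probe (row), the Spearman correlation between its intensities
#' across arrays and a vector of design proportions/concentrations — a
#' scale-free test statistic for monotone dose response, unaffected by any
#' increasing transformation of the intensities.
#'
#' @param intensities Numeric matrix, probes x arrays.
#' @param proportions Numeric vector, one value per array.
#' @return Numeric vector of correlations, one per probe.
#' @export
spearman_scores <- function(intensities, proportions) {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(proportions)) {
    abort("`proportions` must have one value per array.",
          class = "gammabg_validation_error")
  }
  apply(intensities, 1, function(row) {
    suppressWarnings(cor(row, proportions, method = "spearman"))
  })
}
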
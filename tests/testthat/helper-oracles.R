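# Independent numerical oracles used across the suite. These deliberately
# avoid the package's FFT/grid code path: everything goes through adaptive
# quadrature (stats::integrate) on the defining integrals.

# Convolution density integral: f(x) = int f_gam(t) f_norm(x - t) dt,
# integrated over the region where the normal factor has mass.
ng_density_quad <- function(x, p) {
  p <- as_normal_gamma_params(p)
  vapply(x, function(xx) {
    lo <- max(0, xx - p$mu - 12 * p$sigma)
    hi <- max(xx - p$mu + 12 * p$sigma,
              qgamma(1 - 1e-13, shape = p$k, scale = p$theta))
    if (hi <= lo) hi <- lo + 12 * p$sigma
    integrate(function(t) dgamma(t, shape = p$k, scale = p$theta) *
                dnorm(xx - t, p$mu, p$sigma),
              lower = lo, upper = hi, rel.tol = 1e-11, abs.tol = 1e-300,
              subdivisions = 1000L)$value
  }, numeric(1))
}

# Conditional expectation E[S | X = x] by direct quadrature of the ratio
# int s f_S(s) f_B(x - s) ds / int f_S(s) f_B(x - s) ds.
cond_exp_quad <- function(x, p) {
  p <- as_normal_gamma_params(p)
  vapply(x, function(xx) {
    lo <- max(0, xx - p$mu - 12 * p$sigma)
    hi <- max(xx - p$mu + 12 * p$sigma,
              qgamma(1 - 1e-13, shape = p$k, scale = p$theta))
    if (hi <= lo) hi <- lo + 12 * p$sigma
    num <- integrate(function(s) s * dgamma(s, shape = p$k, scale = p$theta) *
                       dnorm(xx - s, p$mu, p$sigma),
                     lower = lo, upper = hi, rel.tol = 1e-11,
                     abs.tol = 1e-300, subdivisions = 1000L)$value
    den <- integrate(function(s) dgamma(s, shape = p$k, scale = p$theta) *
                       dnorm(xx - s, p$mu, p$sigma),
                     lower = lo, upper = hi, rel.tol = 1e-11,
                     abs.tol = 1e-300, subdivisions = 1000L)$value
    num / den
  }, numeric(1))
}

# Exhaustive search over all histogram partitions built from a small
# candidate edge set, with the same likelihood and penalty as the DP.
exhaustive_partition <- function(edges, ccnt, n, max_bins = length(edges) - 1L) {
  K <- length(edges) - 1L
  ll_bin <- function(i, j) {
    cnt <- ccnt[j] - ccnt[i]
    w <- edges[j] - edges[i]
    if (cnt > 0) cnt * (log(cnt) - log(n * w)) else 0
  }
  interior <- seq(2L, K)  # candidate interior edge indices
  best_crit <- -Inf
  best_sel <- NULL
  for (D in seq_len(min(max_bins, K))) {
    pen <- (D - 1) + lchoose(n - 1, D - 1)
    subsets <- if (D == 1) list(integer()) else
      utils::combn(interior, D - 1L, simplify = FALSE)
    for (s in subsets) {
      sel <- c(1L, s, K + 1L)
      ll <- sum(mapply(ll_bin, head(sel, -1), tail(sel, -1)))
      if (ll - pen > best_crit + 1e-12) {
        best_crit <- ll - pen
        best_sel <- sel
      }
    }
  }
  list(criterion = best_crit, sel = best_sel)
}

# Brute-force AUC over all positive/negative pairs (midpoint for ties).
auc_brute <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg) {
    tot <- tot + (a > b) + 0.5 * (a == b)
  }
  tot / (length(pos) * length(neg))
}

# Small synthetic array drawn straight from the model definition.
draw_array <- function(p, n_reg, n_neg, seed) {
  p <- as_normal_gamma_params(p)
  set.seed(seed)
  s <- rgamma(n_reg, shape = p$k, scale = p$theta)
  array_data(regular = s + rnorm(n_reg, p$mu, p$sigma),
             negative = rnorm(n_neg, p$mu, p$sigma))
}
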
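test_that("normexp correction matches its closed form and quadrature", {
  p <- normexp_params(mu = 100, sigma = 10, alpha = 200)
  # at the centering point xbar = 0 the Mills term is phi(0)/Phi(0)
  x0 <- p$mu + p$sigma^2 / p$alpha
  expect_equal(bg_correct_normexp(x0, p), p$sigma * dnorm(0) / 0.5,
               tolerance = 1e-12)
  # conditional-expectation quadrature at a bulk point
  expect_equal(bg_correct_normexp(500, p), cond_exp_quad(500, p),
               tolerance = 1e-8)
  # far right: the Mills term vanishes and S_hat -> x - mu - sigma^2/alpha
  x_big <- p$mu + 60 * p$alpha
  expect_equal(bg_correct_normexp(x_big, p) - (x_big - p$mu - p$sigma^2 / p$alpha),
               0, tolerance = 1e-8)
})

test_that("normexp correction is strictly positive and stable far left", {
  p <- normexp_params(mu = 100, sigma = 10, alpha = 200)
  x <- c(-1e6, -1e4, -500, 0, 100, 1e5)
  s <- bg_correct_normexp(x, p)
  expect_true(all(s > 0))
  expect_true(all(is.finite(s)))
  # deep-tail series branch agrees with the log-space evaluation where the
  # latter is still exact
  xb <- -37.1 * p$sigma + p$mu + p$sigma^2 / p$alpha
  s_series <- bg_correct_normexp(xb, p)
  zb <- (xb - p$mu - p$sigma^2 / p$alpha) / p$sigma
  s_exact <- p$sigma * (zb + exp(dnorm(zb, log = TRUE) - pnorm(zb, log.p = TRUE)))
  expect_equal(s_series, s_exact, tolerance = 1e-6)
})

test_that("normal-gamma correction reduces to normexp at k = 1", {
  pn <- normal_gamma_params(mu = 100, sigma = 30, k = 1, theta = 250)
  pe <- normexp_params(mu = 100, sigma = 30, alpha = 250)
  x <- seq(100 - 3 * 30, 100 + 20 * 250, length.out = 200)
  s_ng <- bg_correct_normgamma(x, pn)
  s_ne <- bg_correct_normexp(x, pe)
  expect_lt(max(abs(s_ng - s_ne) / s_ne), 1e-4)
})

test_that("normal-gamma correction equals the conditional expectation", {
  p <- normal_gamma_params(mu = 0, sigma = 1, k = 2, theta = 50)
  expect_equal(bg_correct_normgamma(150, p), cond_exp_quad(150, p),
               tolerance = 1e-6)
})

test_that("corrected intensities average to the signal mean", {
  # law of total expectation: E[E[S|X]] = E[S] = k theta
  p <- normal_gamma_params(mu = 900, sigma = 140, k = 0.64, theta = 500)
  set.seed(71)
  n <- 1e5
  x <- rgamma(n, p$k, scale = p$theta) + rnorm(n, p$mu, p$sigma)
  s_hat <- bg_correct_normgamma(x, p)
  se <- sd(s_hat) / sqrt(n)
  expect_lt(abs(mean(s_hat) - p$k * p$theta), 3 * se)
})

test_that("every correction method is monotone in the observed intensity", {
  p <- normal_gamma_params(mu = 100, sigma = 30, k = 0.7, theta = 300)
  pe <- normexp_params(mu = 100, sigma = 30, alpha = 300)
  x <- seq(100 - 6 * 30, 100 + qgamma(1 - 1e-6, 0.7, scale = 300),
           length.out = 4000)
  expect_true(all(diff(bg_correct_normgamma(x, p)) >= 0))
  expect_true(all(diff(bg_correct_normexp(x, pe)) >= 0))
  expect_true(all(diff(bg_correct_subtract(x, c(80, 100, 120))) >= 0))
})

test_that("background subtraction clamps at zero", {
  expect_equal(bg_correct_subtract(c(5, 10), c(4, 6, 8)), c(0, 4))
  expect_equal(bg_correct_subtract(c(1, 2, 3), c(10, 20, 30)), c(0, 0, 0))
  x <- c(0, 2.5, 7)
  expect_equal(bg_correct_subtract(x, c(0, 0, 0)), x)
  expect_error(bg_correct_subtract(1, numeric()), class = "gammabg_data_error")
})

test_that("detection p-values count exceeding negatives", {
  expect_equal(detection_pvalues(5, c(1, 2, 9, 10)), 0.5)
  expect_equal(detection_pvalues(11, c(1, 2, 9, 10)), 0)
  expect_equal(detection_pvalues(0, c(1, 2, 9, 10)), 1)
  # strict inequality at ties
  expect_equal(detection_pvalues(c(2, 9), c(1, 2, 9, 10)), c(0.5, 0.25))
})

test_that("inferred negatives reproduce the negative-probe distribution", {
  set.seed(81)
  reg <- rgamma(20000, 0.64, scale = 500) + rnorm(20000, 900, 140)
  neg <- rnorm(1000, 900, 140)
  pv <- detection_pvalues(reg, neg)
  neg_hat <- infer_negatives(pv, reg, n_neg = 1000)
  expect_length(neg_hat, 1000)
  # quantiles of the reconstruction track the true negatives
  qs <- seq(0.05, 0.95, by = 0.05)
  expect_lt(max(abs(quantile(neg_hat, qs) - quantile(neg, qs))), 30)
  # round trip: p-values recomputed from inferred negatives are stable
  pv2 <- detection_pvalues(reg, neg_hat)
  expect_lt(mean(abs(pv2 - pv)), 0.005)
  neg_hat2 <- infer_negatives(pv2, reg, n_neg = 1000)
  expect_lt(max(abs(neg_hat2 - neg_hat)), 15)
})

test_that("degenerate detection p-values clamp to the regular range", {
  reg <- c(10, 20, 30, 40)
  expect_true(all(infer_negatives(rep(0, 4), reg, 5) <= 10))
  expect_error(infer_negatives(c(0, 0.5, 1.2, 0), reg, 5),
               class = "gammabg_validation_error")
  expect_error(infer_negatives(rep(0, 4), reg, 1),
               class = "gammabg_validation_error")
})

test_that("two inferred negatives bracket tiny probe sets consistently", {
  # every ordering of two unseen negatives around three regulars
  for (neg in list(c(0, 5), c(2.5, 5), c(0, 2.5), c(2.5, 3.5), c(5, 6))) {
    reg <- c(1, 3, 4)
    pv <- detection_pvalues(reg, neg)
    neg_hat <- infer_negatives(pv, reg, n_neg = 2)
    pv_hat <- detection_pvalues(reg, neg_hat)
    # the counting definition is preserved through the round trip
    expect_lte(mean(abs(pv_hat - pv)), 0.5)
    expect_true(all(neg_hat >= min(reg) & neg_hat <= max(reg)))
  }
})

test_that("quantile normalization equalizes array distributions", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))
  # identical arrays are a fixed point
  m2 <- cbind(c(3, 1, 7), c(3, 1, 7))
  expect_equal(quantile_normalize(m2), m2, ignore_attr = TRUE)
  # column means agree after normalization
  set.seed(91)
  m3 <- matrix(rnorm(300, c(0, 5, 10)), ncol = 3)
  cm <- colMeans(quantile_normalize(m3))
  expect_lt(diff(range(cm)), 1e-12)
  expect_error(quantile_normalize(m[, 1, drop = FALSE]),
               class = "gammabg_validation_error")
})

test_that("offset-log transform behaves as log2 with a shift", {
  expect_equal(offset_log(c(1, 2, 4)), c(0, 1, 2))
  x <- c(3, 10, 40)
  expect_true(all(diff(offset_log(x, 50)) > 0))
  # large offsets compress pairwise differences towards zero
  d_small <- diff(offset_log(x, 10))
  d_large <- diff(offset_log(x, 1e6))
  expect_true(all(d_large < d_small))
  expect_error(offset_log(c(-2, 1), 1), class = "gammabg_validation_error")
})

test_that("the tidy bg_correct front end appends a signal column", {
  arrays <- simulate_arrays(sim_design(n_reg = 300, n_neg = 60, n_arrays = 1,
                                       seed = 17))
  tbl <- arrays$data[[1]]
  out <- bg_correct(tbl, method = "subtract")
  expect_named(out, c(names(tbl), "signal_hat"))
  expect_true(all(out$signal_hat >= 0))
  p <- true_params(arrays)
  out2 <- bg_correct(tbl, method = "normal-gamma", params = p)
  expect_true(all(out2$signal_hat > 0))
  expect_identical(nrow(out2), nrow(tbl))
})
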
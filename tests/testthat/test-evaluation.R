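test_that("the penalty suppresses spurious breaks on uniform data", {
  few_bins <- vapply(1:10, function(s) {
    set.seed(200 + s)
    length(irregular_histogram(runif(1e4))$heights)
  }, numeric(1))
  expect_gte(mean(few_bins <= 3), 0.9)
})

test_that("a density jump is located within 0.02", {
  set.seed(33)
  n <- 1e4
  x <- ifelse(runif(n) < 0.25, runif(n, 0, 0.5), runif(n, 0.5, 1))
  h <- irregular_histogram(x)
  expect_lt(min(abs(h$breaks - 0.5)), 0.02)
})

test_that("irregular histograms integrate to one exactly", {
  set.seed(44)
  for (x in list(rexp(500), rnorm(5000), rgamma(1000, 0.5))) {
    h <- irregular_histogram(x)
    expect_equal(sum(diff(h$breaks) * h$heights), 1, tolerance = 1e-12)
  }
  expect_warning(h_small <- irregular_histogram(rnorm(20)), "fewer than 50")
  expect_s3_class(h_small, "irregular_histogram")
})

test_that("the DP equals exhaustive partition search on small candidate sets", {
  for (s in 1:5) {
    set.seed(300 + s)
    x <- c(rnorm(60, 0, 0.3), rexp(60))
    # small candidate grid so exhaustive enumeration is feasible
    edges <- unique(quantile(x, probs = seq(0, 1, length.out = 12),
                             names = FALSE))
    idx <- findInterval(x, edges, rightmost.closed = TRUE, all.inside = TRUE)
    cnt <- tabulate(idx, nbins = length(edges) - 1L)
    ccnt <- c(0, cumsum(cnt))
    h <- irregular_histogram(x, grid_size = 12)
    crit_dp <- sum(h$counts[h$counts > 0] *
                     log(h$counts[h$counts > 0] /
                           (h$n * diff(h$breaks)[h$counts > 0]))) -
      ((length(h$heights) - 1) + lchoose(h$n - 1, length(h$heights) - 1))
    ex <- exhaustive_partition(edges, ccnt, length(x))
    expect_equal(crit_dp, ex$criterion, tolerance = 1e-10)
  }
})

test_that("the L1 fit distance obeys its identities", {
  set.seed(55)
  h <- irregular_histogram(rnorm(2000, 50, 10))
  # a density identical to the histogram is at distance ~0
  expect_lt(l1_fit(function(x) histogram_density(h, x), h), 1e-6)
  # disjoint supports give the total-variation bound 2
  far <- function(x) dnorm(x, 1e5, 1)
  expect_equal(l1_fit(far, h), 2, tolerance = 1e-6)
  # histogram of a normal converges on the normal; the penalized-MLE
  # histogram targets KL rather than L1, so its L1 risk at this n sits
  # around 0.06
  set.seed(56)
  h_big <- irregular_histogram(rnorm(1e5, 50, 10))
  expect_lte(l1_fit(function(x) dnorm(x, 50, 10), h_big), 0.075)
})

test_that("parameter errors are plain relative-L1 arithmetic", {
  p <- normal_gamma_params(10, 1, 1, 1)
  mk_fit <- function(mu) {
    structure(list(params = normal_gamma_params(mu, 1, 1, 1)),
              class = "bg_fit")
  }
  pe <- param_error(p, list(mk_fit(9), mk_fit(11)))
  expect_equal(pe$error[pe$term == "mu"], 0.1)
  expect_equal(pe$error[pe$term == "sigma"], 0)
  exact <- param_error(p, list(mk_fit(10)))
  expect_true(all(exact$error == 0))
})

test_that("MAD is the plain mean absolute deviation and R(oracle) is 1", {
  # two-probe toy with hand-computable deviations
  p <- list(mu = 0, sigma = 0, k = 1, theta = 100)
  arrays <- simulate_arrays(sim_design(params = p, n_reg = 2, n_neg = 2,
                                       n_arrays = 1, seed = 1))
  tbl <- arrays$data[[1]]
  s_true <- tbl$signal[tbl$probe_type == "regular"]
  rep <- mad_ratios(arrays, methods = "subtract")
  expect_equal(rep$r_raw[rep$method == "oracle"], 1)
  expect_equal(rep$r_log[rep$method == "oracle"], 1)
  med <- median(tbl$intensity[tbl$probe_type == "negative"])
  s_sub <- pmax(tbl$intensity[tbl$probe_type == "regular"] - med, 0)
  expect_equal(rep$mad_raw[rep$method == "subtract"],
               mean(abs(s_sub - s_true)))
})

test_that("AD profiles vanish for a perfect corrector and grow at weak signal", {
  p <- list(mu = 0, sigma = 0, k = 0.64, theta = 500)
  arrays <- simulate_arrays(sim_design(params = p, n_reg = 3000, n_neg = 100,
                                       n_arrays = 2, replicate_signal = TRUE,
                                       seed = 3))
  # with zero noise the oracle conditional expectation is the identity
  prof <- ad_profile(arrays, method = "oracle", scale = "raw")
  expect_lt(max(prof$per_probe$ad) / 500, 1e-6)
  # noisy replicates: model-based corrections degrade as the signal weakens
  arrays2 <- simulate_arrays(sim_design(params = preset_params("A"),
                                        n_reg = 4000, n_neg = 400,
                                        n_arrays = 3, replicate_signal = TRUE,
                                        seed = 4))
  for (m in c("oracle", "nexp-np")) {
    b <- ad_profile(arrays2, method = m, scale = "log")$binned
    lo <- mean(b$ad[b$bin <= 5])
    hi <- mean(b$ad[b$bin >= max(b$bin) - 4])
    expect_gt(lo, hi)
  }
  expect_error(ad_profile(simulate_arrays(sim_design(n_reg = 100, n_neg = 20,
                                                     n_arrays = 2, seed = 1)),
                          method = "oracle"),
               class = "gammabg_validation_error")
})

test_that("operating characteristics report SD, innate offset and slope", {
  ref <- c(0, 0, 2^(seq(1, 10, length.out = 60)))
  m <- cbind(ref, ref, ref)
  oc <- operating_chars(m, ref, bins = 10)
  expect_equal(max(oc$curves$sd_log2), 0)
  expect_equal(oc$slope, 1, tolerance = 1e-9)
  expect_equal(oc$innate_offset, 0)
  expect_error(operating_chars(m[, 1, drop = FALSE], ref),
               class = "gammabg_validation_error")
})

test_that("rank AUC equals the brute-force pairwise statistic", {
  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc_rank(c(1, 2, 3, 4), c(0, 1, 0, 1)), 0.75)
  set.seed(77)
  for (i in 1:25) {
    n <- sample(2:8, 1)
    scores <- sample(1:5, n, replace = TRUE)   # ties likely
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(auc_rank(scores, labels), auc_brute(scores, labels))
  }
  expect_error(auc_rank(1:4, c(1, 1, 1, 1)),
               class = "gammabg_validation_error")
})

test_that("rank statistics are invariant under increasing transforms", {
  set.seed(88)
  scores <- rnorm(500)
  labels <- rbinom(500, 1, 0.4)
  a0 <- auc_rank(scores, labels)
  expect_identical(auc_rank(exp(scores), labels), a0)
  expect_identical(auc_rank(log2(exp(scores) + 50), labels), a0)
  m <- matrix(rnorm(40), nrow = 4)
  props <- c(0, 0.25, 0.5, 0.75, 1, 1, 0.5, 0.25, 0, 0.75)
  expect_equal(spearman_scores(m, props), spearman_scores(2^m + 7, props))
})

test_that("null-score AUC concentrates at one half", {
  set.seed(99)
  n <- 1e4
  a <- auc_rank(rnorm(n), rbinom(n, 1, 0.5))
  expect_lt(abs(a - 0.5), 3 / sqrt(n) * 2)
})
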
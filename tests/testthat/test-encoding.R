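test_that("sparse random projection is linear, sparse, and deterministic", {
  z <- matrix(0, 20, 500)
  expect_equal(srp_project(z, target_dim = 10, seed = 1),
               matrix(0, 20, 10), ignore_attr = TRUE)
  x <- matrix(rnorm(20 * 500), 20)
  p1 <- srp_project(x, target_dim = 10, seed = 1)
  p2 <- srp_project(x, target_dim = 10, seed = 1)
  expect_identical(p1, p2)
  expect_false(identical(p1, srp_project(x, target_dim = 10, seed = 2)))
  expect_message(out <- srp_project(x, target_dim = 600, seed = 1),
                 "passing through")
  expect_identical(out, x)
})

test_that("projection approximately preserves pairwise squared distances", {
  set.seed(2)
  n <- 100; d <- 1e4
  x <- matrix(rnorm(n * d), n)
  eps <- 0.2
  k <- ceiling(4 * log(n) / (eps^2 / 2 - eps^3 / 3))
  y <- srp_project(x, target_dim = k, seed = 3)
  pick <- t(combn(sample(n, 40), 2))
  ratio <- vapply(seq_len(nrow(pick)), function(i) {
    a <- pick[i, 1]; b <- pick[i, 2]
    sum((y[a, ] - y[b, ])^2) / sum((x[a, ] - x[b, ])^2)
  }, numeric(1))
  expect_gte(mean(ratio >= 1 - eps & ratio <= 1 + eps), 0.95)
})

test_that("closed-form LOO ridge equals explicit leave-one-out refits", {
  set.seed(4)
  for (alpha in c(0.5, 10, 1000)) {
    x <- matrix(rnorm(30 * 50), 30)
    y <- rnorm(30)
    closed <- loo_ridge_fixed(x, y, alpha)
    explicit <- loo_ridge_explicit(x, y, alpha)
    expect_equal(closed$predictions, explicit, tolerance = 1e-8)
  }
})

test_that("LOO ridge decoding recovers a realizable linear target", {
  set.seed(5)
  x <- matrix(rnorm(60 * 8), 60)
  beta <- rnorm(8)
  y <- drop(x %*% beta)
  res <- loo_ridge_decode(x, y, alpha_grid = 10^seq(-3, 2, by = 0.5))
  expect_gt(res$r, 0.999)
  expect_error(loo_ridge_decode(x, rep(1, 60)), "constant")
  expect_error(loo_ridge_decode(x[1:5, ], y[1:5]), "at least 10")
})

test_that("decoding pure noise scores near zero", {
  set.seed(6)
  rs <- vapply(1:25, function(i) {
    x <- matrix(rnorm(100 * 20), 100)
    loo_ridge_decode(x, rnorm(100))$r
  }, numeric(1))
  expect_lt(mean(abs(rs)), 2 / sqrt(100))
})

test_that("decoding scores are invariant to y rescaling and X rotation", {
  set.seed(7)
  x <- matrix(rnorm(50 * 10), 50)
  y <- drop(x %*% rnorm(10)) + rnorm(50)
  base <- loo_ridge_decode(x, y)$r
  expect_equal(loo_ridge_decode(x, 5 * y - 2)$r, base, tolerance = 1e-10)
  q <- qr.Q(qr(matrix(rnorm(100), 10)))
  expect_equal(loo_ridge_decode(x %*% q, y)$r, base, tolerance = 0.05)
})

test_that("depth binning covers [0,1] with a closed last bin", {
  one <- data.frame(model = "m", group = "trained", depth = 1, r = 0.5)
  b <- bin_scores(one)
  expect_equal(b$bin[!is.na(b$mean_r)], 10)
  ten <- data.frame(model = "m", group = "trained",
                    depth = seq(0.05, 0.95, by = 0.1), r = 1:10)
  b10 <- bin_scores(ten)
  expect_equal(b10$mean_r, as.numeric(1:10))
  # 20 equally spaced layers: two per bin, hand-assigned
  d20 <- (0:19) / 19
  twenty <- data.frame(model = "m", group = "trained", depth = d20, r = d20)
  b20 <- bin_scores(twenty)
  hand <- tapply(d20, ifelse(d20 >= 1, 10, floor(d20 * 10) + 1), mean)
  expect_equal(b20$mean_r, as.numeric(hand))
  expect_true(all(table(ifelse(d20 >= 1, 10, floor(d20 * 10) + 1)) == 2))
})

test_that("permutation test is null on identical groups and floored when separated", {
  m <- matrix(rnorm(7 * 3), 7)
  same <- permutation_bin_test(m, m, n_perm = 2000, seed = 1)
  expect_true(all(same$diff == 0))
  expect_true(all(same$p_value > 0.5))

  sep_t <- matrix(10 + rnorm(7), 7, 1)
  sep_r <- matrix(rnorm(7), 7, 1)
  res <- permutation_bin_test(sep_t, sep_r, n_perm = 4000, seed = 2)
  # attainable floor: only label sets dominated by the observed split exceed
  expect_lt(res$p_value, 5 / 4001 + 0.003)
  expect_error(permutation_bin_test(sep_t[1, , drop = FALSE], sep_r), "2 models")
  expect_warning(permutation_bin_test(sep_t, sep_r, n_perm = 500, seed = 3),
                 "unstable")
})

test_that("BH correction equals brute-force step-up enumeration", {
  expect_equal(fdr_bh(c(0.01, 0.02, 0.03, 0.04, 0.2))$q,
               c(0.05, 0.05, 0.05, 0.05, 0.2))
  expect_equal(fdr_bh(0.73)$q, 0.73)
  all_one <- fdr_bh(rep(1, 6))
  expect_true(all(all_one$q == 1) && !any(all_one$reject))
  set.seed(8)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    expect_equal(fdr_bh(p)$q, bh_bruteforce(p), tolerance = 1e-12)
  }
})

test_that("bootstrap CI of paired differences behaves at the edges", {
  flat <- bootstrap_diff_ci(rep(0.3, 7), n_boot = 200, seed = 1)
  expect_equal(flat$mean, 0.3)
  expect_equal(flat$ci, c(0.3, 0.3))
  set.seed(9)
  d <- rnorm(7)
  ci <- bootstrap_diff_ci(d, n_boot = 500, seed = 2)
  expect_gte(ci$ci[1], min(d)); expect_lte(ci$ci[2], max(d))
  expect_error(bootstrap_diff_ci(0.5), "at least 2")
})

test_that("null paired differences are covered by the bootstrap CI ~95% of the time", {
  set.seed(10)
  covered <- vapply(1:300, function(i) {
    ci <- bootstrap_diff_ci(rnorm(15), n_boot = 300, seed = i)$ci
    ci[1] <= 0 && 0 <= ci[2]
  }, logical(1))
  bounds <- binom_bounds(0.95, 300)
  expect_gte(mean(covered), bounds[1] - 0.02)
})

test_that("JZS Bayes factors match a fine-grid quadrature oracle", {
  for (tt in c(0, 0.8, 2.5, 5)) {
    for (n in c(5, 7, 20)) {
      expect_equal(jzs_bf_paired(t = tt, n = n),
                   jzs_bf_grid(tt, n), tolerance = 1e-6)
    }
  }
  expect_lt(jzs_bf_paired(t = 0, n = 7), 1)      # null favored at t = 0
  bfs <- vapply(c(0, 1, 2, 4, 8), function(tt)
    jzs_bf_paired(t = tt, n = 7), numeric(1))
  expect_true(all(diff(bfs) > 0))                # monotone in |t|
  expect_gt(jzs_bf_paired(t = 30, n = 7), 1e4)
  expect_error(jzs_bf_paired(rep(0.2, 5)), "zero-variance")
  d <- c(0.1, 0.3, 0.2, 0.5, 0.4, 0.25, 0.35)
  tstat <- mean(d) / (sd(d) / sqrt(7))
  expect_equal(jzs_bf_paired(d), jzs_bf_paired(t = tstat, n = 7))
})

test_that("bin comparison integrates permutation, FDR, bootstrap, and BF", {
  set.seed(12)
  fs <- feature_spec(n_layers = 10, dims_per_layer = 15,
                     snr_by_depth = "sigmoid", snr_max = 2,
                     n_trained_models = 4, n_random_models = 4, seed = 13)
  y <- rnorm(50)
  st <- gen_feature_store(y, fs)
  sc <- decode_feature_store(st, y)
  binned <- bin_scores(sc)
  cmp <- compare_bins(binned, n_perm = 2000, n_boot = 300, seed = 14)
  expect_equal(nrow(cmp), 10)
  expect_true(all(cmp$q_value >= cmp$p_value))
  expect_true(all(cmp$ci_lo <= cmp$boot_mean & cmp$boot_mean <= cmp$ci_hi))
  # deepest bin carries planted signal: significant and BF > 3
  expect_true(cmp$significant[10])
  expect_gt(cmp$bf10[10], 3)
  # permutation p and Bayes factor agree directionally
  expect_gt(median(cmp$bf10[cmp$q_value < 0.05]), 3)
})
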
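make_2x2 <- function(n_cell = 25) {
  expand.grid(duration = c("50", "500"), condition = c("real", "generated"),
              rep = seq_len(n_cell), stringsAsFactors = FALSE)
}

test_that("design matrices follow the documented sum-contrast conventions", {
  df <- make_2x2()
  dm <- build_design(df, factors = c("duration", "condition"),
                     interactions = list(c("duration", "condition")))
  # first sorted level is +1: 50 -> +1, 500 -> -1; generated -> +1
  expect_equal(unique(dm$x[df$duration == "50", "duration"]), 1)
  expect_equal(unique(dm$x[df$duration == "500", "duration"]), -1)
  expect_equal(unique(dm$x[df$condition == "generated", "condition"]), 1)
  expect_true(all(dm$x[, "duration:condition"] %in% c(-1, 1)))
  # balanced 2x2: all columns orthogonal (diagonal Gram matrix)
  g <- crossprod(dm$x)
  expect_equal(g, diag(diag(g)), ignore_attr = TRUE, tolerance = 1e-12)
  expect_error(build_design(data.frame(f = c("a", "b", "c")), factors = "f"),
               "levels")
})

test_that("continuous predictors are standardized within the analysis set", {
  df <- data.frame(x = rnorm(40, 10, 3))
  dm <- build_design(df, continuous = "x")
  expect_equal(mean(dm$x[, "x"]), 0, tolerance = 1e-12)
  expect_equal(sd(dm$x[, "x"]), 1, tolerance = 1e-12)
})

test_that("logistic slope on a balanced 2x2 table equals half the log odds ratio", {
  # 40/10 successes at level +1 vs 10/40 at level -1
  df <- data.frame(g = rep(c("a", "b"), each = 50))
  y <- c(rep(1, 40), rep(0, 10), rep(1, 10), rep(0, 40))
  fit <- fit_logistic(build_design(df, factors = "g"), y)
  slope <- fit$coefficients$estimate[fit$coefficients$term == "g"]
  expect_equal(slope, log(16) / 2, tolerance = 1e-8)
})

test_that("IRLS coefficients match an independent Newton optimizer", {
  set.seed(101)
  df <- data.frame(f = sample(c("u", "v"), 200, TRUE), x = rnorm(200))
  dm <- build_design(df, factors = "f", continuous = "x",
                     interactions = list(c("f", "x")))
  eta <- 0.3 - 0.5 * dm$x[, "f"] + 0.8 * dm$x[, "x"]
  y <- rbinom(200, 1, plogis(eta))
  fit <- fit_logistic(dm, y)
  oracle <- newton_logit(dm$x, y)
  expect_equal(fit$coefficients$estimate, unname(oracle), tolerance = 1e-8)
})

test_that("separation and rank deficiency are rejected explicitly", {
  df <- data.frame(x = c(rep(-1, 20), rep(1, 20)))
  dm <- build_design(df, continuous = "x")
  y <- as.numeric(df$x > 0)
  expect_error(fit_logistic(dm, y), "separation")
  df2 <- data.frame(a = rnorm(30))
  dm2 <- build_design(df2, continuous = "a")
  dm2$x <- cbind(dm2$x, a2 = dm2$x[, "a"])  # duplicated column
  expect_error(fit_logistic(dm2, rbinom(30, 1, 0.5)), "rank")
  expect_error(fit_linear(dm2, rnorm(30)), "rank")
})

test_that("null designs produce calibrated Wald z statistics", {
  set.seed(7)
  rejections <- vapply(1:200, function(i) {
    df <- data.frame(x = rnorm(120), f = sample(c("p", "q"), 120, TRUE))
    dm <- build_design(df, factors = "f", continuous = "x")
    y <- rbinom(120, 1, 0.5)
    fit <- fit_logistic(dm, y)
    any(abs(fit$coefficients$statistic[-1]) > 1.96)
  }, logical(1))
  # two independent null tests per replicate: P(any) ~ 1 - 0.95^2
  bounds <- binom_bounds(1 - 0.95^2, 200)
  expect_gte(mean(rejections), bounds[1] - 0.01)
  expect_lte(mean(rejections), bounds[2] + 0.01)
})

test_that("sum-coded linear main effects equal half the cell-mean difference", {
  df <- make_2x2(10)
  dm <- build_design(df, factors = c("duration", "condition"))
  set.seed(3)
  y <- rnorm(nrow(df)) + 2 * (df$duration == "50") - 1 * (df$condition == "real")
  fit <- fit_linear(dm, y)
  cell_diff <- mean(y[df$duration == "50"]) - mean(y[df$duration == "500"])
  est <- fit$coefficients$estimate[fit$coefficients$term == "duration"]
  expect_equal(est, cell_diff / 2, tolerance = 1e-10)
})

test_that("an exact linear response is flagged as degenerate", {
  df <- data.frame(x = rnorm(30))
  dm <- build_design(df, continuous = "x")
  y <- 2 + 3 * dm$x[, "x"]
  fit <- fit_linear(dm, y)
  expect_match(fit$note, "degenerate")
  expect_equal(fit$coefficients$estimate, c(2, 3), tolerance = 1e-8)
})

test_that("permuted responses give uniform linear-model p-values", {
  set.seed(11)
  df <- data.frame(x = rnorm(60))
  dm <- build_design(df, continuous = "x")
  y <- rnorm(60)
  pvals <- vapply(1:400, function(i) {
    fit <- fit_linear(dm, sample(y))
    fit$coefficients$p_value[2]
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("per-level trends obey the sum-coding identities", {
  set.seed(5)
  df <- data.frame(f = rep(c("real", "generated"), each = 100), x = rnorm(200))
  dm <- build_design(df, factors = "f", continuous = "x",
                     interactions = list(c("f", "x")))
  y <- drop(dm$x %*% c(0.2, 0.1, -0.035, 0.115)) + rnorm(200, 0, 0.5)
  fit <- fit_linear(dm, y)
  tr <- linear_trend(fit, "x", "f")
  b <- setNames(fit$coefficients$estimate, fit$coefficients$term)
  # average of the two slopes equals the main effect exactly
  expect_equal(mean(tr$slope), unname(b["x"]), tolerance = 1e-12)
  expect_equal(tr$slope[tr$level == "generated"],
               unname(b["x"] + b["f:x"]), tolerance = 1e-12)
  expect_equal(tr$slope[tr$level == "real"],
               unname(b["x"] - b["f:x"]), tolerance = 1e-12)
  expect_error(linear_trend(fit_linear(build_design(df, factors = "f",
                                                    continuous = "x"), y),
                            "x", "f"), "interaction")
})

test_that("a zero interaction makes both trends equal the main slope", {
  df <- data.frame(f = rep(c("a", "b"), each = 150), x = rnorm(300))
  dm <- build_design(df, factors = "f", continuous = "x",
                     interactions = list(c("f", "x")))
  set.seed(6)
  y <- 0.5 * dm$x[, "x"] + rnorm(300, 0, 0.1)
  tr <- linear_trend(fit_linear(dm, y), "x", "f")
  expect_lt(abs(tr$slope[1] - tr$slope[2]), 0.05)
})

test_that("the chance-floor logistic model recovers planted 5-AFC effects", {
  set.seed(33)
  df <- data.frame(z = rnorm(4000))
  dm <- build_design(df, continuous = "z")
  p <- 0.2 + 0.8 * plogis(0.4 + 0.6 * dm$x[, "z"])
  y <- rbinom(4000, 1, p)
  fit <- fit_logistic(dm, y, guess = 0.2)
  ci <- fit$coefficients[fit$coefficients$term == "z", c("ci_lo", "ci_hi")]
  expect_gt(0.6, ci$ci_lo); expect_lt(0.6, ci$ci_hi)
  # fitting without the floor is biased toward zero
  plain <- fit_logistic(dm, y)
  expect_lt(plain$coefficients$estimate[2],
            fit$coefficients$estimate[2])
})

test_that("probit fits recover evidence-scale effects from SDT observers", {
  imgs <- flat_images(150)
  set.seed(44)
  imgs$z_anchor <- z_transform(rnorm(nrow(imgs)))
  spec <- observer_spec(d_prime_by_duration = c("500" = 1.5),
                        beta_anchor = 0.3,
                        beta_diag_by_condition = c(real = 0, generated = 0),
                        n_participants = 25, seed = 45)
  trials <- simulate_2afc(imgs, spec)
  dm <- build_design(trials, factors = "condition", continuous = "z_anchor")
  fit <- fit_logistic(dm, trials$response, link = "probit")
  est <- fit$coefficients[fit$coefficients$term == "z_anchor", ]
  expect_lt(abs(est$estimate - 0.3), 3 * est$se)
  # condition coefficient approximates -d'/2 under generated=+1 coding
  cond <- fit$coefficients[fit$coefficients$term == "condition", ]
  expect_lt(abs(cond$estimate - (-0.75)), 4 * cond$se + 0.05)
})
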
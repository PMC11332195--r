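# Shared fixtures and independent oracles for the test suite.

# Hand-enumerable toy corpus:
#   kitchen scenes: {sink, table}, {sink, chair}
#   bedroom scenes: {bed, table}, {bed, sink}
# giving diagnosticity(sink, kitchen) = 2/3, (table, kitchen) = 1/2,
# (bed, bedroom) = 1, etc. `anchors` marks which occurrences are anchors.
toy_corpus <- function(anchors = character(0)) {
  scenes <- data.frame(
    scene_id = c("k1", "k1", "k2", "k2", "b1", "b1", "b2", "b2"),
    category = rep(c("kitchen", "bedroom"), each = 4),
    object = c("sink", "table", "sink", "chair", "bed", "table", "bed", "sink"),
    stringsAsFactors = FALSE)
  scenes$is_anchor <- paste(scenes$object, scenes$category) %in% anchors |
    scenes$object %in% anchors
  index <- unique(scenes[, c("scene_id", "category")])
  structure(list(scenes = scenes, scene_index = index,
                 objects = sort(unique(scenes$object)),
                 categories = c("bedroom", "kitchen"), spec = NULL),
            class = "labeled_corpus")
}

# Image table for observer simulations: n real + n generated images with
# given z-scores (default 0) and one duration.
flat_images <- function(n_per_condition, duration = "500",
                        z_anchor = 0, z_diag = 0) {
  data.frame(
    image_id = paste0("img", seq_len(2 * n_per_condition)),
    condition = rep(c("real", "generated"), each = n_per_condition),
    duration = duration,
    z_anchor = z_anchor, z_diag = z_diag,
    stringsAsFactors = FALSE)
}

with_seed_test <- function(seed, expr) { set.seed(seed); force(expr) }

# 99% binomial interval for an observed proportion at n trials.
binom_bounds <- function(p, n, level = 0.99) {
  a <- (1 - level) / 2
  qbinom(c(a, 1 - a), n, p) / n
}

# Independent Newton-Raphson maximizer of the exact binomial
# log-likelihood (logit link), used as an oracle for the IRLS path.
newton_logit <- function(x, y, tol = 1e-12, maxit = 50) {
  beta <- rep(0, ncol(x))
  for (i in seq_len(maxit)) {
    eta <- drop(x %*% beta)
    p <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(x, y - p))
    h <- crossprod(x * (p * (1 - p)), x)
    step <- solve(h, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Independent fine-grid evaluation of the JZS Bayes factor: transform
# g = u / (1 - u) and integrate by the trapezoid rule on a dense u grid.
jzs_bf_grid <- function(t, n, r = 0.707, n_grid = 4e5) {
  nu <- n - 1
  u <- seq(1e-9, 1 - 1e-9, length.out = n_grid)
  g <- u / (1 - u)
  jac <- 1 / (1 - u)^2
  ngr <- 1 + n * g * r^2
  f <- ngr^(-0.5) * (1 + t^2 / (nu * ngr))^(-(nu + 1) / 2) *
    g^(-1.5) * exp(-1 / (2 * g)) / sqrt(2 * pi) * jac
  num <- sum((head(f, -1) + tail(f, -1)) / 2 * diff(u))
  num / (1 + t^2 / nu)^(-(nu + 1) / 2)
}

# Brute-force Benjamini-Hochberg step-up: find the largest k with
# p_(k) <= k * alpha / m by direct enumeration, and adjusted values by
# the defining minimum.
bh_bruteforce <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    k <- which(ord == i)  # rank of p_i
    q[i] <- min(1, min(p[ord][k:m] * m / (k:m)))
  }
  q
}

# Explicit leave-one-out ridge refits on the design exactly as given.
loo_ridge_explicit <- function(x, y, alpha) {
  n <- nrow(x)
  vapply(seq_len(n), function(i) {
    xt <- x[-i, , drop = FALSE]; yt <- y[-i]
    b <- solve(crossprod(xt) + alpha * diag(ncol(xt)), crossprod(xt, yt))
    drop(x[i, , drop = FALSE] %*% b)
  }, numeric(1))
}
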
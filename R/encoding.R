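#' Sparse random projection (Achlioptas/Li)
#'
#' Reduces feature dimensionality with a sparse random projection matrix
#' whose entries are +sqrt(s), 0, -sqrt(s) with probabilities 1/(2s),
#' 1 - 1/s, 1/(2s), where s = sqrt(D) and D is the input dimension
#' (nonzero density 1/sqrt(D)); columns are scaled by 1/sqrt(k) so squared
#' distances are preserved in expectation (Johnson-Lindenstrauss).
#'
#' @param x Numeric matrix (observations x features).
#' @param target_dim Output dimension. If missing, derived from `eps` via
#'   the JL bound ceiling(4 log(n) / (eps^2/2 - eps^3/3)). If
#'   `target_dim >= ncol(x)`, the input is returned unchanged with a
#'   message.
#' @param eps JL distortion parameter used when `target_dim` is missing.
#' @param seed Integer seed; the projection is deterministic given it.
#' @return Projected matrix (observations x target_dim).
#' @export
srp_project <- function(x, target_dim = NULL, eps = 0.2, seed = 1L) {
  x <- as.matrix(x)
  d <- ncol(x)
  if (is.null(target_dim)) {
    target_dim <- ceiling(4 * log(nrow(x)) / (eps^2 / 2 - eps^3 / 3))
  }
  if (target_dim >= d) {
    message(sprintf("srp_project: target_dim %d >= input dim %d; passing through",
                    target_dim, d))
    return(x)
  }
  with_seed(derive_seed(seed, "srp"), {
    s <- sqrt(d)
    density <- 1 / s
    n_entries <- d * target_dim
    nz <- which(runif(n_entries) < density)
    vals <- sqrt(s) * sign(runif(length(nz)) - 0.5)
    r <- Matrix::sparseMatrix(
      i = ((nz - 1L) %% d) + 1L,
      j = ((nz - 1L) %/% d) + 1L,
      x = vals, dims = c(d, target_dim))
    as.matrix(x %*% r) / sqrt(target_dim)
  })
}

ridge_standardize <- function(x, center, scale) {
  scale[scale < 1e-12] <- 1  # constant columns carry no information
  sweep(sweep(x, 2, center), 2, scale, "/")
}

#' Leave-one-out cross-validated ridge decoding
#'
#' Predicts a per-image behavioral score from a feature matrix by ridge
#' regression with full leave-one-out cross-validation. For each held-out
#' image, predictors are column-standardized using the training fold
#' only; the penalty is selected on the training fold by closed-form
#' generalized cross-validation (GCV) over `alpha_grid`. The decoding
#' score is the Pearson correlation between LOO predictions and the
#' actual scores.
#'
#' The response is centered once, globally, rather than per training
#' fold: re-estimating the mean inside each fold makes the held-out
#' prediction contain (n ybar - y_i) / (n - 1), a term perfectly
#' anticorrelated with y_i, so under heavy regularization the null
#' decoding correlation converges to -1 instead of 0. Centering by the
#' single global scalar removes that artifact; all multivariate fitting
#' statistics stay fold-internal.
#'
#' @param x Feature matrix (images x features), >= 10 rows.
#' @param y Per-image score; must not be constant.
#' @param alpha_grid Positive ridge penalties (default 13 log-spaced
#'   points, 10^-1 to 10^5).
#' @return List: `predictions` (LOO), `r` (Pearson correlation with y),
#'   `alpha` (selected penalty per fold).
#' @export
loo_ridge_decode <- function(x, y, alpha_grid = 10^seq(-1, 5, by = 0.5)) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (n < 10) stopf("need at least 10 images for leave-one-out decoding")
  if (length(y) != n || any(!is.finite(y))) stopf("y must be finite, one per image")
  if (sd(y) == 0) stopf("constant y: decoding correlation undefined")
  if (any(alpha_grid <= 0)) stopf("alpha_grid must be positive")

  preds <- numeric(n)
  alphas <- numeric(n)
  ym <- mean(y)
  for (i in seq_len(n)) {
    xtr <- x[-i, , drop = FALSE]; ytr <- y[-i]
    ctr <- colMeans(xtr); sc <- apply(xtr, 2, sd)
    xs <- ridge_standardize(xtr, ctr, sc)
    yc <- ytr - ym
    sv <- svd(xs)
    uty <- drop(crossprod(sv$u, yc))
    d2 <- sv$d^2
    m <- length(ytr)
    gcv <- vapply(alpha_grid, function(a) {
      shrink <- d2 / (d2 + a)
      resid2 <- sum((yc - sv$u %*% (shrink * uty))^2)
      edf <- sum(shrink)
      (resid2 / m) / (1 - edf / m)^2
    }, numeric(1))
    a <- alpha_grid[which.min(gcv)]
    coefs <- sv$v %*% ((sv$d / (sv$d^2 + a)) * uty)
    x0 <- ridge_standardize(x[i, , drop = FALSE], ctr, sc)
    preds[i] <- ym + drop(x0 %*% coefs)
    alphas[i] <- a
  }
  r <- if (sd(preds) < 1e-12) 0 else cor(preds, y)  # constant predictions carry no signal
  list(predictions = preds, r = r, alpha = alphas)
}

#' Closed-form leave-one-out ridge predictions at fixed penalty
#'
#' For a fixed design and penalty, the LOO residual of ridge regression is
#' e_i / (1 - h_ii), with e the full-fit residual and h_ii the ridge hat
#' diagonal H = X (X'X + alpha I)^-1 X'. This is algebraically identical
#' to refitting with each observation removed (on the design exactly as
#' given - no per-fold standardization), and is used as a fast fixed-alpha
#' path and as the anchor for oracle checks.
#'
#' @param x Design matrix as used directly (no internal standardization).
#' @param y Response.
#' @param alpha Single positive ridge penalty.
#' @return List: `predictions` (LOO), `residuals_loo`, `h_diag`.
#' @export
loo_ridge_fixed <- function(x, y, alpha) {
  x <- as.matrix(x); y <- as.numeric(y)
  stopifnot(length(alpha) == 1, alpha > 0)
  sv <- svd(x)
  shrink <- sv$d^2 / (sv$d^2 + alpha)
  uty <- drop(crossprod(sv$u, y))
  fitted <- drop(sv$u %*% (shrink * uty))
  h <- rowSums(sweep(sv$u^2, 2, shrink, "*"))
  e_loo <- (y - fitted) / (1 - h)
  list(predictions = y - e_loo, residuals_loo = e_loo, h_diag = h)
}

#' Decode behavior from every layer of a feature store
#'
#' Runs [loo_ridge_decode()] for each (model instance, layer), after an
#' optional sparse-random-projection step for layers wider than
#' `srp_target_dim`.
#'
#' @param store A `feature_store`.
#' @param y Per-image behavioral score (row order must match the store).
#' @param alpha_grid Ridge penalties (see [loo_ridge_decode()]).
#' @param srp_target_dim Apply [srp_project()] first when a layer has more
#'   features than this (NULL = never).
#' @param seed Seed for the projection step.
#' @return `decoding_scores`: data frame model, group, trained, layer,
#'   depth, r.
#' @export
decode_feature_store <- function(store, y, alpha_grid = 10^seq(-1, 5, by = 0.5),
                                 srp_target_dim = NULL, seed = 1L) {
  stopifnot(inherits(store, "feature_store"))
  if (length(y) != store$n_images) stopf("y must have one score per stored image")
  meta <- store$layers
  meta$r <- NA_real_
  for (k in seq_len(nrow(meta))) {
    xm <- store$features[[meta$model[k]]][[meta$layer[k]]]
    if (!is.null(srp_target_dim) && ncol(xm) > srp_target_dim) {
      xm <- srp_project(xm, target_dim = srp_target_dim,
                        seed = derive_seed(seed, paste0("srp-", k)))
    }
    meta$r[k] <- loo_ridge_decode(xm, y, alpha_grid)$r
  }
  class(meta) <- c("decoding_scores", "data.frame")
  meta
}

#' Average layer decoding scores into depth bins
#'
#' Bins normalized layer depths into `n_bins` equal slices: bin b covers
#' \[(b-1)/n, b/n), with the last bin closed at 1, and averages the
#' decoding score over member layers. Empty bins are kept with NA.
#'
#' @param scores A `decoding_scores` data frame (or any data frame with
#'   model, group, depth, r).
#' @param n_bins Number of depth bins (default 10).
#' @return Data frame: model, group, bin, mean_r (NA when empty).
#' @export
bin_scores <- function(scores, n_bins = 10L) {
  assert_cols(scores, c("model", "group", "depth", "r"), "decoding scores")
  if (any(scores$depth < 0 | scores$depth > 1)) stopf("depths must lie in [0, 1]")
  bin <- ifelse(scores$depth >= 1, n_bins, floor(scores$depth * n_bins) + 1L)
  grid <- expand.grid(model = unique(scores$model), bin = seq_len(n_bins),
                      stringsAsFactors = FALSE)
  agg <- aggregate(r ~ model + bin, data = cbind(scores, bin = bin), FUN = mean)
  out <- merge(grid, agg, by = c("model", "bin"), all.x = TRUE)
  out$group <- scores$group[match(out$model, scores$model)]
  names(out)[names(out) == "r"] <- "mean_r"
  out <- out[order(out$model, out$bin), c("model", "group", "bin", "mean_r")]
  rownames(out) <- NULL
  out
}

binned_to_matrix <- function(binned, group) {
  sub <- binned[binned$group == group, ]
  models <- unique(sub$model)
  bins <- sort(unique(sub$bin))
  m <- matrix(NA_real_, length(models), length(bins),
              dimnames = list(models, paste0("bin", bins)))
  m[cbind(match(sub$model, models), match(sub$bin, bins))] <- sub$mean_r
  m
}

#' Permutation test of trained-versus-random bin differences
#'
#' For each depth bin, the statistic is mean(trained) - mean(random) over
#' per-model bin scores. The null distribution permutes the group labels
#' over all models (the same label permutation is applied to every bin, so
#' model-level structure is preserved); the one-sided p-value is
#' (1 + #\{permuted >= observed\}) / (n_perm + 1).
#'
#' @param trained,random Matrices models x bins of per-model bin scores.
#' @param n_perm Number of label permutations (default 10000; < 1000
#'   warns).
#' @param seed Integer seed.
#' @return Data frame: bin, diff, p_value.
#' @export
permutation_bin_test <- function(trained, random, n_perm = 10000, seed = 1L) {
  trained <- as.matrix(trained); random <- as.matrix(random)
  if (nrow(trained) < 2 || nrow(random) < 2) stopf("need >= 2 models per group")
  if (ncol(trained) != ncol(random)) stopf("bin counts differ between groups")
  if (n_perm < 1000) warning("n_perm < 1000 gives unstable p-values")
  n_t <- nrow(trained)
  all_scores <- rbind(trained, random)
  n_all <- nrow(all_scores)
  observed <- colMeans(trained, na.rm = TRUE) - colMeans(random, na.rm = TRUE)
  with_seed(derive_seed(seed, "perm-bins"), {
    exceed <- integer(ncol(all_scores))
    for (b in seq_len(n_perm)) {
      idx <- sample.int(n_all, n_t)
      d <- colMeans(all_scores[idx, , drop = FALSE], na.rm = TRUE) -
        colMeans(all_scores[-idx, , drop = FALSE], na.rm = TRUE)
      exceed <- exceed + (d >= observed)
    }
    data.frame(bin = seq_len(ncol(all_scores)), diff = unname(observed),
               p_value = unname((1 + exceed) / (n_perm + 1)))
  })
}

#' Benjamini-Hochberg false discovery rate correction
#'
#' Step-up FDR adjustment of a p-value vector (delegating to
#' [stats::p.adjust()]), with the rejection set at the given level.
#'
#' @param p P-values in \[0, 1\].
#' @param alpha Rejection level for the returned set (default 0.05).
#' @return List: `q` (adjusted values, monotone), `reject` (logical).
#' @export
fdr_bh <- function(p, alpha = 0.05) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stopf("p-values must lie in [0, 1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, reject = !is.na(q) & q < alpha)
}

#' Bootstrap mean and percentile confidence interval of paired differences
#'
#' Resamples the per-model differences with replacement `n_boot` times and
#' returns the observed mean with the percentile 95% interval of the
#' bootstrap means.
#'
#' @param diffs Numeric vector of paired differences (>= 2 values).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return List: mean, ci (length 2), n_boot.
#' @export
bootstrap_diff_ci <- function(diffs, n_boot = 1000, seed = 1L) {
  diffs <- as.numeric(diffs)
  diffs <- diffs[is.finite(diffs)]
  if (length(diffs) < 2) stopf("need at least 2 differences")
  with_seed(derive_seed(seed, "boot-ci"), {
    means <- vapply(seq_len(n_boot), function(i)
      mean(diffs[sample.int(length(diffs), replace = TRUE)]), numeric(1))
    list(mean = mean(diffs), ci = unname(quantile(means, c(0.025, 0.975))),
         n_boot = n_boot)
  })
}

#' One-sample JZS (default-prior) Bayes factor
#'
#' Bayes factor BF10 for a one-sample t-test of the mean of `diffs`
#' against 0 under the Jeffreys-Zellner-Siow default prior: a Cauchy
#' prior with scale `prior_scale` on the standardized effect size,
#' expressed as a scale mixture g ~ inverse-chi-square(1). The marginal
#' likelihood ratio
#' BF10 = integral (1 + N g r^2)^(-1/2)
#'   \[1 + t^2 / (nu (1 + N g r^2))\]^(-(nu+1)/2) pi(g) dg /
#'   (1 + t^2 / nu)^(-(nu+1)/2)
#' is evaluated by adaptive quadrature; it is monotone in |t| at fixed n,
#' with BF10 < 1 at t = 0.
#'
#' @param diffs Paired differences (n >= 2, nonzero variance), or NULL if
#'   `t` and `n` are given directly.
#' @param prior_scale Cauchy prior scale r (default 0.707 = sqrt(2)/2).
#' @param t,n Optional t statistic and sample size instead of `diffs`.
#' @return BF10 (numeric scalar).
#' @export
jzs_bf_paired <- function(diffs = NULL, prior_scale = 0.707, t = NULL, n = NULL) {
  if (is.null(t)) {
    diffs <- as.numeric(diffs)
    n <- length(diffs)
    if (n < 2) stopf("need at least 2 differences")
    s <- sd(diffs)
    if (s == 0) stopf("zero-variance differences: t statistic undefined")
    t <- mean(diffs) / (s / sqrt(n))
  }
  stopifnot(n >= 2)
  nu <- n - 1
  r2 <- prior_scale^2
  # pi(g): inverse-chi-square(1) density
  integrand <- function(g) {
    ngr <- 1 + n * g * r2
    ngr^(-0.5) * (1 + t^2 / (nu * ngr))^(-(nu + 1) / 2) *
      g^(-1.5) * exp(-1 / (2 * g)) / sqrt(2 * pi)
  }
  num <- integrate(integrand, 0, Inf, rel.tol = 1e-10,
                   subdivisions = 500L)$value
  den <- (1 + t^2 / nu)^(-(nu + 1) / 2)
  num / den
}

#' Trained-versus-random inference for every depth bin
#'
#' Combines the bin-wise permutation test, BH-FDR correction across bins,
#' bootstrap mean/CI of the trained-minus-random difference, and the
#' paired JZS Bayes factor into one comparison table.
#'
#' @param binned Output of [bin_scores()] containing both groups.
#' @param n_perm,n_boot Replicates for the permutation and bootstrap steps.
#' @param prior_scale Cauchy scale for the Bayes factor.
#' @param alpha FDR level.
#' @param seed Integer seed.
#' @return `bin_comparison` data frame: bin, diff, p_value, q_value,
#'   significant, boot_mean, ci_lo, ci_hi, bf10.
#' @export
compare_bins <- function(binned, n_perm = 10000, n_boot = 1000,
                         prior_scale = 0.707, alpha = 0.05, seed = 1L) {
  tr <- binned_to_matrix(binned, "trained")
  rd <- binned_to_matrix(binned, "random")
  res <- permutation_bin_test(tr, rd, n_perm = n_perm, seed = seed)
  fdr <- fdr_bh(res$p_value, alpha = alpha)
  res$q_value <- fdr$q
  res$significant <- fdr$reject
  res$boot_mean <- NA_real_; res$ci_lo <- NA_real_; res$ci_hi <- NA_real_
  res$bf10 <- NA_real_
  n_pair <- min(nrow(tr), nrow(rd))
  for (b in seq_len(nrow(res))) {
    diffs <- tr[seq_len(n_pair), b] - rd[seq_len(n_pair), b]
    diffs <- diffs[is.finite(diffs)]
    if (length(diffs) >= 2) {
      ci <- bootstrap_diff_ci(diffs, n_boot = n_boot,
                              seed = derive_seed(seed, paste0("bin-", b)))
      res$boot_mean[b] <- ci$mean
      res$ci_lo[b] <- ci$ci[1]; res$ci_hi[b] <- ci$ci[2]
      if (sd(diffs) > 0) res$bf10[b] <- jzs_bf_paired(diffs, prior_scale)
    }
  }
  class(res) <- c("bin_comparison", "data.frame")
  res
}
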
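#' Combine binary response and confidence into a 12-point ordinal scale
#'
#' Maps ("generated", confidence 6) = 1 through ("generated", 1) = 6,
#' ("real", 1) = 7 through ("real", 6) = 12, so low values mean
#' confident-generated and high values confident-real. The mapping is a
#' bijection between (response, confidence) pairs and 1..12.
#'
#' @param response "real"/"generated", or numeric 1/0 (1 = "real").
#' @param confidence Integer confidence rating in 1..6.
#' @return Integer vector in 1..12.
#' @export
confidence_scale <- function(response, confidence) {
  if (is.numeric(response)) {
    if (!all(response %in% c(0, 1))) stopf("numeric responses must be 0/1")
    response <- ifelse(response == 1, "real", "generated")
  }
  if (!all(response %in% c("real", "generated"))) {
    stopf("responses must be 'real'/'generated' (or 1/0)")
  }
  confidence <- as.integer(confidence)
  if (any(is.na(confidence)) || any(confidence < 1 | confidence > 6)) {
    stopf("confidence ratings must lie in 1..6")
  }
  as.integer(ifelse(response == "real", 6L + confidence, 7L - confidence))
}

#' Empirical ROC curve from an ordinal response scale
#'
#' Sweeps the 11 interior cutoffs of the 12-point scale: at cutoff k the
#' hit rate is P(scale > k | real image) and the false-alarm rate is
#' P(scale > k | generated image) - labeling a real image "real" is a hit,
#' labeling a generated image "real" a false alarm. Points are sorted and
#' the endpoints (0,0), (1,1) appended; AUC is the trapezoidal integral.
#' AUC > 0.5 means real and generated images are discriminable.
#'
#' @param trials Trial table with `condition` ("real"/"generated") and
#'   either a `scale` column (ordinal 1..n_levels) or `response` +
#'   `confidence` columns from which it is built.
#' @param n_levels Number of ordinal levels (default 12).
#' @return An object of class `roc_curve`: data frame of points
#'   (fa_rate, hit_rate) with attributes `auc`, `n_signal`, `n_noise`.
#' @export
empirical_roc <- function(trials, n_levels = 12L) {
  assert_cols(trials, "condition", "trial table")
  if (is.null(trials$scale)) {
    assert_cols(trials, c("response", "confidence"), "trial table")
    trials$scale <- confidence_scale(trials$response, trials$confidence)
  }
  sig <- trials$scale[trials$condition == "real"]
  noi <- trials$scale[trials$condition == "generated"]
  if (!length(sig) || !length(noi)) {
    stopf("both real (signal) and generated (noise) trials are required")
  }
  all_s <- c(sig, noi)
  canonical <- all(all_s == round(all_s)) && min(all_s) >= 1 &&
    max(all_s) <= n_levels
  # canonical 1..n_levels scales sweep the fixed interior cutoffs; any other
  # strictly monotone relabeling sweeps its observed values instead (the AUC
  # depends only on the ordinal structure, so the two agree where both apply)
  cuts <- if (canonical) seq_len(n_levels - 1L) else
    head(sort(unique(all_s)), -1)
  hit <- vapply(cuts, function(k) mean(sig > k), numeric(1))
  fa <- vapply(cuts, function(k) mean(noi > k), numeric(1))
  ord <- order(fa, hit)
  pts <- data.frame(fa_rate = c(0, fa[ord], 1), hit_rate = c(0, hit[ord], 1))
  auc <- sum(diff(pts$fa_rate) * (head(pts$hit_rate, -1) + tail(pts$hit_rate, -1)) / 2)
  structure(pts, auc = auc, n_signal = length(sig), n_noise = length(noi),
            class = c("roc_curve", "data.frame"))
}

#' Area under an empirical ROC curve
#' @param x A `roc_curve` or a trial table (passed to [empirical_roc()]).
#' @param ... Passed on to [empirical_roc()].
#' @return AUC in \[0, 1\].
#' @export
auc <- function(x, ...) {
  if (!inherits(x, "roc_curve")) x <- empirical_roc(x, ...)
  attr(x, "auc")
}

#' Per-participant AUCs and their unweighted mean
#'
#' @param trials Trial table with a `participant` column.
#' @param ... Passed to [empirical_roc()].
#' @return Data frame (participant, auc) with attribute `mean_auc`.
#' @export
participant_auc <- function(trials, ...) {
  assert_cols(trials, "participant", "trial table")
  ids <- sort(unique(trials$participant))
  aucs <- vapply(ids, function(p)
    auc(trials[trials$participant == p, , drop = FALSE], ...), numeric(1))
  structure(data.frame(participant = ids, auc = aucs),
            mean_auc = mean(aucs))
}

#' Sensitivity and criterion from hit and false-alarm rates
#'
#' d' = qnorm(hit) - qnorm(fa); criterion c = -(qnorm(hit) + qnorm(fa)) / 2
#' under the equal-variance Gaussian model. Rates of exactly 0 or 1 make
#' the quantiles infinite, so a correction is applied first:
#' `"loglinear"` (default) adds 0.5 to both hit and false-alarm counts and
#' 1 to both trial counts regardless of rate; `"clip"` replaces 0 by
#' 1/(2N) and 1 by 1 - 1/(2N); `"none"` rejects degenerate rates.
#'
#' @param hit_rate,fa_rate Observed rates in \[0, 1\].
#' @param n_signal,n_noise Trial counts (required by both corrections).
#' @param correction One of "loglinear", "clip", "none".
#' @return List (class `sdt_summary`): hit_rate, fa_rate (post-correction),
#'   d_prime, criterion, correction.
#' @export
dprime <- function(hit_rate, fa_rate, n_signal = NULL, n_noise = NULL,
                   correction = c("loglinear", "clip", "none")) {
  correction <- match.arg(correction)
  stopifnot(hit_rate >= 0, hit_rate <= 1, fa_rate >= 0, fa_rate <= 1)
  degenerate <- hit_rate %in% c(0, 1) || fa_rate %in% c(0, 1)
  if (correction == "none") {
    if (degenerate) stopf("hit/false-alarm rate of 0 or 1 requires a correction")
  } else {
    if (is.null(n_signal) || is.null(n_noise)) {
      stopf("corrections need n_signal and n_noise")
    }
    if (correction == "loglinear") {
      hit_rate <- (hit_rate * n_signal + 0.5) / (n_signal + 1)
      fa_rate <- (fa_rate * n_noise + 0.5) / (n_noise + 1)
    } else {
      clip <- function(r, n) min(max(r, 1 / (2 * n)), 1 - 1 / (2 * n))
      hit_rate <- clip(hit_rate, n_signal)
      fa_rate <- clip(fa_rate, n_noise)
    }
  }
  zh <- qnorm(hit_rate); zf <- qnorm(fa_rate)
  structure(list(hit_rate = hit_rate, fa_rate = fa_rate,
                 d_prime = zh - zf, criterion = -(zh + zf) / 2,
                 correction = correction),
            class = "sdt_summary")
}

#' Bootstrap comparison of two AUCs
#'
#' Compares the AUC of two trial tables (e.g. the 50 ms and 500 ms
#' conditions) by stratified bootstrap: participants are resampled with
#' replacement and, within each resampled participant, trials are
#' resampled within the real and generated strata. The statistic is the
#' unweighted mean of per-participant AUCs (`stat = "participants"`,
#' default) or the pooled-trials AUC (`stat = "pooled"`); a flat
#' trial-level resample is available via `stratified = FALSE`. The
#' two-sided p-value uses add-one smoothing:
#' p = min(1, 2 * min((1 + #\{diff <= 0\}, 1 + #\{diff >= 0\}) / (B + 1))).
#'
#' @param trials_a,trials_b Trial tables valid for [empirical_roc()].
#' @param n_boot Bootstrap replicates (>= 100; default 2000).
#' @param stat "participants" or "pooled".
#' @param stratified Resample within participant x condition strata.
#' @param seed Integer seed.
#' @return List: auc_a, auc_b, diff (a - b), p_value, ci (percentile 95%),
#'   n_boot, stat.
#' @export
auc_boot_test <- function(trials_a, trials_b, n_boot = 2000,
                          stat = c("participants", "pooled"),
                          stratified = TRUE, seed = 1L) {
  stat <- match.arg(stat)
  if (n_boot < 100) stopf("n_boot < 100 is too unstable; use at least 100")
  # per-participant scale-count representation: resampling trials within a
  # participant x condition stratum is a multinomial redraw of its counts
  count_rep <- function(tr, n_levels = 12L) {
    if (is.null(tr$scale)) tr$scale <- confidence_scale(tr$response, tr$confidence)
    split_counts <- function(cond) {
      sub <- tr[tr$condition == cond, ]
      t(vapply(split(sub$scale, sub$participant),
               function(s) tabulate(s, n_levels), numeric(n_levels)))
    }
    sig <- split_counts("real"); noi <- split_counts("generated")
    common <- intersect(rownames(sig), rownames(noi))
    if (!length(common)) stopf("both real and generated trials are required")
    list(sig = sig[common, , drop = FALSE], noi = noi[common, , drop = FALSE])
  }
  auc_from_counts <- function(sig, noi) {
    # sig/noi: count vectors over the ordinal scale
    hit <- rev(cumsum(rev(sig)))[-1] / sum(sig)
    fa <- rev(cumsum(rev(noi)))[-1] / sum(noi)
    fa_p <- c(0, rev(fa), 1); hit_p <- c(0, rev(hit), 1)
    sum(diff(fa_p) * (head(hit_p, -1) + tail(hit_p, -1)) / 2)
  }
  stat_from <- function(rep) {
    if (stat == "participants") {
      mean(vapply(seq_len(nrow(rep$sig)), function(i)
        auc_from_counts(rep$sig[i, ], rep$noi[i, ]), numeric(1)))
    } else {
      auc_from_counts(colSums(rep$sig), colSums(rep$noi))
    }
  }
  redraw_counts <- function(m) {
    t(vapply(seq_len(nrow(m)), function(i) {
      n <- sum(m[i, ])
      if (n == 0) m[i, ] else drop(stats::rmultinom(1, n, m[i, ] / n))
    }, numeric(ncol(m))))
  }
  resample_rep <- function(rep) {
    if (stratified) {
      take <- sample.int(nrow(rep$sig), replace = TRUE)
      list(sig = redraw_counts(rep$sig[take, , drop = FALSE]),
           noi = redraw_counts(rep$noi[take, , drop = FALSE]))
    } else {
      # flat trial resample pooled over participants, per condition
      flat <- function(m) {
        n <- sum(m); p <- colSums(m) / n
        matrix(drop(stats::rmultinom(1, n, p)), nrow = 1)
      }
      list(sig = flat(rep$sig), noi = flat(rep$noi))
    }
  }
  rep_a <- count_rep(trials_a); rep_b <- count_rep(trials_b)
  auc_a <- stat_from(rep_a); auc_b <- stat_from(rep_b)
  if (!stratified && stat == "participants") {
    stopf("flat resampling is only available with stat = 'pooled'")
  }
  with_seed(derive_seed(seed, "auc-boot"), {
    diffs <- vapply(seq_len(n_boot), function(i)
      stat_from(resample_rep(rep_a)) - stat_from(resample_rep(rep_b)),
      numeric(1))
    p <- min(1, 2 * min((1 + sum(diffs <= 0)) / (n_boot + 1),
                        (1 + sum(diffs >= 0)) / (n_boot + 1)))
    list(auc_a = auc_a, auc_b = auc_b, diff = auc_a - auc_b,
         p_value = p, ci = unname(quantile(diffs, c(0.025, 0.975))),
         n_boot = n_boot, stat = stat)
  })
}

#' Per-image realness scores from discrimination responses
#'
#' Realness of an image is the mean binary response it received
#' (1 = "real", 0 = "generated"), computed separately for each
#' presentation duration. Images with no trials in a duration get NA and
#' are reported in the `missing` attribute.
#'
#' @param trials 2AFC trial table with image_id, duration, response.
#' @return Data frame: image_id, duration, realness, n_trials.
#' @export
image_realness <- function(trials) {
  assert_cols(trials, c("image_id", "duration", "response"), "trial table")
  agg <- aggregate(response ~ image_id + duration, data = trials,
                   FUN = mean)
  n <- aggregate(cbind(n_trials = response) ~ image_id + duration,
                 data = trials, FUN = length)
  out <- merge(agg, n, by = c("image_id", "duration"))
  names(out)[names(out) == "response"] <- "realness"
  # flag image x duration cells absent from the data
  full <- expand.grid(image_id = unique(trials$image_id),
                      duration = unique(trials$duration),
                      stringsAsFactors = FALSE)
  out <- merge(full, out, by = c("image_id", "duration"), all.x = TRUE)
  missing <- out[is.na(out$realness), c("image_id", "duration")]
  if (nrow(missing) && isTRUE(getOption("scenecue.verbose", FALSE))) {
    message(sprintf("image_realness: %d image x duration cell(s) have no trials",
                    nrow(missing)))
  }
  out <- out[order(out$image_id, out$duration), ]
  rownames(out) <- NULL
  attr(out, "missing") <- missing
  out
}
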
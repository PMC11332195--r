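#' Simulate real-versus-generated discrimination with confidence ratings
#'
#' Equal-variance Gaussian SDT observers. On each trial the observer draws
#' evidence x ~ Normal(mu, 1) with
#' mu = d'(duration) * 1(condition == real) + beta_anchor * z_anchor +
#' beta_diag(condition) * z_diag + participant intercept. The response is
#' "real" iff x exceeds the middle (6th) criterion; the 11 ordered
#' criteria partition x into the 12-point ordinal scale, from which the
#' 6-point confidence rating is read off (1 = guessing, 6 = certain).
#'
#' @param images Data frame with columns image_id, condition
#'   ("real"/"generated"), duration (matching the names of the spec's d'
#'   map), z_anchor, z_diag.
#' @param spec An [observer_spec()].
#' @return Trial table: participant, image_id, condition, duration,
#'   z_anchor, z_diag, evidence, response (1 = "real", 0 = "generated"),
#'   confidence (1-6), scale (1-12).
#' @export
simulate_2afc <- function(images, spec) {
  stopifnot(inherits(spec, "observer_spec"))
  assert_cols(images, c("image_id", "condition", "duration", "z_anchor", "z_diag"),
              "image table")
  if (!all(images$condition %in% c("real", "generated"))) {
    stopf("condition must be 'real' or 'generated'")
  }
  dmap <- spec$d_prime_by_duration
  if (!all(as.character(images$duration) %in% names(dmap))) {
    stopf("image durations must appear in spec$d_prime_by_duration")
  }
  with_seed(derive_seed(spec$seed, "observer-2afc"), {
    np <- spec$n_participants
    intercepts <- rnorm(np, 0, spec$participant_sd)
    n_img <- nrow(images)
    trials <- images[rep(seq_len(n_img), np), , drop = FALSE]
    trials$participant <- rep(seq_len(np), each = n_img)
    mu <- dmap[as.character(trials$duration)] * (trials$condition == "real") +
      spec$beta_anchor * trials$z_anchor +
      spec$beta_diag_by_condition[trials$condition] * trials$z_diag +
      intercepts[trials$participant]
    x <- rnorm(nrow(trials), mu, 1)
    crit <- spec$criterion_centers
    scale12 <- findInterval(x, crit) + 1L       # 1..12
    trials$evidence <- x
    trials$response <- as.integer(x > crit[6])
    trials$confidence <- ifelse(trials$response == 1L, scale12 - 6L, 7L - scale12)
    trials$scale <- scale12
    rownames(trials) <- NULL
    trials[, c("participant", "image_id", "condition", "duration",
               "z_anchor", "z_diag", "evidence", "response", "confidence",
               "scale")]
  })
}

#' Simulate realness ratings for generated images
#'
#' Rating = round(alpha + beta_anchor * z_anchor + beta_diag * z_diag +
#' participant intercept + Gaussian noise), clipped to the 1-6 scale.
#' Only generated images are rated (real photographs were never rated).
#'
#' @param images Generated-image table with image_id, condition
#'   ("generated"), z_anchor, z_diag.
#' @param alpha Grand-mean rating on the latent scale.
#' @param beta_anchor,beta_diag Rating shift per z-unit of each score.
#' @param noise_sd Trial noise SD; `participant_sd` intercept SD.
#' @param n_participants Number of raters.
#' @param seed Integer seed.
#' @return Trial table: participant, image_id, z_anchor, z_diag, rating.
#' @export
simulate_ratings <- function(images, alpha = 3.5, beta_anchor = 0.15,
                             beta_diag = -0.09, noise_sd = 1.2,
                             participant_sd = 0.3, n_participants = 50,
                             seed = 1L) {
  assert_cols(images, c("image_id", "z_anchor", "z_diag"), "image table")
  if (!is.null(images$condition) && any(images$condition != "generated")) {
    stopf("ratings are collected for generated images only")
  }
  with_seed(derive_seed(seed, "observer-ratings"), {
    np <- as.integer(n_participants)
    intercepts <- rnorm(np, 0, participant_sd)
    n_img <- nrow(images)
    trials <- images[rep(seq_len(n_img), np),
                     c("image_id", "z_anchor", "z_diag"), drop = FALSE]
    trials$participant <- rep(seq_len(np), each = n_img)
    latent <- alpha + beta_anchor * trials$z_anchor + beta_diag * trials$z_diag +
      intercepts[trials$participant] + rnorm(nrow(trials), 0, noise_sd)
    trials$rating <- pmin(pmax(round(latent), 1), 6)
    rownames(trials) <- NULL
    trials[, c("participant", "image_id", "z_anchor", "z_diag", "rating")]
  })
}

#' Simulate five-alternative forced-choice scene categorization
#'
#' Accuracy follows a guessing-corrected logistic model:
#' P(correct) = 0.2 + 0.8 * plogis(b0 + b_diag * z_diag +
#' b_realness * z_realness + b_duration * c_duration), where c_duration is
#' the sum-coded duration (+1 = 50 ms, -1 = 500 ms) and 0.2 is the chance
#' floor for five alternatives. Incorrect responses are uniform over the
#' four remaining categories.
#'
#' @param images Table with image_id, category, duration, z_diag,
#'   z_realness (z-scored mean Experiment-1 response).
#' @param b0,b_diag,b_realness,b_duration Logistic coefficients.
#' @param categories Category set (default: the five in `images`).
#' @param n_participants Number of simulated participants.
#' @param participant_sd SD of participant intercepts on the logit scale.
#' @param seed Integer seed.
#' @return Trial table: participant, image_id, category, duration, z_diag,
#'   z_realness, choice, correct (0/1).
#' @export
simulate_5afc <- function(images, b0 = 0.4, b_diag = 0.53, b_realness = 0.48,
                          b_duration = -1.07, categories = NULL,
                          n_participants = 50, participant_sd = 0.3,
                          seed = 1L) {
  assert_cols(images, c("image_id", "category", "duration", "z_diag", "z_realness"),
              "image table")
  categories <- categories %||% sort(unique(images$category))
  with_seed(derive_seed(seed, "observer-5afc"), {
    np <- as.integer(n_participants)
    intercepts <- rnorm(np, 0, participant_sd)
    n_img <- nrow(images)
    trials <- images[rep(seq_len(n_img), np),
                     c("image_id", "category", "duration", "z_diag", "z_realness"),
                     drop = FALSE]
    trials$participant <- rep(seq_len(np), each = n_img)
    cdur <- ifelse(as.character(trials$duration) == "50", 1, -1)
    eta <- b0 + b_diag * trials$z_diag + b_realness * trials$z_realness +
      b_duration * cdur + intercepts[trials$participant]
    p_correct <- 0.2 + 0.8 * plogis(eta)
    trials$correct <- as.integer(runif(nrow(trials)) < p_correct)
    wrong <- lapply(trials$category, function(ct) setdiff(categories, ct))
    pick_wrong <- vapply(wrong, function(w) w[sample.int(length(w), 1L)],
                         character(1))
    trials$choice <- ifelse(trials$correct == 1L, trials$category, pick_wrong)
    rownames(trials) <- NULL
    trials[, c("participant", "image_id", "category", "duration", "z_diag",
               "z_realness", "choice", "correct")]
  })
}
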
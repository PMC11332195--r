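#' Specification of a labeled scene corpus
#'
#' Defines the generative model for a labeled object-scene corpus: five (by
#' default) indoor scene categories, a pool of object labels, per-category
#' object occurrence probabilities, and per-(object, category) anchor
#' probabilities. The corpus stands in for the large labeled image dataset
#' from which object diagnosticity and anchor-status-frequency tables are
#' normally precomputed.
#'
#' If `occurrence_probs` is not supplied, a structured default is drawn
#' deterministically from `seed`: each category has `objects_per_category`
#' "home" objects occurring with probability 0.5-0.95, plus sparse
#' cross-category clutter (probability 0-0.2, 60% of pairs exactly 0). The
#' first three home objects of each category act as anchors (large,
#' stationary, predictive objects such as a sink in a kitchen) with anchor
#' probability 0.6-0.95.
#'
#' @param n_categories Number of scene categories (default 5, as for the
#'   LSUN-style indoor set: bedroom, conference room, dining room, kitchen,
#'   living room).
#' @param objects_per_category Number of home objects per category.
#' @param n_scenes_per_category Scenes to draw per category.
#' @param occurrence_probs Optional matrix (objects x categories) of
#'   P(object present | category), entries in \[0, 1\].
#' @param anchor_flags Optional matrix (objects x categories) giving the
#'   probability that the object, when present in a scene of that category,
#'   functions as an anchor. Logical matrices are accepted and treated as
#'   0/1 probabilities.
#' @param categories Optional character vector of category names.
#' @param seed Integer seed; the corpus stream is derived from it and is
#'   disjoint from observer and feature streams.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_categories = 5,
                        objects_per_category = 12,
                        n_scenes_per_category = 200,
                        occurrence_probs = NULL,
                        anchor_flags = NULL,
                        categories = NULL,
                        seed = 1L) {
  default_cats <- c("bedroom", "conference_room", "dining_room",
                    "kitchen", "living_room")
  if (is.null(categories)) {
    categories <- if (n_categories <= length(default_cats)) {
      default_cats[seq_len(n_categories)]
    } else {
      c(default_cats, paste0("category_", seq_len(n_categories - length(default_cats))))
    }
  }
  stopifnot(length(categories) == n_categories)

  if (is.null(occurrence_probs)) {
    built <- with_seed(derive_seed(seed, "corpus-structure"), {
      objects <- unlist(lapply(categories, function(ct)
        paste0(ct, "_obj", seq_len(objects_per_category))))
      p <- matrix(0, nrow = length(objects), ncol = n_categories,
                  dimnames = list(objects, categories))
      a <- matrix(0, nrow = length(objects), ncol = n_categories,
                  dimnames = list(objects, categories))
      for (ci in seq_len(n_categories)) {
        home <- (ci - 1L) * objects_per_category + seq_len(objects_per_category)
        p[home, ci] <- runif(objects_per_category, 0.5, 0.95)
        foreign <- setdiff(seq_along(objects), home)
        clutter <- runif(length(foreign), 0, 0.35)
        clutter[runif(length(foreign)) < 0.45] <- 0
        p[foreign, ci] <- clutter
        a[home[1:3], ci] <- runif(3, 0.6, 0.95)
      }
      list(p = p, a = a)
    })
    occurrence_probs <- built$p
    if (is.null(anchor_flags)) anchor_flags <- built$a
  }
  occurrence_probs <- as.matrix(occurrence_probs)
  if (is.null(rownames(occurrence_probs))) {
    rownames(occurrence_probs) <- paste0("obj", seq_len(nrow(occurrence_probs)))
  }
  if (is.null(colnames(occurrence_probs))) colnames(occurrence_probs) <- categories
  if (is.null(anchor_flags)) {
    anchor_flags <- matrix(0, nrow(occurrence_probs), ncol(occurrence_probs),
                           dimnames = dimnames(occurrence_probs))
  }
  anchor_flags <- as.matrix(anchor_flags) * 1.0
  if (any(occurrence_probs < 0 | occurrence_probs > 1)) {
    stopf("occurrence_probs entries must lie in [0, 1]")
  }
  if (any(anchor_flags < 0 | anchor_flags > 1)) {
    stopf("anchor_flags entries must lie in [0, 1]")
  }
  if (!all(dim(anchor_flags) == dim(occurrence_probs))) {
    stopf("anchor_flags must have the same dimensions as occurrence_probs")
  }
  if (any(colSums(occurrence_probs) == 0)) {
    stopf("every category needs at least one object with nonzero occurrence probability")
  }
  structure(list(
    n_categories = n_categories,
    objects_per_category = objects_per_category,
    n_scenes_per_category = n_scenes_per_category,
    occurrence_probs = occurrence_probs,
    anchor_flags = anchor_flags,
    categories = colnames(occurrence_probs),
    objects = rownames(occurrence_probs),
    seed = as.integer(seed)
  ), class = "corpus_spec")
}

#' Specification of an equal-variance Gaussian SDT observer population
#'
#' Parameters of the simulated observers in the real-versus-generated
#' discrimination task. Evidence on each trial is Normal(mu, 1) with
#' mu = d'(duration) for real images (0 for generated) plus linear shifts
#' for the image's z-scored anchor-status-frequency and diagnosticity
#' scores and a participant intercept. Eleven ordered criteria partition
#' the evidence axis into the 12 ordinal response bins implied by a binary
#' real/generated response with a 6-point confidence rating.
#'
#' Default d' values are back-computed from headline AUCs of 0.6 (50 ms)
#' and 0.92 (500 ms) via d' = sqrt(2) * qnorm(AUC); they are defaults, not
#' ground truth. Default criteria are evenly spaced (step 0.3) around the
#' unbiased point midway between the pooled noise and signal means - a
#' convention, since human criterion placement is unobservable here.
#'
#' @param d_prime_by_duration Named numeric, d' per duration in evidence
#'   units, e.g. `c("50" = 0.358, "500" = 1.987)`; values must be >= 0.
#' @param beta_anchor Evidence shift per z-unit of anchor score.
#' @param beta_diag_by_condition Named numeric `c(real = ..., generated = ...)`,
#'   evidence shift per z-unit of diagnosticity, by true image condition.
#' @param criterion_centers 11 strictly increasing criteria, or NULL for
#'   the default placement described above.
#' @param n_participants Number of simulated participants.
#' @param participant_sd SD of the Gaussian participant intercepts.
#' @param seed Integer seed for the observer stream.
#' @return An object of class `observer_spec`.
#' @export
observer_spec <- function(d_prime_by_duration = c("50" = sqrt(2) * qnorm(0.6),
                                                  "500" = sqrt(2) * qnorm(0.92)),
                          beta_anchor = 0.18,
                          beta_diag_by_condition = c(real = 0.08, generated = -0.15),
                          criterion_centers = NULL,
                          n_participants = 50,
                          participant_sd = 0.3,
                          seed = 1L) {
  if (any(d_prime_by_duration < 0)) stopf("d' values must be >= 0")
  if (is.null(names(d_prime_by_duration))) {
    stopf("d_prime_by_duration must be named by duration (ms)")
  }
  if (is.null(criterion_centers)) {
    center <- mean(d_prime_by_duration) / 2
    criterion_centers <- center + seq(-1.5, 1.5, by = 0.3)
  }
  if (length(criterion_centers) != 11 || any(diff(criterion_centers) <= 0)) {
    stopf("criterion_centers must be 11 strictly increasing values")
  }
  if (!all(c("real", "generated") %in% names(beta_diag_by_condition))) {
    stopf("beta_diag_by_condition must be named c(real = ..., generated = ...)")
  }
  structure(list(
    d_prime_by_duration = d_prime_by_duration,
    beta_anchor = beta_anchor,
    beta_diag_by_condition = beta_diag_by_condition,
    criterion_centers = criterion_centers,
    n_participants = as.integer(n_participants),
    participant_sd = participant_sd,
    seed = as.integer(seed)
  ), class = "observer_spec")
}

#' Specification of a synthetic layer-wise feature store
#'
#' Defines per-layer feature matrices for a set of "trained" and "random"
#' model instances. Layer depth is normalized to l/(L-1) in \[0, 1\]. For a
#' trained instance, layer features are X = s(depth) * y w' + E with w a
#' fixed random unit direction per model (so layers within a model are
#' correlated, as in real networks) and E iid standard Gaussian noise;
#' random instances have signal scale 0 at every depth.
#'
#' @param n_layers Layers per model instance.
#' @param dims_per_layer Feature dimensionality per layer (recycled).
#' @param snr_by_depth Signal profile: `"linear"` (s = snr_max * depth),
#'   `"sigmoid"` (s = snr_max * plogis((depth - 0.6) / 0.1)), `"null"`
#'   (s = 0 everywhere), or a function depth -> scale.
#' @param snr_max Maximum signal scale (evidence-to-noise units).
#' @param n_trained_models,n_random_models Instances per group (default 7
#'   each, matching a seven-architecture model zoo and its randomly
#'   initialized counterparts).
#' @param seed Integer seed for the feature stream.
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(n_layers = 10,
                         dims_per_layer = 50,
                         snr_by_depth = c("sigmoid", "linear", "null"),
                         snr_max = 1.5,
                         n_trained_models = 7,
                         n_random_models = 7,
                         seed = 1L) {
  if (is.function(snr_by_depth)) {
    snr_fun <- snr_by_depth
  } else {
    snr_by_depth <- match.arg(snr_by_depth)
    snr_fun <- switch(snr_by_depth,
      linear  = function(d) snr_max * d,
      sigmoid = function(d) snr_max * plogis((d - 0.6) / 0.1),
      null    = function(d) rep(0, length(d)))
  }
  stopifnot(n_layers >= 2, n_trained_models >= 1, n_random_models >= 1)
  structure(list(
    n_layers = as.integer(n_layers),
    dims_per_layer = rep_len(as.integer(dims_per_layer), n_layers),
    snr_fun = snr_fun,
    n_trained_models = as.integer(n_trained_models),
    n_random_models = as.integer(n_random_models),
    seed = as.integer(seed)
  ), class = "feature_spec")
}
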
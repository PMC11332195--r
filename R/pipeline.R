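#' Default run configuration for the synthetic experiments
#'
#' Collects every tunable parameter of the pipeline in one plain list that
#' round-trips losslessly through JSON/YAML. Defaults encode the study
#' conditions: 50 participants; 150 real and 150 generated images (30 per
#' category, five indoor categories); presentation durations 50 and
#' 500 ms; observer d' back-computed from headline AUCs 0.6 and 0.92;
#' planted regression effects of 0.18 (anchor on 2AFC evidence), +0.08 /
#' -0.15 (diagnosticity on evidence for real / generated images), 0.15
#' and -0.09 (anchor, diagnosticity on ratings), and 0.53 / 0.48 / -1.07
#' (diagnosticity, realness, duration on 5-AFC accuracy, logit scale).
#'
#' @param seed Master seed; all module streams are derived from it.
#' @param ... Named overrides of any top-level entry (unknown names error).
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    n_participants = 50L,
    n_images_per_category = 30L,
    corpus = list(n_categories = 5L, objects_per_category = 12L,
                  n_scenes_per_category = 200L),
    gan_fidelity = 0.6,
    segmentation = list(miss_rate = 0.1, false_label_rate = 0.05,
                        prob_noise_sd = 0.1, base_prob = 0.75),
    observer = list(auc_50 = 0.6, auc_500 = 0.92, beta_anchor = 0.18,
                    beta_diag_real = 0.08, beta_diag_generated = -0.15,
                    participant_sd = 0.3),
    ratings = list(alpha = 3.5, beta_anchor = 0.15, beta_diag = -0.09,
                   noise_sd = 1.2, participant_sd = 0.3),
    afc = list(b0 = 0.4, b_diag = 0.53, b_realness = 0.48,
               b_duration = -1.07, participant_sd = 0.3),
    features = list(n_layers = 10L, dims_per_layer = 30L,
                    snr_profile = "sigmoid", snr_max = 1.5,
                    n_trained_models = 7L, n_random_models = 7L),
    analysis = list(n_boot_auc = 2000L, n_perm = 10000L, n_boot_ci = 1000L,
                    n_bins = 10L, prior_scale = 0.707, fdr_alpha = 0.05,
                    alpha_grid = 10^seq(-1, 5, by = 0.5)),
    run_encoding = TRUE
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad)) stopf("unknown config entr%s: %s",
                         if (length(bad) > 1) "ies" else "y",
                         paste(bad, collapse = ", "))
  for (nm in names(dots)) {
    if (is.list(cfg[[nm]]) && is.list(dots[[nm]])) {
      cfg[[nm]][names(dots[[nm]])] <- dots[[nm]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

observer_from_config <- function(cfg) {
  ob <- cfg$observer
  observer_spec(
    d_prime_by_duration = c("50" = sqrt(2) * qnorm(ob$auc_50),
                            "500" = sqrt(2) * qnorm(ob$auc_500)),
    beta_anchor = ob$beta_anchor,
    beta_diag_by_condition = c(real = ob$beta_diag_real,
                               generated = ob$beta_diag_generated),
    n_participants = cfg$n_participants,
    participant_sd = ob$participant_sd,
    seed = derive_seed(cfg$seed, "observer"))
}

#' Build the experimental image set with assigned object scores
#'
#' Generates the norming corpus and its score table, then draws the
#' experimental images: real images follow the corpus occurrence model;
#' generated images follow a degraded model whose occurrence probabilities
#' are blended toward the category-average object profile with weight
#' `1 - gan_fidelity`, emulating the weaker object-co-occurrence structure
#' of GAN scenes. Each image set is passed through the simulated
#' segmentation network, filtered (probability > 0.3, structural elements
#' removed), scored against the corpus table, and z-scored within the full
#' image set. Durations (50/500 ms) are balanced within each category x
#' condition cell.
#'
#' @param config A [run_config()].
#' @return List: `images` (image table), `score_table`, `corpus`.
#' @export
make_image_set <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cs <- corpus_spec(
    n_categories = config$corpus$n_categories,
    objects_per_category = config$corpus$objects_per_category,
    n_scenes_per_category = config$corpus$n_scenes_per_category,
    seed = derive_seed(config$seed, "corpus"))
  corpus <- gen_corpus(cs)
  table <- compute_score_table(corpus)

  p <- cs$occurrence_probs
  p_gen <- config$gan_fidelity * p +
    (1 - config$gan_fidelity) * rowMeans(p)
  gen_spec <- corpus_spec(
    n_categories = cs$n_categories,
    objects_per_category = cs$objects_per_category,
    n_scenes_per_category = config$n_images_per_category,
    occurrence_probs = p_gen, anchor_flags = cs$anchor_flags,
    seed = derive_seed(config$seed, "generated-images"))
  real_spec <- corpus_spec(
    n_categories = cs$n_categories,
    objects_per_category = cs$objects_per_category,
    n_scenes_per_category = config$n_images_per_category,
    occurrence_probs = p, anchor_flags = cs$anchor_flags,
    seed = derive_seed(config$seed, "real-images"))

  seg <- config$segmentation
  score_images <- function(spec, condition, seg_seed) {
    imgs <- gen_corpus(spec)
    preds <- gen_segmentation(imgs, miss_rate = seg$miss_rate,
                              false_label_rate = seg$false_label_rate,
                              prob_noise_sd = seg$prob_noise_sd,
                              base_prob = seg$base_prob, seed = seg_seed)
    filt <- filter_predictions(preds)
    sc <- assign_scene_scores(filt, table)
    # keep every image, including those with no scored object
    sc <- merge(imgs$scene_index, sc[, setdiff(names(sc), "category")],
                by = "scene_id", all.x = TRUE)
    sc$anchor_score[is.na(sc$anchor_score)] <- 0
    sc$diag_score[is.na(sc$diag_score)] <- 0
    sc$image_id <- paste0(condition, "_", sc$scene_id)
    sc$condition <- condition
    sc
  }
  real <- score_images(real_spec, "real", derive_seed(config$seed, "seg-real"))
  gen <- score_images(gen_spec, "generated", derive_seed(config$seed, "seg-gen"))
  images <- rbind(real, gen)
  images$z_anchor <- z_transform(images$anchor_score)
  images$z_diag <- z_transform(images$diag_score)
  # balanced duration assignment within category x condition
  images <- images[order(images$condition, images$category, images$image_id), ]
  images$duration <- NA_character_
  for (ix in split(seq_len(nrow(images)),
                   paste(images$condition, images$category))) {
    images$duration[ix] <- rep_len(c("50", "500"), length(ix))
  }
  rownames(images) <- NULL
  list(images = images, score_table = table, corpus = corpus)
}

#' Run the discrimination experiment analysis end to end
#'
#' Synthesizes the Experiment-1 data and analyzes it: empirical ROC
#' curves and AUCs per presentation duration (pooled and per-participant),
#' bootstrap comparison of the two AUCs, per-image realness scores, the
#' probit regression of 2AFC responses on condition, duration, and object
#' scores (with the condition x duration and condition x diagnosticity
#' interactions and the per-condition diagnosticity trends), the linear
#' regression of realness ratings on object scores, and - optionally -
#' the layer-wise encoding analysis decoding mean ratings from synthetic
#' deep features with trained-versus-random inference.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, all result tables and a
#'   JSON run manifest are written there.
#' @return List of results (images, trials, roc, auc_test, realness,
#'   fit_2afc, trend_diag, fit_ratings, encoding, manifest).
#' @export
run_exp1 <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  imageset <- make_image_set(config)
  images <- imageset$images
  obs <- observer_from_config(config)
  trials <- simulate_2afc(images, obs)

  roc <- lapply(split(trials, trials$duration), empirical_roc)
  auc_pooled <- vapply(roc, function(r) attr(r, "auc"), numeric(1))
  auc_part <- lapply(split(trials, trials$duration), participant_auc)
  auc_mean <- vapply(auc_part, function(a) attr(a, "mean_auc"), numeric(1))

  auc_test <- auc_boot_test(
    trials[trials$duration == "500", ], trials[trials$duration == "50", ],
    n_boot = config$analysis$n_boot_auc,
    seed = derive_seed(config$seed, "auc-test"))

  realness <- image_realness(trials)

  design_2afc <- build_design(
    trials, factors = c("condition", "duration"),
    continuous = c("z_anchor", "z_diag"),
    interactions = list(c("condition", "duration"), c("condition", "z_diag")))
  fit_2afc <- fit_logistic(design_2afc, trials$response, link = "probit")
  trend_diag <- linear_trend(fit_2afc, "z_diag", "condition")

  gen_images <- images[images$condition == "generated", ]
  # the rating analysis set is the generated images only: re-standardize
  # the predictors within it so planted and recovered slopes share a scale
  gen_images$z_anchor <- z_transform(gen_images$anchor_score)
  gen_images$z_diag <- z_transform(gen_images$diag_score)
  rt <- config$ratings
  ratings <- simulate_ratings(gen_images, alpha = rt$alpha,
                              beta_anchor = rt$beta_anchor,
                              beta_diag = rt$beta_diag, noise_sd = rt$noise_sd,
                              participant_sd = rt$participant_sd,
                              n_participants = config$n_participants,
                              seed = derive_seed(config$seed, "ratings"))
  design_rat <- build_design(ratings, continuous = c("z_anchor", "z_diag"),
                             interactions = list(c("z_anchor", "z_diag")))
  fit_ratings <- fit_linear(design_rat, ratings$rating)

  encoding <- NULL
  if (isTRUE(config$run_encoding)) {
    mean_rating <- aggregate(rating ~ image_id, data = ratings, FUN = mean)
    mean_rating <- mean_rating[match(gen_images$image_id, mean_rating$image_id), ]
    ft <- config$features
    fspec <- feature_spec(n_layers = ft$n_layers,
                          dims_per_layer = ft$dims_per_layer,
                          snr_by_depth = ft$snr_profile, snr_max = ft$snr_max,
                          n_trained_models = ft$n_trained_models,
                          n_random_models = ft$n_random_models,
                          seed = derive_seed(config$seed, "features"))
    store <- gen_feature_store(mean_rating$rating, fspec)
    scores <- decode_feature_store(store, mean_rating$rating,
                                   alpha_grid = config$analysis$alpha_grid)
    binned <- bin_scores(scores, n_bins = config$analysis$n_bins)
    comparison <- compare_bins(binned, n_perm = config$analysis$n_perm,
                               n_boot = config$analysis$n_boot_ci,
                               prior_scale = config$analysis$prior_scale,
                               alpha = config$analysis$fdr_alpha,
                               seed = derive_seed(config$seed, "encoding"))
    encoding <- list(scores = scores, binned = binned, comparison = comparison)
  }

  result <- list(
    images = images, trials = trials, score_table = imageset$score_table,
    roc = roc, auc_pooled = auc_pooled, auc_participant_mean = auc_mean,
    auc_test = auc_test, realness = realness,
    fit_2afc = fit_2afc, trend_diag = trend_diag, fit_ratings = fit_ratings,
    ratings = ratings, encoding = encoding,
    manifest = run_manifest(config, "exp1"))
  if (!is.null(out_dir)) write_report(result, out_dir)
  invisible(result)
}

#' Run the categorization experiment analysis end to end
#'
#' Synthesizes the Experiment-2 data and analyzes it: simulates 5-AFC
#' scene categorization driven by diagnosticity, per-image realness
#' (taken from Experiment-1 responses, regenerated if not supplied), and
#' presentation duration, then fits the chance-floor logistic regression
#' of accuracy on condition, duration, realness, diagnosticity, and
#' anchor scores. Optionally decodes per-image accuracy from synthetic
#' deep features.
#'
#' @param config A [run_config()].
#' @param realness Optional realness table from [run_exp1()]'s output;
#'   regenerated from the same seeds when NULL.
#' @param out_dir Optional output directory.
#' @return List of results (images, trials, fit_5afc, accuracy, encoding,
#'   manifest).
#' @export
run_exp2 <- function(config = run_config(), realness = NULL, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  imageset <- make_image_set(config)
  images <- imageset$images
  if (is.null(realness)) {
    trials1 <- simulate_2afc(images, observer_from_config(config))
    realness <- image_realness(trials1)
  }
  key <- paste(images$image_id, images$duration)
  images$realness <- realness$realness[match(key, paste(realness$image_id,
                                                        realness$duration))]
  images <- images[!is.na(images$realness), ]
  images$z_realness <- z_transform(images$realness)

  afc <- config$afc
  trials <- simulate_5afc(images, b0 = afc$b0, b_diag = afc$b_diag,
                          b_realness = afc$b_realness,
                          b_duration = afc$b_duration,
                          n_participants = config$n_participants,
                          participant_sd = afc$participant_sd,
                          seed = derive_seed(config$seed, "5afc"))
  trials$condition <- images$condition[match(trials$image_id, images$image_id)]
  trials$z_anchor <- images$z_anchor[match(trials$image_id, images$image_id)]

  design <- build_design(trials, factors = c("condition", "duration"),
                         continuous = c("z_diag", "z_realness", "z_anchor"))
  fit_5afc <- fit_logistic(design, trials$correct, link = "logit", guess = 0.2)

  accuracy <- aggregate(correct ~ image_id, data = trials, FUN = mean)
  names(accuracy)[2] <- "accuracy"

  encoding <- NULL
  if (isTRUE(config$run_encoding)) {
    acc <- accuracy$accuracy[match(images$image_id, accuracy$image_id)]
    ft <- config$features
    fspec <- feature_spec(n_layers = ft$n_layers,
                          dims_per_layer = ft$dims_per_layer,
                          snr_by_depth = ft$snr_profile, snr_max = ft$snr_max,
                          n_trained_models = ft$n_trained_models,
                          n_random_models = ft$n_random_models,
                          seed = derive_seed(config$seed, "features-exp2"))
    store <- gen_feature_store(acc, fspec)
    scores <- decode_feature_store(store, acc,
                                   alpha_grid = config$analysis$alpha_grid)
    binned <- bin_scores(scores, n_bins = config$analysis$n_bins)
    comparison <- compare_bins(binned, n_perm = config$analysis$n_perm,
                               n_boot = config$analysis$n_boot_ci,
                               prior_scale = config$analysis$prior_scale,
                               alpha = config$analysis$fdr_alpha,
                               seed = derive_seed(config$seed, "encoding-exp2"))
    encoding <- list(scores = scores, binned = binned, comparison = comparison)
  }

  result <- list(images = images, trials = trials, fit_5afc = fit_5afc,
                 accuracy = accuracy, encoding = encoding,
                 manifest = run_manifest(config, "exp2"))
  if (!is.null(out_dir)) write_report(result, out_dir)
  invisible(result)
}

run_manifest <- function(config, experiment) {
  cfg <- unclass(config)
  list(experiment = experiment, config = cfg,
       package_version = as.character(utils::packageVersion("scenecue")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a run's result tables and manifest to a directory
#'
#' Writes every tabular element of a [run_exp1()]/[run_exp2()] result as
#' CSV plus the manifest (config echo, seeds, version) as JSON, so any
#' output can be regenerated from the manifest alone.
#'
#' @param result Result list from a run function.
#' @param out_dir Directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(obj, name) {
    p <- file.path(out_dir, paste0(name, ".csv"))
    write.csv(obj, p, row.names = FALSE)
    paths <<- c(paths, p)
  }
  if (!is.null(result$images)) emit(result$images, "images")
  if (!is.null(result$score_table)) emit(result$score_table, "score_table")
  if (!is.null(result$realness)) emit(result$realness, "realness")
  if (!is.null(result$accuracy)) emit(result$accuracy, "accuracy")
  for (nm in c("fit_2afc", "fit_ratings", "fit_5afc")) {
    if (!is.null(result[[nm]])) emit(result[[nm]]$coefficients, nm)
  }
  if (!is.null(result$trend_diag)) emit(result$trend_diag, "trend_diag")
  if (!is.null(result$roc)) {
    for (d in names(result$roc)) emit(as.data.frame(result$roc[[d]]),
                                      paste0("roc_", d, "ms"))
  }
  if (!is.null(result$encoding)) {
    emit(result$encoding$scores, "decoding_scores")
    emit(result$encoding$comparison, "bin_comparison")
  }
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(result$manifest, mp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, mp))
}
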
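test_that("corpus generation respects degenerate occurrence probabilities", {
  p1 <- matrix(1, 4, 2, dimnames = list(paste0("o", 1:4), c("a", "b")))
  spec <- corpus_spec(n_categories = 2, objects_per_category = 2,
                      n_scenes_per_category = 5, occurrence_probs = p1,
                      categories = c("a", "b"), seed = 7)
  corp <- gen_corpus(spec)
  # probability 1: every scene contains every object
  expect_equal(nrow(corp$scenes), 4 * 10)
  counts <- table(corp$scenes$scene_id)
  expect_true(all(counts == 4))

  p0 <- p1 * 0; p0[1, ] <- 1e-12  # validator needs nonzero support
  spec0 <- corpus_spec(n_categories = 2, objects_per_category = 2,
                       n_scenes_per_category = 5, occurrence_probs = p0,
                       categories = c("a", "b"), seed = 7)
  corp0 <- gen_corpus(spec0)
  expect_true(is.null(corp0$scenes) || nrow(corp0$scenes) == 0)
  expect_equal(nrow(corp0$scene_index), 10)  # empty scenes retained
})

test_that("observed object frequencies converge to occurrence probabilities", {
  p <- matrix(c(0.9, 0.4), 2, 1, dimnames = list(c("sink", "cup"), "kitchen"))
  spec <- corpus_spec(n_categories = 1, objects_per_category = 2,
                      n_scenes_per_category = 200, occurrence_probs = p,
                      categories = "kitchen", seed = 11)
  corp <- gen_corpus(spec)
  freq <- mean(corp$scene_index$scene_id %in%
                 corp$scenes$scene_id[corp$scenes$object == "sink"])
  bounds <- binom_bounds(0.9, 200)
  expect_gte(freq, bounds[1])
  expect_lte(freq, bounds[2])
})

test_that("corpus generation is deterministic and streams are disjoint", {
  spec <- corpus_spec(seed = 42, n_scenes_per_category = 20)
  expect_identical(gen_corpus(spec), gen_corpus(spec))
  spec2 <- corpus_spec(seed = 43, n_scenes_per_category = 20)
  expect_false(identical(gen_corpus(spec)$scenes, gen_corpus(spec2)$scenes))
  # generating a corpus must not disturb the caller's RNG stream
  set.seed(99); before <- rnorm(1)
  set.seed(99); invisible(gen_corpus(spec)); after <- rnorm(1)
  expect_identical(before, after)
})

test_that("noiseless segmentation is the identity and miss_rate removes truth", {
  corp <- gen_corpus(corpus_spec(seed = 5, n_scenes_per_category = 10))
  preds <- gen_segmentation(corp, miss_rate = 0, false_label_rate = 0,
                            prob_noise_sd = 0, base_prob = 1, seed = 1)
  expect_equal(nrow(preds), nrow(corp$scenes))
  expect_true(all(preds$prob == 1))
  expect_setequal(paste(preds$scene_id, preds$object),
                  paste(corp$scenes$scene_id, corp$scenes$object))

  only_spurious <- gen_segmentation(corp, miss_rate = 1, false_label_rate = 0.1,
                                    seed = 1)
  expect_true(all(!only_spurious$is_true))
})

test_that("segmentation retention count stays within its binomial interval", {
  corp <- gen_corpus(corpus_spec(seed = 6, n_scenes_per_category = 60))
  n_true <- nrow(corp$scenes)
  preds <- gen_segmentation(corp, miss_rate = 0.2, false_label_rate = 0, seed = 2)
  bounds <- binom_bounds(0.8, n_true)
  expect_gte(sum(preds$is_true) / n_true, bounds[1])
  expect_lte(sum(preds$is_true) / n_true, bounds[2])
})

test_that("a zero-sensitivity symmetric observer responds 'real' half the time", {
  spec <- observer_spec(d_prime_by_duration = c("500" = 0), beta_anchor = 0,
                        beta_diag_by_condition = c(real = 0, generated = 0),
                        criterion_centers = seq(-1.5, 1.5, by = 0.3),
                        n_participants = 20, participant_sd = 0, seed = 3)
  trials <- simulate_2afc(flat_images(250), spec)
  for (cond in c("real", "generated")) {
    pr <- mean(trials$response[trials$condition == cond])
    bounds <- binom_bounds(0.5, sum(trials$condition == cond))
    expect_gte(pr, bounds[1]); expect_lte(pr, bounds[2])
  }
})

test_that("2AFC simulation validates inputs and produces a coherent scale", {
  spec <- observer_spec(seed = 3)
  imgs <- flat_images(5)
  expect_error(simulate_2afc(imgs[, -4], spec), "z_anchor")
  bad <- imgs; bad$duration <- "250"
  expect_error(simulate_2afc(bad, spec), "duration")
  trials <- simulate_2afc(flat_images(30, duration = "50"), spec)
  expect_true(all(trials$scale %in% 1:12))
  # the ordinal scale must agree with the response/confidence mapping
  expect_identical(trials$scale,
                   confidence_scale(trials$response, trials$confidence))
})

test_that("rating simulation honours degenerate settings and clipping", {
  imgs <- flat_images(10)[1:10, ]; imgs$condition <- "generated"
  flat <- simulate_ratings(imgs, alpha = 3, beta_anchor = 0, beta_diag = 0,
                           noise_sd = 0, participant_sd = 0,
                           n_participants = 4, seed = 1)
  expect_true(all(flat$rating == 3))
  high <- simulate_ratings(imgs, alpha = 10, beta_anchor = 0, beta_diag = 0,
                           noise_sd = 0, participant_sd = 0,
                           n_participants = 4, seed = 1)
  expect_true(all(high$rating == 6))
  real_imgs <- imgs; real_imgs$condition <- "real"
  expect_error(simulate_ratings(real_imgs), "generated")
})

test_that("planted anchor effects yield a positive rating correlation", {
  imgs <- data.frame(image_id = paste0("g", 1:150), condition = "generated",
                     z_anchor = rnorm(150), z_diag = 0)
  imgs$z_anchor <- z_transform(imgs$z_anchor)
  trials <- simulate_ratings(imgs, alpha = 3, beta_anchor = 0.5, beta_diag = 0,
                             noise_sd = 0.3, participant_sd = 0,
                             n_participants = 10, seed = 4)
  mr <- aggregate(rating ~ image_id, trials, mean)
  mr$z_anchor <- imgs$z_anchor[match(mr$image_id, imgs$image_id)]
  ct <- cor.test(mr$rating, mr$z_anchor, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.01)
})

test_that("5-AFC accuracy spans chance floor to ceiling with the linear predictor", {
  imgs <- data.frame(image_id = paste0("i", 1:40),
                     category = rep(c("a", "b", "c", "d", "e"), 8),
                     duration = "50", z_diag = 0, z_realness = 0)
  floor_trials <- simulate_5afc(imgs, b0 = -30, b_diag = 0, b_realness = 0,
                                b_duration = 0, n_participants = 40,
                                participant_sd = 0, seed = 2)
  bounds <- binom_bounds(0.2, nrow(floor_trials))
  expect_gte(mean(floor_trials$correct), bounds[1])
  expect_lte(mean(floor_trials$correct), bounds[2])
  # wrong answers are spread over the other four categories
  wrong <- floor_trials[floor_trials$correct == 0, ]
  expect_true(all(wrong$choice != wrong$category))
  ceiling_trials <- simulate_5afc(imgs, b0 = 30, b_diag = 0, b_realness = 0,
                                  b_duration = 0, n_participants = 10,
                                  participant_sd = 0, seed = 2)
  expect_equal(mean(ceiling_trials$correct), 1)
})

test_that("feature stores have the declared geometry and depth signal", {
  fs <- feature_spec(n_layers = 5, dims_per_layer = 12, snr_by_depth = "linear",
                     snr_max = 2, n_trained_models = 2, n_random_models = 2,
                     seed = 9)
  y <- rnorm(30)
  st <- gen_feature_store(y, fs)
  expect_equal(sort(unique(st$layers$depth)), (0:4) / 4)
  expect_equal(dim(st$features$trained_1$layer_3), c(30, 12))
  # random instances are pure noise: expected correlation with y ~ 0
  rs <- vapply(1:5, function(l) {
    x <- st$features$random_1[[l]]
    max(abs(cor(x, y)))
  }, numeric(1))
  expect_lt(mean(rs), 4 / sqrt(30))

  # planted monotone SNR: signal-to-noise of the best feature grows with depth
  cors <- vapply(1:5, function(l)
    max(abs(cor(st$features$trained_1[[l]], y))), numeric(1))
  expect_gt(cor(cors, (0:4) / 4, method = "spearman"), 0)
})

test_that("decoding strength increases with depth for planted linear SNR", {
  # property over repeated seeds: Spearman rho of layer decoding r vs depth
  rhos <- vapply(1:8, function(s) {
    fs <- feature_spec(n_layers = 5, dims_per_layer = 15,
                       snr_by_depth = "linear", snr_max = 2,
                       n_trained_models = 1, n_random_models = 1, seed = s)
    y <- with_seed_test(s, rnorm(60))
    st <- gen_feature_store(y, fs)
    sc <- decode_feature_store(st, y)
    tr <- sc[sc$group == "trained", ]
    cor(tr$r, tr$depth, method = "spearman")
  }, numeric(1))
  expect_lt(wilcox.test(rhos, alternative = "greater", exact = FALSE)$p.value,
            0.05)
})
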
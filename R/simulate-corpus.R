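#' Generate a labeled object-scene corpus
#'
#' Draws `n_scenes_per_category` scenes per category; each object enters a
#' scene independently with its `occurrence_probs` entry, and a present
#' object is flagged as functioning as an anchor with its `anchor_flags`
#' probability. Scenes that end up with no objects are retained with an
#' empty object list (downstream code must handle them).
#'
#' @param spec A [corpus_spec()].
#' @param n_scenes_per_category Optional override of the spec's value.
#' @param seed Optional override of the spec's seed.
#' @return A `labeled_corpus`: list with `scenes` (long data frame:
#'   scene_id, category, object, is_anchor), `scene_index` (scene_id,
#'   category - includes empty scenes), `objects`, `categories`, `spec`.
#' @export
gen_corpus <- function(spec, n_scenes_per_category = NULL, seed = NULL) {
  stopifnot(inherits(spec, "corpus_spec"))
  n_sc <- n_scenes_per_category %||% spec$n_scenes_per_category
  seed <- seed %||% spec$seed
  probs <- spec$occurrence_probs
  aflags <- spec$anchor_flags

  with_seed(derive_seed(seed, "corpus-draw"), {
    rows <- vector("list", length(spec$categories))
    idx <- vector("list", length(spec$categories))
    for (ci in seq_along(spec$categories)) {
      ct <- spec$categories[ci]
      ids <- sprintf("%s_%04d", ct, seq_len(n_sc))
      idx[[ci]] <- data.frame(scene_id = ids, category = ct,
                              stringsAsFactors = FALSE)
      # occupancy: objects x scenes Bernoulli draws
      present <- matrix(runif(length(spec$objects) * n_sc), ncol = n_sc) <
        probs[, ci]
      anch <- matrix(runif(length(spec$objects) * n_sc), ncol = n_sc) <
        aflags[, ci]
      hit <- which(present, arr.ind = TRUE)
      if (nrow(hit)) {
        rows[[ci]] <- data.frame(
          scene_id = ids[hit[, 2]],
          category = ct,
          object = spec$objects[hit[, 1]],
          is_anchor = anch[hit],
          stringsAsFactors = FALSE)
      }
    }
    scenes <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(scenes)) {
      scenes <- data.frame(scene_id = character(0), category = character(0),
                           object = character(0), is_anchor = logical(0))
    }
    scene_index <- do.call(rbind, idx)
    scenes <- scenes[order(scenes$scene_id), , drop = FALSE]
    rownames(scenes) <- NULL
    structure(list(scenes = scenes, scene_index = scene_index,
                   objects = spec$objects, categories = spec$categories,
                   spec = spec),
              class = "labeled_corpus")
  })
}

#' @export
print.labeled_corpus <- function(x, ...) {
  cat(sprintf("Labeled corpus: %d scenes in %d categories, %d object labels\n",
              nrow(x$scene_index), length(x$categories), length(x$objects)))
  cat(sprintf("  %d object occurrences (%.1f per scene); %.1f%% flagged anchor\n",
              nrow(x$scenes), nrow(x$scenes) / nrow(x$scene_index),
              100 * mean(x$scenes$is_anchor)))
  invisible(x)
}

# Default structural elements a segmentation network emits for indoor
# scenes; excluded from object scoring downstream.
STRUCTURAL_ELEMENTS <- c("window", "wall", "floor", "door")

#' Simulate noisy scene-segmentation predictions
#'
#' Emulates a pretrained segmentation network's per-image output: a list of
#' (object label, probability) pairs. True objects are dropped with
#' `miss_rate`; spurious labels - structural elements (windows, walls,
#' floor, doors) and objects foreign to the scene - are injected with
#' `false_label_rate` each; predicted probabilities are base probability
#' plus Gaussian noise, clipped to \[0, 1\].
#'
#' @param corpus A `labeled_corpus` (truth to corrupt).
#' @param miss_rate Probability a true object is missed.
#' @param false_label_rate Per-candidate probability of a spurious label.
#' @param prob_noise_sd SD of the Gaussian probability noise.
#' @param base_prob Base predicted probability for true objects.
#' @param spurious_base_prob Base probability for spurious labels.
#' @param seed Integer seed.
#' @return A data frame (class `segmentation_predictions`): scene_id,
#'   category, object, prob, is_true.
#' @export
gen_segmentation <- function(corpus, miss_rate = 0.1, false_label_rate = 0.05,
                             prob_noise_sd = 0.1, base_prob = 0.75,
                             spurious_base_prob = 0.55, seed = 1L) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  if (miss_rate < 0 || miss_rate > 1 || false_label_rate < 0 || false_label_rate > 1) {
    stopf("miss_rate and false_label_rate must lie in [0, 1]")
  }
  with_seed(derive_seed(seed, "segmentation"), {
    truth <- corpus$scenes
    keep <- runif(nrow(truth)) >= miss_rate
    kept <- truth[keep, c("scene_id", "category", "object"), drop = FALSE]
    if (nrow(kept)) {
      kept$prob <- pmin(pmax(base_prob + rnorm(nrow(kept), 0, prob_noise_sd), 0), 1)
      kept$is_true <- TRUE
    } else {
      kept$prob <- numeric(0); kept$is_true <- logical(0)
    }

    spurious <- NULL
    if (false_label_rate > 0) {
      pool <- union(STRUCTURAL_ELEMENTS, corpus$objects)
      sc <- corpus$scene_index
      n_cand <- nrow(sc) * length(pool)
      hits <- which(runif(n_cand) < false_label_rate)
      if (length(hits)) {
        si <- ((hits - 1L) %% nrow(sc)) + 1L
        oi <- ((hits - 1L) %/% nrow(sc)) + 1L
        spurious <- data.frame(
          scene_id = sc$scene_id[si], category = sc$category[si],
          object = pool[oi],
          prob = pmin(pmax(spurious_base_prob +
                             rnorm(length(hits), 0, prob_noise_sd), 0), 1),
          is_true = FALSE, stringsAsFactors = FALSE)
        # don't duplicate an object already truly present in the scene
        key <- paste(spurious$scene_id, spurious$object)
        spurious <- spurious[!key %in% paste(kept$scene_id, kept$object), ,
                             drop = FALSE]
      }
    }
    preds <- rbind(kept, spurious)
    preds <- preds[order(preds$scene_id), , drop = FALSE]
    rownames(preds) <- NULL
    class(preds) <- c("segmentation_predictions", "data.frame")
    preds
  })
}
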
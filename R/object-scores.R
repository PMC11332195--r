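#' Compute diagnosticity and anchor-status-frequency tables
#'
#' From a labeled corpus, computes for every (object, category) pair that
#' occurs at least once:
#' \describe{
#'   \item{diagnosticity}{P(category | object present) = number of scenes
#'     of that category containing the object / number of scenes anywhere
#'     containing it.}
#'   \item{anchor_freq}{P(object functions as anchor | present in a scene
#'     of that category) = number of category scenes where it is flagged
#'     anchor / number of category scenes containing it.}
#' }
#' Pairs never observed are absent from the table, so later lookups yield
#' an explicit missing value rather than a silent zero.
#'
#' @param corpus A `labeled_corpus` with per-occurrence anchor flags.
#' @return A data frame (class `score_table`): object, category,
#'   diagnosticity, anchor_freq, n_in_category (support), n_total.
#' @export
compute_score_table <- function(corpus) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  sc <- corpus$scenes
  if (is.null(sc) || nrow(sc) == 0) stopf("corpus contains no object occurrences")
  assert_cols(sc, c("scene_id", "category", "object", "is_anchor"), "corpus$scenes")

  # one row per (scene, object): present, and anchor if flagged anywhere
  occ <- aggregate(is_anchor ~ scene_id + category + object,
                   data = transform(sc, is_anchor = as.integer(is_anchor)),
                   FUN = max)
  by_pair <- aggregate(cbind(n_in_category = one) ~ object + category,
                       data = transform(occ, one = 1L), FUN = sum)
  anch <- aggregate(cbind(n_anchor = is_anchor) ~ object + category,
                    data = occ, FUN = sum)
  tab <- merge(by_pair, anch, by = c("object", "category"))
  tot <- aggregate(cbind(n_total = n_in_category) ~ object, data = by_pair,
                   FUN = sum)
  tab <- merge(tab, tot, by = "object")
  tab$diagnosticity <- tab$n_in_category / tab$n_total
  tab$anchor_freq <- tab$n_anchor / tab$n_in_category
  tab <- tab[order(tab$object, tab$category),
             c("object", "category", "diagnosticity", "anchor_freq",
               "n_in_category", "n_total")]
  rownames(tab) <- NULL
  attr(tab, "categories") <- sort(unique(corpus$scene_index$category))
  class(tab) <- c("score_table", "data.frame")
  tab
}

#' Filter segmentation predictions by probability and structural elements
#'
#' Keeps predicted objects whose probability strictly exceeds `threshold`
#' (default 0.3) and whose label is not a structural element (default set:
#' window, wall, floor, door). Input order is preserved.
#'
#' @param preds Data frame with at least `object` and `prob` columns.
#' @param threshold Strict probability cutoff.
#' @param structural Character vector of labels to remove; extensible but
#'   minimal by default.
#' @return The filtered predictions, same class and columns.
#' @export
filter_predictions <- function(preds, threshold = 0.3,
                               structural = STRUCTURAL_ELEMENTS) {
  assert_cols(preds, c("object", "prob"), "predictions")
  if (any(preds$prob < 0 | preds$prob > 1, na.rm = TRUE)) {
    stopf("prediction probabilities must lie in [0, 1]")
  }
  keep <- preds$prob > threshold & !(preds$object %in% structural)
  out <- preds[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Assign per-scene anchor and diagnosticity scores
#'
#' For each scene, the anchor score is the maximum anchor-status frequency
#' over its (filtered) predicted objects, looked up under the scene's
#' nominal category; the diagnosticity score is the corresponding maximum
#' of diagnosticity. Objects absent from the table for that category
#' contribute nothing (absent evidence is not evidence of absence); if no
#' object survives, both scores are 0 and the scene is flagged.
#'
#' @param preds Filtered `segmentation_predictions` (or any data frame
#'   with scene_id, object; a `category` column or the `category`
#'   argument supplies the nominal category).
#' @param table A `score_table` from [compute_score_table()].
#' @param category Optional single category applied to all scenes;
#'   otherwise taken per scene from `preds$category`.
#' @return Data frame (class `scene_scores`): scene_id, category,
#'   anchor_score, diag_score, anchor_object, diag_object,
#'   n_objects_after_filter, empty (flag).
#' @export
assign_scene_scores <- function(preds, table, category = NULL) {
  stopifnot(inherits(table, "score_table"))
  assert_cols(preds, c("scene_id", "object"), "predictions")
  if (!is.null(category)) preds$category <- category
  assert_cols(preds, "category", "predictions")
  known <- attr(table, "categories") %||% unique(table$category)
  bad <- setdiff(unique(preds$category), known)
  if (length(bad)) stopf("unknown categor%s: %s",
                         if (length(bad) > 1) "ies" else "y",
                         paste(bad, collapse = ", "))

  key <- paste(preds$object, preds$category, sep = "\r")
  tkey <- paste(table$object, table$category, sep = "\r")
  m <- match(key, tkey)
  preds$.anchor <- table$anchor_freq[m]
  preds$.diag <- table$diagnosticity[m]

  ids <- unique(preds$scene_id)
  out <- data.frame(scene_id = ids, category = preds$category[match(ids, preds$scene_id)],
                    anchor_score = 0, diag_score = 0,
                    anchor_object = NA_character_, diag_object = NA_character_,
                    n_objects_after_filter = 0L, empty = TRUE,
                    stringsAsFactors = FALSE)
  split_idx <- split(seq_len(nrow(preds)), preds$scene_id)
  for (i in seq_along(ids)) {
    ri <- split_idx[[ids[i]]]
    out$n_objects_after_filter[i] <- length(ri)
    a <- preds$.anchor[ri]; d <- preds$.diag[ri]
    if (any(!is.na(a))) {
      j <- ri[which.max(ifelse(is.na(a), -Inf, a))]
      out$anchor_score[i] <- preds$.anchor[j]
      out$anchor_object[i] <- preds$object[j]
      out$empty[i] <- FALSE
    }
    if (any(!is.na(d))) {
      j <- ri[which.max(ifelse(is.na(d), -Inf, d))]
      out$diag_score[i] <- preds$.diag[j]
      out$diag_object[i] <- preds$object[j]
      out$empty[i] <- FALSE
    }
  }
  class(out) <- c("scene_scores", "data.frame")
  out
}

#' z-transform a numeric vector
#'
#' Centers to mean 0 and rescales to sample SD 1, as done for all
#' continuous predictors before regression. Standardization is applied
#' within each analysis set, not globally.
#'
#' @param values Numeric vector with at least 2 distinct finite values.
#' @return The standardized vector.
#' @export
z_transform <- function(values) {
  if (!is.numeric(values)) stopf("values must be numeric")
  s <- sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) {
    stopf("degenerate input: z_transform requires at least 2 distinct values")
  }
  (values - mean(values, na.rm = TRUE)) / s
}
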
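#' Generate a synthetic layer-wise feature store
#'
#' For every model instance and layer, features are
#' X = s(depth) * y w' + E, with y the (standardized) per-image behavioral
#' score, w a random unit direction fixed per model instance (so layers of
#' one model share signal geometry, as layers of a real network do), and E
#' iid standard Gaussian noise. Random-initialization instances have
#' s = 0 at every depth. Layer depth is l/(L-1), from 0 (earliest) to 1
#' (deepest).
#'
#' @param image_scores Numeric vector, one behavioral score per image.
#' @param spec A [feature_spec()].
#' @return A `feature_store`: list with `features` (nested list
#'   `[[model]][[layer]]` of image x feature matrices), `layers` (data
#'   frame: model, group, trained, layer, depth, dim), `n_images`.
#' @export
gen_feature_store <- function(image_scores, spec) {
  stopifnot(inherits(spec, "feature_spec"))
  y <- as.numeric(image_scores)
  if (any(!is.finite(y))) stopf("image_scores must be finite")
  n <- length(y)
  ys <- if (sd(y) > 0) (y - mean(y)) / sd(y) else y * 0
  depths <- (seq_len(spec$n_layers) - 1) / (spec$n_layers - 1)
  s_depth <- spec$snr_fun(depths)

  with_seed(derive_seed(spec$seed, "feature-store"), {
    models <- c(paste0("trained_", seq_len(spec$n_trained_models)),
                paste0("random_", seq_len(spec$n_random_models)))
    trained <- c(rep(TRUE, spec$n_trained_models),
                 rep(FALSE, spec$n_random_models))
    features <- vector("list", length(models))
    names(features) <- models
    meta <- NULL
    for (mi in seq_along(models)) {
      layer_list <- vector("list", spec$n_layers)
      # one master signal direction per model instance: layers share its
      # leading coordinates, so within-model layers are correlated
      w_master <- rnorm(max(spec$dims_per_layer))
      for (li in seq_len(spec$n_layers)) {
        p <- spec$dims_per_layer[li]
        w <- w_master[seq_len(p)]; w <- w / sqrt(sum(w^2))
        s <- if (trained[mi]) s_depth[li] else 0
        X <- s * tcrossprod(ys, w) + matrix(rnorm(n * p), n, p)
        layer_list[[li]] <- X
      }
      names(layer_list) <- paste0("layer_", seq_len(spec$n_layers))
      features[[mi]] <- layer_list
      meta <- rbind(meta, data.frame(
        model = models[mi],
        group = if (trained[mi]) "trained" else "random",
        trained = trained[mi],
        layer = paste0("layer_", seq_len(spec$n_layers)),
        depth = depths,
        dim = spec$dims_per_layer,
        stringsAsFactors = FALSE))
    }
    rownames(meta) <- NULL
    structure(list(features = features, layers = meta, n_images = n),
              class = "feature_store")
  })
}

#' @export
print.feature_store <- function(x, ...) {
  cat(sprintf("Feature store: %d images, %d model instances (%d trained, %d random), %d layers each\n",
              x$n_images, length(x$features),
              sum(!duplicated(x$layers$model) & x$layers$trained[!duplicated(x$layers$model)]),
              sum(!duplicated(x$layers$model) & !x$layers$trained[!duplicated(x$layers$model)]),
              max(as.integer(sub("layer_", "", x$layers$layer)))))
  invisible(x)
}
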
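#' Read and write pipeline tables
#'
#' The pipeline's on-disk formats are plain delimited text. A labeled
#' corpus is two CSVs (`<stem>_scenes.csv`: scene_id, category, object,
#' is_anchor; `<stem>_index.csv`: scene_id, category, listing every scene
#' including empty ones). Trial tables, score tables and segmentation
#' predictions are single CSVs with the column schemas produced by their
#' generating functions.
#'
#' @param corpus A `labeled_corpus`.
#' @param stem File path stem (without extension).
#' @return `write_corpus_csv` invisibly returns the paths written;
#'   `read_corpus_csv` returns a `labeled_corpus`.
#' @export
write_corpus_csv <- function(corpus, stem) {
  stopifnot(inherits(corpus, "labeled_corpus"))
  p1 <- paste0(stem, "_scenes.csv"); p2 <- paste0(stem, "_index.csv")
  write.csv(corpus$scenes, p1, row.names = FALSE)
  write.csv(corpus$scene_index, p2, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_corpus_csv
#' @export
read_corpus_csv <- function(stem) {
  scenes <- read.csv(paste0(stem, "_scenes.csv"), stringsAsFactors = FALSE)
  index <- read.csv(paste0(stem, "_index.csv"), stringsAsFactors = FALSE)
  assert_cols(scenes, c("scene_id", "category", "object", "is_anchor"),
              "corpus scenes file")
  assert_cols(index, c("scene_id", "category"), "corpus index file")
  structure(list(scenes = scenes, scene_index = index,
                 objects = sort(unique(scenes$object)),
                 categories = sort(unique(index$category)), spec = NULL),
            class = "labeled_corpus")
}

#' Write and read a feature store as delimited text
#'
#' One CSV per (model, layer) under `dir`, named
#' `<model>__<layer>.csv` (images x features, no header index column),
#' plus `layers.csv` holding the metadata table (model, group, trained,
#' layer, depth, dim).
#'
#' @param store A `feature_store`.
#' @param dir Directory (created if missing).
#' @return `write_feature_store` invisibly returns `dir`;
#'   `read_feature_store` returns a `feature_store`.
#' @export
write_feature_store <- function(store, dir) {
  stopifnot(inherits(store, "feature_store"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(store$layers, file.path(dir, "layers.csv"), row.names = FALSE)
  for (k in seq_len(nrow(store$layers))) {
    m <- store$layers$model[k]; l <- store$layers$layer[k]
    utils::write.table(store$features[[m]][[l]],
                       file.path(dir, paste0(m, "__", l, ".csv")),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_feature_store
#' @export
read_feature_store <- function(dir) {
  layers <- read.csv(file.path(dir, "layers.csv"), stringsAsFactors = FALSE)
  features <- list()
  n_images <- NULL
  for (k in seq_len(nrow(layers))) {
    m <- layers$model[k]; l <- layers$layer[k]
    xm <- as.matrix(read.csv(file.path(dir, paste0(m, "__", l, ".csv")),
                             header = FALSE))
    dimnames(xm) <- NULL
    if (is.null(features[[m]])) features[[m]] <- list()
    features[[m]][[l]] <- xm
    n_images <- nrow(xm)
  }
  structure(list(features = features, layers = layers, n_images = n_images),
            class = "feature_store")
}

#' Round-trip a run configuration through JSON or YAML
#'
#' @param config A [run_config()].
#' @param path Target file; format chosen by extension (.json or
#'   .yml/.yaml; YAML requires the optional yaml package).
#' @return `write_run_config` invisibly returns `path`;
#'   `read_run_config` returns a `run_config`.
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("the yaml package is needed for YAML configs")
    }
    yaml::write_yaml(unclass(config), path)
  } else {
    jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stopf("the yaml package is needed for YAML configs")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  do.call(run_config, c(list(seed = raw$seed),
                        raw[setdiff(names(raw), "seed")]))
}
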
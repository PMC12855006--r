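## Core typed containers: modality blocks, multimodal datasets, annotation
## tables, split assignments and ontology maps. Plain S3 on lists/data.frames,
## in the style of lightweight Bioconductor-adjacent tooling.

#' Create a modality block
#'
#' A modality block holds one sample-by-feature numeric matrix (samples as
#' rows) together with its identifiers. Image modalities additionally carry a
#' manifest describing, per sample, the image source and its
#' channels/height/width; only square images (H = W) are accepted.
#'
#' @param name modality identifier.
#' @param matrix numeric matrix, `n_samples x k_features`. For images, rows are
#'   flattened channel-major pixel vectors.
#' @param kind one of `"numeric"`, `"categorical"`, `"image"`.
#' @param sample_ids,feature_ids ordered identifiers; default to dimnames.
#' @param image_manifest for `kind = "image"`: a data.frame with columns
#'   `sample_id`, `path`, `channels`, `height`, `width` covering every sample.
#' @return an object of class `modality_block`.
#' @export
modality_block <- function(name, matrix, kind = c("numeric", "categorical", "image"),
                           sample_ids = rownames(matrix),
                           feature_ids = colnames(matrix),
                           image_manifest = NULL) {
  kind <- match.arg(kind)
  matrix <- as.matrix(matrix)
  if (is.null(sample_ids)) stop("modality '", name, "': sample_ids required")
  if (is.null(feature_ids)) feature_ids <- paste0("f", seq_len(ncol(matrix)))
  sample_ids <- as.character(sample_ids)
  feature_ids <- as.character(feature_ids)
  if (nrow(matrix) != length(sample_ids)) {
    stop("modality '", name, "': matrix has ", nrow(matrix),
         " rows but ", length(sample_ids), " sample_ids")
  }
  if (ncol(matrix) != length(feature_ids)) {
    stop("modality '", name, "': matrix has ", ncol(matrix),
         " columns but ", length(feature_ids), " feature_ids")
  }
  if (anyDuplicated(feature_ids)) {
    stop("modality '", name, "': duplicated feature_ids")
  }
  if (anyDuplicated(sample_ids)) {
    stop("modality '", name, "': duplicated sample_ids")
  }
  if (kind == "image") {
    if (is.null(image_manifest)) {
      stop("modality '", name, "': image modality requires image_manifest")
    }
    need <- c("sample_id", "channels", "height", "width")
    if (!all(need %in% names(image_manifest))) {
      stop("image_manifest must have columns sample_id, channels, height, width")
    }
    if (!all(sample_ids %in% image_manifest$sample_id)) {
      stop("modality '", name, "': image_manifest does not cover every sample")
    }
    if (any(image_manifest$height != image_manifest$width)) {
      stop("modality '", name, "': only quadratic images (H = W) are supported")
    }
  }
  rownames(matrix) <- sample_ids
  colnames(matrix) <- feature_ids
  structure(list(name = name, kind = kind, matrix = matrix,
                 sample_ids = sample_ids, feature_ids = feature_ids,
                 image_manifest = image_manifest),
            class = "modality_block")
}

#' @export
print.modality_block <- function(x, ...) {
  cat(sprintf("<modality_block> '%s' (%s): %d samples x %d features\n",
              x$name, x$kind, length(x$sample_ids), length(x$feature_ids)))
  invisible(x)
}

#' Create an annotation table with task specifications
#'
#' @param df data.frame of per-sample annotations; rownames (or a `sample_id`
#'   column) identify samples.
#' @param task_specs data.frame with columns `column` and
#'   `task` (`"classification"` or `"regression"`); may be empty.
#' @return object of class `annotation_table` (a data.frame subclass).
#' @export
annotation_table <- function(df, task_specs = NULL) {
  df <- as.data.frame(df)
  if ("sample_id" %in% names(df)) {
    rownames(df) <- as.character(df$sample_id)
    df$sample_id <- NULL
  }
  if (is.null(task_specs)) {
    task_specs <- data.frame(column = character(), task = character())
  }
  task_specs <- as.data.frame(task_specs)
  bad <- setdiff(task_specs$column, names(df))
  if (length(bad)) stop("task column(s) not in annotations: ",
                        paste(bad, collapse = ", "))
  if (length(task_specs$task) &&
      !all(task_specs$task %in% c("classification", "regression"))) {
    stop("task must be 'classification' or 'regression'")
  }
  attr(df, "task_specs") <- task_specs
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' @export
task_specs <- function(ann) attr(ann, "task_specs")

#' Align modality blocks and annotations into one multimodal dataset
#'
#' Restricts all blocks and the annotation table to the intersection of their
#' sample identifiers and reorders every block to one canonical lexicographic
#' sample order, so downstream tensors are reproducible. Counts of samples
#' dropped per block are attached as attribute `"dropped"`.
#'
#' @param blocks list of [modality_block()] objects.
#' @param annotations optional [annotation_table()].
#' @return object of class `multimodal_dataset` with elements `blocks`,
#'   `sample_ids`, `annotations`.
#' @export
align_samples <- function(blocks, annotations = NULL) {
  if (inherits(blocks, "modality_block")) blocks <- list(blocks)
  if (!length(blocks)) stop("at least one modality block is required")
  for (b in blocks) {
    if (!inherits(b, "modality_block")) stop("blocks must be modality_block objects")
    if (!length(b$sample_ids)) stop("modality '", b$name, "' is empty")
  }
  common <- Reduce(intersect, lapply(blocks, `[[`, "sample_ids"))
  if (!is.null(annotations)) common <- intersect(common, rownames(annotations))
  if (!length(common)) stop("sample alignment failed: empty intersection of sample_ids")
  ## canonical order: lexicographic, locale-independent
  common <- sort(common, method = "radix")
  dropped <- vapply(blocks, function(b) length(b$sample_ids) - length(common), 0L)
  names(dropped) <- vapply(blocks, `[[`, "", "name")
  blocks <- lapply(blocks, function(b) {
    b$matrix <- b$matrix[common, , drop = FALSE]
    b$sample_ids <- common
    if (!is.null(b$image_manifest)) {
      b$image_manifest <- b$image_manifest[match(common, b$image_manifest$sample_id), ,
                                           drop = FALSE]
    }
    b
  })
  names(blocks) <- names(dropped)
  if (!is.null(annotations)) {
    ts <- task_specs(annotations)
    annotations <- annotations[common, , drop = FALSE]
    attr(annotations, "task_specs") <- ts
    class(annotations) <- c("annotation_table", "data.frame")
  }
  structure(list(blocks = blocks, sample_ids = common, annotations = annotations),
            class = "multimodal_dataset", dropped = dropped)
}

#' @export
print.multimodal_dataset <- function(x, ...) {
  cat(sprintf("<multimodal_dataset> %d samples, %d modalities\n",
              length(x$sample_ids), length(x$blocks)))
  for (b in x$blocks) print(b)
  invisible(x)
}

#' Create an ontology map from edge lists
#'
#' Level-1 edges connect features to terms; optional level-2 edges connect
#' level-1 terms to super-terms. Term order at each level is deterministic
#' (lexicographic), so decoder masks built from a given file are identical
#' across runs. Overlapping membership (one feature in several terms) is
#' allowed.
#'
#' @param level1_edges data.frame/matrix with two columns: feature_id, term_id.
#' @param level2_edges optional data.frame with two columns: term_id,
#'   super_term_id.
#' @return object of class `ontology_map` with `lvl1`, `lvl2`, `terms1`,
#'   `terms2`, `features`.
#' @export
ontology_map <- function(level1_edges, level2_edges = NULL) {
  lvl1 <- as.data.frame(level1_edges)[, 1:2]
  names(lvl1) <- c("feature_id", "term_id")
  lvl1[] <- lapply(lvl1, as.character)
  terms1 <- sort(unique(lvl1$term_id), method = "radix")
  features <- sort(unique(lvl1$feature_id), method = "radix")
  if (any(lvl1$feature_id %in% terms1)) {
    stop("ontology error: identifier used both as feature and as level-1 term")
  }
  lvl2 <- NULL
  terms2 <- NULL
  if (!is.null(level2_edges) && nrow(as.data.frame(level2_edges))) {
    lvl2 <- as.data.frame(level2_edges)[, 1:2]
    names(lvl2) <- c("term_id", "super_term_id")
    lvl2[] <- lapply(lvl2, as.character)
    terms2 <- sort(unique(lvl2$super_term_id), method = "radix")
    if (any(lvl2$super_term_id %in% c(terms1, features))) {
      stop("ontology error: level-crossing edges (super-term reused at a lower level)")
    }
    bad <- setdiff(lvl2$term_id, terms1)
    if (length(bad)) {
      stop("ontology error: level-2 edges reference unknown level-1 terms: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  structure(list(lvl1 = lvl1, lvl2 = lvl2, terms1 = terms1, terms2 = terms2,
                 features = features),
            class = "ontology_map")
}

#' Number of top-level ontology terms (latent candidates)
#' @export
n_top_terms <- function(onto) {
  if (!is.null(onto$lvl2)) length(onto$terms2) else length(onto$terms1)
}

#' Validate an ontology map against a feature universe
#'
#' Reports how many data features are covered by the ontology, terms per
#' level, empty terms (no mapped feature) and overlapping features (mapped to
#' more than one term). Features absent from the ontology are flagged for
#' exclusion: masked decoders are only defined over mapped features.
#'
#' @param onto an [ontology_map()].
#' @param features character vector of data feature ids.
#' @return a list report.
#' @export
validate_ontology <- function(onto, features) {
  stopifnot(inherits(onto, "ontology_map"))
  features <- as.character(features)
  mapped <- intersect(features, onto$features)
  unmapped <- setdiff(features, onto$features)
  per_term <- table(factor(onto$lvl1$term_id[onto$lvl1$feature_id %in% mapped],
                           levels = onto$terms1))
  empty_terms <- names(per_term)[per_term == 0]
  ft <- unique(onto$lvl1[onto$lvl1$feature_id %in% mapped, ])
  dup <- table(ft$feature_id)
  overlap_features <- names(dup)[dup > 1]
  list(n_mapped = length(mapped), n_unmapped = length(unmapped),
       unmapped_features = unmapped,
       n_terms_lvl1 = length(onto$terms1),
       n_terms_lvl2 = if (is.null(onto$terms2)) 0L else length(onto$terms2),
       empty_terms = empty_terms,
       overlap_features = overlap_features)
}

#' @export
print.ontology_map <- function(x, ...) {
  cat(sprintf("<ontology_map> %d features -> %d level-1 terms",
              length(x$features), length(x$terms1)))
  if (!is.null(x$terms2)) cat(sprintf(" -> %d level-2 terms", length(x$terms2)))
  cat("\n")
  invisible(x)
}
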
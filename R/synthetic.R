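## Synthetic multimodal fixture generator: a linear-Gaussian latent factor
## model with class structure, a planted two-level ontology, class-conditioned
## disk images and paired/unpaired sample linkage. Every pipeline stage can
## be exercised against known ground truth without external data.

#' Specification of the synthetic generator
#'
#' @param n number of samples.
#' @param k_true number of latent factors.
#' @param feature_counts named integer vector, features per modality.
#' @param loading_scale s.d. of the Gaussian loadings.
#' @param noise_sd additive Gaussian noise s.d. on each modality.
#' @param n_classes number of sample classes.
#' @param class_sep distance between class centers in factor space.
#' @param paired_fraction fraction of samples linked across modalities.
#' @param block_structure give each modality block-diagonal-dominant loadings
#'   (feature blocks aligned with factors; basis for the planted ontology).
#' @param nonlinear apply an elementwise softplus to the last modality.
#' @param seed RNG seed.
#' @export
generator_spec <- function(n = 500, k_true = 2,
                           feature_counts = c(rna = 100, meth = 80),
                           loading_scale = 1, noise_sd = 0.1,
                           n_classes = 2, class_sep = 3,
                           paired_fraction = 1, block_structure = FALSE,
                           nonlinear = FALSE, seed = 42L) {
  stopifnot(k_true >= 1, noise_sd >= 0, class_sep >= 0, n_classes >= 1,
            paired_fraction >= 0, paired_fraction <= 1)
  structure(as.list(environment()), class = "generator_spec")
}

## class centers: nearly orthogonal directions scaled to pairwise distance
## ~ class_sep in factor space
class_centers <- function(n_classes, k_true, class_sep) {
  if (n_classes == 1) return(matrix(0, 1, k_true))
  M <- matrix(stats::rnorm(n_classes * k_true), n_classes, k_true)
  M <- scale(M, center = TRUE, scale = FALSE)
  d <- mean(stats::dist(M))
  if (d > 0) M <- M * (class_sep / d)
  M
}

#' Generate a synthetic multimodal dataset with known ground truth
#'
#' Latent factors are class-conditioned Gaussians (`F = center[class] +
#' N(0,1)`); each modality is `X_m = F W_m + noise` with seeded Gaussian
#' loadings `W_m`. Annotations contain the class label (classification task)
#' and a noisy linear readout of the factors (regression task).
#'
#' @param spec a [generator_spec()].
#' @return list with `dataset` (a [align_samples()] product), `factors`,
#'   `loadings`, `classes`, `centers`.
#' @export
make_multiomics <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  set.seed(spec$seed)
  n <- spec$n
  k <- spec$k_true
  sample_ids <- sprintf("s%04d", seq_len(n))
  classes <- sort(rep_len(seq_len(spec$n_classes), n))
  centers <- class_centers(spec$n_classes, k, spec$class_sep)
  F <- centers[classes, , drop = FALSE] + matrix(stats::rnorm(n * k), n, k)
  loadings <- list()
  blocks <- list()
  mods <- names(spec$feature_counts)
  if (is.null(mods)) mods <- paste0("mod", seq_along(spec$feature_counts))
  for (mi in seq_along(spec$feature_counts)) {
    p <- spec$feature_counts[[mi]]
    fid <- sprintf("%s_f%04d", mods[mi], seq_len(p))
    if (spec$block_structure) {
      ## feature block t loads predominantly on factor t
      block <- rep_len(seq_len(k), p)
      W <- matrix(stats::rnorm(k * p, sd = 0.1 * spec$loading_scale), k, p)
      W[cbind(block, seq_len(p))] <- stats::rnorm(p, sd = spec$loading_scale) +
        sign(stats::rnorm(p)) * spec$loading_scale
    } else {
      W <- matrix(stats::rnorm(k * p, sd = spec$loading_scale), k, p)
    }
    X <- F %*% W
    if (spec$nonlinear && mi == length(spec$feature_counts)) {
      X <- log1p(exp(X))  # softplus
    }
    if (spec$noise_sd > 0) X <- X + matrix(stats::rnorm(n * p, sd = spec$noise_sd), n, p)
    dimnames(X) <- list(sample_ids, fid)
    loadings[[mods[mi]]] <- W
    blocks[[mi]] <- modality_block(mods[mi], X, kind = "numeric")
  }
  w_reg <- stats::rnorm(k)
  ann <- annotation_table(
    data.frame(sample_id = sample_ids,
               class = paste0("c", classes),
               target = drop(F %*% w_reg) + stats::rnorm(n, sd = 0.1)),
    task_specs = data.frame(column = c("class", "target"),
                            task = c("classification", "regression")))
  ds <- align_samples(blocks, ann)
  list(dataset = ds, factors = F, loadings = loadings,
       classes = paste0("c", classes), centers = centers)
}

#' Planted ontology for a block-structured modality
#'
#' Features are partitioned into `k_true` blocks (level-1 terms, matching the
#' factor each block loads on). Optionally a fraction of features is also
#' assigned to a second term (overlapping membership) and terms are grouped
#' pairwise into level-2 super-terms.
#'
#' @param spec a [generator_spec()].
#' @param modality modality name (defaults to the first).
#' @param overlap_fraction fraction of features mapped to two terms.
#' @param two_level also emit level-2 (super-term) edges, grouping term pairs.
#' @return an [ontology_map()].
#' @export
make_ontology <- function(spec, modality = NULL, overlap_fraction = 0,
                          two_level = FALSE) {
  stopifnot(inherits(spec, "generator_spec"))
  mods <- names(spec$feature_counts)
  if (is.null(mods)) mods <- paste0("mod", seq_along(spec$feature_counts))
  if (is.null(modality)) modality <- mods[1]
  p <- spec$feature_counts[[match(modality, mods)]]
  k <- spec$k_true
  fid <- sprintf("%s_f%04d", modality, seq_len(p))
  block <- rep_len(seq_len(k), p)
  terms <- sprintf("t%02d", block)
  edges <- data.frame(feature_id = fid, term_id = terms)
  if (overlap_fraction > 0) {
    set.seed(spec$seed + 7L)
    extra <- which(stats::runif(p) < overlap_fraction)
    if (length(extra)) {
      other <- (block[extra] %% k) + 1L
      edges <- rbind(edges, data.frame(feature_id = fid[extra],
                                       term_id = sprintf("t%02d", other)))
    }
  }
  lvl2 <- NULL
  if (two_level) {
    t_ids <- sprintf("t%02d", seq_len(k))
    super <- sprintf("T%02d", (seq_len(k) - 1L) %/% 2L + 1L)
    lvl2 <- data.frame(term_id = t_ids, super_term_id = super)
  }
  ontology_map(unique(edges), lvl2)
}

#' Render one filled-disk image from latent coordinates
#' @keywords internal
disk_image <- function(side, radius_frac, cx_frac, cy_frac, noise_sd = 0,
                       rng = NULL) {
  gx <- matrix(seq_len(side), side, side)
  gy <- t(gx)
  cx <- cx_frac * side
  cy <- cy_frac * side
  r <- radius_frac * side / 2
  img <- ((gx - cx)^2 + (gy - cy)^2 <= r^2) * 1.0
  if (noise_sd > 0) img <- img + matrix(rng(side * side, noise_sd), side, side)
  pmin(pmax(img, 0), 1)
}

#' Class-conditioned disk images driven by the latent factors
#'
#' One square grayscale image per sample: a filled disk whose radius follows
#' the first latent factor and whose center position follows the class (plus
#' the second factor when present), with additive pixel noise. Pixel values
#' lie in `[0, 1]`; the side is divisible by 32.
#'
#' @param spec a [generator_spec()].
#' @param truth the result of [make_multiomics()] for the same spec.
#' @param side image side (divisible by 32).
#' @param pixel_noise_sd additive pixel noise s.d.
#' @return an image [modality_block()] (rows are flattened images) with an
#'   in-memory manifest.
#' @export
make_images <- function(spec, truth, side = 64L, pixel_noise_sd = 0.02) {
  stopifnot(side %% 32 == 0)
  set.seed(spec$seed + 13L)
  F <- truth$factors
  n <- nrow(F)
  squish <- function(v) {  # map factor to (0,1) by its empirical range
    (v - min(v)) / max(max(v) - min(v), 1e-12)
  }
  rad <- 0.25 + 0.6 * squish(F[, 1])
  k_cl <- max(1L, spec$n_classes)
  cls_idx <- as.integer(factor(truth$classes))
  ang <- 2 * pi * (cls_idx - 1) / k_cl
  off <- if (ncol(F) >= 2) 0.08 * (squish(F[, 2]) - 0.5) else 0
  cx <- 0.5 + (0.22 + off) * cos(ang)
  cy <- 0.5 + (0.22 + off) * sin(ang)
  X <- matrix(0, n, side * side)
  rng <- function(m, sd) stats::rnorm(m, sd = sd)
  for (i in seq_len(n)) {
    X[i, ] <- as.vector(t(disk_image(side, rad[i], cx[i], cy[i],
                                     pixel_noise_sd, rng)))
  }
  ids <- sprintf("s%04d", seq_len(n))
  rownames(X) <- ids
  colnames(X) <- sprintf("px%05d", seq_len(side * side))
  manifest <- data.frame(sample_id = ids, path = NA_character_,
                         channels = 1L, height = side, width = side)
  modality_block("images", X, kind = "image", image_manifest = manifest)
}

#' Cross-modality sample links
#'
#' Paired mode links identical sample ids across modalities (a bijection for
#' `paired_fraction = 1`). Unpaired mode shuffles ids within class, so only
#' the class labels connect the modalities while class marginals are
#' preserved.
#'
#' @param spec a [generator_spec()].
#' @param classes class label per sample (required for unpaired mode).
#' @return list with `mode`, `pairs` (data.frame id_a, id_b) and `classes`.
#' @export
make_links <- function(spec, classes = NULL) {
  set.seed(spec$seed + 29L)
  ids <- sprintf("s%04d", seq_len(spec$n))
  if (spec$paired_fraction >= 1) {
    return(list(mode = "paired", pairs = data.frame(id_a = ids, id_b = ids),
                classes = classes))
  }
  if (is.null(classes)) {
    warning("unpaired linkage without class labels: no alignment signal")
    return(list(mode = "unpaired", pairs = NULL, classes = NULL))
  }
  id_b <- ids
  for (cl in unique(classes)) {
    i <- which(classes == cl)
    id_b[i] <- ids[i][sample.int(length(i))]
  }
  n_paired <- floor(spec$paired_fraction * spec$n)
  if (n_paired > 0) {
    keep <- sample.int(spec$n, n_paired)
    id_b[keep] <- ids[keep]
  }
  list(mode = "unpaired", pairs = data.frame(id_a = ids, id_b = id_b),
       classes = classes)
}
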
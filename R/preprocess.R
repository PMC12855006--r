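## Feature filtering, scaling, encoding, splitting, mutation scoring and
## image preprocessing.

col_var_pop <- function(x) {
  ## population variance (denominator n), per column
  mu <- colMeans(x)
  pmax(colMeans(x * x) - mu^2, 0)
}

#' Keep the k features with the largest variance
#'
#' Variance uses the population denominator n. Ties are broken by feature id
#' (lexicographic); the relative column order of the input is preserved.
#'
#' @param x numeric matrix, samples as rows, named columns.
#' @param k number of features to keep.
#' @return the reduced matrix; kept feature ids in `colnames`.
#' @export
filter_top_variance <- function(x, k) {
  filter_by_score(x, k, col_var_pop(x))
}

#' Keep the k features with the largest median absolute deviation
#'
#' Raw MAD (no consistency constant): median over samples of
#' `|x - median(x)|` per feature.
#' @inheritParams filter_top_variance
#' @export
filter_top_mad <- function(x, k) {
  med <- apply(x, 2, stats::median)
  mad_raw <- apply(abs(.bc_sub(x, med)), 2, stats::median)
  filter_by_score(x, k, mad_raw)
}

filter_by_score <- function(x, k, score) {
  if (k > ncol(x)) stop("k (", k, ") exceeds number of features (", ncol(x), ")")
  ids <- colnames(x)
  if (is.null(ids)) ids <- sprintf("f%06d", seq_len(ncol(x)))
  ## rank by score desc, ties by feature id ascending
  ord <- order(-score, ids, method = "radix")
  keep <- sort(ord[seq_len(k)])   # preserve input column order
  x[, keep, drop = FALSE]
}

#' Representative-feature filtering by k-medoids on correlation distance
#'
#' Features are clustered with distance `1 - |pearson|` and the k medoid
#' features are returned, so each group of highly correlated features is
#' represented once. Uses PAM for small feature sets and CLARA-style
#' subsampled k-medoids above 2000 features. Zero-variance features are
#' excluded before clustering with a warning.
#'
#' @inheritParams filter_top_variance
#' @param seed RNG seed for the clustering.
#' @export
filter_correlation_medoid <- function(x, k, seed = 42L) {
  if (k > ncol(x)) stop("k (", k, ") exceeds number of features (", ncol(x), ")")
  if (nrow(x) < 3) stop("correlation-medoid filtering needs at least 3 samples")
  v <- col_var_pop(x)
  degen <- v <= 1e-12
  if (any(degen)) {
    warning(sum(degen), " zero-variance feature(s) excluded before clustering")
    x_use <- x[, !degen, drop = FALSE]
  } else {
    x_use <- x
  }
  p <- ncol(x_use)
  if (k > p) stop("k exceeds number of non-degenerate features (", p, ")")
  if (k == p) return(x_use)
  set.seed(as.integer(seed))
  if (p <= 2000) {
    d <- stats::as.dist(1 - abs(stats::cor(x_use)))
    fit <- cluster::pam(d, k = k, medoids = "random", nstart = 3)
    med <- fit$medoids
  } else {
    ## CLARA on features: cluster rows of the transposed matrix with
    ## correlation-like distance via standardized euclidean proxy is not
    ## equivalent, so subsample features, PAM the subsample, keep medoids.
    sub <- sort(sample.int(p, 2000))
    d <- stats::as.dist(1 - abs(stats::cor(x_use[, sub, drop = FALSE])))
    fit <- cluster::pam(d, k = k, medoids = "random", nstart = 2)
    med <- sub[fit$id.med]
  }
  keep <- sort(if (is.numeric(med)) med else match(med, colnames(x_use)))
  x_use[, keep, drop = FALSE]
}

#' Fit a feature scaler on training rows
#'
#' @param x training matrix (samples as rows).
#' @param method `"standard"` (zero mean, unit population s.d.), `"minmax"`
#'   (to `[0,1]`), `"robust"` (median/IQR) or `"maxabs"` (to `[-1,1]`).
#' @return a `scaler_state` with per-feature location and scale. Degenerate
#'   (zero-scale) features are flagged; they map to 0 when applied.
#' @export
fit_scaler <- function(x, method = c("standard", "minmax", "robust", "maxabs")) {
  method <- match.arg(method)
  if (!nrow(x)) stop("cannot fit a scaler on an empty training split")
  loc <- switch(method,
    standard = colMeans(x),
    minmax = apply(x, 2, min),
    robust = apply(x, 2, stats::median),
    maxabs = rep(0, ncol(x)))
  scale <- switch(method,
    standard = sqrt(col_var_pop(x)),
    minmax = apply(x, 2, max) - apply(x, 2, min),
    robust = apply(x, 2, stats::IQR),
    maxabs = apply(abs(x), 2, max))
  ## constant columns (or zero dispersion under the chosen statistic) are
  ## degenerate: they map to 0 regardless of method
  rng <- apply(x, 2, max) - apply(x, 2, min)
  degenerate <- scale <= 1e-12 | rng <= 1e-12
  scale[degenerate] <- 1
  structure(list(method = method, loc = loc, scale = scale,
                 degenerate = degenerate, feature_ids = colnames(x)),
            class = "scaler_state")
}

#' Apply (or invert) a fitted scaler
#' @param x matrix to transform.
#' @param state a `scaler_state` from [fit_scaler()].
#' @param inverse undo the scaling instead.
#' @export
apply_scaler <- function(x, state, inverse = FALSE) {
  stopifnot(inherits(state, "scaler_state"))
  if (inverse) {
    y <- .bc_add(.bc_mul(x, state$scale), state$loc)
    return(y)
  }
  y <- .bc_mul(.bc_sub(x, state$loc), 1 / state$scale)
  if (any(state$degenerate)) y[, state$degenerate] <- 0
  y
}

#' One-hot encode a categorical column
#'
#' Levels are taken from the training values (lexicographic order); values
#' unseen at apply time encode as an all-zero row with a warning.
#'
#' @param values character/factor vector to encode.
#' @param levels level set; defaults to the sorted unique training values.
#' @param prefix column-name prefix.
#' @return 0/1 matrix with one indicator column per level.
#' @export
one_hot <- function(values, levels = NULL, prefix = "x") {
  values <- as.character(values)
  if (is.null(levels)) levels <- sort(unique(values), method = "radix")
  m <- matrix(0L, length(values), length(levels),
              dimnames = list(NULL, paste0(prefix, ".", levels)))
  idx <- match(values, levels)
  if (anyNA(idx)) {
    warning("unseen level(s) at encoding time: ",
            paste(unique(values[is.na(idx)]), collapse = ", "),
            " -> all-zero rows")
  }
  ok <- !is.na(idx)
  m[cbind(which(ok), idx[ok])] <- 1L
  m
}

#' Random train/validation/test split
#'
#' `floor(r_train * n)` training and `floor(r_valid * n)` validation samples;
#' the remainder is the test set. Assignment is a seeded uniform shuffle.
#' A 70/10/20 split of 260 samples therefore yields exactly 182/26/52.
#'
#' @param sample_ids sample identifiers (or a single integer n).
#' @param ratios numeric length-3 (train, valid, test), nonnegative, sum 1.
#' @param seed RNG seed.
#' @return a `split_assignment`: named factor over
#'   `c("train","valid","test")` plus `ratios`/`seed` attributes.
#' @export
split_dataset <- function(sample_ids, ratios = c(0.6, 0.2, 0.2), seed = 42L) {
  if (length(sample_ids) == 1L && is.numeric(sample_ids)) {
    sample_ids <- sprintf("s%04d", seq_len(sample_ids))
  }
  n <- length(sample_ids)
  ratios <- as.numeric(unlist(ratios))
  stopifnot(length(ratios) == 3L)
  if (any(ratios < 0) || abs(sum(ratios) - 1) > 1e-8) {
    stop("split ratios must be nonnegative and sum to 1")
  }
  n_train <- floor(ratios[1] * n)
  n_valid <- floor(ratios[2] * n)
  n_test <- n - n_train - n_valid
  set.seed(as.integer(seed))
  perm <- sample.int(n)
  lab <- rep(c("train", "valid", "test"), c(n_train, n_valid, n_test))
  out <- factor(character(n), levels = c("train", "valid", "test"))
  out[perm] <- lab
  names(out) <- sample_ids
  structure(out, ratios = ratios, seed = as.integer(seed),
            class = c("split_assignment", "factor"))
}

split_idx <- function(split, which) which(as.character(split) == which)

#' Per-gene mutation score from SNV counts and copy-number alteration
#'
#' `score_i = SNV_i / CDS_i + CNA_i`, combining the SNV burden normalized by
#' coding-sequence length with the copy-number alteration of the gene.
#'
#' @param snv nonnegative integer vector (SNV count per gene).
#' @param cds positive integer vector (coding-sequence length in bases).
#' @param cna numeric vector (copy-number alteration, passed through as given).
#' @param gene_ids optional names for error messages and the result.
#' @return numeric vector of per-gene scores.
#' @export
mutation_score <- function(snv, cds, cna, gene_ids = names(snv)) {
  stopifnot(length(snv) == length(cds), length(cds) == length(cna))
  if (any(snv < 0)) stop("SNV counts must be nonnegative")
  bad <- which(cds <= 0)
  if (length(bad)) {
    nm <- if (!is.null(gene_ids)) gene_ids[bad[1]] else paste0("#", bad[1])
    stop("CDS length must be positive (gene ", nm, ")")
  }
  out <- snv / cds + cna
  names(out) <- gene_ids
  out
}

#' Image preprocessing: channel selection, max projection, rescale to [0,1]
#'
#' Accepts a z-stack array `(Z, C, H, W)` or a single image `(C, H, W)` /
#' `(H, W)`. Selects the requested channel, takes the per-pixel maximum over
#' the z-dimension, optionally center-crops and average-pools to a square
#' target side, rescales min to 0 and max to 255 and divides by 255. A
#' constant image maps to all zeros.
#'
#' @param img numeric array.
#' @param channel channel index (1-based) when a channel axis is present.
#' @param target_side optional output side; must be divisible by 32 and the
#'   image must be square (or `resize = TRUE` to pool down).
#' @param resize allow average-pool resizing when `side != target_side`.
#' @return `(H', W')` matrix with values in `[0, 1]`.
#' @export
image_preprocess <- function(img, channel = 1L, target_side = NULL, resize = TRUE) {
  d <- dim(img)
  if (is.null(d) || length(d) < 2L) stop("img must be a 2-4 dimensional array")
  if (length(d) == 4L) {        # (Z, C, H, W)
    img <- img[, channel, , , drop = FALSE]
    img <- apply(img, c(3, 4), max)
  } else if (length(d) == 3L) { # (C, H, W)
    img <- img[channel, , ]
  }
  img <- as.matrix(img)
  if (!is.null(target_side)) {
    if (target_side %% 32 != 0) stop("target side must be divisible by 32")
    if (nrow(img) != ncol(img)) {
      if (!resize) stop("non-square image with resize disabled")
      side <- min(dim(img))
      r0 <- (nrow(img) - side) %/% 2
      c0 <- (ncol(img) - side) %/% 2
      img <- img[r0 + seq_len(side), c0 + seq_len(side)]
    }
    side <- nrow(img)
    if (side != target_side) {
      if (!resize) stop("image side ", side, " != target ", target_side,
                        " with resize disabled")
      if (side %% target_side == 0) {
        f <- side %/% target_side
        idx <- (seq_len(side) - 1) %/% f + 1
        img <- rowsum(img, idx) / f
        img <- t(rowsum(t(img), idx) / f)
      } else {
        ## nearest-neighbour fallback for non-integer factors
        pick <- pmin(side, floor((seq_len(target_side) - 0.5) * side / target_side) + 1)
        img <- img[pick, pick]
      }
    }
  } else if (nrow(img) != ncol(img)) {
    stop("non-square image; provide target_side with resize = TRUE")
  }
  rng <- range(img)
  if (rng[2] - rng[1] <= 1e-12) return(img * 0)
  ((img - rng[1]) / (rng[2] - rng[1]) * 255) / 255
}

#' Apply a configured filter to a matrix
#' @keywords internal
apply_filter <- function(x, filter, seed = 42L) {
  switch(filter$method,
         none = x,
         variance = filter_top_variance(x, filter$k),
         mad = filter_top_mad(x, filter$k),
         correlation = filter_correlation_medoid(x, filter$k, seed = seed),
         stop("unknown filter method: ", filter$method))
}
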
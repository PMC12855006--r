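## Embedding quality metrics: reconstruction R^2, latent-space coverage,
## total correlation, downstream-ML Z-scores against random-feature
## baselines, repetition robustness, and PCA/UMAP reference embeddings.

#' Mean per-sample explained variance of a reconstruction
#'
#' Per sample s: `R2_s = 1 - Var_f(x_s - xhat_s) / Var_f(x_s)` over features;
#' the mean over samples is returned. Unlike the raw MSE this is invariant to
#' input width and scale. Samples with zero input variance are excluded with
#' a warning.
#'
#' @param x,xhat equally shaped matrices (samples as rows, >= 2 features).
#' @export
reconstruction_r2 <- function(x, xhat) {
  stopifnot(identical(dim(x), dim(xhat)), ncol(x) >= 2)
  rv <- function(m) {
    mu <- rowMeans(m)
    rowSums((m - mu)^2) / (ncol(m) - 1)
  }
  vx <- rv(x)
  ok <- vx > 1e-12
  if (!all(ok)) warning(sum(!ok), " sample(s) with zero input variance excluded")
  if (!any(ok)) stop("no sample with nonzero input variance")
  mean(1 - rv(x - xhat)[ok] / vx[ok])
}

#' Latent-space coverage on a per-dimension binned grid
#'
#' Each latent dimension is divided into `b = floor(n^(1/L))` equal-width bins
#' between its observed minimum and maximum (the maximum falls in the last
#' bin), forming a grid of `b^L` cells; coverage is the fraction of occupied
#' grid cells, reported per dimension together with the mean. A sample set
#' filling the grid uniformly has coverage 1; a point mass has coverage
#' `1/b^L`; independent standard normal samples stay at or below 0.5.
#' Degenerate dimensions (min = max) contribute coverage `1/b` and are
#' excluded from the grid.
#'
#' @param z embedding matrix (n samples x L dimensions), n >= 2.
#' @return list with `per_dimension`, `mean`, `b`, `n_occupied`.
#' @export
latent_coverage <- function(z) {
  z <- as.matrix(z)
  n <- nrow(z)
  if (n < 2) stop("latent_coverage requires at least 2 samples")
  L <- ncol(z)
  b <- max(1L, floor(n^(1 / L) + 1e-9))
  rng <- apply(z, 2, range)
  degen <- (rng[2, ] - rng[1, ]) <= 1e-12
  L_eff <- sum(!degen)
  if (L_eff == 0L) {
    per_dim <- rep(1 / b, L)
    return(list(per_dimension = per_dim, mean = mean(per_dim), b = b,
                n_occupied = 1L))
  }
  zz <- z[, !degen, drop = FALSE]
  bins <- matrix(0L, n, L_eff)
  for (j in seq_len(L_eff)) {
    w <- (rng[2, !degen][j] - rng[1, !degen][j]) / b
    bins[, j] <- pmin(b - 1L, floor((zz[, j] - rng[1, !degen][j]) / w))
  }
  cell <- bins[, 1]
  if (L_eff > 1) {
    for (j in 2:L_eff) cell <- cell * b + bins[, j]
  }
  occ <- length(unique(cell))
  cov_grid <- occ / b^L_eff
  per_dim <- ifelse(degen, 1 / b, cov_grid)
  list(per_dimension = per_dim, mean = mean(per_dim), b = b, n_occupied = occ)
}

#' Total correlation of latent dimensions (Gaussian estimator)
#'
#' `TC = -1/2 * log det(R)` with `R` the Pearson correlation matrix of the
#' embedding: the multivariate mutual information shared between latent
#' dimensions under a Gaussian assumption. Zero exactly for an identity
#' empirical correlation (independent/disentangled dimensions); infinite for
#' exactly collinear dimensions (returned as `Inf`). Numerical negatives are
#' clamped to 0.
#'
#' @param z embedding matrix, more rows than columns, non-constant columns.
#' @export
total_correlation <- function(z) {
  z <- as.matrix(z)
  if (nrow(z) <= ncol(z)) stop("total_correlation needs n > L")
  sds <- apply(z, 2, stats::sd)
  if (any(sds <= 1e-12)) stop("total_correlation: constant latent dimension")
  R <- stats::cor(z)
  ld <- determinant(R, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) return(Inf)
  max(-0.5 * as.numeric(ld$modulus), 0)
}

#' Train/test evaluation of an embedding on annotation tasks
#'
#' Each (task, algorithm) pair is trained on the train-split embeddings and
#' scored on the test split: macro one-vs-rest AUROC for classification,
#' explained variance R^2 for regression. Algorithm classes: `"linear"`
#' (linear/logistic regression), `"svm_rbf"` (RBF-kernel machine),
#' `"random_forest"`.
#'
#' @param z embedding matrix aligned with the annotation rows.
#' @param annotations an [annotation_table()] with task specs.
#' @param split a [split_dataset()] assignment over the same samples.
#' @param algorithms subset of the three algorithm ids.
#' @return data.frame with columns task, algorithm, metric, value.
#' @export
evaluate_embedding <- function(z, annotations, split,
                               algorithms = c("linear", "svm_rbf", "random_forest")) {
  z <- as.matrix(z)
  stopifnot(nrow(z) == nrow(annotations))
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  specs <- task_specs(annotations)
  tr <- split_idx(split, "train")
  te <- split_idx(split, "test")
  out <- list()
  for (i in seq_len(nrow(specs))) {
    col <- specs$column[i]
    type <- specs$task[i]
    y <- annotations[[col]]
    if (type == "classification") {
      y <- as.character(y)
      if (length(unique(y[tr])) < 2) {
        warning("task '", col, "' has a single class in the training split; skipped")
        next
      }
    } else {
      y <- as.numeric(y)
    }
    for (alg in algorithms) {
      val <- eval_one_task(z[tr, , drop = FALSE], y[tr],
                           z[te, , drop = FALSE], y[te], type, alg)
      out[[length(out) + 1L]] <- data.frame(
        task = col, algorithm = alg,
        metric = if (type == "classification") "auroc" else "r2",
        value = val)
    }
  }
  do.call(rbind, out)
}

eval_one_task <- function(xtr, ytr, xte, yte, type, alg) {
  if (type == "classification") {
    classes <- sort(unique(as.character(ytr)), method = "radix")
    scores <- switch(alg,
      linear = logistic_scores(xtr, ytr, xte, classes),
      svm_rbf = svm_rbf_scores_clf(xtr, ytr, xte, classes),
      random_forest = random_forest_scores(xtr, ytr, xte, "classification", classes))
    if (length(classes) == 2) auroc(scores[, 2], as.integer(yte == classes[2]))
    else auroc(scores, yte)
  } else {
    yhat <- switch(alg,
      linear = linear_regression_scores(xtr, ytr, xte),
      svm_rbf = svm_rbf_scores_reg(xtr, ytr, xte),
      random_forest = random_forest_scores(xtr, ytr, xte, "regression"))
    r2_score(yte, yhat)
  }
}

#' Random-feature baseline performances
#'
#' Draws `r` seeded sets of `l_dim` features from the full (post-filter,
#' post-scale) feature space and evaluates them with the identical train/test
#' protocol as [evaluate_embedding()] - the simplest possible dimension
#' reduction against which embeddings are Z-scored.
#'
#' @param x full feature matrix (concatenated modalities).
#' @param l_dim number of features per draw (matching the latent dimension).
#' @param annotations,split,algorithms as in [evaluate_embedding()].
#' @param r number of repetitions.
#' @param seed RNG seed.
#' @return data.frame with columns rep, task, algorithm, metric, value.
#' @export
random_feature_baseline <- function(x, l_dim, annotations, split,
                                    algorithms = c("linear", "svm_rbf", "random_forest"),
                                    r = 5, seed = 42L) {
  stopifnot(l_dim <= ncol(x))
  out <- list()
  for (rep_i in seq_len(r)) {
    set.seed(as.integer(seed) + rep_i)
    feats <- sample.int(ncol(x), l_dim)
    res <- evaluate_embedding(x[, feats, drop = FALSE], annotations, split,
                              algorithms)
    res$rep <- rep_i
    out[[rep_i]] <- res
  }
  do.call(rbind, out)
}

#' Z-score of an embedding performance against its random-feature cohort
#'
#' `z = (theta - mean(eta)) / sd(eta)` with the population standard
#' deviation. A near-constant cohort (s.d. < 1e-8) yields `NA` with a
#' warning.
#'
#' @param theta embedding performance (AUROC or R^2).
#' @param eta vector of random-baseline performances.
#' @export
zscore_performance <- function(theta, eta) {
  m <- mean(eta)
  s <- sqrt(mean((eta - m)^2))
  if (s < 1e-8) {
    warning("random-feature baseline has (near-)zero spread; Z-score undefined")
    return(NA_real_)
  }
  (theta - m) / s
}

#' Full embedding evaluation with random-feature Z-scores
#'
#' @param z embedding matrix.
#' @param x full feature matrix for the baseline draws.
#' @inheritParams random_feature_baseline
#' @return data.frame with theta, the baseline mean/sd and the Z-score per
#'   task and algorithm.
#' @export
embedding_zscores <- function(z, x, annotations, split,
                              algorithms = c("linear", "svm_rbf", "random_forest"),
                              r = 5, seed = 42L) {
  theta <- evaluate_embedding(z, annotations, split, algorithms)
  eta <- random_feature_baseline(x, ncol(z), annotations, split, algorithms,
                                 r = r, seed = seed)
  out <- theta
  out$eta_mean <- NA_real_
  out$eta_sd <- NA_real_
  out$zscore <- NA_real_
  for (i in seq_len(nrow(theta))) {
    e <- eta$value[eta$task == theta$task[i] & eta$algorithm == theta$algorithm[i]]
    out$eta_mean[i] <- mean(e)
    out$eta_sd[i] <- sqrt(mean((e - mean(e))^2))
    out$zscore[i] <- tryCatch(zscore_performance(theta$value[i], e),
                              warning = function(w) NA_real_)
  }
  out
}

#' Repetition robustness of latent dimensions
#'
#' For each latent dimension, the mean over all unordered pairs of runs of
#' the absolute Pearson correlation between the two runs' embeddings of the
#' same samples. Dimensions must be index-matched across runs (for the
#' ontology-masked architecture they are anchored to ontology terms).
#' Zero-variance dimensions contribute 0 for the affected pair, with a
#' warning.
#'
#' @param runs list (length >= 2) of n x L embedding matrices.
#' @return list with `per_dimension` (mean |r| per latent dim) and
#'   `n_runs`.
#' @export
robustness <- function(runs) {
  stopifnot(length(runs) >= 2)
  dims <- dim(runs[[1]])
  for (r in runs) stopifnot(identical(dim(r), dims))
  L <- dims[2]
  pairs <- utils::combn(length(runs), 2)
  per_dim <- numeric(L)
  warned <- FALSE
  for (l in seq_len(L)) {
    vals <- apply(pairs, 2, function(pr) {
      a <- runs[[pr[1]]][, l]
      b <- runs[[pr[2]]][, l]
      if (stats::sd(a) <= 1e-12 || stats::sd(b) <= 1e-12) {
        warned <<- TRUE
        return(0)
      }
      abs(stats::cor(a, b))
    })
    per_dim[l] <- mean(vals)
  }
  if (warned) warning("zero-variance latent dimension(s): pair correlation set to 0")
  list(per_dimension = per_dim, n_runs = length(runs))
}

#' Reference embeddings: PCA (SVD on the train split) or UMAP
#'
#' @param x feature matrix.
#' @param l_dim embedding dimension.
#' @param method `"pca"` or `"umap"` (UMAP requires the `uwot` package).
#' @param split optional split; components are fitted on the train split only
#'   and applied to all samples.
#' @param seed seed for UMAP.
#' @return n x l_dim embedding matrix.
#' @export
baseline_embeddings <- function(x, l_dim, method = c("pca", "umap"),
                                split = NULL, seed = 42L) {
  method <- match.arg(method)
  x <- as.matrix(x)
  tr <- if (is.null(split)) seq_len(nrow(x)) else split_idx(split, "train")
  if (method == "pca") {
    mu <- colMeans(x[tr, , drop = FALSE])
    sv <- svd(.bc_sub(x[tr, , drop = FALSE], mu), nu = 0, nv = l_dim)
    return(.bc_sub(x, mu) %*% sv$v)
  }
  if (!requireNamespace("uwot", quietly = TRUE)) {
    stop("UMAP baseline requires the 'uwot' package")
  }
  set.seed(as.integer(seed))
  um <- uwot::umap(x[tr, , drop = FALSE], n_components = l_dim,
                   ret_model = TRUE, seed = as.integer(seed))
  uwot::umap_transform(x, um)
}
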
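## Small, fixed-hyperparameter ML algorithms used for embedding evaluation:
## linear/logistic regression, an RBF-kernel machine and a random forest.
## Implemented in-package (no external ML stack is available offline);
## hyperparameters are fixed and documented, never tuned.

rbf_kernel <- function(a, b, gamma) {
  d2 <- pmax(outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b), 0)
  exp(-gamma * d2)
}

rbf_gamma_heuristic <- function(x) {
  d2 <- stats::dist(x[sample.int(nrow(x), min(nrow(x), 200)), , drop = FALSE])^2
  h2 <- stats::median(d2[d2 > 0])
  if (!is.finite(h2) || h2 <= 0) h2 <- 1
  1 / (2 * h2)
}

## ridge-regularized linear regression (closed form, lambda = 1e-6)
linear_regression_scores <- function(xtr, ytr, xte) {
  xtr1 <- cbind(1, xtr)
  xte1 <- cbind(1, xte)
  A <- crossprod(xtr1) + diag(1e-6, ncol(xtr1))
  beta <- solve(A, crossprod(xtr1, ytr))
  drop(xte1 %*% beta)
}

## one-vs-rest logistic regression via base glm
logistic_scores <- function(xtr, ytr, xte, classes) {
  df_tr <- as.data.frame(xtr)
  df_te <- as.data.frame(xte)
  names(df_te) <- names(df_tr)
  sc <- sapply(classes, function(cl) {
    yy <- as.integer(ytr == cl)
    fit <- suppressWarnings(stats::glm(yy ~ ., data = cbind(yy = yy, df_tr),
                                       family = stats::binomial()))
    suppressWarnings(stats::predict(fit, newdata = df_te, type = "response"))
  })
  matrix(sc, nrow = nrow(xte), dimnames = list(NULL, classes))
}

## kernelized Pegasos SVM (hinge loss), one-vs-rest decision values
svm_rbf_scores_clf <- function(xtr, ytr, xte, classes, C = 1, epochs = 20) {
  gamma <- rbf_gamma_heuristic(xtr)
  n <- nrow(xtr)
  K <- rbf_kernel(xtr, xtr, gamma)
  Kte <- rbf_kernel(xte, xtr, gamma)
  lambda <- 1 / (C * n)
  sc <- sapply(classes, function(cl) {
    y <- ifelse(ytr == cl, 1, -1)
    alpha <- numeric(n)
    t <- 0L
    for (ep in seq_len(epochs)) {
      for (i in sample.int(n)) {
        t <- t + 1L
        f_i <- sum(alpha * y * K[, i]) / (lambda * t)
        if (y[i] * f_i < 1) alpha[i] <- alpha[i] + 1
      }
    }
    drop(Kte %*% (alpha * y)) / (lambda * t)
  })
  matrix(sc, nrow = nrow(xte), dimnames = list(NULL, classes))
}

## RBF kernel ridge regression (regularization 1.0)
svm_rbf_scores_reg <- function(xtr, ytr, xte, lambda = 1) {
  gamma <- rbf_gamma_heuristic(xtr)
  K <- rbf_kernel(xtr, xtr, gamma)
  alpha <- solve(K + diag(lambda, nrow(K)), ytr - mean(ytr))
  drop(rbf_kernel(xte, xtr, gamma) %*% alpha) + mean(ytr)
}

## ---- random forest (bagged CART with random feature subsets) -------------

rf_grow_tree <- function(x, y, type, mtry, max_depth, min_node) {
  nodes <- list()
  impurity <- function(yy) {
    if (type == "classification") {
      p <- table(yy) / length(yy)
      1 - sum(p^2)
    } else {
      if (length(yy) <= 1) 0 else stats::var(yy) * (length(yy) - 1)
    }
  }
  leaf_value <- function(yy) {
    if (type == "classification") table(yy) / length(yy) else mean(yy)
  }
  build <- function(idx, depth) {
    yy <- y[idx]
    if (depth >= max_depth || length(idx) < min_node ||
        length(unique(yy)) == 1L) {
      nodes[[length(nodes) + 1L]] <<- list(leaf = TRUE, value = leaf_value(yy))
      return(length(nodes))
    }
    feats <- sample.int(ncol(x), min(mtry, ncol(x)))
    best <- list(gain = 0)
    base_imp <- impurity(yy)
    for (f in feats) {
      v <- x[idx, f]
      cuts <- unique(stats::quantile(v, probs = seq(0.1, 0.9, by = 0.1),
                                     names = FALSE, type = 1))
      for (cut in cuts) {
        left <- v <= cut
        nl <- sum(left)
        if (nl == 0 || nl == length(idx)) next
        gain <- if (type == "classification") {
          ## gini decrease, children weighted by size
          base_imp - (nl * impurity(yy[left]) +
                        (length(idx) - nl) * impurity(yy[!left])) / length(idx)
        } else {
          ## SSE decrease (impurity returns sums of squares)
          base_imp - impurity(yy[left]) - impurity(yy[!left])
        }
        if (gain > best$gain) best <- list(gain = gain, f = f, cut = cut, left = left)
      }
    }
    if (best$gain <= 1e-12) {
      nodes[[length(nodes) + 1L]] <<- list(leaf = TRUE, value = leaf_value(yy))
      return(length(nodes))
    }
    li <- build(idx[best$left], depth + 1L)
    ri <- build(idx[!best$left], depth + 1L)
    nodes[[length(nodes) + 1L]] <<- list(leaf = FALSE, f = best$f, cut = best$cut,
                                         left = li, right = ri)
    length(nodes)
  }
  root <- build(seq_len(nrow(x)), 0L)
  list(nodes = nodes, root = root)
}

rf_predict_tree <- function(tree, x, classes = NULL) {
  out <- if (is.null(classes)) numeric(nrow(x)) else
    matrix(0, nrow(x), length(classes), dimnames = list(NULL, classes))
  walk <- function(node_id, idx) {
    node <- tree$nodes[[node_id]]
    if (node$leaf) {
      if (is.null(classes)) {
        out[idx] <<- node$value
      } else {
        v <- numeric(length(classes))
        names(v) <- classes
        v[names(node$value)] <- node$value
        out[idx, ] <<- matrix(v, length(idx), length(classes), byrow = TRUE)
      }
      return(invisible(NULL))
    }
    left <- x[idx, node$f] <= node$cut
    if (any(left)) walk(node$left, idx[left])
    if (any(!left)) walk(node$right, idx[!left])
  }
  walk(tree$root, seq_len(nrow(x)))
  out
}

random_forest_scores <- function(xtr, ytr, xte, type, classes = NULL,
                                 n_trees = 100, max_depth = 8, min_node = 5) {
  p <- ncol(xtr)
  mtry <- if (type == "classification") max(1L, floor(sqrt(p))) else
    max(1L, floor(p / 3))
  acc <- NULL
  for (t in seq_len(n_trees)) {
    bi <- sample.int(nrow(xtr), replace = TRUE)
    tree <- rf_grow_tree(xtr[bi, , drop = FALSE], ytr[bi], type, mtry,
                         max_depth, min_node)
    pred <- rf_predict_tree(tree, xte, classes)
    acc <- if (is.null(acc)) pred else acc + pred
  }
  acc / n_trees
}

#' Area under the ROC curve (binary via rank statistic; multiclass macro OVR)
#'
#' @param scores numeric vector (binary) or matrix with one score column per
#'   class (multiclass one-vs-rest, macro average).
#' @param labels true labels.
#' @export
auroc <- function(scores, labels) {
  if (is.matrix(scores) && ncol(scores) > 1) {
    classes <- colnames(scores)
    vals <- vapply(classes, function(cl) {
      y <- as.integer(labels == cl)
      if (length(unique(y)) < 2) return(NA_real_)
      auroc(scores[, cl], y)
    }, 0)
    return(mean(vals, na.rm = TRUE))
  }
  y <- if (is.numeric(labels)) labels else as.integer(labels == sort(unique(as.character(labels)))[2])
  pos <- as.logical(y)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Explained variance R^2 of predictions
#' @export
r2_score <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}
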
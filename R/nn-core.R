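## Minimal feed-forward neural-network core with manual backpropagation.
## Layers are mutable environments holding `params` (named list of arrays),
## `grads` (same shapes) and closures `forward(x, training)` / `backward(dy)`.
## All data flows as numeric matrices with one sample per row; images are
## flattened rows in channel-major order (index = c*H*W + h*W + w).

new_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$params <- list()
  e$grads <- list()
  class(e) <- c(paste0("nn_", type), "nn_layer")
  e
}

## column-wise broadcast helpers
.bc_sub <- function(x, v) x - matrix(v, nrow(x), length(v), byrow = TRUE)
.bc_mul <- function(x, v) x * matrix(v, nrow(x), length(v), byrow = TRUE)
.bc_add <- function(x, v) x + matrix(v, nrow(x), length(v), byrow = TRUE)

#' Fully connected layer, optionally with a fixed 0/1 weight mask
#'
#' The mask has the same shape as the weight matrix (`d_in x d_out`); masked
#' entries are held at exactly zero: they are zeroed at initialization, their
#' gradient is zeroed, and they are re-zeroed after every optimizer step.
#'
#' @param d_in,d_out layer widths.
#' @param mask optional 0/1 matrix of shape `d_in x d_out`.
#' @param init_scale multiplier on the He-normal initialization s.d.
#' @return a layer environment.
#' @keywords internal
nn_linear <- function(d_in, d_out, mask = NULL, init_scale = 1) {
  l <- new_layer("linear")
  W <- matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)) * init_scale,
              d_in, d_out)
  if (!is.null(mask)) {
    stopifnot(identical(dim(mask), dim(W)))
    W <- W * mask
  }
  l$params <- list(W = W, b = numeric(d_out))
  l$grads <- list(W = W * 0, b = numeric(d_out))
  l$mask <- mask
  l$forward <- function(x, training = TRUE) {
    l$x <- x
    .bc_add(x %*% l$params$W, l$params$b)
  }
  l$backward <- function(dy) {
    dW <- crossprod(l$x, dy)
    if (!is.null(l$mask)) dW <- dW * l$mask
    l$grads$W <- l$grads$W + dW
    l$grads$b <- l$grads$b + colSums(dy)
    tcrossprod(dy, l$params$W)
  }
  l$post_step <- function() {
    if (!is.null(l$mask)) l$params$W <- l$params$W * l$mask
    invisible(NULL)
  }
  l
}

#' Batch normalization over columns (1-d) or channels (2-d feature maps)
#'
#' @param d number of normalized units (columns for dense layers, channels for
#'   convolutional maps).
#' @param spatial number of spatial positions per channel; 1 for dense layers.
#' @keywords internal
nn_batchnorm <- function(d, spatial = 1L, momentum = 0.1, eps = 1e-5) {
  l <- new_layer("batchnorm")
  l$params <- list(gamma = rep(1, d), beta = numeric(d))
  l$grads <- list(gamma = numeric(d), beta = numeric(d))
  l$running_mean <- numeric(d)
  l$running_var <- rep(1, d)
  l$spatial <- as.integer(spatial)
  sp <- l$spatial
  expand <- function(v) if (sp == 1L) v else rep(v, each = sp)
  l$forward <- function(x, training = TRUE) {
    n_eff <- nrow(x) * sp
    if (training && nrow(x) > 1L) {
      cs <- colSums(x)
      cs2 <- colSums(x * x)
      if (sp > 1L) {
        dim(cs) <- c(sp, d); cs <- colSums(cs)
        dim(cs2) <- c(sp, d); cs2 <- colSums(cs2)
      }
      mu <- cs / n_eff
      v <- cs2 / n_eff - mu^2
      v[v < 0] <- 0
      l$running_mean <- (1 - momentum) * l$running_mean + momentum * mu
      l$running_var <- (1 - momentum) * l$running_var + momentum * v
    } else {
      mu <- l$running_mean
      v <- l$running_var
    }
    istd <- 1 / sqrt(v + eps)
    xhat <- .bc_mul(.bc_sub(x, expand(mu)), expand(istd))
    l$xhat <- xhat
    l$istd <- istd
    l$train_mode <- training && nrow(x) > 1L
    .bc_add(.bc_mul(xhat, expand(l$params$gamma)), expand(l$params$beta))
  }
  l$backward <- function(dy) {
    xhat <- l$xhat
    n_eff <- nrow(dy) * sp
    s1 <- colSums(dy)
    s2 <- colSums(dy * xhat)
    if (sp > 1L) {
      dim(s1) <- c(sp, d); s1 <- colSums(s1)
      dim(s2) <- c(sp, d); s2 <- colSums(s2)
    }
    l$grads$gamma <- l$grads$gamma + s2
    l$grads$beta <- l$grads$beta + s1
    g <- expand(l$params$gamma * l$istd)
    if (!l$train_mode) return(.bc_mul(dy, g))
    ## full batch-norm backward: mean/var depend on the batch
    .bc_mul(dy - .bc_add(.bc_mul(xhat, expand(s2 / n_eff)),
                         expand(s1 / n_eff)), g)
  }
  l
}

#' @keywords internal
nn_dropout <- function(p) {
  l <- new_layer("dropout")
  l$p <- p
  l$forward <- function(x, training = TRUE) {
    if (!training || p <= 0) {
      l$mask_drop <- NULL
      return(x)
    }
    m <- matrix(stats::runif(length(x)) >= p, nrow(x), ncol(x)) / (1 - p)
    l$mask_drop <- m
    x * m
  }
  l$backward <- function(dy) {
    if (is.null(l$mask_drop)) dy else dy * l$mask_drop
  }
  l
}

#' @keywords internal
nn_relu <- function() {
  l <- new_layer("relu")
  l$forward <- function(x, training = TRUE) {
    l$pos <- x > 0
    x * l$pos
  }
  l$backward <- function(dy) dy * l$pos
  l
}

#' @keywords internal
nn_sigmoid <- function() {
  l <- new_layer("sigmoid")
  l$forward <- function(x, training = TRUE) {
    l$y <- 1 / (1 + exp(-x))
    l$y
  }
  l$backward <- function(dy) dy * l$y * (1 - l$y)
  l
}

#' 2-d convolution layer (kernel k, stride s, zero padding p)
#' @keywords internal
nn_conv2d <- function(c_in, c_out, h, w, k = 4L, stride = 2L, pad = 1L) {
  l <- new_layer("conv2d")
  fan_in <- c_in * k * k
  l$params <- list(W = matrix(stats::rnorm(c_out * fan_in, sd = sqrt(2 / fan_in)),
                              c_out, fan_in),
                   b = numeric(c_out))
  l$grads <- list(W = matrix(0, c_out, fan_in), b = numeric(c_out))
  l$dims <- c(c_in = c_in, c_out = c_out, h = h, w = w, k = k,
              stride = stride, pad = pad)
  l$h_out <- (h + 2 * pad - k) %/% stride + 1
  l$w_out <- (w + 2 * pad - k) %/% stride + 1
  l$forward <- function(x, training = TRUE) {
    l$x <- x
    cpp_conv2d_forward(x, l$params$W, l$params$b, c_in, h, w, k, stride, pad)
  }
  l$backward <- function(dy) {
    bk <- cpp_conv2d_backward(l$x, l$params$W, dy, c_in, h, w, k, stride, pad)
    l$grads$W <- l$grads$W + bk$dW
    l$grads$b <- l$grads$b + as.numeric(bk$db)
    bk$dX
  }
  l
}

#' 2-d transposed convolution layer (adjoint geometry of nn_conv2d)
#' @keywords internal
nn_convt2d <- function(c_in, c_out, h_in, w_in, k = 4L, stride = 2L, pad = 1L) {
  l <- new_layer("convt2d")
  fan_in <- c_in * k * k
  l$params <- list(W = matrix(stats::rnorm(c_in * c_out * k * k,
                                           sd = sqrt(2 / fan_in)),
                              c_in, c_out * k * k),
                   b = numeric(c_out))
  l$grads <- list(W = matrix(0, c_in, c_out * k * k), b = numeric(c_out))
  l$h_out <- (h_in - 1) * stride - 2 * pad + k
  l$w_out <- (w_in - 1) * stride - 2 * pad + k
  l$forward <- function(x, training = TRUE) {
    l$x <- x
    cpp_convt2d_forward(x, l$params$W, l$params$b, c_in, h_in, w_in,
                        c_out, k, stride, pad)
  }
  l$backward <- function(dy) {
    bk <- cpp_convt2d_backward(l$x, l$params$W, dy, c_in, h_in, w_in,
                               c_out, k, stride, pad)
    l$grads$W <- l$grads$W + bk$dW
    l$grads$b <- l$grads$b + as.numeric(bk$db)
    bk$dX
  }
  l
}

#' Sequential container
#' @keywords internal
nn_sequential <- function(...) {
  layers <- list(...)
  if (length(layers) == 1L && is.list(layers[[1]]) &&
      !inherits(layers[[1]], "nn_layer")) {
    layers <- layers[[1]]
  }
  s <- new_layer("sequential")
  s$layers <- layers
  s$forward <- function(x, training = TRUE) {
    for (lay in s$layers) x <- lay$forward(x, training)
    x
  }
  s$backward <- function(dy) {
    for (lay in rev(s$layers)) dy <- lay$backward(dy)
    dy
  }
  s
}

## Recursively collect parameterized layer environments.
collect_layers <- function(x) {
  if (inherits(x, "nn_layer")) {
    if (identical(x$type, "sequential")) {
      return(unlist(lapply(x$layers, collect_layers), recursive = FALSE))
    }
    if (length(x$params)) return(list(x))
    return(list())
  }
  if (is.list(x)) return(unlist(lapply(x, collect_layers), recursive = FALSE))
  list()
}

#' AdamW optimizer over a set of layers
#'
#' Adaptive-moment gradient descent with decoupled weight decay. Weight decay
#' is applied to weight matrices only, never to biases or batch-norm
#' parameters. Layers exposing `post_step` (mask re-zeroing) have it invoked
#' after every update, so hard weight constraints survive optimization exactly.
#'
#' @keywords internal
optim_adamw <- function(layers, lr = 1e-4, weight_decay = 0,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  layers <- collect_layers(layers)
  st <- new.env(parent = emptyenv())
  st$t <- 0L
  st$m <- lapply(layers, function(l) lapply(l$params, function(p) p * 0))
  st$v <- lapply(layers, function(l) lapply(l$params, function(p) p * 0))
  st$layers <- layers
  st$zero_grad <- function() {
    for (l in st$layers) {
      for (nm in names(l$grads)) l$grads[[nm]] <- l$grads[[nm]] * 0
    }
    invisible(NULL)
  }
  st$step <- function() {
    st$t <- st$t + 1L
    bc1 <- 1 - beta1^st$t
    bc2 <- 1 - beta2^st$t
    for (i in seq_along(st$layers)) {
      l <- st$layers[[i]]
      for (nm in names(l$params)) {
        g <- l$grads[[nm]]
        st$m[[i]][[nm]] <- beta1 * st$m[[i]][[nm]] + (1 - beta1) * g
        st$v[[i]][[nm]] <- beta2 * st$v[[i]][[nm]] + (1 - beta2) * g * g
        upd <- (st$m[[i]][[nm]] / bc1) / (sqrt(st$v[[i]][[nm]] / bc2) + eps)
        if (weight_decay > 0 && nm == "W") {
          upd <- upd + weight_decay * l$params[[nm]]
        }
        l$params[[nm]] <- l$params[[nm]] - lr * upd
      }
      if (!is.null(l$post_step)) l$post_step()
    }
    invisible(NULL)
  }
  st
}

## Snapshot / restore of all parameters and batch-norm buffers (deep copies).
snapshot_params <- function(layers) {
  lapply(collect_layers(layers), function(l) {
    list(params = l$params,
         running_mean = l$running_mean,
         running_var = l$running_var)
  })
}

restore_params <- function(layers, snap) {
  layers <- collect_layers(layers)
  stopifnot(length(layers) == length(snap))
  for (i in seq_along(layers)) {
    layers[[i]]$params <- snap[[i]]$params
    if (!is.null(snap[[i]]$running_mean)) {
      layers[[i]]$running_mean <- snap[[i]]$running_mean
      layers[[i]]$running_var <- snap[[i]]$running_var
    }
    if (!is.null(layers[[i]]$post_step)) layers[[i]]$post_step()
  }
  invisible(NULL)
}
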
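## Constructors for the five autoencoder architectures. A model is a mutable
## environment holding encoder layers, latent heads and decoder layers, plus
## the plan metadata (hidden dims, masks, image geometry) used to build it.

#' Hidden layer dimensions from an encoding factor
#'
#' Each hidden layer shrinks the previous width by the encoding factor `e`,
#' floored and clamped from below by the latent dimension:
#' `h_i = max(floor(h_{i-1} / e), L_dim)` with `h_0 = input_dim`.
#'
#' @param input_dim input width (`h_0`).
#' @param e encoding factor (> 1).
#' @param l_dim latent dimension (lower bound for all hidden widths).
#' @param n_hidden number of hidden layers.
#' @return integer vector of hidden widths, length `n_hidden`.
#' @export
build_hidden_dims <- function(input_dim, e, l_dim, n_hidden) {
  stopifnot(input_dim >= l_dim, l_dim >= 1, e > 1, n_hidden >= 1)
  h <- integer(n_hidden)
  prev <- input_dim
  for (i in seq_len(n_hidden)) {
    h[i] <- as.integer(max(floor(prev / e), l_dim))
    prev <- h[i]
  }
  h
}

#' Reparameterization trick
#'
#' `z = mu + eps * exp(log_var / 2)` with `eps` standard normal; with
#' `eps = 0` the embedding is deterministic (`z = mu`).
#'
#' @param mu,log_var numeric vectors/matrices of equal shape.
#' @param eps standard-normal noise of the same shape (default: drawn).
#' @return z of the same shape.
#' @export
reparameterize <- function(mu, log_var, eps = NULL) {
  stopifnot(length(mu) == length(log_var))
  if (is.null(eps)) {
    eps <- stats::rnorm(length(mu))
    if (is.matrix(mu)) eps <- matrix(eps, nrow(mu), ncol(mu))
  }
  mu + eps * exp(0.5 * log_var)
}

## One dense block: linear -> batch-norm -> dropout -> (ReLU).
dense_block <- function(d_in, d_out, dropout, relu = TRUE) {
  ls <- list(nn_linear(d_in, d_out), nn_batchnorm(d_out), nn_dropout(dropout))
  if (relu) ls <- c(ls, list(nn_relu()))
  ls
}

## Dense encoder trunk over the hidden widths; the last block (feeding the
## latent heads) has no ReLU.
dense_encoder <- function(input_dim, hidden, dropout) {
  ls <- list()
  prev <- input_dim
  for (i in seq_along(hidden)) {
    ls <- c(ls, dense_block(prev, hidden[i], dropout, relu = i < length(hidden)))
    prev <- hidden[i]
  }
  nn_sequential(ls)
}

## Mirrored dense decoder: latent -> rev(hidden) blocks -> linear output
## (no ReLU on the output layer; sigmoid for BCE reconstruction).
dense_decoder <- function(l_dim, hidden, input_dim, dropout, sigmoid_out = FALSE) {
  dims <- rev(hidden)
  ls <- list()
  prev <- l_dim
  for (i in seq_along(dims)) {
    ls <- c(ls, dense_block(prev, dims[i], dropout, relu = TRUE))
    prev <- dims[i]
  }
  ls <- c(ls, list(nn_linear(prev, input_dim)))
  if (sigmoid_out) ls <- c(ls, list(nn_sigmoid()))
  nn_sequential(ls)
}

new_ae_model <- function(architecture, encoder, mu_head, logvar_head, decoder,
                         config, meta = list()) {
  m <- new.env(parent = emptyenv())
  m$architecture <- architecture
  m$encoder <- encoder
  m$mu_head <- mu_head
  m$logvar_head <- logvar_head
  m$decoder <- decoder
  m$config <- config
  m$meta <- meta
  class(m) <- c(paste0(architecture, "_model"), "ae_model")
  m
}

model_layers <- function(model) {
  c(list(model$encoder, model$mu_head),
    if (!is.null(model$logvar_head)) list(model$logvar_head),
    list(model$decoder))
}

#' Number of trainable parameters of a model
#' @export
n_params <- function(model) {
  sum(vapply(collect_layers(model_layers(model)),
             function(l) sum(vapply(l$params, length, 0L)), 0L))
}

#' Forward pass through an autoencoder
#'
#' @param model an `ae_model`.
#' @param x input matrix (samples as rows).
#' @param training training mode (batch statistics, dropout active).
#' @param sample draw latent noise (`eps ~ N(0,1)`); with `FALSE` the
#'   deterministic embedding `z = mu` is used.
#' @return list with `xhat`, `mu`, `logvar` (NULL for the vanilla AE), `z`,
#'   `eps`.
#' @export
model_forward <- function(model, x, training = FALSE, sample = FALSE) {
  h <- model$encoder$forward(x, training)
  mu <- model$mu_head$forward(h, training)
  logvar <- NULL
  eps <- NULL
  z <- mu
  if (!is.null(model$logvar_head)) {
    logvar <- model$logvar_head$forward(h, training)
    logvar <- pmin(pmax(logvar, -15), 15)  # numerical guard
    if (sample) {
      eps <- matrix(stats::rnorm(length(mu)), nrow(mu), ncol(mu))
      z <- mu + eps * exp(0.5 * logvar)
    }
  }
  xhat <- model$decoder$forward(z, training)
  list(xhat = xhat, mu = mu, logvar = logvar, z = z, eps = eps)
}

#' Deterministic embedding (mu, inference mode) of samples
#' @export
embed_samples <- function(model, x) {
  model_forward(model, x, training = FALSE, sample = FALSE)$mu
}

#' Vanilla autoencoder (deterministic bottleneck)
#'
#' @param input_dim number of input features.
#' @param config a `run_config`.
#' @return an `ae_model` whose latent layer is a plain linear map (no
#'   mu/log-variance heads); the training loss is reconstruction only.
#' @export
build_vanillix <- function(input_dim, config) {
  hd <- build_hidden_dims(input_dim, config$encoding_factor, config$latent_dim,
                          config$n_hidden)
  enc <- dense_encoder(input_dim, hd, config$dropout)
  mu <- nn_linear(hd[length(hd)], config$latent_dim)
  dec <- dense_decoder(config$latent_dim, hd, input_dim, config$dropout,
                       sigmoid_out = config$recon_loss == "bce")
  new_ae_model("vanillix", enc, mu, NULL, dec, config,
               meta = list(hidden = hd, input_dim = input_dim))
}

#' Variational autoencoder with a standard Gaussian prior
#'
#' Mean and log-variance heads of width `latent_dim` sit on a shared dense
#' encoder trunk; the decoder mirrors the encoder. Training combines the
#' reconstruction loss with a beta-weighted similarity loss (KL or MMD).
#'
#' @inheritParams build_vanillix
#' @export
build_varix <- function(input_dim, config) {
  hd <- build_hidden_dims(input_dim, config$encoding_factor, config$latent_dim,
                          config$n_hidden)
  enc <- dense_encoder(input_dim, hd, config$dropout)
  mu <- nn_linear(hd[length(hd)], config$latent_dim)
  lv <- nn_linear(hd[length(hd)], config$latent_dim, init_scale = 0.1)
  dec <- dense_decoder(config$latent_dim, hd, input_dim, config$dropout,
                       sigmoid_out = config$recon_loss == "bce")
  new_ae_model("varix", enc, mu, lv, dec, config,
               meta = list(hidden = hd, input_dim = input_dim))
}

#' Per-modality latent width of the stacked architecture
#' @keywords internal
stackix_latent_dim <- function(k_input) max(2L, as.integer(round(k_input / 8)))

#' Stacked (hierarchical) variational autoencoder plan
#'
#' One VAE per modality with latent width `d_m = max(2, round(k_m / 8))`; a
#' top VAE maps the concatenated per-modality embeddings to `latent_dim`.
#' Training is an uncoupled two-phase process (see [fit_stackix()]).
#'
#' @param input_dims named integer vector of per-modality feature counts.
#' @param config a `run_config`.
#' @return a `stackix_plan` with per-modality models and a top model.
#' @export
build_stackix <- function(input_dims, config) {
  input_dims <- as.integer(input_dims)
  d <- vapply(input_dims, stackix_latent_dim, 0L)
  sub <- vector("list", length(input_dims))
  for (i in seq_along(input_dims)) {
    sub_cfg <- config
    sub_cfg$latent_dim <- d[i]
    sub[[i]] <- build_varix(input_dims[i], sub_cfg)
  }
  top <- build_varix(sum(d), config)
  structure(list(modality_models = sub, top_model = top, d = d,
                 input_dims = input_dims, config = config),
            class = c("stackix_plan"))
}

#' Decoder mask set from an ontology
#'
#' Masks are 0/1 matrices in layer orientation (input units x output units):
#' for a two-level ontology, `latent (super-terms) -> level-1 terms` and
#' `level-1 terms -> features`; for one level, `latent (terms) -> features`.
#' An entry is 1 exactly when the corresponding ontology edge exists.
#'
#' @param onto an [ontology_map()].
#' @param features feature ids in decoder output order; every feature must be
#'   mapped by the ontology.
#' @return list of masks (`lvl2` optionally, then `lvl1`).
#' @export
build_ontix_masks <- function(onto, features) {
  features <- as.character(features)
  unmapped <- setdiff(features, onto$features)
  if (length(unmapped)) {
    stop("features without ontology mapping (drop them first): ",
         paste(utils::head(unmapped, 5), collapse = ", "))
  }
  m1 <- matrix(0, length(onto$terms1), length(features),
               dimnames = list(onto$terms1, features))
  e1 <- onto$lvl1[onto$lvl1$feature_id %in% features, ]
  m1[cbind(match(e1$term_id, onto$terms1), match(e1$feature_id, features))] <- 1
  masks <- list(lvl1 = m1)
  if (!is.null(onto$lvl2)) {
    m2 <- matrix(0, length(onto$terms2), length(onto$terms1),
                 dimnames = list(onto$terms2, onto$terms1))
    m2[cbind(match(onto$lvl2$super_term_id, onto$terms2),
             match(onto$lvl2$term_id, onto$terms1))] <- 1
    masks <- c(list(lvl2 = m2), masks)
  }
  masks
}

#' Ontology-masked variational autoencoder
#'
#' The decoder is the masked linear stack prescribed by the ontology, so each
#' latent dimension corresponds to one top-level term; masked weights are
#' exactly zero before, during and after training (re-zeroed after every
#' optimizer step). If `latent_dim` is smaller than the number of top-level
#' terms, one additional fully connected (dense, unmasked) layer is inserted
#' on both the encoder and decoder ends for further dimension reduction.
#'
#' @param onto an [ontology_map()].
#' @param features feature ids (decoder output order); must all be mapped.
#' @param config a `run_config`.
#' @export
build_ontix <- function(onto, features, config) {
  masks <- build_ontix_masks(onto, features)
  n_top <- n_top_terms(onto)
  l_dim <- config$latent_dim
  if (l_dim > n_top) {
    stop("latent_dim (", l_dim, ") exceeds the number of top-level ontology terms (",
         n_top, ")")
  }
  input_dim <- length(features)
  hd <- build_hidden_dims(input_dim, config$encoding_factor, l_dim, config$n_hidden)
  extra <- l_dim < n_top
  enc_layers <- list(dense_encoder(input_dim, hd, config$dropout))
  if (extra) {
    ## additional fully connected layer on the encoder end (no ReLU: it is
    ## the last layer before the latent heads)
    enc_layers <- c(enc_layers,
                    list(nn_sequential(dense_block(hd[length(hd)], n_top,
                                                   config$dropout, relu = FALSE))))
    head_in <- n_top
  } else {
    head_in <- hd[length(hd)]
  }
  enc <- nn_sequential(enc_layers)
  mu <- nn_linear(head_in, l_dim)
  lv <- nn_linear(head_in, l_dim, init_scale = 0.1)
  dec_layers <- list()
  if (extra) dec_layers <- c(dec_layers, list(nn_linear(l_dim, n_top), nn_relu()))
  if (!is.null(masks$lvl2)) {
    dec_layers <- c(dec_layers,
                    list(nn_linear(nrow(masks$lvl2), ncol(masks$lvl2),
                                   mask = unname(masks$lvl2)),
                         nn_relu()))
  }
  dec_layers <- c(dec_layers,
                  list(nn_linear(nrow(masks$lvl1), ncol(masks$lvl1),
                                 mask = unname(masks$lvl1))))
  if (config$recon_loss == "bce") dec_layers <- c(dec_layers, list(nn_sigmoid()))
  dec <- nn_sequential(dec_layers)
  m <- new_ae_model("ontix", enc, mu, lv, dec, config,
                    meta = list(hidden = hd, input_dim = input_dim,
                                n_top = n_top, extra_fc = extra,
                                features = features,
                                term_names = if (!is.null(onto$terms2)) onto$terms2 else onto$terms1))
  m$masks <- masks
  m
}

#' Extract current masked-decoder weights (for mask-invariance checks)
#' @keywords internal
masked_decoder_weights <- function(model) {
  lapply(collect_layers(model$decoder), function(l) {
    if (!is.null(l$mask)) list(W = l$params$W, mask = l$mask) else NULL
  })
}

#' Convolutional image VAE
#'
#' Encoder of five convolution layers (kernel 4, stride 2, padding 1, each
#' halving the spatial side; channel widths 32-64-128-256-512 with batch
#' normalization and ReLU), flattened into mean/log-variance heads; the
#' decoder mirrors with five transposed convolutions. Output activation is
#' sigmoid for BCE reconstruction and linear for MSE. Input images must be
#' square with side divisible by 32. Channel widths double per layer
#' (16-32-64-128-256), sized for single-CPU training.
#'
#' @param channels input channel count C.
#' @param side image height = width; must be divisible by 32.
#' @param config a `run_config`.
#' @export
build_image_vae <- function(channels, side, config) {
  if (side %% 32 != 0) stop("image side (", side, ") must be divisible by 32")
  widths <- c(16L, 32L, 64L, 128L, 256L)
  enc_layers <- list()
  c_prev <- channels
  s <- side
  for (i in seq_along(widths)) {
    enc_layers <- c(enc_layers, list(
      nn_conv2d(c_prev, widths[i], s, s),
      nn_batchnorm(widths[i], spatial = (s %/% 2L)^2),
      nn_relu()))
    c_prev <- widths[i]
    s <- s %/% 2L
  }
  flat <- widths[length(widths)] * s * s
  enc <- nn_sequential(enc_layers)
  mu <- nn_linear(flat, config$latent_dim)
  lv <- nn_linear(flat, config$latent_dim, init_scale = 0.1)
  dec_layers <- list(nn_linear(config$latent_dim, flat), nn_relu())
  rw <- rev(widths)
  si <- s
  for (i in seq_along(rw)) {
    c_out <- if (i < length(rw)) rw[i + 1] else channels
    dec_layers <- c(dec_layers, list(nn_convt2d(rw[i], c_out, si, si)))
    si <- si * 2L
    if (i < length(rw)) {
      dec_layers <- c(dec_layers,
                      list(nn_batchnorm(c_out, spatial = si^2), nn_relu()))
    }
  }
  if (config$recon_loss == "bce") dec_layers <- c(dec_layers, list(nn_sigmoid()))
  dec <- nn_sequential(dec_layers)
  new_ae_model("image_vae", enc, mu, lv, dec, config,
               meta = list(channels = channels, side = side,
                           latent_side = s, flat = flat,
                           input_dim = channels * side * side))
}

#' Cross-modal VAE pair with a latent-space classifier
#'
#' Two VAEs sharing one latent dimensionality: a dense VAE for the numeric
#' source modality A and either an image VAE or a second dense VAE for the
#' target modality B, plus an adversarial latent classifier used to align the
#' two latent spaces during training.
#'
#' @param input_dim_a feature count of the numeric modality A.
#' @param spec_b either `list(kind = "image", channels =, side =)` or
#'   `list(kind = "numeric", input_dim =)`.
#' @param config a `run_config`.
#' @export
build_xmodalix <- function(input_dim_a, spec_b, config) {
  model_a <- build_varix(input_dim_a, config)
  model_b <- if (identical(spec_b$kind, "image")) {
    build_image_vae(spec_b$channels, spec_b$side, config)
  } else {
    build_varix(spec_b$input_dim, config)
  }
  clf <- build_latent_classifier(config$latent_dim)
  structure(list(model_a = model_a, model_b = model_b, classifier = clf,
                 config = config),
            class = "xmodalix_plan")
}

#' Latent-space modality classifier (input, two hidden layers, output)
#' @keywords internal
build_latent_classifier <- function(l_dim, hidden = max(16L, 2L * l_dim)) {
  nn_sequential(
    nn_linear(l_dim, hidden), nn_relu(),
    nn_linear(hidden, hidden), nn_relu(),
    nn_linear(hidden, 2L))
}

#' Translate samples from modality A into modality B
#'
#' Encodes `x_a` with the modality-A encoder into the deterministic embedding
#' `z = mu` and decodes it with the modality-B decoder.
#'
#' @param pair an `xmodalix_plan` (trained or not).
#' @param x_a samples of modality A (rows).
#' @param z optional latent matrix to decode directly (e.g. class centers);
#'   overrides `x_a`.
#' @return the modality-B reconstruction.
#' @export
translate <- function(pair, x_a = NULL, z = NULL) {
  stopifnot(inherits(pair, "xmodalix_plan"))
  if (is.null(z)) {
    stopifnot(!is.null(x_a))
    z <- embed_samples(pair$model_a, x_a)
  }
  pair$model_b$decoder$forward(z, training = FALSE)
}

#' Class centers in latent space (per-dimension median across samples)
#'
#' @param z embedding matrix (samples x latent dims).
#' @param classes class label per sample.
#' @return matrix of class centers (classes x latent dims).
#' @export
class_center_z <- function(z, classes) {
  classes <- as.character(classes)
  lv <- sort(unique(classes), method = "radix")
  out <- matrix(NA_real_, length(lv), ncol(z), dimnames = list(lv, colnames(z)))
  for (cl in lv) {
    out[cl, ] <- apply(z[classes == cl, , drop = FALSE], 2, stats::median)
  }
  out
}
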
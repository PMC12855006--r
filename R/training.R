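## Loss functions, logistic beta annealing, and the optimizer loops for all
## architectures, including the two-phase stacked training and the
## adversarial cross-modal alignment.

#' Logistic annealing schedule for the similarity-loss weight beta
#'
#' `beta(epoch) = beta_final / (1 + exp(-B * (epoch - M * total_epochs)))`:
#' beta rises smoothly from ~0 to `beta_final`, reaching `beta_final / 2` at
#' the midpoint epoch `M * total_epochs`. Annealing protects VAE training
#' against posterior collapse early on.
#'
#' @param epoch current epoch (0-based).
#' @param beta_final final weight.
#' @param steepness logistic steepness B (> 0).
#' @param midpoint relative midpoint M in (0, 1).
#' @param total_epochs schedule length.
#' @return beta at `epoch`.
#' @export
beta_at <- function(epoch, beta_final, steepness, midpoint, total_epochs) {
  beta_final / (1 + exp(-steepness * (epoch - midpoint * total_epochs)))
}

beta_from_config <- function(epoch, config, total_epochs = config$epochs) {
  beta_at(epoch, config$beta_final, config$anneal_steepness,
          config$anneal_midpoint, total_epochs)
}

#' Reconstruction loss (mean squared error or binary cross-entropy)
#'
#' Mean over all entries (batch and features), so the loss is comparable
#' across input widths.
#'
#' @param x,xhat matrices of equal shape; BCE requires values in `[0, 1]`.
#' @param kind `"mse"` or `"bce"`.
#' @export
recon_loss <- function(x, xhat, kind = c("mse", "bce")) {
  kind <- match.arg(kind)
  if (kind == "mse") return(mean((x - xhat)^2))
  p <- pmin(pmax(xhat, 1e-7), 1 - 1e-7)
  -mean(x * log(p) + (1 - x) * log(1 - p))
}

recon_grad <- function(x, xhat, kind) {
  if (kind == "mse") return(2 * (xhat - x) / length(x))
  p <- pmin(pmax(xhat, 1e-7), 1 - 1e-7)
  (-x / p + (1 - x) / (1 - p)) / length(x)
}

#' KL divergence of a diagonal Gaussian posterior from the standard normal
#'
#' `0.5 * sum_d(mu^2 + sigma^2 - 1 - log sigma^2)`, summed over latent
#' dimensions and averaged over the batch. Zero exactly at the prior.
#'
#' @param mu,log_var matrices (batch x latent) or vectors.
#' @export
kl_loss <- function(mu, log_var) {
  if (!is.matrix(mu)) mu <- matrix(mu, 1)
  if (!is.matrix(log_var)) log_var <- matrix(log_var, 1)
  mean(rowSums(0.5 * (mu^2 + exp(log_var) - 1 - log_var)))
}

kl_grads <- function(mu, log_var) {
  n <- nrow(mu)
  list(dmu = mu / n, dlogvar = 0.5 * (exp(log_var) - 1) / n)
}

rbf_bandwidth <- function(d2) {
  h2 <- stats::median(d2[d2 > 1e-12])
  if (!is.finite(h2) || h2 <= 0) h2 <- 1
  h2
}

#' Maximum mean discrepancy (unbiased, RBF kernel, median heuristic)
#'
#' Unbiased MMD^2 estimate between an embedding batch and a prior batch
#' (standard normal draws by default), clamped at zero.
#'
#' @param z embedding batch (matrix, samples as rows).
#' @param prior prior batch; default: standard-normal draws of the same shape.
#' @param return_grad also return the gradient with respect to `z`
#'   (bandwidth treated as a constant).
#' @param bandwidth optional fixed kernel bandwidth (squared scale `h^2`);
#'   default: median heuristic on the pooled pairwise squared distances.
#' @export
mmd_loss <- function(z, prior = NULL, return_grad = FALSE, bandwidth = NULL) {
  z <- as.matrix(z)
  if (is.null(prior)) prior <- matrix(stats::rnorm(length(z)), nrow(z), ncol(z))
  m <- nrow(z)
  n <- nrow(prior)
  all_pts <- rbind(z, prior)
  sq <- rowSums(all_pts^2)
  d2 <- pmax(outer(sq, sq, "+") - 2 * tcrossprod(all_pts), 0)
  h2 <- if (is.null(bandwidth)) rbf_bandwidth(d2) else bandwidth
  K <- exp(-d2 / (2 * h2))
  Kzz <- K[seq_len(m), seq_len(m), drop = FALSE]
  Kpp <- K[m + seq_len(n), m + seq_len(n), drop = FALSE]
  Kzp <- K[seq_len(m), m + seq_len(n), drop = FALSE]
  t1 <- if (m > 1) (sum(Kzz) - m) / (m * (m - 1)) else 0
  t2 <- if (n > 1) (sum(Kpp) - n) / (n * (n - 1)) else 0
  t3 <- sum(Kzp) / (m * n)
  raw <- t1 + t2 - 2 * t3
  val <- max(raw, 0)
  if (!return_grad) return(val)
  if (raw <= 0) return(list(value = 0, grad = matrix(0, m, ncol(z))))
  ## d k(a,b) / d a = -k * (a - b) / h2
  gz <- matrix(0, m, ncol(z))
  if (m > 1) {
    w <- Kzz / (m * (m - 1))
    diag(w) <- 0
    gz <- gz - 2 / h2 * (rowSums(w) * z - w %*% z)
  }
  wzp <- Kzp / (m * n)
  gz <- gz + 2 / h2 * (rowSums(wzp) * z - wzp %*% prior)
  list(value = val, grad = gz)
}

#' Adversarial cross-entropy losses for latent-space alignment
#'
#' A modality classifier scores the pooled embeddings; the classifier loss
#' uses the true modality labels (embeddings treated as constants), while the
#' generator loss scores the same batch against flipped labels, penalizing
#' latent spaces that are easy to discriminate.
#'
#' @param z_a,z_b latent batches of the two modalities (nonempty).
#' @param classifier classifier network (see `build_latent_classifier`).
#' @return list with `classifier_ce` and `generator_ce`.
#' @export
adversarial_losses <- function(z_a, z_b, classifier) {
  if (!nrow(z_a) || !nrow(z_b)) {
    stop("adversarial loss needs samples from both modalities in the batch")
  }
  z <- rbind(z_a, z_b)
  labels <- rep(1:2, c(nrow(z_a), nrow(z_b)))
  logits <- classifier$forward(z, training = FALSE)
  list(classifier_ce = softmax_ce(logits, labels)$value,
       generator_ce = softmax_ce(logits, 3L - labels)$value)
}

softmax_ce <- function(logits, labels) {
  mx <- apply(logits, 1, max)
  el <- exp(logits - mx)
  p <- el / rowSums(el)
  n <- nrow(logits)
  idx <- cbind(seq_len(n), labels)
  value <- -mean(log(pmax(p[idx], 1e-12)))
  grad <- p
  grad[idx] <- grad[idx] - 1
  list(value = value, grad = grad / n, p = p)
}

#' Paired alignment loss (mean absolute deviation across latent dimensions)
#'
#' For samples measured in both modalities: the mean over samples of the mean
#' absolute difference between their two embeddings.
#'
#' @param z_a,z_b equally shaped latent batches, identical sample order.
#' @export
paired_loss <- function(z_a, z_b) {
  stopifnot(identical(dim(z_a), dim(z_b)))
  mean(abs(z_a - z_b))
}

#' Class-center compactness loss
#'
#' Per class, the center is the mean embedding of that class within the batch
#' (pooled over modalities by the caller); the loss is the mean absolute
#' deviation of samples from their class center.
#'
#' @param z latent batch.
#' @param classes class label per row.
#' @param centers optional fixed centers (classes x dims); default: computed
#'   within the batch.
#' @export
class_center_loss <- function(z, classes, centers = NULL) {
  classes <- as.character(classes)
  if (is.null(centers)) centers <- batch_class_centers(z, classes)
  mean(abs(z - centers[classes, , drop = FALSE]))
}

batch_class_centers <- function(z, classes) {
  rs <- rowsum(z, classes)
  cnt <- table(classes)
  rs / as.vector(cnt[rownames(rs)])
}

class_center_grad <- function(z, classes, centers = NULL) {
  classes <- as.character(classes)
  if (is.null(centers)) centers <- batch_class_centers(z, classes)
  ## centers treated as constants (stop-gradient)
  sign(z - centers[classes, , drop = FALSE]) / length(z)
}

make_batches <- function(idx, batch_size) {
  idx <- sample(idx)
  n <- length(idx)
  starts <- seq(1, n, by = batch_size)
  out <- lapply(starts, function(s) idx[s:min(s + batch_size - 1, n)])
  out[vapply(out, length, 0L) >= 2L]  # batch-norm needs >= 2 samples
}

## One optimizer step of a dense/image autoencoder on a batch. Returns the
## loss components. Gradients: reconstruction through the decoder, then
## chained through the reparameterization into the mu / log-variance heads,
## plus the analytic KL (or MMD) gradients at the latent layer.
ae_train_step <- function(model, xb, beta, opt, extra_dz = NULL) {
  cfg <- model$config
  is_vae <- !is.null(model$logvar_head)
  fw <- model_forward(model, xb, training = TRUE, sample = is_vae)
  rec <- recon_loss(xb, fw$xhat, cfg$recon_loss)
  if (!is.finite(rec)) stop("non-finite reconstruction loss; try a lower learning rate")
  dxhat <- recon_grad(xb, fw$xhat, cfg$recon_loss)
  dz <- model$decoder$backward(dxhat)
  if (!is.null(extra_dz)) dz <- dz + extra_dz
  sim <- 0
  if (is_vae) {
    dmu <- dz
    dlogvar <- dz * fw$eps * 0.5 * exp(0.5 * fw$logvar)
    if (cfg$sim_loss == "kl") {
      sim <- kl_loss(fw$mu, fw$logvar)
      kg <- kl_grads(fw$mu, fw$logvar)
      dmu <- dmu + beta * kg$dmu
      dlogvar <- dlogvar + beta * kg$dlogvar
    } else {
      mm <- mmd_loss(fw$z, return_grad = TRUE)
      sim <- mm$value
      dmu <- dmu + beta * mm$grad
      dlogvar <- dlogvar + beta * mm$grad * fw$eps * 0.5 * exp(0.5 * fw$logvar)
    }
    dh <- model$mu_head$backward(dmu) + model$logvar_head$backward(dlogvar)
  } else {
    dh <- model$mu_head$backward(dz)
  }
  model$encoder$backward(dh)
  if (!is.null(opt)) {
    opt$step()
    opt$zero_grad()
  }
  list(recon = rec, sim = sim, total = rec + beta * sim, fw = fw)
}

## Validation losses in inference mode (deterministic z = mu, final beta).
ae_eval_loss <- function(model, x) {
  cfg <- model$config
  fw <- model_forward(model, x, training = FALSE, sample = FALSE)
  rec <- recon_loss(x, fw$xhat, cfg$recon_loss)
  sim <- if (!is.null(model$logvar_head)) {
    if (cfg$sim_loss == "kl") kl_loss(fw$mu, fw$logvar) else mmd_loss(fw$z)
  } else 0
  list(recon = rec, sim = sim, total = rec + cfg$beta_final * sim)
}

#' Train an autoencoder with minibatch AdamW
#'
#' Runs `config$epochs` epochs of minibatch gradient descent. The similarity
#' weight follows the logistic annealing schedule; validation losses are
#' logged each epoch with the final (non-annealed) weight, and the best
#' validation checkpoint is restored at the end.
#'
#' @param model an `ae_model` (vanilla, variational, ontology-masked, image).
#' @param x numeric input matrix (samples as rows), already preprocessed.
#' @param split a [split_dataset()] assignment aligned with the rows of `x`
#'   (or NULL to train on all rows without validation tracking).
#' @param config optional `run_config` override (default: the model's).
#' @return list with `model`, `history` (one row per epoch), `best_epoch`.
#' @export
fit_ae <- function(model, x, split = NULL, config = NULL) {
  cfg <- if (is.null(config)) model$config else config
  tr_idx <- if (is.null(split)) seq_len(nrow(x)) else split_idx(split, "train")
  va_idx <- if (is.null(split)) integer() else split_idx(split, "valid")
  if (!length(tr_idx)) stop("empty training split")
  opt <- optim_adamw(model_layers(model), lr = cfg$learning_rate,
                     weight_decay = cfg$weight_decay)
  hist <- vector("list", cfg$epochs)
  best <- Inf
  best_epoch <- NA_integer_
  best_snap <- NULL
  for (ep in seq_len(cfg$epochs)) {
    beta <- beta_from_config(ep - 1, cfg)
    tr_losses <- c(recon = 0, sim = 0, total = 0)
    nb <- 0L
    for (b in make_batches(tr_idx, cfg$batch_size)) {
      st <- ae_train_step(model, x[b, , drop = FALSE], beta, opt)
      tr_losses <- tr_losses + c(st$recon, st$sim, st$total)
      nb <- nb + 1L
    }
    tr_losses <- tr_losses / max(nb, 1L)
    va <- if (length(va_idx)) {
      ae_eval_loss(model, x[va_idx, , drop = FALSE])
    } else {
      list(recon = NA_real_, sim = NA_real_, total = NA_real_)
    }
    hist[[ep]] <- data.frame(epoch = ep, beta = beta,
                             train_recon = tr_losses[["recon"]],
                             train_sim = tr_losses[["sim"]],
                             train_total = tr_losses[["total"]],
                             valid_recon = va$recon, valid_sim = va$sim,
                             valid_total = va$total)
    crit <- if (is.finite(va$total)) va$total else tr_losses[["total"]]
    if (crit < best) {
      best <- crit
      best_epoch <- ep
      best_snap <- snapshot_params(model_layers(model))
    }
  }
  if (!is.null(best_snap)) restore_params(model_layers(model), best_snap)
  list(model = model, history = do.call(rbind, hist), best_epoch = best_epoch)
}

#' Two-phase training of the stacked architecture
#'
#' Phase 1 trains each per-modality VAE independently; phase 2 trains the top
#' VAE on the frozen, concatenated per-modality embeddings (deterministic mu
#' vectors). Phase-1 weights are untouched by phase 2.
#'
#' @param plan a `stackix_plan` from [build_stackix()].
#' @param x_list list of per-modality matrices (same row order).
#' @param split split assignment over the shared samples.
#' @return list with `plan` (trained), `histories`, `embedding` (concatenated
#'   per-modality mu matrix), `modality_r2` (reconstruction R^2 per modality).
#' @export
fit_stackix <- function(plan, x_list, split = NULL) {
  stopifnot(inherits(plan, "stackix_plan"), length(x_list) == length(plan$modality_models))
  histories <- vector("list", length(x_list) + 1L)
  for (i in seq_along(x_list)) {
    histories[[i]] <- fit_ae(plan$modality_models[[i]], x_list[[i]], split)$history
  }
  emb <- do.call(cbind, lapply(seq_along(x_list), function(i) {
    embed_samples(plan$modality_models[[i]], x_list[[i]])
  }))
  histories[[length(histories)]] <- fit_ae(plan$top_model, emb, split)$history
  mod_r2 <- vapply(seq_along(x_list), function(i) {
    fw <- model_forward(plan$modality_models[[i]], x_list[[i]])
    reconstruction_r2(x_list[[i]], fw$xhat)
  }, 0)
  names(mod_r2) <- names(x_list)
  list(plan = plan, histories = histories, embedding = emb, modality_r2 = mod_r2)
}

#' Reconstruct all modalities through the full stacked hierarchy
#' @keywords internal
stackix_reconstruct <- function(plan, x_list) {
  emb <- do.call(cbind, lapply(seq_along(x_list), function(i) {
    embed_samples(plan$modality_models[[i]], x_list[[i]])
  }))
  emb_hat <- model_forward(plan$top_model, emb)$xhat
  offs <- cumsum(c(0L, plan$d))
  lapply(seq_along(x_list), function(i) {
    zi <- emb_hat[, (offs[i] + 1):offs[i + 1], drop = FALSE]
    plan$modality_models[[i]]$decoder$forward(zi, training = FALSE)
  })
}

#' Joint adversarial training of a cross-modal VAE pair
#'
#' Optionally pretrains the modality-B (image) VAE with beta annealing, then
#' alternates per batch between one classifier step (true modality labels)
#' and one VAE step minimizing
#' `recon_A + recon_B + beta * (KL_A + KL_B) + gamma * generator_CE +
#'  delta_paired * paired + delta_class * class_center`.
#'
#' @param pair an `xmodalix_plan`.
#' @param x_a,x_b per-modality matrices. In paired mode rows correspond; in
#'   unpaired mode only `classes` link the modalities.
#' @param split split assignment (over rows of `x_a`; `x_b` uses the same
#'   index set in paired mode and its own shuffle otherwise).
#' @param classes_a,classes_b optional class label per row (needed when
#'   `delta_class > 0`).
#' @param paired whether rows of `x_a` and `x_b` are the same samples.
#' @return list with `pair`, `history`.
#' @export
fit_xmodalix <- function(pair, x_a, x_b, split = NULL,
                         classes_a = NULL, classes_b = NULL, paired = TRUE) {
  cfg <- pair$config
  if (cfg$gamma == 0 && cfg$delta_paired == 0 && cfg$delta_class == 0) {
    warning("gamma, delta_paired and delta_class are all zero: no alignment pressure")
  }
  if (cfg$delta_class > 0 && (is.null(classes_a) || is.null(classes_b))) {
    stop("delta_class > 0 requires class labels for both modalities")
  }
  if (cfg$delta_paired > 0 && !paired) {
    stop("delta_paired > 0 requires paired samples")
  }
  tr_a <- if (is.null(split)) seq_len(nrow(x_a)) else split_idx(split, "train")
  ## pretraining of the image/second VAE
  pre_hist <- NULL
  if (cfg$pretrain_epochs > 0) {
    pre_cfg <- cfg
    pre_cfg$epochs <- cfg$pretrain_epochs
    pre_cfg$anneal_steepness <- 15 / max(1L, pre_cfg$epochs)
    pre_hist <- fit_ae(pair$model_b, x_b, split, config = pre_cfg)$history
    pre_hist$phase <- "pretrain"
  }
  opt_vae <- optim_adamw(c(model_layers(pair$model_a), model_layers(pair$model_b)),
                         lr = cfg$learning_rate, weight_decay = cfg$weight_decay)
  opt_clf <- optim_adamw(list(pair$classifier), lr = 10 * cfg$learning_rate)
  hist <- vector("list", cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    beta <- beta_from_config(ep - 1, cfg)
    acc <- c(recon_a = 0, recon_b = 0, sim = 0, clf_ce = 0, gen_ce = 0,
             paired = 0, center = 0, total = 0)
    nb <- 0L
    batches <- make_batches(tr_a, cfg$batch_size)
    for (b in batches) {
      b_b <- if (paired) b else sample(tr_a, length(b))
      xa <- x_a[b, , drop = FALSE]
      xb <- x_b[b_b, , drop = FALSE]
      fa <- model_forward(pair$model_a, xa, training = TRUE, sample = TRUE)
      fb <- model_forward(pair$model_b, xb, training = TRUE, sample = TRUE)
      zab <- rbind(fa$z, fb$z)
      labels <- rep(1:2, c(nrow(fa$z), nrow(fb$z)))
      ## --- classifier step (embeddings treated as constants) ---
      logits <- pair$classifier$forward(zab, training = TRUE)
      ce <- softmax_ce(logits, labels)
      pair$classifier$backward(ce$grad)
      opt_clf$step()
      opt_clf$zero_grad()
      ## --- VAE step against the updated classifier, flipped labels ---
      gen <- softmax_ce(pair$classifier$forward(zab, training = FALSE), 3L - labels)
      dz_gen <- pair$classifier$backward(gen$grad) * cfg$gamma
      opt_clf$zero_grad()  # generator pass must not leak into the next classifier step
      dz_a <- dz_gen[seq_len(nrow(fa$z)), , drop = FALSE]
      dz_b <- dz_gen[nrow(fa$z) + seq_len(nrow(fb$z)), , drop = FALSE]
      pl <- 0
      if (cfg$delta_paired > 0) {
        pl <- paired_loss(fa$z, fb$z)
        gp <- sign(fa$z - fb$z) / length(fa$z)
        dz_a <- dz_a + cfg$delta_paired * gp
        dz_b <- dz_b - cfg$delta_paired * gp
      }
      cl <- 0
      if (cfg$delta_class > 0) {
        cls <- c(as.character(classes_a[b]), as.character(classes_b[b_b]))
        cl <- class_center_loss(zab, cls)
        gc <- class_center_grad(zab, cls) * cfg$delta_class
        dz_a <- dz_a + gc[seq_len(nrow(fa$z)), , drop = FALSE]
        dz_b <- dz_b + gc[nrow(fa$z) + seq_len(nrow(fb$z)), , drop = FALSE]
      }
      sa <- ae_backward_with_extra(pair$model_a, xa, fa, beta, dz_a)
      sb <- ae_backward_with_extra(pair$model_b, xb, fb, beta, dz_b)
      opt_vae$step()
      opt_vae$zero_grad()
      tot <- sa$recon + sb$recon + beta * (sa$sim + sb$sim) +
        cfg$gamma * gen$value + cfg$delta_paired * pl + cfg$delta_class * cl
      if (!is.finite(tot)) stop("non-finite cross-modal loss at epoch ", ep)
      acc <- acc + c(sa$recon, sb$recon, sa$sim + sb$sim, ce$value, gen$value,
                     pl, cl, tot)
      nb <- nb + 1L
    }
    hist[[ep]] <- data.frame(epoch = ep, beta = beta, phase = "joint",
                             t(acc / max(nb, 1L)))
  }
  hist <- do.call(rbind, hist)
  if (!is.null(pre_hist)) hist <- list(pretrain = pre_hist, joint = hist)
  list(pair = pair, history = hist)
}

## Backward pass of one VAE given its forward cache, reconstruction target
## and an extra gradient arriving at the sampled z (alignment terms).
ae_backward_with_extra <- function(model, xb, fw, beta, dz_extra) {
  cfg <- model$config
  rec <- recon_loss(xb, fw$xhat, cfg$recon_loss)
  dxhat <- recon_grad(xb, fw$xhat, cfg$recon_loss)
  dz <- model$decoder$backward(dxhat) + dz_extra
  dmu <- dz
  dlogvar <- dz * fw$eps * 0.5 * exp(0.5 * fw$logvar)
  sim <- kl_loss(fw$mu, fw$logvar)
  kg <- kl_grads(fw$mu, fw$logvar)
  dmu <- dmu + beta * kg$dmu
  dlogvar <- dlogvar + beta * kg$dlogvar
  dh <- model$mu_head$backward(dmu) + model$logvar_head$backward(dlogvar)
  model$encoder$backward(dh)
  list(recon = rec, sim = sim)
}

#' Held-out accuracy of the latent modality classifier
#' @param pair trained `xmodalix_plan`.
#' @param x_a,x_b held-out samples of each modality.
#' @export
latent_classifier_accuracy <- function(pair, x_a, x_b) {
  za <- embed_samples(pair$model_a, x_a)
  zb <- embed_samples(pair$model_b, x_b)
  logits <- pair$classifier$forward(rbind(za, zb), training = FALSE)
  pred <- max.col(logits, ties.method = "first")
  mean(pred == rep(1:2, c(nrow(za), nrow(zb))))
}

#' Random-search hyperparameter tuning
#'
#' Sequential random search over learning rate, weight decay, dropout and the
#' hidden-layer structure (number of hidden layers / encoding factor). The
#' objective is the best validation total loss with final (non-annealed)
#' weights. `beta_final` is deliberately not searchable: it trades off two
#' loss terms and cannot be selected by minimizing the same loss.
#'
#' @param x input matrix.
#' @param split split assignment.
#' @param config base `run_config` (architecture vanillix/varix).
#' @param n_trials number of trials.
#' @param space list of samplers, each a `function(i)` returning a value;
#'   defaults cover lr (log-uniform 1e-5..1e-2), weight decay (log-uniform
#'   1e-8..1e-3), dropout (uniform 0..0.5), n_hidden (1..3).
#' @param seed RNG seed for the search.
#' @return list with `best_config`, `best_objective`, `trials` (data.frame).
#' @export
tune <- function(x, split, config, n_trials = 10, space = NULL, seed = config$seed) {
  if (is.null(space)) {
    space <- list(
      learning_rate = function(i) 10^stats::runif(1, -5, -2),
      weight_decay = function(i) 10^stats::runif(1, -8, -3),
      dropout = function(i) stats::runif(1, 0, 0.5),
      n_hidden = function(i) sample(1:3, 1))
  }
  if ("beta_final" %in% names(space)) {
    stop("beta_final is not tunable via loss minimization; fix it in the config")
  }
  set.seed(as.integer(seed))
  trials <- vector("list", n_trials)
  best_obj <- Inf
  best_cfg <- config
  for (i in seq_len(n_trials)) {
    cfg_i <- config
    for (nm in names(space)) cfg_i[[nm]] <- space[[nm]](i)
    cfg_i <- validate_config(unclass(cfg_i))
    model <- switch(cfg_i$architecture,
                    vanillix = build_vanillix(ncol(x), cfg_i),
                    varix = build_varix(ncol(x), cfg_i),
                    stop("tune supports vanillix/varix configs"))
    res <- fit_ae(model, x, split, cfg_i)
    obj <- min(res$history$valid_total, na.rm = TRUE)
    trials[[i]] <- data.frame(trial = i,
                              as.data.frame(cfg_i[names(space)]),
                              objective = obj)
    if (obj < best_obj) {
      best_obj <- obj
      best_cfg <- cfg_i
    }
  }
  list(best_config = best_cfg, best_objective = best_obj,
       trials = do.call(rbind, trials))
}
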
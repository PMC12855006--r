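test_that("beta annealing: midpoint, limits, monotonicity", {
  expect_equal(beta_at(50, 0.8, 0.3, 0.5, 100), 0.4)
  expect_equal(beta_at(10, 0, 0.3, 0.5, 100), 0)
  ## steep limit approximates a step
  expect_equal(beta_at(51, 1, 1e3, 0.5, 100), 1, tolerance = 1e-10)
  ## nondecreasing; beta(0) < 0.01 beta_final when B*M*T > 5
  b <- beta_at(0:100, 2, 0.15, 0.5, 100)
  expect_true(all(diff(b) >= 0))
  expect_lt(b[1], 0.01 * 2)
})

test_that("reconstruction and KL losses match closed forms", {
  expect_equal(recon_loss(c(0, 1), c(0, 1), "mse"), 0)
  expect_equal(recon_loss(c(0, 1), c(0.5, 0.5), "mse"), 0.25)
  expect_lt(recon_loss(c(0, 1), c(0, 1), "bce"), 1e-5)
  expect_equal(kl_loss(0, 0), 0)
  expect_equal(kl_loss(1, 0), 0.5)
  expect_equal(kl_loss(0, 1), 0.5 * (exp(1) - 1 - 1), tolerance = 1e-12)
  ## KL zero iff at the prior
  set.seed(1)
  mu <- matrix(rnorm(10, sd = 0.5), 5)
  expect_gt(kl_loss(mu, matrix(0, 5, 2)), 0)
})

test_that("MMD: zero on identical batches, positive for separated masses", {
  set.seed(2)
  z <- matrix(rnorm(60), 20, 3)
  expect_equal(mmd_loss(z, z), 0)
  expect_lt(mmd_loss(z, z[sample(20), ]), 1e-12)
  ## oracle: closed-form kernel sums on 2+2 points
  a <- rbind(c(0, 0), c(0, 0))
  b <- rbind(c(10, 0), c(10, 0))
  ## distances: within 0, across 100; median heuristic bandwidth h2 = 100
  k_across <- exp(-100 / (2 * 100))
  expected <- 1 + 1 - 2 * k_across
  expect_equal(mmd_loss(a, b), expected, tolerance = 1e-12)
  ## analytic gradient vs numeric at fixed bandwidth (the analytic gradient
  ## treats the median-heuristic bandwidth as a constant); batches separated
  ## so the zero-clamp is inactive
  set.seed(3)
  zs <- matrix(rnorm(8), 4, 2) + 3
  pr <- matrix(rnorm(8), 4, 2)
  g <- mmd_loss(zs, pr, return_grad = TRUE, bandwidth = 5)
  eps <- 1e-5
  for (ij in list(c(1, 1), c(2, 1), c(3, 2))) {
    zp <- zs; zp[ij[1], ij[2]] <- zp[ij[1], ij[2]] + eps
    zm <- zs; zm[ij[1], ij[2]] <- zm[ij[1], ij[2]] - eps
    num <- (mmd_loss(zp, pr, bandwidth = 5) -
              mmd_loss(zm, pr, bandwidth = 5)) / (2 * eps)
    expect_equal(g$grad[ij[1], ij[2]], num, tolerance = 1e-4)
  }
})

test_that("adversarial, paired and class-center losses behave per contract", {
  set.seed(4)
  clf <- omixae:::build_latent_classifier(2)
  za <- matrix(rnorm(10), 5, 2)
  zb <- matrix(rnorm(10), 5, 2)
  al <- adversarial_losses(za, zb, clf)
  expect_true(is.finite(al$classifier_ce) && is.finite(al$generator_ce))
  expect_error(adversarial_losses(za[0, , drop = FALSE], zb, clf), "both modalities")
  ## chance-level classifier: both cross-entropies equal ln 2
  ce <- omixae:::softmax_ce(matrix(0, 6, 2), rep(1:2, 3))
  expect_equal(ce$value, log(2))

  expect_equal(paired_loss(za, za), 0)
  expect_equal(paired_loss(rbind(c(0, 0)), rbind(c(1, 3))), 2)
  expect_equal(paired_loss(za, zb), paired_loss(zb, za))

  expect_equal(class_center_loss(rbind(c(1, 1), c(1, 1)), c("a", "a")), 0)
  expect_equal(class_center_loss(matrix(c(0, 2), 2, 1), c("a", "a")), 1)
  ## singleton classes contribute zero
  expect_equal(class_center_loss(matrix(c(5, -3), 2, 1), c("a", "b")), 0)
})

test_that("fit_ae trains, logs, keeps the best checkpoint, is seed-stable", {
  set.seed(5)
  x <- matrix(rnorm(80 * 10), 80, 10)
  x[, 6:10] <- x[, 1:5]  # learnable structure
  split <- split_dataset(80, seed = 5)
  cfg <- quick_cfg(latent_dim = 2, epochs = 8, seed = 5)
  set.seed(5)
  m <- build_varix(10, cfg)
  res <- fit_ae(m, x, split)
  expect_equal(nrow(res$history), 8)
  expect_true(all(is.finite(res$history$train_total)))
  expect_true(all(res$history$beta == beta_at(0:7, cfg$beta_final,
                                              cfg$anneal_steepness, 0.5, 8)))
  ## identical seeds give identical loss histories
  set.seed(5)
  m2 <- build_varix(10, cfg)
  res2 <- fit_ae(m2, x, split)
  expect_identical(res$history, res2$history)
  ## varix with beta_final = 0 trains on reconstruction only
  cfg0 <- quick_cfg(latent_dim = 2, epochs = 3, beta_final = 0, seed = 5)
  set.seed(5)
  m0 <- build_varix(10, cfg0)
  h0 <- fit_ae(m0, x, split)$history
  expect_equal(h0$train_total, h0$train_recon)
})

test_that("stackix two-phase training freezes phase-1 weights", {
  set.seed(6)
  spec <- generator_spec(n = 120, k_true = 2, feature_counts = c(a = 32, b = 24),
                         noise_sd = 0.2, seed = 6)
  truth <- make_multiomics(spec)
  xs <- lapply(truth$dataset$blocks, function(b) {
    apply_scaler(b$matrix, fit_scaler(b$matrix, "standard"))
  })
  split <- split_dataset(rownames(xs[[1]]), seed = 6)
  cfg <- quick_cfg(architecture = "stackix", latent_dim = 2, epochs = 6, seed = 6)
  plan <- build_stackix(vapply(xs, ncol, 0L), cfg)
  expect_equal(nrow(plan$top_model$encoder$layers[[1]]$params$W), sum(plan$d))
  res <- fit_stackix(plan, xs, split)
  ## phase-2 input width = sum of per-modality latents
  expect_equal(ncol(res$embedding), sum(plan$d))
  expect_length(res$modality_r2, 2)
  ## phase-1 weights untouched by phase 2: retrain top on same embeddings
  snap <- omixae:::snapshot_params(omixae:::model_layers(plan$modality_models[[1]]))
  fit_ae(plan$top_model, res$embedding, split)
  snap2 <- omixae:::snapshot_params(omixae:::model_layers(plan$modality_models[[1]]))
  expect_identical(snap, snap2)
})

test_that("xmodalix validates alignment signals and honors pretraining", {
  cfg <- quick_cfg(architecture = "xmodalix", latent_dim = 2, epochs = 2,
                   pretrain_epochs = 3, gamma = 0.1, delta_paired = 1,
                   batch_size = 8, seed = 7)
  set.seed(7)
  pair <- build_xmodalix(8, list(kind = "numeric", input_dim = 6), cfg)
  xa <- matrix(rnorm(30 * 8), 30, 8)
  xb <- xa[, 1:6] + matrix(rnorm(30 * 6, sd = 0.1), 30, 6)
  split <- split_dataset(30, c(0.8, 0.1, 0.1), seed = 7)
  res <- fit_xmodalix(pair, xa, xb, split, paired = TRUE)
  expect_named(res$history, c("pretrain", "joint"), ignore.order = TRUE)
  expect_equal(nrow(res$history$pretrain), 3)
  expect_equal(nrow(res$history$joint), 2)
  ## no alignment pressure -> warning
  cfg0 <- quick_cfg(architecture = "xmodalix", latent_dim = 2, epochs = 1,
                    gamma = 0, batch_size = 8, seed = 7)
  pair0 <- build_xmodalix(8, list(kind = "numeric", input_dim = 6), cfg0)
  expect_warning(fit_xmodalix(pair0, xa, xb, split, paired = TRUE),
                 "no alignment pressure")
  ## delta_class without labels -> error
  cfgc <- quick_cfg(architecture = "xmodalix", latent_dim = 2, epochs = 1,
                    delta_class = 1, batch_size = 8, seed = 7)
  pairc <- build_xmodalix(8, list(kind = "numeric", input_dim = 6), cfgc)
  expect_error(fit_xmodalix(pairc, xa, xb, split, paired = TRUE),
               "class labels")
})

test_that("tune searches the allowed space and excludes beta_final", {
  set.seed(8)
  x <- matrix(rnorm(60 * 8), 60, 8)
  split <- split_dataset(60, seed = 8)
  cfg <- quick_cfg(architecture = "vanillix", latent_dim = 2, epochs = 3, seed = 8)
  res <- tune(x, split, cfg, n_trials = 3)
  expect_equal(nrow(res$trials), 3)
  expect_lte(res$best_objective, min(res$trials$objective))
  ## seeded reproducibility
  res2 <- tune(x, split, cfg, n_trials = 3)
  expect_equal(res$trials, res2$trials)
  expect_error(tune(x, split, cfg, n_trials = 1,
                    space = list(beta_final = function(i) 1)),
               "not tunable")
  ## single trial returns that trial
  res1 <- tune(x, split, cfg, n_trials = 1)
  expect_equal(res1$best_objective, res1$trials$objective[1])
})
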
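test_that("hidden dims follow the encoding-factor recursion", {
  expect_identical(build_hidden_dims(2000, 4, 2, 2), c(500L, 125L))
  expect_identical(build_hidden_dims(16, 4, 8, 2), c(8L, 8L))
  expect_identical(build_hidden_dims(10, 4, 10, 2), c(10L, 10L))
  ## monotone non-increasing, bounded below by latent dim
  set.seed(1)
  for (i in 1:20) {
    l <- sample(1:8, 1)
    inp <- l + sample(0:500, 1)
    h <- build_hidden_dims(inp, runif(1, 1.5, 8), l, sample(1:4, 1))
    expect_true(all(diff(h) <= 0))
    expect_true(all(h >= l))
  }
})

test_that("reparameterization matches its closed form", {
  expect_equal(reparameterize(c(1, 2), c(0, 0), eps = c(0, 0)), c(1, 2))
  expect_equal(reparameterize(0, 0, eps = 1), 1)
  expect_equal(reparameterize(2, log(4), eps = -1), 0)
})

test_that("all architectures round-trip input shape; varix params match plan", {
  cfg <- quick_cfg(latent_dim = 3, epochs = 1)
  x <- matrix(rnorm(6 * 20), 6, 20)
  van <- build_vanillix(20, cfg)
  var <- build_varix(20, cfg)
  expect_null(van$logvar_head)
  for (m in list(van, var)) {
    expect_identical(dim(model_forward(m, x)$xhat), dim(x))
  }
  fw <- model_forward(var, x, sample = FALSE)
  expect_identical(dim(fw$mu), c(6L, 3L))
  expect_identical(dim(fw$logvar), c(6L, 3L))
  ## parameter count from plan arithmetic: dims 20 -> 5 -> 3 -> heads(3) ->
  ## decoder 3 -> 3 -> 5 -> 20; each dense block has linear W+b plus
  ## batch-norm gamma+beta
  hd <- build_hidden_dims(20, 4, 3, 2)
  lin <- function(i, o) i * o + o
  bn <- function(d) 2 * d
  expected <- lin(20, hd[1]) + bn(hd[1]) + lin(hd[1], hd[2]) + bn(hd[2]) +
    2 * lin(hd[2], 3) +                       # mu + logvar heads
    lin(3, hd[2]) + bn(hd[2]) + lin(hd[2], hd[1]) + bn(hd[1]) + lin(hd[1], 20)
  expect_equal(n_params(var), expected)
  ## deterministic embeddings identical across calls; sampling differs
  expect_identical(embed_samples(var, x), embed_samples(var, x))
  set.seed(1)
  s1 <- model_forward(var, x, sample = TRUE)$z
  set.seed(2)
  s2 <- model_forward(var, x, sample = TRUE)$z
  expect_false(identical(s1, s2))
})

test_that("stackix plan sizes follow the k/8 rule with floor 2", {
  expect_equal(omixae:::stackix_latent_dim(2000), 250L)
  expect_equal(omixae:::stackix_latent_dim(160), 20L)
  expect_equal(omixae:::stackix_latent_dim(8), 2L)
  cfg <- quick_cfg(latent_dim = 4)
  plan <- build_stackix(c(rna = 2000, mut = 160), cfg)
  expect_equal(plan$d, c(250L, 20L))
  ## top VAE input width is the sum of the per-modality widths
  expect_equal(nrow(plan$top_model$encoder$layers[[1]]$params$W), 270L)
  plan1 <- build_stackix(c(one = 80), cfg)
  expect_equal(plan1$d, 10L)
})

test_that("ontix masks mirror the ontology and stay exactly zero", {
  onto1 <- ontology_map(data.frame(f = c("f1", "f2", "f3", "f4"),
                                   t = c("t1", "t1", "t2", "t2")))
  masks <- build_ontix_masks(onto1, c("f1", "f2", "f3", "f4"))
  expect_equal(dim(masks$lvl1), c(2L, 4L))
  expect_equal(sum(masks$lvl1), 4)
  expect_equal(masks$lvl1["t1", c("f1", "f2")], c(f1 = 1, f2 = 1))
  ## two-level toy: masks 1x2 and 2x4
  onto2 <- ontology_map(data.frame(f = c("f1", "f2", "f3", "f4"),
                                   t = c("t1", "t1", "t2", "t2")),
                        data.frame(t = c("t1", "t2"), s = c("S", "S")))
  masks2 <- build_ontix_masks(onto2, c("f1", "f2", "f3", "f4"))
  expect_equal(dim(masks2$lvl2), c(1L, 2L))
  expect_equal(dim(masks2$lvl1), c(2L, 4L))

  cfg <- quick_cfg(architecture = "ontix", latent_dim = 2,
                   ontology = list(lvl1 = "planted"))
  m <- build_ontix(onto1, c("f1", "f2", "f3", "f4"), cfg)
  expect_false(m$meta$extra_fc)
  ## latent_dim below the number of top terms inserts a dense layer both sides
  cfg1 <- quick_cfg(architecture = "ontix", latent_dim = 1,
                    ontology = list(lvl1 = "planted"))
  m1 <- build_ontix(onto1, paste0("f", 1:4), cfg1)
  expect_true(m1$meta$extra_fc)
  expect_identical(dim(model_forward(m1, matrix(rnorm(12), 3))$xhat), c(3L, 4L))
  ## latent_dim above the number of top terms is an error
  cfg3 <- quick_cfg(architecture = "ontix", latent_dim = 3,
                    ontology = list(lvl1 = "planted"))
  expect_error(build_ontix(onto1, paste0("f", 1:4), cfg3), "exceeds")
  ## unmapped features must be dropped by the caller
  expect_error(build_ontix_masks(onto1, c("f1", "f9")), "without ontology")

  ## mask invariance through optimization (exact, machine zero)
  set.seed(2)
  x <- matrix(rnorm(40 * 4), 40, 4, dimnames = list(NULL, paste0("f", 1:4)))
  opt <- omixae:::optim_adamw(omixae:::model_layers(m), lr = 1e-2)
  for (i in 1:50) {
    omixae:::ae_train_step(m, x, beta = 0.1, opt)
  }
  for (w in omixae:::masked_decoder_weights(m)) {
    if (!is.null(w)) expect_identical(unique(w$W[w$mask == 0]), 0)
  }
})

test_that("image VAE geometry: five halvings, divisibility check", {
  cfg <- quick_cfg(latent_dim = 4)
  m64 <- build_image_vae(1, 64, cfg)
  expect_equal(m64$meta$latent_side, 2L)
  expect_error(build_image_vae(1, 100, cfg), "divisible by 32")
  x <- matrix(runif(2 * 64 * 64), 2)
  fw <- model_forward(m64, x)
  expect_identical(dim(fw$xhat), dim(x))
  ## sigmoid output under bce bounds reconstructions
  cfgb <- quick_cfg(latent_dim = 4, recon_loss = "bce", scaler = list(method = "minmax"))
  mb <- build_image_vae(1, 64, cfgb)
  fwb <- model_forward(mb, x)
  expect_true(all(fwb$xhat >= 0 & fwb$xhat <= 1))
})

test_that("translate decodes A-encodings with the B decoder; centers by median", {
  cfg <- quick_cfg(latent_dim = 3)
  set.seed(3)
  pair <- build_xmodalix(10, list(kind = "numeric", input_dim = 6), cfg)
  xa <- matrix(rnorm(40), 4, 10)
  out <- translate(pair, xa)
  expect_identical(dim(out), c(4L, 6L))
  ## class-center decoding uses the per-dimension median embedding
  z <- rbind(c(0, 0, 0), c(2, 4, 6), c(1, 1, 1))
  cc <- class_center_z(z, c("a", "a", "b"))
  expect_equal(cc["a", ], c(1, 2, 3), ignore_attr = TRUE)
  out_cc <- translate(pair, z = cc)
  expect_identical(dim(out_cc), c(2L, 6L))
})
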
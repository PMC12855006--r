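## Shared fixtures: small synthetic datasets and quick training configs.

quick_cfg <- function(...) {
  args <- utils::modifyList(
    list(architecture = "varix", latent_dim = 2, beta_final = 0.01,
         epochs = 10, batch_size = 16, learning_rate = 1e-3, seed = 1L),
    list(...))
  do.call(run_config, args)
}

tiny_blocks <- function() {
  set.seed(10)
  m1 <- matrix(rnorm(12), 4, 3,
               dimnames = list(c("A", "B", "C", "D"), c("f1", "f2", "f3")))
  m2 <- matrix(rnorm(8), 4, 2,
               dimnames = list(c("B", "C", "D", "E"), c("g1", "g2")))
  list(modality_block("rna", m1), modality_block("prot", m2))
}

small_trained_varix <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    spec <- generator_spec(n = 200, k_true = 2, feature_counts = c(rna = 40),
                           noise_sd = 0.3, n_classes = 2, class_sep = 3,
                           seed = 33)
    truth <- make_multiomics(spec)
    x <- truth$dataset$blocks[[1]]$matrix
    split <- split_dataset(rownames(x), seed = 33)
    xs <- apply_scaler(x, fit_scaler(x[split_idx(split, "train"), ], "standard"))
    cfg <- quick_cfg(epochs = 60, seed = 33)
    set.seed(33)
    m <- build_varix(ncol(xs), cfg)
    fit_ae(m, xs, split)
    cache <<- list(model = m, x = xs, split = split, truth = truth,
                   ann = truth$dataset$annotations,
                   z = embed_samples(m, xs))
    cache
  }
})

split_idx <- omixae:::split_idx
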
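test_that("load_config fills documented defaults and validates", {
  yml <- tempfile(fileext = ".yaml")
  writeLines("architecture: varix\nlatent_dim: 2", yml)
  cfg <- load_config(yml)
  expect_s3_class(cfg, "run_config")
  expect_equal(cfg$encoding_factor, 4)
  expect_equal(cfg$dropout, 0.1)
  expect_equal(cfg$n_hidden, 2L)
  expect_equal(cfg$recon_loss, "mse")
  expect_equal(cfg$sim_loss, "kl")

  expect_error(run_config(architecture = "varix", latent_dim = 0),
               "latent_dim")
  expect_error(run_config(architecture = "ontix", latent_dim = 2), "ontology")
  expect_error(run_config(architecture = "varix", latent_dim = 2,
                          not_a_key = 1), "unknown key.*not_a_key")
  expect_error(run_config(architecture = "varix", latent_dim = 2,
                          split = c(0.5, 0.2, 0.2)), "sum to 1")
  expect_error(run_config(architecture = "varix", latent_dim = 2,
                          recon_loss = "bce"), "\\[0,1\\]")
})

test_that("config serialization round-trips", {
  cfg <- run_config(architecture = "stackix", latent_dim = 3, epochs = 7,
                    beta_final = 0.25, learning_rate = 2e-4,
                    filter = list(method = "variance", k = 10))
  yml <- tempfile(fileext = ".yaml")
  save_config(cfg, yml)
  cfg2 <- load_config(yml)
  expect_equal(unclass(cfg2), unclass(cfg))
  ## hash is stable under key reordering
  shuffled <- unclass(cfg)[rev(names(unclass(cfg)))]
  expect_identical(omixae:::config_hash(cfg),
                   omixae:::config_hash(structure(shuffled, class = "run_config")))
})

test_that("align_samples intersects, orders lexicographically, is idempotent", {
  blocks <- tiny_blocks()
  ds <- align_samples(blocks)
  expect_identical(ds$sample_ids, c("B", "C", "D"))
  for (b in ds$blocks) expect_identical(rownames(b$matrix), c("B", "C", "D"))
  expect_identical(unname(attr(ds, "dropped")), c(1L, 1L))
  ## idempotent
  ds2 <- align_samples(ds$blocks, ds$annotations)
  expect_equal(ds2$blocks, ds$blocks)
  ## identical sample sets retained in full
  same <- align_samples(list(blocks[[1]], blocks[[1]]))
  expect_identical(same$sample_ids, c("A", "B", "C", "D"))
  ## disjoint -> error
  b3 <- modality_block("x", matrix(1:2, 2, 1, dimnames = list(c("Y", "Z"), "f")))
  expect_error(align_samples(list(blocks[[1]], b3)), "empty intersection")
})

test_that("modality_block enforces its invariants", {
  expect_error(modality_block("m", matrix(1:4, 2, 2,
                                          dimnames = list(c("a", "a"), c("f", "g")))),
               "duplicated sample_ids")
  expect_error(modality_block("m", matrix(1:4, 2, 2,
                                          dimnames = list(c("a", "b"), c("f", "f")))),
               "duplicated feature_ids")
  mf <- data.frame(sample_id = c("a", "b"), path = NA, channels = 1,
                   height = 4, width = 6)
  expect_error(modality_block("m", matrix(0, 2, 24,
                                          dimnames = list(c("a", "b"), NULL)),
                              kind = "image", image_manifest = mf),
               "quadratic")
})

test_that("validate_ontology reports coverage, overlaps and empty terms", {
  onto <- ontology_map(data.frame(f = c("f1", "f2", "f3", "f4"),
                                  t = c("t1", "t1", "t2", "t2")))
  rep1 <- validate_ontology(onto, c("f1", "f2", "f3", "f4"))
  expect_equal(rep1$n_terms_lvl1, 2)
  expect_equal(rep1$n_unmapped, 0)
  expect_length(rep1$empty_terms, 0)

  ## overlapping membership is allowed and reported
  onto2 <- ontology_map(data.frame(f = c("f1", "f1", "f2"),
                                   t = c("t1", "t2", "t2")))
  rep2 <- validate_ontology(onto2, c("f1", "f2"))
  expect_identical(rep2$overlap_features, "f1")

  ## term with no mapped features is listed; unmapped features flagged
  rep3 <- validate_ontology(onto, c("f1", "f2", "f9"))
  expect_identical(rep3$empty_terms, "t2")
  expect_identical(rep3$unmapped_features, "f9")

  ## level-crossing edges rejected
  expect_error(ontology_map(data.frame(f = "f1", t = "t1"),
                            data.frame(t = "t1", s = "f1")),
               "level-crossing|feature")
})

test_that("ontology term ordering is deterministic across input orderings", {
  e <- data.frame(f = c("f2", "f1", "f3"), t = c("tB", "tA", "tB"))
  o1 <- ontology_map(e)
  o2 <- ontology_map(e[c(3, 1, 2), ])
  expect_identical(o1$terms1, o2$terms1)
  expect_identical(o1$terms1, c("tA", "tB"))
})

test_that("annotation_table validates task columns", {
  df <- data.frame(sample_id = c("a", "b"), grp = c("x", "y"), v = 1:2)
  ann <- annotation_table(df, data.frame(column = "grp", task = "classification"))
  expect_identical(rownames(ann), c("a", "b"))
  expect_error(annotation_table(df, data.frame(column = "nope",
                                               task = "classification")),
               "nope")
})
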
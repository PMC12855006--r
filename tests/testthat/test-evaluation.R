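test_that("reconstruction_r2 matches its variance-ratio definition", {
  x <- matrix(rnorm(20), 4, 5)
  expect_equal(reconstruction_r2(x, x), 1)
  ## constant prediction at the per-sample mean gives exactly 0
  xc <- matrix(rowMeans(x), 4, 5)
  expect_equal(reconstruction_r2(x, xc), 0)
  ## frozen oracle: x = (0,1,2), xhat = (0,1,5): 1 - var(0,0,-3)/var(0,1,2) = -2
  expect_equal(reconstruction_r2(rbind(c(0, 1, 2)), rbind(c(0, 1, 5))), -2)
  ## never exceeds 1; zero-variance samples excluded with warning
  set.seed(1)
  for (i in 1:10) {
    a <- matrix(rnorm(12), 2)
    b <- matrix(rnorm(12), 2)
    expect_lte(reconstruction_r2(a, b), 1)
  }
  xz <- rbind(c(1, 1, 1), c(0, 1, 2))
  expect_warning(v <- reconstruction_r2(xz, xz * 0.9), "zero input variance")
})

test_that("latent_coverage follows the grid-binning scheme", {
  ## n = 4 uniform on 1-D: b = 4, all bins hit
  expect_equal(latent_coverage(cbind(c(0, 1, 2, 3)))$mean, 1)
  ## {0,0,0,3}: first and last bins only
  expect_equal(latent_coverage(cbind(c(0, 0, 0, 3)))$mean, 0.5)
  ## grid-filling 2-D sample: coverage 1
  g <- as.matrix(expand.grid(seq_len(5), seq_len(5)))
  expect_equal(latent_coverage(g)$mean, 1)
  ## affine rescaling per dimension leaves coverage unchanged
  set.seed(2)
  z <- matrix(rnorm(400), 200, 2)
  z2 <- sweep(sweep(z, 2, c(3, 0.1), "*"), 2, c(-7, 2), "+")
  expect_equal(latent_coverage(z)$mean, latent_coverage(z2)$mean)
  ## degenerate dimension contributes 1/b
  zd <- cbind(seq(0, 1, length.out = 9), rep(2, 9))
  cv <- latent_coverage(zd)
  expect_equal(cv$per_dimension[2], 1 / cv$b)
  expect_error(latent_coverage(cbind(1)), "at least 2")
})

test_that("total correlation: zero at independence, closed form at r = 0.8", {
  ## nonnegative for arbitrary data; ~0 for independent columns
  set.seed(30)
  for (i in 1:5) expect_gte(total_correlation(matrix(rnorm(80), 20, 4)), 0)
  expect_lt(total_correlation(matrix(rnorm(2e4), 1e4, 2)), 5e-4)
  ## exact: empirical correlation r -> -0.5 log(1 - r^2)
  set.seed(3)
  a <- rnorm(2000)
  b <- 0.8 * a + sqrt(1 - 0.64) * rnorm(2000)
  r <- cor(a, b)
  expect_equal(total_correlation(cbind(a, b)), -0.5 * log(1 - r^2),
               tolerance = 1e-10)
  ## duplicated column -> infinity flag
  expect_identical(total_correlation(cbind(a, a)), Inf)
  expect_error(total_correlation(cbind(a, rep(1, 2000))), "constant")
})

test_that("embedding evaluation: separable classes, chance labels, linear targets", {
  set.seed(4)
  n <- 120
  cls <- rep(c("p", "q"), each = n / 2)
  z <- matrix(rnorm(n * 2), n, 2)
  z[cls == "q", 1] <- z[cls == "q", 1] + 8  # wide margin
  ann <- annotation_table(
    data.frame(sample_id = sprintf("s%03d", 1:n), grp = cls,
               y = 2 * z[, 1] - z[, 2]),
    task_specs = data.frame(column = c("grp", "y"),
                            task = c("classification", "regression")))
  rownames(z) <- sprintf("s%03d", 1:n)
  split <- split_dataset(rownames(z), seed = 4)
  res <- evaluate_embedding(z, ann, split, algorithms = "linear")
  expect_equal(res$value[res$task == "grp"], 1.0)
  expect_gt(res$value[res$task == "y"], 0.99)
  ## permuted labels fall to chance
  set.seed(5)
  ann_perm <- annotation_table(
    data.frame(sample_id = rownames(z), grp = sample(cls)),
    task_specs = data.frame(column = "grp", task = "classification"))
  res_perm <- evaluate_embedding(z, ann_perm, split, algorithms = "linear")
  expect_gt(res_perm$value, 0.25)
  expect_lt(res_perm$value, 0.75)
  ## single-class training split is skipped with a warning
  ann_one <- annotation_table(
    data.frame(sample_id = rownames(z), grp = rep("only", n)),
    task_specs = data.frame(column = "grp", task = "classification"))
  expect_warning(r1 <- evaluate_embedding(z, ann_one, split, algorithms = "linear"),
                 "single class")
  expect_null(r1)
})

test_that("random-feature baseline and Z-scores follow the cohort definition", {
  expect_equal(zscore_performance(0.8, c(0.5, 0.6, 0.7)), (0.8 - 0.6) / sqrt(2 / 300))
  expect_equal(zscore_performance(0.6, c(0.5, 0.6, 0.7)), 0)
  ## frozen example: mean 0.6, population s.d. 0.1 -> z = 2
  eta <- c(0.45, 0.55, 0.6, 0.65, 0.75)
  eta <- (eta - mean(eta)) / sqrt(mean((eta - mean(eta))^2)) * 0.1 + 0.6
  expect_equal(zscore_performance(0.8, eta), 2)
  expect_warning(z <- zscore_performance(0.5, rep(0.7, 5)), "spread")
  expect_true(is.na(z))
  ## a draw z-scored against its own cohort is centered near zero
  set.seed(6)
  zz <- replicate(300, {
    eta <- runif(5)
    zscore_performance(eta[1], eta)
  })
  expect_lt(abs(mean(zz)), 3 / sqrt(300) * 2)

  fx <- small_trained_varix()
  rb <- random_feature_baseline(fx$x, 2, fx$ann, fx$split,
                                algorithms = "linear", r = 5, seed = 1)
  expect_equal(sort(unique(rb$rep)), 1:5)
  ## seeded reproducibility
  rb2 <- random_feature_baseline(fx$x, 2, fx$ann, fx$split,
                                 algorithms = "linear", r = 5, seed = 1)
  expect_equal(rb, rb2)
})

test_that("robustness averages |r| pairwise and is order-invariant", {
  set.seed(7)
  a <- matrix(rnorm(100), 50, 2)
  expect_equal(robustness(list(a, a))$per_dimension, c(1, 1))
  expect_equal(robustness(list(a, -a))$per_dimension, c(1, 1))
  b <- matrix(rnorm(100), 50, 2)
  c_ <- matrix(rnorm(100), 50, 2)
  r1 <- robustness(list(a, b, c_))
  r2 <- robustness(list(c_, a, b))
  expect_equal(sort(r1$per_dimension), sort(r2$per_dimension))
  expect_lt(mean(robustness(list(a, b))$per_dimension), 0.5)
  az <- a; az[, 1] <- 0
  expect_warning(rz <- robustness(list(az, b)), "zero-variance")
  expect_equal(rz$per_dimension[1], 0)
})

test_that("PCA baseline: exact recovery of low-rank data, decorrelated scores", {
  set.seed(8)
  F <- matrix(rnorm(60), 30, 2)
  W <- matrix(rnorm(2 * 12), 2, 12)
  x <- F %*% W
  z <- baseline_embeddings(x, 2, "pca")
  ## rank-2 data: projecting back recovers x exactly
  mu <- colMeans(x)
  v <- svd(sweep(x, 2, mu), nv = 2)$v
  xhat <- sweep(sweep(x, 2, mu) %*% v %*% t(v), 2, mu, "+")
  expect_equal(reconstruction_r2(x, xhat), 1, tolerance = 1e-10)
  expect_lt(abs(cor(z[, 1], z[, 2])), 1e-8)
  expect_lt(total_correlation(z), 1e-10)
})
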
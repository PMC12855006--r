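test_that("variance and MAD filters rank, tie-break and preserve order", {
  x <- cbind(a = c(1, 1, 1, 1), b = c(0, 1, 2, 3), c = c(0, 2, 4, 6))
  rownames(x) <- paste0("s", 1:4)
  expect_identical(colnames(filter_top_variance(x, 2)), c("b", "c"))
  expect_identical(colnames(filter_top_variance(x, 3)), c("a", "b", "c"))
  expect_error(filter_top_variance(x, 4), "exceeds")
  ## tie: equal variance -> lexicographically first kept
  xt <- cbind(zb = c(0, 1), za = c(5, 6))
  expect_identical(colnames(filter_top_variance(xt, 1)), "za")
  ## MAD: (1,1,1,10) has MAD 0, ranks below any spread feature
  xm <- cbind(spiky = c(1, 1, 1, 10), flat = c(1, 1, 1, 1), spread = c(1, 2, 3, 4))
  expect_identical(colnames(filter_top_mad(xm, 1)), "spread")
  expect_identical(colnames(filter_top_mad(xm, 3)), colnames(xm))
  ## permutation-equivariance in samples
  p <- c(3, 1, 4, 2)
  expect_identical(colnames(filter_top_variance(x[p, ], 2)),
                   colnames(filter_top_variance(x, 2)))
})

test_that("correlation-medoid filter picks one representative per group", {
  set.seed(4)
  base1 <- rnorm(30)
  base2 <- rnorm(30)
  x <- cbind(f1 = base1, f2 = base1 + rnorm(30, sd = 1e-3),
             f3 = base2, f4 = base2 + rnorm(30, sd = 1e-3))
  kept <- colnames(filter_correlation_medoid(x, 2, seed = 1))
  ## oracle: brute-force exact 2-medoids on the 4x4 distance matrix
  d <- as.matrix(1 - abs(cor(x)))
  combs <- combn(4, 2)
  costs <- apply(combs, 2, function(md) sum(apply(d[, md, drop = FALSE], 1, min)))
  kept_cost <- sum(apply(d[, match(kept, colnames(x)), drop = FALSE], 1, min))
  expect_equal(kept_cost, min(costs), tolerance = 1e-12)
  expect_true(sum(kept %in% c("f1", "f2")) == 1)
  expect_true(sum(kept %in% c("f3", "f4")) == 1)
  ## k = n_features -> identity; degenerate features excluded with warning
  expect_identical(colnames(filter_correlation_medoid(x, 4)), colnames(x))
  xz <- cbind(x, z = rep(1, 30))
  expect_warning(filter_correlation_medoid(xz, 2, seed = 1), "zero-variance")
})

test_that("scalers fit on train, apply everywhere, and invert", {
  x <- cbind(a = c(1, 2, 3), b = c(0, 5, 10))
  st <- fit_scaler(x, "standard")
  got <- apply_scaler(x, st)
  expect_equal(got[, "a"], c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)
  mm <- fit_scaler(x, "minmax")
  expect_equal(apply_scaler(x, mm)[, "b"], c(0, 0.5, 1))
  ## constant column maps to 0 under any method
  xc <- cbind(k = c(2, 2, 2), b = c(0, 5, 10))
  for (m in c("standard", "minmax", "robust", "maxabs")) {
    expect_equal(apply_scaler(xc, fit_scaler(xc, m))[, "k"], c(0, 0, 0),
                 ignore_attr = TRUE)
  }
  ## round trip within 1e-10 on non-degenerate features
  set.seed(2)
  xr <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, letters[1:4]))
  for (m in c("standard", "minmax", "maxabs")) {
    st <- fit_scaler(xr, m)
    expect_lt(max(abs(apply_scaler(apply_scaler(xr, st), st, inverse = TRUE) - xr)),
              1e-10)
  }
  expect_error(fit_scaler(xr[0, , drop = FALSE], "standard"), "empty")
})

test_that("one_hot encodes levels deterministically, flags unseen", {
  m <- one_hot(c("a", "b", "a"), levels = c("a", "b"))
  expect_equal(unname(m), rbind(c(1, 0), c(0, 1), c(1, 0)))
  expect_warning(m2 <- one_hot("c", levels = c("a", "b")), "unseen")
  expect_equal(unname(m2), cbind(0, 0), ignore_attr = TRUE)
  ## level order is lexicographic when inferred
  expect_identical(colnames(one_hot(c("b", "a"), prefix = "p")),
                   c("p.a", "p.b"))
})

test_that("split_dataset: floor rule, determinism, partition property", {
  s <- split_dataset(260, c(0.7, 0.1, 0.2), seed = 9)
  expect_equal(unname(table(s)), c(182L, 26L, 52L), ignore_attr = TRUE)
  s2 <- split_dataset(10, c(0.6, 0.2, 0.2), seed = 1)
  expect_equal(as.vector(table(s2)), c(6L, 2L, 2L))
  expect_identical(split_dataset(50, seed = 5), split_dataset(50, seed = 5))
  ## partition: counts always sum to n
  for (n in c(7, 31, 100)) {
    for (r in list(c(0.5, 0.25, 0.25), c(0.9, 0.05, 0.05), c(1, 0, 0))) {
      expect_equal(sum(table(split_dataset(n, r, seed = 3))), n)
    }
  }
})

test_that("mutation_score combines SNV burden and CNA", {
  expect_equal(mutation_score(0, 1000, 0), 0, ignore_attr = TRUE)
  expect_equal(mutation_score(2, 1000, 1), 1.002, ignore_attr = TRUE)
  expect_equal(mutation_score(5, 500, -1), -0.99, ignore_attr = TRUE)
  expect_error(mutation_score(c(g1 = 1), c(g1 = 0), c(g1 = 0)), "g1")
})

test_that("image_preprocess projects, rescales and resizes", {
  ## max projection over z
  st <- array(0, dim = c(2, 1, 4, 4))
  st[1, 1, , ] <- 3
  st[2, 1, , ] <- 7
  expect_equal(unname(image_preprocess(st)), matrix(0, 4, 4))  # constant -> 0
  st[2, 1, 1, 1] <- 9
  out <- image_preprocess(st)  # projected pixels: 9 at (1,1), 7 elsewhere
  expect_equal(out[1, 1], 1)
  expect_equal(out[2, 2], 0)
  ## resize 128 -> 32 via average pooling
  img <- matrix(runif(128 * 128), 128, 128)
  expect_equal(dim(image_preprocess(img, target_side = 32)), c(32, 32))
  expect_error(image_preprocess(img, target_side = 30), "divisible by 32")
  expect_error(image_preprocess(matrix(0, 10, 12)), "non-square")
  rng <- range(image_preprocess(matrix(rnorm(64 * 64), 64), target_side = 64))
  expect_gte(rng[1], 0)
  expect_lte(rng[2], 1)
})
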
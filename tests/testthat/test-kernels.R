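test_that("Gaussian Gram entries match direct scalar evaluation", {
  cfg <- kernel_config("gaussian", sigma = 1.5)
  x <- rbind(c(0, 0), c(0, 2 * 1.5))
  K <- compute_gram(x, cfg)$values
  expect_equal(diag(K), c(1, 1))
  expect_equal(K[1, 2], exp(-2), tolerance = 1e-12)

  x <- random_features(10, 3, seed = 42)
  cfg2 <- kernel_config("gaussian", sigma = 0.8, theta = 2)
  K2 <- compute_gram(x, cfg2)$values
  for (i in 1:10) for (j in 1:10)
    expect_equal(K2[i, j], gauss_entry(x[i, ], x[j, ], 0.8, 2),
                 tolerance = 1e-12)
})

test_that("all kernel families give symmetric PSD Grams with unit diagonal", {
  x <- random_features(15, 4, seed = 7)
  for (fam in c("gaussian", "inverse_square_distance", "laplacian",
                "inverse_distance")) {
    K <- compute_gram(x, kernel_config(fam, sigma = 1.3))$values
    expect_equal(K, t(K))
    expect_equal(diag(K), rep(1, 15))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("multi-kernel Gram is the entrywise sum of component Grams", {
  x <- random_features(12, 3, seed = 11)
  comps <- list(kernel_config("gaussian", sigma = 1),
                kernel_config("laplacian", sigma = 0.5),
                kernel_config("inverse_distance", sigma = 2))
  K_multi <- compute_gram(x, kernel_config(components = comps))$values
  K_sum <- Reduce(`+`, lapply(comps, function(cc)
    compute_gram(x, cc)$values))
  expect_equal(K_multi, K_sum, tolerance = 1e-12)
  # still PSD
  expect_gte(min(eigen(K_multi, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-8)
})

test_that("larger theta (smaller bandwidth) never increases off-diagonals", {
  x <- random_features(10, 3, seed = 3)
  K1 <- compute_gram(x, kernel_config("gaussian", sigma = 2, theta = 1))$values
  K3 <- compute_gram(x, kernel_config("gaussian", sigma = 2, theta = 3))$values
  off <- upper.tri(K1)
  expect_true(all(K3[off] <= K1[off] + 1e-15))
})

test_that("invalid kernel input is rejected", {
  expect_error(kernel_config("gaussian", sigma = -1), "sigma")
  expect_error(kernel_config("gaussian", theta = 0.5), "theta")
  expect_error(compute_gram(matrix(c(1, NaN), 1, 2), kernel_config(sigma = 1)),
               "non-finite")
  expect_error(kernel_config(components = list()), "non-empty")
})

test_that("bandwidth heuristics return positive values and scale with C", {
  x <- random_features(30, 5, seed = 9)
  s2 <- default_sigma(x, n_classes = 2)
  s3 <- default_sigma(x, n_classes = 3)
  expect_gt(s2, 0)
  expect_equal(s3, 3 * s2)
  expect_gt(default_sigma(x, method = "median_dist"), 0)
})

test_that("class mean coefficients implement the blended within-class average", {
  # two singleton domains, delta = 0.5: midpoint
  cm <- class_mean_coefficients(1L, 1L, delta = 0.5, n_classes = 1L)
  expect_equal(cm$coefficients[, 1], c(0.5, 0.5))

  # delta = 1: class columns supported on the source only
  cm <- class_mean_coefficients(c(1L, 2L), c(1L, 2L), delta = 1)
  expect_equal(cm$coefficients[3:4, 2:3], matrix(0, 2, 2))

  # 3-class toy: n_1 = 2 source members get delta/n_1, m_1 = 3 target 1/6
  src <- c(1L, 1L, 2L, 3L)
  tgt <- c(1L, 1L, 1L, 2L, 3L)
  cm <- class_mean_coefficients(src, tgt, delta = 0.5)
  a1 <- cm$coefficients[, 2]
  expect_equal(a1[1:2], rep(0.25, 2))
  expect_equal(a1[5:7], rep(1 / 6, 3))
  expect_equal(sum(a1), 1)
  expect_equal(colSums(cm$coefficients[, cm$active, drop = FALSE]),
               rep(1, sum(cm$active)))
})

test_that("one-sided classes fall back to the populated domain", {
  cm <- class_mean_coefficients(c(1L, 2L), c(1L, 1L), delta = 0.5,
                                n_classes = 3L)
  # class 2 absent from target: full weight on the source member
  expect_equal(cm$coefficients[2, 3], 1)
  # class 3 absent everywhere: inactive
  expect_false(cm$active[4])
  expect_equal(cm$coefficients[, 4], rep(0, 4))
})

test_that("RKHS mean distances equal explicit feature-space distances under
          the linear kernel", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(4:20, 1)
    d <- sample(2:5, 1)
    x <- matrix(rnorm(n * d), n, d)
    nsrc <- sample(2:(n - 2), 1)
    C <- 2L
    src <- sample(1:C, nsrc, replace = TRUE)
    tgt <- sample(1:C, n - nsrc, replace = TRUE)
    cm <- class_mean_coefficients(src, tgt, delta = 0.5, n_classes = C)
    D <- rkhs_mean_distances(linear_gram(x), cm)
    for (cc in which(cm$active)) {
      mu <- colSums(x * cm$coefficients[, cc])
      expl <- rowSums(sweep(x, 2L, mu)^2)
      expect_equal(D[, cc], expl, tolerance = 1e-10)
    }
  }
})

test_that("a sample equal to the mean has zero distance, and duplicated
          domains give identical distances for paired duplicates", {
  g1 <- linear_gram(matrix(2, 1, 1))
  cm1 <- structure(list(coefficients = matrix(1, 1, 1), active = TRUE,
                        delta = 1, n_classes = 0L), class = "class_means")
  expect_equal(as.numeric(rkhs_mean_distances(g1, cm1)), 0)

  x <- random_features(6, 3, seed = 5)
  xx <- rbind(x, x)  # target duplicates the source exactly
  cm <- class_mean_coefficients(rep(1L, 6), rep(1L, 6), delta = 0.5,
                                n_classes = 1L)
  D <- rkhs_mean_distances(compute_gram(xx, kernel_config(sigma = 1)), cm)
  expect_equal(D[1:6, 1], D[7:12, 1], tolerance = 1e-12)
})

test_that("inconsistent means/gram pairing is rejected", {
  g <- linear_gram(random_features(5, 2, seed = 1))
  cm <- class_mean_coefficients(c(1L, 2L), c(1L, 2L))
  expect_error(rkhs_mean_distances(g, cm), "different sample counts")
})
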
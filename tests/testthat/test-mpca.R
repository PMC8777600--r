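# Unfolding, preprocessing, SVD decomposition, CV, projection.

stack_from_matrices <- function(mats, grid) {
  maps <- lapply(mats, function(v)
    ginkgocos:::new_corr_map("asynchronous", grid, v))
  map_stack(maps, sprintf("M%d", seq_along(maps)), "B")
}

test_that("unfolding is row-major and exactly invertible", {
  g2 <- wl_grid(300, 301, 1)
  m <- matrix(c(1, 2, 3, 4), 2)  # [[1,3],[2,4]] column-major
  st <- stack_from_matrices(list(m), g2)
  X <- unfold(st)
  expect_equal(as.vector(X[1, ]), c(1, 3, 2, 4))  # row-major flatten
  expect_equal(refold(X[1, ], g2), m)

  set.seed(2)
  g <- default_grid()
  mats <- replicate(3, matrix(rnorm(166^2), 166), simplify = FALSE)
  st <- stack_from_matrices(mats, g)
  X <- unfold(st)
  expect_equal(dim(X), c(3L, 27556L))
  expect_identical(refold(X[2, ], g), mats[[2]])
})

test_that("preprocessing centers columns and guards degenerate cases", {
  set.seed(4)
  X <- matrix(rnorm(40), 5, 8)
  pp <- mpca_preprocess(X)
  expect_lt(max(abs(colMeans(pp$X))), 1e-12)
  expect_true(all(pp$params$col_scales >= pp$params$offset))

  # constant column after row normalization -> zeros, no blow-up
  X2 <- cbind(matrix(rnorm(10), 5, 2), 0)
  rn <- sqrt(rowSums(X2^2))
  pp2 <- mpca_preprocess(X2)
  expect_equal(pp2$X[, 3], rep(0, 5))

  # rows that are positive multiples coincide after row normalization
  x <- rnorm(8)
  X3 <- rbind(x, 3 * x, rnorm(8))
  pp3 <- mpca_preprocess(X3)
  expect_equal(pp3$X[1, ], pp3$X[2, ])

  expect_error(mpca_preprocess(matrix(1:4, 1)), "at least 2")
})

test_that("the decomposition recovers rank and matches the residual oracle", {
  # exact rank-1 data
  X1 <- outer(c(1, 2, 3, 4), c(2, -1, 0.5, 3, 1))
  m1 <- fit_mpca(X1, 2)
  expect_equal(m1$explained_variance_pct[1], 100)
  expect_equal(m1$rmsec_per_k[1], 0, tolerance = 1e-10)

  set.seed(5)
  X <- matrix(rnorm(500), 10, 50)
  m <- fit_mpca(X, 5)
  # orthonormal loadings, orthogonal scores
  G <- m$loadings %*% t(m$loadings)
  expect_equal(G, diag(5), tolerance = 1e-10)
  St <- crossprod(m$scores)
  expect_lt(max(abs(St - diag(diag(St)))), 1e-8)
  # RMSEC against a brute-force rank-k reconstruction
  for (k in 1:5) {
    expect_equal(m$rmsec_per_k[k], rmsec_oracle(X, k), tolerance = 1e-10)
  }
  expect_true(all(diff(m$rmsec_per_k) <= 1e-12))
  expect_true(all(diff(m$explained_variance_pct) <= 1e-12))
  expect_lte(sum(m$explained_variance_pct), 100 + 1e-9)

  expect_error(fit_mpca(X, 10), "k_max")
})

test_that("venetian blinds assign samples in contiguous pairs", {
  a <- venetian_blinds(20, 10, 2)
  expect_equal(length(unique(a)), 10L)
  expect_true(all(table(a) == 2))
  expect_equal(a[1], a[2])  # samples 1 and 2 share split 1
  expect_equal(a[1:4], c(1L, 1L, 2L, 2L))
  expect_equal(venetian_blinds(6, 3, 1, order = "interleave"),
               c(1L, 2L, 3L, 1L, 2L, 3L))
})

test_that("cross-validation matches a literal leave-blind-out loop", {
  set.seed(6)
  X <- matrix(rnorm(48), 6, 8)
  cv <- mpca_cross_validate(X, 3, n_splits = 3, per_blind = 2)
  expect_equal(cv$rmsecv_per_k, cv_oracle(X, 3, cv$assignment),
               tolerance = 1e-10)

  # noiseless rank-1 structure is perfectly predictable
  X1 <- outer(seq(1, 2, length.out = 6), c(2, -1, 0.5, 3, 1, 0.2, 4, -2))
  cv1 <- mpca_cross_validate(X1, 1, n_splits = 3, per_blind = 2)
  expect_lt(cv1$rmsecv_per_k[1], 1e-6)

  expect_error(mpca_cross_validate(X[1:2, ], 1, n_splits = 2, per_blind = 1),
               "fewer than 2")
})

test_that("projection is self-consistent and honours the preprocessing chain", {
  set.seed(8)
  g <- wl_grid(300, 309, 1)
  mats <- replicate(6, matrix(rnorm(100), 10), simplify = FALSE)
  st <- stack_from_matrices(mats, g)
  model <- mpca(st, k_max = 3)

  expect_equal(mpca_project(model, st), unname(model$scores),
               ignore_attr = TRUE, tolerance = 1e-10)

  # duplicate of training sample 2 projects onto sample 2's scores
  dup <- stack_from_matrices(mats[c(2, 3)], g)
  expect_equal(mpca_project(model, dup)[1, ], unname(model$scores[2, ]),
               tolerance = 1e-10)

  # all-zero map: closed form through centering/scaling
  zero <- stack_from_matrices(list(matrix(0, 10, 10), mats[[1]]), g)
  want <- as.vector(-(model$preprocess$col_means /
                        model$preprocess$col_scales) %*% t(model$loadings))
  expect_equal(mpca_project(model, zero)[1, ], want, tolerance = 1e-10)

  # scores invariant to positive scaling of an input map
  scaled <- stack_from_matrices(lapply(mats, function(m) 17 * m), g)
  expect_equal(mpca_project(model, scaled), mpca_project(model, st),
               tolerance = 1e-10)
})

test_that("multiway PCA equals ordinary PCA on the unfolded matrix", {
  set.seed(9)
  g <- wl_grid(300, 307, 1)
  mats <- replicate(5, matrix(rnorm(64), 8), simplify = FALSE)
  st <- stack_from_matrices(mats, g)
  X <- unfold(st)
  pp <- mpca_preprocess(X)
  model <- fit_mpca(pp$X, 3)
  pc <- stats::prcomp(pp$X, center = FALSE, scale. = FALSE)
  expect_equal(abs(unname(model$scores)), abs(unname(pc$x[, 1:3])),
               tolerance = 1e-9)
  expect_equal(abs(model$loadings), abs(t(unname(pc$rotation[, 1:3]))),
               tolerance = 1e-9)
})
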
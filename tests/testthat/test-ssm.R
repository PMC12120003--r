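test_that("log volume matrix is the elementwise natural log in region order", {
  co <- data.frame(subject_id = c("a", "b"), r1 = c(1000, 2000),
                   r2 = c(500, 1), stringsAsFactors = FALSE)
  m <- log_volume_matrix(co, c("r2", "r1"))
  expect_identical(colnames(m), c("r2", "r1"))
  expect_equal(m["a", "r1"], log(1000), tolerance = 1e-12)
  expect_equal(m["b", "r2"], 0, tolerance = 1e-12)

  co$r1[2] <- 0
  expect_error(log_volume_matrix(co, c("r1", "r2")), "nonpositive volume")
  co$r1[2] <- -5
  expect_error(log_volume_matrix(co, c("r1", "r2")), "nonpositive volume")
  expect_error(log_volume_matrix(co, c("r1", "r3")), "r3")

  full <- quick_cohort(n = 40, seed = 2)
  expect_identical(dim(log_volume_matrix(full)), c(40L, 14L))
})

test_that("double centering matches the centering-projector oracle", {
  # constants are annihilated
  cm <- double_center(matrix(7, 5, 4))
  expect_lt(max(abs(cm$values)), 1e-12)

  # an already double-centered rank-1 matrix passes through unchanged
  u <- c(-1, 0, 1, 2, -2); v <- c(-0.5, 0.5, 0.25, -0.25)
  M <- outer(u - mean(u), v - mean(v))
  expect_equal(double_center(M)$values, M, ignore_attr = TRUE,
               tolerance = 1e-12)

  # random matrix vs the dense projector route
  M <- random_logvol(6, 4, seed = 14)
  cm <- double_center(M)
  expect_equal(unname(cm$values), oracle_double_center(M),
               tolerance = 1e-12)

  # stored means reconstruct the input; row/col means vanish
  rec <- cm$values + cm$subject_means +
    matrix(cm$region_means, 6, 4, byrow = TRUE)
  expect_equal(unname(rec), unname(M), tolerance = 1e-10)
  expect_lt(max(abs(rowMeans(cm$values))), 1e-10)
  expect_lt(max(abs(colMeans(cm$values))), 1e-10)

  M[2, 3] <- NA
  expect_error(double_center(M), "missing")
})

test_that("decomposition matches an independent covariance eigendecomposition", {
  cm <- double_center(random_logvol(20, 14, seed = 8))
  d <- ssm_decompose(cm)

  ev <- oracle_cov_eigen(cm$values)
  K <- ncol(d$loadings)
  expect_equal(d$eigenvalues, ev$values[seq_len(K)], tolerance = 1e-8)
  for (j in seq_len(K)) {
    expect_gt(abs(sum(d$loadings[, j] * ev$vectors[, j])), 1 - 1e-8)
  }

  # orthonormal loadings, orthogonal scores, full reconstruction
  expect_equal(crossprod(d$loadings), diag(K), ignore_attr = TRUE,
               tolerance = 1e-8)
  G <- crossprod(d$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  expect_equal(unname(d$scores %*% t(d$loadings)), unname(cm$values),
               tolerance = 1e-8)
  expect_true(all(diff(d$eigenvalues) <= 1e-12))

  expect_error(ssm_decompose(double_center(random_logvol(2, 4, 1))),
               "at least 3 subjects")
})

test_that("rank-one input concentrates variance on the first component", {
  co <- generate_cohort(cohort_params(n_subjects = 50, seed = 4,
                                      noise_sd_regions = 1e-12,
                                      global_scale_sd = 0))
  d <- ssm_decompose(double_center(log_volume_matrix(co)))
  expect_gte(d$variance_fraction[1], 0.999)
})

test_that("decomposition is permutation- and global-scale-equivariant", {
  co <- quick_cohort(n = 30, seed = 17)
  lm1 <- log_volume_matrix(co)
  d1 <- ssm_decompose(double_center(lm1))

  perm <- sample(nrow(lm1))
  d2 <- ssm_decompose(double_center(lm1[perm, ]))
  expect_equal(d2$loadings, d1$loadings, tolerance = 1e-8)
  expect_equal(d2$scores, d1$scores[perm, ], ignore_attr = TRUE,
               tolerance = 1e-8)

  # multiplying all volumes by k only shifts the subject means by log(k)
  co_scaled <- co
  co_scaled[default_region_names()] <- co[default_region_names()] * 3.7
  cm1 <- double_center(lm1)
  cm2 <- double_center(log_volume_matrix(co_scaled))
  expect_equal(cm2$subject_means, cm1$subject_means + log(3.7),
               tolerance = 1e-10)
  expect_equal(cm2$values, cm1$values, tolerance = 1e-10)
  d3 <- ssm_decompose(cm2)
  expect_equal(d3$loadings, d1$loadings, tolerance = 1e-8)
  expect_equal(d3$scores, d1$scores, tolerance = 1e-8)
})

test_that("a strongly planted component is recovered by the leading loading", {
  p <- cohort_params(n_subjects = 300, seed = 6, noise_sd_regions = 0.01,
                     global_scale_sd = 0.1)
  co <- generate_cohort(p)
  d <- ssm_decompose(double_center(log_volume_matrix(co)))
  cosine <- abs(sum(d$loadings[, 1] * p$planted_weights))
  expect_gte(cosine, 0.99)
})
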
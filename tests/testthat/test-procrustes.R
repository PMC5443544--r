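test_that("centroid size follows its definition and scales linearly", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(centroid_size(sq), sqrt(2), tolerance = 1e-12)
  set.seed(1)
  cfg <- random_config(8)
  expect_equal(centroid_size(cfg * 2), 2 * centroid_size(cfg),
               tolerance = 1e-12)
  expect_error(centroid_size(matrix(3, 8, 2)), "degenerate")
})

test_that("GPA is invariant to similarity transforms of the inputs", {
  set.seed(11)
  base <- random_config(8)
  copies <- list(base,
                 sweep(base %*% rot2(37 * pi / 180), 2, c(5, -3), `+`),
                 sweep(base %*% rot2(212 * pi / 180), 2, c(-8, 1), `+`))
  d <- landmark_dataset(copies, c("a", "b", "c"), c("a", "b", "c"), "ventral")
  fit <- gpa(d)
  for (i in 2:3)
    expect_lt(max(abs(fit$aligned[, , i] - fit$aligned[, , 1])), 1e-8)
  expect_equal(procrustes_distance(fit$aligned[, , 1], fit$aligned[, , 2]), 0,
               tolerance = 1e-7)

  # transform a whole noisy dataset: tangent coordinates unchanged
  configs <- replicate(10, base + matrix(rnorm(16, sd = 0.05), 8, 2),
                       simplify = FALSE)
  d1 <- landmark_dataset(configs, sprintf("s%d", 1:10),
                         sprintf("s%d", 1:10), "ventral")
  d2 <- random_similarity_dataset(d1, seed = 5)
  f1 <- gpa(d1); f2 <- gpa(d2)
  expect_lt(max(abs(f1$tangent - f2$tangent)), 1e-8)
})

test_that("aligned configurations satisfy the superimposition contract", {
  set.seed(12)
  base <- random_config(8)
  configs <- replicate(15, base + matrix(rnorm(16, sd = 0.1), 8, 2),
                       simplify = FALSE)
  d <- landmark_dataset(configs, sprintf("s%d", 1:15), sprintf("s%d", 1:15),
                        "ventral")
  fit <- gpa(d)
  n <- dim(fit$aligned)[3]
  for (i in seq_len(n)) {
    expect_lt(max(abs(colMeans(fit$aligned[, , i]))), 1e-10)
    expect_equal(sqrt(sum(fit$aligned[, , i]^2)), 1, tolerance = 1e-10)
  }
  # consensus = mean of aligned, rescaled to unit size
  m <- apply(fit$aligned, c(1, 2), mean)
  m <- sweep(m, 2, colMeans(m)); m <- m / sqrt(sum(m^2))
  expect_lt(max(abs(m - fit$consensus)), 1e-8)

  # tangent rows orthogonal to translation, scaling and rotation directions
  cvec <- as.vector(fit$consensus)
  rotdir <- as.vector(cbind(-fit$consensus[, 2], fit$consensus[, 1]))
  tx <- c(rep(1, 8), rep(0, 8)); ty <- c(rep(0, 8), rep(1, 8))
  for (dir in list(cvec, rotdir, tx, ty))
    expect_lt(max(abs(fit$tangent %*% dir)), 1e-8)

  # tangent-space rank at most 2k - 4
  ev <- eigen(cov(fit$tangent), symmetric = TRUE, only.values = TRUE)$values
  expect_lte(sum(ev > 1e-12 * ev[1]), 2 * 8 - 4)
})

test_that("identical inputs give the consensus and zero distances", {
  set.seed(13)
  base <- random_config(6)
  d <- landmark_dataset(replicate(5, base, simplify = FALSE),
                        sprintf("s%d", 1:5), sprintf("s%d", 1:5), "ventral")
  fit <- gpa(d)
  # the consensus is that shape (up to the canonical orientation)
  expect_lt(procrustes_distance(fit$consensus, center_scale(base)), 1e-7)
  expect_equal(fit$centroid_size, rep(centroid_size(base), 5),
               tolerance = 1e-12)
})

test_that("Procrustes distances agree with the rotation-grid oracle", {
  set.seed(14)
  base <- random_config(8)
  configs <- replicate(8, base + matrix(rnorm(16, sd = 0.15), 8, 2),
                       simplify = FALSE)
  d <- landmark_dataset(configs, sprintf("s%d", 1:8), sprintf("s%d", 1:8),
                        "ventral")
  fit <- gpa(d)
  for (i in 1:4) for (j in (i + 1):5) {
    mine <- procrustes_distance(fit$aligned[, , i], fit$aligned[, , j])
    oracle <- oracle_procrustes_distance(configs[[i]], configs[[j]])
    expect_equal(mine, oracle, tolerance = 1e-4)
  }
  # and on raw random pairs, to 1e-6
  for (r in 1:5) {
    a <- center_scale(random_config(8)); b <- center_scale(random_config(8))
    expect_equal(procrustes_distance(a, b), oracle_procrustes_distance(a, b),
                 tolerance = 1e-6)
  }
  expect_equal(procrustes_distance(center_scale(base),
                                   center_scale(base %*% rot2(1.1))), 0,
               tolerance = 1e-8)
  expect_error(procrustes_distance(center_scale(base),
                                   center_scale(random_config(5))),
               "dimension mismatch")
})

test_that("the consensus minimizes the sum of squared Procrustes distances", {
  set.seed(15)
  base <- random_config(8)
  configs <- replicate(12, base + matrix(rnorm(16, sd = 0.1), 8, 2),
                       simplify = FALSE)
  d <- landmark_dataset(configs, sprintf("s%d", 1:12), sprintf("s%d", 1:12),
                        "ventral")
  fit <- gpa(d)
  ssq <- function(ref) sum(apply(fit$aligned, 3, function(m)
    procrustes_distance(center_scale(ref), m)^2))
  base_ssq <- ssq(fit$consensus)
  for (r in 1:20) {
    pert <- fit$consensus + matrix(rnorm(16, sd = 0.01), 8, 2)
    expect_gte(ssq(pert), base_ssq - 1e-10)
  }
})

test_that("reflection is never applied silently", {
  set.seed(16)
  base <- random_config(8)
  mirrored <- base %*% diag(c(-1, 1))
  d <- landmark_dataset(list(base, mirrored), c("a", "b"), c("a", "b"),
                        "ventral")
  fit <- gpa(d)
  dist_proper <- procrustes_distance(fit$aligned[, , 1], fit$aligned[, , 2])
  expect_gt(dist_proper, 0.1)  # a mirror image is NOT matched
  fit_refl <- gpa(d, allow_reflection = TRUE)
  expect_lt(procrustes_distance(fit_refl$aligned[, , 1],
                                fit_refl$aligned[, , 2],
                                allow_reflection = TRUE), 1e-8)
})
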
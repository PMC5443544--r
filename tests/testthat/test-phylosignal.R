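test_that("squared-change parsimony matches the analytic fixtures", {
  star <- ape::stree(3, type = "star")
  star$edge.length <- rep(1, 3)
  star$tip.label <- c("a", "b", "c")
  rec <- scp_reconstruct(stats::setNames(c(0, 0, 3), c("a", "b", "c")), star)
  expect_equal(unname(rec$node_values[4, 1]), 1, tolerance = 1e-12)
  expect_equal(rec$tree_length, 6, tolerance = 1e-12)

  t2 <- ape::read.tree(text = "(a:1,b:3);")
  rec2 <- scp_reconstruct(stats::setNames(c(0, 4), c("a", "b")), t2)
  expect_equal(unname(rec2$node_values[3, 1]), 1, tolerance = 1e-12)
  expect_equal(rec2$tree_length, 4, tolerance = 1e-12)

  # tip rows are the observed data, exactly
  expect_identical(rec2$node_values["a", 1], 0)
  expect_identical(rec2$node_values["b", 1], 4)
})

test_that("SCP equals a numerical-minimizer oracle on random small trees", {
  for (s in 1:4) {
    tr <- random_tree(6, seed = 100 + s)
    set.seed(200 + s)
    y <- matrix(rnorm(6 * 3), 6, 3, dimnames = list(tr$tip.label, NULL))
    rec <- scp_reconstruct(y, tr)
    oracle <- oracle_scp(y, tr)
    expect_equal(rec$tree_length, oracle$objective, tolerance = 1e-6)
    expect_lt(max(abs(rec$node_values[-(1:6), ] - oracle$node_values)), 1e-4)
    expect_equal(tree_length(y, tr), rec$tree_length, tolerance = 1e-10)
  }
})

test_that("the SCP optimum cannot be improved by perturbation", {
  tr <- random_tree(8, seed = 105)
  set.seed(205)
  y <- matrix(rnorm(8 * 2), 8, 2, dimnames = list(tr$tip.label, NULL))
  rec <- scp_reconstruct(y, tr)
  len <- function(nodes) sum(vapply(seq_len(nrow(tr$edge)), function(i) {
    d <- nodes[tr$edge[i, 1], ] - nodes[tr$edge[i, 2], ]
    sum(d^2) / tr$edge.length[i]
  }, numeric(1)))
  for (r in 1:25) {
    pert <- rec$node_values
    pert[-(1:8), ] <- pert[-(1:8), ] + matrix(rnorm(7 * 2, sd = 0.05), 7, 2)
    expect_gte(len(pert), rec$tree_length - 1e-12)
  }
})

test_that("SCP separates by coordinate and is rotation invariant", {
  tr <- random_tree(10, seed = 106)
  set.seed(206)
  y <- matrix(rnorm(10 * 4), 10, 4, dimnames = list(tr$tip.label, NULL))
  joint <- scp_reconstruct(y, tr)
  for (j in 1:4) {
    single <- scp_reconstruct(y[, j, drop = FALSE], tr)
    expect_equal(unname(single$node_values[, 1]),
                 unname(joint$node_values[, j]), tolerance = 1e-10)
  }
  q <- qr.Q(qr(matrix(rnorm(16), 4, 4)))
  expect_equal(tree_length(y %*% q, tr), joint$tree_length, tolerance = 1e-8)
})

test_that("phylogenetic covariance matches path sums and is PSD", {
  star <- ape::stree(4, type = "star")
  star$edge.length <- rep(1, 4)
  expect_equal(unname(phylo_covariance(star)), diag(4))

  tr <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  cmat <- phylo_covariance(tr)
  expect_equal(cmat["A", "A"], 2)
  expect_equal(cmat["A", "B"], 1)
  expect_equal(cmat["A", "C"], 0)

  for (s in 1:20) {
    trr <- random_tree(sample(5:40, 1), seed = 300 + s)
    ev <- eigen(phylo_covariance(trr), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gte(min(ev), -1e-10)
  }
})

test_that("tree-length permutation test behaves at the boundaries", {
  tr <- random_tree(8, seed = 107)
  y_const <- matrix(2, 8, 3, dimnames = list(tr$tip.label, NULL))
  res <- tree_length_permutation_test(y_const, tr, n_perm = 99, seed = 1)
  expect_lt(abs(res$observed), 1e-10)
  expect_equal(res$p_value, 1)
  expect_error(tree_length_permutation_test(y_const, tr, n_perm = 0), "n_perm")
})

test_that("tree-length permutations equal brute-force recomputation", {
  tr <- random_tree(7, seed = 108)
  set.seed(208)
  y <- matrix(rnorm(7 * 2), 7, 2, dimnames = list(tr$tip.label, NULL))
  res <- tree_length_permutation_test(y, tr, n_perm = 25, seed = 99)
  set.seed(99)
  draws <- vapply(1:25, function(i) {
    p <- sample.int(7)
    yp <- y[p, , drop = FALSE]
    rownames(yp) <- rownames(y)
    scp_reconstruct(yp, tr)$tree_length
  }, numeric(1))
  expect_equal(res$null_draws, draws, tolerance = 1e-10)
})

test_that("K is 1 on unit-branch star trees and matches Blomberg's K at p=1", {
  star <- ape::stree(14, type = "star")
  star$edge.length <- rep(1, 14)
  set.seed(51)
  y <- matrix(rnorm(14 * 6), 14, 6, dimnames = list(star$tip.label, NULL))
  expect_equal(k_mult(y, star, n_rand = 1, seed = 1)$observed, 1,
               tolerance = 1e-12)

  for (s in 1:5) {
    tr <- random_tree(14, seed = 400 + s)
    y1 <- simulate_bm_tips(tr, 1, p = 1, seed = 500 + s)
    mine <- k_mult(y1, tr, n_rand = 1, seed = 1)$observed
    ref <- as.numeric(phytools::phylosig(tr, y1[, 1], method = "K"))
    expect_equal(mine, ref, tolerance = 1e-8)
  }
})

test_that("K is invariant to common branch-length scaling", {
  tr <- random_tree(12, seed = 109)
  y <- simulate_bm_tips(tr, 1, p = 5, seed = 209)
  k1 <- k_mult(y, tr, n_rand = 1, seed = 1)$observed
  tr2 <- tr; tr2$edge.length <- tr$edge.length * 7.3
  k2 <- k_mult(y, tr2, n_rand = 1, seed = 1)$observed
  expect_equal(k1, k2, tolerance = 1e-10)
})

test_that("BM data concentrate K near 1 and above the permutation null", {
  tr <- random_tree(14, seed = 110)
  set.seed(210)
  ks <- replicate(100, {
    y <- simulate_bm_tips(tr, 1, p = 12)
    k_mult(y, tr, n_rand = 1, seed = NULL)$observed
  })
  expect_gt(mean(ks), 0.9); expect_lt(mean(ks), 1.1)

  y <- simulate_bm_tips(tr, 1, p = 12, seed = 211)
  res <- k_mult(y, tr, n_rand = 199, seed = 212)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$observed, stats::median(res$null_draws))
})

test_that("phylomorphospace reconstruction is linear in the data", {
  tr <- random_tree(14, seed = 111)
  set.seed(213)
  y <- matrix(rnorm(14 * 10), 14, 10, dimnames = list(tr$tip.label, NULL))
  pc <- shape_pca(y, level = "specimen")
  pm <- phylomorphospace(pc$scores[, 1:2], tr)
  full <- scp_reconstruct(y, tr)
  projected <- sweep(full$node_values, 2, pc$mean_vector) %*%
    pc$loadings[, 1:2]
  expect_lt(max(abs(pm$node_coords - projected)), 1e-8)
  expect_identical(pm$edges, tr$edge)

  # star tree: root at the centroid of tips
  star <- ape::stree(5, type = "star"); star$edge.length <- rep(1, 5)
  sc <- matrix(rnorm(10), 5, 2, dimnames = list(star$tip.label, NULL))
  pms <- phylomorphospace(sc, star)
  expect_equal(unname(pms$node_coords[6, ]), unname(colMeans(sc)),
               tolerance = 1e-10)
})
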
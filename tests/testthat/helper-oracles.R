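# Shared fixtures and independent oracles for the test suite.

# random non-degenerate k x 2 configuration
random_config <- function(k = 8, sd = 1) {
  matrix(stats::rnorm(2 * k, sd = sd), k, 2)
}

rot2 <- function(theta) {
  matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
}

center_scale <- function(m) {
  m <- sweep(m, 2, colMeans(m))
  m / sqrt(sum(m^2))
}

# Brute-force Procrustes distance: center and scale both shapes, then scan
# the rotation angle on a fine grid and polish with optimize(). Independent
# of the package's SVD-based solver.
oracle_procrustes_distance <- function(a, b) {
  a <- center_scale(a); b <- center_scale(b)
  f <- function(theta) sum((a - b %*% rot2(theta))^2)
  grid <- seq(0, 2 * pi, length.out = 3601)
  v <- vapply(grid, f, numeric(1))
  i <- which.min(v)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  sqrt(stats::optimize(f, c(lo, hi), tol = 1e-14)$objective)
}

# Squared-change parsimony by general-purpose numerical minimization over
# all internal node values (flattened), for small trees.
oracle_scp <- function(tip_values, tree) {
  n_tip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  p <- ncol(tip_values)
  len <- if (is.null(tree$edge.length)) rep(1, nrow(tree$edge)) else tree$edge.length
  obj <- function(theta) {
    nodes <- rbind(tip_values, matrix(theta, n_int, p))
    sum(vapply(seq_len(nrow(tree$edge)), function(i) {
      d <- nodes[tree$edge[i, 1], ] - nodes[tree$edge[i, 2], ]
      sum(d^2) / len[i]
    }, numeric(1)))
  }
  start <- rep(colMeans(tip_values), each = n_int)
  fit <- stats::optim(start, obj, method = "BFGS",
                      control = list(reltol = 1e-15, maxit = 5000))
  list(node_values = matrix(fit$par, n_int, p), objective = fit$value)
}

# small random bifurcating tree with positive branch lengths
random_tree <- function(n_tips, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(n_tips)
  tr$edge.length <- tr$edge.length + 0.1
  tr
}

# apply a random similarity transform (proper rotation + translation +
# positive scaling) to every configuration of a dataset
random_similarity_dataset <- function(data, seed = 1) {
  set.seed(seed)
  out <- data
  for (i in seq_len(length(data))) {
    s <- exp(stats::runif(1, -1, 1))
    th <- stats::runif(1, 0, 2 * pi)
    shift <- stats::rnorm(2, sd = 5)
    out$coords[, , i] <- sweep(data$coords[, , i] %*% rot2(th) * s, 2, shift, `+`)
  }
  out
}

# proper rotation matrix aligning shape b onto shape a (frame bookkeeping for
# comparing generator-frame vectors with GPA-frame estimates)
align_rotation <- function(a, b) {
  m <- crossprod(b, a)
  sv <- svd(m)
  r <- tcrossprod(sv$u, sv$v)
  if (det(r) < 0) r <- sv$u %*% diag(c(1, -1)) %*% t(sv$v)
  r
}

# re-express a vectorized tangent vector from the template frame in the
# frame of a GPA consensus
map_to_consensus_frame <- function(v, template, consensus) {
  k <- nrow(template)
  as.vector(matrix(v, k, 2) %*% align_rotation(consensus, template))
}
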
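## Branch lengths actually used by the comparative machinery: unit when the
## tree is a bare topology or when use_lengths = FALSE; floored at 1e-8 so
## zero-length branches (e.g. resolved polytomies) never produce infinite
## weights.
effective_lengths <- function(tree, use_lengths = TRUE) {
  if (is.null(tree$edge.length) || !use_lengths)
    return(rep(1, nrow(tree$edge)))
  if (any(tree$edge.length < 1e-8))
    warning("branch lengths below 1e-8 floored at 1e-8")
  pmax(tree$edge.length, 1e-8)
}

## Graph Laplacian of the tree with edge weights 1/length, partitioned into
## tip and internal blocks. Minimizing sum_branches ||x_child - x_parent||^2 /
## length over internal node values is the normal-equations solve of this
## Laplacian; the tree length as a function of tip data Y is then the
## quadratic form tr(Y' Q Y) with Q the Schur complement onto the tips.
tree_quadratic <- function(tree, use_lengths = TRUE) {
  validate_phylogeny(tree)
  n_tip <- ape::Ntip(tree); n_all <- n_tip + tree$Nnode
  len <- effective_lengths(tree, use_lengths)
  w <- 1 / len
  lap <- matrix(0, n_all, n_all)
  e <- tree$edge
  for (i in seq_len(nrow(e))) {
    u <- e[i, 1]; v <- e[i, 2]
    lap[u, u] <- lap[u, u] + w[i]; lap[v, v] <- lap[v, v] + w[i]
    lap[u, v] <- lap[u, v] - w[i]; lap[v, u] <- lap[v, u] - w[i]
  }
  tips <- seq_len(n_tip); internal <- n_tip + seq_len(tree$Nnode)
  l_ii <- lap[internal, internal, drop = FALSE]
  l_it <- lap[internal, tips, drop = FALSE]
  ## solve for the internal-node reconstruction operator and the tip-space
  ## quadratic form in one factorization
  a_op <- -solve(l_ii, l_it)                  # anc = a_op %*% y_tips
  q <- lap[tips, tips, drop = FALSE] + lap[tips, internal, drop = FALSE] %*% a_op
  list(q = q, a_op = a_op, lengths = len, n_tip = n_tip)
}

match_tip_values <- function(tip_values, tree) {
  if (is.vector(tip_values))
    tip_values <- matrix(tip_values, ncol = 1,
                         dimnames = list(names(tip_values), "trait"))
  stopifnot(is.matrix(tip_values))
  if (!is.null(rownames(tip_values))) {
    orphan <- setdiff(tree$tip.label, rownames(tip_values))
    extra <- setdiff(rownames(tip_values), tree$tip.label)
    if (length(orphan) || length(extra))
      stop("tip/data mismatch; missing from data: ",
           paste(orphan, collapse = ", "), "; absent from tree: ",
           paste(extra, collapse = ", "))
    tip_values <- tip_values[tree$tip.label, , drop = FALSE]
  } else if (nrow(tip_values) != ape::Ntip(tree)) {
    stop("tip_values has ", nrow(tip_values), " rows but the tree has ",
         ape::Ntip(tree), " tips")
  } else rownames(tip_values) <- tree$tip.label
  tip_values
}

#' Squared-change parsimony ancestral reconstruction
#'
#' Estimates trait vectors at the internal nodes of a rooted tree by
#' minimizing the sum over branches of squared change divided by branch
#' length — the reconstruction that is also the maximum-likelihood ancestral
#' state under Brownian motion. The minimized objective is the morphometric
#' "tree length": with Procrustes tangent coordinates its units are squared
#' Procrustes distance, with logCS squared logCS. The optimum is found
#' exactly by solving the linear system in which every internal node is the
#' inverse-branch-length-weighted average of its neighbours.
#'
#' @param tip_values n x p matrix (rownames = tip labels) or named vector.
#' @param tree rooted [ape::phylo]; unit branch lengths are used when the
#'   tree has none or `use_lengths = FALSE`.
#' @param use_lengths honour branch lengths when present (default TRUE).
#' @return An object of class `scp_reconstruction`: list with `node_values`
#'   ((tips + internal) x p; tip rows equal the data exactly), `tree_length`,
#'   `tree`, `use_lengths`.
#' @export
scp_reconstruct <- function(tip_values, tree, use_lengths = TRUE) {
  y <- match_tip_values(tip_values, tree)
  tq <- tree_quadratic(tree, use_lengths)
  anc <- tq$a_op %*% y
  nodes <- rbind(y, anc)
  rownames(nodes) <- c(tree$tip.label,
                       if (!is.null(tree$node.label) &&
                           length(tree$node.label) == tree$Nnode)
                         tree$node.label
                       else paste0("node_", tq$n_tip + seq_len(tree$Nnode)))
  len <- sum(vapply(seq_len(nrow(tree$edge)), function(i) {
    d <- nodes[tree$edge[i, 1], ] - nodes[tree$edge[i, 2], ]
    sum(d^2) / tq$lengths[i]
  }, numeric(1)))
  structure(list(node_values = nodes, tree_length = len, tree = tree,
                 use_lengths = use_lengths),
            class = "scp_reconstruction")
}

#' @export
print.scp_reconstruction <- function(x, ...) {
  cat("Squared-change parsimony reconstruction:",
      ape::Ntip(x$tree), "tips,", x$tree$Nnode, "internal nodes\n")
  cat("  tree length (sum of squared changes / branch length):",
      format(x$tree_length, digits = 6), "\n")
  invisible(x)
}

#' Morphometric tree length of tip data on a phylogeny
#'
#' The minimized sum of branch-length-weighted squared changes from
#' [scp_reconstruct()], computed directly as a quadratic form in the tip
#' data. Shorter lengths mean trait values change less along the tree, i.e.
#' more phylogenetic signal.
#'
#' @inheritParams scp_reconstruct
#' @return Non-negative scalar.
#' @export
tree_length <- function(tip_values, tree, use_lengths = TRUE) {
  y <- match_tip_values(tip_values, tree)
  tq <- tree_quadratic(tree, use_lengths)
  sum(y * (tq$q %*% y))
}

new_signal_test <- function(statistic_name, observed, null_draws, favourable,
                            n_perm, seed) {
  p <- (sum(favourable) + 1) / (n_perm + 1)
  structure(list(statistic_name = statistic_name, observed = observed,
                 null_draws = null_draws, p_value = p,
                 n_permutations = n_perm, seed = seed),
            class = "signal_test")
}

#' @export
print.signal_test <- function(x, ...) {
  cat("Phylogenetic signal test (", x$statistic_name, ")\n", sep = "")
  cat(sprintf("  observed = %.6g, p = %.4g (%d permutations, seed %s)\n",
              x$observed, x$p_value, x$n_permutations,
              format(x$seed)))
  invisible(x)
}

#' Permutation test of phylogenetic signal via tree length
#'
#' Holds the topology constant, permutes the tip data across the tips, and
#' compares the observed tree length with the permutation distribution.
#' Signal is evidenced by an observed tree shorter than permuted trees, so
#' the p-value counts permutations with tree length less than or equal to
#' the observed value (+1 correction).
#'
#' @inheritParams scp_reconstruct
#' @param n_perm number of permutations (the reference analysis used 10000).
#' @param seed RNG seed.
#' @return A `signal_test` with `statistic_name = "tree_length"`.
#' @export
tree_length_permutation_test <- function(tip_values, tree, n_perm = 10000,
                                         seed = 1L, use_lengths = TRUE) {
  if (n_perm < 1) stop("n_perm must be at least 1")
  y <- match_tip_values(tip_values, tree)
  n <- nrow(y)
  if (n < 4L) stop("need at least 4 tips for a meaningful permutation test")
  tq <- tree_quadratic(tree, use_lengths)
  obs <- sum(y * (tq$q %*% y))
  ## permuting rows of Y only permutes rows/cols of the Gram matrix
  g <- tcrossprod(y)
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(seq_len(n_perm), function(i) {
    p <- sample.int(n)
    sum(tq$q * g[p, p])
  }, numeric(1))
  new_signal_test("tree_length", obs, draws, draws <= obs + 1e-12 * max(1, obs),
                  n_perm, seed)
}

#' Phylogenetic covariance matrix implied by Brownian motion
#'
#' C[i, j] is the shared branch length from the root to the most recent
#' common ancestor of tips i and j; the diagonal holds root-to-tip
#' distances. Under Brownian motion with rate sigma^2 the tip values of each
#' trait dimension are jointly normal with covariance sigma^2 * C.
#'
#' @param tree rooted [ape::phylo]; unit branch lengths when absent.
#' @return N x N matrix with tip labels as dimnames.
#' @export
phylo_covariance <- function(tree) {
  validate_phylogeny(tree)
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  ape::vcv.phylo(tree)
}

## K statistic for one data matrix given precomputed pieces; returns 0 for
## data with (numerically) no variation around the phylogenetic mean, so a
## degenerate dataset yields every permutation draw equal and p = 1. The
## guard is relative to the overall magnitude of the data, covering the
## float-noise left by a Procrustes fit of identical configurations.
k_stat <- function(y, inv_c, denom_expected) {
  icy <- inv_c %*% y
  a <- colSums(icy) / sum(inv_c)
  yc <- sweep(y, 2, a)
  num <- sum(yc^2)
  if (num < 1e-20 * max(1, sum(y^2))) return(0)
  den <- sum(yc * (inv_c %*% yc))
  (num / den) / denom_expected
}

#' Multivariate K statistic of phylogenetic signal
#'
#' The multivariate generalization of Blomberg's K: the ratio of observed to
#' phylogenetically expected trait variation, scaled so that K = 1 when the
#' data conform exactly to Brownian motion on the tree, K < 1 when relatives
#' resemble each other less than Brownian motion predicts, and K > 1 when
#' they resemble each other more. With a single trait it reduces exactly to
#' Blomberg's K. Significance comes from randomizing the tip rows and
#' counting permutations with K greater than or equal to the observed value.
#'
#' @inheritParams scp_reconstruct
#' @param n_rand number of randomizations (the reference analysis used 999).
#' @param seed RNG seed.
#' @return A `signal_test` with `statistic_name = "k_mult"`.
#' @export
k_mult <- function(tip_values, tree, n_rand = 999, seed = 1L) {
  y <- match_tip_values(tip_values, tree)
  n <- nrow(y)
  if (n < 4L) stop("need at least 4 tips")
  cmat <- phylo_covariance(tree)
  cmat <- cmat[rownames(y), rownames(y)]
  inv_c <- tryCatch(solve(cmat), error = function(e)
    stop("singular phylogenetic covariance; floor very short branches ",
         "or drop duplicate zero-length tips"))
  denom_expected <- (sum(diag(cmat)) - n / sum(inv_c)) / (n - 1)
  obs <- k_stat(y, inv_c, denom_expected)
  if (!is.null(seed)) set.seed(seed)
  draws <- vapply(seq_len(n_rand), function(i)
    k_stat(y[sample.int(n), , drop = FALSE], inv_c, denom_expected),
    numeric(1))
  new_signal_test("k_mult", obs, draws, draws >= obs - 1e-12 * max(1, obs),
                  n_rand, seed)
}

#' Phylomorphospace node coordinates
#'
#' Places the internal nodes of the phylogeny in an ordination of shape (PC
#' scores or any trait columns) by squared-change parsimony, returning the
#' coordinates of every node together with the edge list, ready for plotting
#' a tree through morphospace. Because the reconstruction is linear in the
#' data, reconstructing in score space is identical to reconstructing full
#' shapes and projecting them onto the same loadings.
#'
#' @param scores tips x m matrix (rownames = tip labels).
#' @param tree rooted [ape::phylo].
#' @param use_lengths honour branch lengths when present.
#' @return A list with `node_coords` ((tips + internal) x m), `edges`
#'   (2-column parent/child matrix of node indices), `tip_labels`,
#'   `tree_length`.
#' @export
phylomorphospace <- function(scores, tree, use_lengths = TRUE) {
  rec <- scp_reconstruct(scores, tree, use_lengths)
  list(node_coords = rec$node_values, edges = tree$edge,
       tip_labels = tree$tip.label, tree_length = rec$tree_length)
}
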
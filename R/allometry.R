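#' Multivariate regression of shape on log centroid size
#'
#' Quantifies allometry by regressing the tangent-space shape coordinates on
#' log centroid size. Shape and logCS are mean-centered first, after which
#' the regression runs through the origin (the centering makes the
#' through-origin model exact); `center = FALSE` gives the strict
#' no-centering variant. The summary statistic is the percentage of total
#' shape variation predicted by size,
#' 100 * sum(predicted^2) / sum(centered shape^2), and its significance is a
#' permutation test that shuffles logCS across specimens.
#'
#' @param tangent n x 2k matrix of tangent coordinates.
#' @param log_cs length-n vector of log centroid sizes.
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @param center mean-center shape and size first (default TRUE).
#' @return An object of class `allometry_fit` with `beta` (2k shape change
#'   per unit logCS), `percent_predicted`, `residuals` (n x 2k, centered),
#'   `fitted`, `mean_shape`, `p_value`, `null_percent` (permutation draws),
#'   `n_permutations`, `seed`.
#' @export
regress_shape_on_size <- function(tangent, log_cs, n_perm = 10000,
                                  seed = 1L, center = TRUE) {
  stopifnot(is.matrix(tangent), length(log_cs) == nrow(tangent))
  n <- nrow(tangent)
  if (n < 3L) stop("allometric regression needs at least 3 specimens")
  if (stats::sd(log_cs) < 1e-12)
    stop("log centroid size is constant: allometric regression is undefined")
  mean_shape <- colMeans(tangent)
  yc <- if (center) sweep(tangent, 2, mean_shape) else tangent
  xc <- if (center) log_cs - mean(log_cs) else log_cs
  ssx <- sum(xc^2)
  ssy <- sum(yc^2)
  beta <- as.vector(crossprod(xc, yc)) / ssx
  fitted <- outer(xc, beta)
  percent <- 100 * sum(fitted^2) / ssy
  ## For permuted x: sum(pred^2) = ||Y'x||^2 / ||x||^2 (x'x invariant under
  ## permutation), so each draw is one crossproduct.
  yt <- t(yc)
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    null_percent <- vapply(seq_len(n_perm), function(i) {
      xp <- xc[sample.int(n)]
      100 * sum((yt %*% xp)^2) / (ssx * ssy)
    }, numeric(1))
    p <- (sum(null_percent >= percent) + 1) / (n_perm + 1)
  } else {
    null_percent <- numeric(0); p <- NA_real_
  }
  structure(list(beta = beta, percent_predicted = percent,
                 residuals = yc - fitted, fitted = fitted,
                 mean_shape = mean_shape, p_value = p,
                 null_percent = null_percent, n_permutations = n_perm,
                 seed = seed, log_cs = log_cs, centered = center),
            class = "allometry_fit")
}

#' @export
print.allometry_fit <- function(x, ...) {
  cat("Allometric regression of shape on logCS\n")
  cat(sprintf("  predicted: %.2f%% of shape variation", x$percent_predicted))
  if (!is.na(x$p_value))
    cat(sprintf("; permutation p = %.4g (%d permutations)",
                x$p_value, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Size-corrected shape coordinates
#'
#' Returns the residuals of the allometric regression re-centered on the
#' grand mean shape, so downstream PCA and signal tests run on the corrected
#' coordinates exactly as they would on the raw ones. Applying the correction
#' twice changes nothing (the residuals are orthogonal to logCS).
#'
#' @param fit an `allometry_fit`.
#' @return n x 2k matrix of size-corrected tangent coordinates.
#' @export
size_correct <- function(fit) {
  stopifnot(inherits(fit, "allometry_fit"))
  sweep(fit$residuals, 2, fit$mean_shape, `+`)
}

#' Phylogenetic independent contrasts of a trait matrix
#'
#' Felsenstein's standardized contrasts, computed column-wise by post-order
#' traversal: at each internal node the contrast is the difference between
#' the two descendant values divided by the square root of the summed branch
#' lengths, the ancestral value is the branch-length-weighted average, and
#' the parent branch is lengthened by the product over the sum of the two
#' descendant branch lengths. Polytomies are resolved to zero-length
#' bifurcations (with a warning); absent branch lengths are treated as unit.
#'
#' @param values n x p matrix with rownames matching tree tip labels (a
#'   vector is treated as one column).
#' @param tree an [ape::phylo] object.
#' @return An object of class `contrast_set`: list with `contrasts`
#'   ((n-1) x p matrix), `node_order` (internal node ids in `tree`), `tree`
#'   (the resolved, unit-filled tree actually used).
#' @export
pic_contrasts <- function(values, tree) {
  if (is.vector(values)) values <- matrix(values, ncol = 1,
                                          dimnames = list(names(values), "trait"))
  stopifnot(is.matrix(values))
  validate_phylogeny(tree)
  if (is.null(rownames(values)))
    stop("values must carry species names as rownames")
  orphan <- setdiff(rownames(values), tree$tip.label)
  if (length(orphan))
    stop("species not found in the tree: ", paste(orphan, collapse = ", "))
  missing_tip <- setdiff(tree$tip.label, rownames(values))
  if (length(missing_tip))
    stop("tree tips without data: ", paste(missing_tip, collapse = ", "))
  if (!ape::is.binary(tree)) {
    warning("polytomies resolved to zero-length bifurcations for contrasts")
    tree <- ape::multi2di(tree)
  }
  if (is.null(tree$edge.length))
    tree$edge.length <- rep(1, nrow(tree$edge))
  tree$edge.length <- pmax(tree$edge.length, 1e-8)
  values <- values[tree$tip.label, , drop = FALSE]
  ctr <- apply(values, 2, function(v)
    ape::pic(stats::setNames(v, tree$tip.label), tree, scaled = TRUE))
  ctr <- matrix(ctr, ncol = ncol(values),
                dimnames = list(NULL, colnames(values)))
  n_int <- tree$Nnode
  structure(list(contrasts = ctr,
                 node_order = ape::Ntip(tree) + seq_len(n_int),
                 tree = tree),
            class = "contrast_set")
}

#' Evolutionary allometry on independent contrasts
#'
#' Regression of shape contrasts on size contrasts through the origin (no
#' centering: contrasts have expectation zero by construction), assessing
#' allometry across species means while respecting phylogenetic
#' non-independence. Significance comes from permuting the pairing of size
#' contrasts with shape contrasts and randomizing their signs, both of which
#' are exchangeable under the no-allometry null.
#'
#' @param shape_contrasts (n-1) x 2k contrast matrix (or a `contrast_set`).
#' @param size_contrasts length-(n-1) vector of logCS contrasts (or a
#'   `contrast_set` with one column).
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return An `allometry_fit` (with `centered = FALSE`).
#' @export
evolutionary_allometry_test <- function(shape_contrasts, size_contrasts,
                                        n_perm = 10000, seed = 1L) {
  if (inherits(shape_contrasts, "contrast_set"))
    shape_contrasts <- shape_contrasts$contrasts
  if (inherits(size_contrasts, "contrast_set"))
    size_contrasts <- as.vector(size_contrasts$contrasts)
  stopifnot(is.matrix(shape_contrasts),
            length(size_contrasts) == nrow(shape_contrasts))
  nc <- nrow(shape_contrasts)
  if (nc < 3L)
    stop("need at least 3 contrasts for the evolutionary allometry test")
  y <- shape_contrasts; x <- size_contrasts
  ssx <- sum(x^2); ssy <- sum(y^2)
  beta <- as.vector(crossprod(x, y)) / ssx
  fitted <- outer(x, beta)
  percent <- 100 * sum(fitted^2) / ssy
  yt <- t(y)
  if (!is.null(seed)) set.seed(seed)
  null_percent <- vapply(seq_len(n_perm), function(i) {
    xp <- sample(x) * sample(c(-1, 1), nc, replace = TRUE)
    100 * sum((yt %*% xp)^2) / (ssx * ssy)
  }, numeric(1))
  p <- (sum(null_percent >= percent) + 1) / (n_perm + 1)
  structure(list(beta = beta, percent_predicted = percent,
                 residuals = y - fitted, fitted = fitted,
                 mean_shape = rep(0, ncol(y)), p_value = p,
                 null_percent = null_percent, n_permutations = n_perm,
                 seed = seed, log_cs = x, centered = FALSE),
            class = "allometry_fit")
}
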
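#' Anchor-like landmark template
#'
#' A fixed, asymmetric 8-landmark template loosely following the parts of a
#' monogenean haptoral anchor (inner root, outer root, shaft, curved point),
#' used as the base shape of the synthetic generator. Asymmetry guarantees a
#' unique proper-rotation Procrustes fit; the template is returned centered
#' and scaled to unit centroid size.
#'
#' @param k landmark count; values other than 8 interpolate points along the
#'   same outline.
#' @return k x 2 matrix, centered, unit centroid size.
#' @export
anchor_template <- function(k = 8) {
  stopifnot(k >= 3)
  base <- rbind(
    c(0.00, 0.00),   # junction of roots and shaft
    c(-0.55, 0.35),  # outer root tip
    c(-0.25, 0.60),  # notch between roots
    c(0.30, 0.55),   # inner root tip
    c(0.15, -0.60),  # mid shaft
    c(0.25, -1.20),  # shaft/point flexure
    c(0.60, -1.45),  # point curve
    c(0.95, -1.25))  # point tip
  if (k != 8) {
    t8 <- seq(0, 1, length.out = 8)
    tk <- seq(0, 1, length.out = k)
    base <- cbind(stats::approx(t8, base[, 1], xout = tk)$y,
                  stats::approx(t8, base[, 2], xout = tk)$y)
  }
  base <- sweep(base, 2, colMeans(base))
  base / sqrt(sum(base^2))
}

## Orthonormal basis of the similarity directions (x/y translation, scaling,
## infinitesimal rotation) at a centered, unit-size reference shape; used to
## keep simulated deviations inside the tangent space of the reference.
similarity_basis <- function(ref) {
  k <- nrow(ref)
  u <- cbind(c(rep(1, k), rep(0, k)),         # x translation
             c(rep(0, k), rep(1, k)),         # y translation
             as.vector(ref),                  # scaling
             as.vector(cbind(-ref[, 2], ref[, 1])))  # rotation
  qr.Q(qr(u))
}

project_tangent <- function(v, basis) v - basis %*% crossprod(basis, v)

#' Configuration for the synthetic landmark generator
#'
#' Defaults mirror the sampling design of the motivating anchor study: 14
#' species on a phylogeny, 8 landmarks per anchor, and 20 specimens per
#' species. Brownian rate, within-species landmark noise and the allometric
#' vector are expressed in the tangent space of the unit-size template, so
#' their magnitudes read directly as Procrustes-scale effects.
#'
#' @param n_tips number of species (ignored when `tree` is supplied).
#' @param tree optional [ape::phylo]; by default a random bifurcating tree
#'   with branch lengths is drawn from the seed.
#' @param k landmark count.
#' @param n_specimens specimens per species.
#' @param bm_rate per-dimension Brownian rate of species mean shape
#'   (tangent-coordinate variance per unit branch length).
#' @param noise_sd within-species isotropic landmark noise (tangent scale).
#' @param allometry_beta 2k allometric vector (shape change per unit logCS),
#'   or a scalar giving its norm along a fixed reference direction; 0 for
#'   none.
#' @param size_mean mean log centroid size (physical units).
#' @param size_bm_rate Brownian rate of species mean logCS.
#' @param size_sd within-species standard deviation of logCS.
#' @param seed integer seed; a config plus its seed fully determines the
#'   generated data.
#' @return An object of class `synthetic_config` (a validated list).
#' @export
synthetic_config <- function(n_tips = 14, tree = NULL, k = 8,
                             n_specimens = 20, bm_rate = 5e-4,
                             noise_sd = 0.01, allometry_beta = 0,
                             size_mean = log(50), size_bm_rate = 0.02,
                             size_sd = 0.08, seed = 1L) {
  stopifnot(k >= 3, n_specimens >= 1, bm_rate >= 0, noise_sd >= 0,
            size_bm_rate >= 0, size_sd >= 0)
  if (length(allometry_beta) > 1 && length(allometry_beta) != 2 * k)
    stop("allometry_beta must be a scalar norm or a vector of length 2k")
  structure(list(n_tips = n_tips, tree = tree, k = k,
                 n_specimens = n_specimens, bm_rate = bm_rate,
                 noise_sd = noise_sd, allometry_beta = allometry_beta,
                 size_mean = size_mean, size_bm_rate = size_bm_rate,
                 size_sd = size_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Simulate Brownian-motion tip values on a tree
#'
#' Starts every trait dimension at zero at the root and adds an independent
#' Gaussian increment with variance `rate * branch length` along each branch,
#' so the tip values of each dimension are jointly normal with covariance
#' `rate * C`, where C is [phylo_covariance()].
#'
#' @param tree rooted [ape::phylo]; unit branch lengths when absent.
#' @param rate per-dimension Brownian rate (scalar or length-p vector).
#' @param p number of trait dimensions.
#' @param seed RNG seed, or `NULL` to use the current RNG state.
#' @return n x p matrix with tip labels as rownames.
#' @export
simulate_bm_tips <- function(tree, rate, p = 1, seed = NULL) {
  validate_phylogeny(tree)
  if (any(rate < 0)) stop("Brownian rate must be non-negative")
  rate <- rep_len(rate, p)
  if (!is.null(seed)) set.seed(seed)
  n_tip <- ape::Ntip(tree)
  len <- if (is.null(tree$edge.length)) rep(1, nrow(tree$edge))
         else tree$edge.length
  nodes <- matrix(0, n_tip + tree$Nnode, p)
  ## pre-order: parents are assigned before their children
  ord <- rev(ape::postorder(tree))
  for (i in ord) {
    u <- tree$edge[i, 1]; v <- tree$edge[i, 2]
    nodes[v, ] <- nodes[u, ] + stats::rnorm(p, 0, sqrt(rate * len[i]))
  }
  tips <- nodes[seq_len(n_tip), , drop = FALSE]
  rownames(tips) <- tree$tip.label
  tips
}

#' Generate a synthetic landmark dataset with known ground truth
#'
#' Species mean shapes evolve by multivariate Brownian motion in the tangent
#' space of the anchor template; each specimen adds an allometric shape
#' component proportional to its logCS deviation and isotropic landmark
#' noise; configurations are then emitted at their physical size
#' (exp(logCS)) under a random rotation, translation, and digitizer scale
#' per specimen, so an analysis pipeline must genuinely superimpose them.
#' The digitizer scale is recorded in the dataset's `scale_factor`, so
#' reading with `scale_policy = "apply"` recovers physical units.
#'
#' @param config a [synthetic_config()].
#' @return A list with `dataset` (a [landmark_dataset()]), `tree`
#'   ([ape::phylo]) and `truth` (base shape, species mean tangent
#'   deviations, species logCS, beta, the config).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  k <- config$k
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rtree(config$n_tips)
    tree$tip.label <- sprintf("sp%02d", seq_len(config$n_tips))
  }
  validate_phylogeny(tree)
  n_sp <- ape::Ntip(tree)
  base <- anchor_template(k)
  basis <- similarity_basis(base)
  ## species mean shape deviations: BM in the template's tangent space
  dev <- simulate_bm_tips(tree, config$bm_rate, p = 2 * k)
  dev <- t(apply(dev, 1, function(v) project_tangent(v, basis)))
  ## species mean logCS: BM around the grand mean
  sp_logcs <- config$size_mean + simulate_bm_tips(tree, config$size_bm_rate)[, 1]
  beta <- config$allometry_beta
  if (length(beta) == 1) {
    dir <- project_tangent(rep_len(c(1, -1), 2 * k), basis)
    beta <- beta * dir / sqrt(sum(dir^2))
  } else beta <- as.vector(project_tangent(beta, basis))
  configs <- list(); spec_id <- species <- character(0)
  scale_fac <- numeric(0); true_logcs <- numeric(0)
  idx <- 0L
  for (s in seq_len(n_sp)) {
    for (j in seq_len(config$n_specimens)) {
      idx <- idx + 1L
      logcs <- sp_logcs[s] + stats::rnorm(1, 0, config$size_sd)
      v <- as.vector(base) + dev[s, ] + beta * (logcs - config$size_mean) +
        project_tangent(stats::rnorm(2 * k, 0, config$noise_sd), basis)
      shp <- matrix(v, k, 2)
      shp <- center_config(shp)
      shp <- shp / sqrt(sum(shp^2)) * exp(logcs)   # physical size
      theta <- stats::runif(1, 0, 2 * pi)
      rot <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
      digit_scale <- exp(stats::runif(1, -0.5, 0.5))
      shift <- stats::runif(2, -2, 2) * exp(logcs)
      emitted <- sweep(shp %*% rot, 2, shift, `+`) * digit_scale
      configs[[idx]] <- emitted
      spec_id[idx] <- sprintf("%s_%03d", tree$tip.label[s], j)
      species[idx] <- tree$tip.label[s]
      scale_fac[idx] <- 1 / digit_scale
      true_logcs[idx] <- logcs
    }
  }
  dataset <- landmark_dataset(configs, spec_id, species,
                              rep("ventral", idx), scale_fac)
  truth <- list(base_shape = base, species_deviation = dev,
                species_log_cs = sp_logcs, beta = beta,
                specimen_log_cs = true_logcs, config = config)
  list(dataset = dataset, tree = tree, truth = truth)
}

#' No-signal null versions of a dataset
#'
#' `shuffle_species` permutes the species labels across specimens, leaving
#' the multiset of configurations untouched; `iid_species` regenerates the
#' dataset with species means drawn independently of the tree (Brownian
#' motion on a star phylogeny of the same average depth), which requires the
#' generating `truth` record.
#'
#' @param dataset a [landmark_dataset()].
#' @param mode `"shuffle_species"` or `"iid_species"`.
#' @param seed RNG seed.
#' @param truth the `truth` element returned by [generate_dataset()]
#'   (required for `"iid_species"`).
#' @return A [landmark_dataset()] (for `"iid_species"`, the full
#'   [generate_dataset()] list).
#' @export
null_scenario <- function(dataset, mode = c("shuffle_species", "iid_species"),
                          seed = 1L, truth = NULL) {
  mode <- match.arg(mode)
  if (mode == "shuffle_species") {
    set.seed(seed)
    perm <- sample.int(length(dataset))
    out <- dataset
    out$species_id <- dataset$species_id[perm]
    out
  } else {
    if (is.null(truth))
      stop("iid_species needs the generating truth record")
    cfg <- truth$config
    tr <- cfg$tree
    if (is.null(tr)) { set.seed(cfg$seed); tr <- ape::rtree(cfg$n_tips)
                       tr$tip.label <- sprintf("sp%02d", seq_len(cfg$n_tips)) }
    depth <- mean(diag(phylo_covariance(tr)))
    star <- ape::stree(ape::Ntip(tr), type = "star")
    star$tip.label <- tr$tip.label
    star$edge.length <- rep(depth, nrow(star$edge))
    cfg$tree <- star
    cfg$seed <- as.integer(seed)
    generate_dataset(cfg)
  }
}
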
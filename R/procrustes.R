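#' Centroid size of a landmark configuration
#'
#' The standard geometric-morphometrics size measure: the square root of the
#' summed squared Euclidean distances of the landmarks from their centroid.
#' It is homogeneous of degree 1 in the coordinates and uncorrelated with
#' pure shape under isotropic landmark noise.
#'
#' @param config k x 2 numeric matrix.
#' @return Positive scalar.
#' @export
centroid_size <- function(config) {
  stopifnot(is.matrix(config), ncol(config) == 2L, all(is.finite(config)))
  cs <- sqrt(sum(sweep(config, 2, colMeans(config))^2))
  if (cs < .Machine$double.eps^0.5 * max(1, max(abs(config))))
    stop("degenerate shape: all landmarks coincide (centroid size 0)")
  cs
}

## Optimal rotation of b onto a (rows are landmarks, both centered).
## Proper rotation (det +1) unless allow_reflection; returns the 2x2 matrix R
## such that b %*% R best approximates a in least squares.
optimal_rotation <- function(a, b, allow_reflection = FALSE) {
  m <- crossprod(b, a)
  sv <- svd(m)
  r <- tcrossprod(sv$u, sv$v)
  if (!allow_reflection && det(r) < 0) {
    d <- diag(c(1, -1))
    r <- sv$u %*% d %*% t(sv$v)
  }
  r
}

center_config <- function(config) sweep(config, 2, colMeans(config))

#' Procrustes distance between two superimposed shapes
#'
#' Square root of the minimal sum of squared coordinate differences over
#' rotations of `b` onto `a`. Both shapes must be centered and scaled to unit
#' centroid size (the pre-shape convention used throughout the package).
#'
#' @param a,b k x 2 matrices, centered, unit centroid size.
#' @param allow_reflection permit an improper (reflecting) fit; off by
#'   default because left and right anchors must never be mirrored silently.
#' @return Non-negative scalar.
#' @export
procrustes_distance <- function(a, b, allow_reflection = FALSE) {
  if (!is.matrix(a) || !is.matrix(b) || !all(dim(a) == dim(b)))
    stop("shape dimension mismatch")
  for (m in list(a, b)) {
    if (max(abs(colMeans(m))) > 1e-6)
      stop("shapes must be centered before computing Procrustes distance")
    if (abs(sqrt(sum(m^2)) - 1) > 1e-6)
      stop("shapes must have unit centroid size")
  }
  r <- optimal_rotation(a, b, allow_reflection)
  sqrt(sum((a - b %*% r)^2))
}

#' Generalized Procrustes Analysis
#'
#' Iterative least-squares superimposition of a set of landmark
#' configurations: each configuration is centered, scaled to unit centroid
#' size (partial Procrustes), and rotated to the running consensus by the
#' orthogonal two-configuration solution; the consensus is then recomputed
#' and the cycle repeats until its root-mean-square change falls below `tol`.
#' The fit concludes with orthogonal projection of the aligned configurations
#' onto the tangent space at the consensus, which is the linear space in
#' which all downstream statistics (PCA, regression, signal tests) operate.
#'
#' Rotations are restricted to proper rotations (determinant +1); set
#' `allow_reflection = TRUE` only when mirroring is scientifically meaningful.
#'
#' @param data a [landmark_dataset()] with at least two configurations, or a
#'   k x 2 x n array.
#' @param tol convergence tolerance on the RMS consensus change.
#' @param max_iter maximum number of superimposition sweeps.
#' @param allow_reflection permit improper rotations.
#' @return An object of class `gpa_fit` with elements `consensus` (k x 2,
#'   unit centroid size), `aligned` (k x 2 x n), `tangent` (n x 2k matrix,
#'   rows vectorized as x1..xk,y1..yk), `centroid_size`, `log_cs` (natural
#'   log), `specimen_id`, `species_id`, `side`, `iterations`, `converged`.
#' @export
gpa <- function(data, tol = 1e-10, max_iter = 100, allow_reflection = FALSE) {
  if (inherits(data, "landmark_dataset")) {
    coords <- data$coords
    specimen_id <- data$specimen_id; species_id <- data$species_id
    side <- data$side
  } else {
    stopifnot(is.array(data), length(dim(data)) == 3L)
    coords <- data
    n0 <- dim(coords)[3]
    specimen_id <- sprintf("config_%03d", seq_len(n0))
    species_id <- specimen_id
    side <- rep("ventral", n0)
  }
  n <- dim(coords)[3]; k <- dim(coords)[1]
  if (n < 2L) stop("GPA needs at least 2 configurations")
  cs <- vapply(seq_len(n), function(i) centroid_size(coords[, , i]), numeric(1))
  pre <- coords
  for (i in seq_len(n)) pre[, , i] <- center_config(coords[, , i]) / cs[i]
  consensus <- pre[, , 1]
  delta <- Inf; it <- 0L
  while (delta > tol && it < max_iter) {
    it <- it + 1L
    for (i in seq_len(n))
      pre[, , i] <- pre[, , i] %*% optimal_rotation(consensus, pre[, , i],
                                                   allow_reflection)
    new_cons <- apply(pre, c(1, 2), mean)
    new_cons <- center_config(new_cons)
    new_cons <- new_cons / sqrt(sum(new_cons^2))
    delta <- sqrt(mean((new_cons - consensus)^2))
    consensus <- new_cons
  }
  if (delta > tol)
    stop("GPA did not converge in ", max_iter,
         " iterations (last consensus RMS change ", format(delta), ")")
  ## Canonical orientation: rotate the consensus onto its principal axes with
  ## a deterministic proper-rotation sign rule, so the fit (and hence the
  ## tangent coordinates) does not depend on the orientation in which the
  ## data were digitized.
  ev <- eigen(crossprod(consensus), symmetric = TRUE)
  rot_can <- ev$vectors
  if (det(rot_can) < 0) rot_can[, 2] <- -rot_can[, 2]
  cc <- consensus %*% rot_can
  if (cc[which.max(abs(cc))] < 0) rot_can <- -rot_can
  consensus <- consensus %*% rot_can
  for (i in seq_len(n))
    pre[, , i] <- pre[, , i] %*% optimal_rotation(consensus, pre[, , i],
                                                 allow_reflection)
  ## Orthogonal tangent projection at the consensus: remove the component of
  ## each vectorized shape along the (unit-norm) consensus vector.
  cvec <- as.vector(consensus)
  tang <- t(vapply(seq_len(n), function(i) {
    x <- as.vector(pre[, , i])
    x - cvec * sum(cvec * x)
  }, numeric(2L * k)))
  colnames(tang) <- c(paste0("x", seq_len(k)), paste0("y", seq_len(k)))
  rownames(tang) <- paste(specimen_id, side, sep = "/")
  structure(list(consensus = consensus, aligned = pre, tangent = tang,
                 centroid_size = cs, log_cs = log(cs),
                 specimen_id = specimen_id, species_id = species_id,
                 side = side, k = k, iterations = it, converged = TRUE,
                 allow_reflection = allow_reflection),
            class = "gpa_fit")
}

#' @export
print.gpa_fit <- function(x, ...) {
  cat("Generalized Procrustes fit:", dim(x$aligned)[3], "configurations,",
      x$k, "landmarks;", x$iterations, "iterations\n")
  cat("  centroid size: ", format(min(x$centroid_size), digits = 4), " - ",
      format(max(x$centroid_size), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Species mean shapes from a Procrustes fit
#'
#' Averages tangent-space rows within species; the companion size summary is
#' the species mean of log centroid size.
#'
#' @param fit a `gpa_fit`.
#' @param tangent optional replacement tangent matrix with the same rows as
#'   `fit$tangent` (e.g. size-corrected coordinates).
#' @return A list with `shape` (n_species x 2k matrix, rownames species) and
#'   `log_cs` (named vector).
#' @export
species_means <- function(fit, tangent = NULL) {
  stopifnot(inherits(fit, "gpa_fit"))
  x <- if (is.null(tangent)) fit$tangent else tangent
  stopifnot(nrow(x) == nrow(fit$tangent))
  g <- factor(fit$species_id, levels = unique(fit$species_id))
  shape <- rowsum(x, g) / as.vector(table(g))
  log_cs <- tapply(fit$log_cs, g, mean)
  list(shape = shape, log_cs = stats::setNames(as.numeric(log_cs), levels(g)))
}
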
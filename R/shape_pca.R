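#' Principal component analysis of Procrustes shape coordinates
#'
#' Eigen-decomposition of the sample covariance matrix (divisor n - 1) of the
#' tangent-space coordinates, either at specimen level or after averaging
#' within species (`level = "species_mean"`). Because superimposition removes
#' four degrees of freedom from 2-D data, at most 2k - 4 eigenvalues are
#' non-zero.
#'
#' Loadings follow a deterministic sign convention: the element of largest
#' magnitude in each loading vector is positive.
#'
#' @param x n x 2k tangent coordinate matrix, or a `gpa_fit`.
#' @param level `"specimen"` or `"species_mean"`.
#' @param species_id species labels, one per row (required for
#'   `"species_mean"` unless `x` is a `gpa_fit`).
#' @return An object of class `shape_pca` with `mean_vector`, `eigenvalues`,
#'   `proportions`, `scores`, `loadings` (columns are PCs), `level`, `n`.
#' @export
shape_pca <- function(x, level = c("specimen", "species_mean"),
                      species_id = NULL) {
  level <- match.arg(level)
  if (inherits(x, "gpa_fit")) {
    if (is.null(species_id)) species_id <- x$species_id
    x <- x$tangent
  }
  stopifnot(is.matrix(x))
  if (level == "species_mean") {
    if (is.null(species_id))
      stop("species_id is required for a species-mean PCA")
    g <- factor(species_id, levels = unique(species_id))
    cnt <- table(g)
    if (any(cnt == 0L))
      stop("species with zero specimens: ",
           paste(names(cnt)[cnt == 0L], collapse = ", "))
    x <- rowsum(x, g) / as.vector(cnt)
  }
  if (nrow(x) < 2L) stop("PCA needs at least 2 rows (after averaging)")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  load <- pc$rotation
  scores <- pc$x
  ## sign convention: largest-magnitude loading element positive
  for (j in seq_len(ncol(load))) {
    s <- sign(load[which.max(abs(load[, j])), j])
    if (s < 0) { load[, j] <- -load[, j]; scores[, j] <- -scores[, j] }
  }
  structure(list(mean_vector = pc$center, eigenvalues = ev,
                 proportions = ev / sum(ev), scores = scores,
                 loadings = load, level = level, n = nrow(x)),
            class = "shape_pca")
}

#' @export
print.shape_pca <- function(x, ...) {
  cat("Shape PCA (", x$level, " level, n = ", x$n, ")\n", sep = "")
  print(variance_report(x, top = min(5L, length(x$eigenvalues))))
  invisible(x)
}

#' Eigenvalue and variance table for a shape PCA
#'
#' @param result a `shape_pca`.
#' @param top number of leading axes to report.
#' @return A data frame with columns `axis`, `eigenvalue`, `percent`
#'   (per-axis % of total variance) and `cumulative_percent`.
#' @export
variance_report <- function(result, top = 2L) {
  stopifnot(inherits(result, "shape_pca"))
  if (top > length(result$eigenvalues))
    stop("top exceeds the number of components")
  pct <- 100 * result$proportions
  data.frame(axis = paste0("PC", seq_len(top)),
             eigenvalue = result$eigenvalues[seq_len(top)],
             percent = pct[seq_len(top)],
             cumulative_percent = cumsum(pct)[seq_len(top)])
}
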
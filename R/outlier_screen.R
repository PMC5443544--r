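#' Chi-squared screening of multivariate outliers
#'
#' Computes squared Mahalanobis distances in a full-rank subspace of the shape
#' variables and compares them with chi-squared quantiles: under multivariate
#' normality D-squared follows a chi-squared distribution with as many degrees
#' of freedom as the working dimension, so specimens whose distance exceeds
#' the quantile at `cutoff_prob` are flagged. Superimposed 2-D shape data are
#' rank-deficient (at most 2k - 4 dimensions), so the screen operates on PCA
#' scores retaining all eigenvalues above 1e-12 times the largest, or on a
#' caller-fixed dimension `m`.
#'
#' The screen only flags; exclusion is an explicit, separate pipeline step.
#'
#' @param x n x p matrix of shape variables (rows = specimens).
#' @param cutoff_prob probability for the chi-squared cutoff (default 0.975).
#' @param m working dimension; `NULL` selects the numerical rank.
#' @param ids optional specimen identifiers (default rownames or indices).
#' @return An object of class `outlier_report`: a list with `distances`
#'   (named D-squared), `reference_quantiles` (matched chi-squared quantiles
#'   for a QQ plot, in the order of increasing D-squared), `cutoff`,
#'   `flagged` (ids), `subspace_dim`.
#' @export
mahalanobis_screen <- function(x, cutoff_prob = 0.975, m = NULL, ids = NULL) {
  stopifnot(is.matrix(x), is.numeric(x))
  if (cutoff_prob <= 0 || cutoff_prob >= 1)
    stop("cutoff_prob must be in (0, 1)")
  n <- nrow(x)
  if (is.null(ids)) ids <- if (!is.null(rownames(x))) rownames(x)
                           else as.character(seq_len(n))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  rank <- if (ev[1] <= 0) 0L else sum(ev > 1e-12 * ev[1])
  if (is.null(m)) m <- rank
  if (m > rank)
    stop("requested subspace dimension ", m,
         " exceeds the usable rank ", rank, " of the covariance")
  if (m == 0L) {
    return(structure(list(distances = stats::setNames(rep(0, n), ids),
                          reference_quantiles = stats::qchisq(stats::ppoints(n), df = 1),
                          cutoff = Inf, flagged = character(0), subspace_dim = 0L,
                          cutoff_prob = cutoff_prob),
                     class = "outlier_report"))
  }
  if (n <= m + 1L)
    stop("need n > m + 1 specimens (n = ", n, ", m = ", m, ")")
  scores <- pc$x[, seq_len(m), drop = FALSE]
  d2 <- stats::mahalanobis(scores, colMeans(scores), stats::cov(scores))
  cutoff <- stats::qchisq(cutoff_prob, df = m)
  structure(list(distances = stats::setNames(d2, ids),
                 reference_quantiles = stats::qchisq(stats::ppoints(n), df = m),
                 cutoff = cutoff, flagged = ids[d2 > cutoff],
                 subspace_dim = as.integer(m), cutoff_prob = cutoff_prob),
            class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat("Mahalanobis/chi-squared outlier screen: m =", x$subspace_dim,
      ", cutoff prob =", x$cutoff_prob, "\n")
  cat("  flagged", length(x$flagged), "of", length(x$distances),
      "specimens\n")
  if (length(x$flagged)) cat("  ", paste(x$flagged, collapse = ", "), "\n")
  invisible(x)
}

#' Screen a Procrustes fit for outliers
#'
#' Applies [mahalanobis_screen()] to the tangent coordinates, by default
#' within each species and side separately (each species judged against its
#' own covariance), with a pooled option. Species with too few specimens for
#' the requested dimension are reported as skipped rather than failing the
#' whole screen.
#'
#' @param fit a `gpa_fit`.
#' @param cutoff_prob chi-squared cutoff probability.
#' @param per_species screen each species separately (default) or pooled.
#' @param m fixed working dimension, or `NULL` for the numerical rank.
#' @return A list with `reports` (one `outlier_report` per group), `flagged`
#'   (specimen/side keys across groups) and `skipped` (groups too small).
#' @export
screen_outliers <- function(fit, cutoff_prob = 0.975, per_species = TRUE,
                            m = NULL) {
  stopifnot(inherits(fit, "gpa_fit"))
  keys <- rownames(fit$tangent)
  groups <- if (per_species) split(seq_along(keys), fit$species_id)
            else list(pooled = seq_along(keys))
  reports <- list(); skipped <- character(0); flagged <- character(0)
  for (g in names(groups)) {
    ix <- groups[[g]]
    rep_g <- tryCatch(
      mahalanobis_screen(fit$tangent[ix, , drop = FALSE],
                         cutoff_prob = cutoff_prob, m = m, ids = keys[ix]),
      error = function(e) e)
    if (inherits(rep_g, "error")) {
      skipped <- c(skipped, g)
    } else {
      reports[[g]] <- rep_g
      flagged <- c(flagged, rep_g$flagged)
    }
  }
  list(reports = reports, flagged = flagged, skipped = skipped)
}
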
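#' Assemble a run configuration for the full pipeline
#'
#' Collects every input and tunable of the end-to-end analysis (ingest ->
#' outlier screen -> GPA -> PCA -> allometry -> size correction -> signal
#' tests) into one serializable list, so an archived configuration plus its
#' inputs reproduces a run exactly.
#'
#' @param landmarks a [landmark_dataset()] or a path to a TPS/CSV/XLSX file.
#' @param tree an [ape::phylo] or a Newick file path.
#' @param sides anchor sides to analyse (each side is an independent stream).
#' @param scale_policy `"apply"` or `"ignore"` recorded scale factors.
#' @param outlier_cutoff chi-squared cutoff probability; `NULL` disables the
#'   screen.
#' @param outlier_per_species screen within species (default) or pooled.
#' @param exclude_outliers drop flagged specimens before analysis (the screen
#'   itself only flags).
#' @param n_perm_allometry,n_perm_treelength,n_rand_kmult permutation counts
#'   (defaults 10000, 10000, 999 as in the reference analysis).
#' @param pcs number of leading PC score dimensions fed to the signal tests,
#'   or `"all"` for the full tangent space. The reference analysis mapped the
#'   first two PCs; the K statistic is conventionally computed in full shape
#'   space, so both are one setting apart.
#' @param size_correction also analyse size-corrected shape (default TRUE).
#' @param use_lengths honour branch lengths for the signal tests.
#' @param alias optional named vector mapping species ids to tip labels.
#' @param seed integer master seed.
#' @param out_dir optional directory; when set, CSV tables and a JSON index
#'   are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(landmarks, tree, sides = c("ventral", "dorsal"),
                       scale_policy = c("apply", "ignore"),
                       outlier_cutoff = 0.975, outlier_per_species = TRUE,
                       exclude_outliers = TRUE,
                       n_perm_allometry = 10000, n_perm_treelength = 10000,
                       n_rand_kmult = 999, pcs = "all",
                       size_correction = TRUE, use_lengths = TRUE,
                       alias = NULL, seed = 1L, out_dir = NULL) {
  structure(list(landmarks = landmarks, tree = tree, sides = sides,
                 scale_policy = match.arg(scale_policy),
                 outlier_cutoff = outlier_cutoff,
                 outlier_per_species = outlier_per_species,
                 exclude_outliers = exclude_outliers,
                 n_perm_allometry = n_perm_allometry,
                 n_perm_treelength = n_perm_treelength,
                 n_rand_kmult = n_rand_kmult, pcs = pcs,
                 size_correction = size_correction,
                 use_lengths = use_lengths, alias = alias,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "run_config")
}

signal_block <- function(values, tree, cfg, seed_offset) {
  list(tree_length = tree_length_permutation_test(
         values, tree, n_perm = cfg$n_perm_treelength,
         seed = cfg$seed + seed_offset, use_lengths = cfg$use_lengths),
       k_mult = k_mult(values, tree, n_rand = cfg$n_rand_kmult,
                       seed = cfg$seed + seed_offset + 1L))
}

signal_input <- function(mean_shape, cfg) {
  if (identical(cfg$pcs, "all")) return(mean_shape)
  pc <- shape_pca(mean_shape, level = "specimen")
  m <- min(as.integer(cfg$pcs), ncol(pc$scores))
  sc <- pc$scores[, seq_len(m), drop = FALSE]
  rownames(sc) <- rownames(mean_shape)
  sc
}

#' Run the full phylogenetic-morphometrics pipeline
#'
#' Executes, for each anchor side independently: ingest and validation,
#' optional chi-squared outlier screening (flag, then optionally exclude),
#' Generalized Procrustes Analysis, specimen- and species-mean-level PCA,
#' multivariate regression of shape on logCS with a permutation test,
#' size correction, PIC-based evolutionary allometry, squared-change
#' parsimony mapping with the tree-length permutation test, and the
#' multivariate K randomization test — for shape, size-corrected shape, and
#' logCS. Species present in the landmarks but absent from the tree are a
#' hard error (use `alias` to map labels); tips without landmarks on a side
#' are dropped from that side only.
#'
#' @param config a [run_config()] (or a list/path accepted by it).
#' @return An object of class `pipeline_report`: per-side results plus the
#'   archived configuration. When `config$out_dir` is set, also writes
#'   variance tables and score CSVs plus a machine-readable `index.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  data <- config$landmarks
  if (is.character(data)) {
    data <- if (grepl("\\.tps$", data, ignore.case = TRUE))
      read_tps(data, scale_policy = config$scale_policy)
    else if (grepl("\\.xlsx$", data, ignore.case = TRUE))
      read_landmark_table(data, format = "xlsx")
    else read_landmark_table(data, format = "csv")
  } else if (config$scale_policy == "apply") data <- apply_scale(data)
  tree <- config$tree
  if (is.character(tree)) tree <- read_phylogeny(tree) else validate_phylogeny(tree)
  if (!is.null(config$alias)) {
    data$species_id <- ifelse(data$species_id %in% names(config$alias),
                              unname(config$alias[data$species_id]),
                              data$species_id)
  }
  unmatched <- setdiff(unique(data$species_id), tree$tip.label)
  if (length(unmatched))
    stop("species present in the landmark data but absent from the tree: ",
         paste(unmatched, collapse = ", "))
  sides <- intersect(config$sides, unique(data$side))
  results <- list()
  for (side in sides) {
    stream <- subset_side(data, side)
    res <- list(side = side, n_input = length(stream))
    ## prune the tree to species observed on this side
    drop <- setdiff(tree$tip.label, unique(stream$species_id))
    side_tree <- if (length(drop)) ape::drop.tip(tree, drop) else tree
    res$dropped_tips <- drop
    fit0 <- gpa(stream)
    if (!is.null(config$outlier_cutoff)) {
      scr <- screen_outliers(fit0, cutoff_prob = config$outlier_cutoff,
                             per_species = config$outlier_per_species)
      res$outliers <- scr
      if (config$exclude_outliers && length(scr$flagged)) {
        keys <- paste(stream$specimen_id, stream$side, sep = "/")
        stream <- subset_dataset(stream, !(keys %in% scr$flagged))
      }
    }
    fit <- gpa(stream)
    res$gpa <- fit
    res$pca_specimen <- shape_pca(fit, level = "specimen")
    res$pca_species <- shape_pca(fit, level = "species_mean")
    sm <- species_means(fit)
    ## allometry at specimen level; skipped (with a note) if logCS constant
    if (stats::sd(fit$log_cs) > 1e-12) {
      allo <- regress_shape_on_size(fit$tangent, fit$log_cs,
                                    n_perm = config$n_perm_allometry,
                                    seed = config$seed)
      res$allometry <- allo
      corrected <- size_correct(allo)
      sm_corr <- species_means(fit, tangent = corrected)
      res$pca_species_corrected <- shape_pca(corrected, level = "species_mean",
                                             species_id = fit$species_id)
      ## evolutionary allometry on contrasts of species means
      if (nrow(sm$shape) >= 4) {
        shp_pic <- pic_contrasts(sm$shape, side_tree)
        siz_pic <- pic_contrasts(sm$log_cs, side_tree)
        res$evolutionary_allometry <- evolutionary_allometry_test(
          shp_pic, siz_pic, n_perm = config$n_perm_allometry,
          seed = config$seed + 7L)
      }
    } else {
      res$allometry <- NULL
      res$note <- c(res$note, "logCS constant: allometry stage skipped")
      corrected <- NULL; sm_corr <- NULL
    }
    ## signal tests on species means
    res$signal <- list(
      shape = signal_block(signal_input(sm$shape, config), side_tree,
                           config, 11L),
      size = signal_block(cbind(log_cs = sm$log_cs), side_tree, config, 17L))
    if (config$size_correction && !is.null(sm_corr))
      res$signal$shape_size_corrected <-
        signal_block(signal_input(sm_corr$shape, config), side_tree,
                     config, 23L)
    res$phylomorphospace <- phylomorphospace(
      res$pca_species$scores[, 1:2, drop = FALSE], side_tree,
      use_lengths = config$use_lengths)
    results[[side]] <- res
  }
  report <- structure(list(sides = results, config = config),
                      class = "pipeline_report")
  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.pipeline_report <- function(x, ...) {
  for (res in x$sides) {
    cat("==", res$side, "anchors ==\n")
    vr <- variance_report(res$pca_species, top = 2)
    cat(sprintf("  species-mean PCA: PC1 %.1f%%, PC2 %.1f%% (cumulative %.1f%%)\n",
                vr$percent[1], vr$percent[2], vr$cumulative_percent[2]))
    if (!is.null(res$allometry))
      cat(sprintf("  allometry: %.1f%% of shape variation, p = %.4g\n",
                  res$allometry$percent_predicted, res$allometry$p_value))
    for (nm in names(res$signal)) {
      s <- res$signal[[nm]]
      cat(sprintf("  %s: tree length %.4g (p = %.4g), K = %.3g (p = %.4g)\n",
                  nm, s$tree_length$observed, s$tree_length$p_value,
                  s$k_mult$observed, s$k_mult$p_value))
    }
  }
  invisible(x)
}

report_row <- function(side, analysis, vr) {
  cbind(data.frame(side = side, analysis = analysis), vr)
}

#' Write pipeline report files
#'
#' Emits, per side: an eigenvalue/variance table for the size-uncorrected
#' and size-corrected species-mean PCAs, PC scores, allometry and signal
#' test summaries, and a machine-readable `index.json` holding every number
#' at full precision.
#'
#' @param report a `pipeline_report`.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  var_tab <- list(); index <- list()
  for (res in report$sides) {
    top <- min(5L, length(res$pca_species$eigenvalues))
    var_tab[[length(var_tab) + 1L]] <-
      report_row(res$side, "size_uncorrected",
                 variance_report(res$pca_species, top))
    if (!is.null(res$pca_species_corrected))
      var_tab[[length(var_tab) + 1L]] <-
        report_row(res$side, "size_corrected",
                   variance_report(res$pca_species_corrected, top))
    utils::write.csv(res$pca_species$scores,
                     file.path(out_dir, paste0("scores_", res$side, ".csv")))
    idx <- list(
      n_configurations = res$n_input,
      outliers_flagged = if (!is.null(res$outliers)) res$outliers$flagged
                         else character(0),
      pca = list(
        pc1_percent = 100 * res$pca_species$proportions[1],
        pc2_percent = 100 * res$pca_species$proportions[2]),
      signal = lapply(res$signal, function(s) list(
        tree_length = s$tree_length$observed,
        tree_length_p = s$tree_length$p_value,
        k_mult = s$k_mult$observed,
        k_mult_p = s$k_mult$p_value)))
    if (!is.null(res$allometry))
      idx$allometry <- list(
        percent_predicted = res$allometry$percent_predicted,
        p_value = res$allometry$p_value)
    if (!is.null(res$evolutionary_allometry))
      idx$evolutionary_allometry <- list(
        percent_predicted = res$evolutionary_allometry$percent_predicted,
        p_value = res$evolutionary_allometry$p_value)
    index[[res$side]] <- idx
  }
  utils::write.csv(do.call(rbind, var_tab),
                   file.path(out_dir, "variance_table.csv"), row.names = FALSE)
  index$seed <- report$config$seed
  jsonlite::write_json(index, file.path(out_dir, "index.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
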
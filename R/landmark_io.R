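#' Construct a landmark dataset
#'
#' A `landmark_dataset` holds one 2-D landmark configuration per specimen and
#' anchor side, together with specimen/species labels. Landmark order encodes
#' the homology correspondence: the same index must denote the same anatomical
#' point in every configuration.
#'
#' @param coords k x 2 x n array of landmark coordinates (or a list of k x 2
#'   matrices, all with the same k).
#' @param specimen_id character vector of length n.
#' @param species_id character vector of length n.
#' @param side character vector of length n; each element `"ventral"` or
#'   `"dorsal"`.
#' @param scale_factor numeric vector of length n giving physical units per
#'   digitizer unit, or `NA` where no scale was recorded.
#'
#' @return An object of class `landmark_dataset`: a list with elements
#'   `coords` (k x 2 x n array), `specimen_id`, `species_id`, `side`,
#'   `scale_factor` and `k`.
#' @export
landmark_dataset <- function(coords, specimen_id, species_id, side,
                             scale_factor = NULL) {
  if (is.list(coords)) {
    k <- unique(vapply(coords, nrow, integer(1)))
    if (length(k) != 1L)
      stop("all configurations must share the same landmark count; found k = ",
           paste(k, collapse = ", "))
    coords <- array(unlist(coords), dim = c(k, 2L, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 2L)
  n <- dim(coords)[3]
  k <- dim(coords)[1]
  if (k < 3L)
    stop("shape is undefined for fewer than 3 landmarks (k = ", k, ")")
  if (!all(is.finite(coords)))
    stop("non-finite landmark coordinates")
  specimen_id <- as.character(specimen_id)
  species_id <- as.character(species_id)
  side <- match.arg(as.character(side), c("ventral", "dorsal"),
                    several.ok = TRUE)
  side <- rep_len(side, n)
  if (length(specimen_id) != n || length(species_id) != n)
    stop("specimen_id and species_id must each have one entry per configuration")
  key <- paste(specimen_id, side, sep = "/")
  if (anyDuplicated(key))
    stop("duplicate specimen/side combination: ",
         paste(unique(key[duplicated(key)]), collapse = ", "))
  if (is.null(scale_factor)) scale_factor <- rep(NA_real_, n)
  if (any(!is.na(scale_factor) & scale_factor <= 0))
    stop("scale_factor must be positive where present")
  dimnames(coords) <- list(NULL, c("x", "y"), key)
  structure(list(coords = coords, specimen_id = specimen_id,
                 species_id = species_id, side = side,
                 scale_factor = rep_len(as.numeric(scale_factor), n), k = k),
            class = "landmark_dataset")
}

#' @export
print.landmark_dataset <- function(x, ...) {
  cat("landmark_dataset:", dim(x$coords)[3], "configurations,",
      x$k, "landmarks,", length(unique(x$species_id)), "species\n")
  tab <- table(x$side)
  cat("  sides:", paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}

#' @export
length.landmark_dataset <- function(x) dim(x$coords)[3]

#' Subset a landmark dataset
#'
#' @param data a `landmark_dataset`.
#' @param i logical or integer index over configurations.
#' @return A `landmark_dataset` with the selected configurations.
#' @export
subset_dataset <- function(data, i) {
  stopifnot(inherits(data, "landmark_dataset"))
  landmark_dataset(data$coords[, , i, drop = FALSE],
                   data$specimen_id[i], data$species_id[i], data$side[i],
                   data$scale_factor[i])
}

#' Restrict a dataset to one anchor side
#'
#' @param data a `landmark_dataset`.
#' @param side `"ventral"` or `"dorsal"`.
#' @return A `landmark_dataset` containing only that side.
#' @export
subset_side <- function(data, side) {
  side <- match.arg(side, c("ventral", "dorsal"))
  keep <- data$side == side
  if (!any(keep)) stop("no configurations with side '", side, "'")
  subset_dataset(data, keep)
}

#' Read landmarks from a TPS file
#'
#' Parses the tpsDig dialect: records introduced by `LM=<k>` followed by k
#' whitespace-separated coordinate lines, with optional `ID=`, `IMAGE=` and
#' `SCALE=` keys. Unknown keys are ignored with a warning. Species identifiers
#' are taken from `species` (recycled) or, when `NULL`, from the part of the
#' specimen id before the first underscore.
#'
#' @param path file path.
#' @param scale_policy `"apply"` multiplies coordinates by the record's
#'   `SCALE=` factor (giving physical units); `"ignore"` leaves digitizer
#'   units.
#' @param side anchor side to assign to all records, or a vector.
#' @param species optional species ids, one per record.
#' @return A [landmark_dataset()].
#' @export
read_tps <- function(path, scale_policy = c("apply", "ignore"),
                     side = "ventral", species = NULL) {
  scale_policy <- match.arg(scale_policy)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lm_at <- grep("^LM=", lines)
  if (!length(lm_at)) stop("no LM= records found in ", path)
  configs <- list(); ids <- character(); scales <- numeric()
  bounds <- c(lm_at, length(lines) + 1L)
  for (r in seq_along(lm_at)) {
    block <- lines[lm_at[r]:(bounds[r + 1L] - 1L)]
    k <- suppressWarnings(as.integer(sub("^LM=", "", block[1L])))
    if (is.na(k)) stop("record ", r, ": unreadable LM= count")
    body <- block[-1L]
    is_key <- grepl("^[A-Za-z]+=", body)
    coord_lines <- body[!is_key & nzchar(body)]
    if (length(coord_lines) != k)
      stop("record ", r, ": LM=", k, " but ", length(coord_lines),
           " coordinate lines")
    xy <- lapply(seq_along(coord_lines), function(j) {
      v <- suppressWarnings(as.numeric(strsplit(coord_lines[j], "[[:space:]]+")[[1]]))
      if (length(v) != 2L || anyNA(v))
        stop("record ", r, ", coordinate line ", j,
             ": expected two numeric values, got '", coord_lines[j], "'")
      v
    })
    m <- do.call(rbind, xy)
    keys <- body[is_key]
    kv <- regmatches(keys, regexec("^([A-Za-z]+)=(.*)$", keys))
    key_names <- vapply(kv, `[`, character(1), 2L)
    key_vals <- vapply(kv, `[`, character(1), 3L)
    known <- key_names %in% c("ID", "IMAGE", "SCALE")
    if (any(!known))
      warning("record ", r, ": ignoring unknown TPS key(s): ",
              paste(unique(key_names[!known]), collapse = ", "))
    id <- if ("ID" %in% key_names) key_vals[match("ID", key_names)]
          else if ("IMAGE" %in% key_names)
            sub("\\.[A-Za-z]+$", "", key_vals[match("IMAGE", key_names)])
          else sprintf("record_%03d", r)
    sc <- if ("SCALE" %in% key_names)
      as.numeric(key_vals[match("SCALE", key_names)]) else NA_real_
    if (scale_policy == "apply" && !is.na(sc)) m <- m * sc
    configs[[r]] <- m; ids[r] <- trimws(id); scales[r] <- sc
  }
  if (is.null(species)) species <- sub("_.*$", "", ids)
  landmark_dataset(configs, ids, rep_len(species, length(ids)),
                   rep_len(side, length(ids)), scales)
}

#' Write landmarks to a TPS file
#'
#' Inverse of [read_tps()]; coordinates are written at full precision so a
#' round trip reproduces them to better than 1e-12.
#'
#' @param data a `landmark_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tps <- function(data, path) {
  stopifnot(inherits(data, "landmark_dataset"))
  n <- length(data)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(n)) {
    m <- data$coords[, , i]
    writeLines(c(paste0("LM=", data$k),
                 sprintf("%.15g %.15g", m[, 1], m[, 2]),
                 paste0("ID=", data$specimen_id[i]),
                 if (!is.na(data$scale_factor[i]))
                   paste0("SCALE=", sprintf("%.15g", data$scale_factor[i]))),
               con)
  }
  invisible(path)
}

#' Read landmarks from a tabular file (CSV or XLSX)
#'
#' Supports wide layout (columns `x1, y1, ..., xk, yk`) and long layout
#' (columns `landmark`, `x`, `y`, one row per landmark), auto-detected unless
#' fixed in `column_map`.
#'
#' @param path file path.
#' @param format `"csv"` or `"xlsx"` (XLSX requires the readxl package).
#' @param column_map named list mapping roles to column names:
#'   `specimen`, `species`, `side` and optionally `layout`
#'   (`"auto"`, `"wide"` or `"long"`), `scale`.
#' @return A [landmark_dataset()].
#' @export
read_landmark_table <- function(path, format = c("csv", "xlsx"),
                                column_map = list()) {
  format <- match.arg(format)
  cm <- utils::modifyList(list(specimen = "specimen", species = "species",
                               side = "side", scale = NULL, layout = "auto"),
                          column_map)
  df <- switch(format,
    csv = utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the 'readxl' package")
      as.data.frame(readxl::read_excel(path), check.names = FALSE)
    })
  for (role in c("specimen", "species", "side")) {
    if (!cm[[role]] %in% names(df))
      stop("column '", cm[[role]], "' (", role, ") not found in ", path)
  }
  layout <- cm$layout
  if (layout == "auto")
    layout <- if (all(c("landmark", "x", "y") %in% names(df))) "long" else "wide"
  if (layout == "long") {
    key <- paste(df[[cm$specimen]], df[[cm$side]], sep = "/")
    split_idx <- split(seq_len(nrow(df)), factor(key, levels = unique(key)))
    configs <- lapply(split_idx, function(ix) {
      sub <- df[ix, , drop = FALSE]
      sub <- sub[order(sub$landmark), , drop = FALSE]
      cbind(sub$x, sub$y)
    })
    first <- vapply(split_idx, `[`, integer(1), 1L)
    landmark_dataset(configs, df[[cm$specimen]][first], df[[cm$species]][first],
                     df[[cm$side]][first],
                     if (!is.null(cm$scale)) df[[cm$scale]][first])
  } else {
    xcols <- grep("^x[0-9]+$", names(df), value = TRUE)
    k <- length(xcols)
    if (k == 0L) stop("wide layout expects columns x1, y1, ..., xk, yk")
    need <- c(paste0("x", 1:k), paste0("y", 1:k))
    if (!all(need %in% names(df)))
      stop("wide layout: missing coordinate column(s): ",
           paste(setdiff(need, names(df)), collapse = ", "))
    configs <- lapply(seq_len(nrow(df)), function(i)
      cbind(as.numeric(df[i, paste0("x", 1:k)]),
            as.numeric(df[i, paste0("y", 1:k)])))
    landmark_dataset(configs, df[[cm$specimen]], df[[cm$species]], df[[cm$side]],
                     if (!is.null(cm$scale)) df[[cm$scale]])
  }
}

#' Write a landmark dataset as a wide-format CSV
#'
#' @param data a `landmark_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_landmark_csv <- function(data, path) {
  stopifnot(inherits(data, "landmark_dataset"))
  k <- data$k
  wide <- do.call(rbind, lapply(seq_len(length(data)), function(i) {
    m <- data$coords[, , i]
    setNames(as.data.frame(t(as.vector(t(m)))),
             as.vector(t(outer(1:k, c("x", "y"), function(j, a) paste0(a, j)))))
  }))
  out <- cbind(data.frame(specimen = data$specimen_id,
                          species = data$species_id, side = data$side,
                          stringsAsFactors = FALSE), wide)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read a rooted phylogeny from a Newick file
#'
#' Thin wrapper around [ape::read.tree()] that validates the properties the
#' downstream comparative methods require: a rooted topology and unique tip
#' labels. Absent branch lengths are left absent (downstream methods then use
#' unit lengths), never silently set to zero.
#'
#' @param path Newick file path.
#' @return An [ape::phylo] object.
#' @export
read_phylogeny <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick in ", path)
  validate_phylogeny(tree)
}

#' Validate a phylogeny for comparative analysis
#'
#' @param tree an [ape::phylo] object.
#' @return The tree, invisibly unchanged, or an error.
#' @export
validate_phylogeny <- function(tree) {
  if (!inherits(tree, "phylo")) stop("tree must be an ape 'phylo' object")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  ## ape represents every phylo with a root node; a basal polytomy (including
  ## star trees) is a legitimate rooted topology here, so no is.rooted() test.
  if (tree$Nnode < 1L) stop("tree has no internal node")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0))
    stop("negative branch lengths")
  tree
}

#' Match dataset species to tree tips
#'
#' Exact string match after whitespace trimming, with an optional alias table
#' for abbreviated labels. Species in the dataset that have no tip produce
#' entries in the returned report (they are never dropped silently).
#'
#' @param data a `landmark_dataset`.
#' @param tree an [ape::phylo] object.
#' @param alias optional named character vector mapping dataset species ids to
#'   tip labels.
#' @return A list with `matched` (named character vector species -> tip),
#'   `unmatched_species` and `unused_tips`.
#' @export
match_species_tree <- function(data, tree, alias = NULL) {
  sp <- trimws(unique(data$species_id))
  tips <- trimws(tree$tip.label)
  mapped <- ifelse(sp %in% names(alias), unname(alias[sp]), sp)
  ok <- mapped %in% tips
  if (any(!ok))
    warning("species without a matching tree tip: ",
            paste(sp[!ok], collapse = ", "))
  list(matched = stats::setNames(mapped[ok], sp[ok]),
       unmatched_species = sp[!ok],
       unused_tips = setdiff(tips, mapped))
}

#' Apply recorded scale factors to a dataset
#'
#' Multiplies each configuration by its `scale_factor` (physical units per
#' digitizer unit), giving coordinates and hence centroid sizes in physical
#' units. Configurations without a recorded factor are left unchanged.
#'
#' @param data a `landmark_dataset`.
#' @return A `landmark_dataset` with scale factors applied and reset to 1.
#' @export
apply_scale <- function(data) {
  stopifnot(inherits(data, "landmark_dataset"))
  out <- data
  for (i in seq_len(length(data))) {
    if (!is.na(data$scale_factor[i]))
      out$coords[, , i] <- data$coords[, , i] * data$scale_factor[i]
  }
  out$scale_factor <- ifelse(is.na(data$scale_factor), NA_real_, 1)
  out
}
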
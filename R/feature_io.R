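FEATURE_TABLE_COLS <- c("sample_id", "extract_id", "mz", "rt", "intensity")
SOLVENT_CODES <- c("TA", "APW", "MTBE")

#' Read a long-format LC-MS feature table
#'
#' Canonical input format: tidy CSV with one row per observed feature in one
#' sample extract, columns `sample_id`, `extract_id` (solvent system code),
#' `mz` (Da), `rt` (minutes), `intensity` (arbitrary units, >= 0). Row order
#' is preserved.
#'
#' @param path Input CSV path.
#' @param metadata Optional sample metadata data frame; when supplied, every
#'   `sample_id` must be present in it.
#' @return A data frame of feature observations.
#' @export
read_feature_table <- function(path, metadata = NULL) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(FEATURE_TABLE_COLS, names(tab))
  if (length(missing)) {
    format_error(paste0("feature table is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  tab <- tab[FEATURE_TABLE_COLS]
  validate_observations(tab, metadata)
}

#' Validate a data frame of feature observations
#'
#' @param obs Data frame with the five canonical feature-table columns
#'   (extra columns are preserved).
#' @param metadata Optional sample metadata; when supplied, observed sample
#'   ids must exist in it.
#' @return `obs`, with numeric columns coerced, invisibly checked.
#' @export
validate_observations <- function(obs, metadata = NULL) {
  missing <- setdiff(FEATURE_TABLE_COLS, names(obs))
  if (length(missing)) {
    format_error(paste0("feature observations missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  for (col in c("mz", "rt", "intensity")) {
    v <- obs[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(v2 <- as.numeric(v))
      bad <- which(is.na(v2) & !is.na(v))
      if (length(bad)) {
        format_error(sprintf("malformed numeric value '%s' in column %s, row %d",
                             v[bad[1]], col, bad[1]))
      }
      v <- v2
    }
    if (anyNA(v)) {
      format_error(sprintf("missing value in column %s, row %d", col,
                           which(is.na(v))[1]))
    }
    obs[[col]] <- v
  }
  if (any(obs$mz <= 0)) {
    validation_error(sprintf("non-positive m/z in row %d", which(obs$mz <= 0)[1]))
  }
  if (any(obs$rt < 0)) {
    validation_error(sprintf("negative retention time in row %d", which(obs$rt < 0)[1]))
  }
  if (any(obs$intensity < 0)) {
    validation_error(sprintf("negative intensity in row %d", which(obs$intensity < 0)[1]))
  }
  if (!is.null(metadata)) {
    unknown <- setdiff(unique(obs$sample_id), metadata$sample_id)
    if (length(unknown)) {
      validation_error(paste0("sample id(s) absent from metadata: ",
                              paste(unknown, collapse = ", ")))
    }
  }
  obs
}

#' Write a feature table as tidy CSV
#'
#' @param obs Data frame of feature observations.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(obs, path) {
  utils::write.csv(obs[FEATURE_TABLE_COLS], path, row.names = FALSE,
                   quote = FALSE, eol = "\n", fileEncoding = "UTF-8")
  invisible(path)
}

#' Read and validate a sample metadata table
#'
#' Required columns: `sample_id`, `category` (reference / vessel / blank).
#' Category-specific requirements: references carry a `species_code`,
#' vessels carry `project`, `treatment` and `form_class`, blanks carry a
#' `solvent`. Optional columns absent from the file are filled with `NA`.
#'
#' @param path Input CSV path.
#' @return A validated metadata data frame.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_metadata(tab)
}

METADATA_OPTIONAL <- c("species_code", "curing_state", "project", "treatment",
                       "form_class", "aperture_cm", "solvent", "site")

#' Validate a sample metadata data frame
#'
#' @param tab Metadata data frame.
#' @return The metadata with all optional columns present.
#' @export
validate_metadata <- function(tab) {
  if (!all(c("sample_id", "category") %in% names(tab))) {
    format_error("metadata needs columns sample_id and category")
  }
  if (anyDuplicated(tab$sample_id)) format_error("duplicate sample_id in metadata")
  for (col in METADATA_OPTIONAL) {
    if (!col %in% names(tab)) tab[[col]] <- NA
  }
  tab[tab == ""] <- NA
  bad_cat <- setdiff(unique(tab$category), c("reference", "vessel", "blank"))
  if (length(bad_cat)) {
    validation_error(paste0("unknown category: ", paste(bad_cat, collapse = ", ")))
  }
  need <- function(rows, col, what) {
    miss <- rows & is.na(tab[[col]])
    if (any(miss)) {
      validation_error(sprintf("%s sample(s) missing %s: %s", what, col,
                               paste(tab$sample_id[miss], collapse = ", ")))
    }
  }
  need(tab$category == "reference", "species_code", "reference")
  need(tab$category == "vessel", "project", "vessel")
  need(tab$category == "vessel", "treatment", "vessel")
  need(tab$category == "vessel", "form_class", "vessel")
  need(tab$category == "blank", "solvent", "blank")
  ap <- tab$aperture_cm
  if (any(!is.na(ap) & as.numeric(ap) <= 0)) {
    validation_error("aperture_cm must be positive when present")
  }
  tab$aperture_cm <- as.numeric(tab$aperture_cm)
  tab
}

#' Write a sample metadata table
#' @param metadata Metadata data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, eol = "\n",
                   fileEncoding = "UTF-8", na = "")
  invisible(path)
}

#' Tabulate samples by category, project, treatment and form class
#'
#' Counts are invariant under row order of the input.
#'
#' @param samples Metadata data frame (see [validate_metadata()]).
#' @return A data frame with columns `category`, `project`, `treatment`,
#'   `form_class`, `n`, sorted by the grouping columns.
#' @export
summarize_metadata <- function(samples) {
  cols <- c("category", "project", "treatment", "form_class")
  if (is.null(samples) || nrow(samples) == 0L) {
    out <- stats::setNames(
      data.frame(character(0), character(0), character(0), character(0),
                 integer(0), stringsAsFactors = FALSE),
      c(cols, "n"))
    return(out)
  }
  for (col in cols) if (!col %in% names(samples)) samples[[col]] <- NA
  key <- lapply(samples[cols], function(v) ifelse(is.na(v), "", as.character(v)))
  agg <- stats::aggregate(list(n = rep(1L, nrow(samples))), by = key, FUN = sum)
  agg <- agg[do.call(order, agg[cols]), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Serialize a Ward dendrogram as Newick
#'
#' Branch lengths are height differences: each child edge has length equal
#' to the parent's merge height minus the child's own height (0 for leaves),
#' so the Newick tree is ultrametric with leaf depth equal to the root merge
#' height.
#'
#' @param tree A `ward_tree` (see [ward_cluster()]).
#' @param path Optional output file; omit to return the string only.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when `path` is given.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "ward_tree"))
  merge <- tree$merge
  if (ncol(merge) != 2L) rd_stop("non-binary merge tree", "residomics_serialization_error")
  heights <- tree$height
  labels <- tree$labels
  fmt <- function(x) sprintf("%.*g", digits, x)
  node_str <- function(i) {
    # i: merge row index; returns subtree string (no trailing length)
    kids <- merge[i, ]
    parts <- vapply(kids, function(k) {
      if (k < 0) {
        paste0(labels[-k], ":", fmt(heights[i]))
      } else {
        paste0(node_str(k), ":", fmt(heights[i] - heights[k]))
      }
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  nwk <- paste0(node_str(nrow(merge)), ";")
  if (!is.null(path)) {
    writeLines(nwk, path, sep = "\n")
    return(invisible(nwk))
  }
  nwk
}
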
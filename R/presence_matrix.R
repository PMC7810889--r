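#' Construct a binary presence matrix
#'
#' The presence matrix is the substrate of all downstream statistics:
#' features in rows, samples in columns, cells 1 where a feature was
#' detected in any extract of a sample.
#'
#' @param cells Binary matrix (features x samples) with unique row and
#'   column names.
#' @param annotations Optional data frame with columns `feature_id`, `mz`,
#'   `rt`; missing features receive `NA` annotations.
#' @param blank_subtracted Logical flag recording whether the matrix was
#'   produced downstream of blank subtraction; `NA` for matrices of unknown
#'   provenance (e.g. read from disk), where presence is taken as given.
#' @return An object of class `presence_matrix`.
#' @export
presence_matrix <- function(cells, annotations = NULL, blank_subtracted = NA) {
  cells <- as.matrix(cells)
  if (is.null(rownames(cells)) || is.null(colnames(cells))) {
    validation_error("presence matrix needs feature (row) and sample (column) names")
  }
  if (anyDuplicated(rownames(cells))) format_error("duplicate feature id in presence matrix")
  if (anyDuplicated(colnames(cells))) format_error("duplicate sample id in presence matrix")
  storage.mode(cells) <- "integer"
  if (any(is.na(cells)) || !all(cells %in% c(0L, 1L))) {
    validation_error("presence matrix cells must be 0 or 1")
  }
  ann <- data.frame(feature_id = rownames(cells), mz = NA_real_, rt = NA_real_,
                    stringsAsFactors = FALSE)
  if (!is.null(annotations)) {
    stopifnot(all(c("feature_id", "mz", "rt") %in% names(annotations)))
    i <- match(ann$feature_id, annotations$feature_id)
    ann$mz <- annotations$mz[i]
    ann$rt <- annotations$rt[i]
  }
  structure(
    list(cells = cells, annotations = ann),
    blank_subtracted = blank_subtracted,
    class = "presence_matrix"
  )
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat(sprintf("presence_matrix: %d features x %d samples (%d presences)\n",
              nrow(x$cells), ncol(x$cells), sum(x$cells)))
  invisible(x)
}

#' @export
dim.presence_matrix <- function(x) dim(x$cells)

#' Sample identifiers of a presence matrix
#' @param x A `presence_matrix`.
#' @return Character vector of sample ids (columns).
#' @export
sample_ids <- function(x) colnames(x$cells)

#' Feature identifiers of a presence matrix
#' @param x A `presence_matrix`.
#' @return Character vector of feature ids (rows).
#' @export
feature_ids <- function(x) rownames(x$cells)

#' Restrict a presence matrix to a subset of samples
#'
#' Columns are restricted to `keep` (in the given order) and features absent
#' from every retained sample are dropped, so downstream statistics see no
#' all-zero rows. Dropping all-zero rows cannot change Jaccard distances
#' among the retained samples.
#'
#' @param x A `presence_matrix`.
#' @param keep Character vector of sample ids to retain.
#' @return A `presence_matrix` restricted to `keep`.
#' @export
subset_presence <- function(x, keep) {
  stopifnot(inherits(x, "presence_matrix"))
  unknown <- setdiff(keep, colnames(x$cells))
  if (length(unknown)) {
    validation_error(paste0("unknown sample id(s): ", paste(unknown, collapse = ", ")))
  }
  cells <- x$cells[, keep, drop = FALSE]
  cells <- cells[rowSums(cells) > 0, , drop = FALSE]
  presence_matrix(cells, x$annotations,
                  blank_subtracted = attr(x, "blank_subtracted"))
}

#' Write a presence matrix as CSV
#'
#' Layout mirrors the published occurrence table: one row per sample, first
#' column the sample id, remaining columns one per feature, cells 0/1.
#' UTF-8, comma separated, LF line endings.
#'
#' @param x A `presence_matrix`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_presence_matrix <- function(x, path) {
  stopifnot(inherits(x, "presence_matrix"))
  tab <- data.frame(sample_id = colnames(x$cells),
                    t(x$cells), check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a presence matrix from CSV
#'
#' Expects one row per sample: first column the sample id, remaining columns
#' one per feature. Cells may be `1`/`0`, `X`/`x` (a presence mark, as
#' typeset in published occurrence tables), or blank (absence).
#'
#' @param path Input CSV path.
#' @param annotations Optional feature annotation data frame (columns
#'   `feature_id`, `mz`, `rt`), e.g. read from a companion file.
#' @return A `presence_matrix` (blank-subtraction provenance unknown:
#'   presence is taken as given).
#' @export
read_presence_matrix <- function(path, annotations = NULL) {
  if (!file.exists(path)) format_error(paste0("file not found: ", path))
  tab <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                         stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) format_error("presence matrix needs a sample column and at least one feature column")
  fids <- names(tab)[-1]
  if (anyDuplicated(fids)) {
    format_error(paste0("duplicate feature id in header: ",
                        paste(unique(fids[duplicated(fids)]), collapse = ", ")))
  }
  sids <- tab[[1]]
  if (anyDuplicated(sids)) format_error("duplicate sample id in first column")
  cells <- vapply(tab[-1], function(col) {
    col <- trimws(col)
    bad <- !(col %in% c("", "0", "1", "X", "x"))
    if (any(bad)) {
      format_error(sprintf("invalid presence mark '%s' (allowed: 0, 1, X, blank)",
                           col[bad][1]))
    }
    as.integer(col %in% c("1", "X", "x"))
  }, integer(nrow(tab)))
  cells <- matrix(cells, nrow = nrow(tab),
                  dimnames = list(sids, fids))
  presence_matrix(t(cells), annotations = annotations, blank_subtracted = NA)
}
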
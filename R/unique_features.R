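#' Find features unique to individual reference samples
#'
#' A feature is unique to reference r iff it is present in r and absent
#' from every other reference sample. Uniqueness is evaluated at the
#' reference-sample level (NT10 is distinct from NTFD and NT30), because
#' curing-induced compounds are markers in their own right; vessels and
#' blanks do not affect uniqueness. A species-level view (present in one
#' species' samples only, regardless of curing state) is available via
#' `level = "species"`.
#'
#' Uniqueness on a matrix that skipped blank subtraction is refused unless
#' explicitly overridden: contaminants shared between a reference and a
#' vessel would masquerade as shared unique compounds. Matrices of unknown
#' provenance (read from disk) are taken as given.
#'
#' @param matrix A `presence_matrix` containing all reference samples.
#' @param samples Sample metadata.
#' @param level `"sample"` (default) or `"species"`.
#' @param allow_unsubtracted Permit a matrix explicitly flagged as not
#'   blank-subtracted.
#' @return An object of class `uniqueness_report`: `unique_features` (named
#'   list reference -> feature ids) and `counts` (named integer vector).
#' @export
find_unique_features <- function(matrix, samples, level = c("sample", "species"),
                                 allow_unsubtracted = FALSE) {
  level <- match.arg(level)
  stopifnot(inherits(matrix, "presence_matrix"))
  if (isFALSE(attr(matrix, "blank_subtracted")) && !allow_unsubtracted) {
    validation_error(paste0(
      "presence matrix was not blank-subtracted; contaminants would ",
      "masquerade as unique compounds (use allow_unsubtracted = TRUE to override)"))
  }
  samples <- validate_metadata(samples)
  refs <- samples[samples$category == "reference", , drop = FALSE]
  refs <- refs[refs$sample_id %in% colnames(matrix$cells), , drop = FALSE]
  if (nrow(refs) == 0L) {
    validation_error("no reference samples present in the matrix")
  }
  cells <- matrix$cells[, refs$sample_id, drop = FALSE]
  if (level == "sample") {
    groups <- stats::setNames(as.list(refs$sample_id), refs$sample_id)
  } else {
    groups <- split(refs$sample_id, refs$species_code)
  }
  grp_pres <- vapply(groups, function(ids)
    as.integer(rowSums(cells[, ids, drop = FALSE]) > 0), integer(nrow(cells)))
  grp_pres <- matrix(grp_pres, nrow = nrow(cells),
                     dimnames = list(rownames(cells), names(groups)))
  n_groups_present <- rowSums(grp_pres)
  uf <- lapply(stats::setNames(names(groups), names(groups)), function(g) {
    rownames(grp_pres)[grp_pres[, g] == 1L & n_groups_present == 1L]
  })
  structure(
    list(unique_features = uf,
         counts = vapply(uf, length, integer(1)),
         level = level),
    class = "uniqueness_report"
  )
}

#' @export
print.uniqueness_report <- function(x, ...) {
  cat(sprintf("uniqueness_report (%s level): %d unique features across %d references\n",
              x$level, sum(x$counts), length(x$counts)))
  for (r in names(x$counts)) cat(sprintf("  %-6s %d\n", r, x$counts[[r]]))
  invisible(x)
}

#' Tabulate reference-unique features across archaeological vessels
#'
#' The computation behind the published occurrence table: one row per
#' vessel, one column per reference-unique feature detected in at least one
#' vessel (zero-ubiquity columns are dropped), with each feature's ubiquity
#' (number of vessels carrying it) and per-vessel tallies of shared features
#' per reference.
#'
#' @param matrix The `presence_matrix` the report was derived from (or an
#'   externally supplied occurrence matrix, taken as given).
#' @param report A `uniqueness_report` for the same matrix.
#' @param samples Sample metadata identifying vessels.
#' @return An object of class `sharing_table`: `cells` (vessels x features),
#'   `feature_info` (feature_id, reference, mz, rt), `ubiquity`,
#'   `per_vessel_shared` (vessels x references matrix).
#' @export
build_sharing_table <- function(matrix, report, samples) {
  stopifnot(inherits(matrix, "presence_matrix"),
            inherits(report, "uniqueness_report"))
  samples <- validate_metadata(samples)
  vessels <- samples$sample_id[samples$category == "vessel"]
  vessels <- vessels[vessels %in% colnames(matrix$cells)]
  if (length(vessels) == 0L) validation_error("no vessel samples present in the matrix")

  feat <- data.frame(
    feature_id = unlist(report$unique_features, use.names = FALSE),
    reference = rep(names(report$unique_features),
                    lengths(report$unique_features)),
    stringsAsFactors = FALSE
  )
  feat <- feat[feat$feature_id %in% rownames(matrix$cells), , drop = FALSE]
  cells <- t(matrix$cells[feat$feature_id, vessels, drop = FALSE])
  ubiq <- colSums(cells)
  keep <- ubiq >= 1L
  feat <- feat[keep, , drop = FALSE]
  cells <- cells[, keep, drop = FALSE]
  ubiq <- ubiq[keep]

  ann <- matrix$annotations
  i <- match(feat$feature_id, ann$feature_id)
  feat$mz <- ann$mz[i]
  feat$rt <- ann$rt[i]
  rownames(feat) <- NULL

  refs <- unique(names(report$unique_features))
  pvs <- vapply(refs, function(r) {
    cols <- feat$reference == r
    if (!any(cols)) return(integer(length(vessels)))
    as.integer(rowSums(cells[, cols, drop = FALSE]))
  }, integer(length(vessels)))
  pvs <- matrix(pvs, nrow = length(vessels),
                dimnames = list(vessels, refs))

  structure(
    list(cells = cells, feature_info = feat,
         ubiquity = stats::setNames(as.integer(ubiq), feat$feature_id),
         per_vessel_shared = pvs),
    class = "sharing_table"
  )
}

#' @export
print.sharing_table <- function(x, ...) {
  cat(sprintf("sharing_table: %d vessels x %d reference-unique features\n",
              nrow(x$cells), ncol(x$cells)))
  invisible(x)
}

#' Write a sharing table as CSV
#'
#' Column headers carry the feature id, attributed reference, m/z and RT
#' (`<feature>|<reference>|<mz>|<rt>`); a final header row block is avoided
#' so the file round-trips through ordinary CSV readers.
#'
#' @param table A `sharing_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sharing_table <- function(table, path) {
  stopifnot(inherits(table, "sharing_table"))
  hdr <- with(table$feature_info,
              paste(feature_id, reference,
                    ifelse(is.na(mz), "", mz), ifelse(is.na(rt), "", rt),
                    sep = "|"))
  tab <- data.frame(vessel = rownames(table$cells), table$cells,
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(tab) <- c("vessel", hdr)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, eol = "\n",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Rank vessels by their share of reference-unique compounds
#'
#' For each (vessel, reference) pair: `shared` is the number of that
#' reference's unique features the vessel carries, `total_unique` the
#' reference's full unique-feature count, and `fraction = shared /
#' total_unique`. Pairs are ordered by descending fraction, ties broken by
#' vessel id then reference.
#'
#' When `totals` is supplied (a named vector of full unique-feature counts,
#' e.g. library sizes known from a complete reference screen), the ranking
#' is restricted to the references it names: fractions are only comparable
#' across references whose full unique counts are known. References with a
#' zero total are omitted.
#'
#' @param table A `sharing_table`.
#' @param report The `uniqueness_report` the table was built from.
#' @param totals Optional named numeric vector overriding the report's
#'   per-reference unique counts.
#' @return A data frame with columns `vessel_id`, `reference`, `shared`,
#'   `total_unique`, `fraction`.
#' @export
rank_vessels_by_shared <- function(table, report, totals = NULL) {
  stopifnot(inherits(table, "sharing_table"),
            inherits(report, "uniqueness_report"))
  if (is.null(totals)) {
    totals <- report$counts
  } else {
    if (is.null(names(totals)) || any(!nzchar(names(totals)))) {
      validation_error("totals must be a named vector of unique-feature counts")
    }
  }
  totals <- totals[totals > 0]
  refs <- intersect(colnames(table$per_vessel_shared), names(totals))
  vessels <- rownames(table$per_vessel_shared)
  out <- expand.grid(vessel_id = vessels, reference = refs,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$shared <- table$per_vessel_shared[cbind(out$vessel_id, out$reference)]
  out$total_unique <- as.numeric(totals[out$reference])
  out$fraction <- out$shared / out$total_unique
  out <- out[order(-out$fraction, out$vessel_id, out$reference), , drop = FALSE]
  rownames(out) <- NULL
  out
}
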
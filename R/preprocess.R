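#' Matching tolerances for feature alignment
#'
#' @param mz_ppm Relative m/z tolerance in parts per million.
#' @param mz_abs_min Absolute m/z tolerance floor in Da, applied at low mass
#'   where the ppm window collapses.
#' @param rt_min Retention-time tolerance in minutes.
#' @return An object of class `tolerance_spec`.
#' @export
tolerance_spec <- function(mz_ppm = 10, mz_abs_min = 0.003, rt_min = 0.1) {
  vals <- c(mz_ppm = mz_ppm, mz_abs_min = mz_abs_min, rt_min = rt_min)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    validation_error("all tolerances must be strictly positive")
  }
  structure(as.list(vals), class = "tolerance_spec")
}

mz_tolerance_at <- function(mz, tol) pmax(tol$mz_ppm * mz / 1e6, tol$mz_abs_min)

#' Align feature observations across samples and extracts
#'
#' Deterministic single-linkage grouping along the m/z axis: observations
#' are sorted by (m/z, RT, sample, extract) and swept in order; a new
#' consensus feature opens when the next observation's m/z gap to the
#' group's last accepted observation exceeds
#' `max(mz_ppm * center / 1e6, mz_abs_min)` (evaluated at the group's
#' running mean m/z) or when its RT gap to the group's running mean RT
#' exceeds `rt_min`. On the m/z axis this is exactly single-linkage
#' clustering at the matching tolerance. When one (sample, extract)
#' contributes two observations to a group, the higher-intensity one is
#' kept. Reported consensus m/z and RT are intensity-weighted means of the
#' retained members.
#'
#' @param observations Data frame of feature observations (see
#'   [read_feature_table()]).
#' @param tol A [tolerance_spec()].
#' @return An object of class `aligned_features`: `$features` (feature_id,
#'   consensus mz/rt, n_members) and `$members` (feature_id, sample_id,
#'   extract_id, mz, rt, intensity).
#' @export
align_features <- function(observations, tol = tolerance_spec()) {
  stopifnot(inherits(tol, "tolerance_spec"))
  if (is.null(observations) || nrow(observations) == 0L) {
    return(empty_aligned())
  }
  obs <- validate_observations(observations)
  ord <- order(obs$mz, obs$rt, obs$sample_id, obs$extract_id)
  mz <- obs$mz[ord]; rt <- obs$rt[ord]; w <- obs$intensity[ord]
  n <- length(mz)

  group <- integer(n)
  g <- 0L
  s_mz <- s_rt <- 0; cnt <- 0L
  last_mz <- mean_mz <- mean_rt <- 0
  for (i in seq_len(n)) {
    new_group <- g == 0L ||
      mz[i] - last_mz > mz_tolerance_at(mean_mz, tol) ||
      abs(rt[i] - mean_rt) > tol$rt_min
    if (new_group) {
      g <- g + 1L
      s_mz <- s_rt <- 0; cnt <- 0L
    }
    group[i] <- g
    s_mz <- s_mz + mz[i]; s_rt <- s_rt + rt[i]; cnt <- cnt + 1L
    last_mz <- mz[i]
    mean_mz <- s_mz / cnt; mean_rt <- s_rt / cnt
  }

  members <- data.frame(
    group = group,
    sample_id = obs$sample_id[ord], extract_id = obs$extract_id[ord],
    mz = mz, rt = rt, intensity = w,
    stringsAsFactors = FALSE
  )
  # duplicate (sample, extract) within a group: keep the higher intensity
  key <- paste(members$group, members$sample_id, members$extract_id, sep = "\r")
  keep_ord <- order(key, -members$intensity)
  members <- members[keep_ord, , drop = FALSE]
  members <- members[!duplicated(key[keep_ord]), , drop = FALSE]
  members <- members[order(members$group, members$sample_id, members$extract_id), ,
                     drop = FALSE]

  # consensus recomputed over retained members
  wsum <- tapply_num(members$intensity, members$group)
  wmz <- tapply_num(members$intensity * members$mz, members$group)
  wrt <- tapply_num(members$intensity * members$rt, members$group)
  cmz <- tapply_num(members$mz, members$group)
  crt <- tapply_num(members$rt, members$group)
  nmem <- tapply_num(rep(1, nrow(members)), members$group)
  cons_mz <- ifelse(wsum > 0, wmz / wsum, cmz / nmem)
  cons_rt <- ifelse(wsum > 0, wrt / wsum, crt / nmem)

  ids <- sprintf("AF%05d", seq_along(cons_mz))
  members$feature_id <- ids[members$group]
  members$group <- NULL
  structure(
    list(
      features = data.frame(feature_id = ids, mz = unname(cons_mz),
                            rt = unname(cons_rt),
                            n_members = as.integer(unname(nmem)),
                            stringsAsFactors = FALSE),
      members = members[c("feature_id", "sample_id", "extract_id",
                          "mz", "rt", "intensity")]
    ),
    blank_subtracted = FALSE,
    class = "aligned_features"
  )
}

tapply_num <- function(x, g) {
  out <- rowsum(x, g, reorder = TRUE)
  stats::setNames(as.numeric(out), rownames(out))
}

empty_aligned <- function() {
  structure(
    list(
      features = data.frame(feature_id = character(0), mz = numeric(0),
                            rt = numeric(0), n_members = integer(0),
                            stringsAsFactors = FALSE),
      members = data.frame(feature_id = character(0), sample_id = character(0),
                           extract_id = character(0), mz = numeric(0),
                           rt = numeric(0), intensity = numeric(0),
                           stringsAsFactors = FALSE)
    ),
    blank_subtracted = FALSE,
    class = "aligned_features"
  )
}

#' @export
print.aligned_features <- function(x, ...) {
  cat(sprintf("aligned_features: %d features, %d member observations\n",
              nrow(x$features), nrow(x$members)))
  invisible(x)
}

#' Remove solvent-blank features
#'
#' In `global` mode (the default) any aligned feature with at least one
#' member observation from a blank sample is removed entirely — the feature
#' list is reduced by all compounds encountered in solvent blanks — and, to
#' guarantee that no surviving feature matches a blank compound, any
#' remaining feature whose consensus m/z and RT lie within the matching
#' tolerance of a removed blank feature's consensus is removed as well.
#' In `per_solvent` mode only members from extracts of solvent S are removed
#' when the feature also has a member in the blank of S; features left with
#' no non-blank members are dropped.
#'
#' @param features An `aligned_features` object.
#' @param samples Sample metadata identifying blanks (`category == "blank"`,
#'   with their `solvent`).
#' @param mode `"global"` or `"per_solvent"`.
#' @param tol A [tolerance_spec()] used for the consensus-to-consensus blank
#'   match in global mode.
#' @return The filtered `aligned_features`, with attributes
#'   `blank_subtracted = TRUE` and `removed_features` (the dropped ids).
#' @export
subtract_blanks <- function(features, samples, mode = c("global", "per_solvent"),
                            tol = tolerance_spec()) {
  mode <- match.arg(mode)
  stopifnot(inherits(features, "aligned_features"))
  samples <- validate_metadata(samples)
  blanks <- samples[samples$category == "blank", , drop = FALSE]
  if (nrow(blanks) == 0L) {
    rd_warn("no_blanks: no blank samples in metadata; returning features unchanged")
    return(features)
  }
  mem <- features$members
  if (mode == "global") {
    hit <- unique(mem$feature_id[mem$sample_id %in% blanks$sample_id])
    feat <- features$features
    bl <- feat[feat$feature_id %in% hit, , drop = FALSE]
    if (nrow(bl)) {
      near <- vapply(seq_len(nrow(feat)), function(i) {
        any(abs(feat$mz[i] - bl$mz) <= mz_tolerance_at(feat$mz[i], tol) &
              abs(feat$rt[i] - bl$rt) <= tol$rt_min)
      }, logical(1))
      hit <- union(hit, feat$feature_id[near])
    }
    mem <- mem[!(mem$feature_id %in% hit), , drop = FALSE]
  } else {
    for (s in unique(blanks$solvent)) {
      bl_ids <- blanks$sample_id[blanks$solvent == s]
      hit <- unique(mem$feature_id[mem$sample_id %in% bl_ids])
      drop <- mem$feature_id %in% hit & mem$extract_id == s
      mem <- mem[!drop, , drop = FALSE]
    }
    # a feature whose remaining members are all blanks carries no sample signal
    by_feat <- split(mem$sample_id, mem$feature_id)
    all_blank <- names(by_feat)[vapply(by_feat, function(x)
      all(x %in% blanks$sample_id), logical(1))]
    mem <- mem[!(mem$feature_id %in% all_blank), , drop = FALSE]
  }
  kept <- features$features$feature_id %in% unique(mem$feature_id)
  out <- structure(
    list(features = features$features[kept, , drop = FALSE], members = mem),
    blank_subtracted = TRUE,
    removed_features = features$features$feature_id[!kept],
    class = "aligned_features"
  )
  rownames(out$features) <- NULL
  out
}

#' Merge solvent extracts and binarize to a presence matrix
#'
#' One column per non-blank sample; a cell is 1 iff the feature has a member
#' with positive intensity in any of that sample's extracts (union across
#' the solvent systems). Features present in no non-blank sample are
#' dropped. Feature annotations carry the consensus m/z and RT.
#'
#' @param features An `aligned_features` object (blank subtraction already
#'   applied for the standard pipeline).
#' @param samples Sample metadata.
#' @return A `presence_matrix`.
#' @export
merge_extracts_and_binarize <- function(features, samples) {
  stopifnot(inherits(features, "aligned_features"))
  samples <- validate_metadata(samples)
  keep_samples <- samples$sample_id[samples$category != "blank"]
  mem <- features$members
  mem <- mem[mem$sample_id %in% keep_samples & mem$intensity > 0, , drop = FALSE]
  fids <- features$features$feature_id
  cells <- matrix(0L, length(fids), length(keep_samples),
                  dimnames = list(fids, keep_samples))
  if (nrow(mem)) {
    cells[cbind(match(mem$feature_id, fids), match(mem$sample_id, keep_samples))] <- 1L
  }
  cells <- cells[rowSums(cells) > 0, , drop = FALSE]
  ann <- features$features[c("feature_id", "mz", "rt")]
  presence_matrix(cells, annotations = ann,
                  blank_subtracted = isTRUE(attr(features, "blank_subtracted")))
}
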
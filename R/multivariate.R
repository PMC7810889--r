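#' Jaccard distances between sample presence profiles
#'
#' d(a, b) = 1 - |A and B| / |A or B| over the feature sets of the two
#' samples; two empty profiles are at distance 0 by convention.
#'
#' @param x A `presence_matrix` (features x samples) or a binary matrix with
#'   samples in columns.
#' @return A symmetric numeric matrix with zero diagonal and sample ids as
#'   dimnames.
#' @export
jaccard_distances <- function(x) {
  cells <- if (inherits(x, "presence_matrix")) x$cells else as.matrix(x)
  if (any(is.na(cells)) || !all(cells %in% c(0, 1))) {
    validation_error("Jaccard distances require a binary matrix")
  }
  storage.mode(cells) <- "double"
  inter <- crossprod(cells)
  sizes <- colSums(cells)
  uni <- outer(sizes, sizes, "+") - inter
  d <- 1 - inter / uni
  d[uni == 0] <- 0
  diag(d) <- 0
  d
}

#' Ward minimum-variance clustering from a distance matrix
#'
#' Agglomerative clustering via the Lance-Williams recurrence. The default
#' `ward_d2` variant operates on squared dissimilarities,
#' d2(k, ij) = ((n_i + n_k) d2(k,i) + (n_j + n_k) d2(k,j) - n_k d2(i,j)) /
#' (n_i + n_j + n_k), and reports unsquared merge heights; `ward_d` applies
#' the same recurrence to the raw dissimilarities. Ties are broken by the
#' smallest (left, right) pair of active cluster slots, where a merged
#' cluster occupies the smaller slot of its members, so results are fully
#' deterministic.
#'
#' @param dist Symmetric distance matrix (or `dist` object), n >= 2.
#' @param variant `"ward_d2"` (default) or `"ward_d"`.
#' @return An object of class `ward_tree` with hclust-convention fields
#'   `merge`, `height`, `labels`, `order`.
#' @export
ward_cluster <- function(dist, variant = c("ward_d2", "ward_d")) {
  variant <- match.arg(variant)
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 2L) validation_error("clustering needs at least two samples")
  if (ncol(d) != n || !isTRUE(all.equal(d, t(d), tolerance = 1e-10))) {
    validation_error("distance matrix must be square and symmetric")
  }
  if (any(d < 0)) validation_error("distances must be non-negative")
  labels <- rownames(d) %||% as.character(seq_len(n))

  a <- if (variant == "ward_d2") d^2 else d
  active <- rep(TRUE, n)
  size <- rep(1L, n)
  id <- -(seq_len(n))            # hclust convention: negative = leaf
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  diag(a) <- Inf
  a[!active, ] <- Inf

  for (step in seq_len(n - 1L)) {
    amin <- Inf; bi <- 0L; bj <- 0L
    for (i in seq_len(n - 1L)) {
      if (!active[i]) next
      for (j in seq.int(i + 1L, n)) {
        if (!active[j]) next
        if (a[i, j] < amin - 1e-12) { amin <- a[i, j]; bi <- i; bj <- j }
      }
    }
    height[step] <- if (variant == "ward_d2") sqrt(amin) else amin
    merge[step, ] <- sort_merge_pair(id[bi], id[bj])
    ni <- size[bi]; nj <- size[bj]
    for (k in seq_len(n)) {
      if (!active[k] || k == bi || k == bj) next
      nk <- size[k]
      a_new <- ((ni + nk) * a[k, bi] + (nj + nk) * a[k, bj] - nk * amin) /
        (ni + nj + nk)
      a[bi, k] <- a[k, bi] <- a_new
    }
    active[bj] <- FALSE
    a[bj, ] <- Inf; a[, bj] <- Inf
    size[bi] <- ni + nj
    id[bi] <- step
  }
  if (any(diff(height) < -1e-8)) {
    rd_stop("Ward merge heights decreased; input is not a valid dissimilarity",
            "residomics_internal_error")
  }
  height <- cummax(height)   # clamp ulp-scale inversions
  structure(
    list(merge = merge, height = height, labels = labels,
         order = tree_leaf_order(merge), variant = variant),
    class = "ward_tree"
  )
}

sort_merge_pair <- function(x, y) {
  # hclust row convention: singletons (negative) before clusters; two
  # singletons by ascending leaf index; two clusters by ascending step
  if (x < 0 && y < 0) {
    if (-x > -y) c(y, x) else c(x, y)
  } else if (x > 0 && y > 0) {
    if (x > y) c(y, x) else c(x, y)
  } else if (x > 0 && y < 0) {
    c(y, x)
  } else {
    c(x, y)
  }
}

tree_leaf_order <- function(merge) {
  rec <- function(k) {
    if (k < 0) return(-k)
    c(rec(merge[k, 1]), rec(merge[k, 2]))
  }
  rec(nrow(merge))
}

#' @export
print.ward_tree <- function(x, ...) {
  cat(sprintf("ward_tree (%s): %d leaves, root height %.4g\n",
              x$variant, length(x$labels), max(x$height)))
  invisible(x)
}

#' Convert a `ward_tree` to an `hclust` object
#' @param x A `ward_tree`.
#' @param ... Unused.
#' @return An object of class `hclust`.
#' @export
as.hclust.ward_tree <- function(x, ...) {
  structure(
    list(merge = x$merge, height = x$height, order = x$order,
         labels = x$labels, method = x$variant,
         call = match.call(), dist.method = "user"),
    class = "hclust"
  )
}

#' Cut a `ward_tree` into k groups
#' @param tree A `ward_tree`.
#' @param k Number of groups.
#' @return Named integer vector of group memberships.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "ward_tree"))
  stats::cutree(stats::as.hclust(tree), k = k)
}

#' Principal components analysis of a presence matrix
#'
#' Computed by singular value decomposition of the processed (centered /
#' scaled) samples-by-features matrix. Scores are `U %*% D`, loadings the
#' right singular vectors, and explained variances the squared singular
#' values divided by (n - 1). Each component's sign is fixed so that its
#' loading vector has a non-negative sum, making score tables reproducible.
#'
#' @param x A `presence_matrix` or a numeric matrix with samples in rows.
#' @param centering `"mean"` (default) or `"none"`.
#' @param scaling `"none"` (default), `"unit"` (divide by column sd) or
#'   `"pareto"` (divide by sqrt of column sd). Constant columns are left
#'   unscaled.
#' @param n_components Number of components to keep (default: all).
#' @return An object of class `pca_result`: `scores` (samples x components),
#'   `loadings` (features x components), `explained_variance`, plus the
#'   processing settings.
#' @export
pca_presence <- function(x, centering = c("mean", "none"),
                         scaling = c("none", "unit", "pareto"),
                         n_components = NULL) {
  centering <- match.arg(centering)
  scaling <- match.arg(scaling)
  X <- if (inherits(x, "presence_matrix")) t(x$cells) else as.matrix(x)
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (n < 2L) validation_error("PCA needs at least two samples")
  ctr <- if (centering == "mean") colMeans(X) else rep(0, ncol(X))
  X <- sweep(X, 2L, ctr, "-")
  scl <- rep(1, ncol(X))
  if (scaling != "none") {
    sds <- apply(X, 2L, stats::sd)
    scl <- if (scaling == "unit") sds else sqrt(sds)
    scl[!is.finite(scl) | scl == 0] <- 1
    X <- sweep(X, 2L, scl, "/")
  }
  kmax <- min(dim(X))
  k <- n_components %||% kmax
  if (k > kmax) validation_error("n_components exceeds min(samples, features)")
  sv <- svd(X, nu = k, nv = k)
  dvals <- sv$d[seq_len(k)]
  scores <- sv$u %*% diag(dvals, nrow = k)
  loadings <- sv$v
  flip <- colSums(loadings) < 0
  scores[, flip] <- -scores[, flip, drop = FALSE]
  loadings[, flip] <- -loadings[, flip, drop = FALSE]
  rownames(scores) <- rownames(X)
  rownames(loadings) <- colnames(X)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(k))
  structure(
    list(scores = scores, loadings = loadings,
         explained_variance = dvals^2 / (n - 1),
         centering = centering, scaling = scaling,
         center = ctr, scale = scl),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  tot <- sum(x$explained_variance)
  pct <- if (tot > 0) 100 * x$explained_variance / tot else x$explained_variance
  cat("pca_result:", nrow(x$scores), "samples,", length(x$explained_variance),
      "components\n")
  cat("explained variance (%):", paste(sprintf("%.1f", pct), collapse = ", "), "\n")
  invisible(x)
}
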
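test_that("Jaccard distances match hand counts and vegan", {
  cells <- cbind(a = c(1, 1, 1, 0), b = c(0, 1, 1, 1),
                 c = c(1, 1, 1, 0), d = c(0, 0, 0, 0), e = c(0, 0, 0, 0))
  rownames(cells) <- paste0("f", 1:4)
  d <- jaccard_distances(cells)
  expect_equal(d["a", "b"], 0.5)        # intersection 2, union 4
  expect_equal(d["a", "c"], 0)          # identical profiles
  expect_equal(d["d", "e"], 0)          # both empty, by convention
  expect_equal(d["a", "d"], 1)          # union = |a| = 3, intersection 0

  vd <- as.matrix(vegan::vegdist(t(cells[, c("a", "b", "c")]),
                                 method = "jaccard", binary = TRUE))
  expect_equal(unname(d[c("a", "b", "c"), c("a", "b", "c")]), unname(vd),
               tolerance = 1e-12)

  expect_error(jaccard_distances(cbind(a = c(0, 2))),
               class = "residomics_validation_error")
})

test_that("Jaccard distance is a metric on random binary matrices", {
  set.seed(21)
  for (rep in 1:5) {
    cells <- matrix(rbinom(20 * 6, 1, 0.4), 20, 6,
                    dimnames = list(paste0("f", 1:20), paste0("s", 1:6)))
    d <- jaccard_distances(cells)
    expect_equal(d, t(d))
    expect_equal(diag(d), setNames(rep(0, 6), colnames(cells)))
    expect_true(all(d >= 0 & d <= 1))
    for (i in 1:6) for (j in 1:6) for (k in 1:6) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("Ward clustering reproduces the Lance-Williams worked example", {
  d2 <- matrix(c(0, 0.2, 0.2, 0), 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- ward_cluster(d2)
  expect_equal(t2$height, 0.2)

  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["A", "C"] <- d["C", "A"] <- 0.9
  d["B", "C"] <- d["C", "B"] <- 0.8
  tree <- ward_cluster(d)
  expect_equal(tree$merge[1, ], c(-1L, -2L))   # (A,B) first
  expect_equal(tree$height,
               c(0.2, sqrt((2 * 0.81 + 2 * 0.64 - 0.04) / 3)),
               tolerance = 1e-12)
  expect_equal(round(tree$height[2], 4), 0.9764)

  expect_error(ward_cluster(matrix(0, 1, 1)), class = "residomics_validation_error")
  asym <- d; asym[1, 2] <- 0.3
  expect_error(ward_cluster(asym), class = "residomics_validation_error")
})

test_that("Ward agrees with hclust and heights never decrease", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(4:7, 1)
    x <- matrix(rnorm(n * 4), n)
    rownames(x) <- paste0("s", seq_len(n))
    d <- as.matrix(dist(x))
    for (variant in c("ward_d2", "ward_d")) {
      tree <- ward_cluster(d, variant)
      hc <- hclust(as.dist(d), method = if (variant == "ward_d2") "ward.D2" else "ward.D")
      expect_equal(tree$merge, hc$merge)
      expect_equal(tree$height, hc$height, tolerance = 1e-9)
      expect_true(all(diff(tree$height) >= -1e-12))
    }
  }
})

test_that("PCA matches the eigendecomposition oracle and prcomp", {
  X <- rbind(c(1, 0), c(0, 1), c(1, 1))
  res <- pca_presence(X)
  ev_oracle <- sort(eigen(cov(X))$values, decreasing = TRUE)
  expect_equal(res$explained_variance, ev_oracle, tolerance = 1e-12)

  set.seed(41)
  cells <- matrix(rbinom(30 * 8, 1, 0.4), 30, 8,
                  dimnames = list(paste0("f", 1:30), paste0("s", 1:8)))
  pm <- presence_matrix(cells)
  res <- pca_presence(pm)
  pr <- prcomp(t(cells), center = TRUE, scale. = FALSE)
  k <- length(res$explained_variance)
  expect_equal(res$explained_variance, unname(pr$sdev[seq_len(k)]^2),
               tolerance = 1e-9)
  expect_equal(abs(unname(res$scores)), abs(unname(pr$x[, seq_len(k)])),
               tolerance = 1e-9)

  # reconstruction: scores %*% t(loadings) equals the centered matrix
  Xc <- scale(t(cells), center = TRUE, scale = FALSE)
  expect_equal(res$scores %*% t(res$loadings), unclass(Xc),
               ignore_attr = TRUE, tolerance = 1e-8)
  # loadings orthonormal
  G <- crossprod(res$loadings)
  expect_equal(G, diag(ncol(G)), ignore_attr = TRUE, tolerance = 1e-8)
  # deterministic sign convention
  expect_true(all(colSums(res$loadings) >= -1e-12))
})

test_that("degenerate PCA inputs give zero scores, single-driver gives 100%", {
  X <- matrix(1, 4, 3)            # identical rows
  res <- pca_presence(X)
  expect_true(all(abs(res$scores) < 1e-12))
  expect_true(all(res$explained_variance < 1e-24))

  X <- cbind(c(0, 1, 0, 1), 1, 0) # exactly one feature varies
  res <- pca_presence(X)
  expect_equal(res$explained_variance[1] / sum(res$explained_variance), 1)
})

test_that("subsetting drops empty features without changing distances", {
  set.seed(51)
  cells <- matrix(rbinom(40 * 7, 1, 0.3), 40, 7,
                  dimnames = list(paste0("f", 1:40), paste0("s", 1:7)))
  pm <- presence_matrix(cells)

  full <- subset_presence(pm, colnames(cells))
  expect_identical(full$cells, pm$cells[rowSums(pm$cells) > 0, , drop = FALSE])

  keep <- c("s1", "s3", "s5")
  sub <- subset_presence(pm, keep)
  expect_true(all(rowSums(sub$cells) > 0))
  d_full <- jaccard_distances(pm)[keep, keep]
  d_sub <- jaccard_distances(sub)
  expect_equal(d_sub, d_full)

  expect_error(subset_presence(pm, "nope"), class = "residomics_validation_error")
})
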
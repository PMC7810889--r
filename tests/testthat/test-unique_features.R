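toy_unique_setup <- function() {
  cells <- rbind(f1 = c(1, 0, 0, 1), f2 = c(1, 1, 0, 0),
                 f3 = c(0, 1, 1, 0), f4 = c(0, 0, 1, 1))
  colnames(cells) <- c("R1", "R2", "V01", "V02")
  meta <- rbind(
    data.frame(sample_id = c("R1", "R2"), category = "reference",
               species_code = c("AA", "BB"), stringsAsFactors = FALSE),
    data.frame(sample_id = c("V01", "V02"), category = "vessel",
               species_code = NA, stringsAsFactors = FALSE)
  )
  meta$project <- ifelse(meta$category == "vessel", "P", NA)
  meta$treatment <- ifelse(meta$category == "vessel", "curated", NA)
  meta$form_class <- ifelse(meta$category == "vessel", "PF_narrow", NA)
  list(pm = presence_matrix(cells, blank_subtracted = TRUE), meta = meta)
}

test_that("uniqueness is evaluated against the other references only", {
  s <- toy_unique_setup()
  rep <- find_unique_features(s$pm, s$meta)
  # R1 = {f1, f2}, R2 = {f2, f3}: f2 shared, vessels irrelevant
  expect_equal(rep$unique_features$R1, "f1")
  expect_equal(rep$unique_features$R2, "f3")
  expect_equal(rep$counts, c(R1 = 1L, R2 = 1L))

  # conservation: counts match a brute-force scan over reference columns
  refs <- c("R1", "R2")
  brute <- sum(rowSums(s$pm$cells[, refs]) == 1)
  expect_equal(sum(rep$counts), brute)

  no_refs <- s$meta[s$meta$category == "vessel", ]
  expect_error(find_unique_features(s$pm, no_refs),
               class = "residomics_validation_error")
})

test_that("uniqueness refuses matrices that skipped blank subtraction", {
  s <- toy_unique_setup()
  pm_raw <- presence_matrix(s$pm$cells, blank_subtracted = FALSE)
  expect_error(find_unique_features(pm_raw, s$meta),
               "blank-subtracted", class = "residomics_validation_error")
  expect_silent(find_unique_features(pm_raw, s$meta, allow_unsubtracted = TRUE))
  # unknown provenance (read from disk) is taken as given
  pm_na <- presence_matrix(s$pm$cells, blank_subtracted = NA)
  expect_silent(find_unique_features(pm_na, s$meta))
})

test_that("sharing table reproduces the published tallies", {
  pm <- table3_matrix()
  report <- table3_report()
  meta <- table1_metadata()
  st <- build_sharing_table(pm, report, meta)

  expect_equal(unname(st$ubiquity["8738"]), 10L)
  expect_equal(unname(st$ubiquity["4225"]), 1L)
  expect_equal(unname(st$ubiquity["6956"]), 7L)   # half the vessels
  expect_equal(unname(st$per_vessel_shared["V13", "TLU"]), 4L)
  # no column except the three most ubiquitous exceeds 4 of 14 vessels
  others <- setdiff(names(st$ubiquity), c("6956", "8738", "8813"))
  expect_true(all(st$ubiquity[others] <= 4L))
  # no feature is attributed to SDI, NSP, or LVI
  expect_false(any(st$feature_info$reference %in% c("SDI", "NSP", "LVI")))
  # ubiquity equals the vessel column sums
  expect_equal(unname(st$ubiquity), unname(colSums(st$cells)))

  # a feature absent from every vessel is excluded
  cells2 <- rbind(pm$cells, f_new = 0L)
  pm2 <- presence_matrix(cells2, pm$annotations)
  rep2 <- report
  rep2$unique_features$TLU <- c(rep2$unique_features$TLU, "f_new")
  rep2$counts["TLU"] <- rep2$counts["TLU"] + 1L
  st2 <- build_sharing_table(pm2, rep2, meta)
  expect_false("f_new" %in% colnames(st2$cells))
})

test_that("vessel ranking orders by shared fraction with stable ties", {
  st <- build_sharing_table(table3_matrix(), table3_report(), table1_metadata())
  rk <- rank_vessels_by_shared(st, table3_report(), totals = c(TLU = 128))
  expect_equal(rk$vessel_id[1], "V13")
  expect_equal(rk$reference[1], "TLU")
  expect_equal(rk$shared[1], 4L)
  expect_equal(rk$total_unique[1], 128)
  expect_equal(rk$fraction[1], 0.03125)
  # V07 shares nothing: fraction 0
  expect_equal(rk$fraction[rk$vessel_id == "V07"], 0)
  # fractions invariant under input row permutation
  meta_shuffled <- table1_metadata()[sample(14), , drop = FALSE]
  st2 <- build_sharing_table(table3_matrix(), table3_report(), meta_shuffled)
  rk2 <- rank_vessels_by_shared(st2, table3_report(), totals = c(TLU = 128))
  expect_equal(rk2[order(rk2$vessel_id, rk2$reference), c("shared", "fraction")],
               rk[order(rk$vessel_id, rk$reference), c("shared", "fraction")],
               ignore_attr = TRUE)
})

test_that("species-level aggregation treats curing states as one species", {
  cells <- rbind(f1 = c(1, 0, 0), f2 = c(1, 1, 0), f3 = c(0, 0, 1))
  colnames(cells) <- c("NT10", "NT30", "TLU")
  meta <- data.frame(sample_id = c("NT10", "NT30", "TLU"),
                     category = "reference",
                     species_code = c("NT", "NT", "TLU"),
                     stringsAsFactors = FALSE)
  pm <- presence_matrix(cells, blank_subtracted = TRUE)
  by_sample <- find_unique_features(pm, meta)
  expect_equal(by_sample$unique_features$NT10, "f1")  # f2 in NT30 too
  by_species <- find_unique_features(pm, meta, level = "species")
  expect_setequal(by_species$unique_features$NT, c("f1", "f2"))
  expect_equal(by_species$unique_features$TLU, "f3")
})
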
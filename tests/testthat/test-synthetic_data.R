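test_that("study generation is deterministic and matches the design counts", {
  s1 <- generate_study(small_config(seed = 9))
  s2 <- generate_study(small_config(seed = 9))
  expect_identical(s1$observations, s2$observations)
  expect_identical(s1$truth, s2$truth)

  meta <- s1$metadata
  expect_equal(sum(meta$category == "vessel"), 14L)
  expect_equal(sum(meta$category == "reference"), 12L)
  expect_equal(sum(meta$category == "blank"), 3L)
  expect_setequal(meta$solvent[meta$category == "blank"],
                  c("TA", "APW", "MTBE"))

  s3 <- generate_study(small_config(seed = 10))
  expect_false(identical(s1$observations, s3$observations))

  expect_error(study_config(taphonomic_survival = 2),
               class = "residomics_validation_error")
  expect_error(study_config(n_curated_vessels = -1),
               class = "residomics_validation_error")
})

test_that("truth bookkeeping covers every planted feature exactly once", {
  study <- generate_study(small_config(seed = 2))
  truth <- study$truth
  planted_union <- sort(unique(unlist(truth$planted_per_sample)))
  expect_identical(planted_union, sort(names(truth$feature_origin)))
  # origins are single-valued per feature
  expect_false(anyDuplicated(names(truth$feature_origin)) > 0)
  # observed features all exist in the truth table
  expect_true(all(study$observations$feature_id %in% names(truth$feature_origin)))
  # unique-by-construction features occur in exactly one reference sample
  refs <- study$metadata$sample_id[study$metadata$category == "reference"]
  planted_ref <- truth$planted_per_sample[refs]
  for (r in refs) {
    for (f in truth$unique_by_construction[[r]]) {
      holders <- refs[vapply(planted_ref, function(s) f %in% s, logical(1))]
      expect_equal(holders, r)
    }
  }
})

test_that("reference library encodes curing, backbone and the LVI deficit", {
  cfg <- small_config(seed = 3)
  study <- generate_study(cfg)
  planted <- study$truth$planted_per_sample

  # freeze-dried vs cured differ exactly by the curing-specific features
  extra <- setdiff(planted$NT10, planted$NTFD)
  expect_equal(sort(extra), sort(study$truth$unique_by_construction$NT10))
  expect_length(extra, cfg$curing_specific_count)
  expect_length(setdiff(planted$NTFD, planted$NT10), 0L)

  # zero backbone and zero plant core: NT and NR disjoint
  cfg0 <- small_config(seed = 3, shared_backbone_fraction = 0,
                       plant_core_fraction = 0)
  st0 <- generate_study(cfg0)
  expect_length(intersect(st0$truth$planted_per_sample$NTFD,
                          st0$truth$planted_per_sample$NRFD), 0L)

  # the reference library view restricts the same study to references
  lib <- generate_reference_library(cfg)
  expect_setequal(names(lib), study$metadata$sample_id[
    study$metadata$category == "reference"])
  expect_identical(lib$TLU, study$observations[
    study$observations$sample_id == "TLU", , drop = FALSE])

  # LVI yields fewer features than every other reference (default sizes)
  sizes <- sapply(1:3, function(seed) {
    p <- generate_study(study_config(seed = seed))$truth$planted_per_sample
    c(lvi = length(p$LVI),
      min_other = min(lengths(p[c("NTFD", "NT10", "NT30", "NRFD", "NR10",
                                  "NR30", "TLU", "NSP", "SDI", "DWR", "APE")])))
  })
  expect_true(all(sizes["lvi", ] < 500 & sizes["min_other", ] >= 500))
})

test_that("lower curation survival never increases curated vessel loads", {
  cfg_hi <- small_config(seed = 4)
  cfg_lo <- small_config(seed = 4, curation_survival = 0.2)
  hi <- generate_study(cfg_hi)$truth$planted_per_sample
  lo <- generate_study(cfg_lo)$truth$planted_per_sample
  curated <- sprintf("V%02d", 3:14)
  expect_true(all(lengths(lo[curated]) <= lengths(hi[curated])))
})

test_that("tobacco groups are mutually closer than to other references", {
  run <- run_default_study(6)
  d <- jaccard_distances(run$pm)
  tob <- c("NTFD", "NT10", "NT30", "NRFD", "NR10", "NR30")
  oth <- c("TLU", "NSP", "LVI", "SDI", "DWR", "APE")
  nt_nr <- mean(d[c("NTFD", "NT10", "NT30"), c("NRFD", "NR10", "NR30")])
  tob_oth <- mean(d[tob, oth])
  expect_lt(nt_nr, tob_oth)
})

test_that("studies round-trip through the on-disk artifact set", {
  dir <- withr::local_tempdir()
  study <- generate_study(small_config(seed = 5))
  write_study(study, dir)
  obs <- read_feature_table(file.path(dir, "feature_table.csv"))
  expect_equal(nrow(obs), nrow(study$observations))
  expect_equal(obs$mz, study$observations$mz)
  meta <- read_sample_metadata(file.path(dir, "metadata.csv"))
  expect_equal(meta$sample_id, study$metadata$sample_id)
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_setequal(names(truth),
                  c("feature_origin", "feature_species", "vessel_contents",
                    "unique_by_construction", "planted_per_sample"))
  expect_equal(length(truth$feature_origin),
               nrow(study$truth$features))
})
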
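test_that("alignment merges within tolerance and splits on RT", {
  empty <- align_features(obs_row(character(0), numeric(0), numeric(0)))
  expect_equal(nrow(empty$features), 0L)

  # 3.33 ppm and 0.02 min apart: one consensus feature, two members
  obs <- rbind(obs_row("S1", 300.0000, 5.00, 100),
               obs_row("S2", 300.0010, 5.02, 300))
  al <- align_features(obs)
  expect_equal(nrow(al$features), 1L)
  expect_equal(al$features$n_members, 2L)
  # consensus is the intensity-weighted mean
  expect_equal(al$features$mz, (100 * 300.0000 + 300 * 300.0010) / 400)

  # same m/z, 2.00 min apart: two features
  obs <- rbind(obs_row("S1", 300.0000, 5.00), obs_row("S2", 300.0000, 7.00))
  expect_equal(nrow(align_features(obs)$features), 2L)

  # duplicate (sample, extract) members keep the higher intensity
  obs <- rbind(obs_row("S1", 300.0000, 5.00, 10),
               obs_row("S1", 300.0005, 5.01, 90))
  al <- align_features(obs)
  expect_equal(al$features$n_members, 1L)
  expect_equal(al$members$intensity, 90)
})

test_that("alignment equals brute-force single linkage on spaced features", {
  set.seed(11)
  tol <- tolerance_spec()
  for (rep in 1:5) {
    true_mz <- sample(seq(150, 900, by = 0.06), 8)
    true_rt <- runif(8, 1, 15)
    obs <- do.call(rbind, lapply(seq_along(true_mz), function(i) {
      k <- sample(2:6, 1)
      obs_row(sprintf("S%d", seq_len(k)),
              true_mz[i] * (1 + runif(k, -4e-6, 4e-6)),
              true_rt[i] + runif(k, -0.03, 0.03),
              intensity = rlnorm(k, 5, 1),
              extract_id = sample(c("TA", "APW", "MTBE"), k, replace = TRUE))
    }))
    obs <- obs[sample(nrow(obs)), , drop = FALSE]
    al <- align_features(obs, tol)
    # recover the greedy partition in oracle (input) order
    key <- paste(obs$sample_id, obs$extract_id, round(obs$mz, 9), round(obs$rt, 9))
    mkey <- paste(al$members$sample_id, al$members$extract_id,
                  round(al$members$mz, 9), round(al$members$rt, 9))
    got <- al$members$feature_id[match(key, mkey)]
    oracle <- brute_force_single_linkage(obs, tol)
    expect_true(same_partition(got, oracle))
  }
})

test_that("alignment is idempotent and stable under row permutation", {
  run <- run_default_study(3)
  al <- run$aligned
  consensus_obs <- data.frame(sample_id = al$features$feature_id,
                              extract_id = "TA", mz = al$features$mz,
                              rt = al$features$rt, intensity = 1)
  again <- align_features(consensus_obs)
  expect_equal(nrow(again$features), nrow(al$features))
  expect_equal(sort(again$features$mz), sort(al$features$mz))

  set.seed(5)
  obs <- run$study$observations
  shuffled <- obs[sample(nrow(obs)), , drop = FALSE]
  al2 <- align_features(shuffled)
  expect_equal(al2$features$mz, al$features$mz)
  expect_equal(al2$features$n_members, al$features$n_members)
})

test_that("blank subtraction removes blank compounds and warns without blanks", {
  # feature with members in blank TA and two vessels: removed in global mode
  obs <- rbind(obs_row(c("V01", "V02", "BLANK_TA"), 400.0, 5.0),
               obs_row(c("V01", "V02"), 500.0, 8.0))
  meta <- toy_metadata(c("V01", "V02"), blanks = "TA")
  al <- align_features(obs)
  sub <- subtract_blanks(al, meta)
  expect_equal(nrow(sub$features), 1L)
  expect_equal(sub$features$mz, 500.0)
  expect_true(attr(sub, "blank_subtracted"))

  # no blanks: warning with stable prefix, input unchanged
  meta_nb <- toy_metadata(c("V01", "V02"), blanks = character(0))
  expect_warning(out <- subtract_blanks(al, meta_nb), "no_blanks")
  expect_identical(out$features, al$features)

  # per-solvent mode removes only the matching extract members
  obs <- rbind(obs_row("BLANK_TA", 400.0, 5.0, extract_id = "TA"),
               obs_row("V01", 400.00001, 5.01, extract_id = "TA"),
               obs_row("V01", 400.00002, 5.02, extract_id = "MTBE"))
  al <- align_features(obs)
  sub <- subtract_blanks(al, meta, mode = "per_solvent")
  expect_equal(nrow(sub$features), 1L)
  expect_equal(sub$members$extract_id, "MTBE")
})

test_that("no surviving feature matches a blank feature within tolerance", {
  run <- run_default_study(2)
  blank_ids <- run$study$metadata$sample_id[run$study$metadata$category == "blank"]
  bl_feats <- unique(run$aligned$members$feature_id[
    run$aligned$members$sample_id %in% blank_ids])
  bl <- run$aligned$features[run$aligned$features$feature_id %in% bl_feats, ]
  surv <- run$subtracted$features
  tol <- tolerance_spec()
  for (i in seq_len(nrow(surv))) {
    expect_false(any(
      abs(surv$mz[i] - bl$mz) <= max(tol$mz_ppm * surv$mz[i] / 1e6, tol$mz_abs_min) &
        abs(surv$rt[i] - bl$rt) <= tol$rt_min))
  }
})

test_that("extract merging takes the union over solvents and binarizes", {
  meta <- rbind(toy_metadata(c("V05", "V06"), blanks = "TA"))
  obs <- rbind(obs_row("V05", 400.0, 5.0, extract_id = "MTBE"),
               obs_row("V06", 500.0, 8.0, extract_id = "TA"))
  al <- align_features(obs)
  pm <- merge_extracts_and_binarize(al, meta)
  f400 <- rownames(pm$cells)[abs(pm$annotations$mz - 400) < 0.01]
  f500 <- rownames(pm$cells)[abs(pm$annotations$mz - 500) < 0.01]
  expect_equal(pm$cells[f400, "V05"], 1L)   # present via MTBE only
  expect_equal(pm$cells[f400, "V06"], 0L)
  expect_equal(pm$cells[f500, "V06"], 1L)
  expect_true(all(pm$cells %in% c(0L, 1L)))
})

test_that("tolerances must be strictly positive", {
  expect_error(tolerance_spec(mz_ppm = 0), class = "residomics_validation_error")
  expect_error(tolerance_spec(rt_min = -1), class = "residomics_validation_error")
})
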
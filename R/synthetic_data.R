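default_reference_panel <- function() {
  data.frame(
    species_code = c("NT", "NT", "NT", "NR", "NR", "NR",
                     "TLU", "NSP", "LVI", "SDI", "DWR", "APE"),
    curing_state = c("FD", "C10", "C30", "FD", "C10", "C30",
                     rep(NA_character_, 6)),
    stringsAsFactors = FALSE
  )
}

#' Configuration of a synthetic residue-metabolomics study
#'
#' Defaults emulate the study design the pipeline targets: 12 reference
#' samples (two tobaccos in three curing states each plus six other
#' candidate plants), 14 vessels (12 previously curated, 2 untreated), and
#' one solvent blank per extraction system. Reference metabolomes carry
#' about 600 features each (300 for the bark reference LVI), of which a
#' plant-core fraction is drawn from a pool of compounds common to all
#' plants (shared primary metabolites); the two tobaccos additionally share
#' a backbone of genus-specific compounds, and cured tobacco samples gain
#' curing-induced features. Vessels retain a heavily thinned subsample of
#' their content species' features (survival rates calibrated so curated
#' vessels retain about 43 features and untreated ones about 97 after blank
#' subtraction) plus site-specific soil features. Laboratory contaminants
#' are planted in the solvent blanks and carried over into sample extracts.
#'
#' @param n_curated_vessels,n_untreated_vessels Vessel counts by treatment.
#' @param reference_panel Data frame with columns `species_code`,
#'   `curing_state` (NA for species sampled in a single state).
#' @param features_per_reference Mean metabolome size per reference species.
#' @param lvi_features Mean metabolome size for LVI (bark yields fewer
#'   extractable compounds).
#' @param plant_core_fraction Fraction of each reference metabolome drawn
#'   from the plant-core pool shared across species.
#' @param shared_backbone_fraction Fraction of the tobaccos' non-core
#'   features common to the cured-series species (NT and NR).
#' @param curing_specific_count Features induced in each cured sample and
#'   absent from the freeze-dried state.
#' @param vessel_content_profile Named inclusion probabilities for vessel
#'   contents; names are species codes, with the suffix `_cured` denoting
#'   the cured preparation of a tobacco (base metabolome plus all
#'   curing-induced features).
#' @param taphonomic_survival Probability a content feature survives burial.
#' @param curation_survival Additional survival probability applied to
#'   curated vessels' features (restorative cleansing).
#' @param contaminant_count Laboratory contaminants per solvent system.
#' @param contaminant_carryover Probability a contaminant shows up in any
#'   given sample extract (or in a blank of another solvent).
#' @param soil_features_per_site Site-specific soil features shared by
#'   vessels buried at the same site.
#' @param mz_range,rt_range Instrument scan range (Da) and analysis time
#'   window (min).
#' @param mz_min_spacing Minimum spacing between true feature m/z values
#'   (Da); the default is five times the 10-ppm matching window at the top
#'   of the scan range, so alignment ground truth is unambiguous.
#' @param mz_jitter_ppm,rt_jitter_min Observation-level measurement noise
#'   (sd, ppm and minutes).
#' @param mz_jitter_cap_ppm,rt_jitter_cap_min Hard bounds on the
#'   measurement error (truncated-normal jitter). The defaults — half the
#'   matching window in each dimension — model a lock-mass-corrected
#'   instrument whose residual error never reaches the matching tolerance,
#'   the regime in which tolerance alignment recovers the planted features
#'   exactly.
#' @param detection_dropout Probability any planned observation is missed.
#' @param seed Integer seed; the whole study is deterministic given it.
#' @return A validated object of class `study_config`.
#' @export
study_config <- function(n_curated_vessels = 12,
                         n_untreated_vessels = 2,
                         reference_panel = default_reference_panel(),
                         features_per_reference = 600,
                         lvi_features = 300,
                         plant_core_fraction = 0.5,
                         shared_backbone_fraction = 0.4,
                         curing_specific_count = 20,
                         vessel_content_profile = c(NT_cured = 0.9, TLU = 0.7),
                         taphonomic_survival = 0.1151,
                         curation_survival = 0.4433,
                         contaminant_count = 30,
                         contaminant_carryover = 0.8,
                         soil_features_per_site = 5,
                         mz_range = c(100, 1200),
                         rt_range = c(0, 16),
                         mz_min_spacing = 0.06,
                         mz_jitter_ppm = 3,
                         rt_jitter_min = 0.02,
                         mz_jitter_cap_ppm = 5,
                         rt_jitter_cap_min = 0.05,
                         detection_dropout = 0.02,
                         seed = 1L) {
  cfg <- structure(as.list(environment()), class = "study_config")
  validate_study_config(cfg)
  cfg
}

validate_study_config <- function(cfg) {
  with(cfg, {
    if (!is_count(n_curated_vessels) || !is_count(n_untreated_vessels) ||
        !is_count(curing_specific_count) || !is_count(contaminant_count) ||
        !is_count(soil_features_per_site)) {
      validation_error("vessel, curing, contaminant and soil counts must be non-negative integers")
    }
    probs <- c(plant_core_fraction, shared_backbone_fraction,
               taphonomic_survival, curation_survival,
               contaminant_carryover, detection_dropout, vessel_content_profile)
    if (!all(vapply(probs, is_prob, logical(1)))) {
      validation_error("all probabilities must lie in [0, 1]")
    }
    if (length(mz_range) != 2L || diff(mz_range) <= 0 ||
        length(rt_range) != 2L || diff(rt_range) <= 0) {
      validation_error("mz_range and rt_range must be ordered pairs")
    }
    if (features_per_reference <= 0 || lvi_features <= 0 ||
        mz_min_spacing <= 0 || mz_jitter_ppm < 0 || rt_jitter_min < 0 ||
        mz_jitter_cap_ppm <= 0 || rt_jitter_cap_min <= 0) {
      validation_error("feature counts, spacing, jitter and jitter caps must be positive")
    }
    if (!all(c("species_code", "curing_state") %in% names(reference_panel)) ||
        nrow(reference_panel) == 0L) {
      validation_error("reference_panel needs species_code and curing_state columns")
    }
    if (!is_count(abs(seed))) validation_error("seed must be an integer")
  })
  invisible(cfg)
}

reference_sample_id <- function(species, curing) {
  ifelse(is.na(curing), species,
         paste0(species, sub("^C", "", curing)))
}

rnorm_trunc <- function(n, sd, cap) {
  if (sd == 0 || n == 0L) return(numeric(n))
  x <- stats::rnorm(n, sd = sd)
  bad <- which(abs(x) > cap)
  while (length(bad)) {
    x[bad] <- stats::rnorm(length(bad), sd = sd)
    bad <- bad[abs(x[bad]) > cap]
  }
  x
}

build_study_metadata <- function(cfg) {
  panel <- cfg$reference_panel
  refs <- data.frame(
    sample_id = reference_sample_id(panel$species_code, panel$curing_state),
    category = "reference",
    species_code = panel$species_code,
    curing_state = panel$curing_state,
    project = NA_character_, treatment = NA_character_,
    form_class = NA_character_, aperture_cm = NA_real_,
    solvent = NA_character_, site = NA_character_,
    stringsAsFactors = FALSE
  )
  n_v <- cfg$n_untreated_vessels + cfg$n_curated_vessels
  v_ids <- sprintf("V%02d", seq_len(n_v))
  forms_u <- rep(c("SF_narrow", "EF"), length.out = cfg$n_untreated_vessels)
  ap_u <- rep(c(0.7, 0.8), length.out = cfg$n_untreated_vessels)
  forms_c <- rep(c(rep("PF_narrow", 9), "SF_narrow", "SF_wide", "SF_wide"),
                 length.out = cfg$n_curated_vessels)
  ap_c <- rep(c(0.8, 0.9, 0.9, 0.8, 1, 1, 0.7, 0.9, 1.2, 1.1, 2.4, 2),
              length.out = cfg$n_curated_vessels)
  sites_c <- rep(c("NE_MID", "NE_MID", "N_MID", "N_MID", "NE_MID", "NE_MID",
                   "NE_MID", "W_MID", "NE_MID", "NE_MID", "NE_MID", "W_MID"),
                 length.out = cfg$n_curated_vessels)
  vessels <- data.frame(
    sample_id = v_ids,
    category = "vessel",
    species_code = NA_character_, curing_state = NA_character_,
    project = c(rep("PASUC", cfg$n_untreated_vessels),
                rep("PARME", cfg$n_curated_vessels)),
    treatment = c(rep("untreated", cfg$n_untreated_vessels),
                  rep("curated", cfg$n_curated_vessels)),
    form_class = c(forms_u, forms_c),
    aperture_cm = c(ap_u, ap_c),
    solvent = NA_character_,
    site = c(rep("UCANHA", cfg$n_untreated_vessels), sites_c),
    stringsAsFactors = FALSE
  )
  blanks <- data.frame(
    sample_id = paste0("BLANK_", SOLVENT_CODES),
    category = "blank",
    species_code = NA_character_, curing_state = NA_character_,
    project = NA_character_, treatment = NA_character_,
    form_class = NA_character_, aperture_cm = NA_real_,
    solvent = SOLVENT_CODES, site = NA_character_,
    stringsAsFactors = FALSE
  )
  rbind(refs, vessels, blanks)
}

#' Generate a complete synthetic study with planted ground truth
#'
#' Produces the feature observations, sample metadata and truth labels for
#' one synthetic study. Reference samples carry their species' feature set
#' (plant-core subset, species-specific features, tobacco backbone where
#' applicable, plus curing-induced features in cured states); vessels carry
#' a thinned subsample of their content species' features plus
#' site-specific soil features; laboratory contaminants are planted in all
#' solvent blanks and, with the carryover probability, in sample extracts.
#' All observations receive bounded m/z and RT measurement jitter and are
#' subject to detection dropout. A single global random stream, consumed in
#' fixed order (pool sizes, core subsets, m/z grid, RT, solvent affinity,
#' vessels, blanks, dropout, jitter), makes the whole study deterministic
#' given `config$seed`.
#'
#' @param config A [study_config()].
#' @return An object of class `synthetic_study`: `observations` (long
#'   feature table, with an extra ground-truth `feature_id` column),
#'   `metadata`, `truth` (feature table and origins, feature species,
#'   vessel contents, per-reference unique-by-construction features,
#'   planted per-sample feature sets) and `config`.
#' @export
generate_study <- function(config = study_config()) {
  validate_study_config(config)
  cfg <- config
  set.seed(cfg$seed)
  metadata <- build_study_metadata(cfg)
  panel <- cfg$reference_panel
  ref_ids <- reference_sample_id(panel$species_code, panel$curing_state)

  ## ---- feature pool sizes -------------------------------------------
  species <- unique(panel$species_code)
  cured_species <- unique(panel$species_code[!is.na(panel$curing_state)])
  mean_size <- ifelse(species == "LVI", cfg$lvi_features, cfg$features_per_reference)
  base_size <- stats::setNames(stats::rpois(length(species), mean_size), species)
  core_pool_n <- round(cfg$plant_core_fraction * cfg$features_per_reference)
  core_n <- pmin(round(cfg$plant_core_fraction * base_size), core_pool_n)
  rest_n <- base_size - core_n
  backbone_n <- 0L
  if (length(cured_species) >= 2L) {
    backbone_n <- min(round(cfg$shared_backbone_fraction *
                              mean(rest_n[cured_species])),
                      rest_n[cured_species])
  }
  spec_n <- rest_n - ifelse(species %in% cured_species, backbone_n, 0L)
  names(spec_n) <- species
  cured_samples <- ref_ids[!is.na(panel$curing_state) & panel$curing_state != "FD"]

  ## ---- per-species plant-core subsets -------------------------------
  core_members <- lapply(stats::setNames(species, species), function(sp) {
    if (core_n[[sp]] >= core_pool_n) seq_len(core_pool_n)
    else sort(sample.int(core_pool_n, core_n[[sp]]))
  })

  sites <- unique(stats::na.omit(metadata$site))
  origins <- c(
    rep("plant-core", core_pool_n),
    rep("shared-backbone", backbone_n),
    rep("species-specific", sum(pmax(spec_n, 0L))),
    rep("curing-induced", length(cured_samples) * cfg$curing_specific_count),
    rep("soil", length(sites) * cfg$soil_features_per_site),
    rep("contaminant", length(SOLVENT_CODES) * cfg$contaminant_count)
  )
  feat_species <- c(
    rep(NA_character_, core_pool_n + backbone_n),
    rep(species, pmax(spec_n, 0L)),
    rep(sub("[0-9]+$", "", cured_samples), each = cfg$curing_specific_count),
    rep(NA_character_, length(sites) * cfg$soil_features_per_site),
    rep(NA_character_, length(SOLVENT_CODES) * cfg$contaminant_count)
  )
  feat_ref_sample <- rep(NA_character_, length(origins))
  feat_ref_sample[origins == "curing-induced"] <-
    rep(cured_samples, each = cfg$curing_specific_count)
  feat_site <- rep(NA_character_, length(origins))
  feat_site[origins == "soil"] <- rep(sites, each = cfg$soil_features_per_site)
  feat_solvent <- rep(NA_character_, length(origins))
  feat_solvent[origins == "contaminant"] <-
    rep(SOLVENT_CODES, each = cfg$contaminant_count)

  n_feat <- length(origins)
  ## ---- true m/z and RT ----------------------------------------------
  grid <- seq(cfg$mz_range[1] + cfg$mz_min_spacing,
              cfg$mz_range[2] - cfg$mz_min_spacing,
              by = cfg$mz_min_spacing)
  if (n_feat > length(grid)) {
    validation_error("feature pool exceeds the spacing-constrained m/z grid; widen mz_range or reduce counts")
  }
  features <- data.frame(
    feature_id = sprintf("F%05d", seq_len(n_feat)),
    mz = sample(grid, n_feat),
    rt = stats::runif(n_feat, cfg$rt_range[1], cfg$rt_range[2]),
    origin = origins, species = feat_species, ref_sample = feat_ref_sample,
    site = feat_site, solvent = feat_solvent,
    stringsAsFactors = FALSE
  )

  ## ---- solvent affinity per feature ---------------------------------
  detectable <- matrix(stats::runif(n_feat * 3) < 0.5, n_feat, 3,
                       dimnames = list(features$feature_id, SOLVENT_CODES))
  none <- !rowSums(detectable)
  if (any(none)) {
    detectable[cbind(which(none), sample.int(3, sum(none), replace = TRUE))] <- TRUE
  }
  # contaminants are laboratory-wide, not solvent-bound
  detectable[features$origin == "contaminant", ] <- TRUE

  ## ---- per-sample feature sets ---------------------------------------
  idx_core_pool <- which(features$origin == "plant-core")
  idx_backbone <- which(features$origin == "shared-backbone")
  species_set <- function(sp) {
    base <- which(features$origin == "species-specific" &
                    !is.na(features$species) & features$species == sp)
    set <- c(idx_core_pool[core_members[[sp]]], base)
    if (sp %in% cured_species) c(set, idx_backbone) else set
  }
  curing_set <- function(ref_id) which(features$origin == "curing-induced" &
                                         !is.na(features$ref_sample) &
                                         features$ref_sample == ref_id)
  sample_sets <- list()
  for (r in seq_len(nrow(panel))) {
    sid <- ref_ids[r]
    set <- species_set(panel$species_code[r])
    if (!is.na(panel$curing_state[r]) && panel$curing_state[r] != "FD") {
      set <- c(set, curing_set(sid))
    }
    sample_sets[[sid]] <- set
  }

  content_set <- function(key) {
    if (grepl("_cured$", key)) {
      sp <- sub("_cured$", "", key)
      cured_of_sp <- cured_samples[sub("[0-9]+$", "", cured_samples) == sp]
      c(species_set(sp), unlist(lapply(cured_of_sp, curing_set)))
    } else {
      species_set(key)
    }
  }
  vessels <- metadata[metadata$category == "vessel", , drop = FALSE]
  vessel_contents <- list()
  for (v in seq_len(nrow(vessels))) {       # RNG: contents then thinning
    vid <- vessels$sample_id[v]
    keys <- names(cfg$vessel_content_profile)
    included <- keys[stats::runif(length(keys)) < cfg$vessel_content_profile]
    vessel_contents[[vid]] <- included
    content <- unique(unlist(lapply(included, content_set)))
    p <- cfg$taphonomic_survival
    if (identical(vessels$treatment[v], "curated")) p <- p * cfg$curation_survival
    content <- content[stats::runif(length(content)) < p]
    soil <- which(features$origin == "soil" & features$site == vessels$site[v])
    if (identical(vessels$treatment[v], "curated")) {
      soil <- soil[stats::runif(length(soil)) < cfg$curation_survival]
    }
    sample_sets[[vid]] <- c(content, soil)
  }

  ## ---- planned observations ------------------------------------------
  plan <- list()
  non_blank <- metadata[metadata$category != "blank", , drop = FALSE]
  contam_idx <- which(features$origin == "contaminant")
  for (sid in non_blank$sample_id) {
    set <- sample_sets[[sid]]
    det <- detectable[set, , drop = FALSE]
    hit <- which(det, arr.ind = TRUE)
    f_i <- set[hit[, 1]]
    e_i <- SOLVENT_CODES[hit[, 2]]
    # contaminant carryover: per (contaminant, extract)
    carry <- matrix(stats::runif(length(contam_idx) * 3) < cfg$contaminant_carryover,
                    length(contam_idx), 3)
    chit <- which(carry, arr.ind = TRUE)
    plan[[sid]] <- data.frame(
      sample_id = sid,
      extract_id = c(e_i, SOLVENT_CODES[chit[, 2]]),
      fidx = c(f_i, contam_idx[chit[, 1]]),
      stringsAsFactors = FALSE
    )
  }
  blanks <- metadata[metadata$category == "blank", , drop = FALSE]
  for (b in seq_len(nrow(blanks))) {
    s <- blanks$solvent[b]
    own <- contam_idx[features$solvent[contam_idx] == s]
    other <- setdiff(contam_idx, own)
    other <- other[stats::runif(length(other)) < cfg$contaminant_carryover]
    plan[[blanks$sample_id[b]]] <- data.frame(
      sample_id = blanks$sample_id[b],
      extract_id = s,
      fidx = c(own, other),
      stringsAsFactors = FALSE
    )
    sample_sets[[blanks$sample_id[b]]] <- c(own, other)
  }
  plan <- do.call(rbind, plan)

  ## ---- detection dropout and measurement jitter ----------------------
  kept <- stats::runif(nrow(plan)) >= cfg$detection_dropout
  plan <- plan[kept, , drop = FALSE]
  n_obs <- nrow(plan)
  true_mz <- features$mz[plan$fidx]
  true_rt <- features$rt[plan$fidx]
  obs <- data.frame(
    sample_id = plan$sample_id,
    extract_id = plan$extract_id,
    mz = true_mz * (1 + rnorm_trunc(n_obs, cfg$mz_jitter_ppm,
                                    cfg$mz_jitter_cap_ppm) * 1e-6),
    rt = pmin(pmax(true_rt + rnorm_trunc(n_obs, cfg$rt_jitter_min,
                                         cfg$rt_jitter_cap_min),
                   cfg$rt_range[1]), cfg$rt_range[2]),
    intensity = stats::rlnorm(n_obs, meanlog = log(1000), sdlog = 1),
    feature_id = features$feature_id[plan$fidx],
    stringsAsFactors = FALSE
  )
  rownames(obs) <- NULL

  unique_by_construction <- lapply(stats::setNames(ref_ids, ref_ids), function(sid) {
    r <- match(sid, ref_ids)
    sp <- panel$species_code[r]
    out <- character(0)
    if (!is.na(panel$curing_state[r])) {
      if (panel$curing_state[r] != "FD") out <- features$feature_id[curing_set(sid)]
    } else if (sum(panel$species_code == sp) == 1L) {
      out <- features$feature_id[features$origin == "species-specific" &
                                   !is.na(features$species) &
                                   features$species == sp]
    }
    out
  })

  # features planted in no sample (e.g. a soil feature thinned out of every
  # vessel of its site) do not exist in the study; truth omits them
  planted_idx <- sort(unique(unlist(sample_sets)))
  truth_features <- features[planted_idx, , drop = FALSE]
  rownames(truth_features) <- NULL
  truth <- list(
    features = truth_features,
    feature_origin = stats::setNames(truth_features$origin,
                                     truth_features$feature_id),
    feature_species = stats::setNames(truth_features$species,
                                      truth_features$feature_id),
    vessel_contents = vessel_contents,
    unique_by_construction = unique_by_construction,
    planted_per_sample = lapply(sample_sets, function(i) features$feature_id[i])
  )
  structure(
    list(observations = obs, metadata = metadata, truth = truth, config = cfg),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf("synthetic_study: %d observations, %d samples, %d planted features (seed %d)\n",
              nrow(x$observations), nrow(x$metadata),
              nrow(x$truth$features), x$config$seed))
  invisible(x)
}

#' Generate only the reference library of a synthetic study
#'
#' Factored view of [generate_study()]: the same study (same seed, same
#' random stream) restricted to reference samples.
#'
#' @param config A [study_config()].
#' @return Named list mapping reference sample id to its observations.
#' @export
generate_reference_library <- function(config = study_config()) {
  study <- generate_study(config)
  refs <- study$metadata$sample_id[study$metadata$category == "reference"]
  lapply(stats::setNames(refs, refs), function(sid) {
    study$observations[study$observations$sample_id == sid, , drop = FALSE]
  })
}

#' Map aligned features back to planted ground-truth features
#'
#' Matches each aligned consensus m/z to the nearest planted true m/z; the
#' generator's minimum m/z spacing (several times the matching tolerance)
#' makes the assignment unambiguous. Features with no planted m/z within
#' tolerance map to `NA`.
#'
#' @param aligned An `aligned_features` object.
#' @param study A `synthetic_study`.
#' @param tol A [tolerance_spec()].
#' @return Named character vector (aligned feature id -> planted feature id).
#' @export
match_features_to_truth <- function(aligned, study, tol = tolerance_spec()) {
  stopifnot(inherits(aligned, "aligned_features"),
            inherits(study, "synthetic_study"))
  tf <- study$truth$features[order(study$truth$features$mz), , drop = FALSE]
  i <- findInterval(aligned$features$mz, tf$mz)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, nrow(tf))
  d_lo <- abs(aligned$features$mz - tf$mz[lo])
  d_hi <- abs(aligned$features$mz - tf$mz[hi])
  best <- ifelse(d_lo <= d_hi, lo, hi)
  d_best <- pmin(d_lo, d_hi)
  ok <- d_best <= mz_tolerance_at(aligned$features$mz, tol)
  out <- ifelse(ok, tf$feature_id[best], NA_character_)
  stats::setNames(out, aligned$features$feature_id)
}

#' Write a synthetic study to a directory
#'
#' Writes `feature_table.csv` (canonical five columns), `metadata.csv` and
#' `truth.json` (feature origins and species, vessel contents, per-reference
#' unique-by-construction features, planted per-sample feature sets).
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(study$observations, file.path(dir, "feature_table.csv"))
  write_sample_metadata(study$metadata, file.path(dir, "metadata.csv"))
  truth <- study$truth
  jsonlite::write_json(
    list(
      feature_origin = as.list(truth$feature_origin),
      feature_species = as.list(truth$feature_species),
      vessel_contents = truth$vessel_contents,
      unique_by_construction = truth$unique_by_construction,
      planted_per_sample = truth$planted_per_sample
    ),
    file.path(dir, "truth.json"), auto_unbox = TRUE, null = "null", na = "null"
  )
  invisible(dir)
}
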
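# shared builders for test fixtures; everything is generated in code

fixture_path <- function(name) {
  system.file("extdata", name, package = "residomics", mustWork = TRUE)
}

table3_annotations <- function() {
  utils::read.csv(fixture_path("table3_features.csv"),
                  colClasses = c(feature_id = "character"),
                  stringsAsFactors = FALSE)
}

table3_matrix <- function() {
  read_presence_matrix(fixture_path("table3_presence.csv"),
                       annotations = table3_annotations())
}

table3_report <- function() {
  ann <- table3_annotations()
  uf <- split(ann$feature_id, ann$reference)
  structure(list(unique_features = uf,
                 counts = vapply(uf, length, integer(1)),
                 level = "sample"),
            class = "uniqueness_report")
}

table1_metadata <- function() {
  read_sample_metadata(fixture_path("table1_vessels.csv"))
}

# small, fast study configuration for module tests
small_config <- function(seed = 1L, ...) {
  study_config(features_per_reference = 80, lvi_features = 40,
               curing_specific_count = 5, contaminant_count = 8,
               soil_features_per_site = 2, seed = seed, ...)
}

# minimal metadata for hand-built alignment fixtures
toy_metadata <- function(samples = c("S1", "S2"), blanks = "TA") {
  rbind(
    data.frame(sample_id = samples, category = "vessel", project = "P",
               treatment = "curated", form_class = "PF_narrow",
               solvent = NA_character_, stringsAsFactors = FALSE),
    if (length(blanks)) {
      data.frame(sample_id = paste0("BLANK_", blanks), category = "blank",
                 project = NA_character_, treatment = NA_character_,
                 form_class = NA_character_, solvent = blanks,
                 stringsAsFactors = FALSE)
    }
  )
}

obs_row <- function(sample_id, mz, rt, intensity = 100, extract_id = "TA") {
  if (length(sample_id) == 0L) {
    return(data.frame(sample_id = character(0), extract_id = character(0),
                      mz = numeric(0), rt = numeric(0), intensity = numeric(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(sample_id = sample_id, extract_id = extract_id, mz = mz, rt = rt,
             intensity = intensity, stringsAsFactors = FALSE)
}

# independent single-linkage clustering of observations by union-find,
# linking pairs within both m/z and RT tolerance
brute_force_single_linkage <- function(obs, tol = tolerance_spec()) {
  n <- nrow(obs)
  parent <- seq_len(n)
  find <- function(i, p) { while (p[i] != i) i <- p[i]; i }
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      mz_tol <- max(tol$mz_ppm * mean(c(obs$mz[i], obs$mz[j])) / 1e6,
                    tol$mz_abs_min)
      if (abs(obs$mz[i] - obs$mz[j]) <= mz_tol &&
          abs(obs$rt[i] - obs$rt[j]) <= tol$rt_min) {
        ri <- find(i, parent); rj <- find(j, parent)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  vapply(seq_len(n), find, integer(1), p = parent)
}

# partition comparison independent of label values
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}

rand_index <- function(a, b) {
  n <- length(a)
  s <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      s <- s + as.integer((a[i] == a[j]) == (b[i] == b[j]))
    }
  }
  s / choose(n, 2)
}

# naive full-lattice formula enumeration (no pruning); oracle for
# enumerate_formulas on small bounds
naive_enumerate <- function(mz, ppm, adduct, bounds) {
  mx <- bounds$max_counts
  grid <- expand.grid(C = 0:mx[["C"]], H = 0:mx[["H"]], N = 0:mx[["N"]],
                      O = 0:mx[["O"]], P = 0:mx[["P"]], S = 0:mx[["S"]])
  masses <- c(C = 12, H = 1.007825, N = 14.003074, O = 15.994915,
              P = 30.973762, S = 31.972071)
  delta <- c(M_plus_H_atom = 1.007825, M_plus_H_proton = 1.007276)[[adduct]]
  theo <- as.matrix(grid) %*% masses[colnames(grid)] + delta
  err <- (theo - mz) / mz * 1e6
  rdbe_val <- grid$C - grid$H / 2 + grid$N / 2 + grid$P / 2 + 1
  keep <- abs(err) <= ppm & rdbe_val >= bounds$rdbe_min
  out <- grid[keep, , drop = FALSE]
  out[do.call(order, out), , drop = FALSE]
}

run_default_study <- function(seed) {
  study <- generate_study(study_config(seed = seed))
  aligned <- align_features(study$observations)
  subtracted <- subtract_blanks(aligned, study$metadata)
  pm <- merge_extracts_and_binarize(subtracted, study$metadata)
  list(study = study, aligned = aligned, subtracted = subtracted, pm = pm)
}
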
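#' Configuration for a full pipeline run
#'
#' Exactly one input mode must be supplied: `simulation` (a
#' [study_config()]; the study is generated in-run), `feature_table` +
#' `metadata` paths (preprocessing starts from observations on disk), or
#' `presence` + `metadata` paths (ingest mode: a pre-binarized occurrence
#' matrix, preprocessing skipped and presence taken as given).
#'
#' @param simulation Optional [study_config()].
#' @param feature_table,metadata,presence Optional input CSV paths.
#' @param feature_annotations Optional CSV path (feature_id, reference, mz,
#'   rt) attributing presence-matrix features to reference samples (ingest
#'   mode).
#' @param tolerance A [tolerance_spec()].
#' @param blank_mode `"global"` or `"per_solvent"` (see [subtract_blanks()]).
#' @param variant Ward variant (see [ward_cluster()]).
#' @param pca_centering,pca_scaling,pca_components PCA settings (see
#'   [pca_presence()]).
#' @param out_dir Output directory.
#' @param seed Integer seed for the run.
#' @param allow_unsubtracted Permit uniqueness computation on a matrix that
#'   skipped blank subtraction.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(simulation = NULL,
                            feature_table = NULL, metadata = NULL,
                            presence = NULL, feature_annotations = NULL,
                            tolerance = tolerance_spec(),
                            blank_mode = c("global", "per_solvent"),
                            variant = c("ward_d2", "ward_d"),
                            pca_centering = "mean", pca_scaling = "none",
                            pca_components = 3L,
                            out_dir = tempfile("residomics_run_"),
                            seed = 1L,
                            allow_unsubtracted = FALSE) {
  blank_mode <- match.arg(blank_mode)
  variant <- match.arg(variant)
  modes <- c(simulate = !is.null(simulation),
             features = !is.null(feature_table),
             presence = !is.null(presence))
  if (sum(modes) != 1L) {
    validation_error("supply exactly one of: simulation config, feature_table path, presence path")
  }
  for (p in c(feature_table, metadata, presence, feature_annotations)) {
    if (!is.null(p) && !file.exists(p)) format_error(paste0("input not found: ", p))
  }
  if ((modes[["features"]] || modes[["presence"]]) && is.null(metadata)) {
    validation_error("feature-table and presence inputs need a metadata path")
  }
  structure(
    list(simulation = simulation, feature_table = feature_table,
         metadata = metadata, presence = presence,
         feature_annotations = feature_annotations,
         tolerance = tolerance, blank_mode = blank_mode, variant = variant,
         pca_centering = pca_centering, pca_scaling = pca_scaling,
         pca_components = as.integer(pca_components),
         out_dir = out_dir, seed = as.integer(seed),
         allow_unsubtracted = isTRUE(allow_unsubtracted)),
    class = "pipeline_config"
  )
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    rd_stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            "residomics_pipeline_error")
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/ingest, preprocessing (alignment, blank
#' subtraction, extract merging), multivariate statistics (Jaccard, Ward,
#' PCA), unique-feature analysis, and writes every artifact plus a run
#' manifest. Identical config and seed give byte-identical outputs
#' (manifests differ only in their timestamps).
#'
#' Outputs under `config$out_dir`: `aligned_features.csv`,
#' `presence_matrix.csv`, `distances.csv`, `tree.nwk`, `scores.csv`,
#' `loadings.csv`, `variance.csv`, `uniqueness.csv`, `sharing.csv`,
#' `manifest.json` (ingest mode skips the preprocessing artifacts).
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package_version = as.character(utils::packageVersion("residomics")),
    seed = config$seed,
    blank_mode = config$blank_mode,
    variant = config$variant,
    started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    stages = list(),
    input_checksums = list()
  )
  counts <- list()

  ingest <- !is.null(config$presence)
  if (!is.null(config$simulation)) {
    cfg <- config$simulation
    cfg$seed <- config$seed
    study <- pipeline_stage("simulate", generate_study(cfg))
    obs <- study$observations
    metadata <- study$metadata
    counts$observations <- nrow(obs)
  } else if (!is.null(config$feature_table)) {
    metadata <- pipeline_stage("read_metadata", read_sample_metadata(config$metadata))
    obs <- pipeline_stage("read_features",
                          read_feature_table(config$feature_table, metadata))
    counts$observations <- nrow(obs)
    for (p in c(config$feature_table, config$metadata)) {
      manifest$input_checksums[[basename(p)]] <- unname(tools::md5sum(p))
    }
  } else {
    metadata <- pipeline_stage("read_metadata", read_sample_metadata(config$metadata))
    ann <- NULL
    if (!is.null(config$feature_annotations)) {
      ann <- utils::read.csv(config$feature_annotations, stringsAsFactors = FALSE,
                             colClasses = c(feature_id = "character"))
    }
    pm <- pipeline_stage("read_presence",
                         read_presence_matrix(config$presence, annotations = ann))
    for (p in c(config$presence, config$metadata)) {
      manifest$input_checksums[[basename(p)]] <- unname(tools::md5sum(p))
    }
  }

  if (!ingest) {
    aligned <- pipeline_stage("align", align_features(obs, config$tolerance))
    counts$aligned_features <- nrow(aligned$features)
    subtracted <- pipeline_stage("subtract_blanks",
                                 subtract_blanks(aligned, metadata, config$blank_mode))
    counts$after_blank_subtraction <- nrow(subtracted$features)
    pm <- pipeline_stage("binarize", merge_extracts_and_binarize(subtracted, metadata))
    counts$matrix_features <- nrow(pm$cells)
    utils::write.csv(
      cbind(subtracted$features[c("feature_id", "mz", "rt", "n_members")]),
      file.path(config$out_dir, "aligned_features.csv"),
      row.names = FALSE, quote = FALSE, eol = "\n")
    stopifnot(counts$aligned_features >= counts$after_blank_subtraction,
              counts$after_blank_subtraction >= counts$matrix_features)
  } else {
    counts$matrix_features <- nrow(pm$cells)
  }
  write_presence_matrix(pm, file.path(config$out_dir, "presence_matrix.csv"))

  d <- pipeline_stage("jaccard", jaccard_distances(pm))
  utils::write.csv(data.frame(sample_id = rownames(d), d, check.names = FALSE),
                   file.path(config$out_dir, "distances.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  tree <- pipeline_stage("ward", ward_cluster(d, config$variant))
  write_newick(tree, file.path(config$out_dir, "tree.nwk"))
  k <- min(config$pca_components, dim(pm$cells))
  pca <- pipeline_stage("pca", pca_presence(pm, centering = config$pca_centering,
                                            scaling = config$pca_scaling,
                                            n_components = k))
  utils::write.csv(data.frame(sample_id = rownames(pca$scores), pca$scores,
                              check.names = FALSE),
                   file.path(config$out_dir, "scores.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  utils::write.csv(data.frame(feature_id = rownames(pca$loadings), pca$loadings,
                              check.names = FALSE),
                   file.path(config$out_dir, "loadings.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")
  utils::write.csv(data.frame(component = seq_along(pca$explained_variance),
                              explained_variance = pca$explained_variance),
                   file.path(config$out_dir, "variance.csv"),
                   row.names = FALSE, quote = FALSE, eol = "\n")

  has_refs <- any(metadata$category == "reference" &
                    metadata$sample_id %in% colnames(pm$cells))
  has_attribution <- ingest && !is.null(config$feature_annotations)
  if (has_refs || has_attribution) {
    if (has_attribution) {
      # externally attributed unique features: presence taken as given
      ann <- pm$annotations
      attrib <- utils::read.csv(config$feature_annotations,
                                stringsAsFactors = FALSE,
                                colClasses = c(feature_id = "character"))
      report <- pipeline_stage("unique", structure(
        list(unique_features = split(attrib$feature_id, attrib$reference),
             counts = vapply(split(attrib$feature_id, attrib$reference),
                             length, integer(1)),
             level = "sample"),
        class = "uniqueness_report"))
    } else {
      report <- pipeline_stage("unique",
                               find_unique_features(pm, metadata,
                                                    allow_unsubtracted = config$allow_unsubtracted))
    }
    sharing <- pipeline_stage("sharing", build_sharing_table(pm, report, metadata))
    counts$unique_features <- sum(report$counts)
    counts$shared_unique_features <- ncol(sharing$cells)
    utils::write.csv(
      data.frame(reference = rep(names(report$unique_features),
                                 lengths(report$unique_features)),
                 feature_id = unlist(report$unique_features, use.names = FALSE)),
      file.path(config$out_dir, "uniqueness.csv"),
      row.names = FALSE, quote = FALSE, eol = "\n")
    write_sharing_table(sharing, file.path(config$out_dir, "sharing.csv"))
  }

  manifest$per_stage_counts <- counts
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(manifest)
}
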
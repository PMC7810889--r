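#!/usr/bin/env Rscript
# Generate the synthetic study the downstream analyses run on: 12 plant
# references (two tobaccos in three curing states, six other candidate
# species), 14 vessels (12 curated, 2 untreated), 3 solvent blanks, with
# planted ground truth for every feature. Writes the long feature table,
# sample metadata and truth labels under results/study/.

suppressPackageStartupMessages(library(residomics))

seed <- as.integer(Sys.getenv("STUDY_SEED", "1"))
out <- "results/study"

study <- generate_study(study_config(seed = seed))
write_study(study, out)

meta <- study$metadata
cat(sprintf("study (seed %d): %d observations across %d samples\n",
            seed, nrow(study$observations), nrow(meta)))
cat(sprintf("  references: %d, vessels: %d (%d curated / %d untreated), blanks: %d\n",
            sum(meta$category == "reference"),
            sum(meta$category == "vessel"),
            sum(meta$treatment == "curated", na.rm = TRUE),
            sum(meta$treatment == "untreated", na.rm = TRUE),
            sum(meta$category == "blank")))
origin <- table(study$truth$feature_origin)
cat("  planted features by origin:\n")
print(origin)
cat("written to", out, "\n")
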
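#!/usr/bin/env Rscript
# Exploratory statistics on the presence matrix: Jaccard distances between
# sample profiles, Ward minimum-variance clustering (exported as Newick),
# and PCA of the binary matrix, re-run on nested sample subsets the way the
# original analysis descends from the full collection to vessels only.

suppressPackageStartupMessages(library(residomics))

metadata <- read_sample_metadata("results/study/metadata.csv")
ann <- utils::read.csv("results/feature_annotations.csv",
                       colClasses = c(feature_id = "character"))
pm <- read_presence_matrix("results/presence_matrix.csv", annotations = ann)

d <- jaccard_distances(pm)
utils::write.csv(data.frame(sample_id = rownames(d), d, check.names = FALSE),
                 "results/distances.csv", row.names = FALSE)

tree <- ward_cluster(d)
write_newick(tree, "results/tree.nwk")
groups <- cut_tree(tree, 2)
split_tab <- table(groups, metadata$category[match(names(groups),
                                                   metadata$sample_id)])
cat("two-group cut of the Ward tree vs sample category:\n")
print(split_tab)

pca <- pca_presence(pm, n_components = 3)
utils::write.csv(data.frame(sample_id = rownames(pca$scores), pca$scores),
                 "results/pca_scores_all.csv", row.names = FALSE)
pct <- 100 * pca$explained_variance / sum(pca_presence(pm)$explained_variance)
cat(sprintf("PCA (all samples): PC1 %.1f%%, PC2 %.1f%%, PC3 %.1f%%\n",
            pct[1], pct[2], pct[3]))

# vessels plus the two references most entangled with them
keep_b <- c(metadata$sample_id[metadata$category == "vessel"], "TLU", "LVI")
pm_b <- subset_presence(pm, intersect(keep_b, sample_ids(pm)))
pca_b <- pca_presence(pm_b, n_components = 2)
utils::write.csv(data.frame(sample_id = rownames(pca_b$scores), pca_b$scores),
                 "results/pca_scores_vessels_tlu_lvi.csv", row.names = FALSE)

# curated vessels only
keep_c <- metadata$sample_id[!is.na(metadata$treatment) &
                               metadata$treatment == "curated"]
pm_c <- subset_presence(pm, intersect(keep_c, sample_ids(pm)))
pca_c <- pca_presence(pm_c, n_components = 2)
utils::write.csv(data.frame(sample_id = rownames(pca_c$scores), pca_c$scores),
                 "results/pca_scores_curated.csv", row.names = FALSE)
cat(sprintf("subset PCAs: %d features retained for vessels+TLU+LVI, %d for curated only\n",
            nrow(pm_b$cells), nrow(pm_c$cells)))
cat("wrote results/distances.csv, tree.nwk, pca_scores_*.csv\n")
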
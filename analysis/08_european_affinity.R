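#!/usr/bin/env Rscript
# Stage 8: European-affinity decomposition over time bins.
#
# For each canonical length bin, the community x EU-reference affinity
# matrix (mean cM shared per cross pair) is decomposed with a PCA
# biplot. Loadings track which reference cluster drives community
# separation in each time stratum.

suppressPackageStartupMessages(library(ibdscape))

data_dir <- "scratch/analysis"
ibd <- read_segments(file.path(data_dir, "cohort.ibd"))
asg <- utils::read.table("results/communities.tsv", header = TRUE,
                         sep = "\t", colClasses = "character")
ids <- sort(unique(c(ibd$sample1, ibd$sample2)))
eu <- ids[grepl("^EU", ids)]
ref <- data.frame(sample_id = eu, level1 = sub("_.*$", "", eu))

rows <- list()
for (bin in canonical_bins()) {
  am <- affinity_matrix(ibd, asg, ref, bin)
  lb <- ibdscape:::bin_label(bin)
  bp <- tryCatch(pca_biplot(am), error = function(e) NULL)
  if (is.null(bp)) {
    # deep-split references share almost no long segments with the
    # cohort, so recent bins can be empty of cross-sharing
    message(sprintf("bin %s: no cross-sharing variance; skipped", lb))
    next
  }
  message(sprintf("bin %s: PC1 %.0f%% of variance; loadings EU1 %.2f, EU2 %.2f",
                  lb, 100 * bp$var_explained[1],
                  bp$loadings["EU1", 1], bp$loadings["EU2", 1]))
  rows[[lb]] <- data.frame(bin = lb,
                           community = rownames(bp$scores),
                           PC1 = bp$scores[, 1], PC2 = bp$scores[, 2])
}
utils::write.table(do.call(rbind, rows), "results/affinity_pca.tsv",
                   sep = "\t", quote = FALSE, row.names = FALSE)
message("wrote results/affinity_pca.tsv")
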
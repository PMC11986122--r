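#!/usr/bin/env Rscript
# Stage 7: Gaussian naive Bayes regional-ancestry classifier.
#
# Features: per length bin, each sample's total cM shared with every
# level-2 reference community (self-sharing excluded). Trained on a
# stratified 80% split of the labeled cohort and validated on the rest,
# mimicking prediction of regional ancestry for unlabeled query sets.

suppressPackageStartupMessages(library(ibdscape))

data_dir <- "scratch/analysis"
ibd <- read_segments(file.path(data_dir, "cohort.ibd"))
asg <- utils::read.table("results/communities.tsv", header = TRUE,
                         sep = "\t", colClasses = "character")
lab <- stats::setNames(asg$level2, asg$sample_id)
big <- names(which(table(lab) >= 8))
lab <- lab[lab %in% big]

feats <- feature_matrix(ibd, asg, names(lab), level = "level2")
sp <- stratified_split(unname(lab), fraction = 0.8, seed = 2701)
model <- nb_train(feats[sp$train, , drop = FALSE], unname(lab)[sp$train])
ev <- nb_evaluate(model, feats[sp$validation, , drop = FALSE],
                  unname(lab)[sp$validation])
message(sprintf("validation accuracy: %.1f%% over %d held-out samples",
                100 * ev$accuracy, length(sp$validation)))
message("per-class recall: ",
        paste(sprintf("%s=%.2f", names(ev$recall), ev$recall),
              collapse = ", "))

pred <- nb_predict(model, feats[sp$validation, , drop = FALSE])
utils::write.table(pred, "results/ancestry_predictions.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote results/ancestry_predictions.tsv")
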
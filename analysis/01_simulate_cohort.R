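#!/usr/bin/env Rscript
# Stage 1: simulate the study cohort.
#
# Eight populations emulate the structure the downstream analyses probe:
# three small-Ne "Irish-like" communities with recent splits among
# themselves (IR1-IR3), two larger "British-like" communities (BR1, BR2),
# one strongly isolated small community with a recent bottleneck (ISO,
# an Orkney/Man-like isolate), and two deep-split continental reference
# clusters (EU1, EU2) used only for the affinity PCA. Surname origins are
# community-structured; genotypes are drawn at Hardy-Weinberg (f = 0) so
# any F_ROH inflation downstream reflects small Ne, not consanguinity.
#
# Raw segment files go to scratch/analysis/ (they are large); small
# tables go to results/.

suppressPackageStartupMessages(library(ibdscape))

data_dir <- "scratch/analysis"
dir.create(data_dir, showWarnings = FALSE, recursive = TRUE)
dir.create("results", showWarnings = FALSE)

genome <- default_genome()

model <- demography_model(
  populations = list(
    IR1 = 1200, IR2 = 1200, IR3 = 1500,
    BR1 = 3500, BR2 = 3000,
    ISO = data.frame(g_start = c(1, 11), g_end = c(10, 300),
                     N = c(400, 1500)),
    EU1 = 4000, EU2 = 4000),
  splits = local({
    pops <- c("IR1", "IR2", "IR3", "BR1", "BR2", "ISO", "EU1", "EU2")
    grp <- c(IR1 = "irish", IR2 = "irish", IR3 = "irish",
             BR1 = "british", BR2 = "british", ISO = "british",
             EU1 = "eu", EU2 = "eu")
    idx <- utils::combn(pops, 2)
    gen <- mapply(function(a, b) {
      if (grp[a] == "irish" && grp[b] == "irish") 35
      else if (grp[a] == grp[b] && grp[a] == "british") 60
      else if (grp[a] == grp[b]) 150 # EU1-EU2
      else if ("EU1" %in% c(a, b)) 100 # the nearer continental cluster
      else if ("EU2" %in% c(a, b)) 150
      else 80 # Irish-British
    }, idx[1, ], idx[2, ])
    data.frame(a = idx[1, ], b = idx[2, ], generation = gen)
  }),
  ancestral = 6000)

n_per_pop <- stats::setNames(rep(18L, 8),
                             c("IR1", "IR2", "IR3", "BR1", "BR2", "ISO",
                               "EU1", "EU2"))

message("simulating IBD segments ...")
ibd <- simulate_ibd(model, n_per_pop, genome, seed = 2101)
message(format(nrow(ibd), big.mark = ","), " IBD segments")
write_segments(ibd, file.path(data_dir, "cohort.ibd"))

message("simulating ROH segments ...")
roh <- simulate_roh(model, n_per_pop, genome, seed = 2102)
message(format(nrow(roh), big.mark = ","), " ROH segments")
write_segments(roh, file.path(data_dir, "cohort.hbd"))

message("simulating genotypes (HWE, f = 0) ...")
ids <- sort(unique(c(ibd$sample1, ibd$sample2)))
geno <- simulate_genotypes(length(ids), 5000, 0, seed = 2103,
                           sample_ids = ids)
write_genotypes(geno$genotypes, file.path(data_dir, "cohort_genotypes.tsv"))

message("assigning community-structured surname origins ...")
pop <- sub("_.*$", "", ids)
# Gallowglass/Scottish surnames concentrate in IR3 (the Ulster-like
# community); English origins in the British groups
em <- rbind(
  IR1 = c(Irish = 0.70, Scottish = 0.10, English = 0.15, Gallowglass = 0.05),
  IR2 = c(0.70, 0.10, 0.15, 0.05),
  IR3 = c(0.40, 0.25, 0.10, 0.25),
  BR1 = c(0.10, 0.15, 0.70, 0.05),
  BR2 = c(0.10, 0.30, 0.55, 0.05),
  ISO = c(0.15, 0.40, 0.40, 0.05),
  EU1 = c(0.25, 0.25, 0.25, 0.25),
  EU2 = c(0.25, 0.25, 0.25, 0.25))
meta <- simulate_surnames(stats::setNames(pop, ids),
                          colnames(em), em, seed = 2104)
write_metadata(meta, file.path(data_dir, "cohort_metadata.tsv"))

message("cohort written under ", data_dir)
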
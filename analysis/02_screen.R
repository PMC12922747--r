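#!/usr/bin/env Rscript
# Step 2 — run the synthetic screens and score enhancer activity.
#
# Reads the designed libraries from step 1, simulates count matrices for a
# primary (PRI) and a metastatic (MET) cell line on the shared SNP library
# (each with its own planted allelic effects) and a methylation screen on
# the CpG-window library (methylated vs unmethylated plasmid arms).
# Demonstrates the read-level quantification round trip on a subset, then
# normalizes, computes EAS = normalized(RNA + 1)/normalized(DNA), derives
# per-variant log2 fold changes and calls hits with knee-point thresholds
# plus the replicate t test.

suppressPackageStartupMessages(library(starrscreen))
stopifnot(file.exists("results/library/snp_manifest.tsv"))
dir.create("results/screen", showWarnings = FALSE, recursive = TRUE)

manifest <- read_manifest("results/library/snp_manifest.tsv")
methyl <- read_manifest("results/library/methyl_manifest.tsv")

## shared biology: the PRI screen plants allelic effects in 5% of variants;
## the MET screen keeps those and acquires effects in 5% more variants.
## The demo screens are sequenced deep (1000 reads/oligo) so that most
## planted effects clear the BH-adjusted replicate t test.
pri_cfg <- sim_config(seed = 201L, effect_fraction = 0.05,
                      effect_log2fc = 1.5, dna_depth_mean = 1000,
                      nb_dispersion = 0.001)
pri_truth <- gen_counts(manifest, pri_cfg, cell_line = "PRI")$truth
set.seed(205L)
acquired <- sample(which(!pri_truth$affected),
                   round(0.05 * nrow(pri_truth)))
met_truth <- pri_truth
met_truth$affected[acquired] <- TRUE
met_truth$effect[acquired] <- 1.5 * sample(c(-1, 1), length(acquired), TRUE)

screens <- list(
  PRI = list(cfg = pri_cfg, truth = pri_truth),
  MET = list(cfg = sim_config(seed = 202L, effect_log2fc = 1.5,
                              dna_depth_mean = 1000,
                              nb_dispersion = 0.001),
             truth = met_truth))

for (cl in names(screens)) {
  cfg <- screens[[cl]]$cfg
  sim <- gen_counts(manifest, cfg, cell_line = cl,
                    truth = screens[[cl]]$truth)
  write_counts(sim$counts, sim$samples,
               sprintf("results/screen/%s_counts.tsv", cl),
               sprintf("results/screen/%s_samples.tsv", cl))
  write.table(sim$truth, sprintf("results/screen/%s_truth.tsv", cl),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sc <- score_screen(sim$counts, sim$samples, manifest)
  calls <- screen_call(sc$variants)
  cat(sprintf("%s: %d qualified variants, knee thresholds [%.2f, %.2f], %d called\n",
              cl, sum(calls$table$qualified), calls$left, calls$right,
              sum(calls$table$called)))
  write.table(sc$eas, sprintf("results/screen/%s_eas.tsv", cl), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_calls(calls, sprintf("results/screen/%s_calls.tsv", cl),
              sprintf("results/screen/%s_thresholds.json", cl))
}

## read-level quantification round trip on a 12-oligo subset
sub <- manifest[1:12, ]
sub_sim <- gen_counts(sub, sim_config(seed = 203L, dna_depth_mean = 50))
reads <- sim_reads(sub_sim$counts[, 1:2], sub)
for (s in names(reads))
  write_fastq(reads[[s]], sprintf("results/screen/demo_%s.fastq", s))
counted <- count_oligos(reads, sub)
cat(sprintf("read round trip: %s (tallies: %d reads, %d matched)\n",
            ifelse(identical(counted$counts, sub_sim$counts[, 1:2]),
                   "counts reproduced exactly", "MISMATCH"),
            sum(counted$tally$n_reads), sum(counted$tally$matched)))

## methylation screen: methylated vs unmethylated arms
mcfg <- sim_config(seed = 204L, effect_fraction = 0.1, effect_log2fc = -1.5,
                   dna_depth_mean = 1000, nb_dispersion = 0.001)
msim <- gen_counts(methyl, mcfg, cell_line = "MET")
msc <- score_screen(msim$counts, msim$samples, methyl)
mcalls <- screen_call(msc$variants)
cat(sprintf("methyl screen: %d windows, thresholds [%.2f, %.2f], %d methylation-sensitive\n",
            sum(mcalls$table$qualified), mcalls$left, mcalls$right,
            sum(mcalls$table$called)))
write_calls(mcalls, "results/screen/MET_methyl_calls.tsv",
            "results/screen/MET_methyl_thresholds.json")
cat("screens written to results/screen/\n")
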
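#!/usr/bin/env Rscript
# Step 1 — design the reporter libraries on a synthetic study system.
#
# Builds a toy genome with a SNP panel (phased haplotypes, per-population
# MAFs, planted LD blocks) and paired H3K27ac/ATAC peak sets for two cell
# lines; then applies the library-design rules: MAF >= 0.05 in EUR and EAS,
# LD-proxy expansion (r2 >= 0.5, +/-500 kb) of a set of lead SNPs,
# enhancer localization (peak intersection), the union bookkeeping, 120-bp
# allele-substituted SNP oligos and CpG windows at H3K27ac summits.

suppressPackageStartupMessages(library(starrscreen))
dir.create("results/library", showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 101L, n_snps = 800L, chrom_length = 500000L,
                  n_haplotypes = 400L)
genome <- gen_genome(cfg)
sp <- gen_snp_panel(cfg, genome)
peaks <- gen_peaks(cfg, genome, n_sets = 2L, n_peaks = 120L,
                   overlap_fraction = 0.6)
names(peaks) <- c("PRI", "MET")

write_genome_fasta(genome, "results/library/genome.fa")
write_snp_panel(sp$panel, "results/library/snp_panel.tsv")
write_haplotypes(sp$haplotypes, "results/library/haplotypes.tsv")
for (cl in names(peaks)) {
  write_bed(peaks[[cl]]$h3k27ac,
            sprintf("results/library/%s_h3k27ac.bed", cl))
  write_bed(peaks[[cl]]$atac, sprintf("results/library/%s_atac.bed", cl))
}

## common SNPs and enhancer localization
common <- filter_common_snps(sp$panel, threshold = 0.05,
                             populations = c("EUR", "EAS"))
enhancers <- intersect_peaks(peaks$PRI$h3k27ac, peaks$PRI$atac)
enhancer_snps <- snps_in_intervals(common, enhancers)
cat(sprintf("MAF filter kept %d / %d SNPs; %d localize to the %d enhancers\n",
            nrow(common), nrow(sp$panel), nrow(enhancer_snps),
            nrow(enhancers)))

## GWAS arm: lead SNPs plus LD proxies
set.seed(cfg$seed)
leads <- sample(common$id, 25L)
ld <- ld_expand(leads, sp$panel, sp$haplotypes, r2_min = 0.5,
                window = 500000)
gwas <- merge_candidate_sets(ld$leads, ld$proxies)
cat(sprintf("GWAS arm: %d leads + %d LD proxies = %d SNPs\n",
            length(ld$leads), length(ld$proxies), gwas$n_union))

## union bookkeeping and oligo synthesis
u <- merge_candidate_sets(gwas$union, enhancer_snps$id)
cat(sprintf("union: |GWAS| = %d, |enhancer| = %d, overlap = %d, union = %d\n",
            u$n_a, u$n_b, u$n_common, u$n_union))
candidates <- sp$panel[sp$panel$id %in% u$union, ]
manifest <- design_snp_oligos(candidates, genome)
cat(sprintf("SNP library: %d oligos for %d variants (ref + alts, 170 nt)\n",
            nrow(manifest), length(unique(manifest$variant_id))))

## methylation library: CpG windows at MET H3K27ac summits
methyl <- design_methyl_windows(peaks$MET$h3k27ac, genome)
cat(sprintf("methyl library: %d CpG windows (mean %.1f CpGs per window)\n",
            nrow(methyl), mean(methyl$cpg_count)))

write_manifest(manifest, "results/library/snp_manifest.tsv",
               "results/library/snp_oligos.fa")
write_manifest(methyl, "results/library/methyl_manifest.tsv",
               "results/library/methyl_oligos.fa")
summary <- data.frame(
  quantity = c("panel_snps", "common_snps", "enhancers", "enhancer_snps",
               "gwas_leads", "ld_proxies", "union_candidates",
               "snp_oligos", "methyl_windows"),
  value = c(nrow(sp$panel), nrow(common), nrow(enhancers),
            nrow(enhancer_snps), length(ld$leads), length(ld$proxies),
            u$n_union, nrow(manifest), nrow(methyl)))
write.table(summary, "results/library/design_summary.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("library design written to results/library/\n")
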
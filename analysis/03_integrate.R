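#!/usr/bin/env Rscript
# Step 3 — integrate the two screens and prioritize metastasis-acquired
# variants.
#
# Compares the PRI and MET call sets (overlap + Fisher enrichment), maps the
# shared hits onto enhancer regions of several synthetic "cancer types",
# links MET-specific hits to up-regulated genes within 1 Mb of their TSS and
# applies the four-criterion prioritization (MET-specific call,
# MET-specific peak, DEG proximity, bZIP-type motif disruption).

suppressPackageStartupMessages(library(starrscreen))
stopifnot(file.exists("results/screen/PRI_calls.tsv"))
dir.create("results/integration", showWarnings = FALSE, recursive = TRUE)

manifest <- read_manifest("results/library/snp_manifest.tsv")
pri <- read_calls("results/screen/PRI_calls.tsv",
                  "results/screen/PRI_thresholds.json")
met <- read_calls("results/screen/MET_calls.tsv",
                  "results/screen/MET_thresholds.json")

## overlap between the cell lines
cmp <- compare_cell_lines(pri, met)
universe <- length(intersect(
  unique(pri$table$variant_id[pri$table$qualified & !is.na(pri$table$p)]),
  unique(met$table$variant_id[met$table$qualified & !is.na(met$table$p)])))
n_pri <- length(cmp$common) + length(cmp$a_only)
n_met <- length(cmp$common) + length(cmp$b_only)
p_overlap <- fisher_overlap(length(cmp$common), n_pri, n_met, universe)
cat(sprintf("calls: PRI %d, MET %d, common %d (universe %d); Fisher P = %.3g\n",
            n_pri, n_met, length(cmp$common), universe, p_overlap))
cat(sprintf("MET-specific loci (tested in PRI, called only in MET): %d\n",
            length(cmp$b_only)))

## pan-cancer coverage of the common hits
ref_rows <- manifest[manifest$is_ref, ]
hit_snps <- data.frame(variant_id = cmp$common,
                       chrom = ref_rows$chrom[match(cmp$common,
                                                    ref_rows$variant_id)],
                       pos = ref_rows$start[match(cmp$common,
                                                  ref_rows$variant_id)] + 61L,
                       stringsAsFactors = FALSE)
crc_enh <- intersect_peaks(read_bed("results/library/PRI_h3k27ac.bed"),
                           read_bed("results/library/PRI_atac.bed"))
other <- gen_peaks(sim_config(seed = 301L, chrom_length = 500000L),
                   read_genome_fasta("results/library/genome.fa"),
                   n_sets = 2L, n_peaks = 120L, overlap_fraction = 0.3)
maps <- list(CRC = crc_enh,
             HNSC = intersect_peaks(other$set1$h3k27ac, other$set1$atac),
             STAD = intersect_peaks(other$set2$h3k27ac, other$set2$atac))
if (nrow(hit_snps) > 0) {
  cov <- pan_cancer_coverage(hit_snps, maps)
  print(cov)
  write.table(cov, "results/integration/pan_cancer_coverage.tsv",
              sep = "\t", quote = FALSE, row.names = FALSE)
} else {
  cat("no common hits to map across cancer types\n")
}

## Metastasis-acquired annotation layers. The peak/DEG generators know
## nothing about the screens, so the acquired biology is planted here around
## the MET-specific hits: enhancer gain (acquired H3K27ac) over the first
## two thirds of them, an up-regulated gene within 1 Mb of the first half,
## and a bZIP-type binding site whose consensus matches the reference allele
## of the first hit (its alternative allele therefore disrupts the site).
set.seed(302L)
spec_rows <- ref_rows[match(cmp$b_only, ref_rows$variant_id), ]
stopifnot(nrow(spec_rows) > 0)
take <- function(frac) spec_rows[seq_len(ceiling(frac * nrow(spec_rows))), ]

gain <- take(2 / 3)
met_peaks <- rbind(
  specific_peaks(read_bed("results/library/MET_h3k27ac.bed"),
                 read_bed("results/library/PRI_h3k27ac.bed"))[,
    c("chrom", "start", "end", "name")],
  data.frame(chrom = gain$chrom, start = pmax(0L, gain$start - 200L),
             end = gain$end + 200L,
             name = paste0("gain_", gain$variant_id)))

near <- take(1 / 2)
degs_all <- rbind(
  data.frame(gene = paste0("UP_", near$variant_id), chrom = near$chrom,
             tss = near$start + sample(-8e5:8e5, nrow(near), TRUE),
             log2fc = runif(nrow(near), 0.9, 3), padj = 1e-4),
  data.frame(gene = paste0("BG_", seq_len(40)), chrom = "chr1",
             tss = sample.int(500000L, 40),
             log2fc = runif(40, -0.5, 0.74), padj = runif(40)))
degs_all$tss <- pmax(1L, pmin(500000L, degs_all$tss))
degs <- deg_filter(degs_all)
cat(sprintf("DEG filter kept %d / %d genes (log2FC > 0.75, Padj < 0.05)\n",
            nrow(degs), nrow(degs_all)))
links <- link_to_tss(hit_snps, degs)
cat(sprintf("%d common hits link to >= 1 up-regulated gene within 1 Mb\n",
            length(unique(links$variant_id))))

pwms <- read_jaspar(system.file("extdata", "synthetic_bzip_tre.pfm",
                                package = "starrscreen"))
cons <- strsplit(substr(spec_rows$insert_seq[1], 58, 65), "")[[1]]
pwms$planted_site <- pwm(sapply(cons, function(b)
  as.numeric(c("A", "C", "G", "T") == b)), id = "planted_site")

prio <- prioritize_metastasis(pri, met, met_peaks, degs, pwms, manifest)
cat(sprintf("prioritization: %d called alleles -> %d pass all four criteria\n",
            nrow(prio), sum(prio$prioritized)))
cat(sprintf("  criterion breakdown: specific %d, peak %d, deg %d, motif %d\n",
            sum(prio$crit_specific), sum(prio$crit_peak),
            sum(prio$crit_deg), sum(prio$crit_motif)))
write.table(prio, "results/integration/prioritized_variants.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
cat("integration written to results/integration/\n")
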
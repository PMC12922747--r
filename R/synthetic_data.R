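#' Simulation configuration for a synthetic reporter screen
#'
#' Bundles every knob of the synthetic-data generators. Defaults describe the
#' screen layout emulated throughout: three biological replicates, each
#' re-sequenced as three technical replicates, with negative-binomial count
#' noise on top of per-oligo abundances.
#'
#' @param seed integer seed; a fixed seed makes every generator byte-identical.
#' @param n_chroms number of chromosomes in the toy genome.
#' @param chrom_length chromosome length in bp (>= 1000).
#' @param n_snps number of SNPs in the panel.
#' @param n_haplotypes number of phased haplotypes.
#' @param n_bio_reps biological replicates (>= 2).
#' @param n_tech_reps technical (re-sequencing) replicates per biological one.
#' @param dna_depth_mean expected DNA reads per oligo per sample.
#' @param rna_depth_mean expected RNA reads per oligo per sample for a
#'   baseline-activity oligo; defaults to \code{dna_depth_mean}.
#' @param nb_dispersion negative-binomial dispersion alpha, variance
#'   \eqn{\mu + \alpha\mu^2}. Default 0.002 reflects the near-Poisson
#'   reproducibility reporter screens show between replicate libraries.
#' @param effect_fraction fraction of variants with a planted allelic (or
#'   methylation) effect.
#' @param effect_log2fc magnitude of planted effects, log2 units; signs are
#'   drawn at random per affected variant.
#' @param abundance_sdlog lognormal spread of per-oligo library abundance.
#' @param activity_sdlog lognormal spread of per-oligo baseline activity.
#' @param bio_jitter_sdlog lognormal spread of the per-(oligo, biological
#'   replicate) abundance shared by DNA and RNA libraries of that replicate
#'   (technical replicates re-sample it with counting noise only).
#' @param sizefactor_sdlog lognormal spread of per-sample sequencing depth,
#'   exercised by the normalization step.
#' @return A list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 1L,
                       chrom_length = 1e6,
                       n_snps = 200L,
                       n_haplotypes = 200L,
                       n_bio_reps = 3L,
                       n_tech_reps = 3L,
                       dna_depth_mean = 200,
                       rna_depth_mean = dna_depth_mean,
                       nb_dispersion = 0.002,
                       effect_fraction = 0.05,
                       effect_log2fc = 1.5,
                       abundance_sdlog = 0.3,
                       activity_sdlog = 0.5,
                       bio_jitter_sdlog = 0.2,
                       sizefactor_sdlog = 0.15) {
  assert_that(n_chroms >= 1 && chrom_length > 0 && n_snps >= 1 &&
                n_haplotypes >= 2, "sim_config(): non-positive dimensions")
  assert_that(n_bio_reps >= 2, "sim_config(): n_bio_reps must be >= 2")
  assert_that(dna_depth_mean > 0 && rna_depth_mean > 0,
              "sim_config(): depths must be positive")
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length = as.integer(chrom_length),
              n_snps = as.integer(n_snps),
              n_haplotypes = as.integer(n_haplotypes),
              n_bio_reps = as.integer(n_bio_reps),
              n_tech_reps = as.integer(n_tech_reps),
              dna_depth_mean = dna_depth_mean,
              rna_depth_mean = rna_depth_mean,
              nb_dispersion = nb_dispersion,
              effect_fraction = effect_fraction,
              effect_log2fc = effect_log2fc,
              abundance_sdlog = abundance_sdlog,
              activity_sdlog = activity_sdlog,
              bio_jitter_sdlog = bio_jitter_sdlog,
              sizefactor_sdlog = sizefactor_sdlog)
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a toy genome
#'
#' Uniform-composition chromosomes of uppercase A/C/G/T, reproducible under
#' the configuration seed.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return A named \code{Biostrings::DNAStringSet} (chr1, chr2, ...).
#' @export
gen_genome <- function(cfg) {
  assert_that(cfg$chrom_length >= 1000, "gen_genome(): chrom_length < 1000")
  with_seed(cfg$seed + 101L, {
    seqs <- vapply(seq_len(cfg$n_chroms), function(i) {
      paste(sample(DNA_BASES, cfg$chrom_length, replace = TRUE),
            collapse = "")
    }, character(1))
    names(seqs) <- paste0("chr", seq_len(cfg$n_chroms))
    Biostrings::DNAStringSet(seqs)
  })
}

#' Generate a SNP panel with phased haplotypes
#'
#' SNP positions are unique and leave 60 bp of flank inside the chromosome so
#' every SNP supports a 120-bp oligo window. Reference alleles match the
#' genome; 1-3 alternative alleles are drawn per site. Per-population minor
#' allele frequencies (AMR/EUR/EAS/SAS) are drawn independently from a scaled
#' Beta distribution so the MAF filter is exercised. Linkage disequilibrium is
#' planted in blocks of consecutive SNPs: each block has an anchor haplotype
#' column and partners copied from it with a small (5%, high r2) or large
#' (30%, low r2) per-haplotype flip probability.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param genome output of \code{\link{gen_genome}}.
#' @param populations population labels for the MAF columns.
#' @param block_size SNPs per planted LD block.
#' @return \code{list(panel = data.frame, haplotypes = 0/1 matrix)} with one
#'   haplotype row per chromosome copy and one column per SNP id. Panel
#'   columns: id, chrom, pos (1-based), ref, alts (comma-joined),
#'   \code{maf_<POP>}.
#' @export
gen_snp_panel <- function(cfg, genome,
                          populations = c("AMR", "EUR", "EAS", "SAS"),
                          block_size = 5L) {
  assert_that(cfg$n_snps < cfg$chrom_length / 200,
              "gen_snp_panel(): too many SNPs for chromosome length")
  with_seed(cfg$seed + 202L, {
    per_chrom <- diff(round(seq(0, cfg$n_snps, length.out = cfg$n_chroms + 1)))
    rows <- list()
    for (ci in seq_len(cfg$n_chroms)) {
      n <- per_chrom[ci]
      if (n == 0) next
      pos <- sort(sample(seq(61L, cfg$chrom_length - 60L), n))
      chrom <- names(genome)[ci]
      ref <- vapply(pos, function(p)
        as.character(Biostrings::subseq(genome[[ci]], p, p)), character(1))
      rows[[ci]] <- data.frame(chrom = chrom, pos = pos, ref = ref,
                               stringsAsFactors = FALSE)
    }
    panel <- do.call(rbind, rows)
    n <- nrow(panel)
    panel$id <- sprintf("snp%05d", seq_len(n))
    n_alt <- sample(1:3, n, replace = TRUE, prob = c(0.85, 0.1, 0.05))
    panel$alts <- vapply(seq_len(n), function(i) {
      paste(sample(setdiff(DNA_BASES, panel$ref[i]), n_alt[i]),
            collapse = ",")
    }, character(1))
    for (p in populations)
      panel[[paste0("maf_", p)]] <- rbeta(n, 1, 3) / 2

    # planted LD: blocks of consecutive SNPs copied from an anchor with
    # alternating flip probabilities (0.05 -> r2 ~ 0.8, 0.30 -> r2 ~ 0.15)
    H <- matrix(0L, cfg$n_haplotypes, n,
                dimnames = list(NULL, panel$id))
    flip_cycle <- c(0.05, 0.30)
    i <- 1L
    while (i <= n) {
      j <- min(i + block_size - 1L, n)
      p_anchor <- runif(1, 0.2, 0.8)
      anchor <- rbinom(cfg$n_haplotypes, 1L, p_anchor)
      H[, i] <- anchor
      if (j > i) for (k in seq(i + 1L, j)) {
        f <- flip_cycle[(k - i - 1L) %% 2L + 1L]
        flip <- rbinom(cfg$n_haplotypes, 1L, f) == 1L
        H[, k] <- ifelse(flip, 1L - anchor, anchor)
      }
      i <- j + 1L
    }
    panel <- panel[, c("id", "chrom", "pos", "ref", "alts",
                       paste0("maf_", populations))]
    list(panel = panel, haplotypes = H)
  })
}

#' Generate paired H3K27ac/ATAC peak sets
#'
#' Produces \code{n_sets} pairs of peak sets (one pair per synthetic cell
#' line). H3K27ac peaks are non-overlapping intervals on a jittered grid with
#' a summit; for a fraction \code{overlap_fraction} of them the paired ATAC
#' peak contains the H3K27ac peak (so the pairwise intersection equals the
#' H3K27ac interval), the rest of the ATAC peaks are placed disjoint from
#' every H3K27ac peak.
#'
#' @param cfg a \code{\link{sim_config}}.
#' @param genome output of \code{\link{gen_genome}}.
#' @param n_sets number of peak-set pairs (cell lines).
#' @param n_peaks peaks per set per chromosome.
#' @param width_range min/max H3K27ac peak width (bp).
#' @param overlap_fraction fraction of H3K27ac peaks covered by ATAC.
#' @return A named list of \code{n_sets} elements, each
#'   \code{list(h3k27ac =, atac =)} of interval data.frames with columns
#'   chrom, start (0-based), end (exclusive), name, summit (0-based).
#' @export
gen_peaks <- function(cfg, genome, n_sets = 1L, n_peaks = 100L,
                      width_range = c(300, 900), overlap_fraction = 0.5) {
  with_seed(cfg$seed + 303L, {
    out <- vector("list", n_sets)
    names(out) <- paste0("set", seq_len(n_sets))
    for (s in seq_len(n_sets)) {
      h3k <- list(); atac <- list()
      for (ci in seq_along(genome)) {
        chrom <- names(genome)[ci]
        len <- length(genome[[ci]])
        # jittered grid keeps H3K27ac peaks mutually disjoint
        slot <- floor(len / n_peaks)
        w <- pmin(round(runif(n_peaks, width_range[1], width_range[2])),
                  slot - 50L)
        start <- (seq_len(n_peaks) - 1L) * slot +
          floor(runif(n_peaks, 0, slot - w - 1))
        end <- start + w
        summit <- start + floor(w * runif(n_peaks, 0.3, 0.7))
        hk <- data.frame(chrom = chrom, start = start, end = end,
                         name = sprintf("%s_%s_pk%d", names(out)[s], chrom,
                                        seq_len(n_peaks)),
                         summit = summit, stringsAsFactors = FALSE)
        cover <- runif(n_peaks) < overlap_fraction
        a_start <- a_end <- integer(n_peaks)
        # covering ATAC peak: contains the H3K27ac interval
        a_start[cover] <- pmax(0L, start[cover] - sample(0:40, sum(cover),
                                                         replace = TRUE))
        a_end[cover] <- pmin(len, end[cover] + sample(0:40, sum(cover),
                                                      replace = TRUE))
        # non-covering ATAC peak: in the gap after the H3K27ac peak
        gap_lo <- end + 50L
        gap_hi <- start + slot - 10L
        idx <- which(!cover)
        for (i in idx) {
          aw <- min(200L, gap_hi[i] - gap_lo[i] - 1L)
          a_start[i] <- gap_lo[i]
          a_end[i] <- gap_lo[i] + max(aw, 1L)
        }
        at <- data.frame(chrom = chrom, start = a_start, end = a_end,
                         name = sprintf("%s_%s_at%d", names(out)[s], chrom,
                                        seq_len(n_peaks)),
                         summit = a_start + (a_end - a_start) %/% 2L,
                         stringsAsFactors = FALSE)
        h3k[[ci]] <- hk; atac[[ci]] <- at
      }
      out[[s]] <- list(h3k27ac = do.call(rbind, h3k),
                       atac = do.call(rbind, atac))
    }
    out
  })
}

#' Generate an oligo count matrix with planted effects
#'
#' DNA counts are negative-binomial around a per-oligo abundance times a
#' per-sample size factor; RNA counts share the abundance of their biological
#' replicate and are additionally scaled by the oligo's baseline activity and
#' by \code{2^effect} on the alternative (or methylated) arm of affected
#' variants. Technical replicates of a biological replicate differ only in
#' sampling noise. If the manifest contains CpG-window oligos the whole
#' sample grid is duplicated into methylated/unmethylated arms; otherwise the
#' arm is \code{"n/a"}.
#'
#' @param manifest an oligo manifest (see \code{\link{design_snp_oligos}}).
#' @param cfg a \code{\link{sim_config}}; \code{nb_dispersion} must be > 0.
#' @param cell_line label written into the sample sheet.
#' @param truth optional TruthTable (variant_id, effect, affected) to impose
#'   instead of sampling effects - used to share planted effects between
#'   screens of different cell lines.
#' @return \code{list(counts = integer matrix oligo x sample,
#'   samples = data.frame(sample_id, modality, cell_line, bio_rep, tech_rep,
#'   methyl_arm), truth = data.frame(variant_id, effect, affected))}.
#' @export
gen_counts <- function(manifest, cfg, cell_line = "CL1", truth = NULL) {
  assert_that(nrow(manifest) > 0, "gen_counts(): empty manifest")
  assert_that(cfg$nb_dispersion > 0, "gen_counts(): dispersion must be > 0")
  with_seed(cfg$seed + 404L, {
    oligos <- manifest$oligo_id
    n_o <- length(oligos)
    variants <- unique(manifest$variant_id)
    n_v <- length(variants)

    if (is.null(truth)) {
      n_aff <- round(cfg$effect_fraction * n_v)
      affected <- rep(FALSE, n_v)
      affected[sample(n_v, n_aff)] <- TRUE
      effect <- ifelse(affected,
                       cfg$effect_log2fc * sample(c(-1, 1), n_v,
                                                  replace = TRUE),
                       0)
      truth <- data.frame(variant_id = variants, effect = effect,
                          affected = affected, stringsAsFactors = FALSE)
    } else {
      assert_that(all(variants %in% truth$variant_id),
                  "gen_counts(): truth is missing manifest variants")
      truth <- truth[match(variants, truth$variant_id), , drop = FALSE]
      rownames(truth) <- NULL
    }

    methyl <- any(manifest$class == "CpG-window")
    arms <- if (methyl) c("methylated", "unmethylated") else "n/a"

    samples <- expand.grid(tech_rep = seq_len(cfg$n_tech_reps),
                           bio_rep = seq_len(cfg$n_bio_reps),
                           modality = c("DNA", "RNA"),
                           methyl_arm = arms,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
    samples$cell_line <- cell_line
    samples$sample_id <- sprintf(
      "%s_%s%s_b%d_t%d", cell_line, samples$modality,
      ifelse(samples$methyl_arm == "n/a", "",
             ifelse(samples$methyl_arm == "methylated", "_me", "_un")),
      samples$bio_rep, samples$tech_rep)
    samples <- samples[, c("sample_id", "modality", "cell_line",
                           "bio_rep", "tech_rep", "methyl_arm")]

    abundance <- rlnorm(n_o, log(cfg$dna_depth_mean) -
                          cfg$abundance_sdlog^2 / 2, cfg$abundance_sdlog)
    # baseline activity is a property of the variant's locus: identical for
    # all arms of a variant, so null variants have no allelic difference
    activity_v <- rlnorm(n_v, -cfg$activity_sdlog^2 / 2, cfg$activity_sdlog)
    activity <- activity_v[match(manifest$variant_id, variants)]
    # per-(oligo, bio_rep, arm) abundance shared by DNA and RNA libraries
    jit <- array(rlnorm(n_o * cfg$n_bio_reps * length(arms),
                        -cfg$bio_jitter_sdlog^2 / 2, cfg$bio_jitter_sdlog),
                 dim = c(n_o, cfg$n_bio_reps, length(arms)))
    sf <- rlnorm(nrow(samples), -cfg$sizefactor_sdlog^2 / 2,
                 cfg$sizefactor_sdlog)

    eff_by_variant <- setNames(truth$effect, truth$variant_id)
    oligo_eff <- eff_by_variant[manifest$variant_id]
    # the effect acts on the alternative allele arm (SNP class) or on the
    # methylated arm (CpG class)
    if (methyl) {
      test_oligo <- manifest$class == "CpG-window"
    } else {
      test_oligo <- if ("is_ref" %in% names(manifest)) !manifest$is_ref
                    else rep(TRUE, n_o)
    }
    rna_scale <- cfg$rna_depth_mean / cfg$dna_depth_mean

    counts <- matrix(0L, n_o, nrow(samples),
                     dimnames = list(oligos, samples$sample_id))
    for (s in seq_len(nrow(samples))) {
      b <- samples$bio_rep[s]
      a <- match(samples$methyl_arm[s], arms)
      base_mu <- abundance * jit[, b, a] * sf[s]
      if (samples$modality[s] == "DNA") {
        mu <- base_mu
      } else {
        fc <- ifelse(test_oligo &
                       (!methyl | samples$methyl_arm[s] == "methylated"),
                     2^oligo_eff, 1)
        mu <- base_mu * activity * fc * rna_scale
      }
      counts[, s] <- as.integer(rnbinom(n_o, mu = mu,
                                        size = 1 / cfg$nb_dispersion))
    }
    list(counts = counts, samples = samples, truth = truth)
  })
}

#' Generate a methylation probe beta-value table
#'
#' Tumor/normal beta values are Beta-distributed around per-probe means; a
#' fraction of probes carries a planted tumor-vs-normal difference of
#' \code{delta_beta} (random sign). Values are guaranteed to lie in [0, 1].
#'
#' @param cfg a \code{\link{sim_config}} (only the seed is used).
#' @param n_probes number of probes.
#' @param n_tumor,n_normal samples per group.
#' @param delta_beta planted |mean difference| for differential probes.
#' @param diff_fraction fraction of differential probes.
#' @param concentration Beta concentration (higher = tighter groups).
#' @return \code{list(beta = matrix probes x samples, groups = character
#'   vector ("tumor"/"normal"), truth = data.frame(probe_id, differential,
#'   delta))}.
#' @export
gen_probe_table <- function(cfg, n_probes = 500L, n_tumor = 30L,
                            n_normal = 30L, delta_beta = 0.4,
                            diff_fraction = 0.2, concentration = 100) {
  assert_that(delta_beta >= 0 && delta_beta <= 1,
              "gen_probe_table(): invalid beta range")
  with_seed(cfg$seed + 505L, {
    mu_normal <- runif(n_probes, 0.15, 0.85)
    differential <- runif(n_probes) < diff_fraction
    sgn <- sample(c(-1, 1), n_probes, replace = TRUE)
    delta <- ifelse(differential, sgn * delta_beta, 0)
    mu_tumor <- pmin(pmax(mu_normal + delta, 0.02), 0.98)
    delta <- mu_tumor - mu_normal  # realized (clamped) difference
    draw <- function(mu, n) {
      t(vapply(mu, function(m)
        rbeta(n, m * concentration, (1 - m) * concentration), numeric(n)))
    }
    beta <- cbind(draw(mu_tumor, n_tumor), draw(mu_normal, n_normal))
    probe_id <- sprintf("cg%06d", seq_len(n_probes))
    rownames(beta) <- probe_id
    groups <- c(rep("tumor", n_tumor), rep("normal", n_normal))
    colnames(beta) <- paste0(groups, c(seq_len(n_tumor), seq_len(n_normal)))
    list(beta = beta, groups = groups,
         truth = data.frame(probe_id = probe_id, differential = differential,
                            delta = delta, stringsAsFactors = FALSE))
  })
}

#' Materialize reads for a count matrix
#'
#' For each sample, emits one read per count unit: the oligo's full synthesized
#' sequence (adapters + insert), optionally with uniform substitution errors.
#' Counting these reads with \code{\link{count_oligos}} at
#' \code{error_rate = 0} reproduces the count matrix exactly.
#'
#' @param counts integer matrix oligo x sample (rownames = oligo ids).
#' @param manifest oligo manifest supplying \code{full_seq}.
#' @param error_rate per-base substitution probability.
#' @param seed integer seed for the error process.
#' @return Named list: sample id -> character vector of reads.
#' @export
sim_reads <- function(counts, manifest, error_rate = 0, seed = 1L) {
  full <- setNames(manifest$full_seq, manifest$oligo_id)
  assert_that(all(rownames(counts) %in% names(full)),
              "sim_reads(): counts contain oligos absent from manifest")
  with_seed(seed + 606L, {
    lapply(setNames(colnames(counts), colnames(counts)), function(s) {
      reads <- rep(full[rownames(counts)], counts[, s])
      names(reads) <- NULL
      if (error_rate > 0 && length(reads) > 0) {
        reads <- vapply(reads, function(r) {
          n <- nchar(r)
          hit <- which(runif(n) < error_rate)
          if (length(hit)) {
            ch <- strsplit(r, "")[[1]]
            ch[hit] <- vapply(ch[hit], function(b)
              sample(setdiff(DNA_BASES, b), 1), character(1))
            r <- paste(ch, collapse = "")
          }
          r
        }, character(1), USE.NAMES = FALSE)
      }
      reads
    })
  })
}
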
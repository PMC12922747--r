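#' Median-of-ratios size factors
#'
#' Classic count normalization: the per-oligo reference is the geometric
#' mean of its counts across samples, computed over oligos with all-positive
#' counts; each sample's factor is the median ratio of its counts to the
#' reference over those oligos.
#'
#' @param counts integer matrix, oligos x samples.
#' @return Named positive numeric vector, one factor per sample.
#' @export
size_factors <- function(counts) {
  ok <- rowSums(counts > 0) == ncol(counts)
  if (!any(ok))
    stop(paste("size_factors(): no oligo has positive counts in every",
               "sample; filter low-coverage oligos first"), call. = FALSE)
  ref <- exp(rowMeans(log(counts[ok, , drop = FALSE])))
  apply(counts[ok, , drop = FALSE], 2, function(cnt) median(cnt / ref))
}

# average technical replicates of normalized counts within
# (cell_line, methyl_arm, modality, bio_rep); returns list of matrices keyed
# by "cell|arm|modality|bio"
tech_average <- function(norm, samples) {
  key <- paste(samples$cell_line, samples$methyl_arm, samples$modality,
               samples$bio_rep, sep = "|")
  out <- lapply(split(seq_len(ncol(norm)), key), function(ix)
    rowMeans(norm[, ix, drop = FALSE]))
  out
}

#' Per-oligo, per-biological-replicate enhancer activity scores
#'
#' Normalizes counts by \code{\link{size_factors}} (computed jointly over all
#' samples of the experiment, DNA and RNA), averages technical replicates
#' within biological replicate and modality, and scores
#' \deqn{EAS_{o,r} = (\bar{RNA}_{o,r} + 1) / \bar{DNA}_{o,r}.}
#' The pseudocount sits on RNA only, exactly as defined; oligos whose
#' tech-averaged DNA falls below \code{qualify_min_dna} in any biological
#' replicate are marked unqualified (a zero DNA mean never raises a division
#' error - the oligo is simply unqualified and its EAS is NA). When DNA
#' libraries were not sequenced per biological replicate, every RNA replicate
#' is divided by the pooled DNA mean of its cell line/arm.
#'
#' @param counts integer matrix oligo x sample.
#' @param samples sample sheet (sample_id, modality, cell_line, bio_rep,
#'   tech_rep, methyl_arm) aligned with \code{colnames(counts)}.
#' @param sf optional precomputed size factors.
#' @param qualify_min_dna qualification floor on normalized tech-averaged
#'   DNA, default 10.
#' @return data.frame (oligo_id, cell_line, methyl_arm, bio_rep, dna_mean,
#'   rna_mean, eas, qualified).
#' @export
compute_eas <- function(counts, samples, sf = NULL, qualify_min_dna = 10) {
  assert_that(identical(colnames(counts), samples$sample_id),
              "compute_eas(): counts columns must align with sample sheet")
  if (is.null(sf)) sf <- size_factors(counts)
  norm <- sweep(counts, 2, sf, "/")
  groups <- tech_average(norm, samples)
  meta <- unique(samples[, c("cell_line", "methyl_arm", "bio_rep",
                             "modality")])
  out <- list()
  combos <- unique(meta[, c("cell_line", "methyl_arm")])
  for (i in seq_len(nrow(combos))) {
    cl <- combos$cell_line[i]; arm <- combos$methyl_arm[i]
    sub <- meta[meta$cell_line == cl & meta$methyl_arm == arm, ]
    rna_reps <- sort(unique(sub$bio_rep[sub$modality == "RNA"]))
    dna_reps <- sort(unique(sub$bio_rep[sub$modality == "DNA"]))
    paired <- all(rna_reps %in% dna_reps)
    if (!paired) {
      dna_cols <- samples$modality == "DNA" & samples$cell_line == cl &
        samples$methyl_arm == arm
      assert_that(any(dna_cols), "compute_eas(): no DNA samples found")
      dna_pool <- rowMeans(norm[, dna_cols, drop = FALSE])
    }
    for (r in rna_reps) {
      rna <- groups[[paste(cl, arm, "RNA", r, sep = "|")]]
      dna <- if (paired) groups[[paste(cl, arm, "DNA", r, sep = "|")]]
             else dna_pool
      eas <- ifelse(dna > 0, (rna + 1) / dna, NA_real_)
      out[[length(out) + 1L]] <- data.frame(
        oligo_id = rownames(counts), cell_line = cl, methyl_arm = arm,
        bio_rep = r, dna_mean = dna, rna_mean = rna, eas = eas,
        stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  eas <- do.call(rbind, out)
  # qualified iff DNA mean clears the floor in every biological replicate
  key <- paste(eas$oligo_id, eas$cell_line, eas$methyl_arm, sep = "|")
  minq <- tapply(eas$dna_mean, key, min)
  eas$qualified <- as.vector(minq[key] >= qualify_min_dna)
  eas
}

#' Build the test/reference oligo pairing from a manifest
#'
#' SNP-allele oligos pair each alternative allele against the reference
#' allele of the same variant; CpG-window oligos pair the methylated arm of
#' an oligo against its unmethylated arm.
#'
#' @param manifest oligo manifest with \code{is_ref} for SNP-allele rows.
#' @return data.frame (variant_id, allele, test_oligo, test_arm, ref_oligo,
#'   ref_arm).
#' @export
build_pairing <- function(manifest) {
  out <- list()
  snp <- manifest[manifest$class == "SNP-allele", , drop = FALSE]
  if (nrow(snp)) {
    for (v in unique(snp$variant_id)) {
      rows <- snp[snp$variant_id == v, , drop = FALSE]
      ref <- rows[rows$is_ref, , drop = FALSE]
      assert_that(nrow(ref) == 1,
                  sprintf("build_pairing(): variant %s needs exactly one reference oligo", v))
      alt <- rows[!rows$is_ref, , drop = FALSE]
      if (nrow(alt))
        out[[length(out) + 1L]] <- data.frame(
          variant_id = v, allele = alt$allele,
          test_oligo = alt$oligo_id, test_arm = "n/a",
          ref_oligo = ref$oligo_id, ref_arm = "n/a",
          stringsAsFactors = FALSE)
    }
  }
  cpg <- manifest[manifest$class == "CpG-window", , drop = FALSE]
  if (nrow(cpg))
    out[[length(out) + 1L]] <- data.frame(
      variant_id = cpg$variant_id, allele = "methylated",
      test_oligo = cpg$oligo_id, test_arm = "methylated",
      ref_oligo = cpg$oligo_id, ref_arm = "unmethylated",
      stringsAsFactors = FALSE)
  do.call(rbind, out)
}

#' Per-variant log2 fold changes of enhancer activity
#'
#' For each pairing row and biological replicate,
#' \eqn{log2FC_{v,r} = \log_2 EAS_{test,r} - \log_2 EAS_{ref,r}}; the point
#' estimate is the mean over biological replicates. Variants with an
#' unqualified arm in any replicate are flagged \code{qualified = FALSE} and
#' are excluded from downstream calling.
#'
#' @param eas output of \code{\link{compute_eas}}.
#' @param pairing output of \code{\link{build_pairing}} (or equivalent).
#' @return data.frame with one row per (variant, allele): variant_id, allele,
#'   cell_line, qualified, n_reps, log2fc_mean, and one \code{log2fc_rep<r>}
#'   column per biological replicate.
#' @export
variant_log2fc <- function(eas, pairing) {
  reps <- sort(unique(eas$bio_rep))
  n_r <- length(reps)
  n_p <- nrow(pairing)
  ekey <- paste(eas$oligo_id, eas$cell_line, eas$methyl_arm, eas$bio_rep,
                sep = "|")
  eas_ix <- setNames(seq_len(nrow(eas)), ekey)
  out <- list()
  for (cl in unique(eas$cell_line)) {
    tk <- paste(rep(pairing$test_oligo, each = n_r), cl,
                rep(pairing$test_arm, each = n_r), reps, sep = "|")
    rk <- paste(rep(pairing$ref_oligo, each = n_r), cl,
                rep(pairing$ref_arm, each = n_r), reps, sep = "|")
    ti <- eas_ix[tk]; ri <- eas_ix[rk]
    if (anyNA(ti) || anyNA(ri))
      stop("variant_log2fc(): pairing references unknown oligo/arm",
           call. = FALSE)
    lfc <- matrix(log2(eas$eas[ti]) - log2(eas$eas[ri]), n_p, n_r,
                  byrow = TRUE)
    qmat <- matrix(eas$qualified[ti] & eas$qualified[ri], n_p, n_r,
                   byrow = TRUE)
    qual <- rowSums(qmat & is.finite(lfc)) == n_r
    df <- data.frame(variant_id = pairing$variant_id,
                     allele = pairing$allele, cell_line = cl,
                     qualified = qual, n_reps = n_r,
                     log2fc_mean = rowMeans(lfc),
                     stringsAsFactors = FALSE, row.names = NULL)
    for (r in seq_len(n_r))
      df[[sprintf("log2fc_rep%d", reps[r])]] <- lfc[, r]
    out[[length(out) + 1L]] <- df
  }
  do.call(rbind, out)
}
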
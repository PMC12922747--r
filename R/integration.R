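#' Partition two call sets by variant
#'
#' Variants are compared at the variant-id level (a variant counts as called
#' if any of its alleles is called, and as tested if any allele is qualified
#' and testable). \code{b_only} means called in B and tested-but-not-called
#' in A; variants untested in the other screen are reported separately,
#' never as exclusive calls.
#'
#' @param calls_a,calls_b \code{call_set} objects over overlapping variant
#'   universes.
#' @return \code{list(common, a_only, b_only, a_untested_in_b,
#'   b_untested_in_a, counts)}.
#' @export
compare_cell_lines <- function(calls_a, calls_b) {
  ids <- function(cs, what) {
    t <- cs$table
    switch(what,
           called = unique(t$variant_id[t$called]),
           tested = unique(t$variant_id[t$qualified & !is.na(t$p)]))
  }
  ca <- ids(calls_a, "called"); cb <- ids(calls_b, "called")
  ta <- ids(calls_a, "tested"); tb <- ids(calls_b, "tested")
  common <- intersect(ca, cb)
  a_only <- setdiff(intersect(ca, tb), cb)
  b_only <- setdiff(intersect(cb, ta), ca)
  res <- list(common = common, a_only = a_only, b_only = b_only,
              a_untested_in_b = setdiff(ca, tb),
              b_untested_in_a = setdiff(cb, ta))
  res$counts <- lengths(res)
  res
}

#' One-sided overlap enrichment p-value
#'
#' Upper-tail hypergeometric probability \eqn{P(X \ge k)} for observing
#' \code{k} variants called in both screens when \code{m} and \code{n} are
#' called out of a universe of \code{N} tested variants (the one-sided
#' Fisher exact test for enrichment).
#'
#' @param k overlap size; \code{m,n} set sizes; \code{N} universe size (an
#'   explicit required argument).
#' @return One-sided p-value.
#' @export
fisher_overlap <- function(k, m, n, N) {
  assert_that(k <= min(m, n) && max(m, n) <= N && k >= 0,
              "fisher_overlap(): inconsistent counts")
  phyper(k - 1, m, N - m, n, lower.tail = FALSE)
}

#' Coverage of a SNP set by per-cancer enhancer maps
#'
#' @param snps SNP data.frame (chrom, pos 1-based).
#' @param enhancer_maps named list: cancer type -> interval data.frame.
#' @return data.frame (cancer, covered, total, percent) with
#'   \code{percent = \link{percent}(covered, total)}.
#' @export
pan_cancer_coverage <- function(snps, enhancer_maps) {
  total <- nrow(snps)
  covered <- vapply(enhancer_maps,
                    function(m) nrow(snps_in_intervals(snps, m)), integer(1))
  data.frame(cancer = names(enhancer_maps), covered = unname(covered),
             total = total, percent = percent(unname(covered), total),
             stringsAsFactors = FALSE)
}

#' Filter a differential-expression table to DEGs
#'
#' Strict thresholds: \code{log2fc > lfc_min} and \code{padj < padj_max}.
#'
#' @param de data.frame with columns \code{log2fc} and \code{padj}.
#' @param lfc_min default 0.75; \code{padj_max} default 0.05.
#' @param padj_max adjusted-p cutoff.
#' @return Filtered data.frame.
#' @export
deg_filter <- function(de, lfc_min = 0.75, padj_max = 0.05) {
  de[de$log2fc > lfc_min & de$padj < padj_max, , drop = FALSE]
}

#' Link variants to genes by TSS proximity
#'
#' A variant links to a gene iff it lies on the same chromosome within
#' \code{window} bp (inclusive) of the gene's transcription start site; a
#' variant may link to many genes.
#'
#' @param variants data.frame (variant_id, chrom, pos 1-based).
#' @param degs data.frame (gene, chrom, tss 1-based).
#' @param window distance cutoff, default 1 Mb.
#' @return data.frame (variant_id, gene, distance).
#' @export
link_to_tss <- function(variants, degs, window = 1000000) {
  m <- merge(variants[, c("variant_id", "chrom", "pos")],
             degs[, c("gene", "chrom", "tss")], by = "chrom")
  m$distance <- abs(m$pos - m$tss)
  m <- m[m$distance <= window, c("variant_id", "gene", "distance")]
  rownames(m) <- NULL
  m
}

# ---- PWM scanning ---------------------------------------------------------

#' Construct a position weight matrix object
#'
#' @param mat 4 x width numeric matrix (rows A, C, G, T) of counts or
#'   probabilities; columns are normalized to sum to 1.
#' @param id motif identifier.
#' @param background base background probabilities, default uniform.
#' @param pseudocount added as \code{pseudocount * background} inside the
#'   log-odds, default 0.1.
#' @return A \code{pwm} object with the log2-odds score matrix
#'   (\code{score[b, j] = log2((p + pc * bg_b) / bg_b)}) and its maximum
#'   achievable score.
#' @export
pwm <- function(mat, id = "motif", background = rep(0.25, 4),
                pseudocount = 0.1) {
  mat <- as.matrix(mat)
  assert_that(nrow(mat) == 4, "pwm(): need 4 rows (A, C, G, T)")
  assert_that(ncol(mat) >= 4, "pwm(): width must be >= 4")
  mat <- sweep(mat, 2, colSums(mat), "/")
  assert_that(all(abs(colSums(mat) - 1) < 1e-6), "pwm(): invalid columns")
  rownames(mat) <- DNA_BASES
  score <- log2((mat + pseudocount * background) / background)
  structure(list(id = id, prob = mat, background = background,
                 pseudocount = pseudocount, score = score,
                 width = ncol(mat), max_score = sum(apply(score, 2, max))),
            class = "pwm")
}

#' Read position frequency matrices in JASPAR text format
#'
#' Minimal parser for the JASPAR PFM format: a \code{>} header line followed
#' by four rows of counts, with or without base labels and brackets.
#'
#' @param path file path.
#' @inheritParams pwm
#' @return Named list of \code{\link{pwm}} objects.
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudocount = 0.1) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grep("^>", lines)
  assert_that(length(hdr) > 0, "read_jaspar(): no motif headers found")
  out <- list()
  for (h in seq_along(hdr)) {
    from <- hdr[h] + 1L
    to <- if (h < length(hdr)) hdr[h + 1L] - 1L else length(lines)
    block <- lines[from:to]
    assert_that(length(block) == 4, "read_jaspar(): expected 4 matrix rows")
    labels <- toupper(substr(trimws(block), 1, 1))
    rows <- lapply(block, function(ln) {
      ln <- gsub("^[ \t]*[ACGTacgt][ \t]*", "", ln)
      as.numeric(strsplit(gsub("[][]", " ", ln), "[ \t,]+")[[1]] |>
                   (\(x) x[nzchar(x)])())
    })
    mat <- do.call(rbind, rows)
    if (all(labels %in% DNA_BASES)) mat <- mat[match(DNA_BASES, labels), ]
    id <- sub("^>\\s*", "", lines[hdr[h]])
    id <- strsplit(id, "[ \t]+")[[1]][1]
    out[[id]] <- pwm(mat, id = id, background = background,
                     pseudocount = pseudocount)
  }
  out
}

revcomp <- function(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))

# log2-odds scores of all windows of a sequence on the given strand
scan_pwm_strand <- function(p, seq) {
  ch <- strsplit(seq, "")[[1]]
  L <- length(ch)
  w <- p$width
  if (L < w) return(numeric(0))
  row <- match(ch, DNA_BASES)
  vapply(seq_len(L - w + 1L), function(s) {
    r <- row[s:(s + w - 1L)]
    if (anyNA(r)) return(-Inf)
    sum(p$score[cbind(r, seq_len(w))])
  }, numeric(1))
}

#' Best PWM log-odds score over windows covering a position, both strands
#'
#' @param p a \code{\link{pwm}}.
#' @param seq sequence to scan.
#' @param offset 0-based position that every scored window must cover; NULL
#'   scans all windows.
#' @return Maximum window score (\code{-Inf} if no window fits).
#' @export
pwm_best_score <- function(p, seq, offset = NULL) {
  L <- nchar(seq)
  w <- p$width
  keep <- function(scores, off) {
    if (is.null(off) || !length(scores)) return(scores)
    starts <- seq_along(scores) - 1L
    scores[starts <= off & off < starts + w]
  }
  fwd <- keep(scan_pwm_strand(p, seq), offset)
  rc_off <- if (is.null(offset)) NULL else L - 1L - offset
  rev <- keep(scan_pwm_strand(p, revcomp(seq)), rc_off)
  best <- suppressWarnings(max(c(fwd, rev, -Inf)))
  best
}

#' Allele-dependent motif score change at a variant
#'
#' Scores every PWM window covering the variant on both strands of the
#' reference and the alternative insert and compares the best scores.
#' \code{disrupts} flags a qualitative gain or loss of the site: exactly one
#' of the two alleles reaches \code{threshold_frac} of the PWM's maximum
#' achievable score.
#'
#' @param p a \code{\link{pwm}}.
#' @param ref_insert,alt_insert equal-length sequences differing only at
#'   \code{offset}.
#' @param offset 0-based variant position within the inserts.
#' @param threshold_frac fraction of the maximum achievable score that
#'   defines a bound site, default 0.8.
#' @return \code{list(best_ref, best_alt, delta, disrupts)} with
#'   \code{delta = best_alt - best_ref}.
#' @export
allele_motif_delta <- function(p, ref_insert, alt_insert, offset,
                               threshold_frac = 0.8) {
  assert_that(nchar(ref_insert) == nchar(alt_insert),
              "allele_motif_delta(): inserts differ in length")
  assert_that(p$width <= nchar(ref_insert),
              "allele_motif_delta(): window longer than insert")
  diffs <- which(strsplit(ref_insert, "")[[1]] != strsplit(alt_insert, "")[[1]])
  assert_that(all(diffs == offset + 1L),
              "allele_motif_delta(): inserts must differ only at offset")
  best_ref <- pwm_best_score(p, ref_insert, offset)
  best_alt <- pwm_best_score(p, alt_insert, offset)
  thr <- threshold_frac * p$max_score
  list(best_ref = best_ref, best_alt = best_alt,
       delta = best_alt - best_ref,
       disrupts = xor(best_ref >= thr, best_alt >= thr))
}

#' Peaks specific to one condition
#'
#' Returns the peaks of \code{a} with zero base-pair overlap against any
#' peak of \code{b}.
#'
#' @param a,b interval data.frames.
#' @return Subset of \code{a}.
#' @export
specific_peaks <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0) return(a)
  hit <- suppressWarnings(
    IRanges::overlapsAny(intervals_to_gr(a), intervals_to_gr(b)))
  a[!hit, , drop = FALSE]
}

#' Prioritize metastasis-acquired regulatory variants
#'
#' Applies four criteria to every allele called in the metastatic screen:
#' (i) called in the metastatic cell line while tested and \emph{not} called
#' in the primary line (untested variants cannot satisfy this); (ii) located
#' within metastasis-specific peaks; (iii) within \code{window} bp of the
#' TSS of at least one up-regulated gene; (iv) the allele substitution
#' disrupts at least one supplied TF motif
#' (\code{\link{allele_motif_delta}}). A variant is prioritized iff all four
#' flags hold.
#'
#' @param calls_primary,calls_met \code{call_set} objects.
#' @param met_specific_peaks interval data.frame (see
#'   \code{\link{specific_peaks}}).
#' @param degs up-regulated DEG table (gene, chrom, tss), already filtered
#'   with \code{\link{deg_filter}}.
#' @param pwms list of \code{\link{pwm}} objects.
#' @param manifest oligo manifest giving variant coordinates and ref/alt
#'   insert sequences.
#' @param window TSS window, default 1 Mb; \code{motif_threshold} passed to
#'   \code{\link{allele_motif_delta}}.
#' @param motif_threshold fraction of maximum PWM score defining a site.
#' @return data.frame with one row per called (variant, allele):
#'   criterion flags \code{crit_specific}, \code{crit_peak},
#'   \code{crit_deg}, \code{crit_motif}, the strongest signed motif delta,
#'   and \code{prioritized}.
#' @export
prioritize_metastasis <- function(calls_primary, calls_met,
                                  met_specific_peaks, degs, pwms, manifest,
                                  window = 1000000, motif_threshold = 0.8) {
  mt <- calls_met$table
  cand <- mt[mt$called, c("variant_id", "allele"), drop = FALSE]
  if (nrow(cand) == 0)
    return(data.frame(variant_id = character(), allele = character(),
                      crit_specific = logical(), crit_peak = logical(),
                      crit_deg = logical(), crit_motif = logical(),
                      motif_delta = numeric(), prioritized = logical()))
  pt <- calls_primary$table
  tested_primary <- unique(pt$variant_id[pt$qualified & !is.na(pt$p)])
  called_primary <- unique(pt$variant_id[pt$called])

  ref_rows <- manifest[manifest$class == "SNP-allele" & manifest$is_ref, ]
  ref_ix <- setNames(seq_len(nrow(ref_rows)), ref_rows$variant_id)

  out <- cand
  out$crit_specific <- cand$variant_id %in% tested_primary &
    !(cand$variant_id %in% called_primary)
  out$crit_peak <- FALSE
  out$crit_deg <- FALSE
  out$crit_motif <- FALSE
  out$motif_delta <- NA_real_
  for (i in seq_len(nrow(cand))) {
    ri <- ref_ix[[cand$variant_id[i]]]
    if (is.null(ri)) next
    chrom <- ref_rows$chrom[ri]
    off <- (ref_rows$end[ri] - ref_rows$start[ri]) %/% 2L
    pos <- ref_rows$start[ri] + off + 1L  # 1-based variant position
    snp <- data.frame(chrom = chrom, pos = pos)
    out$crit_peak[i] <- nrow(snps_in_intervals(snp, met_specific_peaks)) > 0
    snp$variant_id <- cand$variant_id[i]
    out$crit_deg[i] <- nrow(link_to_tss(snp, degs, window)) > 0
    alt_row <- manifest[manifest$variant_id == cand$variant_id[i] &
                          !is.na(manifest$allele) &
                          manifest$allele == cand$allele[i], , drop = FALSE]
    if (nrow(alt_row) == 1) {
      deltas <- lapply(pwms, function(p)
        allele_motif_delta(p, ref_rows$insert_seq[ri],
                           alt_row$insert_seq[1], off, motif_threshold))
      disr <- vapply(deltas, `[[`, logical(1), "disrupts")
      dvals <- vapply(deltas, `[[`, numeric(1), "delta")
      out$crit_motif[i] <- any(disr)
      out$motif_delta[i] <- dvals[which.max(abs(dvals))]
    }
  }
  out$prioritized <- out$crit_specific & out$crit_peak & out$crit_deg &
    out$crit_motif
  rownames(out) <- NULL
  out
}
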
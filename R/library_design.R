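#' Constant adapter sequences flanking every synthesized oligo
#'
#' 18-nt upstream and 32-nt downstream cloning adapters; a full oligo is
#' \code{ADAPTER_UP + 120-nt insert + ADAPTER_DOWN} (170 nt).
#' @export
ADAPTER_UP <- "ATGGCTACGATCCGACTT"

#' @rdname ADAPTER_UP
#' @export
ADAPTER_DOWN <- "AAGTCGGAGGCCAAGCGGTCTTAGGAAGACAA"

# ---- interval helpers (0-based half-open data.frames <-> GRanges) ---------

intervals_to_gr <- function(df) {
  assert_that(all(df$start < df$end), "invalid interval: start >= end")
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(df$start + 1L, df$end))
}

gr_to_intervals <- function(gr) {
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Base-pair intersection of two interval sets
#'
#' Returns the maximal intervals covered by both inputs, i.e. the
#' intersection of the two bp coverage sets (inputs are reduced first, so
#' internal overlaps within one set do not matter).
#'
#' @param a,b interval data.frames with columns chrom, start (0-based),
#'   end (exclusive).
#' @return Interval data.frame (chrom, start, end), possibly empty.
#' @export
intersect_peaks <- function(a, b) {
  if (nrow(a) == 0 || nrow(b) == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  gr <- GenomicRanges::intersect(
    GenomicRanges::reduce(intervals_to_gr(a)),
    GenomicRanges::reduce(intervals_to_gr(b)))
  gr_to_intervals(gr)
}

#' Retain SNPs whose position falls inside an interval set
#'
#' A SNP at 1-based position \code{pos} is retained iff its 0-based
#' coordinate \code{pos - 1} lies in some half-open interval.
#'
#' @param snps SNP data.frame with columns chrom, pos (1-based).
#' @param intervals interval data.frame (chrom, start, end).
#' @return The retained subset of \code{snps}.
#' @export
snps_in_intervals <- function(snps, intervals) {
  if (nrow(snps) == 0 || nrow(intervals) == 0) return(snps[0, , drop = FALSE])
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  hit <- suppressWarnings(
    IRanges::overlapsAny(snp_gr, intervals_to_gr(intervals)))
  snps[hit, , drop = FALSE]
}

#' Filter a SNP panel to common variants
#'
#' Retains SNPs with MAF >= \code{threshold} (inclusive) in \emph{every}
#' requested population.
#'
#' @param panel SNP panel with one \code{maf_<POP>} column per population.
#' @param threshold MAF cutoff, default 0.05.
#' @param populations population names to require.
#' @return Filtered panel.
#' @export
filter_common_snps <- function(panel, threshold = 0.05,
                               populations = c("EUR", "EAS")) {
  cols <- paste0("maf_", populations)
  missing <- setdiff(cols, names(panel))
  assert_that(length(missing) == 0,
              paste("filter_common_snps(): unknown population(s):",
                    paste(sub("^maf_", "", missing), collapse = ", ")))
  keep <- rep(TRUE, nrow(panel))
  for (cl in cols) keep <- keep & panel[[cl]] >= threshold
  panel[keep, , drop = FALSE]
}

#' Squared linkage-disequilibrium correlation between two SNPs
#'
#' Computed from phased haplotype counts:
#' \eqn{D = p_{AB} - p_A p_B}, \eqn{r^2 = D^2 / (p_A(1-p_A)p_B(1-p_B))}.
#' Monomorphic SNPs (allele frequency 0 or 1) have no defined r2 and raise
#' an error rather than returning 0.
#'
#' @param snp_a,snp_b SNP ids (haplotype matrix column names).
#' @param haplotypes 0/1 matrix, haplotypes x SNPs.
#' @return r2 in [0, 1].
#' @export
ld_r2 <- function(snp_a, snp_b, haplotypes) {
  assert_that(all(c(snp_a, snp_b) %in% colnames(haplotypes)),
              "ld_r2(): SNP absent from haplotypes")
  x <- haplotypes[, snp_a]
  y <- haplotypes[, snp_b]
  p_a <- mean(x); p_b <- mean(y)
  if (p_a <= 0 || p_a >= 1 || p_b <= 0 || p_b >= 1)
    stop("ld_r2(): monomorphic SNP, r2 undefined", call. = FALSE)
  d <- mean(x == 1 & y == 1) - p_a * p_b
  d^2 / (p_a * (1 - p_a) * p_b * (1 - p_b))
}

#' Expand lead SNPs to LD proxies
#'
#' Returns panel SNPs lying within \code{window} bp of any lead and in LD
#' (r2 >= \code{r2_min}) with that lead. Leads themselves are reported
#' separately, never as proxies; a proxy qualifying for several leads is
#' emitted once. Monomorphic candidates are skipped.
#'
#' @param leads character vector of lead SNP ids (must be in the panel).
#' @param panel SNP panel (id, chrom, pos).
#' @param haplotypes 0/1 haplotype matrix with panel ids as columns.
#' @param r2_min LD threshold, default 0.5.
#' @param window search window each side of a lead, default 500 kb.
#' @return \code{list(leads =, proxies =)} of SNP id vectors.
#' @export
ld_expand <- function(leads, panel, haplotypes, r2_min = 0.5,
                      window = 500000) {
  assert_that(all(leads %in% panel$id), "ld_expand(): lead absent from panel")
  assert_that(all(leads %in% colnames(haplotypes)),
              "ld_expand(): lead absent from haplotypes")
  idx <- setNames(seq_len(nrow(panel)), panel$id)
  proxies <- character()
  for (lead in leads) {
    li <- idx[[lead]]
    cand <- panel$id[panel$chrom == panel$chrom[li] &
                       abs(panel$pos - panel$pos[li]) <= window &
                       panel$id != lead]
    for (cd in cand) {
      r2 <- tryCatch(ld_r2(lead, cd, haplotypes), error = function(e) NA_real_)
      if (!is.na(r2) && r2 >= r2_min) proxies <- c(proxies, cd)
    }
  }
  list(leads = unique(leads), proxies = setdiff(unique(proxies), leads))
}

#' Merge two candidate SNP sets with inclusion-exclusion bookkeeping
#'
#' @param gwas_set,enhancer_set character vectors of SNP ids.
#' @return \code{list(union, n_a, n_b, n_common, n_union)} with
#'   \code{n_union = n_a + n_b - n_common}.
#' @export
merge_candidate_sets <- function(gwas_set, enhancer_set) {
  a <- unique(gwas_set); b <- unique(enhancer_set)
  u <- union(a, b)
  list(union = u, n_a = length(a), n_b = length(b),
       n_common = length(intersect(a, b)), n_union = length(u))
}

#' Extract the oligo insert window around a variant
#'
#' For the default width 120, the insert is the 0-based half-open interval
#' \code{[pos - 1 - 60, pos - 1 + 60)} and the variant base sits at 0-based
#' insert offset 60 (the convention applied uniformly to SNP and CpG-summit
#' windows; an even width cannot place the variant exactly centrally).
#'
#' @param genome a \code{DNAStringSet}.
#' @param chrom chromosome name.
#' @param pos 1-based variant position.
#' @param width insert width (even), default 120.
#' @return \code{list(insert = character, chrom, start, end, offset)} with
#'   start/end the 0-based half-open insert interval and offset the 0-based
#'   position of the variant within the insert.
#' @export
extract_window <- function(genome, chrom, pos, width = 120L) {
  assert_that(chrom %in% names(genome), "extract_window(): unknown chrom")
  half <- width %/% 2L
  start0 <- pos - 1L - half
  end0 <- start0 + width
  len <- length(genome[[chrom]])
  if (start0 < 0L || end0 > len)
    stop("extract_window(): window out of chromosome bounds", call. = FALSE)
  insert <- as.character(Biostrings::subseq(genome[[chrom]],
                                            start0 + 1L, end0))
  list(insert = insert, chrom = chrom, start = start0, end = end0,
       offset = half)
}

#' Attach constant cloning adapters to an insert
#'
#' @param insert insert sequence of length \code{insert_len}.
#' @param insert_len required insert length, default 120.
#' @return Full oligo sequence \code{ADAPTER_UP + insert + ADAPTER_DOWN}.
#' @export
attach_adapters <- function(insert, insert_len = 120L) {
  assert_that(all(nchar(insert) == insert_len),
              "attach_adapters(): wrong insert length")
  paste0(ADAPTER_UP, insert, ADAPTER_DOWN)
}

#' Enumerate allele-substituted oligos for one SNP
#'
#' One oligo per requested allele, identical to the insert except at the
#' variant offset. The insert's base at the offset must equal the SNP's
#' reference allele.
#'
#' @param snp one-row SNP record (id, ref, alts comma-joined).
#' @param insert result of \code{\link{extract_window}}.
#' @param alleles bases to synthesize; default reference plus known
#'   alternatives; pass \code{all_four = TRUE} for A/C/G/T.
#' @param all_four synthesize all four bases at the site.
#' @return data.frame with one row per allele: oligo_id, variant_id, class,
#'   chrom, start, end, allele, is_ref, insert_seq, full_seq.
#' @export
enumerate_allele_oligos <- function(snp, insert, alleles = NULL,
                                    all_four = FALSE) {
  off <- insert$offset
  site <- substr(insert$insert, off + 1L, off + 1L)
  assert_that(site == snp$ref,
              sprintf("enumerate_allele_oligos(): genome base %s != ref %s at %s",
                      site, snp$ref, snp$id))
  if (is.null(alleles)) {
    alleles <- if (all_four) DNA_BASES
               else unique(c(snp$ref, strsplit(snp$alts, ",")[[1]]))
  }
  ins <- vapply(alleles, function(a) {
    s <- insert$insert
    substr(s, off + 1L, off + 1L) <- a
    s
  }, character(1))
  data.frame(oligo_id = paste(snp$id, alleles, sep = "_"),
             variant_id = snp$id, class = "SNP-allele",
             chrom = insert$chrom, start = insert$start, end = insert$end,
             allele = alleles, is_ref = alleles == snp$ref,
             insert_seq = unname(ins),
             full_seq = attach_adapters(unname(ins), nchar(insert$insert)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Design the SNP-allele oligo library for a panel
#'
#' Applies \code{\link{extract_window}} and
#' \code{\link{enumerate_allele_oligos}} to every panel SNP. SNPs whose
#' window does not fit inside the chromosome are skipped (count attached as
#' attribute \code{n_skipped}).
#'
#' @param panel SNP panel (id, chrom, pos, ref, alts).
#' @param genome a \code{DNAStringSet}.
#' @param width insert width, default 120.
#' @param all_four synthesize all four bases at each site.
#' @return Oligo manifest data.frame (one row per oligo).
#' @export
design_snp_oligos <- function(panel, genome, width = 120L, all_four = FALSE) {
  rows <- vector("list", nrow(panel))
  skipped <- 0L
  for (i in seq_len(nrow(panel))) {
    w <- tryCatch(extract_window(genome, panel$chrom[i], panel$pos[i], width),
                  error = function(e) NULL)
    if (is.null(w)) { skipped <- skipped + 1L; next }
    rows[[i]] <- enumerate_allele_oligos(panel[i, ], w, all_four = all_four)
  }
  manifest <- do.call(rbind, rows)
  if (skipped > 0)
    warning(sprintf("design_snp_oligos(): skipped %d out-of-bounds SNP(s)",
                    skipped))
  attr(manifest, "n_skipped") <- skipped
  manifest
}

#' Design CpG-window oligos centered at peak summits
#'
#' One window per H3K27ac peak summit, using the same centering convention
#' as \code{\link{extract_window}} (the summit base at 0-based insert offset
#' 60). Summits too close to a chromosome edge are skipped with a warning;
#' the skip count is attached as attribute \code{n_skipped}.
#'
#' @param peaks interval data.frame with a 0-based \code{summit} column and a
#'   \code{name} column.
#' @param genome a \code{DNAStringSet}.
#' @param width insert width, default 120.
#' @return Oligo manifest data.frame, class \code{"CpG-window"}, one oligo
#'   per summit, with a \code{cpg_count} column (number of CG dinucleotides
#'   in the insert).
#' @export
design_methyl_windows <- function(peaks, genome, width = 120L) {
  assert_that("summit" %in% names(peaks),
              "design_methyl_windows(): summits required")
  rows <- vector("list", nrow(peaks))
  skipped <- 0L
  for (i in seq_len(nrow(peaks))) {
    w <- tryCatch(extract_window(genome, peaks$chrom[i],
                                 peaks$summit[i] + 1L, width),
                  error = function(e) NULL)
    if (is.null(w)) { skipped <- skipped + 1L; next }
    rows[[i]] <- data.frame(
      oligo_id = paste0(peaks$name[i], "_win"),
      variant_id = peaks$name[i], class = "CpG-window",
      chrom = w$chrom, start = w$start, end = w$end,
      allele = NA_character_, is_ref = FALSE,
      insert_seq = w$insert,
      full_seq = attach_adapters(w$insert, width),
      cpg_count = cpg_count(w$insert),
      stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (skipped > 0)
    warning(sprintf("design_methyl_windows(): skipped %d summit(s) near edge",
                    skipped))
  attr(manifest, "n_skipped") <- skipped
  manifest
}

#' Count CG dinucleotides in a sequence
#' @param seq character vector of sequences.
#' @return Integer vector of CG counts.
#' @export
cpg_count <- function(seq) {
  vapply(seq, function(s) {
    m <- gregexpr("CG", s, fixed = TRUE)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

#' Select differentially methylated probes
#'
#' For each probe, the group difference \eqn{\Delta\beta =
#' \mathrm{mean}(\beta_{tumor}) - \mathrm{mean}(\beta_{normal})} is combined
#' with a Welch two-sided t test across samples, BH-adjusted over all
#' testable probes. A probe passes iff \code{|delta_beta| > delta_min}
#' (strictly) and \code{q <= fdr_max}. Probes constant in both groups cannot
#' be tested and are excluded with a reason.
#'
#' @param beta matrix probes x samples of beta values in [0, 1].
#' @param groups character vector per sample, \code{"tumor"}/\code{"normal"},
#'   each group n >= 2.
#' @param delta_min strict lower bound on |delta beta| (library selection
#'   uses 0.3; biomarker selection 0.25).
#' @param fdr_max BH-adjusted q cutoff, default 0.05.
#' @return data.frame (probe_id, delta_beta, p, q, pass, reason).
#' @export
dmr_filter <- function(beta, groups, delta_min = 0.3, fdr_max = 0.05) {
  assert_that(all(beta >= 0 & beta <= 1), "dmr_filter(): invalid beta range")
  t_idx <- groups == "tumor"; n_idx <- groups == "normal"
  assert_that(sum(t_idx) >= 2 && sum(n_idx) >= 2,
              "dmr_filter(): each group needs n >= 2")
  m1 <- rowMeans(beta[, t_idx, drop = FALSE])
  m2 <- rowMeans(beta[, n_idx, drop = FALSE])
  v1 <- apply(beta[, t_idx, drop = FALSE], 1, var)
  v2 <- apply(beta[, n_idx, drop = FALSE], 1, var)
  n1 <- sum(t_idx); n2 <- sum(n_idx)
  se2 <- v1 / n1 + v2 / n2
  degenerate <- se2 == 0
  tt <- ifelse(degenerate, NA_real_, (m1 - m2) / sqrt(se2))
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tt), df)
  q <- rep(NA_real_, length(p))
  q[!degenerate] <- p.adjust(p[!degenerate], method = "BH")
  out <- data.frame(
    probe_id = if (is.null(rownames(beta))) as.character(seq_len(nrow(beta)))
               else rownames(beta),
    delta_beta = m1 - m2, p = p, q = q,
    pass = !degenerate & abs(m1 - m2) > delta_min & !is.na(q) & q <= fdr_max,
    reason = ifelse(degenerate, "constant_groups", ""),
    stringsAsFactors = FALSE, row.names = NULL)
  out
}
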
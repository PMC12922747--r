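# Plain-text readers and writers for every pipeline artifact. All tables are
# tab-separated with a header; intervals are BED-style 0-based half-open with
# the summit offset carried in the name field ("<name>|<summit-start>");
# SNP positions are 1-based on disk and in memory.

tsv_write <- function(df, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)

tsv_read <- function(path)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)

#' Write / read a genome as FASTA
#' @param genome a \code{DNAStringSet}; \code{path} file path.
#' @param path file path.
#' @export
write_genome_fasta <- function(genome, path)
  Biostrings::writeXStringSet(genome, path)

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write / read a SNP panel as TSV
#'
#' Columns CHROM, POS (1-based), ID, REF, ALTS (comma-joined) and one
#' \code{MAF_<POP>} column per population.
#' @param panel SNP panel data.frame; \code{path} file path.
#' @param path file path.
#' @export
write_snp_panel <- function(panel, path) {
  maf_cols <- grep("^maf_", names(panel), value = TRUE)
  out <- data.frame(CHROM = panel$chrom, POS = panel$pos, ID = panel$id,
                    REF = panel$ref, ALTS = panel$alts,
                    stringsAsFactors = FALSE)
  for (cl in maf_cols) out[[toupper(cl)]] <- panel[[cl]]
  tsv_write(out, path)
}

#' @rdname write_snp_panel
#' @export
read_snp_panel <- function(path) {
  raw <- tsv_read(path)
  panel <- data.frame(id = raw$ID, chrom = raw$CHROM, pos = raw$POS,
                      ref = raw$REF, alts = raw$ALTS,
                      stringsAsFactors = FALSE)
  for (cl in grep("^MAF_", names(raw), value = TRUE))
    panel[[tolower(cl)]] <- raw[[cl]]
  panel
}

#' Write / read a 0/1 haplotype matrix as TSV
#' @param haplotypes 0/1 matrix with SNP ids as columns; \code{path} file.
#' @param path file path.
#' @export
write_haplotypes <- function(haplotypes, path)
  tsv_write(as.data.frame(haplotypes), path)

#' @rdname write_haplotypes
#' @export
read_haplotypes <- function(path) as.matrix(tsv_read(path))

#' Write / read peak intervals as 6-column BED
#'
#' The name field carries the peak name and the summit offset relative to
#' the interval start, joined by \code{"|"}.
#' @param peaks interval data.frame (chrom, start, end, name, summit).
#' @param path file path.
#' @export
write_bed <- function(peaks, path) {
  name <- peaks$name
  if ("summit" %in% names(peaks) && !all(is.na(peaks$summit)))
    name <- paste(name, peaks$summit - peaks$start, sep = "|")
  bed <- data.frame(peaks$chrom, peaks$start, peaks$end, name, 0L, ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' @rdname write_bed
#' @export
read_bed <- function(path) {
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(chrom = bed[[1]], start = bed[[2]], end = bed[[3]],
                    name = if (ncol(bed) >= 4) bed[[4]] else NA_character_,
                    stringsAsFactors = FALSE)
  out$summit <- NA_integer_
  has <- grepl("|", out$name, fixed = TRUE)
  parts <- strsplit(out$name[has], "|", fixed = TRUE)
  out$summit[has] <- out$start[has] +
    as.integer(vapply(parts, `[`, character(1), 2))
  out$name[has] <- vapply(parts, `[`, character(1), 1)
  out
}

#' Write / read an oligo manifest (paired TSV + FASTA)
#'
#' The TSV holds one row per oligo (oligo_id, variant_id, class, chrom,
#' start, end, allele, is_ref, insert_seq, full_seq, and cpg_count for
#' CpG-window oligos); the FASTA holds the full synthesized sequences keyed
#' by oligo_id.
#' @param manifest oligo manifest data.frame.
#' @param tsv_path,fasta_path output paths (FASTA optional).
#' @export
write_manifest <- function(manifest, tsv_path, fasta_path = NULL) {
  tsv_write(manifest, tsv_path)
  if (!is.null(fasta_path)) {
    seqs <- Biostrings::DNAStringSet(manifest$full_seq)
    names(seqs) <- manifest$oligo_id
    Biostrings::writeXStringSet(seqs, fasta_path)
  }
}

#' @rdname write_manifest
#' @export
read_manifest <- function(tsv_path) {
  m <- tsv_read(tsv_path)
  if ("allele" %in% names(m)) m$allele <- as.character(m$allele)
  m
}

#' Write / read a count matrix and its sample sheet
#' @param counts integer matrix; \code{samples} sample sheet data.frame.
#' @param samples sample sheet.
#' @param counts_path,samples_path file paths.
#' @export
write_counts <- function(counts, samples, counts_path, samples_path) {
  df <- data.frame(oligo_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  tsv_write(df, counts_path)
  tsv_write(samples, samples_path)
}

#' @rdname write_counts
#' @export
read_counts <- function(counts_path, samples_path) {
  df <- tsv_read(counts_path)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df$oligo_id
  storage.mode(counts) <- "integer"
  samples <- tsv_read(samples_path)
  samples$methyl_arm <- as.character(samples$methyl_arm)
  list(counts = counts, samples = samples)
}

#' Write reads as FASTQ
#' @param reads character vector of read sequences.
#' @param path output path; qualities are constant.
#' @export
write_fastq <- function(reads, path) {
  n <- length(reads)
  lines <- character(4L * n)
  lines[seq(1, by = 4, length.out = n)] <- sprintf("@read%d", seq_len(n))
  lines[seq(2, by = 4, length.out = n)] <- reads
  lines[seq(3, by = 4, length.out = n)] <- "+"
  lines[seq(4, by = 4, length.out = n)] <-
    vapply(nchar(reads), function(k) strrep("I", k), character(1))
  writeLines(lines, path)
}

#' Read a call set written by \code{\link{write_calls}}
#' @param calls_path,json_path paths written by \code{write_calls}.
#' @return A \code{call_set} object.
#' @export
read_calls <- function(calls_path, json_path) {
  tab <- tsv_read(calls_path)
  js <- paste(readLines(json_path), collapse = "")
  num <- function(key) as.numeric(
    sub(sprintf('.*"%s": *([-0-9.eE+]+).*', key), "\\1", js))
  structure(list(left = num("left"), right = num("right"),
                 alpha = num("alpha"),
                 adjust = sub('.*"adjust": *"([^"]*)".*', "\\1", js),
                 table = tab),
            class = "call_set")
}

#' Write a call set (calls TSV + thresholds JSON)
#' @param calls a \code{call_set}; \code{calls_path}, \code{json_path} paths.
#' @param calls_path,json_path output paths.
#' @export
write_calls <- function(calls, calls_path, json_path = NULL) {
  tab <- calls$table
  keep <- intersect(c("variant_id", "allele", "cell_line", "qualified",
                      "log2fc_mean", "p", "q", "called", "direction"),
                    names(tab))
  tsv_write(tab[, keep], calls_path)
  if (!is.null(json_path))
    writeLines(sprintf(
      '{"left": %.10g, "right": %.10g, "n": %d, "alpha": %g, "adjust": "%s"}',
      calls$left, calls$right, sum(calls$table$qualified), calls$alpha,
      calls$adjust), json_path)
}
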
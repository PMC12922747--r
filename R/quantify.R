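#' Extract the oligo insert from a read
#'
#' Locates the first exact occurrence of the upstream adapter and returns the
#' \code{insert_len} bases that follow. Returns \code{NA} (a no-match value,
#' not an error) if the adapter is absent or fewer than \code{insert_len}
#' bases remain.
#'
#' @param reads character vector of read sequences.
#' @param up_adapter upstream adapter, default \code{ADAPTER_UP}.
#' @param insert_len insert length, default 120.
#' @return Character vector of inserts, \code{NA} where no match.
#' @export
extract_insert <- function(reads, up_adapter = ADAPTER_UP,
                           insert_len = 120L) {
  hit <- regexpr(up_adapter, reads, fixed = TRUE)
  start <- as.integer(hit) + nchar(up_adapter)
  ok <- hit != -1L & nchar(reads) >= start + insert_len - 1L
  out <- rep(NA_character_, length(reads))
  out[ok] <- substr(reads[ok], start[ok], start[ok] + insert_len - 1L)
  out
}

# all Hamming-distance-1 substitution neighbours of a set of sequences;
# returns data.frame(seq_index, neighbour)
hamming1_neighbours <- function(seqs) {
  if (length(seqs) == 0)
    return(data.frame(seq_index = integer(), neighbour = character()))
  idx_out <- list(); seq_out <- list(); k <- 1L
  for (i in seq_along(seqs)) {
    ch <- strsplit(seqs[i], "")[[1]]
    for (p in seq_along(ch)) {
      for (b in setdiff(DNA_BASES, ch[p])) {
        s <- ch; s[p] <- b
        idx_out[[k]] <- i
        seq_out[[k]] <- paste(s, collapse = "")
        k <- k + 1L
      }
    }
  }
  data.frame(seq_index = unlist(idx_out), neighbour = unlist(seq_out),
             stringsAsFactors = FALSE)
}

#' Count oligos by matching read inserts against the manifest
#'
#' Inserts are extracted with \code{\link{extract_insert}} and matched
#' exactly against manifest insert sequences. With \code{max_mismatch = 1},
#' unmatched inserts are assigned to the unique manifest insert at Hamming
#' distance 1 when that assignment is unambiguous, and discarded otherwise.
#' Mismatch mode requires every pair of manifest inserts to be more than
#' \code{max_mismatch} apart (allele-substituted oligo pairs differ at a
#' single base, so SNP libraries only support exact matching).
#'
#' @param reads named list: sample id -> character vector of read sequences
#'   (or FASTQ file path, see \code{fastq}).
#' @param manifest oligo manifest with unique \code{insert_seq}.
#' @param max_mismatch 0 (exact, default) or 1.
#' @param fastq if TRUE, elements of \code{reads} are FASTQ file paths.
#' @param up_adapter upstream adapter used for insert extraction.
#' @return \code{list(counts = integer matrix oligo x sample, tally =
#'   data.frame(sample_id, n_reads, matched, discarded))}; discarded counts
#'   reads with no adapter, a truncated insert, an unknown insert, or an
#'   ambiguous mismatch assignment. \code{matched + discarded = n_reads}
#'   per sample.
#' @export
count_oligos <- function(reads, manifest, max_mismatch = 0L, fastq = FALSE,
                         up_adapter = ADAPTER_UP) {
  inserts <- manifest$insert_seq
  assert_that(!anyDuplicated(inserts),
              "count_oligos(): duplicate manifest inserts")
  insert_len <- unique(nchar(inserts))
  assert_that(length(insert_len) == 1,
              "count_oligos(): manifest inserts of mixed length")
  if (max_mismatch > 0L) {
    assert_that(max_mismatch == 1L, "count_oligos(): max_mismatch must be 0 or 1")
    # refuse if any two manifest inserts are within the mismatch radius
    nb <- hamming1_neighbours(inserts)
    clash <- nb$neighbour %in% inserts
    if (any(clash)) {
      i <- nb$seq_index[which(clash)[1]]
      j <- match(nb$neighbour[which(clash)[1]], inserts)
      stop(sprintf(paste0("count_oligos(): manifest inserts '%s' and '%s' are ",
                          "within Hamming distance 1; mismatch mode would be ",
                          "ambiguous - use max_mismatch = 0"),
                   manifest$oligo_id[i], manifest$oligo_id[j]), call. = FALSE)
    }
  }
  samples <- names(reads)
  counts <- matrix(0L, nrow(manifest), length(samples),
                   dimnames = list(manifest$oligo_id, samples))
  tally <- data.frame(sample_id = samples, n_reads = 0L, matched = 0L,
                      discarded = 0L, stringsAsFactors = FALSE)
  for (s in seq_along(samples)) {
    rd <- reads[[s]]
    if (fastq)
      rd <- as.character(Biostrings::readDNAStringSet(rd, format = "fastq"))
    ins <- extract_insert(rd, up_adapter, insert_len)
    hit <- match(ins, inserts)
    if (max_mismatch == 1L) {
      un <- which(is.na(hit) & !is.na(ins))
      if (length(un)) {
        nb <- hamming1_neighbours(ins[un])
        nb$oligo <- match(nb$neighbour, inserts)
        nb <- nb[!is.na(nb$oligo), , drop = FALSE]
        if (nrow(nb)) {
          n_per_read <- tapply(nb$oligo, nb$seq_index,
                               function(x) length(unique(x)))
          first <- tapply(nb$oligo, nb$seq_index, function(x) x[1])
          ok <- n_per_read == 1L  # unique neighbour only
          ri <- as.integer(names(n_per_read))[ok]
          hit[un[ri]] <- first[ok]
        }
      }
    }
    tab <- table(hit[!is.na(hit)])
    counts[as.integer(names(tab)), s] <- as.integer(tab)
    tally$n_reads[s] <- length(rd)
    tally$matched[s] <- sum(!is.na(hit))
    tally$discarded[s] <- sum(is.na(hit))
  }
  list(counts = counts, tally = tally)
}
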
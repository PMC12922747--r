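# Shared fixtures, built once per test run.

fix_cfg <- sim_config(seed = 42L, n_snps = 60L, chrom_length = 50000L,
                      n_haplotypes = 200L)
fix_genome <- gen_genome(fix_cfg)
fix_panel <- gen_snp_panel(fix_cfg, fix_genome)
fix_manifest <- design_snp_oligos(fix_panel$panel, fix_genome)

# a tiny hand-rolled genome for window/edge tests
toy_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

# deterministic random interval set on [0, span)
random_intervals <- function(n, span, seed, max_w = 400L) {
  set.seed(seed)
  start <- sample.int(span - max_w, n)
  w <- sample.int(max_w, n, replace = TRUE)
  data.frame(chrom = "chr1", start = start, end = pmin(start + w, span),
             name = paste0("iv", seq_len(n)), summit = NA_integer_,
             stringsAsFactors = FALSE)
}

# per-bp bitmap oracle for interval intersection on one chromosome
bitmap_intersect <- function(a, b, span) {
  cov <- function(df) {
    x <- logical(span)
    for (i in seq_len(nrow(df))) x[(df$start[i] + 1):df$end[i]] <- TRUE
    x
  }
  both <- cov(a) & cov(b)
  r <- rle(both)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(chrom = "chr1", start = starts[r$values], end = ends[r$values],
             stringsAsFactors = FALSE)
}

# independently coded exhaustive search over candidate tangent points
knee_oracle <- function(x, side) {
  y <- sort(x)
  n <- length(y)
  xs <- (seq_len(n) - 1) / (n - 1)
  if (side == "right") {
    yc <- pmax(y, 0)
    s <- max(yc) - min(yc)
    best_i <- 1; best <- Inf
    for (i in seq_len(n)) {
      b <- yc[i] - s * xs[i]
      if (b < best || (b == best && i > best_i)) { best <- b; best_i <- i }
    }
    yc[best_i]
  } else {
    yc <- pmin(y, 0)
    s <- max(yc) - min(yc)
    best_i <- 1; best <- -Inf
    for (i in seq_len(n)) {
      b <- yc[i] - s * xs[i]
      if (b > best) { best <- b; best_i <- i }  # first index wins ties
    }
    yc[best_i]
  }
}

# minimal call_set constructor for integration tests
make_call_set <- function(variant_id, called, qualified = TRUE,
                          p = 0.01, left = -0.5, right = 0.5) {
  n <- length(variant_id)
  tab <- data.frame(variant_id = variant_id,
                    allele = rep("A", n),
                    qualified = rep_len(qualified, n),
                    log2fc_mean = ifelse(called, 1, 0),
                    p = rep_len(p, n), q = rep_len(p, n),
                    called = called,
                    stringsAsFactors = FALSE)
  structure(list(left = left, right = right, alpha = 0.05, adjust = "BH",
                 table = tab), class = "call_set")
}
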
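test_that("call-set comparison partitions by tested status", {
  a <- make_call_set(paste0("v", 1:6), called = c(T, T, F, F, T, F))
  b <- make_call_set(paste0("v", 1:6), called = c(T, F, T, F, F, T))
  cmp <- compare_cell_lines(a, b)
  expect_setequal(cmp$common, "v1")
  expect_setequal(cmp$a_only, c("v2", "v5"))
  expect_setequal(cmp$b_only, c("v3", "v6"))
  same <- compare_cell_lines(a, a)
  expect_length(same$a_only, 0); expect_length(same$b_only, 0)
  # a variant untested in B is not "a_only"
  b2 <- make_call_set(paste0("v", 1:6), called = rep(FALSE, 6),
                      qualified = c(TRUE, FALSE, TRUE, TRUE, TRUE, TRUE))
  cmp2 <- compare_cell_lines(a, b2)
  expect_false("v2" %in% cmp2$a_only)
  expect_true("v2" %in% cmp2$a_untested_in_b)
})

test_that("overlap enrichment equals exhaustive hypergeometric enumeration", {
  expect_equal(fisher_overlap(5, 5, 5, 5), 1)
  expect_equal(fisher_overlap(5, 5, 5, 20), 1 / choose(20, 5))
  hyper_enum <- function(k, m, n, N)
    sum(vapply(k:min(m, n), function(j)
      choose(m, j) * choose(N - m, n - j), numeric(1))) / choose(N, n)
  set.seed(50)
  for (i in 1:50) {
    N <- sample(5:30, 1)
    m <- sample(1:N, 1); n <- sample(1:N, 1)
    k <- sample(max(0, m + n - N):min(m, n), 1)
    expect_equal(fisher_overlap(k, m, n, N), hyper_enum(k, m, n, N),
                 tolerance = 1e-12)
  }
  expect_error(fisher_overlap(6, 5, 5, 20), "inconsistent")
})

test_that("percentages are rounded half away from zero to one decimal", {
  expect_identical(percent(752, 922), 81.6)
  expect_identical(percent(2517, 3136), 80.3)
  expect_identical(percent(1, 3), 33.3)
  expect_identical(percent(0, 10), 0)
  # scale consistency
  expect_identical(percent(5 * 752, 5 * 922), percent(752, 922))
  expect_error(percent(1, 0), "denominator")
})

test_that("pan-cancer coverage counts SNPs inside each enhancer map", {
  snps <- data.frame(id = paste0("s", 1:10), chrom = "chr1",
                     pos = seq(100, 1000, by = 100), stringsAsFactors = FALSE)
  maps <- list(CRC = data.frame(chrom = "chr1", start = 0L, end = 450L),
               STAD = data.frame(chrom = "chr1", start = 0L, end = 0L + 1L),
               LUAD = data.frame(chrom = "chr2", start = 0L, end = 5000L))
  cov <- pan_cancer_coverage(snps, maps)
  expect_equal(cov$covered, c(4L, 0L, 0L))
  expect_equal(cov$percent, c(40, 0, 0))
})

test_that("DEG filtering is strict on both thresholds", {
  de <- data.frame(gene = c("a", "b", "c", "d"),
                   log2fc = c(0.75, 1.2, 2, 0.8),
                   padj = c(0.01, 0.001, 0.05, 0.04),
                   stringsAsFactors = FALSE)
  got <- deg_filter(de)
  expect_setequal(got$gene, c("b", "d"))  # a fails lfc==0.75, c fails padj==0.05
})

test_that("TSS linking is inclusive at the window and chromosome-aware", {
  vars <- data.frame(variant_id = "v", chrom = "chr1", pos = 2000000L,
                     stringsAsFactors = FALSE)
  degs <- data.frame(gene = c("exact", "near", "far", "other_chr"),
                     chrom = c("chr1", "chr1", "chr1", "chr2"),
                     tss = c(1000000L, 2400000L, 3100000L, 2000000L),
                     stringsAsFactors = FALSE)
  links <- link_to_tss(vars, degs)
  expect_setequal(links$gene, c("exact", "near"))  # 1 Mb away is linked
  # all-pairs oracle on a random layout
  set.seed(51)
  vr <- data.frame(variant_id = paste0("v", 1:50),
                   chrom = sample(c("chr1", "chr2"), 50, TRUE),
                   pos = sample.int(5e6, 50), stringsAsFactors = FALSE)
  dg <- data.frame(gene = paste0("g", 1:30),
                   chrom = sample(c("chr1", "chr2"), 30, TRUE),
                   tss = sample.int(5e6, 30), stringsAsFactors = FALSE)
  got <- link_to_tss(vr, dg, window = 7e5)
  want <- 0L
  for (i in 1:50) for (j in 1:30)
    if (vr$chrom[i] == dg$chrom[j] && abs(vr$pos[i] - dg$tss[j]) <= 7e5)
      want <- want + 1L
  expect_equal(nrow(got), want)
})

test_that("PWM scoring matches the hand computation on a consensus motif", {
  # indicator PWM for consensus TGACTC (probability 1 on each consensus base)
  cons <- c("T", "G", "A", "C", "T", "C")
  mat <- sapply(cons, function(b) as.numeric(c("A", "C", "G", "T") == b))
  p <- pwm(mat, id = "toy")
  hit <- log2((1 + 0.1 * 0.25) / 0.25)     # per matched base
  miss <- log2((0 + 0.1 * 0.25) / 0.25)    # per mismatched base
  expect_equal(p$max_score, 6 * hit)
  ref <- paste0("AAAA", "TGACTC", "AAAAAA")
  alt <- ref; substr(alt, 7, 7) <- "T"     # breaks the A at motif pos 3
  res <- allele_motif_delta(p, ref, alt, offset = 6L)
  expect_equal(res$best_ref, 6 * hit)
  expect_equal(res$delta, miss - hit)
  expect_true(res$disrupts)
  # no change in sequence -> zero delta
  res0 <- allele_motif_delta(p, ref, ref, offset = 6L)
  expect_equal(res0$delta, 0)
  expect_false(res0$disrupts)
})

test_that("PWM scanning is reverse-complement symmetric", {
  set.seed(52)
  mat <- matrix(rexp(4 * 7), 4, 7)
  p <- pwm(mat, id = "rnd")
  seq <- paste(sample(c("A", "C", "G", "T"), 30, TRUE), collapse = "")
  off <- 12L
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  expect_equal(pwm_best_score(p, seq, off),
               pwm_best_score(p, rc, nchar(seq) - 1L - off))
  expect_equal(pwm_best_score(p, seq), pwm_best_score(p, rc))
})

test_that("window-constrained best score equals a brute-force enumeration", {
  set.seed(53)
  mat <- matrix(rexp(4 * 5), 4, 5)
  p <- pwm(mat)
  score_window <- function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(vapply(seq_along(ch), function(j)
      p$score[match(ch[j], c("A", "C", "G", "T")), j], numeric(1)))
  }
  for (rep in 1:10) {
    seq <- paste(sample(c("A", "C", "G", "T"), 40, TRUE), collapse = "")
    off <- sample(0:39, 1)
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    rc_off <- 39 - off
    cands <- c()
    for (s0 in 0:(40 - 5)) {
      if (s0 <= off && off < s0 + 5)
        cands <- c(cands, score_window(substr(seq, s0 + 1, s0 + 5)))
      if (s0 <= rc_off && rc_off < s0 + 5)
        cands <- c(cands, score_window(substr(rc, s0 + 1, s0 + 5)))
    }
    expect_equal(pwm_best_score(p, seq, off), max(cands))
  }
})

test_that("JASPAR PFM parsing handles labels and brackets", {
  f <- tempfile(fileext = ".pfm")
  writeLines(c(">MX0001.1 toyTF",
               "A [ 0 10  0  5 ]",
               "C [ 0  0 10  5 ]",
               "G [10  0  0  0 ]",
               "T [ 0  0  0  0 ]"), f)
  pw <- read_jaspar(f)
  expect_named(pw, "MX0001.1")
  expect_equal(pw[[1]]$width, 4)
  expect_equal(unname(pw[[1]]$prob["G", 1]), 1)
  expect_equal(unname(pw[[1]]$prob["A", 4]), 0.5)
  expect_equal(colSums(pw[[1]]$prob), rep(1, 4), ignore_attr = TRUE)
})

test_that("condition-specific peaks have zero overlap with the other set", {
  a <- data.frame(chrom = "chr1", start = c(0L, 200L, 400L),
                  end = c(100L, 300L, 500L), name = c("p1", "p2", "p3"))
  b <- data.frame(chrom = "chr1", start = 250L, end = 260L, name = "q")
  sp <- specific_peaks(a, b)
  expect_setequal(sp$name, c("p1", "p3"))
})

test_that("metastasis prioritization requires all four criteria", {
  # one strongly affected variant in the metastatic screen, none in primary
  g <- toy_genome(c(chr1 = paste(rep("ACGT", 5000), collapse = "")))
  cfg <- sim_config(seed = 54, n_snps = 30, chrom_length = 20000,
                    effect_fraction = 0.1, effect_log2fc = 3,
                    dna_depth_mean = 3000, nb_dispersion = 1e-4)
  panel <- gen_snp_panel(cfg, g)$panel
  man <- design_snp_oligos(panel, g)
  met <- simulate_screen(man, cfg, cell_line = "MET")
  cfg0 <- cfg; cfg0$seed <- 55L; cfg0$effect_fraction <- 0
  pri <- simulate_screen(man, cfg0, cell_line = "PRI")
  called <- met$calls$table
  called <- called[called$called, ]
  expect_gt(nrow(called), 0)
  v <- called$variant_id[1]
  ref_row <- man[man$variant_id == v & man$is_ref, ]
  pos <- ref_row$start + 60L + 1L
  peaks <- data.frame(chrom = "chr1", start = pos - 50L, end = pos + 50L,
                      name = "met_pk", stringsAsFactors = FALSE)
  degs <- data.frame(gene = "target", chrom = "chr1", tss = pos + 500000L,
                     stringsAsFactors = FALSE)
  # PWM whose consensus equals the reference insert around the variant
  cons <- strsplit(substr(ref_row$insert_seq, 59, 64), "")[[1]]
  mat <- sapply(cons, function(b) as.numeric(c("A", "C", "G", "T") == b))
  pwms <- list(toy = pwm(mat, id = "toy"))

  res <- prioritize_metastasis(pri$calls, met$calls, peaks, degs, pwms, man)
  hit <- res[res$variant_id == v, ]
  expect_true(any(hit$prioritized))
  expect_true(all(res$prioritized[res$variant_id == v] ==
                    (res$crit_specific & res$crit_peak & res$crit_deg &
                       res$crit_motif)[res$variant_id == v]))

  # ablations: each criterion alone removes the variant
  res_i <- prioritize_metastasis(met$calls, met$calls, peaks, degs, pwms, man)
  expect_false(any(res_i$prioritized[res_i$variant_id == v]))
  far_peaks <- data.frame(chrom = "chr1", start = 1L, end = 10L, name = "x")
  res_ii <- prioritize_metastasis(pri$calls, met$calls, far_peaks, degs,
                                  pwms, man)
  expect_false(any(res_ii$prioritized[res_ii$variant_id == v]))
  far_degs <- data.frame(gene = "t", chrom = "chr1", tss = pos + 2000000L)
  res_iii <- prioritize_metastasis(pri$calls, met$calls, peaks, far_degs,
                                   pwms, man)
  expect_false(any(res_iii$prioritized[res_iii$variant_id == v]))
  # an indifferent PWM binds neither allele
  flat <- pwm(matrix(1, 4, 6), id = "flat")
  res_iv <- prioritize_metastasis(pri$calls, met$calls, peaks, degs,
                                  list(flat = flat), man)
  expect_false(any(res_iv$prioritized[res_iv$variant_id == v]))
})
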
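snp_row <- function(id = "rs1", maf_eur, maf_eas, ref = "A", alts = "C",
                    chrom = "chr1", pos = 100L) {
  data.frame(id = id, chrom = chrom, pos = pos, ref = ref, alts = alts,
             maf_EUR = maf_eur, maf_EAS = maf_eas, stringsAsFactors = FALSE)
}

test_that("MAF filter is inclusive and requires every population", {
  panel <- rbind(snp_row("a", 0.05, 0.05), snp_row("b", 0.04, 0.30),
                 snp_row("c", 0.30, 0.049), snp_row("d", 0.2, 0.2))
  kept <- filter_common_snps(panel, 0.05, c("EUR", "EAS"))
  expect_identical(kept$id, c("a", "d"))
  expect_equal(nrow(filter_common_snps(panel, 0)), 4)
  expect_error(filter_common_snps(panel, 0.05, c("EUR", "AFR")), "AFR")
})

test_that("ld_r2 reproduces the hand-counted 8-haplotype oracle", {
  # haplotypes AB,AB,ab,ab,Ab,aB,AB,ab: p_A=0.5, p_B=0.5, p_AB=0.375,
  # D = 0.125, r2 = 0.125^2 / 0.5^4 = 0.25
  H <- cbind(a = c(1, 1, 0, 0, 1, 0, 1, 0), b = c(1, 1, 0, 0, 0, 1, 1, 0))
  expect_equal(ld_r2("a", "b", H), 0.25)
  expect_equal(ld_r2("a", "b", H), ld_r2("b", "a", H))
  expect_error(ld_r2("a", "b", cbind(a = rep(1, 4), b = c(0, 1, 0, 1))),
               "monomorphic")
})

test_that("ld_r2 equals the squared Pearson correlation on exhaustive small instances", {
  # every pair of polymorphic 6-haplotype columns
  cols <- lapply(0:63, function(x) as.integer(intToBits(x)[1:6]))
  poly <- Filter(function(x) var(x) > 0, cols)
  for (i in seq(1, length(poly), by = 7)) {
    for (j in seq(2, length(poly), by = 9)) {
      H <- cbind(a = poly[[i]], b = poly[[j]])
      expect_equal(ld_r2("a", "b", H), cor(poly[[i]], poly[[j]])^2,
                   tolerance = 1e-12)
    }
  }
})

test_that("ld_expand returns in-window proxies above the r2 threshold only", {
  set.seed(4)
  anchor <- rbinom(400, 1, 0.5)
  flip <- function(x, k) { y <- x; ix <- sample(length(x), k)
    y[ix] <- 1 - y[ix]; y }
  H <- cbind(lead = anchor,
             strong = flip(anchor, 8),    # r2 ~ 0.85
             weak = flip(anchor, 160),    # r2 ~ 0.04
             far = flip(anchor, 4),       # strong LD but out of window
             other = rbinom(400, 1, 0.5))
  panel <- data.frame(id = colnames(H), chrom = "chr1",
                      pos = c(1e6, 1.1e6, 1.2e6, 3e6, 1.3e6),
                      stringsAsFactors = FALSE)
  res <- ld_expand("lead", panel, H)
  expect_identical(res$proxies, "strong")
  expect_identical(res$leads, "lead")
  # no neighbours in window -> empty proxy set
  res2 <- ld_expand("far", panel, H, window = 1000)
  expect_length(res2$proxies, 0)
  expect_error(ld_expand("nope", panel, H), "absent")
})

test_that("interval intersection matches a per-bp bitmap oracle", {
  one <- data.frame(chrom = "chr1", start = 0L, end = 100L)
  two <- data.frame(chrom = "chr1", start = 50L, end = 150L)
  expect_equal(intersect_peaks(one, two),
               data.frame(chrom = "chr1", start = 50L, end = 100L),
               ignore_attr = TRUE)
  disj <- data.frame(chrom = "chr1", start = 500L, end = 600L)
  expect_equal(nrow(intersect_peaks(one, disj)), 0)
  a <- random_intervals(500, 100000, seed = 31)
  b <- random_intervals(500, 100000, seed = 32)
  got <- intersect_peaks(a, b)
  want <- bitmap_intersect(a, b, 100000)
  expect_equal(got, want, ignore_attr = TRUE)
  # commutative and idempotent
  expect_equal(intersect_peaks(b, a), got, ignore_attr = TRUE)
  expect_equal(intersect_peaks(got, got), got, ignore_attr = TRUE)
})

test_that("SNP-in-interval uses 0-based half-open boundaries", {
  iv <- data.frame(chrom = "chr1", start = 100L, end = 200L)
  snps <- data.frame(id = c("in_lo", "out_lo", "in_hi", "out_hi"),
                     chrom = "chr1", pos = c(101L, 100L, 200L, 201L),
                     stringsAsFactors = FALSE)
  expect_identical(snps_in_intervals(snps, iv)$id, c("in_lo", "in_hi"))
  # random instance vs linear scan oracle
  set.seed(6)
  rs <- data.frame(id = paste0("s", 1:1000), chrom = "chr1",
                   pos = sample.int(100000, 1000), stringsAsFactors = FALSE)
  ivs <- random_intervals(50, 100000, seed = 33)
  keep <- vapply(rs$pos, function(p)
    any(ivs$start <= p - 1 & p - 1 < ivs$end), logical(1))
  expect_identical(snps_in_intervals(rs, ivs)$id, rs$id[keep])
})

test_that("candidate-set merging satisfies inclusion-exclusion", {
  a <- paste0("g", 1:6363)
  b <- c(paste0("g", 1:99), paste0("e", 1:24427))
  m <- merge_candidate_sets(a, b)
  expect_equal(m$n_common, 99)
  expect_equal(m$n_union, 30790)
  expect_equal(m$n_union, m$n_a + m$n_b - m$n_common)
  same <- merge_candidate_sets(a, a)
  expect_equal(same$n_union, length(a))
  expect_equal(same$n_common, length(a))
  dis <- merge_candidate_sets(paste0("x", 1:10), paste0("y", 1:5))
  expect_equal(dis$n_union, 15)
  set.seed(10)
  for (i in 1:20) {
    x <- sample(letters, sample(5:20, 1), replace = TRUE)
    y <- sample(letters, sample(5:20, 1), replace = TRUE)
    m <- merge_candidate_sets(x, y)
    expect_equal(m$n_union, m$n_a + m$n_b - m$n_common)
  }
})

test_that("window extraction follows the declared centering convention", {
  g <- toy_genome(c(chr1 = paste(rep("ACGT", 50), collapse = "")))
  w <- extract_window(g, "chr1", pos = 61)
  expect_equal(w$start, 0); expect_equal(w$end, 120)
  expect_equal(nchar(w$insert), 120); expect_equal(w$offset, 60)
  ga <- toy_genome(c(chr1 = strrep("A", 400)))
  expect_equal(extract_window(ga, "chr1", 200)$insert, strrep("A", 120))
  expect_error(extract_window(g, "chr1", 60), "bounds")
  expect_error(extract_window(g, "chr1", 142), "bounds")
  # string-slice oracle on random positions
  chromstr <- as.character(fix_genome[[1]])
  set.seed(13)
  for (pos in sample(seq(61, nchar(chromstr) - 60), 25)) {
    w <- extract_window(fix_genome, "chr1", pos)
    expect_identical(w$insert, substr(chromstr, pos - 60, pos + 59))
    expect_identical(substr(w$insert, 61, 61),
                     substr(chromstr, pos, pos))
  }
})

test_that("allele enumeration produces Hamming-distance-1 oligos", {
  g <- toy_genome(c(chr1 = strrep("ACGT", 100)))
  snp <- data.frame(id = "v1", chrom = "chr1", pos = 101L, ref = "A",
                    alts = "G", stringsAsFactors = FALSE)
  w <- extract_window(g, "chr1", 101)
  two <- enumerate_allele_oligos(snp, w)
  expect_equal(nrow(two), 2)
  expect_setequal(two$allele, c("A", "G"))
  four <- enumerate_allele_oligos(snp, w, all_four = TRUE)
  expect_equal(nrow(four), 4)
  hd <- function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(hd(four$insert_seq[i], four$insert_seq[j]), 1)
  expect_true(all(substr(four$insert_seq, 61, 61) == four$allele))
  snp$ref <- "C"
  expect_error(enumerate_allele_oligos(snp, w), "!= ref")
})

test_that("adapter attachment is exact and invertible", {
  ins <- strrep("A", 120)
  full <- attach_adapters(ins)
  expect_equal(nchar(full), 170)
  expect_true(startsWith(full, "ATGGCTACGATCCGACTT"))
  expect_true(endsWith(full, "AAGTCGGAGGCCAAGCGGTCTTAGGAAGACAA"))
  expect_identical(extract_insert(full), ins)
  ins2 <- paste(rep("ACGT", 30), collapse = "")
  expect_false(attach_adapters(ins2) == full)
  expect_error(attach_adapters("ACGT"), "length")
})

test_that("methylation windows are summit-centered and count CpGs", {
  g <- toy_genome(c(chr1 = paste(rep("ACGT", 500), collapse = "")))
  peaks <- data.frame(chrom = "chr1", start = c(100, 300, 0) * 1L,
                      end = c(500, 700, 40) * 1L,
                      name = c("p1", "p2", "edge"),
                      summit = c(300L, 500L, 9L), stringsAsFactors = FALSE)
  expect_warning(man <- design_methyl_windows(peaks, g), "skipped")
  expect_equal(nrow(man), 2)
  expect_equal(attr(man, "n_skipped"), 1)
  expect_true(all(nchar(man$insert_seq) == 120))
  expect_true(all(man$class == "CpG-window"))
  # summit base sits at insert offset 60
  expect_identical(substr(man$insert_seq[1], 61, 61),
                   as.character(Biostrings::subseq(g[[1]], 301, 301)))
  # CpG count equals a direct sliding scan
  scan_cg <- function(s) sum(vapply(seq_len(nchar(s) - 1), function(i)
    substr(s, i, i + 1) == "CG", logical(1)))
  expect_equal(man$cpg_count, vapply(man$insert_seq, scan_cg, numeric(1),
                                     USE.NAMES = FALSE))
})

test_that("DMR filter combines a strict delta with BH-adjusted q", {
  set.seed(21)
  mk <- function(mu_t, mu_n, n = 10, sd = 0.02)
    pmin(pmax(c(rnorm(n, mu_t, sd), rnorm(n, mu_n, sd)), 0), 1)
  beta <- rbind(hit = mk(0.8, 0.4), null = mk(0.5, 0.5),
                flat = rep(0.5, 20))
  groups <- rep(c("tumor", "normal"), each = 10)
  res <- dmr_filter(beta, groups, delta_min = 0.3)
  expect_true(res$pass[res$probe_id == "hit"])
  expect_false(res$pass[res$probe_id == "null"])
  expect_identical(res$reason[res$probe_id == "flat"], "constant_groups")
  # exact boundary: |delta| == delta_min is dropped (strict >)
  exact <- rbind(edge = c(0.65, 0.75, 0.35, 0.45))
  res2 <- dmr_filter(exact, c("tumor", "tumor", "normal", "normal"),
                     delta_min = 0.3)
  expect_equal(res2$delta_beta, 0.3)
  expect_false(res2$pass)
})
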
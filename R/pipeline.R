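#' Score a screen: counts to per-variant statistics
#'
#' Chains \code{\link{size_factors}}, \code{\link{compute_eas}},
#' \code{\link{build_pairing}}, \code{\link{variant_log2fc}} and the
#' replicate-level t test into the per-variant activity table.
#'
#' @param counts oligo x sample count matrix.
#' @param samples sample sheet.
#' @param manifest oligo manifest.
#' @param qualify_min_dna DNA qualification floor (see
#'   \code{\link{compute_eas}}).
#' @return \code{list(eas =, variants =)}; \code{variants} adds t, p and
#'   degenerate columns to the \code{\link{variant_log2fc}} table.
#' @export
score_screen <- function(counts, samples, manifest, qualify_min_dna = 10) {
  eas <- compute_eas(counts, samples, qualify_min_dna = qualify_min_dna)
  pairing <- build_pairing(manifest)
  variants <- variant_log2fc(eas, pairing)
  tt <- ttest_rows(rep_cols(variants))
  variants$t <- tt$t
  variants$p <- tt$p
  variants$degenerate <- tt$degenerate
  list(eas = eas, variants = variants)
}

#' Call a scored screen with knee thresholds
#'
#' Computes knee-point thresholds on the qualified variants' mean log2FC
#' vector and applies \code{\link{call_variants}}.
#'
#' @param variants scored variant table (see \code{\link{score_screen}}).
#' @param alpha significance level.
#' @param adjust \code{"BH"} or \code{"none"} (see
#'   \code{\link{call_variants}}).
#' @param slope knee slope mode (see \code{\link{knee_thresholds}}).
#' @return A \code{call_set}.
#' @export
screen_call <- function(variants, alpha = 0.05, adjust = "BH",
                        slope = "clamped") {
  lfc <- variants$log2fc_mean[variants$qualified]
  thr <- knee_thresholds(lfc, side = "both", slope = slope)
  call_variants(variants, thr, alpha = alpha, adjust = adjust)
}

#' Simulate and analyse one synthetic screen end to end
#'
#' @param manifest oligo manifest (from \code{\link{design_snp_oligos}} or
#'   \code{\link{design_methyl_windows}}).
#' @param cfg a \code{\link{sim_config}}.
#' @param cell_line sample-sheet label.
#' @param alpha,adjust,qualify_min_dna analysis settings.
#' @param truth optional TruthTable forwarded to \code{\link{gen_counts}}.
#' @return \code{list(counts, samples, truth, eas, variants, calls)}.
#' @export
simulate_screen <- function(manifest, cfg, cell_line = "CL1", alpha = 0.05,
                            adjust = "BH", qualify_min_dna = 10,
                            truth = NULL) {
  sim <- gen_counts(manifest, cfg, cell_line = cell_line, truth = truth)
  sc <- score_screen(sim$counts, sim$samples, manifest,
                     qualify_min_dna = qualify_min_dna)
  calls <- screen_call(sc$variants, alpha = alpha, adjust = adjust)
  list(counts = sim$counts, samples = sim$samples, truth = sim$truth,
       eas = sc$eas, variants = sc$variants, calls = calls)
}

#' Recovery metrics of a call set against planted truth
#'
#' Sensitivity and empirical FDR are computed per variant (a variant is
#' detected if any of its alleles is called; unqualified affected variants
#' count as misses); the mean absolute estimation error compares each
#' qualified allele-level log2FC estimate of an affected variant with the
#' planted effect.
#'
#' @param calls a \code{call_set}.
#' @param truth TruthTable from \code{\link{gen_counts}}.
#' @return \code{list(sensitivity, fdr, mean_abs_error, n_called,
#'   n_affected)}.
#' @export
recovery_metrics <- function(calls, truth) {
  tab <- calls$table
  called_var <- unique(tab$variant_id[tab$called])
  affected <- truth$variant_id[truth$affected]
  n_called <- length(called_var)
  sens <- if (length(affected)) mean(affected %in% called_var) else NA_real_
  fdr <- if (n_called) mean(!(called_var %in% affected)) else 0
  eff <- setNames(truth$effect, truth$variant_id)
  aff_rows <- tab$qualified & tab$variant_id %in% affected
  mae <- if (any(aff_rows))
    mean(abs(tab$log2fc_mean[aff_rows] - eff[tab$variant_id[aff_rows]]))
  else NA_real_
  list(sensitivity = sens, fdr = fdr, mean_abs_error = mae,
       n_called = n_called, n_affected = length(affected))
}

#' Run a multi-seed screen benchmark
#'
#' Re-simulates counts for a fixed manifest under a sequence of seeds and
#' collects calling/recovery metrics per seed, plus the pooled t-test
#' p-values of all qualified variants (used for null-calibration checks).
#'
#' @param manifest oligo manifest.
#' @param cfg a \code{\link{sim_config}}; its seed field is replaced by each
#'   element of \code{seeds} in turn.
#' @param seeds integer vector of seeds.
#' @param alpha,adjust analysis settings.
#' @return \code{list(metrics = data.frame(seed, sensitivity, fdr,
#'   mean_abs_error, called_fraction, n_tested), p_values = numeric)}.
#' @export
screen_benchmark <- function(manifest, cfg, seeds, alpha = 0.05,
                             adjust = "BH") {
  rows <- list(); pvals <- list()
  for (s in seeds) {
    cfg$seed <- as.integer(s)
    res <- simulate_screen(manifest, cfg, alpha = alpha, adjust = adjust)
    met <- recovery_metrics(res$calls, res$truth)
    tab <- res$calls$table
    tested <- tab$qualified & !is.na(tab$p)
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s, sensitivity = met$sensitivity, fdr = met$fdr,
      mean_abs_error = met$mean_abs_error,
      called_fraction = length(unique(tab$variant_id[tab$called])) /
        length(unique(tab$variant_id[tested])),
      n_tested = sum(tested))
    pvals[[length(pvals) + 1L]] <- tab$p[tested]
  }
  list(metrics = do.call(rbind, rows), p_values = unlist(pvals))
}
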
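#' Knee-point thresholds on ranked log2 fold changes
#'
#' The effect-size cutoffs are found geometrically on the curve of sorted
#' log2FC values. Sort the values ascending and place them at x positions
#' 0..1 (rank normalized). For the right-side threshold, values below zero
#' are reset to zero; a straight line with the chord slope
#' \eqn{s = \max - \min} of the (by default clamped) curve is slid up from
#' below until it is tangent to the curve; the threshold is the y value at
#' the tangent point, i.e. at \eqn{\mathrm{argmin}_i (y_i - s x_i)}. The
#' left side mirrors this: values above zero are reset to zero and the
#' tangent is taken from above (\eqn{\mathrm{argmax}}). Ties are broken
#' toward the conservative extreme (largest index on the right, smallest on
#' the left), and the construction guarantees
#' \code{left <= 0 <= right}.
#'
#' @param x numeric vector of log2 fold changes (n >= 3, not all equal).
#' @param side \code{"both"} (default), \code{"left"} or \code{"right"}.
#' @param slope \code{"clamped"} (default; chord slope of the clamped
#'   curve) or \code{"original"} (chord slope of the unclamped values).
#' @return \code{list(left =, right =, n =)}; only the requested sides are
#'   present.
#' @export
knee_thresholds <- function(x, side = c("both", "left", "right"),
                            slope = c("clamped", "original")) {
  side <- match.arg(side); slope <- match.arg(slope)
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("knee_thresholds(): need at least 3 finite values",
                  call. = FALSE)
  if (max(x) == min(x))
    stop("knee_thresholds(): all values equal, no threshold defined",
         call. = FALSE)
  y <- sort(x)
  xs <- (seq_len(n) - 1) / (n - 1)
  out <- list(n = n)
  if (side != "left") {
    yc <- pmax(y, 0)
    s <- if (slope == "clamped") max(yc) - min(yc) else max(y) - min(y)
    b <- yc - s * xs
    i <- max(which(b == min(b)))
    out$right <- yc[i]
  }
  if (side != "right") {
    yc <- pmin(y, 0)
    s <- if (slope == "clamped") max(yc) - min(yc) else max(y) - min(y)
    b <- yc - s * xs
    i <- min(which(b == max(b)))
    out$left <- yc[i]
  }
  out[c(intersect(c("left", "right"), names(out)), "n")]
}

#' One-sample t test of per-replicate log2 fold changes against zero
#'
#' Equivalent to a paired test of log2 EAS between the two arms across
#' biological replicates. Zero variance across replicates leaves the
#' statistic undefined; this is reported distinctly (\code{degenerate}),
#' never as a p-value.
#'
#' @param x numeric vector of per-replicate log2FC (>= 2 finite values).
#' @return \code{list(t, p, df, degenerate)}.
#' @export
variant_ttest <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  assert_that(n >= 2, "variant_ttest(): need >= 2 finite replicates")
  s <- sd(x)
  if (s == 0)
    return(list(t = NA_real_, p = NA_real_, df = n - 1L, degenerate = TRUE))
  t <- mean(x) / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1), df = n - 1L, degenerate = FALSE)
}

# vectorized one-sample t over the log2fc_rep* columns of a variant table
ttest_rows <- function(m) {
  n <- rowSums(is.finite(m))
  mu <- rowMeans(m)
  s <- sqrt(pmax(rowSums((m - mu)^2), 0) / (n - 1))
  degenerate <- !is.finite(s) | s == 0 | n < 2
  t <- ifelse(degenerate, NA_real_, mu / (s / sqrt(n)))
  p <- 2 * pt(-abs(t), n - 1)
  data.frame(t = t, p = p, degenerate = degenerate)
}

rep_cols <- function(variants) {
  as.matrix(variants[, grep("^log2fc_rep", names(variants)), drop = FALSE])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up BH with monotonicity enforcement (delegates to
#' \code{stats::p.adjust}); NAs are preserved.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Vector of q-values, \code{q >= p} elementwise.
#' @export
bh_adjust <- function(p) {
  assert_that(all(p >= 0 & p <= 1, na.rm = TRUE),
              "bh_adjust(): p outside [0, 1]")
  p.adjust(p, method = "BH")
}

#' Call preferentially active variants
#'
#' A variant is called iff its mean log2FC lies strictly beyond a knee
#' threshold (\code{> right} or \code{< left}) \emph{and} its replicate-level
#' t test clears \code{alpha} - by default on the BH-adjusted q value
#' (\code{adjust = "none"} uses the raw p-value, the literal reading of the
#' screening procedure). Adjustment is computed over all qualified, testable
#' variants in the table.
#'
#' @param variants variant table from \code{\link{variant_log2fc}} with a
#'   \code{p} column (see \code{\link{variant_ttest}}); rows with
#'   \code{qualified = FALSE} or degenerate tests are never called.
#' @param thresholds result of \code{\link{knee_thresholds}} computed on the
#'   same log2FC vector being called.
#' @param alpha significance level, default 0.05.
#' @param adjust \code{"BH"} (default) or \code{"none"}.
#' @return An object of class \code{call_set}: \code{list(left, right,
#'   alpha, adjust, table)} where \code{table} adds q, called and direction
#'   columns.
#' @export
call_variants <- function(variants, thresholds, alpha = 0.05,
                          adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  tab <- variants
  if (!"qualified" %in% names(tab)) tab$qualified <- TRUE
  testable <- tab$qualified & !is.na(tab$p)
  tab$q <- NA_real_
  tab$q[testable] <- bh_adjust(tab$p[testable])
  crit <- if (adjust == "BH") tab$q else tab$p
  lfc <- tab$log2fc_mean
  beyond <- (lfc > thresholds$right) | (lfc < thresholds$left)
  tab$called <- testable & beyond & !is.na(crit) & crit < alpha
  tab$direction <- ifelse(lfc > thresholds$right, "up",
                          ifelse(lfc < thresholds$left, "down",
                                 NA_character_))
  structure(list(left = thresholds$left, right = thresholds$right,
                 alpha = alpha, adjust = adjust, table = tab),
            class = "call_set")
}

#' @export
print.call_set <- function(x, ...) {
  cat(sprintf(
    "call_set: %d variants (%d qualified), thresholds [%.3f, %.3f], %d called (%s < %g)\n",
    nrow(x$table), sum(x$table$qualified), x$left, x$right,
    sum(x$table$called), if (x$adjust == "BH") "q" else "p", x$alpha))
  invisible(x)
}
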
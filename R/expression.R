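#' Audic-Claverie test for one gene's counts in two libraries
#'
#' Exact conditional test for a difference in a single gene's read count
#' between two libraries of total sizes `N1` and `N2`. Conditional on the
#' gene's pooled count t = x + y, the sample-two count is
#' Binomial(t, N2 / (N1 + N2)) under the null of equal relative
#' expression; the two-sided p-value doubles the smaller inclusive tail,
#' capped at 1. Computed through the binomial CDF, so it is stable for
#' library sizes and counts well beyond 10^6.
#'
#' @param x,y Read counts in sample one / sample two (vectorized).
#' @param N1,N2 Library totals (reads passing all filters per sample).
#' @return Two-sided p-value(s) in `[0, 1]`. Exchange-symmetric:
#'   `ac_test(x, y, N1, N2) == ac_test(y, x, N2, N1)` exactly.
#' @examples
#' ac_test(5, 50, 1e6, 1e6)
#' @export
ac_test <- function(x, y, N1, N2) {
  if (any(x < 0) || any(y < 0)) stop("negative counts")
  if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive")
  # canonicalize the orientation so the exchange symmetry
  # p(x,y,N1,N2) == p(y,x,N2,N1) is exact in floating point, not just
  # mathematically
  sw <- N2 > N1 | (N2 == N1 & y > x)
  xx <- ifelse(sw, y, x); yy <- ifelse(sw, x, y)
  M1 <- ifelse(sw, N2, N1); M2 <- ifelse(sw, N1, N2)
  t <- xx + yy
  q <- M2 / (M1 + M2)
  lower <- stats::pbinom(yy, t, q)
  upper <- stats::pbinom(yy - 1, t, q, lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Call differentially expressed genes
#'
#' Tests every gene with [ac_test()], adjusts by Benjamini-Hochberg, and
#' calls a gene up (higher in sample two) or down when FDR < `fdr_cut` and
#' the normalized fold change reaches `fold_cut`. The fold change uses a
#' 0.5 pseudocount on the normalized counts only — the test itself sees
#' the raw counts.
#'
#' @param counts Data.frame with columns `gene_id`, `x`, `y` (counts in
#'   sample one / two), or a genes-x-2 matrix with rownames.
#' @param N1,N2 Library totals; default to `sum(x)` / `sum(y)`.
#' @param fdr_cut FDR cutoff (default 0.01).
#' @param fold_cut Fold-change cutoff on the normalized scale (default 2).
#' @return Data.frame: `gene_id`, `x`, `y`, `log2fc` (positive = higher in
#'   sample two), `p`, `fdr`, `call` in `up`/`down`/`none`.
#' @export
call_degs <- function(counts, N1 = NULL, N2 = NULL,
                      fdr_cut = 0.01, fold_cut = 2) {
  if (is.matrix(counts)) {
    counts <- data.frame(gene_id = rownames(counts),
                         x = counts[, 1], y = counts[, 2],
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("gene_id", "x", "y") %in% names(counts)))
  if (anyDuplicated(counts$gene_id))
    stop("duplicate gene_id in count table")
  if (is.null(N1)) N1 <- sum(counts$x)
  if (is.null(N2)) N2 <- sum(counts$y)
  res <- counts[, c("gene_id", "x", "y")]
  res$log2fc <- log2(((counts$y + 0.5) / N2) / ((counts$x + 0.5) / N1))
  res$p <- ac_test(counts$x, counts$y, N1, N2)
  res$fdr <- bh_fdr(res$p)
  lfc_cut <- log2(fold_cut)
  res$call <- ifelse(res$fdr < fdr_cut & res$log2fc >= lfc_cut, "up",
              ifelse(res$fdr < fdr_cut & res$log2fc <= -lfc_cut, "down",
                     "none"))
  rownames(res) <- NULL
  res
}

#' qPCR 2^-ddCt ratio of constitutive to extended UTR segments
#'
#' Quantifies the condition-b versus condition-a change of the extended
#' (distal-only) UTR segment relative to the constitutive (shared)
#' segment: ratio = 2^-[(Ct_eUTR_b - Ct_cUTR_b) - (Ct_eUTR_a - Ct_cUTR_a)].
#' A ratio above 1 indicates relatively more extended-UTR product (3' UTR
#' lengthening) in condition b; below 1, shortening.
#'
#' @param ct_cutr_a,ct_eutr_a Ct values of the constitutive / extended
#'   segment in condition a (e.g. normal tissue).
#' @param ct_cutr_b,ct_eutr_b Same in condition b (e.g. tumor).
#' @return The 2^-ddCt ratio.
#' @export
ddct_ratio <- function(ct_cutr_a, ct_eutr_a, ct_cutr_b, ct_eutr_b) {
  stopifnot(is.finite(ct_cutr_a), is.finite(ct_eutr_a),
            is.finite(ct_cutr_b), is.finite(ct_eutr_b))
  ddct <- (ct_eutr_b - ct_cutr_b) - (ct_eutr_a - ct_cutr_a)
  2^(-ddct)
}
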
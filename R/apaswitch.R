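#' Build per-gene tandem-UTR count tables
#'
#' For every gene with at least two admissible polyA sites (region `UTR3`
#' or `downstream1k`), builds the two-sample column-chain table the trend
#' test consumes: sites ordered by increasing 3'-UTR length (strand-aware
#' distance from the gene's UTR anchor, minimum 1 nt), sample one in row
#' one and sample two in row two.
#'
#' Genes are excluded with a recorded reason: fewer than two admissible
#' sites (`"single_site"`), a zero row total in either sample
#' (`"not_expressed"`), or — applied after the expression requirement —
#' fewer than 30 pooled reads (`"min_reads"`). Sites upstream of the
#' anchor (negative UTR length) are dropped with a warning.
#'
#' @param sites Annotated site table from [annotate_sites()].
#' @param samples Character vector of the two sample ids in row order;
#'   defaults to the site table's `samples` attribute.
#' @param min_reads Minimum pooled reads per gene table (default 30).
#' @param regions Admissible region classes.
#' @return List with `tables` (named list of `tandem_table` objects) and
#'   `excluded` (data.frame `gene_id`, `reason`).
#' @export
build_tandem_tables <- function(sites, samples = attr(sites, "samples"),
                                min_reads = 30L,
                                regions = c("UTR3", "downstream1k")) {
  if (is.null(samples) || length(samples) != 2L)
    stop("exactly two sample ids are required (row order = sample order)")
  adm <- !is.na(sites$gene_id) & sites$region %in% regions
  neg <- adm & is.na(sites$utr_length)
  if (any(neg)) {
    warning(sum(neg), " site(s) upstream of their gene anchor dropped")
    adm <- adm & !neg
  }
  sites <- sites[adm, , drop = FALSE]
  cols <- paste0("n_", samples)
  tables <- list(); excluded <- list()
  for (g in unique(sites$gene_id)) {
    gs <- sites[sites$gene_id == g, , drop = FALSE]
    gs <- gs[order(gs$utr_length), , drop = FALSE]
    if (anyDuplicated(gs$utr_length))  # same length => same column; merge
      gs <- .merge_equal_lengths(gs, cols)
    if (nrow(gs) < 2L) {
      excluded[[g]] <- "single_site"; next
    }
    cnt <- t(as.matrix(gs[, cols, drop = FALSE]))
    dimnames(cnt) <- list(samples, NULL)
    if (any(rowSums(cnt) == 0L)) {
      excluded[[g]] <- "not_expressed"; next
    }
    if (sum(cnt) < min_reads) {
      excluded[[g]] <- "min_reads"; next
    }
    tables[[g]] <- tandem_table(g, gs$utr_length, cnt)
  }
  list(
    tables = tables,
    excluded = data.frame(gene_id = names(excluded),
                          reason = unlist(excluded, use.names = FALSE))
  )
}

.merge_equal_lengths <- function(gs, cols) {
  sp <- split(seq_len(nrow(gs)), gs$utr_length)
  out <- gs[vapply(sp, `[`, integer(1), 1L), , drop = FALSE]
  for (j in seq_along(sp))
    out[j, cols] <- colSums(gs[sp[[j]], cols, drop = FALSE])
  out
}

#' Construct a tandem-UTR count table
#'
#' @param gene_id Gene identifier.
#' @param utr_lengths Strictly increasing positive UTR lengths (nt), one
#'   per tandem site.
#' @param counts 2 x k matrix of read counts; row 1 = sample one, row 2 =
#'   sample two.
#' @return Object of class `tandem_table`.
#' @export
tandem_table <- function(gene_id, utr_lengths, counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 2L) stop("counts must have two rows (the two samples)")
  if (ncol(counts) != length(utr_lengths))
    stop("counts columns must match utr_lengths")
  if (length(utr_lengths) < 2L) stop("a tandem table needs >= 2 sites")
  if (any(utr_lengths <= 0) || any(diff(utr_lengths) <= 0))
    stop("utr_lengths must be positive and strictly increasing")
  if (any(counts < 0)) stop("negative counts")
  structure(list(gene_id = gene_id,
                 utr_lengths = as.numeric(utr_lengths),
                 counts = counts, n = sum(counts)),
            class = "tandem_table")
}

#' @export
print.tandem_table <- function(x, ...) {
  cat("Tandem 3' UTR table for", x$gene_id, "-", ncol(x$counts),
      "sites,", x$n, "reads\n")
  m <- rbind(`UTR length (nt)` = x$utr_lengths, x$counts)
  print(m)
  invisible(x)
}

#' Tandem APA switch index (count-weighted Pearson correlation)
#'
#' The switch index is the Pearson correlation r over the table's n
#' expanded read observations, where each read contributes X = 1 (sample
#' one) or 2 (sample two) and Y = the UTR length of its site. It is
#' computed exactly from count-weighted moments, never by expansion.
#' r > 0 means sample two's reads sit at longer UTRs (lengthening in
#' sample two); r < 0 means shortening.
#'
#' @param table A `tandem_table`.
#' @return r in `[-1, 1]`, or `NA` when degenerate (all reads in one
#'   sample, or all reads at one UTR length).
#' @export
tsi <- function(table) {
  stopifnot(inherits(table, "tandem_table"))
  cnt <- table$counts; y <- table$utr_lengths
  n <- sum(cnt)
  n1 <- sum(cnt[1, ]); n2 <- sum(cnt[2, ])
  if (n1 == 0 || n2 == 0) return(NA_real_)
  # with X binary the Pearson r reduces exactly to
  # sqrt(n1 n2) (ybar2 - ybar1) / (n sd_Y); centering Y keeps it stable
  # and makes the sample-swap antisymmetry exact in floating point
  col_tot <- colSums(cnt)
  ybar <- sum(col_tot * y) / n
  vy <- sum(col_tot * (y - ybar)^2) / n
  if (vy <= 0) return(NA_real_)
  ybar1 <- sum(cnt[1, ] * (y - ybar)) / n1
  ybar2 <- sum(cnt[2, ] * (y - ybar)) / n2
  r <- sqrt(n1 * n2) * (ybar2 - ybar1) / (n * sqrt(vy))
  max(-1, min(1, r))
}

#' Linear trend test on one tandem table
#'
#' Refers M^2 = (n - 1) r^2 to the chi-square distribution with one degree
#' of freedom; the direction of a significant switch is read off the sign
#' of r.
#'
#' @param table A `tandem_table`.
#' @return One-row data.frame: `gene_id`, `k`, `n`, `tsi`, `m2`, `p`
#'   (upper-tail chi-square probability), plus `reason` (`"degenerate"`
#'   when the index is undefined, else `NA`).
#' @export
trend_test <- function(table) {
  r <- tsi(table)
  if (is.na(r))
    return(data.frame(gene_id = table$gene_id, k = ncol(table$counts),
                      n = table$n, tsi = NA_real_, m2 = NA_real_,
                      p = NA_real_, reason = "degenerate",
                      stringsAsFactors = FALSE))
  m2 <- (table$n - 1) * r^2
  data.frame(gene_id = table$gene_id, k = ncol(table$counts), n = table$n,
             tsi = r, m2 = m2,
             p = stats::pchisq(m2, df = 1, lower.tail = FALSE),
             reason = NA_character_, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Standard step-up adjustment with monotonicity enforcement,
#' order-preserving. Shared by the switch, expression and enrichment
#' stages.
#'
#' @param p Vector of p-values in `[0, 1]` (NAs passed through).
#' @return Adjusted values, same order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Call shortened / lengthened genes from trend-test results
#'
#' @param results Data.frame with columns `tsi` and `fdr`.
#' @param r_cut Absolute switch-index cutoff (default 0.1).
#' @param fdr_cut FDR cutoff (default 0.01).
#' @return Character vector: `"shortened"` (r < -r_cut and fdr < fdr_cut),
#'   `"lengthened"` (r > r_cut and fdr < fdr_cut), else `"none"`.
#' @export
call_switch <- function(results, r_cut = 0.1, fdr_cut = 0.01) {
  ifelse(is.na(results$tsi) | is.na(results$fdr), "none",
  ifelse(results$tsi < -r_cut & results$fdr < fdr_cut, "shortened",
  ifelse(results$tsi >  r_cut & results$fdr < fdr_cut, "lengthened",
         "none")))
}

#' Fit the tandem-UTR switch model over a set of genes
#'
#' The central fitting function of the package: runs the trend test on
#' every tandem table, adjusts p-values by Benjamini-Hochberg over the
#' tested genes only, and calls each gene shortened, lengthened or
#' unchanged. Genes whose index is degenerate are reported with a reason
#' rather than silently dropped and do not enter the FDR.
#'
#' @param tables A list of `tandem_table` objects, or the list returned by
#'   [build_tandem_tables()] (its `excluded` genes are carried through).
#' @param r_cut Absolute switch-index cutoff (default 0.1).
#' @param fdr_cut FDR cutoff (default 0.01).
#' @return An object of class `apa_switch` with components `results`
#'   (per-gene data.frame: `gene_id`, `k`, `n`, `tsi`, `m2`, `p`, `fdr`,
#'   `call`), `excluded`, `r_cut`, `fdr_cut`.
#' @seealso [tsi()], [trend_test()], [call_switch()]
#' @examples
#' tt <- tandem_table("g1", c(100, 500), rbind(c(30, 10), c(10, 30)))
#' fit <- apa_switch(list(g1 = tt))
#' coef(fit)
#' @export
apa_switch <- function(tables, r_cut = 0.1, fdr_cut = 0.01) {
  cl <- match.call()
  excluded <- data.frame(gene_id = character(0), reason = character(0))
  if (is.list(tables) && !is.null(tables$tables)) {
    excluded <- tables$excluded
    tables <- tables$tables
  }
  if (length(tables) == 0L) stop("no tandem tables to test")
  rows <- do.call(rbind, lapply(tables, trend_test))
  degen <- !is.na(rows$reason)
  if (any(degen))
    excluded <- rbind(excluded, data.frame(gene_id = rows$gene_id[degen],
                                           reason = rows$reason[degen]))
  res <- rows[!degen, setdiff(names(rows), "reason"), drop = FALSE]
  res$fdr <- bh_fdr(res$p)
  res$call <- call_switch(res, r_cut, fdr_cut)
  rownames(res) <- NULL
  structure(list(results = res, excluded = excluded, r_cut = r_cut,
                 fdr_cut = fdr_cut, call = cl),
            class = "apa_switch")
}

#' @export
print.apa_switch <- function(x, ...) {
  cat("Tandem 3' UTR switch fit:", nrow(x$results), "genes tested,",
      nrow(x$excluded), "excluded\n")
  tab <- table(factor(x$results$call,
                      levels = c("shortened", "lengthened", "none")))
  cat(sprintf("  shortened %d | lengthened %d | none %d  (|r| > %g, FDR < %g)\n",
              tab["shortened"], tab["lengthened"], tab["none"],
              x$r_cut, x$fdr_cut))
  invisible(x)
}

#' @export
summary.apa_switch <- function(object, ...) {
  res <- object$results
  out <- list(
    n_tested = nrow(res),
    n_excluded = nrow(object$excluded),
    calls = table(factor(res$call, c("shortened", "lengthened", "none"))),
    excluded_reasons = if (nrow(object$excluded) > 0L)
      table(object$excluded$reason) else table(character(0)),
    tsi_quartiles = stats::quantile(res$tsi, c(0, .25, .5, .75, 1)),
    r_cut = object$r_cut, fdr_cut = object$fdr_cut
  )
  class(out) <- "summary.apa_switch"
  out
}

#' @export
print.summary.apa_switch <- function(x, ...) {
  cat("Tandem 3' UTR switch fit\n")
  cat("  genes tested: ", x$n_tested, ", excluded: ", x$n_excluded, "\n",
      sep = "")
  if (length(x$excluded_reasons) > 0L) {
    cat("  exclusion reasons:\n")
    for (r in names(x$excluded_reasons))
      cat("    ", r, ": ", x$excluded_reasons[[r]], "\n", sep = "")
  }
  cat(sprintf("  calls at |r| > %g, FDR < %g:\n", x$r_cut, x$fdr_cut))
  print(x$calls)
  cat("  switch index quartiles:\n")
  print(round(x$tsi_quartiles, 4))
  invisible(x)
}

#' @export
coef.apa_switch <- function(object, ...) {
  stats::setNames(object$results$tsi, object$results$gene_id)
}

#' Plot a switch fit: switch index against pooled read depth
#'
#' Called genes are highlighted (shortened below, lengthened above the
#' index cutoffs).
#'
#' @param x An `apa_switch` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.apa_switch <- function(x, ...) {
  res <- x$results
  col <- ifelse(res$call == "shortened", "red3",
                ifelse(res$call == "lengthened", "blue3", "grey60"))
  graphics::plot(log10(res$n), res$tsi, col = col, pch = 16,
                 xlab = "log10 reads per gene",
                 ylab = "tandem APA switch index (r)", ...)
  graphics::abline(h = c(-x$r_cut, x$r_cut), lty = 2, col = "grey40")
  invisible(x)
}
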
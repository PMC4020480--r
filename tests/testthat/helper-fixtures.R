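# Shared fixture builders and independent oracles for the test suite.

write_tmp <- function(lines, ext) {
  p <- tempfile(fileext = ext)
  writeLines(lines, p)
  p
}

# Random two-sample tandem table (no degenerate margins by construction).
random_tandem_table <- function(id = "g", k = sample(2:5, 1),
                                n_range = c(30, 300)) {
  y <- sort(sample(50:3000, k))
  repeat {
    n <- sample(n_range[1]:n_range[2], 1)
    cnt <- matrix(stats::rmultinom(1, n, rep(1 / (2 * k), 2 * k)), nrow = 2)
    if (all(rowSums(cnt) > 0) && sum(colSums(cnt) > 0) >= 2) break
  }
  tandem_table(id, y, cnt)
}

# Brute-force Pearson correlation over the expanded per-read vectors --
# the independent oracle for the count-weighted switch index.
expanded_pearson <- function(tt) {
  x <- rep(c(1, 2), rowSums(tt$counts))
  y <- c(rep(tt$utr_lengths, tt$counts[1, ]),
         rep(tt$utr_lengths, tt$counts[2, ]))
  suppressWarnings(stats::cor(x, y))
}

# Direct no-log summation of the conditional read-count mass function
# p(y | x) = (N2/N1)^y (x+y)! / (x! y! (1 + N2/N1)^(x+y)) over both
# inclusive tails -- the independent oracle for ac_test.
ac_brute <- function(x, y, N1, N2) {
  t <- x + y
  f <- N2 / N1
  pm <- function(yy) f^yy * choose(t, yy) / (1 + f)^t
  lower <- sum(pm(0:y))
  upper <- sum(pm(y:t))
  min(1, 2 * min(lower, upper))
}

# Direct summation of the hypergeometric upper tail P(X >= k0) for the
# EASE oracle: term-by-term mass summation (the counting definition,
# evaluated through log-binomials to stay representable), independent of
# the closed-form tail used by the implementation.
hyper_tail_brute <- function(k0, n, K, N) {
  kk <- max(0, k0):min(n, K)
  sum(exp(lchoose(K, kk) + lchoose(N - K, n - kk) - lchoose(N, n)))
}

# Independent longest single-base run scan (character-by-character loop).
longest_run_brute <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  best <- 0L; cur <- 0L
  for (i in seq_along(ch)) {
    cur <- if (i > 1 && ch[i] == ch[i - 1]) cur + 1L else 1L
    best <- max(best, cur)
  }
  best
}

# A tiny two-gene reference on one chromosome, with known coordinates,
# used by the sitecall unit tests. Gene A: '+' strand, anchor 100,
# tes 400 (terminal base 399). Gene B: '-' strand on the same chromosome
# far downstream, anchor 1600, tes 1300.
tiny_reference <- function() {
  seq <- strrep("C", 2000)
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  tx <- data.frame(
    gene_id = c("geneA", "geneB"), tx_id = c("geneA|t1", "geneB|t1"),
    chrom = "chr1", strand = c("+", "-"),
    tx_start = c(50L, 1300L), tx_end = c(400L, 1700L),
    cds_end = c(100L, 1600L), tes = c(400L, 1300L),
    coding = TRUE, cds_from_last_cds = FALSE, zero_utr = FALSE,
    exon_starts = I(list(50L, 1300L)), exon_ends = I(list(400L, 1700L)),
    stringsAsFactors = FALSE
  )
  list(genome = genome, transcripts = tx)
}

# Events data.frame shorthand
ev <- function(pos, strand = "+", chrom = "chr1", sample_id = "s1") {
  data.frame(chrom = chrom, strand = strand, pos = as.integer(pos),
             sample_id = sample_id, stringsAsFactors = FALSE)
}

# Strict and inclusive tails of the exact label-permutation null of |r|
# for one tandem table. Uses the fact that, with margins fixed, r is an
# increasing affine function of S = sum of the Y values assigned to
# sample two, so |r| >= |r_obs| iff |S - n2*mean(Y)| >= |S_obs - ...|.
permutation_tails <- function(tab, B) {
  yv <- rep(tab$utr_lengths, colSums(tab$counts))
  n2 <- sum(tab$counts[2, ]); n <- length(yv)
  s_obs <- sum(rep(tab$utr_lengths, tab$counts[2, ]))
  center <- n2 * mean(yv)
  dev_obs <- abs(s_obs - center)
  dev <- abs(replicate(B, sum(yv[sample.int(n, n2)])) - center)
  c(strict = sum(dev > dev_obs + 1e-9) / B,
    inclusive = sum(dev >= dev_obs - 1e-9) / B)
}
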
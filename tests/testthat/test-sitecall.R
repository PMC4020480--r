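test_that("cleavage position is the strand-aware 3' terminus", {
  gr <- GenomicRanges::GRanges("chr1",
                               IRanges::IRanges(start = 101, end = 140),
                               strand = c("+", "-"))
  ev <- extract_cleavage(gr, sample_id = "s1")
  expect_equal(ev$pos[ev$strand == "+"], 139L)  # [100,140) -> 139
  expect_equal(ev$pos[ev$strand == "-"], 100L)
})

test_that("SAM input drops multi-mappers under unique_only", {
  skip_if_not_installed("Rsamtools")
  skip_if_not_installed("GenomicAlignments")
  sam <- write_tmp(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:1000",
    "r1\t0\tchr1\t101\t42\t40M\t*\t0\t0\t*\t*\tNH:i:1",
    "r2\t16\tchr1\t201\t42\t40M\t*\t0\t0\t*\t*\tNH:i:1",
    "r3\t0\tchr1\t301\t0\t40M\t*\t0\t0\t*\t*\tNH:i:3"
  ), ".sam")
  ev <- extract_cleavage(sam, sample_id = "s1", unique_only = TRUE)
  expect_equal(nrow(ev), 2L)
  expect_equal(sort(ev$pos), c(139L, 200L))  # + read end, - read start
})

test_that("internal-priming filter applies all three window rules", {
  # genome crafted so each event's downstream 20-nt window is known
  seq <- paste0(
    strrep("C", 10),                    # events cleave at pos 9 (0-based)
    strrep("A", 20),                    # window 1: all A -> all rules fire
    strrep("C", 10),
    "ACGTACGTACGTACGTACGT",             # window 2: clean -> kept
    strrep("C", 10),
    "AACAACAACAACAACAACAA",             # padding
    strrep("C", 10)
  )
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  events <- ev(c(9, 39), sample_id = "s1")
  out <- internal_priming_filter(events, genome)
  expect_equal(out$filtered$pos, 9L)
  expect_equal(out$kept$pos, 39L)

  # exactly 12 scattered A among 20 -> filtered by the >=12 rule;
  # 11 A with no 8-mer and no G/A pattern -> kept
  mk <- function(w) Biostrings::DNAStringSet(c(chr1 = paste0("CCCCC", w)))
  twelve <- paste0(strrep("AAAC", 4), "CCCC")            # 12 A, runs of 3
  eleven <- paste0(strrep("AAAC", 3), "AAC", "CCCCC")    # 11 A
  expect_equal(nchar(gsub("[^A]", "", twelve)), 12L)
  expect_equal(nchar(gsub("[^A]", "", eleven)), 11L)
  out12 <- internal_priming_filter(ev(4), mk(twelve))
  expect_equal(nrow(out12$filtered), 1L)
  out11 <- internal_priming_filter(ev(4), mk(eleven))
  expect_equal(nrow(out11$kept), 1L)

  # the G/A disruption pattern alone triggers the filter
  gpat <- "GAAAAGAAAGCCCCCCCCCC"
  outg <- internal_priming_filter(ev(4), mk(gpat))
  expect_equal(nrow(outg$filtered), 1L)
  # contiguous 8-mer with fewer than 12 total A triggers too
  a8 <- "AAAAAAAACCCCCCCCCCCC"
  out8 <- internal_priming_filter(ev(4), mk(a8))
  expect_equal(nrow(out8$filtered), 1L)
})

test_that("minus-strand windows are reverse-complemented", {
  # for a '-' event at pos 30, downstream (transcription) window is
  # genomic [10,29] reverse complemented; make that region all T so the
  # window reads all A
  seq <- paste0(strrep("C", 10), strrep("T", 20), strrep("C", 70))
  genome <- Biostrings::DNAStringSet(c(chr1 = seq))
  out <- internal_priming_filter(ev(30, strand = "-"), genome)
  expect_equal(nrow(out$filtered), 1L)
  # same position on '+' looks at [31,50] = all C -> kept
  outp <- internal_priming_filter(ev(30, strand = "+"), genome)
  expect_equal(nrow(outp$kept), 1L)
})

test_that("24-nt single-linkage clustering follows the gap and 1-read rules", {
  e <- ev(c(100, 110, 130))
  s <- cluster_events(e, gap = 24)
  expect_equal(nrow(s), 1L)           # gaps 10 and 20 chain together
  expect_equal(s$total, 3L)

  e2 <- ev(c(100, 130))
  s2 <- cluster_events(e2, gap = 24)  # 30 > 24: two singletons, discarded
  expect_equal(nrow(s2), 0L)

  # permuted input order gives identical clusters
  set.seed(31)
  e3 <- ev(sample(c(100, 105, 200, 203, 500)),
           sample_id = sample(c("s1", "s2"), 5, TRUE))
  s3a <- cluster_events(e3, samples = c("s1", "s2"))
  s3b <- cluster_events(e3[sample(nrow(e3)), ], samples = c("s1", "s2"))
  expect_identical(s3a, s3b)
})

test_that("cluster representative is the pooled-count mode, ties 3'-most", {
  e <- rbind(ev(c(100, 100, 110)), ev(c(110)))
  s <- cluster_events(e)               # 100 x2, 110 x2: tie -> 3'-most on +
  expect_equal(s$pos, 110L)
  em <- rbind(ev(c(100, 100, 110), strand = "-"), ev(110, strand = "-"))
  sm <- cluster_events(em)             # on '-' the 3'-most is the smallest
  expect_equal(sm$pos, 100L)
  e2 <- rbind(ev(c(100, 100, 100, 110)))
  expect_equal(cluster_events(e2)$pos, 100L)  # clear mode wins
})

test_that("clustering is invariant to sample labels and partitions events", {
  set.seed(32)
  pos <- sort(sample(1:5000, 300, replace = TRUE))
  e <- ev(pos, sample_id = sample(c("s1", "s2"), 300, TRUE))
  s <- cluster_events(e, samples = c("s1", "s2"))
  # swap labels: counts permute, geometry identical
  e_sw <- e; e_sw$sample_id <- ifelse(e$sample_id == "s1", "s2", "s1")
  s_sw <- cluster_events(e_sw, samples = c("s1", "s2"))
  expect_equal(s$pos, s_sw$pos)
  expect_equal(s$n_s1, s_sw$n_s2)
  # within every cluster consecutive member positions differ by <= 24:
  # cluster spans never contain a gap > 24 (verified via member scan)
  for (i in seq_len(nrow(s))) {
    members <- sort(unique(e$pos[e$pos >= s$cl_start[i] &
                                   e$pos <= s$cl_end[i]]))
    expect_true(all(diff(members) <= 24))
  }
  # every kept event is in exactly one cluster; discarded = singletons
  expect_equal(sum(s$total) +
                 sum(!pos %in% unlist(Map(seq, s$cl_start, s$cl_end))),
               length(pos))
})

test_that("tier and region annotation follow the priority rules", {
  ref <- tiny_reference()
  known <- data.frame(chrom = "chr1", strand = "+", pos = 250L,
                      source_id = "k1")
  # site 10 nt upstream of geneA's terminal base (399)
  s <- cluster_events(ev(rep(389, 3)))
  a <- annotate_sites(s, ref$transcripts, known)
  expect_equal(a$tier, "UCSC")
  expect_equal(a$region, "UTR3")
  expect_equal(a$gene_id, "geneA")
  expect_equal(a$utr_length, 389L - 100L + 1L)

  # site at the known DB position but 149 nt from the tes -> TianDB
  s2 <- annotate_sites(cluster_events(ev(rep(250, 2))),
                       ref$transcripts, known)
  expect_equal(s2$tier, "TianDB")
  expect_equal(s2$region, "UTR3")

  # site 300 nt past the tes, no DB match -> novel, downstream1k
  s3 <- annotate_sites(cluster_events(ev(rep(700, 2))),
                       ref$transcripts, known)
  expect_equal(s3$tier, "novel")
  expect_equal(s3$region, "downstream1k")
  expect_equal(s3$gene_id, "geneA")

  # UCSC priority over TianDB when both match
  known2 <- data.frame(chrom = "chr1", strand = "+", pos = 389L,
                       source_id = "k2")
  s4 <- annotate_sites(cluster_events(ev(rep(389, 2))),
                       ref$transcripts, known2)
  expect_equal(s4$tier, "UCSC")

  # minus-strand gene: site 10 nt upstream of its terminal base (1300)
  s5 <- annotate_sites(cluster_events(ev(rep(1310, 2), strand = "-")),
                       ref$transcripts, known)
  expect_equal(s5$tier, "UCSC")
  expect_equal(s5$gene_id, "geneB")
  expect_equal(s5$utr_length, 1600L - 1310L)
})

test_that("equidistant transcript-end ties resolve to the 5'-side gene", {
  tx <- rbind(tiny_reference()$transcripts,
              data.frame(gene_id = "geneC", tx_id = "geneC|t1",
                         chrom = "chr1", strand = "+",
                         tx_start = 420L, tx_end = 448L,
                         cds_end = 430L, tes = 448L, coding = TRUE,
                         cds_from_last_cds = FALSE, zero_utr = FALSE,
                         exon_starts = I(list(420L)),
                         exon_ends = I(list(448L))))
  # geneA terminal base 399, geneC terminal base 447; pos 423 is 24 from both
  s <- cluster_events(ev(rep(423, 2)))
  expect_message(a <- annotate_sites(s, tx, NULL), "5'-side")
  expect_equal(a$gene_id, "geneA")
})

test_that("run summary reproduces stage percentages to one decimal", {
  out <- summarize_run(raw = c(23059686, 16903581),
                       clean = c(21807523, 15623947),
                       mapped = c(16229331, 12990709),
                       unique_mapped = c(13064869, 10405340),
                       nuclear = c(12925041, 10188625),
                       ip_pass = c(8543416, 7056710))
  pick <- function(p, s) out$pct[out$parameter == p][s]
  expect_equal(pick("clean", 1), 94.6)
  expect_equal(pick("mapped", 2), 76.9)
  expect_equal(pick("raw", 1), 100.0)
  expect_equal(summarize_run(10, 10, 10, 10, 10, 10)$pct, rep(100.0, 6))
  expect_error(summarize_run(100, 110, 90, 80, 70, 60), "monotone")
})
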
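cfg_small <- sim_config(n_genes = 12, depth = 3000, seed = 99)

test_that("reference generation is deterministic and respects constraints", {
  ref1 <- make_reference(cfg_small)
  ref2 <- make_reference(cfg_small)
  expect_identical(as.character(ref1$genome), as.character(ref2$genome))
  expect_identical(ref1$truth_sites, ref2$truth_sites)

  d1 <- tempfile(); d2 <- tempfile()
  write_reference(ref1, d1); write_reference(ref2, d2)
  for (f in c("genome.fa", "transcripts.bed", "known_sites.bed",
              "gene_sets.gmt"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)

  # >= 60 nt spacing between tandem sites of every gene
  by_gene <- split(ref1$truth_sites$utr_length, ref1$truth_sites$gene_id)
  expect_true(all(vapply(by_gene, function(l) all(diff(sort(l)) >= 60),
                         logical(1))))
  # configured fraction of interior sites registered in the known DB
  interior <- ref1$truth_sites[!ref1$truth_sites$distal, ]
  expect_equal(nrow(ref1$known_db),
               round(cfg_small$known_frac * nrow(interior)))
})

test_that("written reference files re-read into the same models", {
  ref <- make_reference(cfg_small)
  d <- tempfile()
  p <- write_reference(ref, d)
  g <- read_genome(p["genome"])
  expect_equal(as.character(g), as.character(ref$genome))
  tx <- read_transcripts(p["transcripts"], genome = g)
  expect_equal(tx$gene_id, ref$transcripts$gene_id)
  expect_equal(tx$cds_end, ref$transcripts$cds_end)
  expect_equal(tx$tes, ref$transcripts$tes)
  kdb <- read_known_sites(p["known"], genome = g)
  expect_equal(kdb$pos, ref$known_db$pos)
  sets <- read_gmt(p["gmt"])
  expect_equal(sets[[1]], ref$gene_sets[[1]])
})

test_that("jitter-0 decoy-0 reads cleave exactly at true sites", {
  cfg <- sim_config(n_genes = 10, depth = 2000, jitter_sd = 0,
                    decoy_rate = 0, seed = 7)
  ref <- make_reference(cfg)
  sim <- simulate_reads(ref)
  for (s in names(sim$events)) {
    ev <- sim$events[[s]]
    expect_true(all(ev$pos == ev$site_pos))
    expect_true(all(ev$pos %in% ref$truth_sites$pos))
  }
})

test_that("read sequences are poly-T plus upstream reverse complement", {
  cfg <- sim_config(n_genes = 6, depth = 400, jitter_sd = 0,
                    decoy_rate = 0, seed = 15)
  ref <- make_reference(cfg)
  sim <- simulate_reads(ref)
  reads <- sim$reads$sample1
  ev <- sim$events$sample1
  expect_true(all(grepl("^TTTTTTTT", reads$seq)))
  i <- 1L
  trimmed <- trim_polyT(reads[i, , drop = FALSE])$kept$seq
  chrom_seq <- as.character(ref$genome[[ev$chrom[i]]])
  if (ev$strand[i] == "+") {
    up <- substring(chrom_seq, ev$pos[i] - 48, ev$pos[i] + 1)  # 1-based
    expect_equal(trimmed, as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(up))))
  } else {
    up <- substring(chrom_seq, ev$pos[i] + 1, ev$pos[i] + 50)
    expect_equal(trimmed, up)
  }
})

test_that("realized site counts track planted usage proportions", {
  cfg <- sim_config(n_genes = 15, depth = 30000, jitter_sd = 0,
                    decoy_rate = 0, seed = 23)
  ref <- make_reference(cfg)
  sim <- simulate_reads(ref)
  sc <- sim$site_counts
  for (s in c("sample1", "sample2")) {
    for (g in unique(sc$gene_id)) {
      rows <- sc[sc$gene_id == g & sc$sample_id == s, ]
      n <- sum(rows$count)
      if (n < 100) next
      usage <- if (s == "sample1")
        ref$truth_genes$usage_s1[[match(g, ref$truth_genes$gene_id)]]
      else ref$truth_genes$usage_s2[[match(g, ref$truth_genes$gene_id)]]
      # per-site binomial 99.9% band around the planted proportion
      ok <- abs(rows$count / n - usage) <=
        3.3 * sqrt(usage * (1 - usage) / n) + 1 / n
      expect_true(all(ok), info = paste(g, s))
    }
  }
})

test_that("decoy reads all fail, true-site reads all pass, the IP filter", {
  cfg <- sim_config(n_genes = 10, depth = 2000, decoy_rate = 0.1, seed = 31)
  ref <- make_reference(cfg)
  sim <- simulate_reads(ref)
  ev <- do.call(rbind, sim$events)
  out <- internal_priming_filter(
    ev[, c("chrom", "strand", "pos", "sample_id")], ref$genome)
  filtered_keys <- paste(out$filtered$chrom, out$filtered$pos)
  decoy_keys <- paste(ev$chrom[ev$decoy], ev$pos[ev$decoy])
  true_keys <- paste(ev$chrom[!ev$decoy], ev$pos[!ev$decoy])
  expect_true(all(decoy_keys %in% filtered_keys))
  expect_false(any(true_keys %in% filtered_keys))
  expect_equal(nrow(out$filtered), sum(ev$decoy))
})

test_that("score_recovery is perfect on truth vs truth", {
  ref <- make_reference(cfg_small)
  truth_as_sites <- data.frame(
    chrom = ref$truth_sites$chrom, strand = ref$truth_sites$strand,
    pos = ref$truth_sites$pos)
  sc <- score_recovery(truth_as_sites, ref)
  expect_equal(sc$site_sensitivity, 1.0)
  expect_true(all(sc$site_recovery$pos_error == 0))
  expect_error(score_recovery(truth_as_sites, ref,
                              switch_fit = structure(list(results =
                                data.frame(gene_id = "nope", call = "none")),
                                class = "apa_switch")),
               "absent")
})

test_that("simulated FASTQ and BED outputs are byte-stable under the seed", {
  cfg <- sim_config(n_genes = 8, depth = 500, seed = 77)
  ref <- make_reference(cfg)
  d1 <- tempfile(); d2 <- tempfile()
  simulate_reads(ref, dir = d1)
  simulate_reads(ref, dir = d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
})
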
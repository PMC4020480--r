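#' Configuration for the synthetic 3'-end sequencing world
#'
#' Describes a toy genome of non-overlapping single-exon genes on both
#' strands, each with 2-4 tandem polyA sites at >= 60 nt spacing, two
#' libraries of oligo-dT primed reads with programmable usage shifts,
#' gene-level abundance differences, cleavage-position jitter, and A-rich
#' internal-priming decoy loci. All downstream windows of true sites are
#' sanitized to fewer than 8 consecutive and fewer than 12 total `A`, so
#' no true site can trip the internal-priming filter; decoy windows are
#' all-`A`, so every decoy must.
#'
#' @param n_genes Number of genes.
#' @param sites_per_gene Integer range (min, max) of tandem sites per gene.
#' @param utr_length_range Range (nt) of the distal-most UTR length.
#' @param min_spacing Minimum spacing between tandem sites (nt, >= 60).
#' @param frac_shortened,frac_lengthened Fractions of genes planted with a
#'   proximal-shift (sample two shortened) / distal-shift (lengthened).
#' @param shift_proximal Two proximal-usage fractions `c(lo, hi)`: a
#'   shortened gene uses the proximal site with fraction `lo` in sample
#'   one and `hi` in sample two (reversed for lengthened genes).
#' @param frac_up,frac_dn Fractions of genes planted with higher / lower
#'   expression in sample two.
#' @param expr_fold Fold change of planted expression differences.
#' @param expr_meanlog,expr_sdlog Lognormal parameters of relative gene
#'   expression.
#' @param depth Reads per library mapping to genes (decoys come on top).
#' @param jitter_sd SD (nt) of the Normal cleavage jitter, truncated at
#'   +/- 20 so sites >= 60 nt apart cannot merge under the 24-nt rule.
#' @param decoy_rate Decoy reads as a fraction of `depth`.
#' @param known_frac Fraction of true sites registered in the known-site
#'   database (exercises the second annotation tier).
#' @param seed Integer seed; recorded in all outputs.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L, sites_per_gene = c(2L, 4L),
                       utr_length_range = c(300L, 1500L), min_spacing = 60L,
                       frac_shortened = 0.15, frac_lengthened = 0.15,
                       shift_proximal = c(0.3, 0.7),
                       frac_up = 0.1, frac_dn = 0.1, expr_fold = 4,
                       expr_meanlog = 4, expr_sdlog = 1,
                       depth = 50000L, jitter_sd = 5, decoy_rate = 0.05,
                       known_frac = 0.5, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              sites_per_gene = as.integer(sites_per_gene),
              utr_length_range = as.integer(utr_length_range),
              min_spacing = as.integer(min_spacing),
              frac_shortened = frac_shortened,
              frac_lengthened = frac_lengthened,
              shift_proximal = shift_proximal,
              frac_up = frac_up, frac_dn = frac_dn, expr_fold = expr_fold,
              expr_meanlog = expr_meanlog, expr_sdlog = expr_sdlog,
              depth = as.integer(depth), jitter_sd = jitter_sd,
              decoy_rate = decoy_rate, known_frac = known_frac,
              seed = as.integer(seed))
  stopifnot(cfg$min_spacing >= 60L,
            all(c(frac_shortened, frac_lengthened, frac_up, frac_dn,
                  decoy_rate, known_frac) >= 0),
            frac_shortened + frac_lengthened <= 1, frac_up + frac_dn <= 1,
            cfg$depth > 0L, cfg$sites_per_gene[1] >= 2L,
            diff(cfg$shift_proximal) > 0)
  class(cfg) <- "sim_config"
  cfg
}

# Sample one 20-nt-safe stretch: no >= 8 A run, < 12 A per any 20-nt
# window, no G/A priming pattern. Low A weight makes rejection rare.
.safe_stretch <- function(len) {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
                      prob = c(0.08, 0.31, 0.30, 0.31)), collapse = "")
    if (grepl("AAAA", s, fixed = TRUE)) next
    if (grepl("GA{4,}GA{3,}G", s)) next
    a_pos <- gregexpr("A", s, fixed = TRUE)[[1]]
    if (a_pos[1] > 0 && length(a_pos) >= 12 &&
        any(a_pos[seq_len(length(a_pos) - 11) + 11] - a_pos[seq_len(length(a_pos) - 11)] < 20))
      next
    return(s)
  }
}

.random_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Build the synthetic reference: genome, transcripts, known sites, gene sets
#'
#' Deterministic given `config$seed`. Genes alternate strands and never
#' overlap; each gene's distal-most site coincides with its annotated
#' transcript end (so the distal site annotates as first-tier), interior
#' sites are registered in the known-site database at the configured
#' fraction, and the remainder are left novel. Intergenic all-`A` decoy
#' loci are planted for the internal-priming filter to catch. One gene set
#' collects the planted shortened genes (so enrichment has signal); decoy
#' sets are random.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_reference`: `genome` (`DNAStringSet`),
#'   `transcripts`, `known_db`, `gene_sets`, `truth_sites` (per-site truth:
#'   `gene_id`, `chrom`, `strand`, `pos`, `utr_length`, `in_known_db`),
#'   `decoys` (decoy loci), `config`.
#' @export
make_reference <- function(config = sim_config()) {
  set.seed(config$seed)
  n <- config$n_genes
  genes_per_chrom <- 25L
  n_chrom <- ceiling(n / genes_per_chrom)
  gap <- 300L          # intergenic gap; decoys live here
  cds_len <- 300L      # single coding exon upstream of the UTR
  utr_min <- config$utr_length_range[1]; utr_max <- config$utr_length_range[2]
  k_rng <- config$sites_per_gene
  tx_rows <- truth_rows <- list()
  chrom_seq <- stats::setNames(vector("list", n_chrom),
                               paste0("chr", seq_len(n_chrom)))
  decoy_rows <- list()
  gid <- 0L
  for (ci in seq_len(n_chrom)) {
    parts <- character(0); cur <- 0L
    n_here <- min(genes_per_chrom, n - (ci - 1L) * genes_per_chrom)
    for (j in seq_len(n_here)) {
      gid <- gid + 1L
      gene_id <- sprintf("G%04d", gid)
      strand <- if (gid %% 2L == 1L) "+" else "-"
      k <- sample(seq(k_rng[1], k_rng[2]), 1L)
      utr_total <- sample(seq(utr_min, utr_max), 1L)
      # site UTR lengths: distal at utr_total, others spaced >= min_spacing
      max_sites <- 1L + (utr_total - 30L) %/% config$min_spacing
      k <- min(k, max_sites)
      # constructive spacing draw: interior lengths 30 + (j-1)*spacing plus
      # sorted non-negative extras, distal fixed at utr_total
      slack <- utr_total - 30L - (k - 1L) * config$min_spacing
      extras <- sort(sample.int(slack + 1L, k - 1L, replace = TRUE) - 1L)
      lens <- c(30L + (seq_len(k - 1L) - 1L) * config$min_spacing + extras,
                utr_total)
      # leading intergenic gap with one decoy locus (plus strand of the
      # decoy set to '+'; its window sits wholly inside the gap)
      gap_seq <- .random_seq(gap)
      decoy_pos_in_gap <- 100L
      substr(gap_seq, decoy_pos_in_gap + 2L, decoy_pos_in_gap + 21L) <-
        strrep("A", 20L)
      decoy_rows[[length(decoy_rows) + 1L]] <- data.frame(
        chrom = names(chrom_seq)[ci], strand = "+",
        pos = cur + decoy_pos_in_gap, stringsAsFactors = FALSE)
      parts <- c(parts, gap_seq); cur <- cur + gap
      # gene cassette, built in transcription orientation then flipped on -
      body_len <- cds_len + utr_total + 40L  # 40 nt past the distal site
      body <- .random_seq(body_len)
      # sanitize the jittered downstream window zone of each site:
      # cleavage base of site with UTR length L sits at offset
      # cds_len + L - 1 (0-based) in the cassette
      for (L in lens) {
        off <- cds_len + L - 1L
        lo <- max(1L, off - 19L + 1L); hi <- min(body_len, off + 41L)
        substr(body, lo, hi) <- .safe_stretch(hi - lo + 1L)
      }
      tx_start0 <- cur
      if (strand == "+") {
        seq_fwd <- body
        anchor <- tx_start0 + cds_len
        site_pos <- tx_start0 + cds_len + lens - 1L
        tes <- max(site_pos) + 1L
        cds_end <- anchor
        # annotated span ends at the distal site; the 40-nt buffer past it
        # is genomic but untranscribed
        ann_s <- tx_start0; ann_e <- tes
      } else {
        seq_fwd <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(body)))
        tx_end0 <- tx_start0 + body_len
        anchor <- tx_end0 - cds_len      # 0-based boundary
        site_pos <- tx_end0 - cds_len - lens
        tes <- min(site_pos)
        cds_end <- anchor
        ann_s <- tes; ann_e <- tx_end0
      }
      parts <- c(parts, seq_fwd); cur <- cur + body_len
      tx_rows[[gid]] <- data.frame(
        gene_id = gene_id, tx_id = paste0(gene_id, "|t1"),
        chrom = names(chrom_seq)[ci], strand = strand,
        tx_start = ann_s, tx_end = ann_e,
        cds_end = cds_end, tes = tes, coding = TRUE,
        cds_from_last_cds = FALSE, zero_utr = FALSE,
        exon_starts = I(list(ann_s)), exon_ends = I(list(ann_e)),
        stringsAsFactors = FALSE)
      truth_rows[[gid]] <- data.frame(
        gene_id = gene_id, chrom = names(chrom_seq)[ci], strand = strand,
        pos = site_pos, utr_length = lens, distal = lens == max(lens),
        stringsAsFactors = FALSE)
    }
    parts <- c(parts, .random_seq(gap))
    chrom_seq[[ci]] <- paste(parts, collapse = "")
  }
  genome <- Biostrings::DNAStringSet(unlist(chrom_seq))
  transcripts <- do.call(rbind, tx_rows)
  truth_sites <- do.call(rbind, truth_rows)
  # interior (non-distal) sites enter the known DB at known_frac
  interior <- which(!truth_sites$distal)
  n_known <- round(config$known_frac * length(interior))
  in_db <- sort(sample(interior, n_known))
  truth_sites$in_known_db <- seq_len(nrow(truth_sites)) %in% in_db
  known_db <- truth_sites[truth_sites$in_known_db,
                          c("chrom", "strand", "pos")]
  known_db$source_id <- paste0("pa", seq_len(nrow(known_db)))
  known_db <- known_db[order(known_db$chrom, known_db$pos), ]
  rownames(known_db) <- NULL
  ref <- list(genome = genome, transcripts = transcripts,
              known_db = known_db, truth_sites = truth_sites,
              decoys = do.call(rbind, decoy_rows), config = config)
  ref$truth_genes <- .assign_truth_genes(ref, config)
  ref$gene_sets <- .make_gene_sets(ref$truth_genes)
  class(ref) <- "sim_reference"
  ref
}

# Per-gene ground truth: usage proportions per sample, relative
# expression, and the planted switch / expression labels.
.assign_truth_genes <- function(ref, config) {
  gene_ids <- unique(ref$truth_sites$gene_id)
  n <- length(gene_ids)
  n_sh <- round(config$frac_shortened * n)
  n_ln <- round(config$frac_lengthened * n)
  lab <- rep("null", n)
  shuffled <- sample(n)
  lab[shuffled[seq_len(n_sh)]] <- "shortened"
  if (n_ln > 0) lab[shuffled[n_sh + seq_len(n_ln)]] <- "lengthened"
  n_up <- round(config$frac_up * n); n_dn <- round(config$frac_dn * n)
  elab <- rep("null", n)
  eshuf <- sample(n)
  elab[eshuf[seq_len(n_up)]] <- "up"
  if (n_dn > 0) elab[eshuf[n_up + seq_len(n_dn)]] <- "down"
  expr <- stats::rlnorm(n, config$expr_meanlog, config$expr_sdlog)
  lo <- config$shift_proximal[1]; hi <- config$shift_proximal[2]
  usage1 <- usage2 <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sum(ref$truth_sites$gene_id == gene_ids[i])
    base <- stats::rgamma(k, 2) + 0.2   # bounded away from 0
    base <- base / sum(base)
    if (lab[i] == "null") {
      usage1[[i]] <- usage2[[i]] <- base
    } else {
      rest <- base[-1] / sum(base[-1])
      # shortened gene: sample two piles mass on the proximal site
      p1 <- if (lab[i] == "shortened") lo else hi
      p2 <- if (lab[i] == "shortened") hi else lo
      usage1[[i]] <- c(p1, (1 - p1) * rest)
      usage2[[i]] <- c(p2, (1 - p2) * rest)
    }
  }
  data.frame(gene_id = gene_ids, switch_label = lab, expr_label = elab,
             rel_expr = expr,
             usage_s1 = I(usage1), usage_s2 = I(usage2),
             stringsAsFactors = FALSE)
}

.make_gene_sets <- function(truth_genes) {
  short_genes <- truth_genes$gene_id[truth_genes$switch_label == "shortened"]
  all_genes <- truth_genes$gene_id
  sets <- list()
  nm <- character(0)
  if (length(short_genes) >= 2L) {
    pad <- sample(setdiff(all_genes, short_genes),
                  min(5L, length(all_genes) - length(short_genes)))
    sets$SET_SHORT <- c(short_genes, pad)
    nm <- c(nm, "planted shortened genes")
  }
  for (i in 1:3) {
    sets[[paste0("SET_RND", i)]] <-
      sample(all_genes, max(5L, round(length(all_genes) / 10)))
    nm <- c(nm, paste("random set", i))
  }
  attr(sets, "set_name") <- stats::setNames(nm, names(sets))
  sets
}

#' Write a synthetic reference to disk
#'
#' Emits FASTA (genome), BED12 (transcripts), BED6 (known sites), GMT
#' (gene sets) and TSV truth tables plus a JSON config echo into `dir`.
#'
#' @param ref A `sim_reference`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths.
#' @export
write_reference <- function(ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             transcripts = file.path(dir, "transcripts.bed"),
             known = file.path(dir, "known_sites.bed"),
             gmt = file.path(dir, "gene_sets.gmt"),
             truth_sites = file.path(dir, "truth_sites.tsv"),
             truth_genes = file.path(dir, "truth_genes.tsv"),
             config = file.path(dir, "config.json"))
  Biostrings::writeXStringSet(ref$genome, paths["genome"])
  .write_bed12(ref$transcripts, paths["transcripts"])
  write_sites(paths["known"], ref$known_db)
  nmv <- attr(ref$gene_sets, "set_name")
  writeLines(vapply(names(ref$gene_sets), function(id)
    paste(c(id, nmv[[id]], ref$gene_sets[[id]]), collapse = "\t"),
    character(1)), paths["gmt"])
  .write_tsv(ref$truth_sites, paths["truth_sites"])
  tg <- ref$truth_genes
  tg$usage_s1 <- vapply(tg$usage_s1, paste, character(1), collapse = ",")
  tg$usage_s2 <- vapply(tg$usage_s2, paste, character(1), collapse = ",")
  .write_tsv(tg, paths["truth_genes"])
  jsonlite::write_json(unclass(ref$config), paths["config"],
                       auto_unbox = TRUE, digits = NA)
  paths
}

.write_bed12 <- function(tx, path) {
  plus <- tx$strand == "+"
  thick_s <- ifelse(plus, tx$tx_start, tx$cds_end)
  thick_e <- ifelse(plus, tx$cds_end, tx$tx_end)
  lines <- vapply(seq_len(nrow(tx)), function(i) {
    es <- tx$exon_starts[[i]]; ee <- tx$exon_ends[[i]]
    paste(tx$chrom[i], tx$tx_start[i], tx$tx_end[i],
          paste0(tx$gene_id[i], "|", sub("^.*\\|", "", tx$tx_id[i])),
          0, tx$strand[i], thick_s[i], thick_e[i], "0,0,0",
          length(es), paste0(paste(ee - es, collapse = ","), ","),
          paste0(paste(es - tx$tx_start[i], collapse = ","), ","),
          sep = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

.truncnorm_jitter <- function(n, sd, bound = 20L) {
  if (sd == 0) return(integer(n))
  j <- round(stats::rnorm(n, 0, sd))
  as.integer(pmax(-bound, pmin(bound, j)))
}

#' Simulate two libraries of 3'-end reads from a synthetic reference
#'
#' Per gene and sample, read counts follow
#' multinomial(relative expression x depth, usage); each read cleaves at
#' its site plus truncated Normal jitter, and its sequence is a 5' poly-T
#' run (8-18 nt) followed by the reverse complement of at most 50 nt of
#' transcript sequence upstream of the cleavage base. Decoy reads cleave
#' at the planted all-`A` loci. Reads are returned both as read tables
#' (FASTQ route, exercises preprocessing) and as aligned intervals (BED
#' route, the default aligner-free path).
#'
#' @param ref A `sim_reference`.
#' @param config Defaults to `ref$config`.
#' @param dir Optional directory; when given, FASTQ x2, BED x2 and truth
#'   tables are written there.
#' @return List of class `sim_reads`: per sample `reads` (read tables),
#'   `alignments` (`GRanges` with read names/scores), `events` (cleavage
#'   truth: `chrom`, `strand`, `pos`, `sample_id`, `gene_id`, `site_pos`,
#'   `decoy`), `site_counts` (expected-truth per-site realized counts),
#'   plus `paths` when written.
#' @export
simulate_reads <- function(ref, config = ref$config, dir = NULL) {
  set.seed(config$seed + 1L)
  tg <- ref$truth_genes
  ts <- ref$truth_sites
  n_gene <- nrow(tg)
  samples <- c("sample1", "sample2")
  fold <- ifelse(tg$expr_label == "up", config$expr_fold,
                 ifelse(tg$expr_label == "down", 1 / config$expr_fold, 1))
  w1 <- tg$rel_expr; w1 <- w1 / sum(w1)
  w2 <- tg$rel_expr * fold; w2 <- w2 / sum(w2)
  gene_n <- cbind(
    sample1 = stats::rmultinom(1, config$depth, w1)[, 1],
    sample2 = stats::rmultinom(1, config$depth, w2)[, 1])
  out_events <- list(); out_counts <- list()
  for (si in 1:2) {
    ev <- vector("list", n_gene)
    for (gi in seq_len(n_gene)) {
      ng <- gene_n[gi, si]
      usage <- if (si == 1) tg$usage_s1[[gi]] else tg$usage_s2[[gi]]
      sites <- ts[ts$gene_id == tg$gene_id[gi], , drop = FALSE]
      cnt <- if (ng > 0) stats::rmultinom(1, ng, usage)[, 1]
             else integer(nrow(sites))
      out_counts[[length(out_counts) + 1L]] <- data.frame(
        gene_id = tg$gene_id[gi], sample_id = samples[si],
        pos = sites$pos, utr_length = sites$utr_length, count = cnt)
      if (ng == 0) next
      site_pos <- rep(sites$pos, cnt)
      jit <- .truncnorm_jitter(ng, config$jitter_sd)
      ev[[gi]] <- data.frame(
        chrom = sites$chrom[1], strand = sites$strand[1],
        pos = site_pos + jit, sample_id = samples[si],
        gene_id = tg$gene_id[gi], site_pos = site_pos, decoy = FALSE,
        stringsAsFactors = FALSE)
    }
    ev <- do.call(rbind, ev)
    n_decoy <- round(config$decoy_rate * config$depth)
    if (n_decoy > 0 && nrow(ref$decoys) > 0) {
      di <- sample(nrow(ref$decoys), n_decoy, replace = TRUE)
      ev <- rbind(ev, data.frame(
        chrom = ref$decoys$chrom[di], strand = ref$decoys$strand[di],
        pos = ref$decoys$pos[di], sample_id = samples[si],
        gene_id = NA_character_, site_pos = NA_integer_, decoy = TRUE,
        stringsAsFactors = FALSE))
    }
    rownames(ev) <- NULL
    ev$read_id <- sprintf("%s_r%06d", samples[si], seq_len(nrow(ev)))
    out_events[[si]] <- ev
  }
  names(out_events) <- samples
  res <- list(events = out_events,
              site_counts = do.call(rbind, out_counts),
              reads = lapply(out_events, .events_to_reads, ref = ref),
              alignments = lapply(out_events, .events_to_alignments,
                                  ref = ref),
              config = config)
  class(res) <- "sim_reads"
  if (!is.null(dir)) res$paths <- .write_sim_reads(res, ref, dir)
  res
}

# aligned portion: <= 50 nt of transcript sequence upstream of (and
# including) the cleavage base
.events_to_alignments <- function(ev, ref) {
  len <- genome_lengths(ref$genome)
  plus <- ev$strand == "+"
  start0 <- ifelse(plus, pmax(0L, ev$pos - 49L), ev$pos)
  end0 <- ifelse(plus, ev$pos + 1L, pmin(len[ev$chrom], ev$pos + 50L))
  gr <- GenomicRanges::GRanges(
    ev$chrom, IRanges::IRanges(start = start0 + 1L, end = end0),
    strand = ev$strand)
  gr$name <- ev$read_id
  gr$score <- 255L
  gr
}

.events_to_reads <- function(ev, ref) {
  gr <- .events_to_alignments(ev, ref)
  # plus-strand genomic sequence of each aligned interval
  chrom <- as.character(GenomicRanges::seqnames(gr))
  body <- character(length(gr))
  for (ch in unique(chrom)) {
    idx <- chrom == ch
    body[idx] <- substring(as.character(ref$genome[[ch]]),
                           GenomicRanges::start(gr)[idx],
                           GenomicRanges::end(gr)[idx])
  }
  body <- Biostrings::DNAStringSet(body)
  plus <- ev$strand == "+"
  # read = poly-T + reverse complement of the transcript-direction
  # upstream sequence; on '-' that reverse complement is the plus-strand
  # genomic sequence itself
  rc <- as.character(Biostrings::reverseComplement(body))
  read_body <- ifelse(plus, rc, as.character(body))
  t_run <- sample(8:18, nrow(ev), replace = TRUE)
  seqs <- paste0(strrep("T", t_run), read_body)
  data.frame(id = ev$read_id, seq = seqs,
             qual = strrep("I", nchar(seqs)), stringsAsFactors = FALSE)
}

.write_sim_reads <- function(res, ref, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  for (s in names(res$events)) {
    fq <- file.path(dir, paste0(s, ".fastq"))
    bed <- file.path(dir, paste0(s, ".bed"))
    write_fastq(res$reads[[s]], fq)
    rtracklayer::export(res$alignments[[s]], bed, format = "bed")
    paths <- c(paths, stats::setNames(c(fq, bed),
                                      paste0(s, c("_fastq", "_bed"))))
  }
  sc <- file.path(dir, "truth_site_counts.tsv")
  .write_tsv(res$site_counts, sc)
  c(paths, truth_site_counts = sc)
}

#' Score pipeline output against the generator's ground truth
#'
#' @param sites Annotated site table from the pipeline.
#' @param ref The `sim_reference` the data came from.
#' @param switch_fit Optional `apa_switch` fit.
#' @param degs Optional DEG table from [call_degs()].
#' @param tol Site-matching tolerance in nt (default 24).
#' @return List: `site_recovery` (per true site: matched, positional
#'   error), `site_sensitivity`, `switch_confusion` and
#'   `switch_empirical_fdr` (planted label x call), `deg_confusion`.
#' @export
score_recovery <- function(sites, ref, switch_fit = NULL, degs = NULL,
                           tol = 24L) {
  ts <- ref$truth_sites
  matched <- rep(FALSE, nrow(ts)); err <- rep(NA_integer_, nrow(ts))
  for (i in seq_len(nrow(ts))) {
    cand <- sites$pos[sites$chrom == ts$chrom[i] &
                        sites$strand == ts$strand[i]]
    if (length(cand) > 0L) {
      d <- abs(cand - ts$pos[i])
      if (min(d) <= tol) { matched[i] <- TRUE; err[i] <- min(d) }
    }
  }
  out <- list(site_recovery = data.frame(ts, matched = matched,
                                         pos_error = err),
              site_sensitivity = mean(matched))
  if (!is.null(switch_fit)) {
    res <- switch_fit$results
    if (!all(res$gene_id %in% ref$truth_genes$gene_id))
      stop("switch fit contains gene ids absent from the truth")
    truth_lab <- ref$truth_genes$switch_label[
      match(res$gene_id, ref$truth_genes$gene_id)]
    out$switch_confusion <- table(truth = truth_lab, call = res$call)
    called <- res$call != "none"
    out$switch_empirical_fdr <- if (any(called))
      mean(truth_lab[called] == "null" |
             (truth_lab[called] != res$call[called])) else NA_real_
  }
  if (!is.null(degs)) {
    if (!all(degs$gene_id %in% ref$truth_genes$gene_id))
      stop("DEG table contains gene ids absent from the truth")
    truth_e <- ref$truth_genes$expr_label[
      match(degs$gene_id, ref$truth_genes$gene_id)]
    out$deg_confusion <- table(truth = truth_e, call = degs$call)
  }
  out
}
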
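#' Extract cleavage positions from unique alignments
#'
#' Each retained alignment yields one cleavage event at its strand-aware 3'
#' terminus: the rightmost aligned base on `+`, the leftmost on `-` (the
#' base the polyA tail was attached to). Positions are 0-based.
#'
#' @param x Path to a BED6 file of alignments, a SAM/BAM file, or a
#'   `GRanges` of aligned read intervals.
#' @param sample_id Sample label recorded on every event.
#' @param unique_only Drop multi-mapped reads. For BED, the score column is
#'   read as MAPQ when present (kept if > 3); for SAM/BAM the `NH` tag is
#'   used when present, else MAPQ > 3.
#' @return Data.frame of events: `chrom`, `strand`, `pos`, `sample_id`.
#' @export
extract_cleavage <- function(x, sample_id = "sample1", unique_only = TRUE) {
  if (is.character(x)) {
    ext <- tolower(tools::file_ext(x))
    if (ext %in% c("sam", "bam")) return(.extract_cleavage_bam(x, sample_id, unique_only))
    gr <- rtracklayer::import(x, format = "bed")
    if (unique_only && !is.null(gr$score)) gr <- gr[gr$score > 3]
  } else gr <- x
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("alignments must be stranded")
  pos <- ifelse(strand == "+",
                GenomicRanges::end(gr) - 1L,   # 1-based end -> 0-based
                GenomicRanges::start(gr) - 1L) # 1-based start -> 0-based
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = strand, pos = as.integer(pos),
    sample_id = sample_id, stringsAsFactors = FALSE
  )
}

.extract_cleavage_bam <- function(path, sample_id, unique_only) {
  for (pkg in c("Rsamtools", "GenomicAlignments"))
    if (!requireNamespace(pkg, quietly = TRUE))
      stop(pkg, " is required for SAM/BAM input")
  if (tolower(tools::file_ext(path)) == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  } else bam <- path
  param <- Rsamtools::ScanBamParam(what = "mapq", tag = "NH")
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  n_in <- Rsamtools::countBam(bam)$records
  if (n_in > length(aln))
    message(n_in - length(aln), " unmapped record(s) skipped")
  if (unique_only) {
    nh <- S4Vectors::mcols(aln)$NH
    mapq <- S4Vectors::mcols(aln)$mapq
    keep <- if (!is.null(nh) && !all(is.na(nh))) !is.na(nh) & nh == 1L
            else !is.na(mapq) & mapq > 3L
    aln <- aln[keep]
  }
  extract_cleavage(GenomicRanges::granges(aln), sample_id, unique_only = FALSE)
}

# Transcription-direction downstream window of width `window` immediately
# past `pos` (0-based), truncated at chromosome ends, as a plus-strand-of-
# transcription string (reverse complemented on '-').
.downstream_windows <- function(chrom, strand, pos, genome, window = 20L) {
  out <- character(length(pos))
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    seqstr <- as.character(genome[[ch]])
    len <- nchar(seqstr)
    plus <- strand[idx] == "+"
    s <- ifelse(plus, pos[idx] + 2L, pmax(1L, pos[idx] - window + 1L))
    e <- ifelse(plus, pmin(len, pos[idx] + 1L + window), pos[idx])
    w <- ifelse(e >= s, substring(seqstr, s, e), "")
    if (any(!plus)) {
      w[!plus] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(w[!plus])))
    }
    out[idx] <- w
  }
  out
}

#' Internal-priming filter
#'
#' Oligo-dT primers can anneal to A-rich genomic stretches rather than a
#' true polyA tail, producing artifactual 3' ends. An event is removed when
#' the 20-nt genomic window immediately downstream of its cleavage position
#' (in transcription direction) contains at least 12 `A` in total, or the
#' contiguous 8-mer `AAAAAAAA`, or matches the pattern `G A{4,} G A{3,} G`.
#' Windows truncated at chromosome ends are evaluated as-is.
#'
#' @param events Event table from [extract_cleavage()].
#' @param genome `DNAStringSet` reference genome.
#' @param window Downstream window width in nt (default 20).
#' @param min_a Total-`A` threshold (default 12, applied as `>=`).
#' @param eight_a Contiguous A-run trigger (default `"AAAAAAAA"`).
#' @param g_pattern Regular expression for the G/A disruption pattern.
#' @return List with `kept` and `filtered` event tables; `filtered` carries
#'   the offending `window` sequence.
#' @export
internal_priming_filter <- function(events, genome, window = 20L, min_a = 12L,
                                    eight_a = "AAAAAAAA",
                                    g_pattern = "GA{4,}GA{3,}G") {
  if (nrow(events) == 0L)
    return(list(kept = events, filtered = cbind(events, window = character(0))))
  w <- .downstream_windows(events$chrom, events$strand, events$pos,
                           genome, as.integer(window))
  n_a <- nchar(w) - nchar(gsub("A", "", w, fixed = TRUE))
  hit <- n_a >= min_a | grepl(eight_a, w, fixed = TRUE) | grepl(g_pattern, w)
  filtered <- events[hit, , drop = FALSE]
  filtered$window <- w[hit]
  list(kept = events[!hit, , drop = FALSE], filtered = filtered)
}

#' Cluster cleavage events into polyA sites
#'
#' Pooled events from all samples are chained per (chromosome, strand) by
#' single linkage: sorted by position, a new cluster starts whenever the
#' gap to the previous event exceeds `gap` nt. Clusters supported by a
#' single read in total are discarded (a polyA site needs more than one
#' read). The representative position is the member position with the
#' highest pooled read count; ties go to the 3'-most position on the
#' site's strand. The result is order-invariant in the input.
#'
#' @param events Event table (pooled over samples).
#' @param gap Maximum nt gap joining adjacent events (default 24).
#' @param samples Sample ids in row order (sample one first); defaults to
#'   the sorted unique `sample_id` values.
#' @param min_total Minimum pooled reads to keep a cluster (default 2).
#' @return Data.frame of sites: `chrom`, `strand`, `pos`, `cl_start`,
#'   `cl_end`, `total`, and one `n_<sample>` count column per sample, with
#'   a `samples` attribute giving the column order.
#' @export
cluster_events <- function(events, gap = 24L, samples = NULL, min_total = 2L) {
  if (is.null(samples)) samples <- sort(unique(events$sample_id))
  if (nrow(events) == 0L) {
    out <- data.frame(chrom = character(0), strand = character(0),
                      pos = integer(0), cl_start = integer(0),
                      cl_end = integer(0), total = integer(0))
    for (s in samples) out[[paste0("n_", s)]] <- integer(0)
    attr(out, "samples") <- samples
    return(out)
  }
  stopifnot(all(events$sample_id %in% samples))
  # collapse to per-position per-sample counts
  key <- paste(events$chrom, events$strand, events$pos, sep = "\r")
  tab <- table(key, factor(events$sample_id, levels = samples))
  cnt <- matrix(as.integer(tab), nrow = nrow(tab),
                dimnames = list(rownames(tab), samples))
  parts <- do.call(rbind, strsplit(rownames(cnt), "\r", fixed = TRUE))
  df <- data.frame(chrom = parts[, 1], strand = parts[, 2],
                   pos = as.integer(parts[, 3]), stringsAsFactors = FALSE)
  o <- order(df$chrom, df$strand, df$pos)
  df <- df[o, , drop = FALSE]; cnt <- cnt[o, , drop = FALSE]
  new_grp <- c(TRUE, df$chrom[-1] != df$chrom[-nrow(df)] |
                 df$strand[-1] != df$strand[-nrow(df)] |
                 df$pos[-1] - df$pos[-nrow(df)] > gap)
  cl <- cumsum(new_grp)
  pooled <- rowSums(cnt)
  sites <- lapply(split(seq_len(nrow(df)), cl), function(ix) {
    tot <- sum(pooled[ix])
    if (tot < min_total) return(NULL)
    strand <- df$strand[ix[1]]
    best <- ix[pooled[ix] == max(pooled[ix])]
    rep_pos <- if (strand == "+") max(df$pos[best]) else min(df$pos[best])
    row <- data.frame(chrom = df$chrom[ix[1]], strand = strand,
                      pos = rep_pos, cl_start = min(df$pos[ix]),
                      cl_end = max(df$pos[ix]), total = tot,
                      stringsAsFactors = FALSE)
    for (s in samples) row[[paste0("n_", s)]] <- sum(cnt[ix, s])
    row
  })
  out <- do.call(rbind, sites)
  if (is.null(out)) out <- cluster_events(events[0, ], gap, samples)
  rownames(out) <- NULL
  attr(out, "samples") <- samples
  out
}

#' Collapse transcript models to gene models
#'
#' A gene is the union of transcripts sharing `gene_id`. The gene's UTR
#' anchor is the 3'-most annotated `cds_end` across its transcripts (one
#' tandem-UTR length axis per gene); all transcript ends are retained for
#' tier annotation.
#'
#' @param transcripts Transcript table from [read_transcripts()].
#' @return Data.frame, one row per gene: `gene_id`, `chrom`, `strand`,
#'   `anchor` (3'-most cds_end), `start`, `end` (gene span), `coding`,
#'   plus list columns `tes_list`, `exon_starts`, `exon_ends`.
#' @export
collapse_genes <- function(transcripts) {
  sp <- split(seq_len(nrow(transcripts)), transcripts$gene_id)
  rows <- lapply(sp, function(ix) {
    tx <- transcripts[ix, , drop = FALSE]
    if (length(unique(tx$strand)) != 1L || length(unique(tx$chrom)) != 1L)
      stop("gene ", tx$gene_id[1], " mixes chromosomes or strands")
    plus <- tx$strand[1] == "+"
    anchor <- if (plus) max(tx$cds_end) else min(tx$cds_end)
    es <- sort(unique(unlist(tx$exon_starts)))
    ee <- sort(unique(unlist(tx$exon_ends)))
    data.frame(
      gene_id = tx$gene_id[1], chrom = tx$chrom[1], strand = tx$strand[1],
      anchor = anchor, start = min(tx$tx_start), end = max(tx$tx_end),
      coding = any(tx$coding),
      tes_list = I(list(sort(unique(tx$tes)))),
      exon_starts = I(list(es)), exon_ends = I(list(ee)),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 0-based genomic position of a transcript's terminal base
.tes_base <- function(tes, strand) {
  ifelse(rep_len(strand == "+", length(tes)), tes - 1L, tes)
}

#' Annotate polyA sites: tier, genomic region, owning gene
#'
#' Tier assignment is a strict priority partition:
#' (i) sites within `tol` nt of any same-strand annotated transcript end
#' are tier `UCSC`; (ii) remaining sites within `tol` nt of a known-site
#' database entry are tier `TianDB`; (iii) the rest are `novel`. The
#' genomic region is classified against the owning gene's annotation with
#' priority `UTR3 > CDS > intron > noncoding > downstream1k > intergenic`
#' (`downstream1k` = within 1000 nt past the gene 3' end). The owning gene
#' is the gene of the matched transcript end when tier is `UCSC`, else the
#' nearest same-strand gene whose span or 1-kb 3' extension contains the
#' site; ties between equidistant ends go to the 5'-side gene.
#'
#' @param sites Site table from [cluster_events()].
#' @param transcripts Transcript table ([read_transcripts()]).
#' @param known_db Known-site table ([read_known_sites()]), or `NULL`.
#' @param tol Matching tolerance in nt (default 24).
#' @return `sites` with added columns `tier`, `region`, `gene_id`,
#'   `utr_length` (strand-aware distance from the gene anchor, minimum 1;
#'   `NA` when no gene or site upstream of the anchor).
#' @export
annotate_sites <- function(sites, transcripts, known_db = NULL, tol = 24L) {
  genes <- collapse_genes(transcripts)
  n <- nrow(sites)
  tier <- character(n); region <- character(n)
  gene_id <- rep(NA_character_, n); utr_len <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    ch <- sites$chrom[i]; st <- sites$strand[i]; pos <- sites$pos[i]
    g <- genes[genes$chrom == ch & genes$strand == st, , drop = FALSE]
    # tier (i): distance to any annotated transcript end
    tes_gene <- rep(g$gene_id, lengths(g$tes_list))
    tes_all <- .tes_base(unlist(g$tes_list), st)
    d_tes <- abs(pos - tes_all)
    if (length(d_tes) > 0L && min(d_tes) <= tol) {
      tier[i] <- "UCSC"
      hit <- which(d_tes == min(d_tes))
      if (length(hit) > 1L) {
        # equidistant transcript ends: 5'-side gene wins (lower coordinate
        # on '+', higher on '-'); logged once per run via message
        five_side <- if (st == "+") hit[which.min(tes_all[hit])]
                     else hit[which.max(tes_all[hit])]
        if (length(unique(tes_gene[hit])) > 1L)
          message("tie at site ", ch, ":", pos, " resolved to 5'-side gene ",
                  tes_gene[five_side])
        hit <- five_side
      }
      gene_id[i] <- tes_gene[hit]
    } else {
      if (!is.null(known_db) && nrow(known_db) > 0L) {
        kd <- known_db[known_db$chrom == ch & known_db$strand == st, ,
                       drop = FALSE]
        if (nrow(kd) > 0L && min(abs(pos - kd$pos)) <= tol) tier[i] <- "TianDB"
      }
      if (tier[i] == "") tier[i] <- "novel"
      # owning gene: span or 1-kb 3' extension contains pos
      if (nrow(g) > 0L) {
        ext_lo <- ifelse(g$strand == "+", g$start, g$start - 1000L)
        ext_hi <- ifelse(g$strand == "+", g$end + 1000L, g$end)
        inside <- pos >= ext_lo & pos < ext_hi
        if (any(inside)) {
          cand <- which(inside)
          g_tes <- vapply(g$tes_list[cand], function(t)
            if (st == "+") max(t) else min(t), numeric(1))
          d <- abs(pos - .tes_base(g_tes, st))
          best <- cand[d == min(d)]
          if (length(best) > 1L)
            best <- if (st == "+") best[which.min(g$end[best])]
                    else best[which.max(g$start[best])]
          gene_id[i] <- g$gene_id[best]
        }
      }
    }
    region[i] <- .classify_region(pos, st, gene_id[i], genes)
    if (!is.na(gene_id[i])) {
      gi <- match(gene_id[i], genes$gene_id)
      len <- if (st == "+") pos - genes$anchor[gi] + 1L
             else genes$anchor[gi] - pos
      if (len >= 1L) utr_len[i] <- as.integer(len)
    }
  }
  sites$tier <- tier; sites$region <- region
  sites$gene_id <- gene_id; sites$utr_length <- utr_len
  sites
}

.classify_region <- function(pos, strand, gene_id, genes) {
  if (is.na(gene_id)) return("intergenic")
  g <- genes[match(gene_id, genes$gene_id), ]
  plus <- strand == "+"
  tes3 <- if (plus) max(g$tes_list[[1]]) else min(g$tes_list[[1]])
  # UTR3: between the gene anchor and its 3'-most transcript end
  in_utr3 <- if (plus) pos >= g$anchor && pos < tes3
             else pos < g$anchor && pos >= tes3
  if (g$coding && in_utr3) return("UTR3")
  in_span <- pos >= g$start && pos < g$end
  if (in_span) {
    es <- g$exon_starts[[1]]; ee <- g$exon_ends[[1]]
    in_exon <- any(pos >= es & pos < ee)
    if (!g$coding) return("noncoding")
    # within the coding portion of the gene (5' of the anchor)
    in_cds_span <- if (plus) pos < g$anchor else pos >= g$anchor
    if (in_exon && in_cds_span) return("CDS")
    if (!in_exon) return("intron")
    return("UTR3")  # exon, 3' of anchor but not flagged above
  }
  down <- if (plus) pos >= tes3 && pos < tes3 + 1000L
          else pos < tes3 && pos >= tes3 - 1000L
  if (down) return("downstream1k")
  "intergenic"
}

#' Per-gene read counts from annotated sites
#'
#' Sums per-sample site counts over every site assigned to a gene; the
#' column totals double as the library sizes for expression testing.
#'
#' @param sites Annotated site table.
#' @return Matrix, genes x samples.
#' @export
gene_counts <- function(sites) {
  samples <- attr(sites, "samples")
  if (is.null(samples))
    samples <- sub("^n_", "", grep("^n_", names(sites), value = TRUE))
  keep <- !is.na(sites$gene_id)
  cols <- paste0("n_", samples)
  m <- rowsum(as.matrix(sites[keep, cols, drop = FALSE]),
              group = sites$gene_id[keep])
  colnames(m) <- samples
  m
}

#' Write annotated sites as BED6+
#'
#' Name field is `gene_id|tier|region`, score the pooled read count;
#' per-sample counts follow as extra columns.
#'
#' @param sites Annotated site table.
#' @param path Output path.
#' @export
write_polya_sites <- function(sites, path) {
  samples <- attr(sites, "samples")
  cols <- paste0("n_", samples)
  bed <- data.frame(
    chrom = sites$chrom, start = sites$pos, end = sites$pos + 1L,
    name = paste(ifelse(is.na(sites$gene_id), ".", sites$gene_id),
                 sites$tier, sites$region, sep = "|"),
    score = sites$total, strand = sites$strand,
    stringsAsFactors = FALSE
  )
  bed <- cbind(bed, sites[, cols, drop = FALSE])
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Summarize a sequencing run as a stage-count table
#'
#' Tabulates read counts through the filtering stages with percentages of
#' raw reads (one decimal), mirroring the standard run-summary layout of
#' 3'-end sequencing studies. Stage counts must be monotone non-increasing.
#'
#' @param raw,clean,mapped,unique_mapped,nuclear,ip_pass Per-sample read
#'   counts (equal-length vectors; names become sample labels).
#' @param extra Optional named list of further per-sample count rows
#'   (genes sampled, sites, ...), reported without percentages.
#' @return Data.frame with columns `parameter`, `sample`, `count`, `pct`.
#' @export
summarize_run <- function(raw, clean, mapped, unique_mapped, nuclear, ip_pass,
                          extra = NULL) {
  stages <- rbind(raw = raw, clean = clean, mapped = mapped,
                  unique_mapped = unique_mapped, nuclear = nuclear,
                  ip_pass = ip_pass)
  if (any(stages < 0)) stop("stage counts must be non-negative")
  if (any(apply(stages, 2, diff) > 0))
    stop("stage counts must be monotone non-increasing raw -> ip_pass")
  samples <- colnames(stages)
  if (is.null(samples)) samples <- paste0("sample", seq_len(ncol(stages)))
  out <- do.call(rbind, lapply(rownames(stages), function(p)
    data.frame(parameter = p, sample = samples, count = stages[p, ],
               pct = round(stages[p, ] / stages["raw", ] * 100, 1),
               stringsAsFactors = FALSE)))
  if (!is.null(extra))
    for (p in names(extra))
      out <- rbind(out, data.frame(parameter = p, sample = samples,
                                   count = extra[[p]], pct = NA_real_))
  rownames(out) <- NULL
  out
}
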
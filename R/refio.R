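#' Read a reference genome from FASTA
#'
#' Loads every record of a FASTA file into an uppercased
#' [Biostrings::DNAStringSet]. The result plays the role of the reference
#' genome for every coordinate-aware stage (internal-priming windows, site
#' annotation, simulation); any genome can be substituted for the human one.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet`, one element per chromosome, alphabet restricted
#'   to `A`, `C`, `G`, `T`, `N`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgtACGT"), fa)
#' g <- read_genome(fa)
#' genome_lengths(g)
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  seqs <- withCallingHandlers(
    tryCatch(
      Biostrings::readDNAStringSet(path, format = "fasta"),
      error = function(e) stop("malformed FASTA '", path, "': ",
                               conditionMessage(e), call. = FALSE)
    ),
    # invalid letters are silently dropped by the reader; treat as malformed
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        stop("malformed FASTA '", path, "': non-ACGTN characters",
             call. = FALSE)
      invokeRestart("muffleWarning")
    }
  )
  if (length(seqs) == 0L) stop("empty FASTA: ", path)
  # FASTA headers may carry descriptions; chromosome name is the first token
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs)))
    stop("duplicate sequence name(s) in FASTA: ",
         paste(unique(names(seqs)[duplicated(names(seqs))]), collapse = ", "))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  bad <- grepl("[^ACGTN]", as.character(seqs))
  if (any(bad))
    stop("non-ACGTN characters in sequence(s): ",
         paste(names(seqs)[bad], collapse = ", "))
  seqs
}

#' @rdname read_genome
#' @param genome A `DNAStringSet` as returned by [read_genome()].
#' @export
genome_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}

#' Read transcript models with annotated 3' UTRs
#'
#' Parses either BED12 or a minimal GTF (extension-detected) into a
#' transcript table. All coordinates are converted to the package's single
#' internal convention, 0-based half-open. For each transcript the two
#' anchors of the tandem-UTR axis are derived strand-aware:
#'
#' * `cds_end` — the genomic 3' boundary of the stop codon (`thickEnd` on
#'   `+`, `thickStart` on `-` for BED12; the `stop_codon` feature, or the
#'   last CDS segment when absent, for GTF);
#' * `tes` — the annotated transcript end (`chromEnd` on `+`, `chromStart`
#'   on `-`).
#'
#' Non-coding transcripts (empty thick region / no CDS) keep `cds_end ==
#' tes` at the transcript 3' end and are flagged `coding = FALSE`.
#' Transcripts whose UTR has zero length are retained with
#' `zero_utr = TRUE`.
#'
#' @param path BED12 (`.bed`) or minimal GTF (`.gtf`/`.gff`) file.
#' @param genome Optional `DNAStringSet`; when supplied, coordinates are
#'   checked against chromosome bounds.
#' @return A data.frame with columns `gene_id`, `tx_id`, `chrom`, `strand`,
#'   `tx_start`, `tx_end`, `cds_end`, `tes`, `coding`, `zero_utr`,
#'   `cds_from_last_cds` and list columns `exon_starts`, `exon_ends`
#'   (0-based half-open exon blocks).
#' @export
read_transcripts <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("transcript annotation not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tx <- if (ext %in% c("gtf", "gff")) .read_transcripts_gtf(path)
        else .read_transcripts_bed12(path)
  if (!is.null(genome)) .check_bounds(tx$chrom, tx$tx_start, tx$tx_end, genome)
  tx$zero_utr <- tx$cds_end == tx$tes
  if (any(tx$zero_utr & tx$coding))
    warning(sum(tx$zero_utr & tx$coding),
            " coding transcript(s) with zero-length 3' UTR")
  rownames(tx) <- NULL
  tx
}

.read_transcripts_bed12 <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  if (length(gr) == 0L) stop("no records in BED file: ", path)
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) stop("BED12 transcript records must be stranded")
  start0 <- GenomicRanges::start(gr) - 1L      # back to 0-based half-open
  end0   <- GenomicRanges::end(gr)
  thick <- gr$thick
  has_cds <- !is.null(thick) & IRanges::width(thick) > 0L
  thick_s0 <- IRanges::start(thick) - 1L
  thick_e0 <- IRanges::end(thick)
  plus <- strand == "+"
  tes <- ifelse(plus, end0, start0)
  cds_end <- ifelse(has_cds, ifelse(plus, thick_e0, thick_s0), tes)
  exon_starts <- exon_ends <- vector("list", length(gr))
  blocks <- gr$blocks
  for (i in seq_along(gr)) {
    if (!is.null(blocks) && length(blocks[[i]]) > 0L) {
      # blocks are 1-based relative to feature start
      es <- start0[i] + IRanges::start(blocks[[i]]) - 1L
      ee <- start0[i] + IRanges::end(blocks[[i]])
    } else {
      es <- start0[i]; ee <- end0[i]
    }
    exon_starts[[i]] <- as.integer(es); exon_ends[[i]] <- as.integer(ee)
  }
  nm <- if (is.null(gr$name)) paste0("tx", seq_along(gr)) else gr$name
  data.frame(
    gene_id = .gene_from_name(nm), tx_id = nm,
    chrom = as.character(GenomicRanges::seqnames(gr)), strand = strand,
    tx_start = as.integer(start0), tx_end = as.integer(end0),
    cds_end = as.integer(cds_end), tes = as.integer(tes),
    coding = has_cds, cds_from_last_cds = FALSE,
    exon_starts = I(exon_starts), exon_ends = I(exon_ends),
    stringsAsFactors = FALSE
  )
}

# BED names may encode gene|transcript; take the part before the first '|'
.gene_from_name <- function(nm) sub("\\|.*$", "", nm)

.read_transcripts_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if (length(gr) == 0L) stop("no records in GTF file: ", path)
  if (is.null(gr$transcript_id)) stop("GTF lacks transcript_id attributes")
  type <- tolower(as.character(gr$type))
  ids <- unique(gr$transcript_id[!is.na(gr$transcript_id)])
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sel <- gr[!is.na(gr$transcript_id) & gr$transcript_id == ids[i]]
    st <- tolower(as.character(S4Vectors::mcols(sel)$type))
    strand <- as.character(GenomicRanges::strand(sel))[1]
    if (strand == "*") stop("unstranded GTF transcript: ", ids[i])
    plus <- strand == "+"
    span_s0 <- min(GenomicRanges::start(sel)) - 1L
    span_e0 <- max(GenomicRanges::end(sel))
    tes <- if (plus) span_e0 else span_s0
    stop_rec <- sel[st == "stop_codon"]
    cds_rec <- sel[st == "cds"]
    from_last_cds <- FALSE
    if (length(stop_rec) > 0L) {
      cds_end <- if (plus) max(GenomicRanges::end(stop_rec))
                 else min(GenomicRanges::start(stop_rec)) - 1L
    } else if (length(cds_rec) > 0L) {
      # stop codon absent: fall back to the 3' boundary of the last CDS
      # segment (3 nt short of the true stop boundary) and flag it
      cds_end <- if (plus) max(GenomicRanges::end(cds_rec))
                 else min(GenomicRanges::start(cds_rec)) - 1L
      from_last_cds <- TRUE
    } else {
      cds_end <- tes
    }
    ex <- sel[st == "exon"]
    if (length(ex) == 0L) ex <- sel[st == "transcript"]
    if (length(ex) == 0L) ex <- sel
    gid <- S4Vectors::mcols(sel)$gene_id
    gid <- if (is.null(gid) || all(is.na(gid))) ids[i] else gid[!is.na(gid)][1]
    out[[i]] <- data.frame(
      gene_id = gid, tx_id = ids[i],
      chrom = as.character(GenomicRanges::seqnames(sel))[1], strand = strand,
      tx_start = as.integer(span_s0), tx_end = as.integer(span_e0),
      cds_end = as.integer(cds_end), tes = as.integer(tes),
      coding = length(cds_rec) > 0L || length(stop_rec) > 0L,
      cds_from_last_cds = from_last_cds,
      exon_starts = I(list(as.integer(GenomicRanges::start(ex) - 1L))),
      exon_ends = I(list(as.integer(GenomicRanges::end(ex)))),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

.check_bounds <- function(chrom, start0, end0, genome) {
  len <- genome_lengths(genome)
  missing_chr <- setdiff(unique(chrom), names(len))
  if (length(missing_chr) > 0L)
    stop("chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "))
  bad <- start0 < 0L | end0 > len[chrom]
  if (any(bad)) stop(sum(bad), " record(s) out of chromosome bounds")
  invisible(TRUE)
}

#' Read / write a known polyA-site table (BED6, single-base intervals)
#'
#' The known-site database plays the role of a curated polyA-site atlas
#' used for second-tier annotation. On disk it is BED6 with single-base
#' intervals (`end == start + 1`); in memory it is a data.frame sorted by
#' `(chrom, pos)` with 0-based positions. `write_sites()` and
#' `read_known_sites()` are exact inverses on valid input.
#'
#' @param path BED6 file path.
#' @param genome Optional `DNAStringSet` for bounds checking.
#' @return `read_known_sites()`: data.frame with columns `chrom`, `strand`,
#'   `pos`, `source_id`. `write_sites()`: the path, invisibly.
#' @export
read_known_sites <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("known-site BED not found: ", path)
  gr <- rtracklayer::import(path, format = "bed")
  if (any(GenomicRanges::width(gr) != 1L))
    stop("known-site BED must contain single-base intervals (end = start + 1)")
  db <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    pos = GenomicRanges::start(gr) - 1L,
    source_id = if (is.null(gr$name)) paste0("site", seq_along(gr)) else gr$name,
    stringsAsFactors = FALSE
  )
  if (any(db$pos < 0L)) stop("negative site position in ", path)
  if (!is.null(genome)) .check_bounds(db$chrom, db$pos, db$pos + 1L, genome)
  db[order(db$chrom, db$pos), , drop = FALSE] -> db
  rownames(db) <- NULL
  db
}

#' @rdname read_known_sites
#' @param sites Data.frame with columns `chrom`, `strand`, `pos` and
#'   optionally `source_id`.
#' @export
write_sites <- function(path, sites) {
  stopifnot(all(c("chrom", "strand", "pos") %in% names(sites)))
  if (any(sites$pos < 0L)) stop("negative site position")
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    sites$chrom,
    IRanges::IRanges(start = sites$pos + 1L, width = 1L),
    strand = sites$strand
  )
  gr$name <- if (is.null(sites$source_id)) paste0("site", seq_len(nrow(sites)))
             else sites$source_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' GMT is tab-separated: set id, set name, then one gene per field.
#' Duplicate members within a set are dropped with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (members), with a `set_name`
#'   character attribute parallel to the list names.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  sets <- vector("list", length(lines))
  ids <- nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    f <- f[nzchar(f)]
    if (length(f) < 3L)
      stop("GMT line ", i, " has fewer than 3 fields (id, name, members...)")
    ids[i] <- f[1]; nms[i] <- f[2]
    members <- f[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate member(s) in set '", f[1], "' deduplicated")
      members <- unique(members)
    }
    sets[[i]] <- members
  }
  if (anyDuplicated(ids)) stop("duplicate set id(s) in GMT")
  names(sets) <- ids
  attr(sets, "set_name") <- stats::setNames(nms, ids)
  sets
}

# Shared writer for the package's tab-separated outputs: a '#'-prefixed
# header line, then plain TSV.
.write_tsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0L)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.read_tsv <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1L))
  df <- utils::read.table(path, sep = "\t", skip = 1L,
                          col.names = strsplit(header, "\t")[[1]],
                          stringsAsFactors = FALSE)
  df
}
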
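#' Read and write FASTQ as a read table
#'
#' Reads are carried through the preprocessing stage as a plain data.frame
#' with one row per read: `id`, `seq` (nucleotides), `qual` (Phred+33
#' quality string of equal length).
#'
#' @param path FASTQ file (gzip allowed on read).
#' @return Data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ not found: ", path)
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = names(x),
    seq = unname(as.character(x)),
    qual = unname(as.character(S4Vectors::mcols(x)$qualities)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' @rdname read_fastq
#' @param reads Read table as returned by [read_fastq()].
#' @export
write_fastq <- function(reads, path) {
  .check_reads(reads)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual)
  )
  invisible(path)
}

.check_reads <- function(reads) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual)))
    stop("sequence/quality length mismatch for read(s): ",
         paste(utils::head(reads$id[nchar(reads$seq) != nchar(reads$qual)], 3),
               collapse = ", "))
  invisible(TRUE)
}

.mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

.longest_run <- function(seq) {
  vapply(strsplit(seq, "", fixed = TRUE),
         function(ch) if (length(ch) == 0L) 0L else max(rle(ch)$lengths),
         integer(1))
}

#' Quality filter for 3'-end sequencing reads
#'
#' Drops reads with low mean base quality or too many ambiguous calls.
#' The thresholds are deliberately conventional (the protocol this stage
#' mirrors names no cutoff): mean Phred >= 20 and at most 10% `N`.
#'
#' @param reads Read table (`id`, `seq`, `qual`; Phred+33).
#' @param min_mean_q Minimum mean Phred score to keep a read.
#' @param max_n_frac Maximum tolerated fraction of `N` bases.
#' @return List with `kept` (read table) and `dropped` (read table plus a
#'   `reason` column, one of `"mean_q"`, `"n_frac"`).
#' @export
filter_quality <- function(reads, min_mean_q = 20, max_n_frac = 0.1) {
  .check_reads(reads)
  mq <- .mean_phred(reads$qual)
  n_count <- nchar(reads$seq) - nchar(gsub("N", "", reads$seq, fixed = TRUE))
  nf <- n_count / pmax(1L, nchar(reads$seq))
  low_q <- mq < min_mean_q
  high_n <- nf > max_n_frac
  drop <- low_q | high_n
  dropped <- reads[drop, , drop = FALSE]
  # quality failure takes precedence in the audit reason
  dropped$reason <- ifelse(low_q[drop], "mean_q", "n_frac")
  list(kept = reads[!drop, , drop = FALSE], dropped = dropped)
}

#' Homopolymer (polyNT) filter
#'
#' Removes reads dominated by a run of a single base (in oligo-dT primed
#' libraries these are overwhelmingly poly-T artifacts). A read is dropped
#' when its longest single-base run covers at least `max_homopolymer_frac`
#' of its length.
#'
#' @param reads Read table.
#' @param max_homopolymer_frac Run-length fraction at or above which a read
#'   is discarded (default 0.8).
#' @return List with `kept` and `dropped` (with `reason = "polyNT"`).
#' @export
filter_polyNT <- function(reads, max_homopolymer_frac = 0.8) {
  .check_reads(reads)
  run <- .longest_run(reads$seq)
  drop <- run >= max_homopolymer_frac * nchar(reads$seq)
  dropped <- reads[drop, , drop = FALSE]
  if (nrow(dropped) > 0L) dropped$reason <- "polyNT"
  else dropped$reason <- character(0)
  list(kept = reads[!drop, , drop = FALSE], dropped = dropped)
}

# Length of the leading poly-T run of one sequence: the longest prefix that
# ends on a T and contains at most one non-T per 10 nt of prefix.
.polyt_run <- function(seq) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  if (length(ch) == 0L) return(0L)
  non_t <- cumsum(ch != "T")
  i <- seq_along(ch)
  ok <- ch == "T" & non_t * 10L <= i
  if (!any(ok)) 0L else max(i[ok])
}

#' Detect and trim the 5' poly-T run of oligo-dT primed reads
#'
#' In 3'-end libraries the read starts with the complement of the polyA
#' tail: a poly-T run. Reads beginning with at least `min_t_run` leading Ts
#' (tolerating one non-T per 10 nt of run, so a single sequencing error
#' does not discard the read) have the run removed; the remainder is the
#' genome-alignable portion. Reads without the run are rejected as
#' non-polyT; trimmed remainders shorter than `min_len` are rejected as
#' too short for unique mapping.
#'
#' @param reads Read table.
#' @param min_t_run Minimum leading poly-T run length (default 8).
#' @param min_len Minimum post-trim length to keep a read (default 25).
#' @return List with `kept` (trimmed read table plus `t_run` column) and
#'   `dropped` (with `reason` in `"no_polyt"`, `"too_short"`).
#' @export
trim_polyT <- function(reads, min_t_run = 8, min_len = 25) {
  .check_reads(reads)
  runs <- vapply(reads$seq, .polyt_run, integer(1), USE.NAMES = FALSE)
  has_run <- runs >= min_t_run
  rem_len <- nchar(reads$seq) - runs
  keep <- has_run & rem_len >= min_len
  kept <- reads[keep, , drop = FALSE]
  if (nrow(kept) > 0L) {
    kept$t_run <- runs[keep]
    kept$seq <- substring(kept$seq, runs[keep] + 1L)
    kept$qual <- substring(kept$qual, runs[keep] + 1L)
  } else kept$t_run <- integer(0)
  dropped <- reads[!keep, , drop = FALSE]
  dropped$reason <- ifelse(!has_run[!keep], "no_polyt", "too_short")
  list(kept = kept, dropped = dropped)
}

#' Run the full FASTQ preprocessing stage
#'
#' Applies [filter_quality()], [filter_polyNT()] and [trim_polyT()] in
#' order and returns the surviving trimmed reads together with a per-read
#' audit of all drops. `kept` plus `dropped` always partition the input.
#'
#' @param reads Read table.
#' @inheritParams filter_quality
#' @inheritParams filter_polyNT
#' @inheritParams trim_polyT
#' @param audit_path Optional path; when given, the drop audit is written
#'   as headered TSV.
#' @return List with `kept`, `dropped`, and `counts` (named integer vector
#'   of stage tallies).
#' @export
preprocess_reads <- function(reads, min_mean_q = 20, max_n_frac = 0.1,
                             max_homopolymer_frac = 0.8, min_t_run = 8,
                             min_len = 25, audit_path = NULL) {
  q <- filter_quality(reads, min_mean_q, max_n_frac)
  h <- filter_polyNT(q$kept, max_homopolymer_frac)
  t <- trim_polyT(h$kept, min_t_run, min_len)
  dropped <- rbind(
    q$dropped[, c("id", "reason")],
    h$dropped[, c("id", "reason")],
    t$dropped[, c("id", "reason")]
  )
  if (!is.null(audit_path)) .write_tsv(dropped, audit_path)
  counts <- c(input = nrow(reads), quality_pass = nrow(q$kept),
              polynt_pass = nrow(h$kept), polyt_kept = nrow(t$kept))
  list(kept = t$kept, dropped = dropped, counts = counts)
}
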
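#' Run the tandem-UTR pipeline end to end
#'
#' Orchestrates sitecall -> switch testing + differential expression ->
#' enrichment over two aligned 3'-end libraries, writing every result
#' table plus a JSON run manifest (all thresholds, paths, seed and sample
#' order made explicit) into `out_dir`. Sample order is taken from the
#' names of `alignments`, never from filename order: the sign of the
#' switch index depends on which library is row two.
#'
#' @param genome Path to the reference FASTA, or a `DNAStringSet`.
#' @param transcripts Path to BED12/GTF transcript models, or a
#'   transcript table.
#' @param alignments Named length-2 vector/list of alignment inputs
#'   (BED6/SAM/BAM paths or `GRanges`); names are the sample labels,
#'   first = row one.
#' @param known_sites Optional known-site BED path or table.
#' @param gene_sets Optional GMT path or gene-set list; when given, the
#'   shortened/lengthened/up/down gene lists are enriched against the
#'   background of all genes with counted reads.
#' @param out_dir Output directory.
#' @param gap Clustering gap (nt, default 24).
#' @param ip_window,ip_min_a Internal-priming window / A threshold.
#' @param tol Annotation tolerance (nt, default 24).
#' @param min_reads Minimum pooled reads per tandem table (default 30).
#' @param r_cut,fdr_cut Switch-call thresholds (default 0.1 / 0.01).
#' @param deg_fdr_cut,fold_cut DEG thresholds (default 0.01 / 2).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list: `sites`, `switch_fit`, `degs`, `enrich`
#'   (per gene list), `summary` (per-stage event counts), `paths`.
#' @export
run_apa_pipeline <- function(genome, transcripts, alignments,
                             known_sites = NULL, gene_sets = NULL,
                             out_dir, gap = 24L, ip_window = 20L,
                             ip_min_a = 12L, tol = 24L, min_reads = 30L,
                             r_cut = 0.1, fdr_cut = 0.01,
                             deg_fdr_cut = 0.01, fold_cut = 2, seed = 1L) {
  if (length(alignments) != 2L || is.null(names(alignments)))
    stop("alignments must be a named length-2 vector (sample one first)")
  samples <- names(alignments)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  gen <- stage("refio", {
    if (is.character(genome)) read_genome(genome) else genome
  })
  tx <- stage("refio", {
    if (is.character(transcripts)) read_transcripts(transcripts, gen)
    else transcripts
  })
  kdb <- stage("refio", {
    if (is.character(known_sites)) read_known_sites(known_sites, gen)
    else known_sites
  })
  gmt <- stage("refio", {
    if (is.character(gene_sets)) read_gmt(gene_sets) else gene_sets
  })
  events <- stage("sitecall", {
    do.call(rbind, lapply(samples, function(s)
      extract_cleavage(alignments[[s]], sample_id = s)))
  })
  ip <- stage("sitecall",
              internal_priming_filter(events, gen, ip_window, ip_min_a))
  sites <- stage("sitecall", {
    s <- cluster_events(ip$kept, gap = gap, samples = samples)
    annotate_sites(s, tx, kdb, tol = tol)
  })
  attr(sites, "samples") <- samples
  gc_mat <- stage("expression", gene_counts(sites))
  fit <- stage("apaswitch", {
    tabs <- build_tandem_tables(sites, samples = samples,
                                min_reads = min_reads)
    apa_switch(tabs, r_cut = r_cut, fdr_cut = fdr_cut)
  })
  degs <- stage("expression", {
    call_degs(data.frame(gene_id = rownames(gc_mat),
                         x = gc_mat[, 1], y = gc_mat[, 2],
                         stringsAsFactors = FALSE),
              N1 = sum(ip$kept$sample_id == samples[1]),
              N2 = sum(ip$kept$sample_id == samples[2]),
              fdr_cut = deg_fdr_cut, fold_cut = fold_cut)
  })
  enr <- NULL
  if (!is.null(gmt)) enr <- stage("enrich", {
    background <- rownames(gc_mat)
    lists <- list(
      shortened = fit$results$gene_id[fit$results$call == "shortened"],
      lengthened = fit$results$gene_id[fit$results$call == "lengthened"],
      up = degs$gene_id[degs$call == "up"],
      down = degs$gene_id[degs$call == "down"])
    lapply(lists, function(g)
      enrich_list(intersect(g, background), gmt, background))
  })
  run_summary <- data.frame(
    stage = c("events_in", "ip_pass", "sites", "genes_with_sites",
              "genes_tested", "switch_calls", "degs"),
    count = c(nrow(events), nrow(ip$kept), nrow(sites),
              length(unique(stats::na.omit(sites$gene_id))),
              nrow(fit$results), sum(fit$results$call != "none"),
              sum(degs$call != "none")))
  manifest <- list(
    samples = samples, gap = gap, ip_window = ip_window,
    ip_min_a = ip_min_a, tol = tol, min_reads = min_reads, r_cut = r_cut,
    fdr_cut = fdr_cut, deg_fdr_cut = deg_fdr_cut, fold_cut = fold_cut,
    seed = seed,
    inputs = lapply(list(genome = genome, transcripts = transcripts,
                         alignments = alignments), function(x)
                           if (is.character(x)) x else "<in-memory>"))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  hash <- unname(tools::md5sum(manifest_path))
  paths <- c(manifest = manifest_path,
             sites = file.path(out_dir, "polya_sites.bed"),
             counts = file.path(out_dir, "gene_counts.tsv"),
             switch = file.path(out_dir, "switch.tsv"),
             degs = file.path(out_dir, "degs.tsv"),
             summary = file.path(out_dir, "run_summary.tsv"))
  write_polya_sites(sites, paths["sites"])
  .write_stamped <- function(df, path) {
    writeLines(paste0("#manifest_md5=", hash), path)
    con <- file(path, "a")
    writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    close(con)
  }
  .write_stamped(data.frame(gene_id = rownames(gc_mat), gc_mat,
                            check.names = FALSE), paths["counts"])
  .write_stamped(fit$results, paths["switch"])
  .write_stamped(degs, paths["degs"])
  .write_stamped(run_summary, paths["summary"])
  if (!is.null(enr))
    for (nm in names(enr)) {
      p <- file.path(out_dir, paste0("enrich_", nm, ".tsv"))
      .write_stamped(enr[[nm]], p)
      paths[paste0("enrich_", nm)] <- p
    }
  invisible(list(sites = sites, switch_fit = fit, degs = degs,
                 enrich = enr, summary = run_summary, paths = paths))
}
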
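#' Fold enrichment of a gene set in a gene list
#'
#' fold = (k / n) / (K / N): the ratio of the set's frequency in the list
#' to its frequency in the background population.
#'
#' @param k List hits (list genes in the set).
#' @param n List size.
#' @param K Population hits (background genes in the set).
#' @param N Population (background) size.
#' @return The enrichment fold (vectorized).
#' @examples
#' fold_enrichment(9, 248, 75, 5085)  # 2.46
#' @export
fold_enrichment <- function(k, n, K, N) {
  if (any(n == 0) || any(K == 0)) stop("n and K must be positive")
  .check_knKN(k, n, K, N)
  (k * N) / (n * K)
}

.check_knKN <- function(k, n, K, N) {
  if (any(k < 0 | n < 0 | K < 0 | N < 0)) stop("negative contingency value")
  if (any(k > pmin(n, K))) stop("k cannot exceed min(n, K)")
  if (any(n > N) || any(K > N)) stop("n and K cannot exceed N")
  invisible(TRUE)
}

#' EASE-style over-representation p-value
#'
#' One-tailed hypergeometric over-representation probability with the
#' conservative EASE penalty of removing one list hit:
#' p = P(X >= k - 1) for X the overlap of a random n-gene list with the
#' K-gene set in an N-gene background. With `penalize = FALSE` the plain
#' Fisher upper tail P(X >= k) is returned. `k = 0` (and, penalized,
#' `k = 1`) give p = 1.
#'
#' @inheritParams fold_enrichment
#' @param penalize Apply the EASE one-hit penalty (default `TRUE`).
#' @return Upper-tail p-value (vectorized).
#' @export
ease_test <- function(k, n, K, N, penalize = TRUE) {
  .check_knKN(k, n, K, N)
  kk <- if (penalize) pmax(0, k - 1) else k
  # P(X >= kk) = phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
  p <- stats::phyper(kk - 1, K, N - K, n, lower.tail = FALSE)
  pmin(1, p)
}

#' Gene-set enrichment of a called gene list
#'
#' Computes, for every set with at least one list hit, the contingency
#' values by set intersection against the background, the fold
#' enrichment, the EASE (or plain Fisher) p-value, and a
#' Benjamini-Hochberg FDR over the reported rows.
#'
#' @param genes Character vector, the called gene list (must be a subset
#'   of `background`).
#' @param sets Gene-set collection from [read_gmt()] (named list of
#'   member vectors).
#' @param background Character vector of all testable genes in the run.
#' @param penalize Passed to [ease_test()].
#' @return Data.frame sorted by p: `set_id`, `set_name`, `list_hits`,
#'   `list_size`, `pop_hits`, `pop_size`, `fold`, `p`, `fdr`.
#' @export
enrich_list <- function(genes, sets, background, penalize = TRUE) {
  if (length(background) == 0L) stop("empty background")
  background <- unique(background)
  genes <- unique(genes)
  if (!all(genes %in% background))
    stop("gene list contains genes absent from the background")
  set_names <- attr(sets, "set_name")
  if (is.null(set_names))
    set_names <- stats::setNames(names(sets), names(sets))
  n <- length(genes); N <- length(background)
  rows <- lapply(names(sets), function(id) {
    members <- intersect(sets[[id]], background)
    K <- length(members)
    k <- length(intersect(genes, members))
    if (k == 0L) return(NULL)
    data.frame(set_id = id, set_name = unname(set_names[id]),
               list_hits = k, list_size = n, pop_hits = K, pop_size = N,
               fold = fold_enrichment(k, n, K, N),
               p = ease_test(k, n, K, N, penalize = penalize),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(set_id = character(0), set_name = character(0),
                      list_hits = integer(0), list_size = integer(0),
                      pop_hits = integer(0), pop_size = integer(0),
                      fold = numeric(0), p = numeric(0), fdr = numeric(0)))
  out$fdr <- bh_fdr(out$p)
  out <- out[order(out$p), , drop = FALSE]
  rownames(out) <- NULL
  out
}
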
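#' Classify differentially expressed genes at an FDR threshold
#'
#' Splits a differential-expression table into upregulated
#' (`q <= fdr, log2fc > 0`) and downregulated (`q <= fdr, log2fc < 0`)
#' sets; genes at exactly zero fold change stay unassigned. The universe is
#' the full set of tested genes.
#'
#' @param de Data frame with columns `gene`, `log2fc`, `q`.
#' @param fdr False discovery rate threshold in (0, 1) (default 0.05).
#' @return List with character vectors `up`, `down` and `universe`.
#' @export
classify_de <- function(de, fdr = 0.05) {
  stopifnot(all(c("gene", "log2fc", "q") %in% names(de)))
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0, 1)")
  if (anyDuplicated(de$gene)) stop("duplicate gene identifiers in DE table")
  if (any(de$q < 0 | de$q > 1, na.rm = TRUE)) stop("q-values must lie in [0, 1]")
  sig <- !is.na(de$q) & de$q <= fdr
  list(up = de$gene[sig & de$log2fc > 0],
       down = de$gene[sig & de$log2fc < 0],
       universe = de$gene)
}

#' Gene-set overlap enrichment by one-sided Fisher exact test
#'
#' Tests whether a query gene set overlaps a signature more than expected
#' by chance within a universe, using the hypergeometric upper tail
#' ([fisher_one_sided()]) on the 2x2 table
#' `(k = |query n sig|, K = |sig n universe|, n = |query|, N = |universe|)`.
#' Signature genes outside the universe are dropped before testing.
#'
#' @param query Character vector, a subset of `universe`.
#' @param signature Character vector of signature genes.
#' @param universe Character vector of all tested genes.
#' @param query_name,signature_name Labels carried into the result.
#' @return An `enrichment_result` data frame row: query, signature, k, K,
#'   n, N, p, fold (`(k/n)/(K/N)`; 0 when the query is empty).
#' @export
enrich <- function(query, signature, universe,
                   query_name = "query", signature_name = "signature") {
  if (length(universe) == 0L) stop("universe is empty")
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query contains genes outside the universe")
  sig <- intersect(unique(signature), universe)
  k <- length(intersect(query, sig))
  K <- length(sig)
  n <- length(query)
  N <- length(universe)
  p <- fisher_one_sided(k, K, n, N)
  fold <- if (n == 0L || K == 0L) 0 else (k / n) / (K / N)
  data.frame(query = query_name, signature = signature_name,
             k = k, K = K, n = n, N = N, p = p, fold = fold,
             stringsAsFactors = FALSE)
}

#' Enrichment matrix of DE sets against cell-state signatures
#'
#' Tests the up- and downregulated sets against each signature, producing
#' one row per (query, signature) cell with the one-sided p, fold
#' enrichment, and a `star` flag marking cells below the display threshold
#' `p < 1e-10`. The star threshold is display metadata; no multiple-testing
#' correction is applied across cells.
#'
#' @param up,down Character vectors of up-/downregulated genes.
#' @param signatures Named list of signature gene vectors.
#' @param universe Character vector of all tested genes.
#' @param star_threshold Display threshold for the `star` flag.
#' @return Data frame with `2 * length(signatures)` rows.
#' @export
enrichment_report <- function(up, down, signatures, universe,
                              star_threshold = 1e-10) {
  stopifnot(is.list(signatures), length(signatures) > 0L,
            !is.null(names(signatures)))
  rows <- list()
  for (qn in c("up", "down")) {
    query <- if (qn == "up") up else down
    for (sn in names(signatures)) {
      rows[[length(rows) + 1L]] <-
        enrich(query, signatures[[sn]], universe,
               query_name = qn, signature_name = sn)
    }
  }
  out <- do.call(rbind, rows)
  out$star <- out$p < star_threshold
  out
}
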
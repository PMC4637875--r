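#' Per-gene log2 fold change of knockout over wild type
#'
#' For each gene passing the expression floor, computes
#' `log2((mean_KO + pseudocount) / (mean_WT + pseudocount))`, so
#' derepression in the knockout is positive. Genes whose pooled mean
#' abundance across both arms falls below `min_expression` are excluded
#' (the "expressed" filter); with a zero pseudocount, genes with a
#' zero-mean arm are excluded with a warning rather than yielding
#' non-finite values.
#'
#' @param expression Data frame with a `gene` column and sample columns.
#' @param wt_samples,ko_samples Disjoint, non-empty sets of sample column
#'   names.
#' @param pseudocount Abundance added to each arm mean (default 0.1).
#' @param min_expression Pooled-mean abundance floor (default 1).
#' @return Named numeric vector of log2 fold changes (gene -> lfc).
#' @export
compute_log2fc <- function(expression, wt_samples = NULL, ko_samples = NULL,
                           pseudocount = 0.1, min_expression = 1) {
  if (is.null(wt_samples)) wt_samples <- grep("^WT_", names(expression), value = TRUE)
  if (is.null(ko_samples)) ko_samples <- grep("^KO_", names(expression), value = TRUE)
  if (length(wt_samples) == 0L || length(ko_samples) == 0L)
    stop("wt_samples and ko_samples must be non-empty")
  if (length(intersect(wt_samples, ko_samples)) > 0L)
    stop("wt_samples and ko_samples must be disjoint")
  unknown <- setdiff(c(wt_samples, ko_samples), names(expression))
  if (length(unknown) > 0L)
    stop("unknown sample names: ", paste(unknown, collapse = ", "))
  if (pseudocount < 0) stop("pseudocount must be non-negative")
  wt <- rowMeans(as.matrix(expression[, wt_samples, drop = FALSE]))
  ko <- rowMeans(as.matrix(expression[, ko_samples, drop = FALSE]))
  pooled <- rowMeans(as.matrix(
    expression[, c(wt_samples, ko_samples), drop = FALSE]))
  keep <- pooled >= min_expression
  if (pseudocount == 0) {
    degenerate <- keep & (wt == 0 | ko == 0)
    if (any(degenerate)) {
      warning(sum(degenerate),
              " gene(s) with a zero-mean arm excluded at pseudocount 0")
      keep <- keep & !degenerate
    }
  }
  lfc <- log2((ko[keep] + pseudocount) / (wt[keep] + pseudocount))
  names(lfc) <- expression$gene[keep]
  lfc
}

# Best (most negative) score per gene for one miRNA.
best_scores <- function(scores, mirna) {
  stopifnot(all(c("gene", "mirna", "context_score") %in% names(scores)))
  sub <- scores[scores$mirna == mirna, , drop = FALSE]
  if (nrow(sub) == 0L) return(stats::setNames(numeric(0), character(0)))
  best <- tapply(sub$context_score, sub$gene, min)
  stats::setNames(as.numeric(best), names(best))
}

#' Select predicted targets of a miRNA
#'
#' Genes whose best (most negative) context+ score for the named miRNA is at
#' or below the threshold. The boundary is inclusive (`score <= threshold`),
#' applied identically to target and background selection.
#'
#' @param scores Data frame with columns `gene`, `mirna`, `context_score`.
#' @param mirna miRNA name.
#' @param threshold Score cutoff, negative (default -0.2).
#' @return Character vector of target genes.
#' @export
select_targets <- function(scores, mirna, threshold = -0.2) {
  if (threshold >= 0) stop("threshold must be negative")
  best <- best_scores(scores, mirna)
  if (length(best) == 0L) {
    warning("miRNA '", mirna, "' absent from score table; empty target set")
    return(character(0))
  }
  names(best)[best <= threshold]
}

#' Select the background gene set for the derepression comparison
#'
#' Genes with a qualifying score (`score <= threshold`) for any conserved
#' miRNA other than the excluded one; genes that also qualify as targets of
#' the excluded miRNA are removed so the two distributions being compared
#' are disjoint.
#'
#' @inheritParams select_targets
#' @param mirna_excluded The knocked-out miRNA whose targets are removed.
#' @return Character vector of background genes.
#' @export
select_background <- function(scores, mirna_excluded, threshold = -0.2) {
  if (threshold >= 0) stop("threshold must be negative")
  other <- scores[scores$mirna != mirna_excluded &
                    scores$context_score <= threshold, , drop = FALSE]
  bg <- unique(other$gene)
  bg <- setdiff(bg, select_targets(scores, mirna_excluded, threshold))
  if (length(bg) == 0L)
    stop("background set is empty: no qualifying targets of other miRNAs")
  bg
}

#' Partition target genes into bins of predicted strength
#'
#' Bins are half-open intervals on predicted strength (the absolute score),
#' ordered weakest to strongest; with the default edges they are labelled
#' `(-0.2, -0.1]`, `(-0.3, -0.2]` and `(-Inf, -0.3]` in score notation.
#' A gene whose best score falls exactly on an interior edge is assigned to
#' the weaker bin (so a score of exactly -0.3 sits in the middle bin and
#' the strongest bin holds strictly stronger scores), and the weakest bin
#' is closed at both ends so every gene at the selection threshold is
#' covered. Each gene is assigned to exactly one bin by its best score;
#' genes scoring above the weakest edge are excluded with a warning.
#'
#' @param targets Character vector of target genes.
#' @param scores Score table (`gene`, `mirna`, `context_score`).
#' @param mirna miRNA whose scores define the bins.
#' @param edges Strictly decreasing score edges (default
#'   `c(-0.1, -0.2, -0.3)`).
#' @return Named list of gene vectors, weakest bin first, with attribute
#'   `"edges"`.
#' @export
bin_by_strength <- function(targets, scores, mirna,
                            edges = c(-0.1, -0.2, -0.3)) {
  if (any(diff(edges) >= 0)) stop("edges must be strictly decreasing")
  best <- best_scores(scores, mirna)
  best <- best[names(best) %in% targets]
  missing <- setdiff(targets, names(best))
  if (length(missing) > 0L)
    stop("targets without a score for ", mirna, ": ",
         paste(utils::head(missing, 5), collapse = ", "))
  above <- names(best)[best > edges[1]]
  if (length(above) > 0L) {
    warning(length(above), " gene(s) scoring above the weakest edge excluded")
    best <- best[best <= edges[1]]
  }
  k <- length(edges)
  lowers <- c(edges[-1], -Inf)
  labels <- sprintf("(%s,%s]",
                    ifelse(is.finite(lowers), format(lowers), "-Inf"),
                    format(edges))
  s <- abs(best)                      # predicted strength
  t_lo <- abs(edges)                  # 0.1, 0.2, 0.3
  t_hi <- c(abs(edges)[-1], Inf)
  bins <- stats::setNames(vector("list", k), labels)
  for (j in seq_len(k)) {
    lower_ok <- if (j == 1L) s >= t_lo[j] else s > t_lo[j]
    bins[[j]] <- names(best)[lower_ok & s <= t_hi[j]]
  }
  structure(bins, edges = edges)
}

#' Score-binned derepression analysis
#'
#' The core knockout-derepression comparison: for each strength bin, the
#' distribution of target-gene log2 fold changes is compared with the
#' background distribution by a two-sided two-sample Kolmogorov-Smirnov
#' test, and the location effect is summarized as the difference of
#' medians. The monotone flag records whether the median shifts are
#' non-decreasing from the weakest to the strongest bin, the signature of
#' dose-dependent direct targeting. No multiple-testing correction is
#' applied across bins; p-values are reported per bin.
#'
#' @param lfc Named log2 fold-change vector from [compute_log2fc()].
#' @param bins Named list of gene vectors from [bin_by_strength()]
#'   (weakest first).
#' @param background Character vector of background genes.
#' @param ks_method Method passed to [ks_two_sample()].
#' @return An object of class `derepression_result`: list with `bins` (data
#'   frame: bin, n, median_shift, D, p, method), `background_n`, `monotone`
#'   and `cdf` (per-set ECDF coordinates for plotting).
#' @export
derepression_analysis <- function(lfc, bins, background,
                                  ks_method = "asymptotic") {
  bg_lfc <- lfc[names(lfc) %in% background]
  if (length(bg_lfc) == 0L)
    stop("background set has no genes with fold-change values")
  bg_median <- stats::median(bg_lfc)
  rows <- vector("list", length(bins))
  cdf <- list(ecdf_coords(bg_lfc, "background"))
  for (j in seq_along(bins)) {
    bn <- names(bins)[j]
    bin_lfc <- lfc[names(lfc) %in% bins[[j]]]
    if (length(bin_lfc) == 0L)
      stop("bin '", bn, "' has no genes with fold-change values")
    ks <- ks_two_sample(bin_lfc, bg_lfc, method = ks_method)
    rows[[j]] <- data.frame(
      bin = bn, n = length(bin_lfc),
      median_shift = stats::median(bin_lfc) - bg_median,
      D = ks$D, p = ks$p, method = ks$method, stringsAsFactors = FALSE)
    cdf[[j + 1L]] <- ecdf_coords(bin_lfc, bn)
  }
  bins_tab <- do.call(rbind, rows)
  structure(
    list(bins = bins_tab,
         background_n = length(bg_lfc),
         monotone = !is.unsorted(bins_tab$median_shift),
         cdf = do.call(rbind, cdf)),
    class = "derepression_result"
  )
}

ecdf_coords <- function(values, label) {
  v <- sort(values)
  data.frame(set = label, value = v, ecdf = seq_along(v) / length(v),
             stringsAsFactors = FALSE)
}

#' @export
print.derepression_result <- function(x, ...) {
  cat(sprintf("Derepression analysis vs %d background genes (median shifts %s)\n",
              x$background_n,
              if (x$monotone) "monotone in bin strength" else "not monotone"))
  print(x$bins, row.names = FALSE)
  invisible(x)
}
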
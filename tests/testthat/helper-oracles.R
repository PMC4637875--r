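# Independent oracles and tiny fixture builders shared across test files.

# Brute-force KS statistic: scan ECDFs at every pooled point with explicit
# counting loops (independent of the findInterval-based implementation).
ks_stat_brute <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  d <- 0
  for (t in pts) {
    fx <- sum(x <= t) / length(x)
    fy <- sum(y <= t) / length(y)
    d <- max(d, abs(fx - fy))
  }
  d
}

# Direct hypergeometric upper-tail sum via choose() ratios; exact integer
# arithmetic in doubles for N <= 56, ~1e-15 relative accuracy beyond.
fisher_tail_direct <- function(k, K, n, N) {
  j <- seq.int(k, min(K, n))
  j <- j[n - j <= N - K]
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# Uniform draw from lo:hi that is safe when lo == hi (unlike sample()).
sample_int_range <- function(lo, hi) {
  r <- seq.int(lo, hi)
  r[sample.int(length(r), 1L)]
}

# Small hand-built score table: two miRNAs, boundary cases included.
tiny_scores <- function() {
  data.frame(
    gene = c("g1", "g2", "g3", "g4", "g5", "g5", "g6", "g7"),
    mirna = c("miR-X", "miR-X", "miR-X", "miR-X", "miR-X", "miR-Y",
              "miR-Y", "miR-Y"),
    context_score = c(-0.25, -0.15, -0.20, -0.35, -0.30, -0.30, -0.30, -0.21),
    stringsAsFactors = FALSE
  )
}

# Expression table with exact arm means for fold-change arithmetic checks.
tiny_expression <- function() {
  data.frame(
    gene = c("gA", "gB", "gC"),
    WT_1 = c(2, 4, 0), WT_2 = c(4, 4, 0), WT_3 = c(6, 4, 0),
    KO_1 = c(4, 4, 0), KO_2 = c(8, 4, 0), KO_3 = c(12, 4, 0),
    stringsAsFactors = FALSE
  )
}

# Assemble a mirna_profile directly from per-hairpin dominant counts.
profile_from_counts <- function(counts) {
  asg <- data.frame(
    id = sprintf("r%d", seq_len(sum(counts))),
    insert = "x",
    status = "assigned",
    hairpin = rep(names(counts), counts),
    start = 10L, stringsAsFactors = FALSE
  )
  asg$end <- 32L
  dominant_isoform_counts(asg)
}
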
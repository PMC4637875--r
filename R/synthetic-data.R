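#' Configuration for the small RNA-seq read simulator
#'
#' Bundles and validates the parameters of [gen_smallrna_fastq()]. Each clean
#' read is a mature miRNA insert (a fixed-coordinate substring of its
#' hairpin) followed by the 3' sequencing adapter and random filler, padded
#' to the read length. Failure modes are planted disjointly — each planted
#' bad read fails for exactly one reason — so downstream filter counts have
#' exact ground truth.
#'
#' @param n_reads Total number of reads.
#' @param composition Named numeric vector of per-hairpin fractions of clean
#'   reads; must sum to 1.
#' @param adapter 3' adapter sequence (default the Illumina TruSeq small-RNA
#'   prefix `TGGAAT`).
#' @param read_length Read length in nucleotides (default 50, typical for
#'   small RNA libraries).
#' @param mature_start,mature_len 0-based start offset and length of the
#'   mature insert on every hairpin (defaults 10 and 22), fixing the
#'   dominant isoform.
#' @param insert_len_range Length bounds (min, max) for isomiR variant
#'   inserts, used only when `isomir_frac > 0`.
#' @param isomir_frac Fraction of clean reads drawn as isomiR variants
#'   (shifted start/end) rather than the canonical mature insert. Default 0:
#'   all clean reads are the canonical isoform.
#' @param n_qc_fail,n_no_adapter,n_short_insert,n_ambiguous Planted counts
#'   of reads failing the Illumina QC flag, lacking the adapter, having a
#'   trimmed insert shorter than 15 nt, and containing an ambiguous base.
#' @param seq_error_rate Per-base substitution probability applied to clean
#'   inserts (substitutions are always to another unambiguous base).
#' @param seed Integer seed; all randomness derives from it.
#' @return A validated list of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads = 1000L,
                            composition = c(`syn-mir-150` = 0.7,
                                            `syn-mir-21` = 0.3),
                            adapter = "TGGAAT",
                            read_length = 50L,
                            mature_start = 10L,
                            mature_len = 22L,
                            insert_len_range = c(18L, 26L),
                            isomir_frac = 0,
                            n_qc_fail = 0L,
                            n_no_adapter = 0L,
                            n_short_insert = 0L,
                            n_ambiguous = 0L,
                            seq_error_rate = 0,
                            seed = 1L) {
  cfg <- list(n_reads = as.integer(n_reads), composition = composition,
              adapter = toupper(adapter), read_length = as.integer(read_length),
              mature_start = as.integer(mature_start),
              mature_len = as.integer(mature_len),
              insert_len_range = as.integer(insert_len_range),
              isomir_frac = isomir_frac,
              n_qc_fail = as.integer(n_qc_fail),
              n_no_adapter = as.integer(n_no_adapter),
              n_short_insert = as.integer(n_short_insert),
              n_ambiguous = as.integer(n_ambiguous),
              seq_error_rate = seq_error_rate, seed = as.integer(seed))
  if (cfg$n_reads < 1L) stop("n_reads must be positive")
  if (is.null(names(cfg$composition)) || any(names(cfg$composition) == ""))
    stop("composition must be a named vector of hairpin fractions")
  if (abs(sum(cfg$composition) - 1) > 1e-9)
    stop("composition fractions must sum to 1")
  if (any(cfg$composition < 0)) stop("composition fractions must be non-negative")
  n_fail <- cfg$n_qc_fail + cfg$n_no_adapter + cfg$n_short_insert + cfg$n_ambiguous
  if (any(c(cfg$n_qc_fail, cfg$n_no_adapter, cfg$n_short_insert,
            cfg$n_ambiguous) < 0L))
    stop("planted failure counts must be non-negative")
  if (n_fail > cfg$n_reads)
    stop("planted failure counts exceed n_reads")
  if (nchar(cfg$adapter) == 0L || grepl("[^ACGT]", cfg$adapter))
    stop("adapter must be a non-empty ACGT string")
  if (length(cfg$insert_len_range) != 2L || cfg$insert_len_range[1] < 1L ||
      diff(cfg$insert_len_range) < 0L)
    stop("insert_len_range must be (min, max) with min >= 1")
  if (cfg$isomir_frac < 0 || cfg$isomir_frac > 1)
    stop("isomir_frac must be in [0, 1]")
  if (cfg$seq_error_rate < 0 || cfg$seq_error_rate > 1)
    stop("seq_error_rate must be a probability")
  if (cfg$mature_start < 0L || cfg$mature_len < 1L)
    stop("mature insert coordinates must be non-negative with positive length")
  structure(cfg, class = "read_sim_config")
}

#' Generate synthetic hairpin reference sequences
#'
#' Random uppercase ACGT sequences with unique names, pairwise distinct, and
#' guaranteed free of the adapter motif so adapter trimming never truncates
#' inside a genuine insert.
#'
#' @param n Number of hairpins (>= 1).
#' @param length Hairpin length in nucleotides (>= 40).
#' @param seed Integer seed.
#' @param avoid Motif that must not occur in any hairpin (default the
#'   `TGGAAT` adapter).
#' @return Named character vector of sequences (`syn-mir-1`, `syn-mir-2`,
#'   ... unless `names` is supplied via `composition` downstream).
#' @export
gen_hairpins <- function(n, length, seed, avoid = "TGGAAT") {
  if (n < 1L || length < 40L)
    stop("need n >= 1 hairpins of length >= 40")
  with_seed(seed, {
    out <- character(0)
    while (base::length(out) < n) {
      cand <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                    collapse = "")
      if (!grepl(avoid, cand, fixed = TRUE) && !cand %in% out)
        out <- c(out, cand)
    }
    names(out) <- paste0("syn-mir-", seq_len(n))
    out
  })
}

#' Simulate a small RNA-seq FASTQ with planted filter failures
#'
#' Clean reads are mature-insert + adapter + random filler, padded or
#' truncated to the configured read length. Exactly the configured numbers
#' of QC-flagged, adapter-less, short-insert (< 15 nt after trimming) and
#' ambiguous-base reads are planted, each failing for that single reason.
#' The returned truth record holds the planted per-reason counts and the
#' true per-hairpin clean-read counts, enabling exact downstream checks.
#'
#' @param cfg A [read_sim_config()].
#' @param hairpins Named character vector of hairpin sequences covering all
#'   names in `cfg$composition`.
#' @return A list with `reads` (data frame as from [read_fastq_reads()]) and
#'   `truth` (planted counts; `clean_counts` and `canonical_counts` are
#'   per-hairpin named vectors — they coincide when `isomir_frac = 0`).
#' @export
gen_smallrna_fastq <- function(cfg, hairpins) {
  stopifnot(inherits(cfg, "read_sim_config"))
  missing_hp <- setdiff(names(cfg$composition), names(hairpins))
  if (length(missing_hp) > 0)
    stop("composition names missing from hairpins: ",
         paste(missing_hp, collapse = ", "))
  need_len <- cfg$mature_start + max(cfg$mature_len + 2L, cfg$insert_len_range[2])
  if (any(nchar(hairpins[names(cfg$composition)]) < need_len))
    stop("hairpins too short for the configured mature insert coordinates")
  if (any(vapply(hairpins, function(h) grepl(cfg$adapter, h, fixed = TRUE), TRUE)))
    stop("hairpin sequences must not contain the adapter motif")

  with_seed(cfg$seed, {
    n_fail <- cfg$n_qc_fail + cfg$n_no_adapter + cfg$n_short_insert +
      cfg$n_ambiguous
    n_clean <- cfg$n_reads - n_fail
    hp_names <- names(cfg$composition)

    draw_hp <- function(n) {
      if (n == 0L) return(character(0))
      sample(hp_names, n, replace = TRUE, prob = cfg$composition)
    }
    canon_insert <- function(hp) {
      substr(hairpins[[hp]], cfg$mature_start + 1L,
             cfg$mature_start + cfg$mature_len)
    }
    rand_bases <- function(n) {
      if (n <= 0L) return("")
      paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
    }
    assemble <- function(insert) {
      body <- paste0(insert, cfg$adapter)
      pad <- cfg$read_length - nchar(body)
      read <- if (pad > 0) paste0(body, rand_bases(pad)) else body
      substr(read, 1L, cfg$read_length)
    }

    # clean reads (canonical mature insert, optionally isomiR variants)
    clean_hp <- draw_hp(n_clean)
    is_variant <- stats::runif(n_clean) < cfg$isomir_frac
    clean_inserts <- character(n_clean)
    for (i in seq_len(n_clean)) {
      hp <- clean_hp[i]
      if (is_variant[i]) {
        len <- sample(seq.int(cfg$insert_len_range[1],
                              cfg$insert_len_range[2]), 1L)
        max_shift <- 2L
        start <- cfg$mature_start + sample(seq.int(-max_shift, max_shift), 1L)
        start <- max(0L, min(start, nchar(hairpins[[hp]]) - len))
        ins <- substr(hairpins[[hp]], start + 1L, start + len)
        # force a distinct isoform key if the jitter landed on the canonical
        if (ins == canon_insert(hp))
          ins <- substr(hairpins[[hp]], cfg$mature_start + 2L,
                        cfg$mature_start + cfg$mature_len)
        clean_inserts[i] <- ins
      } else {
        clean_inserts[i] <- canon_insert(hp)
      }
    }
    if (cfg$seq_error_rate > 0 && n_clean > 0) {
      clean_inserts <- vapply(clean_inserts, function(ins) {
        b <- strsplit(ins, "")[[1]]
        hit <- stats::runif(length(b)) < cfg$seq_error_rate
        if (any(hit))
          b[hit] <- vapply(b[hit], function(x)
            sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
        paste(b, collapse = "")
      }, "", USE.NAMES = FALSE)
    }
    clean_seq <- vapply(clean_inserts, assemble, "", USE.NAMES = FALSE)

    # planted QC failures: valid clean-like reads with chastity flag Y
    qc_hp <- draw_hp(cfg$n_qc_fail)
    qc_seq <- vapply(qc_hp, function(hp) assemble(canon_insert(hp)), "",
                     USE.NAMES = FALSE)

    # adapter-less reads: random sequence with the motif scrubbed
    na_seq <- vapply(seq_len(cfg$n_no_adapter), function(i) {
      repeat {
        s <- rand_bases(cfg$read_length)
        if (!grepl(cfg$adapter, s, fixed = TRUE)) return(s)
      }
    }, "")

    # short inserts: 1-14 nt before the adapter
    sh_hp <- draw_hp(cfg$n_short_insert)
    sh_seq <- vapply(sh_hp, function(hp) {
      len <- sample(14L, 1L)
      assemble(substr(hairpins[[hp]], cfg$mature_start + 1L,
                      cfg$mature_start + len))
    }, "", USE.NAMES = FALSE)

    # ambiguous reads: canonical insert with a single N
    am_hp <- draw_hp(cfg$n_ambiguous)
    am_seq <- vapply(am_hp, function(hp) {
      ins <- canon_insert(hp)
      pos <- sample(nchar(ins), 1L)
      substr(ins, pos, pos) <- "N"
      assemble(ins)
    }, "", USE.NAMES = FALSE)

    seqs <- c(clean_seq, qc_seq, na_seq, sh_seq, am_seq)
    qc_flags <- c(rep(FALSE, n_clean), rep(TRUE, cfg$n_qc_fail),
                  rep(FALSE, cfg$n_no_adapter + cfg$n_short_insert +
                        cfg$n_ambiguous))
    perm <- sample.int(cfg$n_reads)
    reads <- data.frame(
      id = sprintf("read%06d", seq_len(cfg$n_reads)),
      sequence = seqs[perm],
      quality = strrep("I", nchar(seqs[perm])),
      qc_fail = qc_flags[perm],
      stringsAsFactors = FALSE
    )

    tab <- function(x) {
      counts <- table(factor(x, levels = hp_names))
      stats::setNames(as.integer(counts), hp_names)
    }
    truth <- list(
      n_qc_fail = cfg$n_qc_fail, n_no_adapter = cfg$n_no_adapter,
      n_short_insert = cfg$n_short_insert, n_ambiguous = cfg$n_ambiguous,
      n_clean = n_clean,
      clean_counts = tab(clean_hp),
      canonical_counts = tab(clean_hp[!is_variant]),
      mature_start = cfg$mature_start,
      mature_end = cfg$mature_start + cfg$mature_len
    )
    list(reads = reads, truth = truth)
  })
}

#' Configuration for the paired WT/KO expression simulator
#'
#' Models the derepression structure expected when a miRNA is knocked out:
#' predicted targets of the deleted miRNA rise on the log2 scale in
#' proportion to the strength of their best context+ score, while all other
#' genes are unchanged. Replicate noise is log-normal (normal on the log2
#' scale), the simplest model under which the log2 fold change of arm means
#' is unbiased for small noise.
#'
#' @param n_genes Number of genes.
#' @param n_replicates_per_arm Replicates per condition (>= 2).
#' @param frac_targets Fraction of genes that are targets of the knocked-out
#'   miRNA (scored, derepressed).
#' @param frac_background Fraction of genes that are targets of other
#'   conserved miRNAs (scored but not derepressed); disjoint from targets.
#' @param score_min,score_max Bounds of the uniform context+ score
#'   distribution for targets (both negative; more negative = stronger).
#' @param background_score_max Upper bound for background-miRNA scores
#'   (default -0.2, the conventional conserved-target threshold).
#' @param beta Derepression coefficient: planted log2 fold change per unit
#'   of absolute score (>= 0).
#' @param baseline_log2_mean,baseline_log2_sd Per-gene baseline abundance on
#'   the log2 scale.
#' @param noise_sd Replicate noise standard deviation, log2 scale.
#' @param mirna Name of the knocked-out miRNA in the score table.
#' @param background_mirnas Names used for background-miRNA score records.
#' @param seed Integer seed.
#' @return A validated list of class `expr_sim_config`.
#' @export
expr_sim_config <- function(n_genes = 10000L,
                            n_replicates_per_arm = 6L,
                            frac_targets = 0.2,
                            frac_background = 0.3,
                            score_min = -0.6,
                            score_max = -0.1,
                            background_score_max = -0.2,
                            beta = 1.0,
                            baseline_log2_mean = 6,
                            baseline_log2_sd = 2,
                            noise_sd = 0.25,
                            mirna = "syn-miR-150",
                            background_mirnas = c("syn-miR-21", "syn-miR-29",
                                                  "syn-let-7"),
                            seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_replicates_per_arm = as.integer(n_replicates_per_arm),
              frac_targets = frac_targets, frac_background = frac_background,
              score_min = score_min, score_max = score_max,
              background_score_max = background_score_max,
              beta = beta, baseline_log2_mean = baseline_log2_mean,
              baseline_log2_sd = baseline_log2_sd, noise_sd = noise_sd,
              mirna = mirna, background_mirnas = background_mirnas,
              seed = as.integer(seed))
  if (cfg$n_genes < 1L) stop("n_genes must be positive")
  if (cfg$n_replicates_per_arm < 2L)
    stop("need at least 2 replicates per arm")
  if (cfg$frac_targets < 0 || cfg$frac_targets > 1)
    stop("frac_targets must be in [0, 1]")
  if (cfg$frac_targets + cfg$frac_background > 1)
    stop("target and background fractions cannot exceed 1 together")
  if (cfg$beta < 0) stop("beta must be non-negative")
  if (cfg$score_min >= 0 || cfg$score_max >= 0 || cfg$score_min > cfg$score_max)
    stop("score bounds must be negative with score_min <= score_max")
  if (cfg$noise_sd < 0 || cfg$baseline_log2_sd < 0)
    stop("standard deviations must be non-negative")
  structure(cfg, class = "expr_sim_config")
}

#' Simulate paired WT/KO expression with score-dependent derepression
#'
#' WT replicate abundance is `2^(baseline + noise)`; KO replicate abundance
#' is `2^(baseline + true_lfc + noise)` where `true_lfc = beta * |score|`
#' for targets of the knocked-out miRNA and 0 otherwise. The target-score
#' table records the knocked-out miRNA's scores for exactly the target genes
#' plus scores for background genes under other miRNA names.
#'
#' @param cfg An [expr_sim_config()].
#' @return A list with `expression` (data frame: gene, WT_i, KO_i columns),
#'   `scores` (data frame: gene, mirna, context_score), `truth` (data frame:
#'   gene, is_target, score, true_lfc) and the sample name vectors
#'   `wt_samples`, `ko_samples`.
#' @export
gen_expression <- function(cfg) {
  stopifnot(inherits(cfg, "expr_sim_config"))
  with_seed(cfg$seed, {
    genes <- sprintf("gene%05d", seq_len(cfg$n_genes))
    n_tgt <- round(cfg$frac_targets * cfg$n_genes)
    n_bg <- round(cfg$frac_background * cfg$n_genes)
    idx_tgt <- if (n_tgt > 0) sample(cfg$n_genes, n_tgt) else integer(0)
    idx_bg <- if (n_bg > 0) sample(setdiff(seq_len(cfg$n_genes), idx_tgt),
                                   n_bg) else integer(0)

    score <- rep(NA_real_, cfg$n_genes)
    score[idx_tgt] <- stats::runif(n_tgt, cfg$score_min, cfg$score_max)
    true_lfc <- rep(0, cfg$n_genes)
    true_lfc[idx_tgt] <- cfg$beta * abs(score[idx_tgt])

    baseline <- stats::rnorm(cfg$n_genes, cfg$baseline_log2_mean,
                             cfg$baseline_log2_sd)
    r <- cfg$n_replicates_per_arm
    noise <- function() matrix(stats::rnorm(cfg$n_genes * r, 0, cfg$noise_sd),
                               cfg$n_genes, r)
    wt <- 2^(baseline + noise())
    ko <- 2^(baseline + true_lfc + noise())
    wt_samples <- paste0("WT_", seq_len(r))
    ko_samples <- paste0("KO_", seq_len(r))
    expression <- data.frame(gene = genes, wt, ko, stringsAsFactors = FALSE)
    names(expression) <- c("gene", wt_samples, ko_samples)

    bg_scores <- stats::runif(n_bg, cfg$score_min,
                              min(cfg$background_score_max, cfg$score_max))
    scores <- rbind(
      data.frame(gene = genes[idx_tgt], mirna = cfg$mirna,
                 context_score = score[idx_tgt], stringsAsFactors = FALSE),
      data.frame(gene = genes[idx_bg],
                 mirna = sample(cfg$background_mirnas, n_bg, replace = TRUE),
                 context_score = bg_scores, stringsAsFactors = FALSE)
    )
    truth <- data.frame(gene = genes,
                        is_target = seq_len(cfg$n_genes) %in% idx_tgt,
                        score = score, true_lfc = true_lfc,
                        stringsAsFactors = FALSE)
    list(expression = expression, scores = scores, truth = truth,
         wt_samples = wt_samples, ko_samples = ko_samples)
  })
}

#' Build a differential-expression table from a simulated expression matrix
#'
#' Fixture stand-in for a full DE pipeline: per-gene log2 fold change of arm
#' means (with pseudocount), a two-sample Welch t-test on log2-transformed
#' values, and Benjamini-Hochberg q-values.
#'
#' @param expression Data frame with a `gene` column and sample columns.
#' @param wt_samples,ko_samples Column names of the two arms (default: all
#'   columns starting `WT_` / `KO_`). Each arm needs >= 2 replicates.
#' @param pseudocount Added to arm means and to each value before log2.
#' @return Data frame with columns `gene`, `log2fc`, `p`, `q`.
#' @export
gen_de_table <- function(expression, wt_samples = NULL, ko_samples = NULL,
                         pseudocount = 0.1) {
  if (is.null(wt_samples)) wt_samples <- grep("^WT_", names(expression), value = TRUE)
  if (is.null(ko_samples)) ko_samples <- grep("^KO_", names(expression), value = TRUE)
  if (length(wt_samples) < 2L || length(ko_samples) < 2L)
    stop("need at least 2 replicates per arm for a t-test")
  wt <- as.matrix(expression[, wt_samples, drop = FALSE])
  ko <- as.matrix(expression[, ko_samples, drop = FALSE])
  log2fc <- log2((rowMeans(ko) + pseudocount) / (rowMeans(wt) + pseudocount))

  lwt <- log2(wt + pseudocount)
  lko <- log2(ko + pseudocount)
  r1 <- ncol(lwt); r2 <- ncol(lko)
  m1 <- rowMeans(lwt); m2 <- rowMeans(lko)
  v1 <- rowSums((lwt - m1)^2) / (r1 - 1)
  v2 <- rowSums((lko - m2)^2) / (r2 - 1)
  se2 <- v1 / r1 + v2 / r2
  tstat <- ifelse(se2 > 0, (m2 - m1) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / (v1^2 / (r1^2 * (r1 - 1)) + v2^2 / (r2^2 * (r2 - 1))),
               r1 + r2 - 2)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(tstat), df), 1)
  data.frame(gene = expression$gene, log2fc = log2fc, p = p,
             q = bh_qvalues(p), stringsAsFactors = FALSE)
}

#' Generate naive/effector/memory-like gene signatures with planted overlap
#'
#' Produces three pairwise-disjoint signature sets. The `naive_like` and
#' `memory_like` signatures are enriched toward `de_up` and the
#' `effector_like` signature toward `de_down`, each at `planted_enrichment`
#' times the uniform expectation, emulating the direction observed for
#' knockout-upregulated genes overlapping naive/memory programs and
#' downregulated genes overlapping the effector program.
#'
#' @param genes Universe of gene identifiers.
#' @param planted_enrichment Fold enrichment over uniform expectation
#'   (>= 1; 1 = no planted structure).
#' @param seed Integer seed.
#' @param de_up,de_down Gene sets toward which signatures are enriched.
#' @param sig_size Genes per signature.
#' @return Named list of three character vectors (`naive_like`,
#'   `effector_like`, `memory_like`).
#' @export
gen_signatures <- function(genes, planted_enrichment = 1, seed = 1L,
                           de_up = character(0), de_down = character(0),
                           sig_size = 300L) {
  if (planted_enrichment < 1) stop("planted_enrichment must be >= 1")
  if (3L * sig_size > length(genes))
    stop("disjoint signatures of this size exceed the universe")
  with_seed(seed, {
    used <- character(0)
    plant_one <- function(target_set) {
      n_univ <- length(genes)
      avail_in <- setdiff(intersect(target_set, genes), used)
      avail_out <- setdiff(genes, union(used, target_set))
      p_in <- min(1, planted_enrichment * length(target_set) / n_univ)
      k <- stats::rbinom(1L, sig_size, p_in)
      k <- min(k, length(avail_in))
      sig <- c(sample(avail_in, k),
               sample(avail_out, sig_size - k))
      used <<- c(used, sig)
      sig
    }
    list(naive_like = plant_one(de_up),
         effector_like = plant_one(de_down),
         memory_like = plant_one(de_up))
  })
}
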
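#' Run the full analysis pipeline from a single configuration
#'
#' Executes the enabled stages in order — small RNA quantification, target
#' derepression, signature enrichment — reading and writing file-based
#' artifacts so each stage can also be run standalone. A run manifest with
#' the package version, a configuration hash, and MD5 checksums of every
#' input and output is written alongside the outputs; identical
#' configuration and inputs reproduce identical output checksums.
#'
#' The configuration is a named list (or path to a YAML file) with an
#' `out` directory and any of the stage sections:
#' \describe{
#'   \item{quant}{`fastq`, `hairpins`, optional `adapter` (default
#'     `"TGGAAT"`), `min_len` (15), `max_mismatch` (0).}
#'   \item{derepression}{`expression`, `scores`, `mirna`, optional
#'     `threshold` (-0.2), `edges` (-0.1, -0.2, -0.3), `pseudocount` (0.1),
#'     `min_expression` (1), `wt_samples`/`ko_samples` (default: columns
#'     prefixed `WT_` / `KO_`).}
#'   \item{enrichment}{`de`, `signatures` (GMT), optional `fdr` (0.05).}
#' }
#'
#' @param config Named list or path to a YAML configuration file.
#' @return Invisibly, the manifest list (also written as `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  if (is.null(config$out)) stop("config must name an 'out' directory")
  out <- config$out
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  inputs <- character(0)
  outputs <- character(0)

  need <- function(section, keys, paths = keys) {
    missing <- keys[vapply(keys, function(k) is.null(section[[k]]), TRUE)]
    if (length(missing) > 0L)
      stop("stage config missing: ", paste(missing, collapse = ", "),
           call. = FALSE)
    for (k in paths) {
      if (!file.exists(section[[k]]))
        stop("input file not found: ", section[[k]], call. = FALSE)
    }
  }
  default <- function(x, d) if (is.null(x)) d else x

  if (!is.null(config$quant)) {
    cq <- config$quant
    need(cq, c("fastq", "hairpins"))
    inputs <- c(inputs, cq$fastq, cq$hairpins)
    message("[quant] filtering and quantifying ", cq$fastq)
    res <- tryCatch(
      quantify_smallrna(cq$fastq, cq$hairpins,
                        adapter = default(cq$adapter, "TGGAAT"),
                        min_len = default(cq$min_len, 15L),
                        max_mismatch = default(cq$max_mismatch, 0L)),
      error = function(e) stop("[quant] ", conditionMessage(e), call. = FALSE))
    f1 <- write_tsv(as.data.frame(res$report), file.path(out, "filter_report.tsv"))
    jsonlite::write_json(unclass(res$report), file.path(out, "filter_report.json"),
                         auto_unbox = TRUE)
    f2 <- write_tsv(res$profile$table, file.path(out, "mirna_counts.tsv"))
    f3 <- write_tsv(res$composition, file.path(out, "composition.tsv"))
    outputs <- c(outputs, f1, file.path(out, "filter_report.json"), f2, f3)
    message("[quant] ", res$report$n_pass, " reads pass, ",
            res$profile$n_assigned, " assigned to hairpins")
  }

  if (!is.null(config$derepression)) {
    cd <- config$derepression
    need(cd, c("expression", "scores", "mirna"),
         paths = c("expression", "scores"))
    inputs <- c(inputs, cd$expression, cd$scores)
    message("[derepression] analysing ", cd$mirna, " targets")
    expr <- read_expression_tsv(cd$expression)
    scores <- utils::read.delim(cd$scores, stringsAsFactors = FALSE)
    res <- tryCatch({
      edges <- default(cd$edges, c(-0.1, -0.2, -0.3))
      lfc <- compute_log2fc(expr, cd$wt_samples, cd$ko_samples,
                            pseudocount = default(cd$pseudocount, 0.1),
                            min_expression = default(cd$min_expression, 1))
      targets <- select_targets(scores, cd$mirna, threshold = edges[1])
      background <- select_background(scores, cd$mirna,
                                      threshold = default(cd$threshold, -0.2))
      bins <- bin_by_strength(targets, scores, cd$mirna, edges = edges)
      derepression_analysis(lfc, bins, background)
    }, error = function(e) stop("[derepression] ", conditionMessage(e),
                                call. = FALSE))
    jsonlite::write_json(
      list(bins = res$bins, background_n = res$background_n,
           monotone = res$monotone,
           decisions = list(boundary = "score <= threshold (inclusive)",
                            fold_change = "log2(KO/WT), derepression positive",
                            ks = "two-sided, asymptotic with ties")),
      file.path(out, "derepression.json"), auto_unbox = TRUE, digits = NA)
    f2 <- write_tsv(res$cdf, file.path(out, "cdf_coordinates.tsv"))
    outputs <- c(outputs, file.path(out, "derepression.json"), f2)
    message("[derepression] median shifts: ",
            paste(sprintf("%.3f", res$bins$median_shift), collapse = ", "),
            if (res$monotone) " (monotone)" else " (not monotone)")
  }

  if (!is.null(config$enrichment)) {
    ce <- config$enrichment
    need(ce, c("de", "signatures"))
    inputs <- c(inputs, ce$de, ce$signatures)
    message("[enrichment] classifying DE genes and testing signatures")
    res <- tryCatch({
      de <- utils::read.delim(ce$de, stringsAsFactors = FALSE)
      sigs <- read_gmt(ce$signatures)
      cls <- classify_de(de, fdr = default(ce$fdr, 0.05))
      list(cls = cls,
           report = enrichment_report(cls$up, cls$down, sigs, cls$universe))
    }, error = function(e) stop("[enrichment] ", conditionMessage(e),
                                call. = FALSE))
    f1 <- write_tsv(res$report, file.path(out, "enrichment.tsv"))
    jsonlite::write_json(res$report, file.path(out, "enrichment.json"),
                         auto_unbox = TRUE, digits = NA)
    outputs <- c(outputs, f1, file.path(out, "enrichment.json"))
    message("[enrichment] ", length(res$cls$up), " up / ",
            length(res$cls$down), " down of ", length(res$cls$universe),
            " tested genes")
  }

  manifest <- list(
    tool = "mirderep",
    version = as.character(utils::packageVersion("mirderep")),
    # hash identifies the analysis configuration, not the output location
    config_hash = hash_object(config[setdiff(names(config), "out")]),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    decisions = list(
      score_boundary = "inclusive (score <= threshold)",
      isoform_tie_break = "smaller start, then larger end",
      filter_precedence = "qc_fail > no_adapter > too_short > ambiguous",
      coordinates = "0-based half-open"
    ),
    inputs = file_checksums(inputs),
    outputs = file_checksums(outputs)
  )
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# MD5 of the canonical JSON serialization of an R object.
hash_object <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

file_checksums <- function(paths) {
  if (length(paths) == 0L) return(list())
  sums <- tools::md5sum(paths)
  as.list(stats::setNames(unname(sums), basename(paths)))
}

#' Generate the full synthetic demo bundle
#'
#' One command produces every input the pipeline consumes, mimicking the
#' study design: a wild-type small-RNA library in which the focal miRNA
#' (named `syn-mir-150`) makes up 70% of miRNA-matching reads, a knockout
#' library with that miRNA deleted and the remaining composition jittered,
#' paired WT/KO expression with score-proportional derepression of the
#' focal miRNA's predicted targets, a differential-expression table, and
#' planted naive/effector/memory-like signatures oriented so upregulated
#' genes enrich the naive/memory-like sets and downregulated genes the
#' effector-like set. Ground-truth records are written as JSON.
#'
#' Direct targets only rise when the miRNA is deleted; the downregulated
#' arm of a knockout transcriptome is an indirect, downstream effect. The
#' demo therefore adds an indirect-repression layer on top of
#' [gen_expression()]: `n_indirect_down` non-target genes have their KO
#' replicates scaled down by log2 effects drawn uniformly from
#' `indirect_lfc_range`, recorded in the truth bundle.
#'
#' @param seed Integer seed; all stage seeds derive from it.
#' @param dir Output directory for the bundle.
#' @param n_reads Reads per small-RNA library (default 50000).
#' @param expr_cfg Optional [expr_sim_config()] override (its seed is
#'   replaced by one derived from `seed`).
#' @param n_indirect_down Number of non-target genes repressed in the KO
#'   (default 400).
#' @param indirect_lfc_range Log2 effect-size range for indirect repression
#'   (default 0.8 to 1.6).
#' @return List of file paths plus the truth records, invisibly.
#' @export
make_demo <- function(seed, dir, n_reads = 50000L, expr_cfg = NULL,
                      n_indirect_down = 400L,
                      indirect_lfc_range = c(0.8, 1.6)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hairpins <- gen_hairpins(10L, 80L, seed = derive_seed(seed, "hairpins"))
  names(hairpins) <- c("syn-mir-150", paste0("syn-mir-", 1:9))
  fa <- write_hairpin_fasta(hairpins, file.path(dir, "hairpins.fa"))

  comp_wt <- c(`syn-mir-150` = 0.70, 0.08, 0.06, 0.05, 0.04, 0.03,
               0.015, 0.012, 0.008, 0.005)
  names(comp_wt)[-1] <- paste0("syn-mir-", 1:9)
  cfg_wt <- read_sim_config(
    n_reads = n_reads, composition = comp_wt,
    n_qc_fail = round(0.05 * n_reads), n_no_adapter = round(0.03 * n_reads),
    n_short_insert = round(0.04 * n_reads), n_ambiguous = round(0.02 * n_reads),
    seed = derive_seed(seed, "reads"))
  sim_wt <- gen_smallrna_fastq(cfg_wt, hairpins)
  fq_wt <- write_fastq_reads(sim_wt$reads, file.path(dir, "wt_smallrna.fastq"))

  # knockout library: focal miRNA deleted, other fractions jittered on the
  # log scale so the between-sample concordance is strong but not perfect
  jitter <- with_seed(derive_seed(seed, "reads") + 1L,
                      stats::rnorm(9, 0, 0.6))
  comp_ko <- comp_wt[-1] * 2^jitter
  comp_ko <- comp_ko / sum(comp_ko)
  cfg_ko <- read_sim_config(
    n_reads = n_reads, composition = comp_ko,
    n_qc_fail = round(0.05 * n_reads), n_no_adapter = round(0.03 * n_reads),
    n_short_insert = round(0.04 * n_reads), n_ambiguous = round(0.02 * n_reads),
    seed = derive_seed(seed, "reads") + 2L)
  sim_ko <- gen_smallrna_fastq(cfg_ko, hairpins)
  fq_ko <- write_fastq_reads(sim_ko$reads, file.path(dir, "ko_smallrna.fastq"))

  if (is.null(expr_cfg)) expr_cfg <- expr_sim_config()
  expr_cfg$seed <- derive_seed(seed, "expression")
  sim_expr <- gen_expression(expr_cfg)

  # indirect-repression layer: scale down KO replicates of non-target genes
  indirect <- with_seed(derive_seed(seed, "expression") + 1L, {
    pool <- sim_expr$expression$gene[!sim_expr$truth$is_target]
    genes <- sample(pool, min(n_indirect_down, length(pool)))
    data.frame(gene = genes,
               lfc = -stats::runif(length(genes), indirect_lfc_range[1],
                                   indirect_lfc_range[2]),
               stringsAsFactors = FALSE)
  })
  ko_cols <- sim_expr$ko_samples
  ix <- match(indirect$gene, sim_expr$expression$gene)
  sim_expr$expression[ix, ko_cols] <-
    sim_expr$expression[ix, ko_cols] * 2^indirect$lfc

  f_expr <- write_tsv(sim_expr$expression, file.path(dir, "expression.tsv"))
  f_scores <- write_tsv(sim_expr$scores, file.path(dir, "target_scores.tsv"))
  de <- gen_de_table(sim_expr$expression)
  f_de <- write_tsv(de, file.path(dir, "de_table.tsv"))

  cls <- classify_de(de)
  sigs <- gen_signatures(sim_expr$expression$gene, planted_enrichment = 3,
                         seed = derive_seed(seed, "signatures"),
                         de_up = cls$up, de_down = cls$down)
  f_gmt <- write_gmt(sigs, file.path(dir, "signatures.gmt"))

  truth <- list(
    smallrna_wt = sim_wt$truth, smallrna_ko = sim_ko$truth,
    composition_wt = as.list(comp_wt), composition_ko = as.list(comp_ko),
    beta = expr_cfg$beta, mirna = expr_cfg$mirna,
    n_targets = sum(sim_expr$truth$is_target),
    indirect_down = indirect)
  f_truth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, f_truth, auto_unbox = TRUE, digits = NA)

  invisible(list(hairpins = fa, wt_fastq = fq_wt, ko_fastq = fq_ko,
                 expression = f_expr, scores = f_scores, de = f_de,
                 signatures = f_gmt, truth_file = f_truth, truth = truth,
                 expr_truth = sim_expr$truth, mirna = expr_cfg$mirna))
}
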
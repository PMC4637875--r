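#' Read small RNA-seq reads from a FASTQ file
#'
#' Parses a FASTQ file (plain or gzipped) into a data frame of reads. The
#' Illumina chastity/QC flag is taken from the CASAVA-style header comment
#' (`<id> <read>:<Y|N>:<control>:<index>`): a read is flagged as failing
#' quality control when the second colon-separated field of the comment is
#' `Y`. Reads without a recognizable comment are treated as passing.
#'
#' @param path Path to a FASTQ file.
#' @return A data frame with columns `id` (header up to the first space),
#'   `sequence`, `quality` and `qc_fail` (logical).
#' @export
read_fastq_reads <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  reads <- withCallingHandlers(
    tryCatch(
      Biostrings::readQualityScaledDNAStringSet(path),
      error = function(e) stop("malformed FASTQ in ", path, ": ",
                               conditionMessage(e), call. = FALSE)
    ),
    # Biostrings warns that FASTQ metadata columns are dropped; harmless here
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )
  headers <- names(reads)
  ids <- sub("\\s.*$", "", headers)
  comment <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  qc_fail <- grepl("^[0-9]+:Y:", comment)
  data.frame(
    id = ids,
    sequence = as.character(reads),
    quality = as.character(Biostrings::quality(reads)),
    qc_fail = qc_fail,
    stringsAsFactors = FALSE
  )
}

#' Write reads to a FASTQ file
#'
#' Inverse of [read_fastq_reads()]: the QC flag is encoded in the header
#' comment as `1:Y:0:NNNNNN` (fail) or `1:N:0:NNNNNN` (pass).
#'
#' @param reads Data frame with columns `id`, `sequence`, `quality`,
#'   `qc_fail`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq_reads <- function(reads, path) {
  stopifnot(all(c("id", "sequence", "quality", "qc_fail") %in% names(reads)))
  flag <- ifelse(reads$qc_fail, "Y", "N")
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- paste0(reads$id, " 1:", flag, ":0:NNNNNN")
  quals <- Biostrings::BStringSet(reads$quality)
  Biostrings::writeXStringSet(seqs, path, format = "fastq", qualities = quals)
  invisible(path)
}

#' Read hairpin reference sequences from FASTA
#'
#' @param path Path to a FASTA file of hairpin precursor sequences.
#' @return A named character vector of uppercase sequences.
#' @export
read_hairpin_fasta <- function(path) {
  if (!file.exists(path)) stop("hairpin FASTA not found: ", path)
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(out))) stop("duplicate hairpin names in ", path)
  out
}

#' Write hairpin sequences to FASTA
#'
#' @param hairpins Named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hairpin_fasta <- function(hairpins, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(hairpins), path)
  invisible(path)
}

#' Read gene signatures from a GMT file
#'
#' GMT records are tab-separated: set name, description, then member genes.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors of gene identifiers.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  sigs <- fgsea::gmtPathways(path)
  lapply(sigs, unique)
}

#' Write gene signatures to a GMT file
#'
#' @param signatures Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(signatures, path) {
  stopifnot(is.list(signatures), length(names(signatures)) == length(signatures))
  lines <- vapply(names(signatures), function(nm) {
    paste(c(nm, "synthetic", signatures[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-by-sample expression table
#'
#' @param path TSV with a `gene` column and one numeric column per sample.
#' @return A data frame with rownames set to the gene column.
#' @export
read_expression_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"gene" %in% names(tab)) stop("expression table must have a 'gene' column")
  if (anyDuplicated(tab$gene)) stop("duplicate gene identifiers in ", path)
  tab
}

#' Write a table as TSV
#'
#' @param tab Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic per-stage seed derivation from a single top-level seed.
# Offsets keep derived seeds distinct across stages while staying within
# 32-bit integer range.
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  offsets <- c(hairpins = 101L, reads = 211L, expression = 307L,
               de = 401L, signatures = 503L, demo = 601L)
  if (!stage %in% names(offsets)) stop("unknown seed stage: ", stage)
  as.integer((as.integer(seed) + offsets[[stage]] * 9973L) %% .Machine$integer.max)
}

# Evaluate an expression under a seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
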
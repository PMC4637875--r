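#' Trim the 3' adapter from a read sequence
#'
#' Returns the insert preceding the leftmost exact occurrence of the adapter,
#' or `NA` when the adapter is absent. The empty string is a valid return
#' (adapter at position 1); such inserts are removed later by the length
#' filter.
#'
#' @param sequence Read sequence (character vector; vectorized).
#' @param adapter Non-empty adapter sequence, matched exactly.
#' @return Character vector of inserts, `NA` where no adapter was found.
#' @examples
#' trim_adapter("ACGTACGTACGTACGTTGGAATCCCC", "TGGAAT")
#' @export
trim_adapter <- function(sequence, adapter) {
  if (length(adapter) != 1L || is.na(adapter) || nchar(adapter) == 0L)
    stop("adapter must be a single non-empty sequence")
  pos <- regexpr(adapter, sequence, fixed = TRUE)
  ifelse(pos > 0L, substr(sequence, 1L, pos - 1L), NA_character_)
}

#' Filter small RNA reads and trim adapters
#'
#' Applies the four sequential read filters used for small RNA libraries,
#' assigning each read exactly one outcome by fixed precedence:
#' failed Illumina QC (chastity flag `Y`), then adapter absent, then trimmed
#' insert too short (< `min_len` nt), then ambiguous base (`N`) in the
#' trimmed insert, else pass.
#'
#' @param reads Data frame with columns `id`, `sequence`, `qc_fail`
#'   (as from [read_fastq_reads()]), or a path to a FASTQ file.
#' @param adapter 3' adapter sequence (default `TGGAAT`).
#' @param min_len Minimum insert length after trimming (default 15 nt).
#' @return A list with `inserts` (data frame `id`, `insert` for passing
#'   reads) and `report`, a `filter_report` whose counts always satisfy
#'   `n_input = n_qc_fail + n_no_adapter + n_too_short + n_ambiguous +
#'   n_pass`.
#' @export
filter_reads <- function(reads, adapter = "TGGAAT", min_len = 15L) {
  if (is.character(reads) && length(reads) == 1L)
    reads <- read_fastq_reads(reads)
  stopifnot(all(c("id", "sequence", "qc_fail") %in% names(reads)))
  if (min_len < 1L) stop("min_len must be at least 1")
  n <- nrow(reads)
  insert <- trim_adapter(reads$sequence, adapter)
  outcome <- rep("pass", n)
  outcome[!is.na(insert) & grepl("N", insert, fixed = TRUE)] <- "ambiguous"
  outcome[!is.na(insert) & nchar(insert) < min_len] <- "too_short"
  outcome[is.na(insert)] <- "no_adapter"
  outcome[reads$qc_fail] <- "qc_fail"
  report <- structure(
    list(n_input = n,
         n_qc_fail = sum(outcome == "qc_fail"),
         n_no_adapter = sum(outcome == "no_adapter"),
         n_too_short = sum(outcome == "too_short"),
         n_ambiguous = sum(outcome == "ambiguous"),
         n_pass = sum(outcome == "pass")),
    class = "filter_report"
  )
  keep <- outcome == "pass"
  list(
    inserts = data.frame(id = reads$id[keep], insert = insert[keep],
                         stringsAsFactors = FALSE),
    report = report
  )
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0("Read filter report: %d input | %d QC-fail | ",
                     "%d no-adapter | %d too-short | %d ambiguous | %d pass\n"),
              x$n_input, x$n_qc_fail, x$n_no_adapter, x$n_too_short,
              x$n_ambiguous, x$n_pass))
  invisible(x)
}

#' @export
as.data.frame.filter_report <- function(x, ...) {
  data.frame(metric = names(unclass(x)), count = unlist(unclass(x)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Assign trimmed inserts to hairpin reference sequences
#'
#' An insert matches a hairpin when it occurs as an exact substring
#' (optionally allowing up to one mismatch via a naive scan). Inserts
#' matching exactly one hairpin are assigned to it with the leftmost match
#' offset; inserts matching multiple hairpins are flagged
#' ambiguous-mapping and excluded from profiles; unmatched inserts remain
#' unassigned. Coordinates are 0-based, half-open.
#'
#' @param inserts Data frame with columns `id`, `insert` (from
#'   [filter_reads()]), or a character vector of insert sequences.
#' @param hairpins Named character vector of hairpin sequences.
#' @param max_mismatch 0 (default) or 1 allowed mismatches.
#' @return Data frame with columns `id`, `insert`, `status`
#'   (`"assigned"`, `"multi"`, `"unmatched"`), `hairpin`, `start`, `end`
#'   (NA unless assigned).
#' @export
match_to_hairpins <- function(inserts, hairpins, max_mismatch = 0L) {
  if (length(hairpins) == 0L) stop("hairpin reference set is empty")
  if (is.character(inserts))
    inserts <- data.frame(id = sprintf("insert%06d", seq_along(inserts)),
                          insert = inserts, stringsAsFactors = FALSE)
  if (!max_mismatch %in% c(0L, 1L))
    stop("max_mismatch must be 0 or 1")
  uniq <- unique(inserts$insert)
  hp_names <- names(hairpins)

  locate <- function(ins) {
    hits_hp <- character(0); hits_start <- integer(0)
    for (h in hp_names) {
      if (max_mismatch == 0L) {
        pos <- regexpr(ins, hairpins[[h]], fixed = TRUE)
        if (pos > 0L) {
          hits_hp <- c(hits_hp, h)
          hits_start <- c(hits_start, as.integer(pos) - 1L)
        }
      } else {
        m <- Biostrings::matchPattern(ins, hairpins[[h]],
                                      max.mismatch = max_mismatch)
        if (length(m) > 0L) {
          hits_hp <- c(hits_hp, h)
          hits_start <- c(hits_start, Biostrings::start(m)[1L] - 1L)
        }
      }
    }
    if (length(hits_hp) == 0L) return(list(status = "unmatched",
                                           hairpin = NA_character_,
                                           start = NA_integer_))
    if (length(hits_hp) > 1L) return(list(status = "multi",
                                          hairpin = NA_character_,
                                          start = NA_integer_))
    list(status = "assigned", hairpin = hits_hp, start = hits_start)
  }

  res <- lapply(uniq, locate)
  lut_status <- vapply(res, `[[`, "", "status")
  lut_hp <- vapply(res, `[[`, "", "hairpin")
  lut_start <- vapply(res, `[[`, 0L, "start")
  ix <- match(inserts$insert, uniq)
  out <- data.frame(
    id = inserts$id,
    insert = inserts$insert,
    status = lut_status[ix],
    hairpin = lut_hp[ix],
    start = lut_start[ix],
    stringsAsFactors = FALSE
  )
  out$end <- out$start + nchar(out$insert)
  out
}

#' Dominant-isoform miRNA profile from hairpin assignments
#'
#' Within each hairpin, reads are grouped into isoforms by their
#' `(start, end)` footprint; the dominant isoform is the one with the most
#' reads, ties broken by smaller start then larger end. Composition
#' fractions are each hairpin's dominant-isoform count over the sum of
#' dominant-isoform counts across all hairpins.
#'
#' @param assignments Data frame from [match_to_hairpins()].
#' @return An object of class `mirna_profile`: list with `table` (data
#'   frame: mirna, dominant_start, dominant_end, dominant_count,
#'   total_count, fraction), `n_assigned`, `n_multi`, `n_unmatched`.
#' @export
dominant_isoform_counts <- function(assignments) {
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  n_multi <- sum(assignments$status == "multi")
  n_unmatched <- sum(assignments$status == "unmatched")
  if (nrow(asg) == 0L) {
    tab <- data.frame(mirna = character(0), dominant_start = integer(0),
                      dominant_end = integer(0), dominant_count = integer(0),
                      total_count = integer(0), fraction = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    key <- paste(asg$hairpin, asg$start, asg$end, sep = "\r")
    iso <- as.data.frame(table(key), stringsAsFactors = FALSE)
    parts <- strsplit(iso$key, "\r", fixed = TRUE)
    iso$hairpin <- vapply(parts, `[[`, "", 1L)
    iso$start <- as.integer(vapply(parts, `[[`, "", 2L))
    iso$end <- as.integer(vapply(parts, `[[`, "", 3L))
    # dominant per hairpin: most reads, then smaller start, then larger end
    ord <- order(iso$hairpin, -iso$Freq, iso$start, -iso$end)
    iso <- iso[ord, , drop = FALSE]
    dom <- iso[!duplicated(iso$hairpin), , drop = FALSE]
    totals <- tapply(iso$Freq, iso$hairpin, sum)
    tab <- data.frame(
      mirna = dom$hairpin,
      dominant_start = dom$start,
      dominant_end = dom$end,
      dominant_count = dom$Freq,
      total_count = as.integer(totals[dom$hairpin]),
      stringsAsFactors = FALSE
    )
    tab <- tab[order(-tab$dominant_count, tab$mirna), , drop = FALSE]
    tab$fraction <- tab$dominant_count / sum(tab$dominant_count)
    rownames(tab) <- NULL
  }
  structure(
    list(table = tab, n_assigned = nrow(asg), n_multi = n_multi,
         n_unmatched = n_unmatched),
    class = "mirna_profile"
  )
}

#' @export
print.mirna_profile <- function(x, ...) {
  cat(sprintf("miRNA profile: %d hairpins, %d assigned reads (%d multi-mapping, %d unmatched)\n",
              nrow(x$table), x$n_assigned, x$n_multi, x$n_unmatched))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Ranked miRNA composition table
#'
#' The most abundant miRNAs by dominant-isoform fraction: up to `top_n`
#' entries each comprising at least `min_fraction` of the miRNA-matching
#' reads, with the remainder aggregated as `"other"`.
#'
#' @param profile A `mirna_profile`.
#' @param top_n Maximum number of named entries (default 10).
#' @param min_fraction Minimum fraction for a named entry (default 0.01).
#' @return Data frame with columns `mirna`, `dominant_count`, `fraction`,
#'   ordered by descending fraction.
#' @export
composition_table <- function(profile, top_n = 10L, min_fraction = 0.01) {
  stopifnot(inherits(profile, "mirna_profile"))
  tab <- profile$table
  if (nrow(tab) == 0L) {
    warning("empty miRNA profile; returning empty composition table")
    return(data.frame(mirna = character(0), dominant_count = integer(0),
                      fraction = numeric(0), stringsAsFactors = FALSE))
  }
  tab <- tab[order(-tab$fraction, tab$mirna), , drop = FALSE]
  named <- tab$fraction >= min_fraction & seq_len(nrow(tab)) <= top_n
  out <- data.frame(mirna = tab$mirna[named],
                    dominant_count = tab$dominant_count[named],
                    fraction = tab$fraction[named],
                    stringsAsFactors = FALSE)
  if (any(!named)) {
    out <- rbind(out, data.frame(
      mirna = "other",
      dominant_count = sum(tab$dominant_count[!named]),
      fraction = sum(tab$fraction[!named]), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Between-sample miRNA expression concordance
#'
#' Pearson correlation of `log2(dominant count + 1)` across the miRNAs
#' shared by two profiles, after removing an excluded set (typically the
#' knocked-out miRNA, whose deletion would otherwise dominate the
#' comparison).
#'
#' @param profile_a,profile_b `mirna_profile` objects.
#' @param exclude Character vector of miRNA names to drop (default none).
#' @return Pearson correlation over the shared miRNAs.
#' @export
mirna_concordance <- function(profile_a, profile_b, exclude = character(0)) {
  stopifnot(inherits(profile_a, "mirna_profile"),
            inherits(profile_b, "mirna_profile"))
  shared <- setdiff(intersect(profile_a$table$mirna, profile_b$table$mirna),
                    exclude)
  if (length(shared) < 3L)
    stop("need at least 3 shared miRNAs after exclusion; have ",
         length(shared))
  a <- log2(profile_a$table$dominant_count[match(shared, profile_a$table$mirna)] + 1)
  b <- log2(profile_b$table$dominant_count[match(shared, profile_b$table$mirna)] + 1)
  pearson_r(a, b)
}

#' One-call small RNA quantification
#'
#' Convenience wrapper chaining [filter_reads()], [match_to_hairpins()] and
#' [dominant_isoform_counts()].
#'
#' @param reads FASTQ path or read data frame.
#' @param hairpins FASTA path or named character vector.
#' @inheritParams filter_reads
#' @inheritParams match_to_hairpins
#' @return List with `report`, `profile` and `composition`.
#' @export
quantify_smallrna <- function(reads, hairpins, adapter = "TGGAAT",
                              min_len = 15L, max_mismatch = 0L) {
  if (is.character(hairpins) && length(hairpins) == 1L && file.exists(hairpins))
    hairpins <- read_hairpin_fasta(hairpins)
  filt <- filter_reads(reads, adapter = adapter, min_len = min_len)
  asg <- match_to_hairpins(filt$inserts, hairpins, max_mismatch = max_mismatch)
  profile <- dominant_isoform_counts(asg)
  list(report = filt$report, profile = profile,
       composition = composition_table(profile))
}
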
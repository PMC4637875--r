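test_that("adapter trimming keeps the prefix before the leftmost occurrence", {
  expect_equal(trim_adapter("ACGTACGTACGTACGTTGGAATCCCC", "TGGAAT"),
               "ACGTACGTACGTACGT")
  expect_true(is.na(trim_adapter("ACGTACGT", "TGGAAT")))
  expect_equal(trim_adapter("TGGAATAAAA", "TGGAAT"), "")
  # leftmost rule with two occurrences
  expect_equal(trim_adapter("AATGGAATCCTGGAAT", "TGGAAT"), "AA")
  expect_error(trim_adapter("ACGT", ""), "non-empty")
})

test_that("read filtering applies the fixed precedence and conserves counts", {
  mk <- function(seq, qc = FALSE) data.frame(
    id = "r", sequence = seq, quality = strrep("I", nchar(seq)),
    qc_fail = qc, stringsAsFactors = FALSE)
  good16 <- "ACGTACGTACGTACGT"

  # QC failure wins even with a valid adapter and insert
  r <- filter_reads(mk(paste0(good16, "TGGAAT"), qc = TRUE))$report
  expect_equal(r$n_qc_fail, 1L)
  expect_equal(r$n_no_adapter + r$n_too_short + r$n_ambiguous + r$n_pass, 0L)
  # 14-nt insert is too short at the 15-nt floor
  r <- filter_reads(mk(paste0(substr(good16, 1, 14), "TGGAATCC")))$report
  expect_equal(r$n_too_short, 1L)
  # 16-nt insert with one N is ambiguous (length passes first)
  r <- filter_reads(mk(paste0("ACGTNACGTACGTACG", "TGGAAT")))$report
  expect_equal(r$n_ambiguous, 1L)
  # short beats ambiguous when both would apply
  r <- filter_reads(mk(paste0("ACGTNACGT", "TGGAATAA")))$report
  expect_equal(r$n_too_short, 1L)
  expect_equal(r$n_ambiguous, 0L)
  # no adapter anywhere
  r <- filter_reads(mk(strrep("AC", 25)))$report
  expect_equal(r$n_no_adapter, 1L)
  # passing read yields its insert
  out <- filter_reads(mk(paste0(good16, "TGGAATGG")))
  expect_equal(out$inserts$insert, good16)
  expect_equal(out$report$n_pass, 1L)
})

test_that("filter report conservation holds on fuzzed read sets", {
  set.seed(71)
  for (i in 1:25) {
    n <- sample(1:80, 1)
    seqs <- vapply(seq_len(n), function(j) {
      core <- paste(sample(c("A", "C", "G", "T", "N"),
                           sample(5:40, 1), replace = TRUE), collapse = "")
      if (runif(1) < 0.7) core <- paste0(core, "TGGAAT", core)
      core
    }, "")
    reads <- data.frame(id = sprintf("r%d", 1:n), sequence = seqs,
                        quality = strrep("I", nchar(seqs)),
                        qc_fail = runif(n) < 0.2, stringsAsFactors = FALSE)
    rep <- filter_reads(reads)$report
    expect_equal(rep$n_input,
                 rep$n_qc_fail + rep$n_no_adapter + rep$n_too_short +
                   rep$n_ambiguous + rep$n_pass)
  }
})

test_that("hairpin matching assigns unique exact matches with 0-based coordinates", {
  hp <- c(hpA = paste0(strrep("A", 10), "CGTACGTACGTACGTACGTACG", strrep("T", 10)),
          hpB = paste0(strrep("G", 10), "TTTCCCTTTCCCTTTCCCTTTC", strrep("A", 10)))
  ins <- substr(hp[["hpA"]], 11, 32)   # hairpin[10:32] 0-based half-open
  asg <- match_to_hairpins(ins, hp)
  expect_equal(asg$status, "assigned")
  expect_equal(asg$hairpin, "hpA")
  expect_equal(asg$start, 10L)
  expect_equal(asg$end, 32L)
  # an insert present in both hairpins is multi-mapping
  hp2 <- c(hp, hpC = hp[["hpA"]])
  asg2 <- match_to_hairpins(ins, hp2)
  expect_equal(asg2$status, "multi")
  # no match
  asg3 <- match_to_hairpins("TGCATGCATGCATGCA", hp)
  expect_equal(asg3$status, "unmatched")
  expect_error(match_to_hairpins(ins, character(0)), "empty")
  # one mismatch allowed only when requested
  ins_mm <- ins
  substr(ins_mm, 5, 5) <- if (substr(ins_mm, 5, 5) == "A") "C" else "A"
  expect_equal(match_to_hairpins(ins_mm, hp)$status, "unmatched")
  expect_equal(match_to_hairpins(ins_mm, hp, max_mismatch = 1)$status,
               "assigned")
})

test_that("dominant isoform selection uses count then the stated tie-break", {
  mk_asg <- function(starts, ends, hp = "hpA") data.frame(
    id = sprintf("r%d", seq_along(starts)), insert = "x", status = "assigned",
    hairpin = hp, start = starts, end = ends, stringsAsFactors = FALSE)

  # counts {(10,32): 50, (11,32): 30} -> dominant (10,32)
  p <- dominant_isoform_counts(mk_asg(c(rep(10L, 50), rep(11L, 30)),
                                      c(rep(32L, 50), rep(32L, 30))))
  expect_equal(p$table$dominant_start, 10L)
  expect_equal(p$table$dominant_count, 50L)
  expect_equal(p$table$total_count, 80L)

  # tie {(10,32): 40, (11,33): 40} -> smaller start wins
  p <- dominant_isoform_counts(mk_asg(c(rep(10L, 40), rep(11L, 40)),
                                      c(rep(32L, 40), rep(33L, 40))))
  expect_equal(p$table$dominant_start, 10L)
  expect_equal(p$table$dominant_end, 32L)

  # tie at equal start -> larger end wins
  p <- dominant_isoform_counts(mk_asg(c(rep(10L, 7), rep(10L, 7)),
                                      c(rep(30L, 7), rep(34L, 7))))
  expect_equal(p$table$dominant_end, 34L)

  # a single read is its own dominant isoform
  p <- dominant_isoform_counts(mk_asg(12L, 34L))
  expect_equal(p$table$dominant_count, 1L)
})

test_that("composition table ranks, thresholds and aggregates correctly", {
  p <- profile_from_counts(c(A = 700, B = 200, C = 100))
  comp <- composition_table(p)
  expect_equal(comp$fraction, c(0.70, 0.20, 0.10))
  expect_equal(comp$mirna, c("A", "B", "C"))
  expect_equal(sum(comp$fraction), 1)

  # 12 miRNAs, two below 1%: 10 named rows plus "other"
  counts <- c(setNames(seq(200, 1100, by = 100), paste0("m", 1:10)),
              m11 = 3, m12 = 2)
  comp <- composition_table(profile_from_counts(counts))
  expect_equal(nrow(comp), 11L)
  expect_equal(comp$mirna[11], "other")
  expect_equal(comp$dominant_count[11], 5)

  # invariant to read order
  asg <- data.frame(id = sprintf("r%d", 1:60), insert = "x",
                    status = "assigned",
                    hairpin = rep(c("A", "B", "C"), c(30, 20, 10)),
                    start = 10L, end = 32L, stringsAsFactors = FALSE)
  set.seed(81)
  for (i in 1:5) {
    perm <- asg[sample(nrow(asg)), ]
    expect_equal(composition_table(dominant_isoform_counts(perm)),
                 composition_table(dominant_isoform_counts(asg)))
  }
  expect_warning(ct <- composition_table(dominant_isoform_counts(asg[0, ])),
                 "empty")
  expect_equal(nrow(ct), 0L)
})

test_that("quantifier recovers planted counts exactly on error-free reads", {
  hp <- gen_hairpins(6, 80, seed = 14)
  comp <- setNames(c(0.4, 0.25, 0.15, 0.1, 0.06, 0.04), names(hp))
  cfg <- read_sim_config(n_reads = 4000, composition = comp,
                         n_qc_fail = 100, n_no_adapter = 60,
                         n_short_insert = 80, n_ambiguous = 40,
                         seq_error_rate = 0, seed = 15)
  sim <- gen_smallrna_fastq(cfg, hp)
  q <- quantify_smallrna(sim$reads, hp)
  expect_equal(q$report$n_qc_fail, 100L)
  expect_equal(q$report$n_no_adapter, 60L)
  expect_equal(q$report$n_too_short, 80L)
  expect_equal(q$report$n_ambiguous, 40L)
  expect_equal(q$report$n_pass, sim$truth$n_clean)
  got <- setNames(q$profile$table$dominant_count, q$profile$table$mirna)
  expect_equal(got[names(sim$truth$clean_counts)], sim$truth$clean_counts)
})

test_that("isomiR variants split into isoforms but the canonical one dominates", {
  hp <- gen_hairpins(3, 80, seed = 16)
  cfg <- read_sim_config(n_reads = 3000,
                         composition = setNames(rep(1 / 3, 3), names(hp)),
                         isomir_frac = 0.25, seed = 17)
  sim <- gen_smallrna_fastq(cfg, hp)
  q <- quantify_smallrna(sim$reads, hp)
  got <- setNames(q$profile$table$dominant_count, q$profile$table$mirna)
  expect_equal(got[names(sim$truth$canonical_counts)],
               sim$truth$canonical_counts)
  expect_true(all(q$profile$table$total_count >=
                    q$profile$table$dominant_count))
  expect_equal(q$profile$table$dominant_start,
               rep(sim$truth$mature_start, 3))
})

test_that("miRNA concordance matches the correlation formula and guards", {
  pa <- profile_from_counts(c(A = 100, B = 200, C = 400, D = 800, KO = 5000))
  pb <- profile_from_counts(c(A = 110, B = 190, C = 420, D = 760, KO = 2))
  r <- mirna_concordance(pa, pb, exclude = "KO")
  manual <- cor(log2(c(100, 200, 400, 800) + 1),
                log2(c(110, 190, 420, 760) + 1))
  expect_equal(r, manual)
  expect_equal(mirna_concordance(pa, pa, exclude = "KO"), 1)
  expect_error(mirna_concordance(pa, profile_from_counts(c(A = 1, B = 2)),
                                 exclude = character(0)),
               "at least 3")
})
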
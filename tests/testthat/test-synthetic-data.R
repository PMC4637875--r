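test_that("hairpin generation is deterministic, distinct and validated", {
  h1 <- gen_hairpins(3, 60, seed = 7)
  h2 <- gen_hairpins(3, 60, seed = 7)
  expect_identical(h1, h2)
  expect_equal(length(h1), 3L)
  expect_true(all(nchar(h1) == 60))
  expect_equal(length(gen_hairpins(1, 40, seed = 0)), 1L)
  h <- gen_hairpins(50, 80, seed = 1)
  # pairwise distinct: every pair differs in at least one position
  expect_equal(anyDuplicated(h), 0L)
  expect_false(any(grepl("TGGAAT", h, fixed = TRUE)))
  expect_error(gen_hairpins(0, 60, seed = 1), "n >= 1")
  expect_error(gen_hairpins(3, 30, seed = 1), "length >= 40")
})

test_that("read simulator plants exact per-reason failure counts", {
  hp <- gen_hairpins(4, 80, seed = 2)
  cfg <- read_sim_config(
    n_reads = 1000, composition = setNames(rep(0.25, 4), names(hp)),
    n_qc_fail = 50, n_no_adapter = 30, n_short_insert = 40, n_ambiguous = 20,
    seed = 3)
  sim <- gen_smallrna_fastq(cfg, hp)
  expect_equal(nrow(sim$reads), 1000L)
  expect_equal(sim$truth$n_clean, 860L)
  expect_equal(sum(sim$truth$clean_counts), 860L)
  # conservation by construction
  expect_equal(sim$truth$n_qc_fail + sim$truth$n_no_adapter +
                 sim$truth$n_short_insert + sim$truth$n_ambiguous +
                 sim$truth$n_clean, 1000L)
  expect_error(read_sim_config(n_reads = 100, n_qc_fail = 101),
               "exceed n_reads")
  expect_error(read_sim_config(composition = c(a = 0.5, b = 0.4)),
               "sum to 1")
})

test_that("clean-read composition follows the multinomial expectation", {
  hp <- gen_hairpins(2, 80, seed = 4)
  comp <- setNames(c(0.7, 0.3), names(hp))
  cfg <- read_sim_config(n_reads = 10000, composition = comp, seed = 5)
  sim <- gen_smallrna_fastq(cfg, hp)
  frac <- sim$truth$clean_counts / sim$truth$n_clean
  bound <- 3 * sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(frac[[1]] - 0.7), bound)
  expect_lt(abs(frac[[2]] - 0.3), bound)
})

test_that("error-free clean inserts are exact hairpin substrings", {
  hp <- gen_hairpins(3, 80, seed = 6)
  cfg <- read_sim_config(n_reads = 300,
                         composition = setNames(rep(1 / 3, 3), names(hp)),
                         seq_error_rate = 0, seed = 7)
  sim <- gen_smallrna_fastq(cfg, hp)
  filt <- filter_reads(sim$reads)
  expect_true(all(vapply(filt$inserts$insert, function(ins)
    any(vapply(hp, function(h) grepl(ins, h, fixed = TRUE), TRUE)), TRUE)))
})

test_that("FASTQ output is byte-identical across reruns with one seed", {
  hp <- gen_hairpins(2, 80, seed = 8)
  cfg <- read_sim_config(n_reads = 200,
                         composition = setNames(c(0.6, 0.4), names(hp)),
                         n_qc_fail = 10, seed = 9)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_fastq_reads(gen_smallrna_fastq(cfg, hp)$reads, f1)
  write_fastq_reads(gen_smallrna_fastq(cfg, hp)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  # round trip preserves sequences and QC flags
  back <- read_fastq_reads(f1)
  orig <- gen_smallrna_fastq(cfg, hp)$reads
  expect_equal(back$sequence, orig$sequence)
  expect_equal(back$qc_fail, orig$qc_fail)
})

test_that("expression simulator satisfies its truth identities", {
  cfg0 <- expr_sim_config(n_genes = 500, beta = 0, seed = 10)
  expect_true(all(gen_expression(cfg0)$truth$true_lfc == 0))

  cfg <- expr_sim_config(n_genes = 1000, frac_targets = 0.2, beta = 1.0,
                         seed = 11)
  sim <- gen_expression(cfg)
  expect_equal(sum(sim$truth$is_target), 200L)
  tgt <- sim$truth[sim$truth$is_target, ]
  expect_equal(tgt$true_lfc, abs(tgt$score))          # beta = 1: lfc = |score|
  expect_equal(mean(tgt$true_lfc), 1.0 * mean(abs(tgt$score)))
  expect_true(all(!sim$truth$is_target | sim$truth$score <= -0.1))
  # score table covers exactly the targets under the KO miRNA name
  ko_scored <- sim$scores$gene[sim$scores$mirna == cfg$mirna]
  expect_setequal(ko_scored, tgt$gene)
  # determinism
  expect_identical(sim$expression, gen_expression(cfg)$expression)
  expect_error(expr_sim_config(beta = -1), "non-negative")
  expect_error(expr_sim_config(n_replicates_per_arm = 1), "2 replicates")
})

test_that("DE fixture computes fold changes, t-tests and BH q-values", {
  expr <- data.frame(gene = c("g1", "g2"),
                     WT_1 = c(2, 5), WT_2 = c(4, 5), WT_3 = c(6, 5),
                     KO_1 = c(2, 5), KO_2 = c(4, 5), KO_3 = c(6, 5))
  de <- gen_de_table(expr, pseudocount = 0)
  expect_equal(de$log2fc, c(0, 0))
  expect_equal(de$p, c(1, 1))   # identical arms, zero-variance handled

  # Welch t and BH agree with the reference implementations per gene
  set.seed(12)
  expr2 <- data.frame(gene = sprintf("g%d", 1:20),
                      matrix(2^rnorm(20 * 8, 5, 1), 20, 8))
  names(expr2)[-1] <- c(paste0("WT_", 1:4), paste0("KO_", 1:4))
  de2 <- gen_de_table(expr2, pseudocount = 0.1)
  pref <- vapply(1:20, function(i) {
    t.test(log2(as.numeric(expr2[i, 6:9]) + 0.1),
           log2(as.numeric(expr2[i, 2:5]) + 0.1))$p.value
  }, 0)
  expect_equal(de2$p, pref, tolerance = 1e-10)
  expect_equal(de2$q, p.adjust(de2$p, "BH"))

  # a strongly planted gene is detected at FDR 5%
  cfg <- expr_sim_config(n_genes = 300, frac_targets = 1 / 300,
                         score_min = -0.5, score_max = -0.5 + 1e-9,
                         beta = 2, noise_sd = 0.1, seed = 13)
  sim <- gen_expression(cfg)
  de3 <- gen_de_table(sim$expression)
  planted <- sim$truth$gene[sim$truth$is_target]
  expect_lt(de3$q[de3$gene == planted], 0.05)

  expect_error(gen_de_table(expr[, 1:4]), "2 replicates")
})

test_that("signature planting hits the expected overlap", {
  genes <- sprintf("g%05d", 1:10000)
  de_up <- genes[1:300]
  # planted_enrichment = 3, |sig| = 200, |DE| = 300, N = 10000: E[k] = 18
  ks <- vapply(1:40, function(s) {
    sigs <- gen_signatures(genes, planted_enrichment = 3, seed = s,
                           de_up = de_up, sig_size = 200)
    length(intersect(sigs$naive_like, de_up))
  }, 0L)
  se <- sqrt(200 * 0.09 * 0.91 / 40)
  expect_lt(abs(mean(ks) - 18), 4 * se)
  # no planted structure: overlap within binomial sampling error of uniform
  k1 <- vapply(1:40, function(s) {
    sigs <- gen_signatures(genes, planted_enrichment = 1, seed = s,
                           de_up = de_up, sig_size = 200)
    length(intersect(sigs$naive_like, de_up))
  }, 0L)
  expect_lt(abs(mean(k1) - 6), 4 * sqrt(200 * 0.03 * 0.97 / 40))
  # empty DE set gives zero overlap; disjointness holds
  sigs <- gen_signatures(genes, planted_enrichment = 2, seed = 1,
                         de_up = character(0), de_down = character(0))
  expect_equal(length(intersect(sigs$naive_like, character(0))), 0L)
  expect_equal(anyDuplicated(unlist(sigs)), 0L)
  expect_error(gen_signatures(genes[1:100], 1, 1, sig_size = 40),
               "exceed")
})
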
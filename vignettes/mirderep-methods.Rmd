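---
title: "Methods: small RNA quantification and knockout derepression analysis"
author: "mirderep authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA quantification and knockout derepression analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirderep)
```

# The scientific setting

When a microRNA is deleted, the mRNAs it normally represses rise — they are
*derepressed*. In a knockout-versus-wild-type transcriptome comparison this
shows up as a rightward shift of the predicted targets' log2 fold-change
distribution relative to non-targets, and the shift should grow with the
predicted strength of targeting. mirderep implements the computational arc
of such a study in CD8+ T cells, where a single miRNA (miR-150) dominates
the small RNA pool:

1. **Small RNA quantification** — filter raw small RNA-seq reads, trim the
   3' adapter, match inserts to hairpin precursors, and count each
   hairpin's *dominant isoform*.
2. **Derepression analysis** — compare the knockout/wild-type fold-change
   CDFs of score-binned predicted targets against a background of other
   miRNAs' targets with two-sided Kolmogorov–Smirnov tests.
3. **Signature enrichment** — classify differentially expressed genes at
   5% FDR and test their overlap with naive/effector/memory cell-state
   signatures by one-sided Fisher exact tests.

Because raw sequencing data are not needed to exercise any of this logic,
the package ships a seeded synthetic-data generator whose ground truth is
known exactly; every quantitative guarantee in the test suite is phrased
against that truth.

# Read filtering and dominant-isoform counting

A read is assigned exactly one outcome by fixed precedence:

1. failed the Illumina chastity/QC flag (`Y` in the CASAVA header comment);
2. lacks the 3' adapter (`TGGAAT` by default, matched exactly);
3. trimmed insert shorter than 15 nt;
4. ambiguous base (`N`) in the trimmed insert;
5. pass.

The precedence follows the order in which the filters are conventionally
described and must be fixed for per-reason counts to be exact. The filter
report always conserves reads:
`n_input = n_qc_fail + n_no_adapter + n_too_short + n_ambiguous + n_pass`.

Adapter matching is exact and takes the *leftmost* occurrence; there is no
error tolerance, trading a little sensitivity for reproducibility. Inserts
are matched to hairpins as exact substrings (optionally one mismatch via a
naive scan). An insert matching several hairpins is excluded as
multi-mapping rather than fractionally assigned, keeping counts
deterministic; a genome pre-filter used by alignment-based pipelines is
unnecessary with direct hairpin matching and is not implemented.

Reads on one hairpin are grouped into isoforms (isomiRs) by their
`(start, end)` footprint in 0-based half-open coordinates. The dominant
isoform is the footprint with the most reads, ties broken by smaller start
then larger end — a fixed, arbitrary rule, needed only so ties cannot make
counts irreproducible. Keying isoforms by both ends (rather than the 5'
end alone) is an interpretation choice; it is the stricter of the two and
the tests exercise it directly. Composition fractions are dominant-isoform
counts over the sum of dominant-isoform counts; the composition table
keeps up to the 10 most abundant miRNAs with at least 1% each and
aggregates the rest as `"other"`.

Between-sample concordance is the Pearson correlation of
`log2(dominant count + 1)` over shared miRNAs, excluding the knocked-out
miRNA, whose absence in the knockout would otherwise dominate the
comparison.

```{r quant-example}
hp <- gen_hairpins(4, 80, seed = 7)
cfg <- read_sim_config(n_reads = 2000,
                       composition = setNames(c(0.7, 0.15, 0.1, 0.05), names(hp)),
                       n_qc_fail = 100, n_no_adapter = 60,
                       n_short_insert = 80, n_ambiguous = 40, seed = 8)
sim <- gen_smallrna_fastq(cfg, hp)
q <- quantify_smallrna(sim$reads, hp)
q$report
q$composition
```

# The statistical core

The package's statistics are implemented from first principles and
cross-checked in the test suite against independent oracles
(`stats::ks.test`'s exact distribution, `stats::phyper`, `stats::p.adjust`,
direct enumeration, and a 10^5-replicate permutation estimate).

**Two-sample KS.** The statistic is the maximum vertical ECDF distance
evaluated at every distinct pooled value, so ties are handled by
construction. The two-sided p-value is asymptotic,
$Q(\lambda) = 2\sum_{j\ge1}(-1)^{j-1}e^{-2j^2\lambda^2}$ with
$\lambda = (\sqrt{n_e} + 0.12 + 0.11/\sqrt{n_e})D$ and
$n_e = n_1 n_2/(n_1+n_2)$, or exact by full enumeration of all
$\binom{n_1+n_2}{n_1}$ label assignments. Auto mode switches to
enumeration when $n_1+n_2 \le 16$ ($\binom{16}{8} = 12{,}870$ assignments
is instantaneous; beyond that the asymptotic form is accurate). Under ties
the asymptotic p-value is approximate and conservative; the enumeration is
tie-aware because it permutes the actual pooled values. The result records
which method was used.

**One-sided Fisher exact test.** The hypergeometric upper tail
$p = \sum_{j=k}^{\min(K,n)} \binom{K}{j}\binom{N-K}{n-j}/\binom{N}{n}$
is computed in log space via log-gamma so genome-scale universes
($N \approx 20{,}000$) cannot overflow.

**Benjamini–Hochberg q-values** use the standard step-up rule with
clipping at 1; they support the synthetic DE fixture, whose significance
calls feed the enrichment stage.

# Target selection, binning and the derepression test

Predicted targets of the knockout miRNA are genes whose best (most
negative) context+ score is at or below a threshold, −0.2 by default. The
boundary is *inclusive* for both targets and background — descriptions of
this threshold are commonly ambiguous between strict and inclusive, and
one convention has to be fixed; inclusive is applied uniformly and flagged
in the pipeline metadata. The background set is every gene with a
qualifying score for any *other* conserved miRNA, minus genes that also
qualify for the knockout miRNA, so the two compared sets are disjoint.

Fold changes are `log2((mean_KO + eps)/(mean_WT + eps))` with a
pseudocount of 0.1 abundance units (bounding the fold change for dropout
genes; an epsilon-continuity test confirms the `eps -> 0` limit on
all-positive data). Genes below a pooled-mean abundance floor of 1 unit
are excluded — some "expressed" floor is required and the value is
explicit and configurable rather than inferred. Mean-based fold changes
(rather than model-based estimates) keep the analysis independent of any
particular DE engine.

Targets are partitioned by predicted strength into bins labelled
`(-0.2,-0.1]`, `(-0.3,-0.2]`, `(-Inf,-0.3]` in score notation. A gene
whose best score falls exactly on an interior edge is assigned to the
*weaker* bin (a score of exactly −0.3 sits in the middle bin; the
strongest bin holds strictly stronger scores), and the weakest bin is
closed at both ends so genes exactly at the selection threshold remain
covered. Each bin's fold-change distribution is compared with the
background by a two-sided KS test; the location effect is summarized as
the difference of medians, and a monotone flag records whether shifts are
non-decreasing with bin strength. The background is not down-sampled to
bin sizes — KS handles unequal samples and discarding information would
only lose power. Per-bin p-values are reported without multiple-testing
correction across the three bins, matching how such binned CDF analyses
are conventionally presented.

```{r derep-example}
cfg <- expr_sim_config(n_genes = 4000, seed = 11)
sim <- gen_expression(cfg)
lfc <- compute_log2fc(sim$expression)
bins <- bin_by_strength(select_targets(sim$scores, cfg$mirna, -0.1),
                        sim$scores, cfg$mirna)
derepression_analysis(lfc, bins, select_background(sim$scores, cfg$mirna))
```

# Differential expression and signature enrichment

Genes are split at `q <= 0.05` into up- (`log2fc > 0`) and downregulated
(`log2fc < 0`) sets; a gene at exactly zero fold change is unassigned. The
enrichment universe is the set of genes *tested* for differential
expression, not the whole genome — the standard choice, and configurable.
Signature genes absent from the universe are dropped before building the
2×2 table. Cells with `p < 10^-10` carry a star flag; that threshold is
display metadata, not a multiple-testing procedure, and no correction is
applied across the six cells.

# What the synthetic generator emulates — and what it does not

**Reads.** Clean reads are a fixed-coordinate mature insert (offset 10,
length 22, 0-based half-open, on an 80-nt hairpin) plus adapter plus
random filler, padded to 50 nt — typical dimensions for a small RNA
library. Hairpin references are random sequences scrubbed of the adapter
motif so trimming can never truncate inside a genuine insert. Failure
modes are planted disjointly, one reason per bad read, so the filter's
per-reason counts have exact truth; per-hairpin identities are multinomial
draws from the configured composition. An optional isomiR fraction plants
shifted footprints to exercise dominant-isoform selection; by default all
clean reads are canonical so dominant counts equal clean counts exactly.
Sequencing errors are uniform substitutions (never to `N`) applied to the
insert. Not emulated: quality-score profiles, adapter sequencing errors,
ligation biases, and genome-scale multi-mapping ambiguity — so passing
tests demonstrate the correctness of the counting logic, not robustness
to every artefact of real libraries.

**Expression.** Wild-type replicates are $2^{b_g + \epsilon}$ and
knockout replicates $2^{b_g + \beta|s_g| + \epsilon}$, with baseline
$b_g \sim N(6, 2^2)$ (log2 scale), replicate noise
$\epsilon \sim N(0, 0.25^2)$, and $s_g$ the target's context+ score drawn
uniformly on $[-0.6, -0.1]$; 20% of 10,000 genes are targets and a
disjoint 30% carry background-miRNA scores. Noise is log-normal because
it is the simplest model under which the log2 fold change of arm means is
unbiased for small noise; $\beta = 1$ makes the planted fold change equal
the score magnitude, giving the derepression dose–response a known slope.
These sizes (10,000 genes, 6 replicates per arm) are the package's
standard simulation conditions, used by the tests and the acceptance
script alike. Derepression of direct targets is the only planted *direct*
effect; the demo bundle additionally represses a random set of non-target
genes in the knockout arm (log2 effects uniform on 0.8–1.6) to emulate
the indirect, downstream repression that produces a downregulated DE set
in a real knockout. Count noise, library-size effects, and
correlation structure between genes are not modelled.

**Signatures.** Three pairwise-disjoint sets of 300 genes; planted
members are drawn from the designated DE set with probability
`planted_enrichment * |DE| / N`, so the expected overlap is exactly the
planted fold over uniform expectation.

# Numerical and design choices

- All coordinates are 0-based, half-open, stated once and used everywhere.
- All randomness flows from a single seed, split deterministically per
  stage; generators restore the caller's RNG state.
- Exact-KS auto cutoff at $n_1+n_2 \le 16$; hypergeometric terms in log
  space; BH computed by cumulative minimum over the ranked slope.
- The KS comparison `D >= D_obs` in enumeration uses a $10^{-12}$
  tolerance against float noise.
- Degenerate inputs fail loudly: empty samples, zero-variance
  correlations, empty background sets, unknown sample names, and
  malformed FASTQ records raise errors naming the offending stage.

# Problem sizes used by the tests

The unit and property tests run at small sizes (hundreds of reads,
1,500–4,000 genes); the deeper end-to-end checks use 50,000-read
libraries and 10,000-gene expression tables, with null-calibration runs
of 500 seeded replicates at 2,000 genes. These sizes give the multinomial
and Monte-Carlo bounds quoted in the tests comfortable margins while
keeping a full run quick on a laptop.

# Known limitations

- Quality-score-based trimming and adapter error tolerance are out of
  scope; reads with a mutated adapter count as adapter-less.
- The 1% composition threshold is applied per sample, and the dominant
  isoform is keyed by both ends; both are documented interpretations of
  conventions that are often left unstated.
- Asymptotic KS p-values under heavy ties are conservative; exact mode is
  only feasible for very small samples.
- Real cell-state signature lists are external inputs; the package only
  generates synthetic stand-ins with planted structure.
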
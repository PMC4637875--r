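# mirderep

Analysis toolkit for miRNA-knockout transcriptome studies, built around the
case of CD8+ T cells in which a single microRNA (miR-150) makes up the
majority of the small RNA pool. When that miRNA is deleted, its predicted
target mRNAs are *derepressed*: their knockout/wild-type fold-change
distribution shifts right, and the shift grows with predicted targeting
strength. `mirderep` implements the three computational stages of such a
study as a tested R package, with a seeded synthetic-data generator so the
whole pipeline is verifiable against exact ground truth without any
sequencing data.

**Who it is for:** computational biologists who want a transparent,
reproducible implementation of small RNA quantification and
target-derepression statistics — or a fully controlled synthetic testbed for validating
this class of analysis.

## The methods at the core

1. **Small RNA quantification.** Reads are filtered by fixed precedence —
   Illumina QC flag, missing 3' adapter (`TGGAAT`), trimmed insert `< 15`
   nt, ambiguous base — then matched exactly to hairpin references.
   Per hairpin, reads are grouped into isoforms by their `(start, end)`
   footprint and the *dominant isoform* is counted; composition fractions
   are dominant counts over their total.
2. **Derepression analysis.** Targets are genes with best context+ score
   `<= -0.2` for the knockout miRNA (background: targets of other conserved
   miRNAs, knockout targets removed). Per-gene fold change is
   `log2((mean_KO + eps)/(mean_WT + eps))`. Targets are binned by predicted
   strength — `(-0.2,-0.1]`, `(-0.3,-0.2]`, `(-Inf,-0.3]` — and each bin's
   fold-change CDF is compared with the background by a two-sided
   two-sample Kolmogorov–Smirnov test,

   D = max_t | F_bin(t) − F_background(t) |,

   with asymptotic p from the Kolmogorov series (effective size
   n_e = n1·n2/(n1+n2)) or exact p by full enumeration for small samples.
3. **Signature enrichment.** Genes significant at 5% FDR are split by
   fold-change sign and tested against naive/effector/memory cell-state
   signatures with the one-sided Fisher exact (hypergeometric upper-tail)
   test, computed in log space.

The KS test, Fisher tail, Pearson correlation and Benjamini–Hochberg
q-values are implemented from first principles and cross-checked in the
test suite against independent oracles (exact enumeration, `phyper`,
permutation estimates, `p.adjust`).

## Worked example

The `analysis/` directory holds numbered drivers that run the full study on
synthetic data. From the repository root:

```sh
Rscript analysis/01_simulate_inputs.R --seed 42   # build the input bundle
Rscript analysis/02_smallrna_quant.R              # filter + quantify miRNAs
Rscript analysis/03_derepression.R                # binned CDF/KS analysis
Rscript analysis/04_enrichment.R                  # DE sets vs signatures
```

With seed 42 this prints:

```
Read filter report: 50000 input | 2500 QC-fail | 1500 no-adapter | 2000 too-short | 1000 ambiguous | 43000 pass
syn-mir-150 comprises 70.2% of WT miRNA-matching reads
WT/KO concordance over the other 9 miRNAs: Pearson r = 0.924
[derepression] median shifts: 0.165, 0.256, 0.459 (monotone)
[enrichment] 451 up / 412 down of 10000 tested genes
Upregulated genes enrich: naive_like, memory_like
Downregulated genes enrich: effector_like
```

Reading the output: every planted filter failure is recovered exactly
(2500/1500/2000/1000), the focal miRNA's planted 70% share is recovered to
0.2 points, and the other miRNAs stay strongly correlated between WT and
knockout. The three median shifts are the per-bin derepression in log2
units — rising with predicted strength, as direct targeting predicts — and
the enrichment table shows knockout-upregulated genes aligning with
naive/memory programs while downregulated genes align with the effector
program.

Equivalent calls are available in R (`make_demo()`, `quantify_smallrna()`,
`derepression_analysis()`, `enrichment_report()`, or `run_pipeline()` with
a YAML config); see the methods vignette in `vignettes/` for the model,
parameter meanings, and design decisions.

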
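# restpoise

Tools to audit whether genes bound by the transcriptional repressor
REST are held transcriptionally poised independently of Polycomb
(H3K27me3). The package implements each step of that genome-wide
argument as a testable operation:

* **RE1 motif scanning** — PWM log2-odds scoring of full and half RE1
  sites on both strands with *exact* p-values (dynamic-programming
  score distributions), and region classification into same-strand
  multi-site, single full-site, half-site-only and motif-free classes.
* **Interval statistics** — reciprocal peak/domain overlap reports with
  configurable flanks, TSS assignment, bivalent promoter
  classification, consensus filtering. 0-based half-open coordinates
  throughout.
* **Domain calling and comparison** — sliding-window Poisson domain
  calling against a control with background-rate scaling, per-domain
  two-genotype enrichment comparison, gain/loss calling via a
  treatment/control swap, concordance statistics.
* **Expression integration** — CPM log2 fold changes, promoter
  chromatin-mark deltas, multiple regression of expression changes on
  mark changes, per-promoter-class de-repression tests.
* **Bench-assay statistics** — delta-delta Ct with SD propagation
  (SD = fold × ln2 × √(SD_ref² + SD_goi²)), ChIP-qPCR enrichment,
  Welch/pooled/paired t tests, pull-down replicate filtering.
* **A ground-truth simulator** — genomes with planted RE1 motifs
  (rejection-sampled so truth is exact), two-genotype ChIP tracks,
  negative-binomial expression counts tied to the H3K4me3 change, qPCR
  plates and peptide tables. Everything deterministic under one seed.

The methods vignette (`vignettes/rest-poising-audit.Rmd`) explains the
scientific background and every numerical design decision.

## Worked example

Simulate a full study and audit it end to end:

```r
library(restpoise)
cfg <- sim_config(seed = 1)
report <- run_audit(cfg)
print(report)
```

```
audit summary
=============
motif: 100.0% of 60 regions carry a full or half RE1 motif; class accuracy 0.867
overlap: REST vs H3K27me3 10.2%/19.2% at flank 0; 10.2%/19.2% at 1 kb
domains: 26 called; 76.9% stable; Pearson r = 0.274
promoter classes: BIVALENT=18 K27_ONLY=16 K4_ONLY=58 NEITHER=28
expression: H3K4me3 delta coefficient 0.924 (p = 0.00053), model R^2 = 0.400
assays: 10 proteins retained (sensitivity 1.00, 0 false positives)
```

The 76.9% stable domains are exactly the planted picture: 6 of the 26
H3K27me3 domains gain or lose in the knockout. The regression isolates
the H3K4me3 dependence of de-repression:

```r
report$expression$regression$coefficients[, c("term", "estimate", "p")]
```

```
         term estimate        p
1 (Intercept)   0.1971 0.603658
2    dH3K4me3   0.9245 0.000532
3     dH3K9ac   0.1715 0.547551
4    dH3K9me2  -0.0136 0.963615
5   dH3K27me3   0.0551 0.770481
```

The simulated truth is β = 1 on the K4 delta and no direct effect of
the other marks; the fitted coefficient covers it and the null marks
stay quiet. Setting `chip = list(rest_dependence_k27 = 0)` in
`sim_config()` produces the independence null, under which ≥95% of
domains are called stable with domain-level Pearson ≥ 0.8.

## Analysis workflow

Numbered drivers under `analysis/` run the same audit as separate
stages that communicate only through serialized files (FASTA, BED,
bedGraph, TSV) in `results/`:

```sh
Rscript analysis/01_simulate.R   --seed 1 --outdir results
Rscript analysis/02_scan_motifs.R         --outdir results
Rscript analysis/03_overlap.R             --outdir results
Rscript analysis/04_domains.R             --outdir results
Rscript analysis/05_expression.R          --outdir results
Rscript analysis/06_assays.R              --outdir results
```

Each stage can be re-run on its own from the previous stage's outputs
and writes a `summary.txt` plus TSV tables into its stage directory.

## Reproduction

The acceptance script reruns the headline quantities for any seed and
writes them as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
```

Reported quantities include the percentage of bound regions with an
RE1 motif, reciprocal REST/H3K27me3 overlap percentages at 0 and 1 kb
flanks, the stable-domain percentage and concordance under both the
default and the independence-null simulations, swap gain/loss
sensitivity and FDR against the planted truth, the K4 regression
coefficient with its CI, delta-delta Ct worked-example values and the
Welch type-I error rate.
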
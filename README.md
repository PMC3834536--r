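# rcclnc

Analysis stack for intronic antisense long noncoding RNA (lncRNA)
expression in clear cell renal cell carcinoma (ccRCC) microarray studies.
Intronic antisense lncRNAs are long noncoding transcripts mapping wholly
within an intron of a protein-coding gene, transcribed from the opposite
strand; this package implements the statistics used to call them
differentially expressed, survival-associated, co-expressed with mRNAs,
and enriched for regulatory genomic marks and evolutionary conservation.

## What it computes

* **Preprocessing** — per-array detection thresholds (mean + k·SD of
  negative-control probes; k = 3 for the paired design, k = 2 with a
  3-of-4 pool rule for the strand-specific design), a 90% prevalence
  filter in both sample groups, quantile normalization, paired
  log2(T/N) ratios.
* **Malignancy signature** — one-class SAM: d = r/(s + s0) with a
  permutation null from pair sign flips (1000 permutations), asymmetric
  threshold search at FDR <= 5%, a leave-one-out consensus (probes
  selected in 100% of the reduced datasets), and a 1.5-fold
  minimal-change rule.
* **Survival signature** — two-class unpaired SAM (FDR < 10%) intersected
  with the Golub signal-to-noise score P(g) = (mu1 - mu2)/(sigma1 +
  sigma2) at permutation p < 0.01; samples ordered by correlation to the
  dead-group mean profile.
* **Co-expression** — cis Spearman correlation between each lncRNA and
  its host-locus mRNA across tissues (|rho| > 0.5 strict, p < 0.05), trans
  correlation of the 20% most abundant lncRNAs against mRNAs of other loci
  (|rho| >= 0.7 inclusive), and a GO module map with Bonferroni-corrected
  hypergeometric enrichment signed by majority correlation direction.
* **Genomic context** — nearest-mark distances from lncRNA TSSs (CAGE-like
  tags filtered at RPKM >= 1, CpG-island-like, promoter, Pol II and
  histone marks) within 10 kb, binned at 1 kb, tested against ten
  length-matched random control sets by two-sample Kolmogorov-Smirnov.
* **Specificity & conservation** — the fraction-of-expression statistic
  (F.E.T. >= 0.5 flags tissue specificity) with a Fisher comparison
  against mRNA rates; conserved-element, cross-species and syntenic
  overlap enrichment with two-sided Fisher tests.
* **Concordance bookkeeping** — regulation-direction counts, host-gene
  concordance under a strict |FC| > 1.5 rule, per-study sign concordance
  and rounded-percentage reporting, exercised on the packaged
  worked-example tables (`inst/extdata/table1.tsv`, `table2.tsv`).

A seeded synthetic-data generator (`sim_config()`,
`simulate_rcc_dataset()`) produces every input with planted ground truth —
paired log-normal intensities, a toy genome with lncRNAs inside host
introns, mark tracks, FPKM tables, conservation tracks — so the whole
pipeline runs and is tested without any download.

## Worked example

```r
library(rcclnc)
res <- run_pipeline(pipeline_config(seed = 1))
print(res)
```

```
RCC intronic lncRNA pipeline run
  malignancy signature: 57 probes (sensitivity 0.88, FDP 0.00)
  survival signature: 22 genes (sensitivity 0.70)
  cis-correlated: 198 lncRNAs (33% of set, sensitivity 0.95)
  trans: 112 lncRNAs, mean 1.7 partners | module map: 15 enriched cells
  KS max p across tracks: 2.22e-16 | conservation max Fisher p: 1.49e-146
```

Reading: of 1000 simulated probes, the leave-one-out consensus recovered
88% of the planted 2-fold probes with no false discoveries (the strict
100%-presence rule trades a little sensitivity for zero false calls);
detection filtering before the survival screen removes some weakly
expressed planted probes, capping its sensitivity at 0.70; planted cis
pairs, TSS-proximal marks and conserved elements are all detected at
their stated cutoffs (every KS and Fisher comparison against the random
controls rejects decisively). The same run reproduces
the packaged-table bookkeeping exactly: 14 up / 26 down lncRNAs, and 13
altered host genes splitting 7 concordant / 6 inverse
(`res$summary$table1_n_up`, `res$summary$host_n_altered`, ...).

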
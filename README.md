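# chromEGA

Integrative analysis of chromatin accessibility (CA) and gene expression
(GE) across an ordered pre-implantation stage series — oocyte, sperm,
zygote, 2-cell, 4-cell, 8-cell, morula, ICM, TE, two biological replicates
per stage. The package is aimed at epigenomics analysts who have per-stage
peak calls, fragment intervals, count matrices and annotation tables and
want the full downstream integration as tested, reusable R functions:

* **Peak landscape** — replicate-consensus peaks (union-span of mutually
  overlapping replicate peaks; sex chromosomes excluded), a disjoint
  unified peak list with per-stage presence, fragment quantification
  (>= 1 bp overlap), TSS-distance location classes (< 1 kb promoter /
  1–5 kb intermediate / > 5 kb distal), stage-*gained* regions
  (first presence with absence at all earlier analyzed stages), TSS
  enrichment profiles, and a 2-Mb genome-window correlation of read
  density with gene count.
* **Normalization** — median-of-ratios size factors
  `sf_j = median_f ( c_fj / (∏_k c_fk)^{1/n} )` over features positive in
  every sample, values `log2(c/sf + 1)`; repeat families use
  `log2( c / (merged_kb · total_repeat_reads_M) + 1 )`.
* **Time-course fuzzy c-means** — Bezdek updates
  `u_ik ∝ (1/d_ik²)^{1/(m−1)}`, `v_k = Σ u^m x / Σ u^m`, defaults
  `c = 6`, `m = 1.25`, membership threshold 0.3, seeded
  permutation-invariant k-means++ starts with `nstart = 5` restarts,
  non-increasing objective trace `J_m = Σ u^m d²`.
* **EGA gene calling** — expressed (normalized value > 0) in at least one
  of 2-cell..morula AND strictly > 2-fold over oocyte (log2 difference
  > 1 on replicate-averaged values), plus peak→gene assignment over gene
  body ± 10 kb with promoter/distal decomposition per expression cluster.
* **ChIP-site integration** — sites overlapping the union of 2-/4-cell
  gained regions (`n_open / n_sites`), target genes within ± 10 kb, and
  the fraction of accessible repeat elements bound by a factor.
* **Repeat stage specificity** — per-family probabilities
  `p_s = mean_s / Σ mean`, Shannon entropy `H = −Σ p log2 p` (bits),
  per-stage `Q_s = H − log2 p_s`; most specific = lowest entropy,
  assigned stage = argmin `Q_s`.
* **Synthetic data** — a deterministic generator that emulates the whole
  study design with planted ground truth (EGA activation waves, maternal
  decay, stage-gained peaks, replicate-private decoys, stage-specific
  repeat families, promoter CpG classes, sperm fragments in gene-poor
  windows, ChIP sites with an exact planted overlap count), so every
  stage of the pipeline is testable without any download.

## Worked example

One call simulates the default study and runs every stage end to end:

```r
library(chromEGA)
report <- runPipeline("ega_run", seed = 1)
str(report, max.level = 2)
```

```
List of 12
 $ seed                     : num 1
 $ n_unified_peaks          : int 1694
 $ consensus_peaks_per_stage: Named int [1:9] 254 500 395 590 785 980 1100 1220 1340
  ..- attr(*, "names")= chr [1:9] "oocyte" "sperm" "zygote" "2cell" ...
 $ cluster_sizes            :List of 6
 $ n_unassigned             : int 5
 $ n_ega_called             : int 315
 $ ega_precision            : num 0.952
 $ ega_recall               : num 1
 $ chip_overlap             :List of 3
  ..$ n_sites : int 2782
  ..$ n_open  : int 697
  ..$ fraction: num 0.251
 $ repeat_stage_recovery    : num 1
 $ density_pearson          :List of 18
  ..$ sperm_rep1 : num -0.39
  ..$ morula_rep1: num 0.933
  ..  ...
 $ promoter_class_agreement : num 1
```

Reading the numbers: the oocyte is the quietest stage — 254 consensus
peaks, of which only 54 are oocyte-specific (the rest are constitutive) —
while sperm carries 300 stage-specific peaks, and peak numbers rise
steadily from the 2-cell stage on to 1340 in TE; 1694 unified peaks in
all. Of the 315 genes called as EGA genes, 95% are the planted activated
genes and every planted gene is recovered. Of 2782 simulated ChIP binding
sites placed with a 25.05% planted overlap, exactly 697 fall into regions
gained at the 2-/4-cell stages. All 40 planted stage-specific repeat
families are assigned to their true stage. Read density correlates
positively with gene count in every sample (r ≈ 0.93) *except sperm*
(r ≈ −0.39), whose fragments were planted in gene-poor windows. The run
directory contains the per-stage consensus BED files, the unified peak
list, count/normalized tables, cluster assignments, EGA calls, the repeat
specificity table and `report.json`.

The same stages are available as plain functions (`consensusPeaks()`,
`unifyPeaks()`, `quantifyPeaks()`, `gainedRegions()`, `fuzzyCMeans()`,
`callEgaGenes()`, `chipOverlap()`, `stageSpecificity()`, ...) — see the
vignette in `vignettes/` for the model, parameter and design notes.

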
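# occudiff

Spike-in normalized differential occupancy analysis for ChIP-seq of
transcription machinery across matched mutant/wild-type animal pairs.

## What it is for

Loss of a global transcriptional regulator (the motivating case is
MeCP2-null mouse cortex) can change RNA polymerase II binding genome-wide.
Such global shifts are invisible to within-sample normalization, so each
ChIP sample is calibrated against exogenous spike-in chromatin from a
second genome. `occudiff` takes per-sample coverage tracks (bedGraph) for
target and spike-in genomes, a gene annotation (BED/minimal GTF), a sample
sheet of matched animal pairs for three modalities (an elongation-factor
subunit such as AFF4, total RNA pol II, Ser2-phosphorylated RNA pol II),
and an RNA-seq count table, and produces:

* per-sample spike-in scale factors, `s_i = min_j(c_j) / c_i` within each
  modality, where `c_i` is the sample's spike-in fragment count;
* an analysis gene universe: RNA pol II-occupied genes, longer than 2 kb,
  with neighbouring genes at least 2 kb away;
* scale-regions occupancy matrices (2 kb flanks in 50 bp bins, gene body
  in 100 length-weighted bins, strand-oriented) and per-pair
  `log2((null + δ)/(WT + δ))` fold-change matrices;
* Ward hierarchical clustering (k = 3) of per-modality TSS/body/TES
  fold-change features, computed on the most-affected pairs, with
  canonical I/II/III labels ordered by polymerase gene-body depletion;
* per-gene matched-pair **median-of-ratios** summaries, per-cluster
  Spearman correlations (factor vs polymerase body change, factor vs RNA
  expression change), the fraction of genes with decreased polymerase
  body occupancy, and a WT-vs-null Wilcoxon rank-sum comparison of
  cluster expression (RPM);
* a deterministic synthetic-data generator that plants the three-cluster
  structure, known spike-in depths and known effect sizes, so the entire
  pipeline is testable without external data.

## Worked example

Simulate a 500-gene study (3 matched pairs x 3 ChIP modalities + 12 RNA
samples), write it to disk in the package's file formats, and run the full
pipeline on those files:

```r
library(occudiff)
design <- simulation_design(n_genes = 500, seed = 1)
rr <- run_synthetic_pipeline(design, dir = tempfile())
summary(rr$result)
```

```
occupancy_pipeline result
  universe: 375 genes; selected pairs: p1, p3
  clusters: I: 89, II: 272, III: 14
  fraction of genes with decreased polII body occupancy: 0.883

spike-in scale factors:
        sample_id target_fragments spikein_fragments scale_factor modality
       AFF4_p1_WT           219259             49839    0.7976886     AFF4
     AFF4_p1_null           173315             39756    1.0000000     AFF4
       AFF4_p2_WT           273460             62141    0.6397708     AFF4
...

per-cluster Spearman correlations (AFF4 vs polII body change):
 cluster               x                y          rho            p   n
       I AFF4_body_ratio polII_body_ratio -0.185767790 8.134046e-02  89
      II AFF4_body_ratio polII_body_ratio  0.003455086 9.547679e-01 272
     III AFF4_body_ratio polII_body_ratio  0.868131868 5.679819e-05  14

cluster expression WT vs null (Wilcoxon rank sum):
 cluster n_genes statistic          p median_ratio direction
       I      89      4707 0.02998672    1.1637699        up
      II     272     33680 0.07083361    0.9411658      down
     III      14        50 0.02907156    0.6698930      down
```

Reading the output: 375 of 500 genes survive the occupancy/length/gap
filters (the rest are planted violations). The scale factors recover the
planted per-sample depth multipliers to within spike-in counting noise.
Cluster III — the small class with the strongest gene-body polymerase
loss — is the only cluster whose elongation-factor change correlates with
its polymerase change (rho = 0.87 here at n = 14; small-cluster estimates
are noisy), and it shows the strongest expression decrease (median
null/WT ratio 0.67). Checking recovery against the planted truth:

```r
truth <- rr$sim$truth
lab <- with(truth, setNames(label, gene_id))[names(rr$result$cluster_labels)]
adjusted_rand_index(rr$result$cluster_labels, lab)
#> [1] 0.979
```

The same analysis runs from the shell on any dataset in the documented
file formats via a YAML config:

```sh
Rscript inst/cli/occudiff.R simulate --outdir data --n-genes 500 --seed 1
Rscript inst/cli/occudiff.R run-all --config config.yaml
```

## Package layout

* `R/` — annotation/coverage containers and readers, spike-in
  normalization, universe filters, scale-regions matrices, clustering and
  per-cluster statistics, synthetic-data generator, pipeline orchestration.
* `vignettes/differential-occupancy.Rmd` — models, parameter meanings and
  defaults, generator assumptions, design decisions, limitations.
* `tests/testthat/` — unit, property and end-to-end recovery tests with
  independent brute-force oracles.
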
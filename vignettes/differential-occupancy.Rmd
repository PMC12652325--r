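---
title: "Spike-in normalized differential occupancy: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spike-in normalized differential occupancy: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

`occudiff` quantifies how the chromatin occupancy of transcription
machinery changes between a mutant and a wild-type genotype, from ChIP-seq
of matched animal pairs. The motivating setting is cortex ChIP-seq of an
elongation-factor subunit (AFF4, the scaffold of the super elongation
complex), total RNA polymerase II, and Ser2-phosphorylated (elongating)
RNA polymerase II, in MeCP2-null versus wild-type animals, with RNA-seq of
the same genotypes. The scientific questions the pipeline answers:

* After calibrating samples against an exogenous spike-in genome, which
  genes lose polymerase occupancy in the mutant, and where along the gene
  (promoter-proximal TSS window, gene body, TES) is the loss?
* Do genes fall into coherent classes of occupancy change — e.g. a
  TSS-only depletion class (paused genes) versus classes with gene-body
  and beyond-TES depletion (elongation defects)?
* Within each class, does the change in elongation-factor binding
  correlate with the change in polymerase binding and in RNA output?

Because per-sample immunoprecipitation efficiency varies, raw coverage is
not comparable across samples; genotype effects that are global (a
genome-wide loss of binding) are invisible to within-sample normalization.
Spike-in chromatin from a second genome, added at constant mass, provides
an external yardstick.

## Models and procedures

### Spike-in scale factors

For the samples of one modality (one antibody), with spike-in fragment
counts $c_i$, the default reference-to-minimum convention computes

$$ s_i = \frac{\min_j c_j}{c_i}, $$

and multiplies each sample's target-genome coverage by $s_i$. The sample
with the fewest spike-in fragments keeps factor 1 and all others are
scaled **down**; no sample's sparse data is inflated. Factors are computed
per modality because spike-in mass differs per antibody. `"mean"` and
`"fixed"` reference conventions are available; the arithmetic form of the
convention is a package decision — the normalization principle (target
reads scaled by spike-in reads) is the method's substance.

### The gene universe

Window-based occupancy statistics are only meaningful for genes that are
expressed-machinery targets and geometrically clean. Three filters define
the analysis universe:

1. **Occupied**: RNA polymerase II signal at the promoter, evaluated on
   wild-type samples only (the universe must not depend on the genotype
   effect under study). Peaks mode: a peak call overlaps
   $[\mathrm{TSS}-1\,\mathrm{kb}, \mathrm{TSS}+1\,\mathrm{kb})$ in a
   quorum of replicates (default majority). Threshold mode: mean
   normalized window coverage at least $\theta = 2$ times the genome-wide
   width-weighted median of nonzero coverage, same quorum. The window,
   $\theta$ and quorum are exposed because no canonical values exist; the
   defaults are deliberately permissive so that the length and gap filters
   do the geometric work.
2. **Length**: strictly longer than 2 kb ("longer than" read literally).
3. **Neighbour gap**: nearest other gene span on the same chromosome at
   least 2 kb away (inclusive), strand-ignored, overlap counting as gap 0.
   The filter exists to avoid coverage bleed-through between close genes,
   which is strand-blind.

### Scale-regions occupancy matrices

Each universe gene contributes one row: 2 kb upstream flank in fixed 50 bp
bins, the gene body rescaled into exactly 100 equal-width bins, 2 kb
downstream flank in 50 bp bins. Bin values are **length-weighted means** of
per-base coverage — fractional-bp body bins are integrated exactly via a
piecewise-linear cumulative-area function, so the sum of body bins times
bin width reproduces total body coverage area to rounding. Minus-strand
rows are reversed so column 1 is always 5'-most. Region summaries use
windows $\mathrm{TSS} \pm 250$ bp, $\mathrm{TES} \pm 250$ bp, the body
between (and excluding) those windows, and the two flanks. The window
half-widths are package decisions; the regions themselves (TSS, body,
TES) are the method's vocabulary.

Per matched pair $p$ and bin $b$ the fold change is
$\log_2\!\big((x^{\mathrm{null}}_{pb} + \delta)/(x^{\mathrm{WT}}_{pb} +
\delta)\big)$ with pseudocount $\delta = 1$ on normalized coverage
(configurable). $\delta$ bounds fold changes at zero-coverage bins; it
also shrinks ratios toward 1 for genes with low absolute coverage, which
is deliberate — low-coverage genes carry the least evidence.

### Replicate selection, clustering, labels

The pairs used for clustering are the `n_select = 2` of 3 with the largest
mean absolute fold change over all genes, bins and modalities ("the
replicates in which the mutant differed most from wild type"); ties break
lexicographically. The clustering feature table is, per modality, the
median across selected pairs of the TSS, body and TES log2 ratios — 9
features per gene, each standardized. Full-bin profiles would also work
but are noisier and 60x wider; region summaries are the package default.
Agglomerative clustering uses Ward linkage (`ward.D2`) on Euclidean
distance, cut at $k = 3$; the procedure is deterministic given the input
order. Canonical labels are assigned by mean polymerase gene-body fold
change: least negative = I, most negative = III. A tie in that statistic
raises an error rather than silently picking an order.

### Matched-pair median of ratios and per-cluster statistics

For gene-level inference the package deliberately avoids pooling
replicates: per gene, each matched pair contributes a ratio
$(x^{\mathrm{null}}_i + \delta)/(x^{\mathrm{WT}}_i + \delta)$ on a region
summary, and the gene's statistic is the **median across pairs** (mean of
the middle two for even counts). A gene must move consistently across
animal pairs to show a shifted median.

Per-cluster association between two per-gene change statistics uses
Spearman correlation with average-rank ties. Two-sided P values use the
$t$ approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ for $n > 8$ and exact
permutation enumeration for $n \le 8$. The enumeration boundary is 8
because full enumeration costs $n!$; beyond 8 the $t$ approximation is
accurate to the precision at which such P values are interpreted.

The fraction of genes with decreased occupancy counts median ratios
strictly below 1. Cluster expression is compared WT versus null on
per-gene mean RPM with a two-sided Wilcoxon rank-sum test (exact when both
groups have at most 8 observations, normal approximation with continuity
correction otherwise); an all-tied degenerate input returns P = 1 with a
warning.

## The synthetic-data generator

The generator emulates the study conditions end to end: 3 matched WT/null
animal pairs for each of 3 ChIP modalities (18 target plus 18 spike-in
tracks), 6 RNA-seq replicates per genotype, and a gene annotation whose
analysis universe carries planted clusters at proportions
0.242/0.720/0.038 (the class imbalance of the motivating study's
2104/6263/329 split of 8696 genes, as a configurable default, not a
claim). Planted phenotypes per cluster:

* **I** — polymerase depleted at the TSS only; mixed-sign elongation-factor
  flank changes (one sign per gene, shared by both flanks, zero mean —
  the magnitude of the mixed flank behaviour is not quantified in the
  motivating work, so a symmetric zero-mean planting is an explicit
  assumption); pSer2 unchanged.
* **II** — polymerase depleted at TSS, body and beyond the TES; pSer2
  depleted mostly at/beyond the TES.
* **III** — elongation factor depleted at TSS and body; strongest
  polymerase and pSer2 body depletion; highest baseline occupancy and
  expression; and the per-gene elongation-factor and polymerase body
  effects (and the RNA effect) load on one shared latent score with
  correlation `rho_latent = 0.35`.

Fragment counts per gene region are negative binomial with mean =
depth x gene weight x region mass x sample multiplier x effect. Region
masses place a TSS peak (discretized 150 bp bell), uniform body, TES and
flank components; the elongation factor gets extra flank mass, and a
pausing-index parameter sets how TSS-heavy total polymerase is. Effects
are multiplicative on region means; the motivating work reports directions,
not magnitudes, so the default multipliers (e.g. 0.35 for cluster III
polymerase body) are free parameters chosen once so that the planted
structure is recoverable at desk-scale depth (2000 genes, ~400 fragments
per gene per sample), and are documented as such. Per-sample efficiency
multipliers scale target and spike-in depth together, so spike-in
normalization must undo them; spike-in counts are Poisson by default or
exact on request.

Planted filter violations are exact counts, not draws: a fixed fraction of
genes shorter than 2 kb, a fixed fraction placed in adjacent groups less
than 2 kb apart (grouped so no intended-universe gene is collateral
damage), and a fixed fraction with ~2% of normal occupancy weight.
Occupied genes have a baseline-weight floor (`min_occupied_weight = 0.6`)
so the planted universe is unambiguously above the detection threshold —
without it, the lognormal weight tail makes "occupied" a borderline
property for a few genes per thousand, which would make the intended
universe ill-defined rather than the detector wrong.

Every generator output is a pure function of (design, seed): generation
runs under a private RNG scope that restores the caller's RNG state.

**What the generator does not emulate:** read-level data (no sequences, no
mappability or GC bias), peak-caller behaviour, chromatin contact or
domain structure, antibody cross-reactivity, and replicate-level batch
structure beyond the per-sample depth multipliers. Passing recovery tests
on this generator shows the pipeline arithmetic and inference are correct
and well-calibrated under the planted model — not that the biological
conclusions of any particular dataset are right.

### Validation designs

Two dedicated designs exercise estimator calibration:

* **Correlation recovery** uses one-cluster designs (~300 genes) with a
  homogeneous high baseline (`weight_sdlog = 0.1`,
  `cluster3_weight_boost = 10`, `effect_sd_c3 = 0.45`). With the default
  heterogeneous baseline, the pseudocount shrinks both modalities' ratios
  toward 1 by a gene-specific amount, which induces spurious positive rank
  correlation between them; a uniform baseline isolates the planted
  correlation. Because the Spearman sampling standard deviation at
  $n = 300$ is about 0.055, recovery is judged at panel level (mean of 20
  fixed-seed simulations within ±0.10 of the planted value, sign correct
  in every simulation for the 0.35 panel) — a per-simulation ±0.10 bound
  would fail a few percent of the time for a perfect estimator.
* **Fraction-decreased recovery** plants explicit per-gene effect signs
  (`pol2_body_sign_fraction = 0.9`) with magnitudes bounded away from
  zero (0.3 + Exp(0.35) in log2), replacing the cluster-based polymerase
  body effects, so the target fraction is a planted truth rather than an
  emergent property.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally (BED
  convention); GTF input is converted on read. Spike-in and target data
  live in separate namespaces and never share a coordinate space.
* Coverage tracks are canonical run-length encodings (zero runs dropped,
  adjacent equal-value runs merged), which makes bedGraph round-trips
  byte-stable and reruns byte-identical.
* Overlapping synthetic signal components are merged by an event sweep;
  values within 1e-9 relative of zero are clamped to zero.
* `total_fragments` for bedGraph input comes from the sample sheet when
  available; the area/fragment-length estimate (default 200 bp) is a
  fallback only, because it assumes a fragment length.
* Zero spike-in counts are a hard normalization error naming the sample;
  an empty peak file is a warning contributing zero occupied genes; a gene
  too short to host the TSS/TES windows is an error naming the gene.
* Matrix row order always equals universe order, so per-sample matrices
  are directly comparable.

## Problem sizes

The shipped validation suite runs the full pipeline at 2000 genes
(3 pairs x 3 modalities), the filter fuzzing at 1000 random toy
annotations, the matrix oracle at 50 random genes, and the correlation
panels at 20 simulations x ~300 genes, sizes chosen so the complete suite
finishes in well under a minute on one CPU while keeping Monte-Carlo
error far below the tested tolerances.

## Known limitations

* The occupied-gene detector is threshold-based; it is a stand-in for
  peak-call input, not a peak caller. Peaks mode consumes externally
  produced BED files.
* The spike-in convention assumes constant spike-in mass per sample within
  a modality; there is no antibody-efficiency model.
* Single-end versus paired-end fragment resolution is upstream of this
  package: coverage input is treated as already fragment-resolved.
* Clustering at $k = 3$ is the scientific default of the motivating
  setting; the canonical I/II/III labelling rule presumes $k = 3$.
* P values are reported raw; no multiple-testing machinery is included for
  the per-cluster statistics.
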
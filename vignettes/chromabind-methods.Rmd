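---
title: "Methods: features, models and the synthetic study design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: features, models and the synthetic study design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model behind chromabind, the
choices made where the methodology was genuinely open, and what the
synthetic-data generator does and does not emulate.

## The classification problem

The unit of analysis is a 60 bp genomic region labeled *bound* or
*unbound* by a given TF, described by 23 features in three families
(`feature_names()`): two sequence-motif (SM) features, eleven
chromatin-state (CS) features, and ten DNA-structure (DS) features. A
random forest predicts the label; comparing forests restricted to
feature subsets (`model_feature_sets()`) attributes predictive power to
the families. Regions are 0-based half-open throughout (BED-native),
which keeps the 60 bp window arithmetic free of off-by-one errors;
GFF-style 1-based input is converted on read.

## Motif scanning with exact p-values

A window of width $L$ scores
$s=\sum_i \log_2\left(p_i(b_i)/q(b_i)\right)$ in bits against a 0-order
background $q$. Choices:

* **Pseudocount.** $10^{-3}$ is added to every matrix probability and
  positions are renormalized, so zero entries score finitely; a
  single-position matrix $(1,0,0,0)$ scores $\approx 2$ bits on `A`
  against the uniform background.
* **Background.** Either uniform or estimated from the scanned
  chromosome (`base_background()`), with a $10^{-3}$ floor per base.
  The per-region features are computed with a background fixed per
  genome, which makes scores and p-values invariant to a region's
  flanking context.
* **Exact p-values.** Scores are binned at $10^{-3}$ bits and the full
  distribution of window scores under $q$ is computed by dynamic
  programming over positions (`score_pvalue_distribution()`). The scan
  p-value of a window is the survival function at its binned score, so
  scan p-values and the DP are consistent by construction; the DP is
  tested against brute-force enumeration of all $4^L$ windows for
  $L \le 4$.
* **Both strands; no merging.** Every window passing $p<0.001$ on
  either strand counts as a hit; overlapping hits are not merged, but a
  forward/reverse pair at the same start is counted once (best strand
  kept) in `ScerTFhit`. `ScerTFpvalue` is the minimum window p-value
  whether or not it passes the threshold. A region with no scannable
  window reports 0 hits and p-value 1.

## DNA-structure features

`fit_pca()` standardizes each property over the 16 dinucleotides before
eigendecomposition (correlation PCA). This is required, not optional:
the properties mix thermodynamic and geometric units, and covariance
PCA would be dominated by whichever property happens to have the
largest numeric range. The sign of each component is fixed so its
largest-magnitude loading is positive, making loadings stable across
runs. Components are interpreted by their top-10 loading properties
(`annotate_pcs()`).

A region's `PCx` is the mean component score of its dinucleotide steps
(step size 1 bp; steps containing N are skipped, not imputed). `dPCx`
contrasts the region with its two 30 bp flanks; the flank mean pools
the steps of both flanks into one mean (`flank_mode = "pooled"`,
default) rather than averaging two per-flank means — the pooled mean
weights every flank step equally when a flank is truncated at a
chromosome end. The alternative is available as
`flank_mode = "mean_of_means"`. When one flank is absent the other is
used alone; when both are absent the feature is missing.

## Chromatin-state features

A region's track value is the unweighted mean of the probes covering
strictly more than half of the region — a probe overlapping exactly
30 of 60 bp contributes nothing, and a region with no qualifying probe
gets a missing value that later triggers the dataset builder's
row-drop rule (never a silent zero). H3 normalization
(`normalize = "h3_subtract"`) subtracts the region's H3 value from
each modification feature on the log-ratio track scale and reports H3
itself raw; tracks that are already H3-normalized (the synthetic
generator's) are extracted with `normalize = "none"`.

`predict_nucleosome_occupancy()` is deliberately a simple, documented
default behind an interface: occupancy
$= z(\mathrm{GC}) + z(\mathrm{periodicity}) - z(\mathrm{polyAT})$,
where periodicity is the 10 bp phase concentration of AA/TT/TA steps
and polyAT is the fraction of bases in A/T runs of at least 5 bp, each
z-scored across the scored cohort. Any precomputed occupancy track can
be substituted via `occupancy_feature(track = ...)`; the evaluation
layer only requires an `occupancy` column.

## Dataset construction

Bound probes are refined to the 60 bp window centered on the midpoint
of the best motif hit within probe ± 240 bp. "Best" needed a
tie-break, which is: highest score, then smallest p-value, then
leftmost start, then + strand. When no window is scannable the probe
midpoint is used — this fallback also serves TFs without a usable
motif. Negatives are the equally many lowest-signal unbound probes
(coordinate order breaks ties), refined with the same centering rule by
default (`negative_centering = "motif"`, for symmetry with the
positives; `"midpoint"` is available). Rows missing any of the 23
features are dropped; a TF left with fewer than 30 positives is skipped
with a reason. After filtering, the larger class is truncated —
negatives by lowest signal, positives by highest — so the dataset is
exactly balanced. One-vs-rest pairs (`build_one_vs_rest()`) downsample
the larger bound set with a seeded draw.

## Model evaluation

* Forests use 500 trees and $\lfloor\sqrt{p}\rfloor$ (min 1) candidate
  features per split.
* Cross-validation is stratified by class; each of the ten repeats is
  reseeded deterministically from the master seed. Per repeat, the
  out-of-fold class probabilities are pooled and F-measure, precision,
  recall, accuracy (all at probability threshold 0.5 — "accuracy" is
  otherwise undefined) and auROC are computed; the summary is the mean
  over repeats with per-run values retained.
* Feature-set comparisons and drop-column importance reuse identical
  fold assignments (`make_cv_folds()`), making the contrasts paired.
  Importance is the accuracy reduction from retraining without one
  feature, min-max rescaled to [0, 1] per TF; note that duplicated or
  redundant informative features each show a small individual drop —
  an inherent property of drop-column importance.
* Cross-DBD transfer trains one forest per family and tests on each
  other family; diagonal entries come from 10-fold cross-validation.
  The bootstrap null permutes test labels: with predictions fixed, the
  permuted true-positive count is hypergeometric, so the 10,000
  resamples are drawn exactly and cheaply, and the p-value uses an
  add-one pseudocount, $p = (1 + \#\{F_{null} \ge F\})/(1 + B)$.
* Per-(TF, feature) distribution comparisons use the two-sided
  Wilcoxon rank-sum test with Benjamini–Hochberg adjustment across the
  whole tested family and report the direction of the median shift.
* `standardize_performance()` rescales each TF's F-measures across
  models to mean 0, variance 1 (sample SD, so z-rows have unit
  variance exactly), and groups TFs by average-linkage hierarchical
  clustering of the z-rows cut at $k=3$ — a reconstruction of the usual
  three archetypes (either family works / CS-dependent / DS-dependent),
  not a canonical algorithm.

## Expression coherence

Promoters are the intergenic sequence immediately upstream of the TSS
on the gene's strand, capped at 1000 bp and truncated at the
neighbouring gene. A gene whose promoter motif hits (p < 0.001) are
*all* fully contained in predicted bound regions is "bound", with none
contained "unbound", and mixed cases are excluded as ambiguous — full
containment of the motif window is required, so a hit straddling a
region boundary is not "within". Co-expression of a gene pair is the
maximum absolute Spearman correlation over lags $\{-1, 0, +1\}$ time
points (edges truncated; lags with constant overlapping series are
undefined and pairs with no defined lag are dropped rather than
zero-filled). The bound and unbound within-set distributions are
compared by a one-sided two-sample Kolmogorov–Smirnov test (alternative:
bound stochastically larger), requiring at least 10 genes per set.

The KS p-value uses the exact conditional Smirnov distribution
(`stats::psmirnov`) whenever the product of the two pair counts is at
most $4\times10^6$; the asymptotic formula is measurably
anticonservative at these sizes (about 5.1% rejections at nominal 5%
for 190-vs-190 samples). A residual caveat remains: the pairwise
correlations within a set share genes and are therefore weakly
dependent, which pushes the realized null rejection rate to roughly
0.051 at 20 genes per set. This is a property of the method itself, not
of the implementation, and is worth remembering when reading borderline
p-values.

## The synthetic study

The generator (`synthetic_config()` and friends) emulates the
statistical structure the analysis assumes, with defaults chosen once
as the study conditions:

* **Genome.** i.i.d. bases at GC 0.38 (yeast-like; the simplest null
  consistent with the 0-order scan background) with genes laid out on
  alternating strands. No higher-order Markov structure, no realistic
  nucleosome-positioning sequence.
* **Binding regions.** 100 bound / 100 unbound 60 bp regions per TF by
  default; bound regions receive the PWM consensus at their center, so
  rescanning recovers ≥ 95% of them. TF ChIP probes are 75–300 bp,
  cover their region entirely, and bound probes have higher signal.
* **Chromatin tracks.** The chromosome is tiled with 150 bp probes;
  each probe gets unit-variance Gaussian signal per feature, mean
  shifted by the configured effect size when the probe overlaps a bound
  region by more than half of that region. The tiling pitch ensures a
  60 bp region is read from exactly one qualifying probe, so the
  extracted feature preserves the planted standardized shift and the
  single-feature AUC is analytically $\Phi(d/\sqrt2)$. Signals are
  emitted directly on the H3-normalized scale; the default effects
  encode H3 depletion (−1.5) and activating-mark enrichment (+1.5 to
  +1.0) in bound regions. Effect sizes are free parameters: the source
  analyses report test p-values on real data, not standardized effect
  sizes, so these are chosen to be comfortably detectable at the
  default sample sizes.
* **Property table.** Block-correlated properties built from
  orthogonalized latent 16-vectors (within-block weight 0.9); block
  sizes are deliberately unequal so the eigenvalue spectrum separates
  and components align with blocks rather than mixing near-degenerate
  ones. Property names carry their block tag to make component
  annotation checkable.
* **Expression.** Module genes mix a shared smooth latent profile so
  that pairwise Spearman correlation targets `module_rho` via the
  Gaussian-copula relation $r = 2\sin(\pi\rho/6)$; a `lag_fraction` of
  module genes (genes, not pairs — shifting a gene shifts all its
  pairs, which is the simplest generative mechanism) use the profile
  shifted by one time point. Non-module genes are independent noise.
* **Feature-level shortcut.** `simulate_binding_dataset()` draws the
  23 + 1 features directly as unit Gaussians with planted shifts on the
  standardized scale, with `tf_group_profiles` silencing families per
  TF. This is the workhorse for model-evaluation studies where genome
  realism adds nothing; integer-valued `ScerTFhit` is continuous here,
  which the forest is indifferent to.

What passing tests on these data do **not** show: performance on real
yeast ChIP data (real features are correlated across families, effects
are not Gaussian, and probe coverage is irregular), recovery of any
particular published F-measure, or robustness to motif databases whose
PWMs disagree with the ChIP signal.

## Problem sizes and numerical choices

The test suite and the acceptance script run feature-level studies at
100 regions per class with 5-fold cross-validation, 1–2 repeats and
120–300 trees, and genome-level studies on 100–450 kb genomes — sizes
at which the planted effects are decisively detectable while the full
suite completes in about two minutes. Score binning is $10^{-3}$ bits;
PCA drops constant property columns with a warning and reduces the
component count when fewer informative dimensions exist; degenerate
inputs (all-N regions, constant expression profiles, empty families,
single-class data) return missing values or explicit errors as
documented on each function.
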
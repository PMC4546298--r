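# chromabind

Classify transcription-factor (TF) bound versus unbound genomic regions
in yeast from three families of region features, and quantify what each
family contributes. The package is aimed at regulatory genomicists who
want to go beyond motif matching: it implements the full analysis
pipeline — feature extraction, balanced dataset construction,
random-forest evaluation, feature attribution, cross-family transfer,
and a co-expression validation of predicted bound regions — together
with a synthetic-data generator that makes every stage testable without
any external download.

## The model

For each TF, 60 bp candidate regions are described by 23 features in
three families:

* **SM (sequence motif, 2 features).** The region is scanned on both
  strands with the TF's position weight matrix (PWM). A window of width
  `L` scores `s = Σᵢ log₂(p_i(bᵢ) / q(bᵢ))` against a 0-order background
  `q`, and the exact p-value `P(S ≥ s)` under that background is
  computed by dynamic programming over positions (score binning
  10⁻³ bits). Features: `ScerTFhit`, the number of windows with
  p < 0.001, and `ScerTFpvalue`, the minimum window p-value.
* **CS (chromatin state, 11 features).** Histone H3 occupancy, ESA1 and
  GCN5 binding, and seven histone modifications, each read from a
  ChIP-chip style probe track as the mean of probes covering more than
  half of the region, on the H3-normalized scale.
* **DS (DNA structure, 10 features).** A DiProDB-style table of ~125
  physical dinucleotide properties is reduced by correlation PCA over
  the 16 dinucleotides; a region gets the mean score of its
  dinucleotide steps on the top five components (`PC1..PC5`) and the
  difference from its 30 bp flanks (`dPC1..dPC5`).

A balanced dataset per TF (bound probes refined to motif-centered 60 bp
regions; equally many lowest-signal unbound probes; rows with missing
features dropped; TFs with < 30 bound probes skipped) feeds a random
forest (500 trees, √p features per split) evaluated by ten runs of
stratified 10-fold cross-validation, reporting F-measure
(`2PR/(P+R)`), precision, recall and auROC. On top of that sit
drop-column feature importance, the three-feature *intrinsic property
model* (predicted nucleosome occupancy + PC1 + PC2, all computable from
sequence alone), cross-DNA-binding-domain transfer with a
label-permutation bootstrap, and a coherence test asking whether genes
whose promoter motif sites all fall inside predicted bound regions are
more co-expressed (maximal single-time-lag |Spearman|, one-sided exact
Kolmogorov–Smirnov) than genes whose sites all fall outside.

## Worked example

Generate a synthetic study — a 150 kb genome with 60 bound and 80
unbound regions for one TF, bound regions depleted of H3 and enriched
for H3K4me1/H3K9ac — then build the dataset and compare feature-set
models:

```r
library(chromabind)
library(dplyr)

cfg <- synthetic_config(genome_length = 150000, n_tfs = 1,
                        n_bound_per_tf = 60, n_unbound_per_tf = 80,
                        effect_sizes = c(H3 = -1.5, H3K4me1 = 1.5,
                                         H3K9ac = 1.5),
                        seed = 42)
gen     <- generate_genome(cfg)
pwm     <- read_pwm(system.file("extdata", "synthetic_TF1.pwm",
                                package = "chromabind"), tf = "TF1")
planted <- plant_binding_regions(gen$genome, pwm, cfg)
tracks  <- simulate_chromatin_tracks(planted$regions, cfg)
pc      <- fit_pca(generate_dinuc_property_table(125, 5, seed = 42))

dataset <- build_tf_dataset(planted$probes, pwm, planted$genome,
                            tracks, pc, normalize = "none")
dataset |> count(label)
#>   label       n
#> 1 bound      60
#> 2 unbound    60

models <- feature_set_models(dataset, folds = 10, repeats = 2,
                             ntree = 300, seed = 42)
models |> select(model_tag, f_measure, precision, recall, auroc)
#>   model_tag f_measure precision recall auroc
#> 1 SM            0.96      0.923  1     0.95
#> 2 CS            0.833     0.816  0.85  0.882
#> 3 DS            0.558     0.558  0.558 0.601
#> 4 SM+CS         0.927     0.905  0.95  0.962
#> 5 SM+DS         0.934     0.919  0.95  0.935
#> 6 CS+DS         0.848     0.838  0.858 0.884
#> 7 SM+CS+DS      0.927     0.905  0.95  0.954
```

The planted structure is recovered: the motif (planted as an exact
consensus, so SM is very strong here) and the two planted chromatin
marks separate the classes, while DS — which carries no planted signal
in this configuration — stays near the 0.5 random-classifier baseline.
Which single features carry the model:

```r
imp <- drop_column_importance(dataset, feature_names(), folds = 5,
                              repeats = 1, ntree = 200, seed = 42)
imp |> arrange(desc(normalized)) |> head(3)
#>   feature         drop normalized
#> 1 ScerTFpvalue 0.0667         1
#> 2 ESA1         0.00833        0.3
#> 3 H3K9ac       0.00833        0.3
```

`autoplot()` methods exist for cross-validation results, importance
tables, cross-DBD matrices and coherence results;
`plot_performance_heatmap()` and `plot_feature_comparison()` display
the per-TF summaries.

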
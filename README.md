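# hypervar

Differential **variability** analysis of gene expression and DNA methylation
across paired cell types.

Most omics comparisons ask whether a gene's *mean* level differs between
conditions. `hypervar` asks a different question: at which loci does a trait
vary more **between individuals** in one cell type than in another? In
immune cells, inter-individual variability is a readout of phenotypic
plasticity — loci that fluctuate freely in a population are poised to
respond to stimuli. The package is aimed at analysts working with paired
designs: the same donors profiled in several cell types, for bulk RNA-seq
(log2 counts) and/or 450K-style methylation (M values).

## The method

For each feature $g$ in each cell type, with per-donor values $y_i$:

* **Mean-corrected variability score.** Raw variance is confounded by the
  mean, so each feature is scored by
  $\mathrm{EV}_g = v_g / f(\mu_g)$ — observed variance over the variance
  expected at its mean, where $f$ is a robust LOWESS trend of
  $\log(v+\varepsilon)$ on $\mu$ fitted per cell type. The methylation
  analogue on M values is called MV.
* **Paired moderated deviation test.** Donor-wise differences of absolute
  deviations $z_i = |y^A_i - \bar y^A| - |y^B_i - \bar y^B|$ are tested
  with a one-sample empirical-Bayes moderated t
  ($\tilde s^2 = (d_0 s_0^2 + (n{-}1)s^2)/(d_0 + n{-}1)$, $d_0 + n - 1$
  degrees of freedom), pairing out donor effects.
* **Combined rule.** A feature is hypervariable in A vs B iff BH-adjusted
  $p < 0.05$ **and** $\mathrm{EV}_A - \mathrm{EV}_B$ is at least 10% of the
  observed range of the pooled EV values **and** both statistics agree in
  direction.
* **Mutually exclusive classification.** Across the three pairwise
  contrasts, features are labelled `specific:X` (hypervariable in both of
  X's contrasts), `shared:XY` (X and Y each hypervariable versus the
  third), or `none`; no feature appears in more than one list. Features
  variable in *all* cell types are found separately by a worst-rank rule
  over six rankings (MAD and EV in each cell type).

Downstream stages cover sex-specific differential expression, Spearman
screens against donor traits and interpolated weather series,
promoter/body methylation-expression correlation, hypergeometric and
resampling enrichment of CpG annotations, consensus chromatin-state
calling, and thresholded (Pearson r > 0.6) co-expression network modules.

A synthetic paired-cohort generator (`simulate_cohort()`) with known
ground-truth hypervariable features makes the whole pipeline testable
without controlled-access data; see the methods vignette
(`vignettes/differential-variability.Rmd`) for the generative model and all
design decisions.

## Worked example

Simulate a 125-donor cohort with 60 neutrophil-specific hypervariable genes
(variance ×4) and 40 hypervariable CpGs injected, then run the full
pipeline:

```r
library(hypervar)
cfg <- pipeline_config(
  sim = sim_config(
    n_genes = 2000, n_cpgs = 1000, n_donors = 125,
    injected_sets = list(
      list(assay = "expression", ids = 1:60, cells = "neutrophil",
           inflation = 4),
      list(assay = "methylation", ids = 1:40, cells = "neutrophil",
           inflation = 4)),
    seed = 1))
res <- run_pipeline(cfg)
res$expression$counts
#>                 label    n
#> 1 specific:neutrophil   59
#> 2                none 1941
#> 3 common (rank-based)   59
```

59 of the 60 injected genes are recovered as neutrophil-specific with no
false calls:

```r
truth_eval(res$expression$classification,
           subset(res$cohort$truth, assay == "expression"))[1:3]
#> sensitivity 0.98, precision 1.00, label accuracy 1.00
```

The injected CpGs carry the annotation skew the generator emulates
(depletion at CpG islands, concentration in open sea), which the
enrichment stage detects by both the hypergeometric test and 1000-draw
resampling:

```r
res$enrichment$genomic_feature[, c("category", "k_set", "fold",
                                   "p_enrich", "p_deplete", "p_empirical")]
#>   category k_set  fold p_enrich p_deplete p_empirical
#> 1   island     2 0.153 0.999998  2.04e-05    1.000000
#> 2 open_sea    25 1.830 0.000178  1.00e+00    0.000999
#> 3    shelf     7 1.929 0.060016  9.78e-01    0.056943
#> 4    shore     6 0.640 0.947402  1.15e-01    0.935065
```

`run_pipeline(cfg, out_dir = "out/")` additionally writes every result
table as TSV plus a `manifest.yaml` recording all parameters; reruns with
the same configuration reproduce the outputs byte for byte.

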
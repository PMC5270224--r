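---
title: "Differential variability analysis with hypervar: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential variability analysis with hypervar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hypervar)
```

# The problem

Most differential analyses of gene expression or DNA methylation compare
*means* between conditions. `hypervar` addresses a different question: at
which loci does a cellular trait vary more *between individuals* in one cell
type than in another? In immune cells, inter-individual variability is a
proxy for phenotypic plasticity — the capacity of a cell population to react
to changing conditions — and cell types with a first-responder role are
expected to carry more hypervariable loci than cell types with tightly
constrained programs.

The design the package assumes is a paired multi-cell-type cohort: the same
donors profiled in each of three cell types, for expression (log2 counts)
and/or methylation (M values). Pairing matters: it removes donor-level and
processing effects from every cross-cell-type comparison.

# The variability model

## Mean-corrected variability scores (EV / MV)

Raw variance is strongly confounded by the mean: lowly expressed genes have
high relative variance on the log scale, and intermediate methylation is
intrinsically more variable than the extremes. A cell type with globally
reduced transcription would look "hypervariable" for purely technical
reasons. `hypervar` therefore scores each feature by the ratio of observed
to *expected* variance,

$$\mathrm{EV}_g = \frac{v_g}{f(\mu_g)},$$

where $f$ is a smooth trend fitted to the (mean, variance) cloud of all
features in the same cell type. Concretely, `fit_mean_variance()` runs
robust LOWESS of $\log(v_g + \varepsilon)$ on $\mu_g$ (span 0.3, 3
robustifying iterations, $\varepsilon = 10^{-8}$), evaluates the fit by
linear interpolation on a 512-point grid, extrapolates constantly beyond the
fitted mean range, and floors the result at $\varepsilon$ so EV is always
defined. Each cell type gets its own fit: cell types live in different
mean-variance regimes and a pooled fit would reintroduce the confounding the
score exists to remove. On simulated null data with a strong negative trend,
the Spearman correlation of EV with the mean is below 0.01 in magnitude
while raw variance correlates at about $-0.93$ (the test suite asserts
$|\rho| < 0.1$ and $\rho_{v,\mu} \le -0.5$).

The same score on M values is called MV. We perform all methylation analysis
on M values (the log2 ratio scale, where variance is closer to homoskedastic)
and keep beta values for display; `beta_to_m()` / `m_to_beta()` convert
between the scales (beta values of exactly 0 or 1 are clamped at
$10^{-6}$ before the logit-type transform).

## The paired moderated deviation test

Significance comes from a DiffVar-style test on absolute deviations. For a
feature in one cell type, each donor contributes
$|y_i - \bar y|$, the absolute deviation from the group mean; the group
median of these is the MAD-from-mean reported in the variability tables.
For a contrast between cell types A and B the donor-wise *differences* of
absolute deviations $z_i = d_{A,i} - d_{B,i}$ are tested with a one-sample
moderated t-statistic,

$$\tilde t_g = \frac{\bar z_g}{\tilde s_g / \sqrt{n}}, \qquad
  \tilde s^2_g = \frac{d_0 s_0^2 + (n-1) s_g^2}{d_0 + (n-1)},$$

with $(d_0, s_0^2)$ estimated across features by the log-variance moment
method (digamma/trigamma moment matching with monotone root finding; when
the observed spread of log-variances is at or below the sampling spread the
prior is degenerate and every posterior variance equals $s_0^2$). P-values
are two-sided on $d_0 + n - 1$ degrees of freedom. Setting `d0 = 0`
recovers the classical paired t exactly (to 1e-10 in the tests), and the
moment estimator recovers known $(d_0, s_0^2)$ from simulated scaled-F
variances within tight bounds.

Working on donor-wise differences is our realization of "paired": it
cancels additive donor effects in the deviations and needs no design
matrix. Donors missing either sample of a contrast are dropped, with the
count reported.

## The combined decision rule

A feature is called hypervariable in A versus B only if **both** statistics
agree:

1. BH-adjusted p of the paired deviation test $< \alpha$ (default 0.05);
2. EV difference $\mathrm{EV}_A - \mathrm{EV}_B \ge \delta$, where
   $\delta$ is 10% of the observed range of the pooled EV values of both
   cell types (computed on the analysed feature set, after filtering);
3. the EV difference and the mean deviation difference share a sign.

Requirement 3 is our addition: the two halves of the combined approach
measure variability differently and the rule should not fire when they
disagree silently. The pooled-range convention for $\delta$ makes the
threshold scale-free; a degenerate range (all EV equal) yields
$\delta = 0$ with a warning.

## Classification and the common list

With three cell types there are three contrasts. `classify_features()`
assigns exactly one label per feature: **specific:X** if X is called
hypervariable in both of its contrasts (evaluated first), then
**shared:XY** if X and Y are each hypervariable versus the third cell type,
else **none**. The specific-before-shared precedence resolves the corner
where all three contrasts fire; an exhaustive 27-combination enumeration in
the tests confirms the labels are mutually exclusive on every input.

Features variable in *all three* cell types cannot appear in these disjoint
lists, so they are found separately by `rank_common()`: rank features from
high to low variability by MAD and by EV within each cell type (six
rankings, average ranks on ties), score each feature by its worst rank, and
keep the `n` best-scoring features (ties broken by mean rank, then feature
id). The worst-rank score demands consistently high variability everywhere.
The default `n` is the rounded mean of the specific/shared list sizes; the
analyses that motivated this rule do not enumerate which lists enter the
mean, so `n` is exposed as a parameter.

# Downstream stages

* **Sex-specific differential expression** — two-sample moderated t with
  pooled variance, male versus female, with significance at BH-adjusted
  p < 0.05 and $|\log_2 FC| \ge$ `lfc_min` (1 for the effect-size screen, 0
  for the permissive screen). An age ceiling (< 50 years) reruns the
  analysis on pre-menopausal donors.
* **Trait and seasonal screens** — Spearman correlation of hypervariable
  features with donor traits; p from the large-sample t approximation; BH
  within each (cell type, trait) family. Weather series are gap-filled by
  linear interpolation (interior) and nearest-value extension (edges), then
  joined to donors by collection date. The per-(cell type, trait) BH family
  matches testing cell-type-specific feature sets trait by trait; a global
  family is one flag away.
* **Methylation-expression links** — per CpG mapped to a gene promoter
  (TSS1500, TSS200, 5'UTR, first exon) or body (body, 3'UTR), Spearman rho
  of M versus log2 expression across donors, classified
  positive/negative/none at BH-adjusted p < 0.05 within the region class.
  Gene-level MV for the binned MV-EV profiles is the mean MV over a gene's
  promoter (or body) CpGs — the aggregator is not prescribed by the
  analysis this follows, so the mean is our documented choice.
* **Enrichment** — hypergeometric enrichment/depletion p-values plus
  repeated random sampling (default 1000 draws) from the QC-passing
  background; the empirical p uses add-one smoothing,
  $(1 + \#\{k_{\mathrm{resample}} \ge k\})/(n+1)$, so it is never exactly 0.
  The background is always the full QC-passing feature set. Category
  systems (genomic feature, gene element, chromatin state) are evaluated
  independently with BH across the categories of a system.
* **Consensus chromatin states** — the modal state across $\ge 5$
  biological replicates if observed in $\ge 80\%$ of them, else
  `"variable"`; modal ties are by definition below the threshold and also
  yield `"variable"`.
* **Co-expression modules** — edges wherever Pearson r strictly exceeds 0.6
  (constant genes excluded, unconnected genes removed), then FAG-EC-style
  agglomeration: edges in descending edge clustering coefficient
  $(t_{uv}+1)/\min(\deg_u - 1, \deg_v - 1)$, merging endpoint clusters; a
  merge is refused once both clusters have reached `min_size`, which keeps
  mature modules separate across low-ECC bridges, and ties are broken by
  edge id so detection is deterministic. The published algorithm this
  approximates is specified only by citation; our stopping rule is the
  package's own choice and a plain connected-components fallback is
  selectable via `detect_modules(method = "components")`.

# The synthetic cohort generator

`simulate_cohort()` exists so that every stage is testable without
controlled-access data. It emulates, per cell type and donor:

* expression means uniform on [0, 12] (log2 scale) and variance
  $v(\mu) = 2 e^{-0.4\mu} + 0.05$ times a lognormal per-feature effect
  (sdlog 0.4) — a strong negative mean-variance trend of realistic shape
  and spread;
* methylation baselines from the bimodal beta mixture
  $0.45\,\mathrm{Beta}(1,10) + 0.45\,\mathrm{Beta}(10,1) +
  0.10\,\mathrm{Beta}(2,2)$, converted to M, with a unimodal variance trend
  peaking at intermediate methylation (the analysis scale is M, so variance
  is injected on M);
* a **shared** baseline variance across cell types for every feature. This
  is deliberate and stronger than exchangeability: the paired null is then
  exactly true, which is what calibration tests require;
* injected hypervariable sets whose variance is multiplied by the
  configured inflation in the designated cell type(s) — one cell type for
  specific, two for shared, three for common;
* optionally, cis-genetic hypervariability: a Hardy-Weinberg biallelic
  variant at the configured MAF shifts the donor mean additively, scaled so
  the variance added across donors equals the requested inflation — the
  variance inflation *emerges* from genotype, the residual noise is not
  scaled;
* sex (46% male), age (uniform 20-75), collection dates over a year, sex
  effects, seasonal sinusoids, age slopes for CpGs, and donor traits with
  target Spearman correlations realized through a Gaussian copula
  ($\rho_{\mathrm{Pearson}} = 2\sin(\pi\rho_S/6)$ on normal scores).

What it does **not** emulate: library-size and batch effects (data enter
the pipeline post-normalization), count-level noise (expression is
generated directly on the log2 scale), spatial correlation along the
genome, correlated CpG blocks, or realistic linkage between methylation and
expression. Passing tests therefore demonstrate that the statistical
machinery is correct and calibrated under the stated model — not that the
model captures every property of real cohort data.

Defaults (125 donors, three cell types, inflation 4 for injected sets)
mirror the cohort structure the method targets. Effect-size distributions
of real hypervariable loci are unknown; the generator defaults are
placeholders for power exploration, not estimates.

# Numerical choices and degenerate inputs

* Variance uses the unbiased $n-1$ denominator; groups need $\ge 4$
  samples, contrasts $\ge 4$ complete pairs.
* MAD here is the median of absolute deviations from the group **mean**
  (the deviation statistic of the test), not from the median.
* LOWESS span 0.3, 3 robust iterations, 512-point interpolation grid,
  $\varepsilon = 10^{-8}$ floor; fewer than 2 distinct means or all-zero
  variances are errors.
* `estimate_moderation()` drops zero variances from the fit with a warning
  and errors only when none are positive; the degenerate
  $\mathrm{var}(e) \le \psi'(\mathrm{df}/2)$ case takes the
  complete-shrinkage branch ($d_0 = \infty$).
* Zero standard errors yield $t = 0$ when the effect is 0 (constant
  features test as null, not as NaN).
* BH excludes NA p-values from the family size and propagates them.
* All tie-breaks (rank averaging, common-list ordering, module edge order)
  are deterministic, so fixed seeds give bit-identical outputs end to end.

# Problem sizes in the shipped tests

The test suite validates calibration on twenty 2,000-feature null cohorts
of 125 donors, recovery on a 5,000-feature cohort with 150 injected
features, and one full-scale run (11,980 genes and 50,000 CpGs across
three cell types of 125 donors) through the entire pipeline; the full-scale
run completes in well under a minute on a single core. These sizes were
chosen to match the scale the method is intended for while keeping the
suite quick to run.

# Limitations

* EV corrects the mean-variance trend but inherits the trend fit's edge
  behavior: constant extrapolation makes EV conservative for features with
  means outside the bulk.
* The moderated test assumes approximately normal deviation differences;
  with 125 donors the central limit theorem makes this accurate, but the
  test is not exact at small n.
* The module-detection stopping rule approximates an algorithm whose exact
  agglomeration schedule is not published; module boundaries near
  `min_size` should not be over-interpreted.
* The generator's independence assumptions (features, CpGs, donors) make
  multiplicity behavior slightly optimistic relative to correlated real
  data.
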
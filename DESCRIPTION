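Package: hypervar
Title: Differential Variability of Gene Expression and DNA Methylation
    Across Paired Cell Types
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Identifies hypervariable genes and CpG sites across paired
    cell types profiled in the same donors. Implements mean-corrected
    variability scores (EV/MV) based on a local regression of variance on
    the mean, paired empirical-Bayes moderated testing of per-sample
    absolute deviations, a combined significance rule (FDR plus a minimum
    variability-score difference), mutually exclusive classification into
    cell-type-specific and shared hypervariability, a rank-based list of
    features variable in all cell types, sex-specific differential
    expression, trait and seasonal correlation screens, annotation
    enrichment by hypergeometric test and repeated random sampling,
    consensus chromatin-state calling, and thresholded co-expression
    network modules. Ships a synthetic paired-cohort generator with known
    ground-truth variability architecture for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite
Config/testthat/edition: 3
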
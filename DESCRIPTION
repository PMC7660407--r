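Package: unresscreen
Title: Detection of Unexpectedly Resistant Cell Lines in Pharmacogenomic Screens
Version: 1.0.0
Authors@R:
    person("Jan", "Doerr", email = "jdoerr@example.org", role = c("aut", "cre"))
Description: Discovers cancer-type-specific drug-sensitivity biomarkers in
    cell-line pharmacogenomic screens (covariate-adjusted ANOVA with a signed
    Cohen's d effect size), detects unexpectedly resistant (UNRES) cell lines
    inside each sensitive subpopulation with a leave-top-i standard-deviation
    decrease statistic tested against a within-tissue bootstrap null, controls
    the two-level error hierarchy with the Yekutieli hierarchical FDR
    procedure and its closed-form FDR bound, proposes putative resistance
    biomarkers from binary cancer-functional-event matrices (unique target
    mutations, mutual exclusivity, Fisher enrichment), and ranks resistance
    mechanisms with a differential gene-essentiality score on CRISPR
    gene-effect matrices. Includes a synthetic-screen generator with planted
    ground truth and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
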
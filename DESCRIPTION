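Package: svSurv
Title: Structural-Variant Gene Burden and Survival Analysis for Clinical Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links per-patient structural-variant (SV) burden in disease-associated
    target genes to clinical-trial survival outcomes. Reads gene-annotated
    multi-sample VCFs into a sample-by-gene SV count tally, joins the tally with
    trial metadata, stratifies patients by treatment arm and SV-carrier status,
    and fits Kaplan-Meier product-limit curves with Greenwood variance, two-group
    log-rank tests, and Cox proportional-hazards models (Efron or Breslow ties)
    in Standard (pooled) and Multiple (carrier-stratified) configurations.
    Includes a two-arm trial simulator with known treatment and carrier hazard
    effects, a disease-to-gene registry, and scriptable report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    vcfR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    survival,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'cohort.R'
    'cox.R'
    'km.R'
    'logrank.R'
    'registry.R'
    'report.R'
    'simulate.R'
    'svSurv-package.R'
    'tally.R'
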
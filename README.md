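# svSurv

Structural-variant gene burden meets clinical-trial survival analysis.

Clinical trials of drugs with a genetic target implicitly assume the target
gene is intact in every participant. It often is not: structural variants
(SVs — deletions, duplications, insertions, inversions, breakends ≥ 50 bp)
can disrupt the target in a subset of the cohort and change how those
patients respond. svSurv is for trial statisticians and genome analysts who
have (1) a gene-annotated multi-sample SV VCF of the cohort and (2) the
trial metadata, and who want to know whether survival differs jointly by
treatment arm and SV-carrier status of a disease-associated target gene.

## What it computes

Given the sample×gene SV count tally `tally[s, g]` (records in which sample
*s* carries ≥ 1 alternate allele of a variant annotated with gene *g*), a
patient is a **carrier** when `minSV ≤ sv_count ≤ maxSV`. The package then
estimates, per (arm × carrier) stratum:

- the **Kaplan–Meier product-limit curve**
  S̃(t) = ∏_{tᵢ≤t} (1 − dᵢ/nᵢ) with Greenwood variance
  S̃(t)² · Σ dᵢ/(nᵢ(nᵢ−dᵢ)), log-log confidence bounds, life tables and a
  risk table;
- the **two-group log-rank test** with hypergeometric variance per event
  time;
- **Cox proportional-hazards models** h(t|x) = h₀(t)·exp(xᵀβ), maximized by
  Newton–Raphson with Efron (default) or Breslow tie handling, in a
  *Standard* configuration (all patients; arm + carrier + covariates) and
  *Multiple* configurations (carrier and non-carrier subsets separately).

All three estimators are implemented in the package and checked against the
`survival` package to 1e-6 in the test suite. A deterministic trial
simulator with known treatment/carrier/age hazard effects generates matched
metadata + VCF for validation and worked examples.

## Worked example

Simulate the exemplary trial (50 per arm, carriers need ≥ 3 SVs in the
target gene *SETX*/ENSG00000107290), run the pipeline, and test the
arm × carrier effects:

```r
library(svSurv)

cfg <- trialSimConfig(nPlacebo = 50, nTreatment = 50, svCountMin = 3, seed = 1)
dir <- tempfile(); sim <- simulateCohort(cfg, dir = dir)
vcf <- file.path(dir, "cohort.vcf"); simulateSvVcf(cfg, sim$truth, vcf)

tally  <- buildGeneTally(readAnnotatedVcf(vcf))
map    <- columnMap(idCol = "patient_ID", armCol = "Phenotype",
                    eventCol = "survival.status_bin", timeCol = "time",
                    timeUnit = "years",
                    covariateCols = c(age_at_onset = "numeric"))
clin   <- readMetadata(sim$metaPath, map)
cohort <- stratifyBySV(joinCohort(tally, clin, "ENSG00000107290"), minSV = 3)

armSvCrosstab(cohort)
#>         arm carriers non_carriers total prop_carriers
#> 1   placebo        5           45    50          0.10
#> 2 treatment       36           14    50          0.72

kmStrata(cohort)
#> KMStrata with 4 stratum curves (null-model n = 100 )
#>   placebo/SV: n = 5, events = 5
#>   treatment/SV: n = 36, events = 28
#>   placebo/no-SV: n = 45, events = 43
#>   treatment/no-SV: n = 14, events = 8

fits <- fitStandardAndMultiple(cohort, covariates = "age_at_onset")
hazardRatioTable(fits$standard)[, c("term", "hr_label", "p_value", "pct_effect")]
#>           term hr_label     p_value pct_effect
#> 1          arm     0.39 0.002425988    -60.98%
#> 2      carrier     1.66 0.095846417    +66.43%
#> 3 age_at_onset     1.01 0.328633526     +1.23%
```

Reading the output: only 10% of placebo but 72% of treatment patients carry
≥ 3 SVs in the target gene; the treatment hazard ratio 0.39 means the drug
cuts the instantaneous risk of death by about 61% (the simulator's true
treatment log-HR is −0.7, HR 0.50); carrying SVs raises the hazard (HR
1.66, true value e^0.5 ≈ 1.65); and each additional year of onset age
changes the risk by about +1% in this replicate. The per-unit percent
rendering is exactly how a continuous-covariate HR should be read: an HR of
1.02 per year means one extra year raises the risk of death by two percent.

`runSelect()`, `runKm()` and `runCox()` wrap these stages and write
JSON/TSV reports plus a reproducibility manifest (package version, config,
input checksums) into an output directory.

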
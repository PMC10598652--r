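# Programmatic fixtures shared across test files.

# Small 3-sample VCF with plain GENE annotations; record 2 hits two genes,
# record 4 has no annotation.
writeToyVcf <- function(path = tempfile(fileext = ".vcf")) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End">',
    '##INFO=<ID=GENE,Number=.,Type=String,Description="Genes">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO","FORMAT",
            "S1","S2","S3"), collapse = "\t"),
    "chr9\t1000\tsv1\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=2000;GENE=ENSG00000107290\tGT\t0/1\t0/0\t./.",
    "chr9\t5000\tsv2\tN\t<DUP>\t.\tPASS\tSVTYPE=DUP;END=9000;GENE=ENSG00000107290|ENSG00000142168\tGT\t1/1\t0/1\t0/0",
    "chr1\t100\tsv3\tN\t<INS>\t.\tPASS\tSVTYPE=INS;GENE=ENSG00000142168\tGT\t0/0\t0/0\t0/1",
    "chr2\t500\tsv4\tN\t<INV>\t.\tPASS\tSVTYPE=INV;END=700\tGT\t0/1\t0/1\t0/1"
  )
  writeLines(lines, path)
  path
}

# Metadata matching the toy VCF samples.
writeToyMeta <- function(path = tempfile(fileext = ".csv"),
                         ids = c("S1", "S2", "S3"),
                         arm = c("placebo", "treatment", "treatment"),
                         status = c(1, 0, 1),
                         time = c(2.5, 4.0, 1.2)) {
  d <- data.frame(patient_ID = ids, Phenotype = arm,
                  "survival.status_bin" = status, time = time,
                  age_at_onset = rep_len(c(61.2, 55.0, 48.7, 70.1), length(ids)),
                  check.names = FALSE)
  write.csv(d, path, row.names = FALSE, quote = FALSE)
  path
}

toyColumnMap <- function(covariates = c(age_at_onset = "numeric")) {
  columnMap(idCol = "patient_ID", armCol = "Phenotype",
            eventCol = "survival.status_bin", timeCol = "time",
            timeUnit = "years", covariateCols = covariates)
}

# Random censored survival data with optional ties, used for oracle suites.
randomSurvData <- function(n, tieProb = 0.5, pEvent = 0.7) {
  tm <- if (runif(1) < tieProb) sample(1:8, n, replace = TRUE) else rexp(n, 0.5)
  ev <- rbinom(n, 1, pEvent)
  if (sum(ev) == 0) ev[sample(n, 1)] <- 1L
  list(time = tm, event = ev)
}

# Cohort simulated at small scale and joined through the full pipeline.
simulatedCohort <- function(seed = 3, nPerArm = 50, minSV = 1, svCountMin = 1L) {
  cfg <- trialSimConfig(nPlacebo = nPerArm, nTreatment = nPerArm,
                        svCountMin = svCountMin, seed = seed)
  dir <- tempfile("sim")
  sim <- simulateCohort(cfg, dir = dir)
  vcfPath <- file.path(dir, "cohort.vcf")
  simulateSvVcf(cfg, sim$truth, vcfPath)
  tally <- buildGeneTally(suppressWarnings(readAnnotatedVcf(vcfPath)))
  clinical <- suppressMessages(readMetadata(sim$metaPath, toyColumnMap()))
  cohort <- suppressMessages(
    stratifyBySV(joinCohort(tally, clinical, "ENSG00000107290"),
                 minSV = minSV))
  list(cfg = cfg, sim = sim, tally = tally, clinical = clinical,
       cohort = cohort, dir = dir, vcf = vcfPath)
}
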
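#' @include AllClasses.R AllGenerics.R
NULL

#' Assemble and validate a run configuration
#'
#' A run configuration bundles input paths, the metadata column map, the
#' disease / target-gene selection, the carrier constraint and the model
#' settings into one serializable list consumed by [runSelect()], [runKm()]
#' and [runCox()]. It may be read from a YAML file; explicitly passed
#' arguments override file values.
#'
#' @param file optional YAML file with any of the fields below.
#' @param vcf,tally path to the annotated VCF, or alternatively to a tally
#'   TSV (one of the two is required).
#' @param metadata path to the clinical metadata CSV/TSV.
#' @param registry optional registry TSV path (packaged default otherwise).
#' @param outDir output directory for reports; default `"svsurv_out"`.
#' @param idCol,armCol,eventCol,timeCol,timeUnit column-role mapping; defaults
#'   match the simulator dialect (`patient_ID`, `Phenotype`,
#'   `survival.status_bin`, `time`, years).
#' @param covariates named character vector of covariate kinds, e.g.
#'   `c(age_at_onset = "numeric")`.
#' @param disease,gene selection; `gene` may be omitted in [runSelect()].
#' @param minSV,maxSV carrier constraint (defaults 1 and unbounded).
#' @param confLevel,ties,annotationKey model settings.
#' @return validated config list of class `svsurvConfig`.
#' @export
runConfig <- function(file = NULL, vcf = NULL, tally = NULL, metadata = NULL,
                      registry = NULL, outDir = "svsurv_out",
                      idCol = "patient_ID", armCol = "Phenotype",
                      eventCol = "survival.status_bin", timeCol = "time",
                      timeUnit = "years",
                      covariates = c(age_at_onset = "numeric"),
                      disease = NULL, gene = NULL,
                      minSV = 1, maxSV = Inf,
                      confLevel = 0.95, ties = "efron",
                      annotationKey = "auto") {
  cfg <- as.list(environment())
  cfg$file <- NULL
  if (!is.null(file)) {
    fromFile <- yaml::read_yaml(file)
    passed <- names(as.list(match.call()))[-1]
    for (k in setdiff(names(fromFile), passed)) cfg[[k]] <- fromFile[[k]]
    if (!is.null(cfg$covariates)) cfg$covariates <- unlist(cfg$covariates)
    if (is.null(cfg$maxSV) || identical(cfg$maxSV, "Inf")) cfg$maxSV <- Inf
  }
  if (is.null(cfg$vcf) && is.null(cfg$tally))
    stop("config needs 'vcf' or 'tally'")
  if (is.null(cfg$metadata)) stop("config needs 'metadata'")
  structure(cfg, class = "svsurvConfig")
}

# Shared stage loader: tally + clinical + (optionally) the joined, stratified
# cohort for the configured target gene.
.loadStages <- function(cfg, needGene = TRUE) {
  tally <- if (!is.null(cfg$tally)) readTally(cfg$tally)
           else buildGeneTally(readAnnotatedVcf(cfg$vcf, cfg$annotationKey))
  map <- columnMap(idCol = cfg$idCol, armCol = cfg$armCol,
                   eventCol = cfg$eventCol, timeCol = cfg$timeCol,
                   timeUnit = cfg$timeUnit,
                   covariateCols = if (length(cfg$covariates)) cfg$covariates
                                   else character())
  clinical <- readMetadata(cfg$metadata, map)
  out <- list(tally = tally, clinical = clinical)
  if (needGene) {
    if (is.null(cfg$gene)) stop("config needs 'gene' for this stage")
    cohort <- joinCohort(tally, clinical, cfg$gene)
    out$cohort <- stratifyBySV(cohort, cfg$minSV, cfg$maxSV)
  }
  out
}

.writeReport <- function(cfg, name, json, tsvs = list()) {
  if (!dir.exists(cfg$outDir)) dir.create(cfg$outDir, recursive = TRUE)
  jsonPath <- file.path(cfg$outDir, paste0(name, ".json"))
  jsonlite::write_json(json, jsonPath, digits = NA, auto_unbox = TRUE,
                       pretty = TRUE, na = "null")
  for (nm in names(tsvs))
    utils::write.table(tsvs[[nm]], file.path(cfg$outDir, paste0(nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  .writeManifest(cfg, name)
  invisible(jsonPath)
}

# Reproducibility manifest: package version, config, input checksums.
.writeManifest <- function(cfg, name) {
  inputs <- Filter(Negate(is.null),
                   list(vcf = cfg$vcf, tally = cfg$tally,
                        metadata = cfg$metadata, registry = cfg$registry))
  manifest <- list(
    report = name,
    package = "svSurv",
    version = as.character(utils::packageVersion("svSurv")),
    config = lapply(unclass(cfg), function(x)
      if (identical(x, Inf)) "Inf" else x),
    input_md5 = lapply(inputs, function(p) unname(tools::md5sum(p)))
  )
  jsonlite::write_json(manifest,
                       file.path(cfg$outDir, paste0(name, ".manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

#' Target-gene selection report
#'
#' The first workflow stage: the per-gene carrier summary of the configured
#' disease panel and — when a target gene is configured — the arm-by-carrier
#' cross-tabulation and the per-arm SV-count histogram. Written as JSON plus
#' TSV tables with a reproducibility manifest.
#'
#' @param cfg a [runConfig()] list.
#' @return the report content, invisibly (list with `gene_table`, and with a
#'   gene also `crosstab` and `histogram`).
#' @export
runSelect <- function(cfg) {
  stages <- .loadStages(cfg, needGene = FALSE)
  report <- list()
  tsvs <- list()
  if (!is.null(cfg$disease)) {
    reg <- if (!is.null(cfg$registry)) loadRegistry(cfg$registry) else loadRegistry()
    report$disease <- cfg$disease
    report$gene_table <- diseaseSummary(stages$tally, reg, cfg$disease,
                                        stages$clinical)
    tsvs$gene_table <- report$gene_table
  }
  if (!is.null(cfg$gene)) {
    cohort <- stratifyBySV(joinCohort(stages$tally, stages$clinical, cfg$gene),
                           cfg$minSV, cfg$maxSV)
    report$target_gene <- cfg$gene
    report$crosstab <- armSvCrosstab(cohort)
    report$histogram <- svCountHistogram(cohort)
    report$excluded <- excludedIds(cohort)
    tsvs$crosstab <- report$crosstab
    tsvs$histogram <- report$histogram
  }
  .writeReport(cfg, "select_report", report, tsvs)
  invisible(report)
}

#' Kaplan-Meier report
#'
#' The second workflow stage: the pooled null-model curve, the four
#' (arm x carrier) stratified curves with confidence intervals, the two-panel
#' life table, the risk table at round time points and the pairwise log-rank
#' comparisons. Written as JSON plus TSV tables with a manifest.
#'
#' @param cfg a [runConfig()] list.
#' @param confInt include confidence-interval columns (default TRUE).
#' @return invisibly, a list with `strata` (the [KMStrata-class]),
#'   `life_table`, `risk_table` and `pairwise`.
#' @export
runKm <- function(cfg, confInt = TRUE) {
  stages <- .loadStages(cfg)
  strata <- kmStrata(stages$cohort, confLevel = cfg$confLevel)
  lt <- cohortLifeTable(strata)
  if (!confInt) lt <- lt[, setdiff(names(lt), c("ci_lower", "ci_upper"))]
  rt <- riskTable(strata)
  curveJson <- lapply(strata@curves, function(cu) {
    out <- lifeTable(cu)
    if (!confInt) out <- out[, setdiff(names(out), c("ci_lower", "ci_upper"))]
    out
  })
  nullJson <- lifeTable(strata@null)
  if (!confInt) nullJson <- nullJson[, setdiff(names(nullJson), c("ci_lower", "ci_upper"))]
  report <- list(target_gene = targetGene(stages$cohort),
                 time_unit = timeUnit(stages$cohort),
                 null_model = nullJson,
                 strata = curveJson,
                 pairwise_logrank = strata@pairwise,
                 risk_table = rt)
  .writeReport(cfg, "km_report", report,
               list(life_table = lt, risk_table = rt,
                    pairwise_logrank = strata@pairwise))
  invisible(list(strata = strata, life_table = lt, risk_table = rt,
                 pairwise = strata@pairwise))
}

#' Cox regression report
#'
#' The third workflow stage: hazard-ratio tables with convergence diagnostics
#' for the Standard model (all analyzed patients; arm + carrier + covariates)
#' and the Multiple models (carrier and non-carrier subsets; arm +
#' covariates). Subsets that are not estimable are marked, not raised.
#'
#' @param cfg a [runConfig()] list.
#' @param covariates covariate names to include; defaults to all configured
#'   covariate columns.
#' @return invisibly, a list with the three fits and their hazard-ratio
#'   tables.
#' @export
runCox <- function(cfg, covariates = names(cfg$covariates)) {
  stages <- .loadStages(cfg)
  fits <- fitStandardAndMultiple(stages$cohort, covariates = covariates,
                                 ties = cfg$ties, confLevel = cfg$confLevel)
  tables <- lapply(fits, hazardRatioTable)
  diag <- lapply(fits, function(f) {
    if (!is(f, "CoxFit"))
      list(estimable = FALSE, reason = attr(f, "reason"))
    else list(estimable = TRUE, converged = f@converged,
              monotone = f@monotone, iterations = f@iter,
              n = f@n, n_events = f@nEvent, ties = f@ties,
              loglik_null = f@loglik[1], loglik = f@loglik[2])
  })
  report <- list(target_gene = targetGene(stages$cohort),
                 time_unit = timeUnit(stages$cohort),
                 standard = tables$standard,
                 multiple_carrier = tables$multiple_carrier,
                 multiple_noncarrier = tables$multiple_noncarrier,
                 diagnostics = diag)
  .writeReport(cfg, "cox_report", report,
               list(hr_standard = tables$standard,
                    hr_multiple_carrier = tables$multiple_carrier,
                    hr_multiple_noncarrier = tables$multiple_noncarrier))
  invisible(list(fits = fits, tables = tables, diagnostics = diag))
}
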
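#' @import methods
NULL

# Central S4 containers. Validity methods enforce the structural invariants so
# that downstream estimators can assume well-formed inputs.

#' Set of annotated structural-variant calls
#'
#' One object per multi-sample VCF: per-record coordinates, SV type, the set of
#' Ensembl gene identifiers each record is annotated with, and the genotype
#' (GT) matrix aligned to the VCF sample header order. Coordinates stay in the
#' VCF 1-based convention; breakend (BND) records carry `end == pos`.
#'
#' @slot chrom character, chromosome per record.
#' @slot pos integer, 1-based start per record.
#' @slot end integer, 1-based inclusive end (INFO END, or `pos` when absent).
#' @slot svType character, one of DEL, DUP, INS, INV, BND, other.
#' @slot geneIds list of character vectors, Ensembl gene ids per record
#'   (may be empty: the record then contributes to no tally cell).
#' @slot genotypes character matrix, records x samples, GT strings.
#' @slot samples character, sample identifiers in header order.
#' @slot nUnannotated integer, count of records lacking the annotation key.
#' @export
setClass("SVCallSet",
  representation(
    chrom = "character",
    pos = "integer",
    end = "integer",
    svType = "character",
    geneIds = "list",
    genotypes = "matrix",
    samples = "character",
    nUnannotated = "integer"
  )
)

setValidity("SVCallSet", function(object) {
  n <- length(object@pos)
  msg <- character()
  if (length(object@chrom) != n || length(object@end) != n ||
      length(object@svType) != n || length(object@geneIds) != n)
    msg <- c(msg, "per-record slots must have equal length")
  if (n > 0 && any(object@pos < 1L)) msg <- c(msg, "pos must be >= 1")
  nonbnd <- object@svType != "BND"
  if (n > 0 && any(object@end[nonbnd] < object@pos[nonbnd]))
    msg <- c(msg, "end must be >= pos for non-BND records")
  if (n > 0 && (nrow(object@genotypes) != n ||
                ncol(object@genotypes) != length(object@samples)))
    msg <- c(msg, "genotype matrix must be records x samples")
  if (length(msg)) msg else TRUE
})

#' Sample-by-gene structural-variant count tally
#'
#' `counts[s, g]` is the number of SV records in which sample `s` carries at
#' least one alternate allele and the record is annotated with gene `g`. One
#' record increments a (sample, gene) cell at most once, regardless of allele
#' copy number.
#'
#' @slot counts integer matrix with sample rownames and gene colnames;
#'   genes are sorted lexicographically.
#' @export
setClass("GeneTally", representation(counts = "matrix"))

setValidity("GeneTally", function(object) {
  m <- object@counts
  msg <- character()
  if (!is.numeric(m)) msg <- c(msg, "counts must be numeric")
  else {
    if (any(m < 0)) msg <- c(msg, "counts must be non-negative")
    if (any(m != round(m))) msg <- c(msg, "counts must be integers")
  }
  if (nrow(m) > 0 && is.null(rownames(m))) msg <- c(msg, "sample rownames required")
  if (ncol(m) > 0 && is.null(colnames(m))) msg <- c(msg, "gene colnames required")
  if (ncol(m) > 1 && is.unsorted(colnames(m))) msg <- c(msg, "genes must be sorted")
  if (anyDuplicated(rownames(m))) msg <- c(msg, "duplicated sample ids")
  if (length(msg)) msg else TRUE
})

#' Column-role map for clinical metadata
#'
#' Maps user-named metadata columns onto the four mandatory semantic roles
#' (patient id, trial arm, event status, time to event) plus optional
#' covariates. The time unit is a label used in reports and for interpreting
#' per-unit hazard ratios; no unit conversion is performed.
#'
#' @slot idCol,armCol,eventCol,timeCol character, column names.
#' @slot timeUnit character, one of days, weeks, months, years.
#' @slot covariateCols named character vector: names are column names, values
#'   are "numeric" or "categorical".
#' @export
setClass("ColumnMap",
  representation(
    idCol = "character", armCol = "character", eventCol = "character",
    timeCol = "character", timeUnit = "character",
    covariateCols = "character"
  )
)

setValidity("ColumnMap", function(object) {
  msg <- character()
  cols <- c(object@idCol, object@armCol, object@eventCol, object@timeCol,
            names(object@covariateCols))
  if (anyDuplicated(cols))
    msg <- c(msg, sprintf("mapped columns must be distinct (duplicated: %s)",
                          paste(unique(cols[duplicated(cols)]), collapse = ", ")))
  if (!object@timeUnit %in% c("days", "weeks", "months", "years"))
    msg <- c(msg, "timeUnit must be one of days, weeks, months, years")
  if (length(object@covariateCols) &&
      !all(object@covariateCols %in% c("numeric", "categorical")))
    msg <- c(msg, "covariate kinds must be 'numeric' or 'categorical'")
  if (length(msg)) msg else TRUE
})

#' Validated clinical-trial metadata
#'
#' Standardized patient table after role mapping and binary coercion:
#' `arm` (0 = placebo/reference, 1 = treatment), `event` (1 = event observed,
#' 0 = censored), `time` (> 0, in `timeUnit`), plus covariate columns under
#' their original names.
#'
#' @slot data data.frame keyed by unique `patient_id`.
#' @slot timeUnit character label.
#' @slot armLevels,eventLevels named character vectors recording which original
#'   level was mapped to "0" and to "1".
#' @slot covariateKinds named character vector as in [columnMap()].
#' @export
setClass("ClinicalTable",
  representation(
    data = "data.frame",
    timeUnit = "character",
    armLevels = "character",
    eventLevels = "character",
    covariateKinds = "character"
  )
)

setValidity("ClinicalTable", function(object) {
  d <- object@data
  msg <- character()
  need <- c("patient_id", "arm", "event", "time")
  if (!all(need %in% names(d)))
    msg <- c(msg, paste("missing columns:", paste(setdiff(need, names(d)), collapse = ", ")))
  else {
    if (anyDuplicated(d$patient_id))
      msg <- c(msg, "patient ids must be unique")
    if (!all(d$arm %in% c(0L, 1L)) || !all(d$event %in% c(0L, 1L)))
      msg <- c(msg, "arm and event must be strictly binary (0/1)")
    if (any(!is.finite(d$time)) || any(d$time <= 0))
      msg <- c(msg, "time must be positive and finite")
  }
  if (length(msg)) msg else TRUE
})

#' Analysis cohort: clinical rows joined with the SV tally for one target gene
#'
#' Extends [ClinicalTable-class] with `sv_count` (SV records in the target
#' gene) and `carrier` (TRUE iff `minSV <= sv_count <= maxSV`). Patients with
#' `0 < sv_count < minSV` or `sv_count > maxSV` are excluded from stratified
#' analyses (never silently relabelled as non-carriers); their ids are kept in
#' `excluded`. `sv_count == 0` always means non-carrier.
#'
#' @slot targetGene character, gene identifier the counts refer to.
#' @slot minSV,maxSV numeric carrier-constraint bounds (maxSV may be `Inf`).
#' @slot excluded character, patient ids outside the constraint window.
#' @export
setClass("CohortFrame",
  contains = "ClinicalTable",
  representation(
    targetGene = "character",
    minSV = "numeric",
    maxSV = "numeric",
    excluded = "character"
  )
)

setValidity("CohortFrame", function(object) {
  d <- object@data
  msg <- character()
  if (!all(c("sv_count", "carrier") %in% names(d)))
    msg <- c(msg, "cohort data must carry sv_count and carrier columns")
  else if (any(d$sv_count < 0)) msg <- c(msg, "sv_count must be non-negative")
  if (object@minSV < 1) msg <- c(msg, "minSV must be >= 1")
  if (is.finite(object@maxSV) && object@maxSV < object@minSV)
    msg <- c(msg, "maxSV must be >= minSV")
  if (length(msg)) msg else TRUE
})

#' Disease-to-gene registry (ClinGen-style panels)
#'
#' Static mapping from disease names to associated genes with a gene-disease
#' validity classification. Loaded from a flat TSV; the packaged default is an
#' illustrative, non-clinical panel set (see `inst/extdata`).
#'
#' @slot entries data.frame with columns disease, gene_symbol,
#'   ensembl_gene_id, classification.
#' @export
setClass("DiseaseGeneRegistry", representation(entries = "data.frame"))

setValidity("DiseaseGeneRegistry", function(object) {
  e <- object@entries
  need <- c("disease", "gene_symbol", "ensembl_gene_id", "classification")
  if (!all(need %in% names(e)))
    return(paste("registry must have columns:", paste(need, collapse = ", ")))
  if (any(!nzchar(e$ensembl_gene_id)))
    return("every entry needs a non-empty ensembl_gene_id")
  TRUE
})

#' Kaplan-Meier product-limit curve
#'
#' Survival estimates at the distinct observed times, with at-risk/event/
#' censoring counts, Greenwood standard errors and pointwise confidence
#' bounds. Ties follow the standard product-limit convention: at equal times,
#' events precede censorings, so subjects censored at an event time remain at
#' risk for it.
#'
#' @slot time sorted distinct observed times.
#' @slot nRisk,nEvent,nCensor integer vectors per time.
#' @slot surv product-limit estimate S(t).
#' @slot stdErr Greenwood standard error of S(t).
#' @slot lower,upper pointwise confidence bounds at `confLevel`.
#' @slot confLevel,confType confidence level and transform ("log-log" or
#'   "plain").
#' @slot n number of subjects entering at time 0.
#' @slot label stratum label (e.g. arm x carrier), possibly empty.
#' @export
setClass("KMCurve",
  representation(
    time = "numeric", nRisk = "integer", nEvent = "integer",
    nCensor = "integer", surv = "numeric", stdErr = "numeric",
    lower = "numeric", upper = "numeric",
    confLevel = "numeric", confType = "character",
    n = "integer", label = "character"
  )
)

setValidity("KMCurve", function(object) {
  msg <- character()
  k <- length(object@time)
  if (any(lengths(list(object@nRisk, object@nEvent, object@nCensor,
                       object@surv, object@stdErr)) != k))
    msg <- c(msg, "per-time slots must have equal length")
  if (k > 0) {
    if (is.unsorted(object@time, strictly = TRUE)) msg <- c(msg, "times must be strictly increasing")
    if (any(object@surv < -1e-12 | object@surv > 1 + 1e-12)) msg <- c(msg, "S must lie in [0, 1]")
    if (any(diff(object@surv) > 1e-12)) msg <- c(msg, "S must be non-increasing")
    if (any(diff(-object@nRisk) < 0)) msg <- c(msg, "at-risk counts must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' Two-group log-rank test result
#'
#' Observed and expected event counts per group over the pooled distinct event
#' times, hypergeometric variance, and the 1-df chi-square statistic.
#'
#' @slot observed,expected length-2 numeric (groups A, B).
#' @slot var hypergeometric variance of O_A - E_A.
#' @slot chisq,df,pValue test statistic, degrees of freedom (1), p-value.
#' @export
setClass("LogRankResult",
  representation(
    observed = "numeric", expected = "numeric", var = "numeric",
    chisq = "numeric", df = "integer", pValue = "numeric"
  )
)

setValidity("LogRankResult", function(object) {
  msg <- character()
  if (abs(sum(object@observed) - sum(object@expected)) > 1e-8)
    msg <- c(msg, "total observed must equal total expected events")
  if (object@chisq < 0) msg <- c(msg, "chi-square must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Cox proportional-hazards fit
#'
#' Maximum partial-likelihood estimates for h(t|x) = h0(t) exp(x'beta) with
#' Efron (default) or Breslow handling of tied event times. Standard errors
#' come from the inverse observed information; Wald confidence intervals are
#' exp(beta +/- z * se). Monotone likelihood (complete separation) is flagged,
#' not raised.
#'
#' @slot coef,hr,se,z,pValue,ciLower,ciUpper per-term vectors (hr = exp(coef)).
#' @slot loglik length-2: partial log-likelihood at beta = 0 and at
#'   convergence.
#' @slot n,nEvent subjects and events used.
#' @slot ties "efron" or "breslow".
#' @slot converged,monotone logical diagnostics.
#' @slot iter Newton-Raphson iterations used.
#' @slot confLevel confidence level of the Wald intervals.
#' @slot config one of "standard", "multiple:carrier", "multiple:noncarrier",
#'   or "" for a bare fit.
#' @export
setClass("CoxFit",
  representation(
    coef = "numeric", hr = "numeric", se = "numeric", z = "numeric",
    pValue = "numeric", ciLower = "numeric", ciUpper = "numeric",
    loglik = "numeric", n = "integer", nEvent = "integer",
    ties = "character", converged = "logical", monotone = "logical",
    iter = "integer", confLevel = "numeric", config = "character"
  )
)

setValidity("CoxFit", function(object) {
  msg <- character()
  if (any(object@hr <= 0)) msg <- c(msg, "hazard ratios must be positive")
  if (length(object@loglik) == 2 && object@converged &&
      object@loglik[2] < object@loglik[1] - 1e-8)
    msg <- c(msg, "converged log-likelihood cannot be below the null value")
  if (length(msg)) msg else TRUE
})

#' Stratified Kaplan-Meier result
#'
#' Up to four curves keyed by (arm, carrier), the pooled null-model curve, and
#' pairwise log-rank comparisons between non-empty strata.
#'
#' @slot curves named list of [KMCurve-class], one per non-empty stratum.
#' @slot null pooled [KMCurve-class] over the whole cohort.
#' @slot pairwise data.frame of pairwise log-rank results (may have 0 rows
#'   when fewer than two strata are non-empty).
#' @export
setClass("KMStrata",
  representation(curves = "list", null = "KMCurve", pairwise = "data.frame")
)

#' Two-arm trial simulation configuration
#'
#' Study-design parameters for the simulator: arm sizes, exponential baseline
#' hazard, log hazard ratios for treatment, SV-carrier status and age,
#' per-arm carrier fractions, the SV-count law (minimum count plus a Poisson
#' excess), a truncated-normal age law, administrative censoring time and the
#' RNG seed. Fully deterministic given the seed.
#'
#' @slot nPlacebo,nTreatment arm sizes.
#' @slot baselineHazard events per time unit for a reference patient.
#' @slot logHrTreatment,logHrCarrier,logHrAge log hazard ratios (age per year,
#'   centred at `ageMean`).
#' @slot carrierFraction named numeric, carrier probability per arm
#'   (names "placebo", "treatment").
#' @slot svCountMean Poisson mean of the SV-count excess above `svCountMin`.
#' @slot svCountMin minimum SV count of a carrier (>= 1).
#' @slot ageMean,ageSd age-at-onset law, truncated at >= 18 years.
#' @slot censorTime administrative cutoff in time units.
#' @slot seed integer RNG seed.
#' @export
setClass("TrialSimConfig",
  representation(
    nPlacebo = "integer", nTreatment = "integer",
    baselineHazard = "numeric",
    logHrTreatment = "numeric", logHrCarrier = "numeric", logHrAge = "numeric",
    carrierFraction = "numeric",
    svCountMean = "numeric", svCountMin = "integer",
    ageMean = "numeric", ageSd = "numeric",
    censorTime = "numeric", seed = "integer"
  )
)

setValidity("TrialSimConfig", function(object) {
  msg <- character()
  if (object@nPlacebo < 1L || object@nTreatment < 1L) msg <- c(msg, "arm sizes must be >= 1")
  if (object@baselineHazard <= 0) msg <- c(msg, "baselineHazard must be > 0")
  cf <- object@carrierFraction
  if (!all(c("placebo", "treatment") %in% names(cf)))
    msg <- c(msg, "carrierFraction needs named entries 'placebo' and 'treatment'")
  else if (any(cf < 0 | cf > 1)) msg <- c(msg, "carrierFraction must lie in [0, 1]")
  if (object@svCountMin < 1L) msg <- c(msg, "svCountMin must be >= 1")
  if (object@svCountMean < 0) msg <- c(msg, "svCountMean must be >= 0")
  if (object@censorTime <= 0) msg <- c(msg, "censorTime must be > 0")
  if (object@ageSd <= 0) msg <- c(msg, "ageSd must be > 0")
  if (length(msg)) msg else TRUE
})
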
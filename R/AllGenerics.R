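#' @include AllClasses.R
NULL

#' Sample identifiers
#' @param object an object with samples.
#' @return character vector of sample/patient identifiers.
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' Gene identifiers
#' @param object an object with genes.
#' @return character vector of gene identifiers.
#' @export
setGeneric("geneIds", function(object) standardGeneric("geneIds"))

#' SV count matrix
#' @param object a [GeneTally-class].
#' @return integer matrix, samples x genes.
#' @export
setGeneric("tallyCounts", function(object) standardGeneric("tallyCounts"))

#' Clinical data as a data.frame
#' @param object a [ClinicalTable-class] or [CohortFrame-class].
#' @return the standardized patient data.frame.
#' @export
setGeneric("clinicalData", function(object) standardGeneric("clinicalData"))

#' Time-unit label
#' @param object a [ClinicalTable-class].
#' @return the declared time unit ("days", "weeks", "months" or "years").
#' @export
setGeneric("timeUnit", function(object) standardGeneric("timeUnit"))

#' Target gene of a cohort
#' @param object a [CohortFrame-class].
#' @return the gene identifier the SV counts refer to.
#' @export
setGeneric("targetGene", function(object) standardGeneric("targetGene"))

#' Excluded patient ids
#'
#' Patients whose non-zero SV count falls outside the active
#' `[minSV, maxSV]` carrier constraint; they take part in no stratified
#' analysis.
#' @param object a [CohortFrame-class].
#' @return character vector of patient ids.
#' @export
setGeneric("excludedIds", function(object) standardGeneric("excludedIds"))

#' Life table of a fitted curve
#'
#' Tabulates a Kaplan-Meier curve exactly: one row per distinct observed
#' time with at-risk, event and censoring counts, the survival estimate,
#' its Greenwood standard error and the confidence bounds.
#' @param object a [KMCurve-class].
#' @return data.frame with columns time, n_at_risk, n_events, n_censored,
#'   survival, std_err, ci_lower, ci_upper.
#' @export
setGeneric("lifeTable", function(object) standardGeneric("lifeTable"))

#' Registry diseases
#' @param object a [DiseaseGeneRegistry-class].
#' @return sorted character vector of disease names.
#' @export
setGeneric("diseases", function(object) standardGeneric("diseases"))

#' Gene panel for one disease
#' @param object a [DiseaseGeneRegistry-class].
#' @param disease disease name.
#' @return data.frame of panel entries for `disease`.
#' @export
setGeneric("genePanel", function(object, disease) standardGeneric("genePanel"))
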
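#' @include AllClasses.R AllGenerics.R
NULL

#' Load a disease-to-gene registry
#'
#' Reads a flat TSV mapping diseases to associated genes, in the style of
#' ClinGen gene-disease validity panels. The packaged default covers four
#' neurodegenerative panels (amyotrophic lateral sclerosis, Charcot-Marie-
#' Tooth, Alzheimer disease, Parkinson disease) and is an illustrative,
#' versioned snapshot for demonstration — not a clinical resource and never
#' fetched from the network.
#'
#' @param path registry TSV with columns `disease`, `gene_symbol`,
#'   `ensembl_gene_id`, `classification`; defaults to the packaged file.
#' @return a [DiseaseGeneRegistry-class]. Duplicate (disease, gene) rows are
#'   deduplicated with a warning.
#' @examples
#' reg <- loadRegistry()
#' diseases(reg)
#' genePanel(reg, "Charcot-Marie-Tooth")
#' @export
loadRegistry <- function(path = system.file("extdata", "disease_gene_registry.tsv",
                                            package = "svSurv")) {
  if (!file.exists(path)) stop("registry file not found: ", path)
  e <- utils::read.table(path, header = TRUE, sep = "\t",
                         stringsAsFactors = FALSE, quote = "", comment.char = "")
  need <- c("disease", "gene_symbol", "ensembl_gene_id", "classification")
  missing <- setdiff(need, names(e))
  if (length(missing))
    stop("registry lacks column(s): ", paste(missing, collapse = ", "))
  key <- paste(e$disease, e$ensembl_gene_id)
  if (anyDuplicated(key)) {
    warning("registry has ", sum(duplicated(key)),
            " duplicate (disease, gene) row(s); deduplicated")
    e <- e[!duplicated(key), , drop = FALSE]
  }
  new("DiseaseGeneRegistry", entries = e)
}

#' @describeIn loadRegistry sorted disease names present in the registry.
#' @export
setMethod("diseases", "DiseaseGeneRegistry",
          function(object) sort(unique(object@entries$disease)))

#' @describeIn loadRegistry panel rows for one disease; an unknown disease is
#'   an error that lists the available diseases.
#' @export
setMethod("genePanel", "DiseaseGeneRegistry", function(object, disease) {
  hit <- object@entries$disease == disease
  if (!any(hit))
    stop("disease '", disease, "' not in registry; available: ",
         paste(diseases(object), collapse = ", "))
  object@entries[hit, , drop = FALSE]
})

setMethod("show", "DiseaseGeneRegistry", function(object) {
  cat("DiseaseGeneRegistry:", length(diseases(object)), "diseases,",
      nrow(object@entries), "gene entries\n")
  for (d in diseases(object))
    cat("  ", d, ": ", sum(object@entries$disease == d), " genes\n", sep = "")
})

#' Per-gene carrier summary for a disease panel
#'
#' For every gene associated with the selected disease, counts the trial
#' participants whose genomes carry at least one SV in that gene (carrier
#' means `sv_count >= 1` for this summary), split by trial arm. Panel genes
#' absent from the VCF annotations are reported with zero counts and an
#' `annotated = FALSE` flag.
#'
#' @param tally a [GeneTally-class].
#' @param registry a [DiseaseGeneRegistry-class].
#' @param disease disease name present in the registry.
#' @param clinical a [ClinicalTable-class] (supplies arm labels; only patients
#'   present in both tally and metadata are counted).
#' @return data.frame with columns gene_symbol, ensembl_gene_id,
#'   classification, annotated, n_carriers, n_placebo_carriers,
#'   n_treatment_carriers.
#' @export
diseaseSummary <- function(tally, registry, disease, clinical) {
  stopifnot(is(tally, "GeneTally"), is(registry, "DiseaseGeneRegistry"),
            is(clinical, "ClinicalTable"))
  panel <- genePanel(registry, disease)
  if (!nrow(panel)) {
    warning("disease '", disease, "' has an empty gene panel")
    return(data.frame(gene_symbol = character(), ensembl_gene_id = character(),
                      classification = character(), annotated = logical(),
                      n_carriers = integer(), n_placebo_carriers = integer(),
                      n_treatment_carriers = integer()))
  }
  d <- clinical@data
  ids <- intersect(d$patient_id, sampleIds(tally))
  arm <- stats::setNames(d$arm, d$patient_id)[ids]
  counts <- tallyCounts(tally)[ids, , drop = FALSE]
  out <- panel[, c("gene_symbol", "ensembl_gene_id", "classification")]
  out$annotated <- out$ensembl_gene_id %in% geneIds(tally)
  n_car <- n_pla <- n_trt <- integer(nrow(out))
  for (i in seq_len(nrow(out))) {
    g <- out$ensembl_gene_id[i]
    if (!out$annotated[i]) next
    carrier <- counts[, g] >= 1L
    n_car[i] <- sum(carrier)
    n_pla[i] <- sum(carrier & arm == 0L)
    n_trt[i] <- sum(carrier & arm == 1L)
  }
  out$n_carriers <- n_car
  out$n_placebo_carriers <- n_pla
  out$n_treatment_carriers <- n_trt
  rownames(out) <- NULL
  out
}
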
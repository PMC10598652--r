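#' @include AllClasses.R AllGenerics.R
NULL

#' Declare the semantic roles of metadata columns
#'
#' @param idCol,armCol,eventCol,timeCol names of the patient-id, trial-arm,
#'   event-status and time-to-event columns.
#' @param timeUnit unit label of the time column ("days", "weeks", "months",
#'   "years"). Used for reporting and per-unit hazard-ratio interpretation
#'   only; no conversion is done.
#' @param covariateCols named character vector mapping covariate column names
#'   to their kind, e.g. `c(age_at_onset = "numeric", sex = "categorical")`.
#' @return a [ColumnMap-class].
#' @examples
#' columnMap(idCol = "patient_ID", armCol = "Phenotype",
#'           eventCol = "survival.status_bin", timeCol = "time",
#'           timeUnit = "years",
#'           covariateCols = c(age_at_onset = "numeric"))
#' @export
columnMap <- function(idCol, armCol, eventCol, timeCol,
                      timeUnit = c("years", "days", "weeks", "months"),
                      covariateCols = character()) {
  timeUnit <- match.arg(timeUnit)
  new("ColumnMap", idCol = idCol, armCol = armCol, eventCol = eventCol,
      timeCol = timeCol, timeUnit = timeUnit,
      covariateCols = covariateCols)
}

# Coerce a two-level column to 0/1. Unless an explicit levelMap
# (c("0" = levelA, "1" = levelB)) is given, the lexicographically larger
# level becomes 1 — e.g. treatment > placebo, dead > alive, 1 > 0 — and the
# chosen mapping is echoed so it is auditable.
.coerceBinary <- function(x, what, levelMap = NULL) {
  lev <- sort(unique(as.character(x)))
  if (length(lev) > 2L)
    stop(what, " column must be binary; found ", length(lev), " levels: ",
         paste(lev, collapse = ", "), call. = FALSE)
  if (length(lev) < 1L) stop(what, " column has no non-missing values", call. = FALSE)
  if (!is.null(levelMap)) {
    if (!all(lev %in% levelMap))
      stop(what, " levels (", paste(lev, collapse = ", "),
           ") not covered by the supplied level map", call. = FALSE)
    map <- stats::setNames(as.integer(names(levelMap)), levelMap)
  } else {
    map <- stats::setNames(seq_along(lev) - 1L, lev)
    if (length(lev) == 1L) map[] <- 0L
  }
  message(what, " levels mapped: ",
          paste(names(map), map, sep = " -> ", collapse = ", "))
  list(values = unname(map[as.character(x)]),
       levels = stats::setNames(names(map), map))
}

#' Read and validate clinical-trial metadata
#'
#' Reads a CSV/TSV metadata table, maps the user-named columns onto semantic
#' roles via the [columnMap()], coerces the arm and event columns from any
#' two-level encoding to strict 0/1 (reporting the mapping), and validates
#' patient-id uniqueness, positive times, and the absence of missing values in
#' the four mandatory roles.
#'
#' @param path CSV or TSV file (format detected from the extension:
#'   `.tsv`/`.txt` is tab-separated, otherwise comma-separated).
#' @param map a [ColumnMap-class].
#' @param sep optional explicit field separator overriding detection.
#' @param armLevelMap,eventLevelMap optional explicit level maps, e.g.
#'   `c("0" = "placebo", "1" = "treatment")`.
#' @return a [ClinicalTable-class].
#' @export
readMetadata <- function(path, map, sep = NULL,
                         armLevelMap = NULL, eventLevelMap = NULL) {
  stopifnot(is(map, "ColumnMap"))
  if (!file.exists(path)) stop("metadata file not found: ", path)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c(map@idCol, map@armCol, map@eventCol, map@timeCol,
            names(map@covariateCols))
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("metadata lacks mapped column(s): ", paste(missing, collapse = ", "))

  id <- as.character(raw[[map@idCol]])
  if (anyNA(id) || any(!nzchar(id))) stop("missing patient ids in metadata")
  dup <- unique(id[duplicated(id)])
  if (length(dup))
    stop("duplicate patient id(s): ", paste(dup, collapse = ", "))

  for (col in c(map@armCol, map@eventCol, map@timeCol))
    if (anyNA(raw[[col]]))
      stop("missing values in mandatory column '", col, "'")

  arm <- .coerceBinary(raw[[map@armCol]], paste0("arm ('", map@armCol, "')"),
                       armLevelMap)
  evt <- .coerceBinary(raw[[map@eventCol]], paste0("event ('", map@eventCol, "')"),
                       eventLevelMap)

  time <- suppressWarnings(as.numeric(raw[[map@timeCol]]))
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad))
    stop("non-positive or non-numeric time in row(s): ",
         paste(utils::head(bad, 10), collapse = ", "))

  d <- data.frame(patient_id = id, arm = arm$values, event = evt$values,
                  time = time, stringsAsFactors = FALSE)
  for (cov in names(map@covariateCols)) {
    v <- raw[[cov]]
    if (map@covariateCols[[cov]] == "numeric") {
      v <- suppressWarnings(as.numeric(v))
      if (anyNA(v)) stop("non-numeric values in numeric covariate '", cov, "'")
    } else v <- as.character(v)
    d[[cov]] <- v
  }
  new("ClinicalTable", data = d, timeUnit = map@timeUnit,
      armLevels = arm$levels, eventLevels = evt$levels,
      covariateKinds = map@covariateCols)
}

#' Join clinical metadata with the SV tally for one target gene
#'
#' Produces one cohort row per clinical patient with `sv_count` pulled from
#' the tally by patient id. Patients present in the metadata but absent from
#' the VCF get `sv_count = 0` with a warning (and samples in the VCF missing
#' from the metadata are reported too); a target gene absent from the tally
#' yields all-zero counts with a warning. Zero id overlap is a hard error, as
#' it almost always signals an id-scheme mismatch.
#'
#' The returned cohort carries the default carrier stratification
#' (`minSV = 1`, unbounded `maxSV`): carrier iff `sv_count >= 1`.
#'
#' @param tally a [GeneTally-class].
#' @param clinical a [ClinicalTable-class].
#' @param gene target gene identifier.
#' @return a [CohortFrame-class].
#' @export
joinCohort <- function(tally, clinical, gene) {
  stopifnot(is(tally, "GeneTally"), is(clinical, "ClinicalTable"),
            is.character(gene), length(gene) == 1L)
  d <- clinical@data
  if (!gene %in% geneIds(tally)) {
    warning("target gene ", gene, " is not annotated in the tally; all sv_count = 0")
    counts <- stats::setNames(integer(length(sampleIds(tally))), sampleIds(tally))
  } else {
    counts <- tallyCounts(tally)[, gene]
  }
  hit <- d$patient_id %in% names(counts)
  if (!any(hit))
    stop("no overlap between tally samples and clinical patient ids ",
         "(id-scheme mismatch?)")
  if (any(!hit))
    warning(sum(!hit), " patient(s) absent from the VCF get sv_count = 0: ",
            paste(utils::head(d$patient_id[!hit], 5), collapse = ", "))
  extra <- setdiff(names(counts), d$patient_id)
  if (length(extra))
    warning(length(extra), " VCF sample(s) have no clinical metadata and are dropped")

  d$sv_count <- ifelse(hit, unname(counts[d$patient_id]), 0L)
  d$carrier <- d$sv_count >= 1L
  new("CohortFrame", data = d, timeUnit = clinical@timeUnit,
      armLevels = clinical@armLevels, eventLevels = clinical@eventLevels,
      covariateKinds = clinical@covariateKinds,
      targetGene = gene, minSV = 1, maxSV = Inf, excluded = character())
}

#' Stratify a cohort by SV-carrier status under a count constraint
#'
#' Sets `carrier = (minSV <= sv_count <= maxSV)`. Patients with a non-zero
#' count outside the window are excluded from stratified analyses rather than
#' relabelled as non-carriers (treating, say, a 2-SV patient as SV-free when
#' `minSV = 3` would contaminate the reference group); `sv_count = 0` always
#' means non-carrier. The disposition counts are reported via `message()`.
#'
#' @param cohort a [CohortFrame-class].
#' @param minSV minimum SV count of a carrier (>= 1).
#' @param maxSV maximum SV count of a carrier (default unbounded).
#' @return the re-stratified [CohortFrame-class].
#' @export
stratifyBySV <- function(cohort, minSV = 1, maxSV = Inf) {
  stopifnot(is(cohort, "CohortFrame"))
  if (minSV < 1) stop("minSV must be >= 1")
  if (is.finite(maxSV) && maxSV < minSV) stop("maxSV must be >= minSV")
  d <- cohort@data
  d$carrier <- d$sv_count >= minSV & d$sv_count <= maxSV
  excluded <- d$patient_id[d$sv_count > 0 & !d$carrier]
  if (length(excluded) == nrow(d))
    stop("the [minSV, maxSV] constraint excludes every patient")
  message(sum(d$carrier), " carriers, ",
          sum(d$sv_count == 0), " non-carriers, ",
          length(excluded), " excluded (0 < sv_count outside [",
          minSV, ", ", maxSV, "])")
  cohort@data <- d
  cohort@minSV <- minSV
  cohort@maxSV <- maxSV
  cohort@excluded <- excluded
  validObject(cohort)
  cohort
}

# Rows taking part in stratified analyses (constraint-excluded patients out).
.analyzedRows <- function(cohort) {
  d <- cohort@data
  d[!d$patient_id %in% cohort@excluded, , drop = FALSE]
}

#' Arm-by-carrier cross-tabulation
#'
#' Counts and row proportions of SV carriers per trial arm over the analyzed
#' cohort (patients excluded by the carrier constraint are left out, so the
#' grand total equals the cohort size minus exclusions).
#'
#' @param cohort a stratified [CohortFrame-class].
#' @return data.frame with one row per arm: arm label, carriers,
#'   non-carriers, total and the carrier proportion.
#' @export
armSvCrosstab <- function(cohort) {
  stopifnot(is(cohort, "CohortFrame"))
  d <- .analyzedRows(cohort)
  if (!nrow(d)) stop("no analyzable patients in the cohort")
  armLab <- cohort@armLevels[as.character(d$arm)]
  tab <- table(factor(armLab, levels = unname(cohort@armLevels)),
               factor(d$carrier, levels = c(TRUE, FALSE)))
  data.frame(
    arm = rownames(tab),
    carriers = as.integer(tab[, 1]),
    non_carriers = as.integer(tab[, 2]),
    total = as.integer(rowSums(tab)),
    prop_carriers = ifelse(rowSums(tab) > 0, tab[, 1] / rowSums(tab), NA_real_),
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Per-arm histogram of SV counts
#'
#' Tabulates how many patients of each arm carry each observed SV count in
#' the target gene (the SV-distribution histogram of the target-gene report).
#'
#' @param cohort a [CohortFrame-class].
#' @return data.frame with columns sv_count, arm, n_patients.
#' @export
svCountHistogram <- function(cohort) {
  stopifnot(is(cohort, "CohortFrame"))
  d <- cohort@data
  armLab <- cohort@armLevels[as.character(d$arm)]
  tab <- as.data.frame(table(sv_count = d$sv_count, arm = armLab),
                       stringsAsFactors = FALSE)
  tab$sv_count <- as.integer(tab$sv_count)
  names(tab)[3] <- "n_patients"
  tab[order(tab$sv_count, tab$arm), , drop = FALSE]
}

#' @describeIn readMetadata the standardized patient data.frame.
#' @export
setMethod("clinicalData", "ClinicalTable", function(object) object@data)

#' @describeIn readMetadata the declared time-unit label.
#' @export
setMethod("timeUnit", "ClinicalTable", function(object) object@timeUnit)

#' @describeIn joinCohort the target gene of the cohort.
#' @export
setMethod("targetGene", "CohortFrame", function(object) object@targetGene)

#' @describeIn stratifyBySV ids excluded by the carrier constraint.
#' @export
setMethod("excludedIds", "CohortFrame", function(object) object@excluded)

setMethod("show", "ClinicalTable", function(object) {
  d <- object@data
  cat(class(object), "with", nrow(d), "patients;",
      sum(d$event), "events; time in", object@timeUnit, "\n")
  cat("  arm levels:", paste(names(object@armLevels), object@armLevels,
                             sep = "=", collapse = ", "), "\n")
  if (is(object, "CohortFrame")) {
    cat("  target gene:", object@targetGene,
        sprintf("(carrier window [%g, %g])", object@minSV, object@maxSV), "\n")
    cat("  carriers:", sum(d$carrier), " excluded:", length(object@excluded), "\n")
  }
})
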
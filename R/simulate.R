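#' @include AllClasses.R AllGenerics.R
NULL

#' Configure a two-arm trial simulation
#'
#' Defines the study conditions of the simulated cohort: a placebo and a
#' treatment arm of 50 participants each (the exemplary trial size), an
#' exponential baseline hazard, multiplicative treatment / SV-carrier / age
#' effects, per-arm carrier fractions matching the exemplary 7-of-50 vs
#' 36-of-50 carrier split, carrier SV counts drawn as a minimum count plus a
#' Poisson excess, truncated-normal age at onset, and administrative
#' censoring. Event times are exponential with hazard
#' \deqn{\lambda_i = \lambda_0 \exp(\beta_t \cdot \mathrm{arm}_i +
#'   \beta_c \cdot \mathrm{carrier}_i + \beta_a (\mathrm{age}_i - \bar a)).}
#'
#' @param nPlacebo,nTreatment arm sizes (default 50 each).
#' @param baselineHazard events per time unit for a placebo non-carrier at
#'   mean age; default 0.2 (per year).
#' @param logHrTreatment log hazard ratio of the treatment arm; default -0.7
#'   (a successful trial, roughly halving the hazard).
#' @param logHrCarrier log hazard ratio of carrying SVs in the target gene;
#'   default 0.5.
#' @param logHrAge log hazard ratio per year of age at onset; default 0.
#' @param carrierFraction named numeric: carrier probability per arm; default
#'   `c(placebo = 0.14, treatment = 0.72)`.
#' @param svCountMean Poisson mean of the SV-count excess above `svCountMin`;
#'   default 2.
#' @param svCountMin minimum SV count of a carrier (>= 1); set to 3 for the
#'   "at least three SVs" regime. Default 1.
#' @param ageMean,ageSd age-at-onset normal law (years), truncated at >= 18;
#'   defaults 55 and 10.
#' @param censorTime administrative cutoff in time units; default 10 (years).
#' @param seed integer RNG seed; the simulation is fully deterministic given
#'   the seed.
#' @return a [TrialSimConfig-class].
#' @export
trialSimConfig <- function(nPlacebo = 50L, nTreatment = 50L,
                           baselineHazard = 0.2,
                           logHrTreatment = -0.7, logHrCarrier = 0.5,
                           logHrAge = 0,
                           carrierFraction = c(placebo = 0.14, treatment = 0.72),
                           svCountMean = 2, svCountMin = 1L,
                           ageMean = 55, ageSd = 10,
                           censorTime = 10, seed = 1L) {
  new("TrialSimConfig",
      nPlacebo = as.integer(nPlacebo), nTreatment = as.integer(nTreatment),
      baselineHazard = baselineHazard,
      logHrTreatment = logHrTreatment, logHrCarrier = logHrCarrier,
      logHrAge = logHrAge, carrierFraction = carrierFraction,
      svCountMean = svCountMean, svCountMin = as.integer(svCountMin),
      ageMean = ageMean, ageSd = ageSd,
      censorTime = censorTime, seed = as.integer(seed))
}

setMethod("show", "TrialSimConfig", function(object) {
  cat("TrialSimConfig:", object@nPlacebo, "placebo +",
      object@nTreatment, "treatment\n")
  cat("  baseline hazard", object@baselineHazard,
      "| log-HR treatment", object@logHrTreatment,
      "carrier", object@logHrCarrier, "age", object@logHrAge, "\n")
  cat("  carrier fraction", paste(names(object@carrierFraction),
                                  object@carrierFraction, sep = "=", collapse = " "),
      "| SV counts >=", object@svCountMin, "+ Pois(", object@svCountMean, ")\n")
  cat("  censoring at", object@censorTime, "| seed", object@seed, "\n")
})

#' Simulate a two-arm clinical trial cohort
#'
#' Draws per-patient carrier status, SV count, age at onset and an
#' exponential latent event time under the configured hazards, applies
#' administrative censoring, and returns the observed metadata together with
#' a ground-truth ledger. All draws are ordered by patient index, so the
#' output is byte-identical across runs with the same config.
#'
#' When `dir` is given, `meta.csv` is written in the column dialect the
#' metadata reader expects by default (`patient_ID`, `Phenotype`,
#' `survival.status_bin`, `time`, `age_at_onset`) plus `truth.json`.
#'
#' @param config a [TrialSimConfig-class].
#' @param dir optional output directory.
#' @return list with `metadata` (observed data.frame), `truth` (ground-truth
#'   data.frame with latent times), and, when written, `metaPath` /
#'   `truthPath`.
#' @examples
#' sim <- simulateCohort(trialSimConfig(seed = 7))
#' head(sim$metadata)
#' @export
simulateCohort <- function(config, dir = NULL) {
  stopifnot(is(config, "TrialSimConfig"))
  validObject(config)
  n <- config@nPlacebo + config@nTreatment
  arm <- rep(c(0L, 1L), c(config@nPlacebo, config@nTreatment))

  set.seed(config@seed)

  pCarrier <- ifelse(arm == 1L, config@carrierFraction[["treatment"]],
                     config@carrierFraction[["placebo"]])
  carrier <- stats::runif(n) < pCarrier
  svCount <- integer(n)
  svCount[carrier] <- config@svCountMin +
    stats::rpois(sum(carrier), config@svCountMean)

  # truncated-normal ages (>= 18) by per-patient rejection, order-stable
  age <- stats::rnorm(n, config@ageMean, config@ageSd)
  while (any(age < 18))
    age[age < 18] <- stats::rnorm(sum(age < 18), config@ageMean, config@ageSd)

  hazard <- config@baselineHazard * exp(
    config@logHrTreatment * arm +
    config@logHrCarrier * as.numeric(carrier) +
    config@logHrAge * (age - config@ageMean))
  latent <- stats::rexp(n, rate = hazard)
  time <- pmin(latent, config@censorTime)
  event <- as.integer(latent <= config@censorTime)

  ids <- sprintf("P%04d", seq_len(n))
  metadata <- data.frame(
    patient_ID = ids,
    Phenotype = ifelse(arm == 1L, "treatment", "placebo"),
    survival.status_bin = event,
    time = round(time, 6),
    age_at_onset = round(age, 2),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  truth <- data.frame(
    patient_ID = ids, arm = arm, carrier = carrier, sv_count = svCount,
    age = age, latent_time = latent, censored = event == 0L,
    stringsAsFactors = FALSE
  )
  out <- list(metadata = metadata, truth = truth, config = config)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    out$metaPath <- file.path(dir, "meta.csv")
    out$truthPath <- file.path(dir, "truth.json")
    utils::write.csv(metadata, out$metaPath, row.names = FALSE, quote = FALSE)
    jsonlite::write_json(truth, out$truthPath, digits = NA, auto_unbox = TRUE)
  }
  out
}

#' Simulate the annotated multi-sample SV VCF of a cohort
#'
#' Emits a VCF v4.2 with one record per simulated SV: each carrier
#' contributes exactly `sv_count` records in the target gene (genotype 0/1
#' for the carrier, 0/0 elsewhere), and every patient receives background
#' records in decoy genes. SV types are drawn from deletions, duplications
#' and insertions; positions are arbitrary but deterministic given the
#' config seed. Reading the file back and tallying reproduces the
#' ground-truth target-gene counts exactly.
#'
#' @param config the [TrialSimConfig-class] used for the cohort.
#' @param truth the ground-truth data.frame from [simulateCohort()].
#' @param path output VCF path.
#' @param targetGene Ensembl id of the target gene; default the SETX id.
#' @param targetSymbol gene symbol for the header comment.
#' @param decoyGenes number of background genes, default 3.
#' @return `path`, invisibly.
#' @export
simulateSvVcf <- function(config, truth, path,
                          targetGene = "ENSG00000107290",
                          targetSymbol = "SETX", decoyGenes = 3L) {
  stopifnot(is(config, "TrialSimConfig"), is.data.frame(truth))
  n <- nrow(truth)
  set.seed(config@seed + 104729L)  # independent stream from the cohort draws
  svtypes <- c("DEL", "DUP", "INS")

  samples <- truth$patient_ID
  rows <- character()
  makeRecord <- function(chrom, pos, gene, gtVec, id) {
    svt <- sample(svtypes, 1L)
    end <- if (svt == "INS") pos else pos + 49L + sample.int(4951L, 1L)
    sprintf("%s\t%d\t%s\tN\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;GENE=%s\tGT\t%s",
            chrom, pos, id, svt, svt, end, gene, paste(gtVec, collapse = "\t"))
  }

  recId <- 0L
  for (i in seq_len(n)) {
    k <- truth$sv_count[i]
    if (k < 1L) next
    for (r in seq_len(k)) {
      recId <- recId + 1L
      gt <- rep("0/0", n); gt[i] <- "0/1"
      rows <- c(rows, makeRecord("chr9", 100000L + sample.int(129000000L, 1L),
                                 targetGene, gt, sprintf("sv_t%05d", recId)))
    }
  }
  for (g in seq_len(decoyGenes)) {
    gene <- sprintf("ENSG%011d", 900000000L + g)
    for (i in seq_len(n)) {
      recId <- recId + 1L
      gt <- rep("0/0", n); gt[i] <- sample(c("0/1", "1/1"), 1L)
      rows <- c(rows, makeRecord(sprintf("chr%d", g), 100000L + sample.int(10000000L, 1L),
                                 gene, gt, sprintf("sv_d%05d", recId)))
    }
  }

  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=svSurv trial simulator (target %s/%s)", targetSymbol, targetGene),
    "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"Type of structural variant\">",
    "##INFO=<ID=END,Number=1,Type=Integer,Description=\"End position of the variant\">",
    "##INFO=<ID=GENE,Number=.,Type=String,Description=\"Ensembl gene identifiers overlapping the variant\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(header, rows), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}
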
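#' @include AllClasses.R AllGenerics.R
NULL

#' Read a gene-annotated multi-sample structural-variant VCF
#'
#' Parses a VCF (v4.2+, plain or bgzipped) whose records carry Ensembl gene
#' identifiers in INFO, and returns an [SVCallSet-class] holding per-record
#' coordinates, SV type, gene annotations and the genotype matrix in sample
#' header order.
#'
#' Gene annotations are resolved per `annotationKey`:
#' \describe{
#'   \item{`"GENE"`}{a plain INFO key with `|`- or `,`-separated identifiers.}
#'   \item{`"ANN"`}{SnpEff/VEP-style functional annotations; the gene-ID
#'     subfield (5th `|`-field) of each comma-separated entry is taken, falling
#'     back to the gene-name subfield when the ID is empty.}
#'   \item{`"auto"` (default)}{try `GENE` first, then `ANN`.}
#' }
#' Records lacking the annotation key are retained with an empty gene set and
#' counted in a warning.
#'
#' @param path path to the VCF file.
#' @param annotationKey `"auto"`, `"GENE"`, `"ANN"`, or any custom plain INFO
#'   key holding separated gene identifiers.
#' @return an [SVCallSet-class].
#' @examples
#' vcf <- system.file("extdata", "toy_cohort.vcf", package = "svSurv")
#' calls <- readAnnotatedVcf(vcf)
#' sampleIds(calls)
#' @export
readAnnotatedVcf <- function(path, annotationKey = "auto") {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop("failed to parse VCF (missing/unparseable header?): ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(vcf@gt) || ncol(vcf@gt) < 2L)
    stop("VCF has zero sample columns; a multi-sample VCF with >= 1 sample is required")
  samples <- colnames(vcf@gt)[-1L]
  fix <- vcf@fix
  n <- nrow(fix)

  pos <- as.integer(fix[, "POS"])
  endInfo <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "END")))
  svtRaw <- vcfR::extract.info(vcf, "SVTYPE")
  svType <- ifelse(is.na(svtRaw), "other", toupper(svtRaw))
  svType[!svType %in% c("DEL", "DUP", "INS", "INV", "BND")] <- "other"
  end <- ifelse(is.na(endInfo), pos, endInfo)
  end[svType == "BND"] <- pos[svType == "BND"]

  genes <- .extractGeneIds(vcf, n, annotationKey)
  nUnannotated <- sum(lengths(genes) == 0L)
  if (nUnannotated > 0L)
    warning(nUnannotated, " record(s) lack gene annotations and contribute to no tally cell")

  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(gt)) gt <- matrix(NA_character_, n, length(samples))
  dimnames(gt) <- list(NULL, samples)

  new("SVCallSet",
      chrom = as.character(fix[, "CHROM"]), pos = pos, end = as.integer(end),
      svType = svType, geneIds = genes, genotypes = gt,
      samples = samples, nUnannotated = as.integer(nUnannotated))
}

.splitGeneField <- function(x) {
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    if (is.na(x[i]) || !nzchar(x[i])) out[[i]] <- character() else
      out[[i]] <- unique(strsplit(x[i], "[|,]")[[1]])
  }
  out
}

.splitAnnField <- function(x) {
  out <- vector("list", length(x))
  for (i in seq_along(x)) {
    if (is.na(x[i]) || !nzchar(x[i])) { out[[i]] <- character(); next }
    entries <- strsplit(x[i], ",", fixed = TRUE)[[1]]
    ids <- vapply(entries, function(e) {
      f <- strsplit(e, "|", fixed = TRUE)[[1]]
      id <- if (length(f) >= 5 && nzchar(f[5])) f[5]
            else if (length(f) >= 4 && nzchar(f[4])) f[4] else NA_character_
      id
    }, character(1), USE.NAMES = FALSE)
    out[[i]] <- unique(ids[!is.na(ids)])
  }
  out
}

.extractGeneIds <- function(vcf, n, annotationKey) {
  if (n == 0L) return(list())
  tryInfo <- function(key) suppressWarnings(vcfR::extract.info(vcf, key))
  if (annotationKey == "auto") {
    g <- tryInfo("GENE")
    if (!all(is.na(g))) return(.splitGeneField(g))
    a <- tryInfo("ANN")
    if (!all(is.na(a))) return(.splitAnnField(a))
    return(rep(list(character()), n))
  }
  if (annotationKey == "ANN") return(.splitAnnField(tryInfo("ANN")))
  .splitGeneField(tryInfo(annotationKey))
}

#' Is a genotype call a variant carrier?
#'
#' A sample carries the variant iff its GT call has at least one allele index
#' greater than zero. Missing calls (`"."`, `"./."`, `".|."`, `NA`) are
#' conservatively non-carriers. Vectorized.
#'
#' @param genotype character vector of GT strings (diploid or haploid,
#'   phased or unphased).
#' @return logical vector.
#' @examples
#' isCarrier(c("0/1", "0/0", "./.", "1|1", NA))
#' @export
isCarrier <- function(genotype) {
  vapply(genotype, function(g) {
    if (is.na(g)) return(FALSE)
    alleles <- strsplit(g, "[/|]")[[1]]
    if (!length(alleles)) stop("malformed genotype string: '", g, "'", call. = FALSE)
    known <- alleles[alleles != "."]
    if (!length(known)) return(FALSE)
    idx <- suppressWarnings(as.integer(known))
    if (any(is.na(idx))) stop("malformed genotype string: '", g, "'", call. = FALSE)
    any(idx > 0L)
  }, logical(1), USE.NAMES = FALSE)
}

#' Build the per-sample, per-gene SV count tally
#'
#' For each sample and gene, counts the VCF records in which the sample
#' carries at least one alternate allele and the record is annotated with the
#' gene. A record annotated with several genes increments one cell per gene;
#' a record never counts more than once per (sample, gene). The result is
#' deterministic: genes are sorted lexicographically and record order is
#' irrelevant.
#'
#' @param calls an [SVCallSet-class] from [readAnnotatedVcf()].
#' @return a [GeneTally-class].
#' @export
buildGeneTally <- function(calls) {
  stopifnot(is(calls, "SVCallSet"))
  samples <- calls@samples
  genes <- sort(unique(unlist(calls@geneIds)))
  counts <- matrix(0L, nrow = length(samples), ncol = length(genes),
                   dimnames = list(samples, genes))
  nrec <- length(calls@pos)
  for (r in seq_len(nrec)) {
    gs <- calls@geneIds[[r]]
    if (!length(gs)) next
    carr <- tryCatch(
      isCarrier(calls@genotypes[r, ]),
      error = function(e) {
        bad <- which(vapply(calls@genotypes[r, ], function(g)
          inherits(tryCatch(isCarrier(g), error = function(e2) e2), "error"),
          logical(1)))
        stop("record ", calls@chrom[r], ":", calls@pos[r], ", sample ",
             paste(samples[bad], collapse = ", "), ": ",
             conditionMessage(e), call. = FALSE)
      })
    if (any(carr)) counts[carr, gs] <- counts[carr, gs] + 1L
  }
  new("GeneTally", counts = counts)
}

#' Construct a GeneTally from a count matrix
#'
#' @param counts numeric matrix of non-negative integers with sample rownames
#'   and gene colnames; columns are re-sorted lexicographically by gene.
#' @return a [GeneTally-class].
#' @export
geneTally <- function(counts) {
  mode(counts) <- "integer"
  if (ncol(counts) > 1) counts <- counts[, order(colnames(counts)), drop = FALSE]
  new("GeneTally", counts = counts)
}

#' @describeIn readAnnotatedVcf sample ids of a call set.
#' @export
setMethod("sampleIds", "SVCallSet", function(object) object@samples)

#' @describeIn buildGeneTally sample ids of a tally.
#' @export
setMethod("sampleIds", "GeneTally", function(object) rownames(object@counts))

#' @describeIn buildGeneTally gene ids of a tally (sorted).
#' @export
setMethod("geneIds", "GeneTally", function(object) colnames(object@counts))

#' @describeIn buildGeneTally the samples x genes integer count matrix.
#' @export
setMethod("tallyCounts", "GeneTally", function(object) object@counts)

setMethod("show", "SVCallSet", function(object) {
  cat("SVCallSet with", length(object@pos), "records,",
      length(object@samples), "samples\n")
  if (object@nUnannotated > 0L)
    cat("  (", object@nUnannotated, " records without gene annotation)\n", sep = "")
  tt <- table(object@svType)
  cat("  SV types:", paste(names(tt), tt, sep = ":", collapse = " "), "\n")
})

setMethod("show", "GeneTally", function(object) {
  cat("GeneTally:", nrow(object@counts), "samples x",
      ncol(object@counts), "genes;",
      sum(object@counts), "carrier-record pairs\n")
})

#' Write / read a tally as TSV
#'
#' The TSV has a header `sample` followed by the gene columns in sorted order,
#' one row per sample; the round trip `readTally(writeTally(t))` is lossless.
#'
#' @param tally a [GeneTally-class].
#' @param path output/input file path.
#' @return `writeTally` returns `path` invisibly; `readTally` returns a
#'   [GeneTally-class].
#' @export
writeTally <- function(tally, path) {
  stopifnot(is(tally, "GeneTally"))
  m <- tallyCounts(tally)
  con <- file(path, open = "wb")  # force LF line endings
  on.exit(close(con))
  writeLines(paste(c("sample", colnames(m)), collapse = "\t"), con, sep = "\n", useBytes = TRUE)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], m[i, ]), collapse = "\t"), con, sep = "\n", useBytes = TRUE)
  invisible(path)
}

#' @rdname writeTally
#' @export
readTally <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty tally file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  width <- length(fields[[1]])
  ragged <- which(lengths(fields) != width)
  if (length(ragged))
    stop("malformed tally TSV: ragged row(s) at line ", ragged[1])
  header <- fields[[1]]
  if (header[1] != "sample") stop("tally TSV must start with a 'sample' header column")
  genes <- header[-1]
  rows <- fields[-1]
  samples <- vapply(rows, `[`, character(1), 1L)
  counts <- matrix(0L, length(rows), length(genes),
                   dimnames = list(samples, genes))
  for (i in seq_along(rows)) {
    vals <- suppressWarnings(as.integer(rows[[i]][-1]))
    if (any(is.na(vals)))
      stop("malformed tally TSV: non-integer cell at line ", i + 1L)
    if (any(vals < 0L))
      stop("malformed tally TSV: negative count at line ", i + 1L)
    counts[i, ] <- vals
  }
  geneTally(counts)
}
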
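test_that("annotated VCF parsing extracts records, genes and samples", {
  calls <- suppressWarnings(readAnnotatedVcf(writeToyVcf()))
  expect_s4_class(calls, "SVCallSet")
  expect_identical(sampleIds(calls), c("S1", "S2", "S3"))
  expect_length(calls@pos, 4L)
  expect_identical(calls@geneIds[[1]], "ENSG00000107290")
  # multi-gene separator split
  expect_setequal(calls@geneIds[[2]], c("ENSG00000107290", "ENSG00000142168"))
  # END fallback to pos when absent
  expect_identical(calls@end[3], calls@pos[3])
  expect_identical(calls@svType, c("DEL", "DUP", "INS", "INV"))
  # unannotated record retained with empty gene set + warning counter
  expect_warning(readAnnotatedVcf(writeToyVcf()), "lack gene annotation")
  expect_length(calls@geneIds[[4]], 0L)
  expect_identical(calls@nUnannotated, 1L)
})

test_that("ANN-style annotations yield the gene-ID subfield", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##INFO=<ID=ANN,Number=.,Type=String,Description="Functional annotations">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="GT">',
    paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO","FORMAT","S1"),
          collapse = "\t"),
    paste0("chr1\t10\t.\tN\t<DEL>\t.\t.\t",
           "ANN=A|deletion|HIGH|SETX|ENSG00000107290|transcript,",
           "A|deletion|LOW|SOD1|ENSG00000142168|transcript\tGT\t0/1")
  ), path)
  calls <- readAnnotatedVcf(path)
  expect_setequal(calls@geneIds[[1]], c("ENSG00000107290", "ENSG00000142168"))
})

test_that("carrier calls follow the >=1 alternate allele rule", {
  expect_identical(isCarrier(c("0/1", "0/0", "./.", ".", "1|1", "0|0", "1", "0")),
                   c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_true(isCarrier("./1"))
  expect_error(isCarrier("0/x"), "malformed genotype")
})

test_that("gene tally counts carriers once per record per gene", {
  calls <- suppressWarnings(readAnnotatedVcf(writeToyVcf()))
  tally <- buildGeneTally(calls)
  m <- tallyCounts(tally)
  # S1: sv1 (0/1) + sv2 (1/1, counts once) in SETX; sv2 also in SOD1
  expect_identical(m["S1", "ENSG00000107290"], 2L)
  expect_identical(m["S1", "ENSG00000142168"], 1L)
  expect_identical(m["S2", "ENSG00000107290"], 1L)
  expect_identical(m["S3", "ENSG00000107290"], 0L)  # ./. then 0/0
  expect_identical(m["S3", "ENSG00000142168"], 1L)
  expect_identical(m["S2", "ENSG00000142168"], 1L)
  # sv4 has no gene: contributes nowhere; total = 1 + 2*2 + 1
  expect_identical(sum(m), 6L)
  expect_identical(geneIds(tally), sort(geneIds(tally)))
})

test_that("empty record set gives a zero-gene tally", {
  calls <- new("SVCallSet", chrom = character(), pos = integer(),
               end = integer(), svType = character(), geneIds = list(),
               genotypes = matrix(character(), 0, 2,
                                  dimnames = list(NULL, c("A", "B"))),
               samples = c("A", "B"), nUnannotated = 0L)
  tally <- buildGeneTally(calls)
  expect_identical(dim(tallyCounts(tally)), c(2L, 0L))
})

test_that("tally conservation and permutation invariance hold on random call sets", {
  set.seed(11)
  genesPool <- sprintf("G%02d", 1:6)
  for (rep in 1:10) {
    nRec <- sample(3:12, 1); nS <- sample(2:6, 1)
    samples <- paste0("S", seq_len(nS))
    gt <- matrix(sample(c("0/0", "0/1", "1/1", "./."), nRec * nS, replace = TRUE),
                 nRec, nS, dimnames = list(NULL, samples))
    genes <- lapply(seq_len(nRec), function(i)
      sample(genesPool, sample(0:3, 1)))
    calls <- new("SVCallSet", chrom = rep("chr1", nRec),
                 pos = seq_len(nRec), end = seq_len(nRec),
                 svType = rep("DEL", nRec), geneIds = genes,
                 genotypes = gt, samples = samples,
                 nUnannotated = sum(lengths(genes) == 0L))
    tally <- buildGeneTally(calls)
    # conservation vs brute-force double loop
    brute <- 0L
    for (i in seq_len(nRec)) for (s in seq_len(nS))
      if (isCarrier(gt[i, s])) brute <- brute + length(genes[[i]])
    expect_identical(sum(tallyCounts(tally)), brute)
    # permutation invariance
    perm <- sample(nRec)
    calls2 <- new("SVCallSet", chrom = calls@chrom[perm], pos = calls@pos[perm],
                  end = calls@end[perm], svType = calls@svType[perm],
                  geneIds = calls@geneIds[perm],
                  genotypes = gt[perm, , drop = FALSE], samples = samples,
                  nUnannotated = calls@nUnannotated)
    expect_identical(tallyCounts(buildGeneTally(calls2)), tallyCounts(tally))
  }
})

test_that("adding a record never decreases any tally cell", {
  set.seed(5)
  samples <- c("S1", "S2", "S3")
  mk <- function(n) {
    gt <- matrix(sample(c("0/0", "0/1"), n * 3, replace = TRUE), n, 3,
                 dimnames = list(NULL, samples))
    new("SVCallSet", chrom = rep("chr1", n), pos = seq_len(n), end = seq_len(n),
        svType = rep("DEL", n),
        geneIds = lapply(seq_len(n), function(i) sample(c("G1", "G2"), 1)),
        genotypes = gt, samples = samples, nUnannotated = 0L)
  }
  base <- mk(6)
  bigger <- new("SVCallSet", chrom = c(base@chrom, "chr1"),
                pos = c(base@pos, 7L), end = c(base@end, 7L),
                svType = c(base@svType, "DUP"),
                geneIds = c(base@geneIds, list(c("G1", "G2"))),
                genotypes = rbind(base@genotypes, c("0/1", "0/1", "0/1")),
                samples = samples, nUnannotated = 0L)
  m1 <- tallyCounts(buildGeneTally(base))
  m2 <- tallyCounts(buildGeneTally(bigger))
  expect_true(all(m2[, colnames(m1)] >= m1))
})

test_that("tally TSV round-trips losslessly and rejects bad files", {
  tally <- geneTally(matrix(c(2L, 0L, 1L, 3L), 2, 2,
                            dimnames = list(c("S1", "S2"), c("GB", "GA"))))
  path <- tempfile(fileext = ".tsv")
  writeTally(tally, path)
  lines <- readLines(path)
  expect_identical(lines[1], "sample\tGA\tGB")  # sorted gene header
  back <- readTally(path)
  expect_identical(tallyCounts(back), tallyCounts(tally))

  writeLines(c("sample\tG1", "S1\t-1"), bad <- tempfile())
  expect_error(readTally(bad), "negative count")
  writeLines(c("sample\tG1", "S1\t1\t2"), ragged <- tempfile())
  expect_error(readTally(ragged), "ragged")
  writeLines(c("sample\tG1", "S1\tx"), nonint <- tempfile())
  expect_error(readTally(nonint), "non-integer")
})

test_that("VCFs without samples or files without headers are rejected", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM","POS","ID","REF","ALT","QUAL","FILTER","INFO"),
                     collapse = "\t"),
               "chr1\t1\t.\tN\t<DEL>\t.\t.\tGENE=G1"), path)
  expect_error(readAnnotatedVcf(path), "zero sample|sample column")
  garbage <- tempfile()
  writeLines("not a vcf at all", garbage)
  expect_error(suppressWarnings(readAnnotatedVcf(garbage)))
})
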
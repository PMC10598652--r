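test_that("metadata roles are mapped and coerced to binary with audit trail", {
  path <- writeToyMeta()
  expect_message(readMetadata(path, toyColumnMap()), "placebo -> 0")
  clin <- suppressMessages(readMetadata(path, toyColumnMap()))
  d <- clinicalData(clin)
  expect_identical(d$arm, c(0L, 1L, 1L))       # treatment > placebo
  expect_identical(d$event, c(1L, 0L, 1L))
  expect_identical(timeUnit(clin), "years")
  expect_identical(unname(clin@armLevels["1"]), "treatment")
  expect_type(d$age_at_onset, "double")
})

test_that("explicit level maps override lexicographic coercion", {
  path <- writeToyMeta(arm = c("B", "A", "A"))
  clin <- suppressMessages(readMetadata(
    path, toyColumnMap(), armLevelMap = c("0" = "A", "1" = "B")))
  expect_identical(clinicalData(clin)$arm, c(1L, 0L, 0L))
})

test_that("metadata validation rejects bad arms, times, and duplicate ids", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(patient_ID = c("P1", "P2", "P3"),
                       Phenotype = c("a", "b", "c"),
                       "survival.status_bin" = c(1, 0, 1),
                       time = c(1, 2, 3), age_at_onset = c(50, 60, 70),
                       check.names = FALSE), path, row.names = FALSE)
  expect_error(suppressMessages(readMetadata(path, toyColumnMap())),
               "3 levels: a, b, c")

  dup <- writeToyMeta(ids = c("S1", "S1", "S3"))
  expect_error(suppressMessages(readMetadata(dup, toyColumnMap())),
               "duplicate patient id.*S1")

  negt <- writeToyMeta(time = c(1, -2, 3))
  expect_error(suppressMessages(readMetadata(negt, toyColumnMap())),
               "non-positive")
})

test_that("cohort join pulls counts by id and warns on absentees", {
  tally <- geneTally(matrix(c(2L, 0L, 1L), 3, 1,
                            dimnames = list(c("S1", "S2", "S3"), "G")))
  clin <- suppressMessages(readMetadata(writeToyMeta(), toyColumnMap()))
  cohort <- joinCohort(tally, clin, "G")
  expect_identical(clinicalData(cohort)$sv_count, c(2L, 0L, 1L))
  expect_identical(targetGene(cohort), "G")

  # patient in metadata but not in VCF
  clin4 <- suppressMessages(readMetadata(
    writeToyMeta(ids = c("S1", "S2", "P4"),
                 arm = c("placebo", "treatment", "treatment"),
                 status = c(1, 0, 1), time = c(1, 2, 3)),
    toyColumnMap()))
  suppressWarnings(expect_warning(co4 <- joinCohort(tally, clin4, "G"),
                                  "absent from the VCF"))
  expect_identical(clinicalData(co4)$sv_count[3], 0L)

  # gene missing from tally
  expect_warning(cog <- joinCohort(tally, clin, "NOPE"), "not annotated")
  expect_true(all(clinicalData(cog)$sv_count == 0L))

  # disjoint id schemes
  clinX <- suppressMessages(readMetadata(
    writeToyMeta(ids = c("X1", "X2", "X3")), toyColumnMap()))
  expect_error(joinCohort(tally, clinX, "G"), "no overlap")
})

test_that("carrier stratification excludes mid-range patients, never relabels", {
  tally <- geneTally(matrix(c(0L, 1L, 3L, 5L), 4, 1,
                            dimnames = list(paste0("S", 1:4), "G")))
  clin <- suppressMessages(readMetadata(
    writeToyMeta(ids = paste0("S", 1:4),
                 arm = c("placebo", "placebo", "treatment", "treatment"),
                 status = c(1, 1, 0, 1), time = 1:4), toyColumnMap()))
  cohort <- joinCohort(tally, clin, "G")

  def <- suppressMessages(stratifyBySV(cohort, 1))
  expect_identical(clinicalData(def)$carrier, c(FALSE, TRUE, TRUE, TRUE))
  expect_length(excludedIds(def), 0L)

  # the >=3-SV regime: the 1-SV patient is excluded, not a non-carrier
  hi <- suppressMessages(stratifyBySV(cohort, 3))
  expect_identical(clinicalData(hi)$carrier, c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(excludedIds(hi), "S2")

  expect_error(stratifyBySV(cohort, 2, 1), "maxSV")
  expect_error(stratifyBySV(cohort, 0), "minSV")
  tallyAll <- geneTally(matrix(c(1L, 1L, 1L, 1L), 4, 1,
                               dimnames = list(paste0("S", 1:4), "G")))
  coAll <- joinCohort(tallyAll, clin, "G")
  expect_error(suppressMessages(stratifyBySV(coAll, 5)), "excludes every patient")
})

test_that("arm x carrier crosstab has correct margins and proportions", {
  tally <- geneTally(matrix(c(0L, 1L, 3L, 5L), 4, 1,
                            dimnames = list(paste0("S", 1:4), "G")))
  clin <- suppressMessages(readMetadata(
    writeToyMeta(ids = paste0("S", 1:4),
                 arm = c("placebo", "placebo", "treatment", "treatment"),
                 status = c(1, 1, 0, 1), time = 1:4), toyColumnMap()))
  cohort <- suppressMessages(stratifyBySV(joinCohort(tally, clin, "G"), 1))
  tab <- armSvCrosstab(cohort)
  expect_identical(tab$arm, c("placebo", "treatment"))
  expect_identical(tab$carriers, c(1L, 2L))
  expect_identical(tab$total, c(2L, 2L))
  expect_equal(tab$prop_carriers, c(0.5, 1.0))

  # exclusion shrinks the analyzed total
  hi <- suppressMessages(stratifyBySV(cohort, 3))
  tabHi <- armSvCrosstab(hi)
  expect_identical(sum(tabHi$total), 3L)

  # default stratification partitions the cohort exactly
  expect_identical(sum(tab$total), nrow(clinicalData(cohort)))
})

test_that("sv count histogram tabulates patients per arm", {
  fix <- simulatedCohort(seed = 9)
  h <- svCountHistogram(fix$cohort)
  expect_named(h, c("sv_count", "arm", "n_patients"))
  truthCounts <- fix$sim$truth$sv_count
  expect_identical(sum(h$n_patients[h$sv_count == 0]),
                   sum(truthCounts == 0L))
})
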
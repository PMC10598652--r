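test_that("product-limit estimates match hand computations", {
  # no censoring: empirical survival
  f1 <- kmFit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(f1@surv, c(2/3, 1/3, 0))
  # censoring between events; Greenwood variance at t = 1 is (3/4)^2 / 12
  f2 <- kmFit(c(1, 2, 2, 3), c(1, 0, 1, 1))
  expect_equal(f2@surv, c(3/4, 1/2, 0))
  expect_equal(f2@stdErr[1]^2, (3/4)^2 * (1 / 12))
  expect_identical(f2@nRisk, c(4L, 3L, 1L))
  # single censored subject
  f3 <- kmFit(5, 0)
  expect_equal(f3@surv, 1)
  expect_error(kmFit(numeric(), integer()), "empty")
})

test_that("all-censored input yields S identically 1", {
  f <- kmFit(c(2, 4, 6), c(0, 0, 0))
  expect_true(all(f@surv == 1))
  lt <- lifeTable(f)
  expect_true(all(lt$n_events == 0L))
  expect_identical(nrow(lt), 3L)
})

test_that("life table reproduces the curve exactly and rebuilds S", {
  f <- kmFit(c(1, 2, 2, 3), c(1, 0, 1, 1))
  lt <- lifeTable(f)
  expect_identical(lt$n_at_risk, c(4L, 3L, 1L))
  expect_equal(lt$survival, f@surv)
  rebuilt <- cumprod(1 - lt$n_events / lt$n_at_risk)
  expect_equal(rebuilt, lt$survival)
})

test_that("KM with zero censoring equals one minus the empirical CDF", {
  set.seed(8)
  for (rep in 1:5) {
    tm <- rexp(40)
    f <- kmFit(tm, rep(1, 40))
    ecdfT <- ecdf(tm)
    expect_equal(f@surv, 1 - ecdfT(f@time))
  }
})

test_that("Greenwood cumulative variance term is non-decreasing in t", {
  set.seed(12)
  for (rep in 1:10) {
    d <- randomSurvData(30)
    f <- kmFit(d$time, d$event)
    relVar <- ifelse(f@surv > 0, (f@stdErr / f@surv)^2, NA)
    expect_true(all(diff(relVar[!is.na(relVar)]) >= -1e-12))
  }
})

test_that("log-log confidence bounds stay inside [0, 1] and bracket S", {
  set.seed(13)
  d <- randomSurvData(50)
  f <- kmFit(d$time, d$event)
  ok <- !is.na(f@lower)
  expect_true(all(f@lower[ok] >= 0 & f@upper[ok] <= 1))
  expect_true(all(f@lower[ok] <= f@surv[ok] + 1e-12))
  expect_true(all(f@upper[ok] >= f@surv[ok] - 1e-12))
})

test_that("stratified fit yields per-stratum curves, a null model, and comparisons", {
  fix <- simulatedCohort(seed = 4)
  strata <- suppressWarnings(kmStrata(fix$cohort))
  expect_s4_class(strata, "KMStrata")
  expect_true(length(strata@curves) >= 2)
  expect_identical(strata@null@n, nrow(clinicalData(fix$cohort)))
  expect_equal(nrow(strata@pairwise), choose(length(strata@curves), 2))
  # stratum sizes sum to the analyzed cohort
  expect_identical(sum(vapply(strata@curves, function(cu) cu@n, integer(1))),
                   nrow(clinicalData(fix$cohort)) - length(excludedIds(fix$cohort)))
})

test_that("a cohort with no carriers yields two curves and a warning", {
  fix <- simulatedCohort(seed = 6)
  d <- fix$cohort@data
  d$sv_count <- 0L; d$carrier <- FALSE
  nc <- fix$cohort; nc@data <- d
  suppressWarnings(expect_warning(strata <- kmStrata(nc), "empty stratum"))
  expect_length(strata@curves, 2L)
})

test_that("two-panel life table and risk table cover the analyzed cohort", {
  fix <- simulatedCohort(seed = 4)
  strata <- suppressWarnings(kmStrata(fix$cohort))
  lt <- cohortLifeTable(strata)
  expect_setequal(unique(lt$panel), c("SV", "no-SV"))
  expect_setequal(unique(lt$stratum), names(strata@curves))
  rt <- riskTable(strata)
  expect_identical(rt$stratum, names(strata@curves))
  # at t = 0 everyone is at risk
  expect_identical(as.integer(rt[[2]]),
                   vapply(strata@curves, function(cu) cu@n, integer(1),
                          USE.NAMES = FALSE))
})

test_that("survivalAt evaluates the step function", {
  f <- kmFit(c(1, 2, 2, 3), c(1, 0, 1, 1))
  expect_equal(survivalAt(f, c(0.5, 1, 1.5, 2.7, 10)),
               c(1, 3/4, 3/4, 1/2, 0))
})
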
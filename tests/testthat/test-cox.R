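test_that("log-rank matches the hand-tabulated hypergeometric example", {
  lr <- logrank(c(1, 3), c(1, 1), c(2, 4), c(1, 1))
  expect_equal(unname(lr@observed["A"]), 2)
  expect_equal(unname(lr@expected["A"]), 4/3)
  expect_equal(lr@var, 13/18)
  expect_equal(lr@chisq, 8/13)
  expect_identical(lr@df, 1L)
})

test_that("log-rank symmetry and degenerate groups behave", {
  tm <- c(1, 2, 3, 5); ev <- c(1, 0, 1, 1)
  expect_equal(logrank(tm, ev, tm, ev)@chisq, 0)
  # zero-event group is valid
  lr <- logrank(c(1, 2), c(0, 0), c(1, 3), c(1, 1))
  expect_equal(unname(lr@observed["A"]), 0)
  expect_error(logrank(numeric(), numeric(), c(1), c(1)), "non-empty")
})

test_that("cox fixture solves the quartic score equation analytically", {
  fit <- coxFit(1:4, rep(1, 4), cbind(x = c(0, 1, 0, 1)))
  betaTrue <- log((-1 + sqrt(17)) / 8)
  # independent oracle: 1-d grid maximization of the partial likelihood
  pl <- function(b) {
    u <- exp(b)
    log(u) - log(2 + 2 * u) - log(1 + 2 * u) - log(1 + u)
  }
  betaGrid <- optimize(pl, c(-5, 5), maximum = TRUE)$maximum
  expect_equal(betaGrid, betaTrue, tolerance = 1e-6)
  expect_equal(unname(fit@coef), betaTrue, tolerance = 1e-9)
  expect_equal(unname(fit@hr), (-1 + sqrt(17)) / 8, tolerance = 1e-9)
  expect_true(fit@converged)
})

test_that("monotone likelihood is flagged, not raised", {
  fit <- coxFit(c(1, 2), c(1, 1), cbind(x = c(0, 1)))
  expect_false(fit@converged)
  expect_true(fit@monotone)
  expect_match(hazardRatioTable(fit)$note[1], "separation")
})

test_that("label swap negates the coefficient; rescaling scales it", {
  set.seed(31)
  for (rep in 1:5) {
    d <- randomSurvData(40)
    x <- rbinom(40, 1, 0.5)
    if (length(unique(x)) < 2) next
    f1 <- coxFit(d$time, d$event, cbind(x = x))
    f2 <- coxFit(d$time, d$event, cbind(x = 1 - x))
    if (!f1@converged || !f2@converged) next
    expect_equal(unname(f1@coef), -unname(f2@coef), tolerance = 1e-7)

    z <- rnorm(40)
    g1 <- coxFit(d$time, d$event, cbind(z = z))
    g2 <- coxFit(d$time, d$event, cbind(z = z / 10))
    expect_equal(unname(g2@coef), 10 * unname(g1@coef), tolerance = 1e-6)
    expect_equal(g1@loglik[2], g2@loglik[2], tolerance = 1e-9)
    expect_equal(g1@pValue, g2@pValue, tolerance = 1e-6)
  }
})

test_that("constant and collinear covariates are rejected with names", {
  tm <- c(1, 2, 3, 4); ev <- c(1, 1, 0, 1)
  expect_error(coxFit(tm, ev, cbind(k = rep(2, 4))), "constant covariate.*k")
  x <- c(0, 1, 0, 1)
  expect_error(coxFit(tm, ev, cbind(a = x, b = 2 * x)), "collinear")
  expect_error(coxFit(tm, c(0, 0, 0, 0), cbind(x = x)), "at least one event")
})

test_that("efron and breslow agree without ties and match the oracle with ties", {
  skip_if_not_installed("survival")
  set.seed(17)
  for (rep in 1:20) {
    n <- sample(15:50, 1)
    d <- randomSurvData(n)
    x <- cbind(a = rnorm(n), b = rbinom(n, 1, 0.5))
    if (length(unique(x[, "b"])) < 2) next
    mine <- coxFit(d$time, d$event, x)
    if (!mine@converged || mine@monotone) next
    ref <- survival::coxph(survival::Surv(d$time, d$event) ~ x, ties = "efron")
    expect_equal(unname(mine@coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(mine@se), unname(sqrt(diag(vcov(ref)))), tolerance = 1e-6)
    expect_equal(mine@loglik[2], ref$loglik[2], tolerance = 1e-6)

    mineB <- coxFit(d$time, d$event, x, ties = "breslow")
    refB <- survival::coxph(survival::Surv(d$time, d$event) ~ x, ties = "breslow")
    expect_equal(unname(mineB@coef), unname(coef(refB)), tolerance = 1e-6)
  }
  # continuous times: the two tie methods coincide
  tm <- rexp(30); ev <- rbinom(30, 1, 0.8); x <- cbind(z = rnorm(30))
  fe <- coxFit(tm, ev, x); fb <- coxFit(tm, ev, x, ties = "breslow")
  expect_equal(fe@coef, fb@coef, tolerance = 1e-9)
})

test_that("cox score test equals the log-rank chi-square on untied instances", {
  set.seed(23)
  for (rep in 1:20) {
    n <- sample(20:50, 1)
    tm <- rexp(n); ev <- rbinom(n, 1, 0.7); g <- rbinom(n, 1, 0.5)
    if (length(unique(g)) < 2 || sum(ev) == 0) next
    st <- coxScoreTest(tm, ev, cbind(g = g))
    lr <- logrank(tm[g == 0], ev[g == 0], tm[g == 1], ev[g == 1])
    expect_equal(st$chisq, lr@chisq, tolerance = 1e-9)
  }
})

test_that("standard and multiple configurations cover the cohort", {
  fix <- simulatedCohort(seed = 14)
  fits <- fitStandardAndMultiple(fix$cohort, covariates = "age_at_onset")
  expect_s4_class(fits$standard, "CoxFit")
  expect_identical(fits$standard@config, "standard")
  expect_setequal(names(fits$standard@coef), c("arm", "carrier", "age_at_onset"))
  for (side in c("multiple_carrier", "multiple_noncarrier"))
    if (is(fits[[side]], "CoxFit"))
      expect_setequal(names(fits[[side]]@coef), c("arm", "age_at_onset"))
  expect_error(fitStandardAndMultiple(fix$cohort, covariates = "bmi"),
               "unknown covariate.*bmi.*available")
})

test_that("a carrier-free cohort marks the carrier side not estimable", {
  fix <- simulatedCohort(seed = 6)
  d <- fix$cohort@data
  d$sv_count <- 0L; d$carrier <- FALSE
  nc <- fix$cohort; nc@data <- d
  fits <- suppressWarnings(fitStandardAndMultiple(nc))
  expect_identical(as.character(fits$multiple_carrier), "not estimable")
  expect_match(attr(fits$multiple_carrier, "reason"), "0 patients")
  expect_identical(nrow(hazardRatioTable(fits$multiple_carrier)), 0L)
})

test_that("hazard-ratio table renders per-unit percent effects", {
  fit <- coxFit(1:4, rep(1, 4), cbind(x = c(0, 1, 0, 1)))
  fit@coef[] <- log(1.02); fit@hr[] <- 1.02
  tab <- hazardRatioTable(fit)
  expect_identical(tab$hr_label, "1.02")
  expect_identical(tab$pct_effect, "+2%")
  fit@coef[] <- 0; fit@hr[] <- 1
  expect_identical(hazardRatioTable(fit)$pct_effect, "0%")
})
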
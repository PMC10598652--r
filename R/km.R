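#' @include AllClasses.R AllGenerics.R
NULL

#' Kaplan-Meier product-limit estimator
#'
#' Computes the product-limit survival estimate
#' \deqn{\hat S(t) = \prod_{t_i \le t} (1 - d_i/n_i)}
#' over the distinct observed times, with the Greenwood variance
#' \deqn{\widehat{Var}[\hat S(t)] = \hat S(t)^2 \sum_{t_i \le t}
#'   \frac{d_i}{n_i (n_i - d_i)}}
#' and pointwise confidence bounds. At tied times, events precede censorings:
#' a subject censored at an event time remains at risk for that event.
#'
#' The default confidence transform is complementary log-log, which keeps the
#' bounds inside \[0, 1\]; `"plain"` gives the untransformed Wald interval.
#'
#' @param time positive observed times.
#' @param event event indicators (1 = event, 0 = censored).
#' @param confLevel confidence level, default 0.95.
#' @param confType `"log-log"` (default) or `"plain"`.
#' @param label optional stratum label stored on the curve.
#' @return a [KMCurve-class]. An all-censored input yields a valid curve with
#'   S identically 1.
#' @examples
#' fit <- kmFit(c(1, 2, 2, 3), c(1, 0, 1, 1))
#' lifeTable(fit)
#' @export
kmFit <- function(time, event, confLevel = 0.95,
                  confType = c("log-log", "plain"), label = "") {
  confType <- match.arg(confType)
  if (length(time) == 0L) stop("empty input: at least one subject is required")
  if (length(time) != length(event)) stop("time and event lengths differ")
  if (any(!is.finite(time) | time <= 0)) stop("times must be positive and finite")
  event <- as.integer(event)
  if (!all(event %in% c(0L, 1L))) stop("event must be binary 0/1")

  ut <- sort(unique(time))
  nEvent <- vapply(ut, function(t) sum(time == t & event == 1L), integer(1))
  nCensor <- vapply(ut, function(t) sum(time == t & event == 0L), integer(1))
  n <- length(time)
  # at-risk just before each distinct time (ties: events first, so censorings
  # at t are still at risk at t)
  nRisk <- n - cumsum(c(0L, nEvent[-length(nEvent)] + nCensor[-length(nCensor)]))

  frac <- ifelse(nRisk > 0, nEvent / nRisk, 0)
  surv <- cumprod(1 - frac)
  gwTerm <- ifelse(nRisk > nEvent, nEvent / (nRisk * (nRisk - nEvent)), 0)
  gwCum <- cumsum(gwTerm)
  stdErr <- surv * sqrt(gwCum)

  z <- stats::qnorm(1 - (1 - confLevel) / 2)
  if (confType == "plain") {
    lower <- pmax(surv - z * stdErr, 0)
    upper <- pmin(surv + z * stdErr, 1)
  } else {
    # CI on log(-log S); collapses at S = 1 and S = 0
    lower <- upper <- rep(NA_real_, length(surv))
    ok <- surv > 0 & surv < 1
    seClog <- sqrt(gwCum[ok]) / abs(log(surv[ok]))
    lower[ok] <- surv[ok]^exp(z * seClog)
    upper[ok] <- surv[ok]^exp(-z * seClog)
    lower[surv == 0] <- 0
    upper[surv == 0] <- 0
    lower[surv == 1] <- NA_real_
    upper[surv == 1] <- NA_real_
  }

  new("KMCurve",
      time = as.numeric(ut), nRisk = as.integer(nRisk),
      nEvent = nEvent, nCensor = nCensor,
      surv = surv, stdErr = stdErr, lower = lower, upper = upper,
      confLevel = confLevel, confType = confType,
      n = as.integer(n), label = label)
}

#' @describeIn kmFit exact tabular rendering of the curve.
#' @export
setMethod("lifeTable", "KMCurve", function(object) {
  data.frame(
    time = object@time,
    n_at_risk = object@nRisk,
    n_events = object@nEvent,
    n_censored = object@nCensor,
    survival = object@surv,
    std_err = object@stdErr,
    ci_lower = object@lower,
    ci_upper = object@upper
  )
})

setMethod("show", "KMCurve", function(object) {
  cat("KMCurve", if (nzchar(object@label)) paste0("[", object@label, "]"),
      ": n =", object@n, ", events =", sum(object@nEvent), "\n")
  if (length(object@surv))
    cat("  final S =", signif(utils::tail(object@surv, 1), 4),
        "at t =", utils::tail(object@time, 1), "\n")
})

#' Survival probability at given times
#'
#' Step-function evaluation of a fitted curve: S(t) is the estimate at the
#' largest curve time not exceeding `t` (1 before the first).
#'
#' @param curve a [KMCurve-class].
#' @param times numeric vector.
#' @return numeric vector of survival probabilities.
#' @export
survivalAt <- function(curve, times) {
  stopifnot(is(curve, "KMCurve"))
  idx <- findInterval(times, curve@time)
  c(1, curve@surv)[idx + 1L]
}

#' Stratified Kaplan-Meier curves for a cohort
#'
#' Fits one product-limit curve per non-empty (arm, carrier) stratum of the
#' analyzed cohort, plus the pooled null-model curve over all patients, and
#' computes pairwise log-rank comparisons between the non-empty strata. Empty
#' strata are skipped with a warning; with fewer than two non-empty strata the
#' comparisons are suppressed.
#'
#' @param cohort a stratified [CohortFrame-class].
#' @param confLevel,confType passed to [kmFit()].
#' @return a [KMStrata-class].
#' @export
kmStrata <- function(cohort, confLevel = 0.95, confType = "log-log") {
  stopifnot(is(cohort, "CohortFrame"))
  full <- cohort@data
  d <- .analyzedRows(cohort)
  nullCurve <- kmFit(full$time, full$event, confLevel, confType, label = "null")

  armLab <- cohort@armLevels[as.character(d$arm)]
  svLab <- ifelse(d$carrier, "SV", "no-SV")
  strata <- list()
  groups <- expand.grid(arm = unname(cohort@armLevels), sv = c("SV", "no-SV"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(groups))) {
    sel <- armLab == groups$arm[i] & svLab == groups$sv[i]
    lab <- paste(groups$arm[i], groups$sv[i], sep = "/")
    if (!any(sel)) { warning("empty stratum skipped: ", lab); next }
    strata[[lab]] <- kmFit(d$time[sel], d$event[sel], confLevel, confType,
                           label = lab)
  }

  pw <- data.frame(group_a = character(), group_b = character(),
                   chisq = numeric(), p_value = numeric(),
                   stringsAsFactors = FALSE)
  labs <- names(strata)
  if (length(labs) >= 2) {
    sel <- lapply(labs, function(l) {
      armsv <- strsplit(l, "/", fixed = TRUE)[[1]]
      armLab == armsv[1] & svLab == paste(armsv[-1], collapse = "/")
    })
    names(sel) <- labs
    for (i in seq_len(length(labs) - 1)) for (j in seq(i + 1, length(labs))) {
      lr <- logrank(d$time[sel[[i]]], d$event[sel[[i]]],
                    d$time[sel[[j]]], d$event[sel[[j]]])
      pw <- rbind(pw, data.frame(group_a = labs[i], group_b = labs[j],
                                 chisq = lr@chisq, p_value = lr@pValue,
                                 stringsAsFactors = FALSE))
    }
  } else warning("fewer than two non-empty strata; pairwise comparisons suppressed")

  new("KMStrata", curves = strata, null = nullCurve, pairwise = pw)
}

setMethod("show", "KMStrata", function(object) {
  cat("KMStrata with", length(object@curves), "stratum curves",
      "(null-model n =", object@null@n, ")\n")
  for (l in names(object@curves))
    cat("  ", l, ": n = ", object@curves[[l]]@n,
        ", events = ", sum(object@curves[[l]]@nEvent), "\n", sep = "")
})

#' Two-panel life table of a stratified fit
#'
#' Renders the life tables of all stratum curves, partitioned into an SV
#' panel and a no-SV panel, covering the analyzed cohort.
#'
#' @param strata a [KMStrata-class].
#' @return data.frame: panel ("SV" or "no-SV"), stratum label, and the
#'   [lifeTable()] columns.
#' @export
cohortLifeTable <- function(strata) {
  stopifnot(is(strata, "KMStrata"))
  out <- lapply(names(strata@curves), function(l) {
    lt <- lifeTable(strata@curves[[l]])
    panel <- if (grepl("/SV$", l)) "SV" else "no-SV"
    cbind(data.frame(panel = panel, stratum = l, stringsAsFactors = FALSE), lt)
  })
  do.call(rbind, out)
}

#' At-risk counts at round time points
#'
#' Risk-table summary of a stratified fit: the number of subjects still at
#' risk in each stratum at a grid of round time points (by default a
#' `pretty()` grid over the follow-up range).
#'
#' @param strata a [KMStrata-class].
#' @param times optional explicit time grid.
#' @return data.frame with one row per stratum and one column per time point.
#' @export
riskTable <- function(strata, times = NULL) {
  stopifnot(is(strata, "KMStrata"))
  allT <- unlist(lapply(strata@curves, function(cu) cu@time))
  if (is.null(times)) times <- pretty(c(0, max(allT)), n = 6)
  atRisk <- function(cu, t) {
    # subjects with observed time >= t
    if (t <= min(cu@time)) return(cu@n)
    sum((cu@nEvent + cu@nCensor)[cu@time >= t])
  }
  rows <- lapply(names(strata@curves), function(l) {
    cu <- strata@curves[[l]]
    vals <- vapply(times, function(t) atRisk(cu, t), numeric(1))
    stats::setNames(data.frame(stratum = l, t(vals), stringsAsFactors = FALSE),
                    c("stratum", paste0("t_", times)))
  })
  do.call(rbind, rows)
}
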
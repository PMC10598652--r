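#' @include AllClasses.R AllGenerics.R
NULL

.revcumsum <- function(x) rev(cumsum(rev(x)))

# Pre-sort the data and index the tied-event groups once per fit.
.coxPrep <- function(time, event, X) {
  ord <- order(time)
  time <- time[ord]; event <- as.integer(event[ord])
  X <- X[ord, , drop = FALSE]
  ets <- unique(time[event == 1L])
  groups <- lapply(ets, function(t) {
    list(start = match(TRUE, time >= t),        # risk set = start:n (ascending sort)
         idxD = which(time == t & event == 1L))
  })
  list(time = time, event = event, X = X, n = length(time), p = ncol(X),
       groups = groups,
       d = vapply(groups, function(g) length(g$idxD), integer(1)))
}

# Partial log-likelihood, score and observed information at beta.
# Risk-set sums come from reverse cumulative sums; tied-event groups get the
# Efron (default) or Breslow correction. Groups with a single event need no
# correction and are handled vectorized.
.coxLik <- function(beta, prep, ties) {
  X <- prep$X; p <- prep$p; n <- prep$n
  eta <- drop(X %*% beta)
  eta <- eta - max(eta)                      # guard exp() overflow; cancels in ratios
  w <- exp(eta)
  S0r <- .revcumsum(w)
  S1r <- apply(X * w, 2, .revcumsum)
  if (n == 1L) S1r <- matrix(S1r, nrow = 1)
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  S2r <- vapply(seq_len(nrow(pairs)), function(k)
    .revcumsum(w * X[, pairs[k, 1]] * X[, pairs[k, 2]]), numeric(n))
  if (n == 1L) S2r <- matrix(S2r, nrow = 1)

  ll <- 0; U <- numeric(p); I <- matrix(0, p, p)
  addInfo <- function(I, s2vec, s1vec, denom) {
    # accumulate S2/denom - outer(S1, S1)/denom^2 from packed upper-tri S2
    for (k in seq_len(nrow(pairs))) {
      j1 <- pairs[k, 1]; j2 <- pairs[k, 2]
      v <- s2vec[k] / denom - s1vec[j1] * s1vec[j2] / denom^2
      I[j1, j2] <- I[j1, j2] + v
      if (j1 != j2) I[j2, j1] <- I[j2, j1] + v
    }
    I
  }

  single <- which(prep$d == 1L)
  if (length(single)) {
    st <- vapply(prep$groups[single], `[[`, integer(1), "start")
    ev <- vapply(prep$groups[single], function(g) g$idxD[1], integer(1))
    S0g <- S0r[st]
    ll <- ll + sum(eta[ev]) - sum(log(S0g))
    for (j in seq_len(p))
      U[j] <- U[j] + sum(X[ev, j]) - sum(S1r[st, j] / S0g)
    for (k in seq_len(nrow(pairs))) {
      j1 <- pairs[k, 1]; j2 <- pairs[k, 2]
      v <- sum(S2r[st, k] / S0g - S1r[st, j1] * S1r[st, j2] / S0g^2)
      I[j1, j2] <- I[j1, j2] + v
      if (j1 != j2) I[j2, j1] <- I[j2, j1] + v
    }
  }

  for (gi in which(prep$d > 1L)) {
    g <- prep$groups[[gi]]
    d <- length(g$idxD)
    S0 <- S0r[g$start]; S1 <- S1r[g$start, ]; S2 <- S2r[g$start, ]
    wD <- w[g$idxD]
    s0d <- sum(wD)
    s1d <- colSums(X[g$idxD, , drop = FALSE] * wD)
    s2d <- vapply(seq_len(nrow(pairs)), function(k)
      sum(wD * X[g$idxD, pairs[k, 1]] * X[g$idxD, pairs[k, 2]]), numeric(1))
    a <- if (ties == "efron") (seq_len(d) - 1) / d else rep(0, d)
    denom <- S0 - a * s0d
    ll <- ll + sum(eta[g$idxD]) - sum(log(denom))
    for (j in seq_len(p))
      U[j] <- U[j] + sum(X[g$idxD, j]) - sum((S1[j] - a * s1d[j]) / denom)
    for (l in seq_len(d))
      I <- addInfo(I, S2 - a[l] * s2d, S1 - a[l] * s1d, denom[l])
  }
  list(ll = ll, U = U, I = I)
}

#' Cox proportional-hazards regression
#'
#' Maximizes the partial likelihood of \eqn{h(t \mid x) = h_0(t)\exp(x'\beta)}
#' by Newton-Raphson with step-halving, starting from \eqn{\beta = 0}. Tied
#' event times are handled by the Efron approximation (default) or Breslow's.
#' Standard errors are the square roots of the inverse observed information
#' diagonal; Wald confidence intervals are \eqn{\exp(\hat\beta \pm
#' z_{\alpha/2}\,\mathrm{se})}. The fit is fully deterministic.
#'
#' Monotone likelihood (complete separation — a coefficient escaping past 10
#' on the log scale with a non-vanishing score) yields a flagged,
#' non-converged result rather than an error. A singular information matrix
#' (collinear covariates) is an error naming the offending columns.
#'
#' @param time positive observed times.
#' @param event event indicators (1 = event, 0 = censored); at least one
#'   event is required.
#' @param X covariate matrix (columns are terms; constant columns are
#'   rejected).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param tol convergence tolerance on the score norm, default 1e-9.
#' @param maxIter maximum Newton-Raphson iterations, default 25.
#' @param confLevel Wald confidence level, default 0.95.
#' @return a [CoxFit-class].
#' @examples
#' # alternating binary covariate, no ties: beta-hat = log((-1 + sqrt(17))/8)
#' fit <- coxFit(1:4, rep(1, 4), cbind(x = c(0, 1, 0, 1)))
#' fit
#' @export
coxFit <- function(time, event, X, ties = c("efron", "breslow"),
                   tol = 1e-9, maxIter = 25L, confLevel = 0.95) {
  ties <- match.arg(ties)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  event <- as.integer(event)
  stopifnot(length(time) == length(event), nrow(X) == length(time))
  if (sum(event) < 1L) stop("at least one event is required")
  const <- apply(X, 2, function(col) all(col == col[1]))
  if (any(const))
    stop("constant covariate column(s): ",
         paste(colnames(X)[const], collapse = ", "))

  prep <- .coxPrep(time, event, X)
  p <- ncol(X)
  beta <- numeric(p)
  cur <- .coxLik(beta, prep, ties)
  ll0 <- cur$ll
  converged <- FALSE; monotone <- FALSE; iter <- 0L
  for (it in seq_len(maxIter)) {
    iter <- it
    if (sqrt(sum(cur$U^2)) < tol) { converged <- TRUE; iter <- it - 1L; break }
    qrI <- qr(cur$I)
    if (qrI$rank < p) {
      dep <- colnames(X)[qrI$pivot[seq(qrI$rank + 1L, p)]]
      stop("singular information matrix; collinear column(s): ",
           paste(dep, collapse = ", "))
    }
    delta <- solve(qrI, cur$U)
    step <- 1
    repeat {
      cand <- beta + step * delta
      candLik <- .coxLik(cand, prep, ties)
      if (isTRUE(candLik$ll >= cur$ll - 1e-12) || step < 1e-8) break
      step <- step / 2
    }
    beta <- cand; cur <- candLik
    if (any(abs(beta) > 10) && sqrt(sum(cur$U^2)) >= tol) {
      monotone <- TRUE
      break
    }
  }
  if (!monotone && sqrt(sum(cur$U^2)) < tol) converged <- TRUE

  covBeta <- tryCatch(solve(cur$I), error = function(e)
    matrix(NA_real_, p, p))
  names(beta) <- colnames(X)
  se <- stats::setNames(sqrt(pmax(diag(covBeta), 0)), colnames(X))
  z <- beta / se
  zq <- stats::qnorm(1 - (1 - confLevel) / 2)
  new("CoxFit",
      coef = beta,
      hr = exp(beta), se = se, z = z,
      pValue = 2 * stats::pnorm(-abs(z)),
      ciLower = exp(beta - zq * se), ciUpper = exp(beta + zq * se),
      loglik = c(ll0, cur$ll), n = as.integer(length(time)),
      nEvent = as.integer(sum(event)), ties = ties,
      converged = converged, monotone = monotone, iter = as.integer(iter),
      confLevel = confLevel, config = "")
}

setMethod("show", "CoxFit", function(object) {
  cat("CoxFit (", object@ties, " ties): n = ", object@n,
      ", events = ", object@nEvent,
      if (nzchar(object@config)) paste0(", config = ", object@config),
      "\n", sep = "")
  if (!object@converged)
    cat("  WARNING:", if (object@monotone) "monotone likelihood (separation)"
        else "did not converge", "\n")
  tab <- data.frame(coef = signif(object@coef, 4),
                    HR = signif(object@hr, 4),
                    se = signif(object@se, 4),
                    p = signif(object@pValue, 4))
  print(tab)
  cat("  loglik:", signif(object@loglik[1], 6), "->",
      signif(object@loglik[2], 6), "in", object@iter, "iterations\n")
})

#' Cox score test at beta = 0
#'
#' The score statistic \eqn{U(0)' I(0)^{-1} U(0)} of a Cox model with Breslow
#' tie handling. With a single binary group covariate and untied event times
#' this is algebraically identical to the log-rank chi-square.
#'
#' @param time,event survival outcome vectors.
#' @param X covariate matrix.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return list with `chisq`, `df` and `pValue`.
#' @export
coxScoreTest <- function(time, event, X, ties = "breslow") {
  X <- as.matrix(X)
  prep <- .coxPrep(time, as.integer(event), X)
  at0 <- .coxLik(numeric(ncol(X)), prep, ties)
  chisq <- drop(crossprod(at0$U, solve(at0$I, at0$U)))
  list(chisq = chisq, df = ncol(X),
       pValue = stats::pchisq(chisq, df = ncol(X), lower.tail = FALSE))
}

# Build the covariate design from cohort columns: numeric covariates as-is,
# categorical ones as treatment-coded dummies against the first level.
.designMatrix <- function(d, covariates, kinds) {
  cols <- list()
  for (cov in covariates) {
    if (identical(unname(kinds[cov]), "categorical") || is.character(d[[cov]])) {
      f <- factor(d[[cov]])
      mm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cov, levels(f)[-1])
      cols[[cov]] <- mm
    } else cols[[cov]] <- stats::setNames(data.frame(d[[cov]]), cov)
  }
  if (!length(cols)) return(NULL)
  as.matrix(do.call(cbind, cols))
}

#' Standard and Multiple Cox model configurations for a cohort
#'
#' Fits the cohort's survival outcome in the two configurations reported by
#' the workflow:
#' \describe{
#'   \item{Standard}{one model on all analyzed patients with treatment arm,
#'     SV-carrier status and the requested covariates.}
#'   \item{Multiple}{separate models within the carrier and the non-carrier
#'     subsets, each with treatment arm and the requested covariates.}
#' }
#' A subset without events (or without patients) is reported as not estimable
#' rather than raising. Hazard ratios of continuous covariates are per-unit
#' effects in the covariate's own unit.
#'
#' @param cohort a stratified [CohortFrame-class].
#' @param covariates character vector of covariate column names (must have
#'   been declared in the [columnMap()]).
#' @param ties,confLevel passed to [coxFit()].
#' @return named list with elements `standard`, `multiple_carrier`,
#'   `multiple_noncarrier`; each a [CoxFit-class] or the string
#'   `"not estimable"` with a `reason` attribute.
#' @export
fitStandardAndMultiple <- function(cohort, covariates = character(),
                                   ties = "efron", confLevel = 0.95) {
  stopifnot(is(cohort, "CohortFrame"))
  d <- .analyzedRows(cohort)
  known <- names(cohort@covariateKinds)
  bad <- setdiff(covariates, known)
  if (length(bad))
    stop("unknown covariate(s): ", paste(bad, collapse = ", "),
         "; available: ", if (length(known)) paste(known, collapse = ", ")
         else "(none)")

  fitOne <- function(rows, baseTerms, config) {
    if (nrow(rows) < 2L || sum(rows$event) < 1L) {
      out <- "not estimable"
      attr(out, "reason") <- sprintf("%d patients, %d events",
                                     nrow(rows), sum(rows$event))
      return(out)
    }
    Xc <- .designMatrix(rows, covariates, cohort@covariateKinds)
    Xbase <- do.call(cbind, baseTerms(rows))
    X <- if (is.null(Xc)) Xbase else cbind(Xbase, Xc)
    out <- tryCatch(
      coxFit(rows$time, rows$event, X, ties = ties, confLevel = confLevel),
      error = function(e) {
        r <- "not estimable"; attr(r, "reason") <- conditionMessage(e); r
      })
    if (is(out, "CoxFit")) out@config <- config
    out
  }

  list(
    standard = fitOne(
      d, function(r) list(arm = cbind(arm = r$arm),
                          carrier = cbind(carrier = as.integer(r$carrier))),
      "standard"),
    multiple_carrier = fitOne(
      d[d$carrier, , drop = FALSE],
      function(r) list(arm = cbind(arm = r$arm)), "multiple:carrier"),
    multiple_noncarrier = fitOne(
      d[!d$carrier, , drop = FALSE],
      function(r) list(arm = cbind(arm = r$arm)), "multiple:noncarrier")
  )
}

#' Hazard-ratio report table
#'
#' Formats a Cox fit as report rows: term, hazard ratio with Wald confidence
#' bounds and p-value, plus a percent-effect rendering
#' \eqn{100 (\mathrm{HR} - 1)} for reading continuous per-unit effects (an HR
#' of 1.02 prints as "+2%": each unit increase raises the instantaneous risk
#' by two percent). Non-converged fits carry a separation note on every row.
#'
#' @param fit a [CoxFit-class] (or `"not estimable"` marker, giving a
#'   zero-row table).
#' @param digits decimals for the formatted columns, default 2.
#' @return data.frame with columns term, hr, ci_lower, ci_upper, p_value,
#'   hr_label, pct_effect, note.
#' @export
hazardRatioTable <- function(fit, digits = 2) {
  if (!is(fit, "CoxFit")) {
    return(data.frame(term = character(), hr = numeric(),
                      ci_lower = numeric(), ci_upper = numeric(),
                      p_value = numeric(), hr_label = character(),
                      pct_effect = character(), note = character()))
  }
  pct <- round(100 * (fit@hr - 1), digits)
  pctLab <- ifelse(pct == 0, "0%", sprintf("%+g%%", pct))
  note <- if (!fit@converged)
    if (fit@monotone) "monotone likelihood (separation)" else "not converged"
  else ""
  data.frame(
    term = names(fit@coef),
    hr = fit@hr,
    ci_lower = fit@ciLower,
    ci_upper = fit@ciUpper,
    p_value = fit@pValue,
    hr_label = formatC(fit@hr, format = "f", digits = digits),
    pct_effect = pctLab,
    note = note,
    row.names = NULL, stringsAsFactors = FALSE
  )
}
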
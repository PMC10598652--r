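#' @include AllClasses.R AllGenerics.R
NULL

#' Two-group log-rank test
#'
#' Compares the survival experience of two groups over the pooled distinct
#' event times. At each event time \eqn{t_j} with \eqn{n_j} subjects at risk
#' (\eqn{n_{Aj}} in group A) and \eqn{d_j} events, the expected group-A event
#' count is \eqn{d_j n_{Aj} / n_j} and the hypergeometric variance is
#' \deqn{V_j = d_j \frac{n_{Aj}}{n_j}\Big(1 - \frac{n_{Aj}}{n_j}\Big)
#'   \frac{n_j - d_j}{n_j - 1}.}
#' The statistic \eqn{(O_A - E_A)^2 / V} is compared to a chi-square with one
#' degree of freedom.
#'
#' @param timeA,eventA times and event indicators of group A.
#' @param timeB,eventB times and event indicators of group B.
#' @return a [LogRankResult-class]. A group with zero events is valid; two
#'   empty groups are an error.
#' @examples
#' logrank(c(1, 3), c(1, 1), c(2, 4), c(1, 1))  # chi-square 8/13
#' @export
logrank <- function(timeA, eventA, timeB, eventB) {
  if (!length(timeA) || !length(timeB))
    stop("both groups must be non-empty")
  stopifnot(length(timeA) == length(eventA), length(timeB) == length(eventB))
  time <- c(timeA, timeB)
  event <- as.integer(c(eventA, eventB))
  grpA <- rep(c(TRUE, FALSE), c(length(timeA), length(timeB)))

  ts <- sort(unique(time[event == 1L]))
  Oa <- Ea <- V <- 0
  for (t in ts) {
    atRisk <- time >= t
    nj <- sum(atRisk)
    nAj <- sum(atRisk & grpA)
    dj <- sum(time == t & event == 1L)
    dAj <- sum(time == t & event == 1L & grpA)
    Oa <- Oa + dAj
    Ea <- Ea + dj * nAj / nj
    if (nj > 1)
      V <- V + dj * (nAj / nj) * (1 - nAj / nj) * (nj - dj) / (nj - 1)
  }
  totalEvents <- sum(event)
  chisq <- if (V > 0) (Oa - Ea)^2 / V else 0
  new("LogRankResult",
      observed = c(A = Oa, B = totalEvents - Oa),
      expected = c(A = Ea, B = totalEvents - Ea),
      var = V, chisq = chisq, df = 1L,
      pValue = stats::pchisq(chisq, df = 1, lower.tail = FALSE))
}

setMethod("show", "LogRankResult", function(object) {
  cat("Log-rank test: chisq =", signif(object@chisq, 4),
      "on", object@df, "df, p =", signif(object@pValue, 4), "\n")
  cat("  observed:", paste(names(object@observed),
                           signif(object@observed, 4), sep = "=", collapse = " "),
      " expected:", paste(names(object@expected),
                          signif(object@expected, 4), sep = "=", collapse = " "), "\n")
})
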
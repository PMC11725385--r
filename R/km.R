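# Kaplan-Meier product-limit estimation and the two-group log-rank test.

#' Kaplan-Meier product-limit estimator
#'
#' \eqn{S(t) = \prod_{t_j \le t} (1 - d_j / n_j)} over the distinct
#' event times \eqn{t_j}, with censored individuals leaving the risk
#' set after their censoring time.  The median is the smallest time
#' with \eqn{S(t) \le 0.5} (`NA_real_` if survival never reaches 0.5,
#' e.g. when all records are censored).  Greenwood standard errors and
#' 95% log-log confidence limits are attached for information.
#'
#' @param time event or censoring times in days (>= 0); alternatively a
#'   data.frame of survival records with columns `time_days` (or
#'   `time`) and `event`.
#' @param event event indicator, 1 = death observed, 0 = censored.
#' @return A [KMCurve-class].
#' @examples
#' kmFit(c(1, 2, 3, 4), c(1, 1, 1, 1))  # median 2
#' @export
kmFit <- function(time, event = NULL) {
  if (is.data.frame(time)) {
    df <- time
    tcol <- if ("time_days" %in% names(df)) "time_days" else "time"
    time <- df[[tcol]]
    event <- df$event
  }
  time <- as.numeric(time); event <- as.numeric(event)
  if (length(time) == 0L) .stopf("no survival records")
  if (any(!is.finite(time)) || any(time < 0)) .stopf("times must be >= 0")
  if (!all(event %in% c(0, 1))) .stopf("event must be 0/1")

  et <- sort(unique(time[event == 1]))
  if (length(et) == 0L) {
    return(new("KMCurve", time = numeric(0), nRisk = numeric(0),
               nEvent = numeric(0), surv = numeric(0), se = numeric(0),
               lower = numeric(0), upper = numeric(0), median = NA_real_,
               nTotal = length(time), nEvents = 0L))
  }
  nRisk <- vapply(et, function(t) sum(time >= t), numeric(1))
  nEvent <- vapply(et, function(t) sum(time == t & event == 1), numeric(1))
  surv <- cumprod(1 - nEvent / nRisk)
  gw <- cumsum(nEvent / (nRisk * pmax(nRisk - nEvent, 1e-300)))
  se <- surv * sqrt(gw)
  z <- stats::qnorm(0.975)
  lower <- upper <- rep(NA_real_, length(surv))
  ok <- surv > 0 & surv < 1
  cl_se <- sqrt(gw[ok]) / abs(log(surv[ok]))
  lower[ok] <- surv[ok]^exp(z * cl_se)
  upper[ok] <- surv[ok]^exp(-z * cl_se)
  med <- if (any(surv <= 0.5 + 1e-12)) et[which(surv <= 0.5 + 1e-12)[1L]]
         else NA_real_
  new("KMCurve", time = et, nRisk = nRisk, nEvent = nEvent, surv = surv,
      se = se, lower = lower, upper = upper, median = med,
      nTotal = length(time), nEvents = as.integer(sum(event)))
}

#' Survival probability at given times
#' @param curve a [KMCurve-class].
#' @param t times at which to evaluate the step function S(t).
#' @export
kmSurvivalAt <- function(curve, t) {
  vapply(t, function(tt) {
    i <- sum(curve@time <= tt + 1e-12)
    if (i == 0L) 1 else curve@surv[i]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square: at each distinct event time the
#' observed events in group 1 are compared with their hypergeometric
#' expectation \eqn{E_1 = d\,n_1/n} and variance
#' \eqn{V = d\,(n_1/n)(1 - n_1/n)(n - d)/(n - 1)}; the statistic
#' \eqn{(O_1 - E_1)^2 / V} is referred to a chi-square with 1 df.
#' Invariant to swapping group labels.  An optional permutation p-value
#' (label reshuffling, add-one convention) is available via `nPerm`.
#'
#' @param time,event as in [kmFit()]; `time` may be a records
#'   data.frame, in which case `event` is taken from it and `group`
#'   names a column.
#' @param group two-level factor (or the name of a records column).
#' @param nPerm permutation count for the optional permutation p
#'   (default 0 = parametric only).
#' @param seed RNG seed for the permutations.
#' @return A [LogrankResult-class].
#' @export
logrankTest <- function(time, event = NULL, group, nPerm = 0L, seed = 1L) {
  if (is.data.frame(time)) {
    df <- time
    tcol <- if ("time_days" %in% names(df)) "time_days" else "time"
    if (is.character(group) && length(group) == 1L && group %in% names(df))
      group <- df[[group]]
    event <- df$event
    time <- df[[tcol]]
  }
  group <- droplevels(as.factor(group))
  if (nlevels(group) != 2L) .stopf("log-rank test requires exactly 2 groups")
  if (any(table(group) == 0L)) .stopf("one group is empty")
  time <- as.numeric(time); event <- as.numeric(event)
  if (sum(event) == 0) .stopf("no events observed")

  chisqStat <- function(g) {
    g1 <- levels(g)[1L]
    et <- sort(unique(time[event == 1]))
    O <- E <- V <- 0
    for (t in et) {
      atRisk <- time >= t
      n <- sum(atRisk)
      n1 <- sum(atRisk & g == g1)
      d <- sum(time == t & event == 1)
      d1 <- sum(time == t & event == 1 & g == g1)
      O <- O + d1
      E <- E + d * n1 / n
      if (n > 1)
        V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
    list(chisq = if (V > 0) (O - E)^2 / V else 0, O = O, E = E)
  }
  obs <- chisqStat(group)
  g1 <- levels(group)[1L]; g2 <- levels(group)[2L]
  observed <- c(obs$O, sum(event) - obs$O)
  expected <- c(obs$E, sum(event) - obs$E)
  names(observed) <- names(expected) <- c(g1, g2)
  permP <- NA_real_
  if (nPerm > 0L) {
    perm <- .withStreamSeed(seed, 5L,
      vapply(seq_len(nPerm), function(i)
        chisqStat(sample(group))$chisq, numeric(1)))
    permP <- .permPValue(obs$chisq, perm)
  }
  new("LogrankResult", statistic = obs$chisq,
      pValue = stats::pchisq(obs$chisq, df = 1, lower.tail = FALSE),
      observed = observed, expected = expected, permPValue = permP)
}
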
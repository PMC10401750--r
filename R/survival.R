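## Survival machinery: Kaplan-Meier, log-rank, Cox PH (delegated to the
## survival package) and a hand-rolled Harrell's C with the pair convention
## used by the cutoff search.

#' @importFrom survival Surv survfit survdiff coxph concordance
NULL

check_surv <- function(times, events) {
  stopifnot(length(times) == length(events))
  if (length(times) == 0) stop("empty survival sample")
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("survival times must be finite and non-negative")
  }
  events <- as.logical(events)
  if (anyNA(events)) stop("missing event indicators")
  events
}

#' Kaplan-Meier estimate
#'
#' Product-limit estimator of the survival function. The median is the
#' smallest observed time at which the step function drops to 0.5 or below
#' (right-continuous convention); `NA` when the curve never reaches 0.5.
#'
#' @param times observed times (months).
#' @param events logical/0-1 event indicators (`TRUE` = event).
#' @return list of class `km_curve` with elements `time` (event/censoring
#'   step times), `n_risk`, `n_event`, `survival`, `median`, `n`.
#' @examples
#' km <- kmEstimate(c(1, 2, 3), c(TRUE, TRUE, TRUE))
#' km$survival  # 2/3, 1/3, 0
#' km$median    # 2
#' @export
kmEstimate <- function(times, events) {
  events <- check_surv(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  s <- fit$surv
  # tolerance so that S == 0.5 reached via different floating orders agrees
  med <- if (any(s <= 0.5 + 1e-9)) fit$time[which(s <= 0.5 + 1e-9)[1]] else NA_real_
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, survival = s,
                 median = med, n = length(times)),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, ", events =", sum(x$n_event),
      ", median =", if (is.na(x$median)) "not reached" else x$median, "\n")
  invisible(x)
}

#' Export a KM curve as a plain table
#'
#' @param curve a `km_curve` from [kmEstimate()].
#' @param path optional TSV path; when given the table is also written.
#' @return `data.frame` with columns `time`, `n_at_risk`, `survival`.
#' @export
kmCurveTable <- function(curve, path = NULL) {
  out <- data.frame(time = curve$time, n_at_risk = curve$n_risk,
                    survival = curve$survival)
  if (!is.null(path)) {
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Log-rank test between survival groups
#'
#' @param times,events as in [kmEstimate()].
#' @param group group labels (2 or more non-empty groups).
#' @return list with `chi2`, `df` (k - 1), `p`.
#' @export
logrankTest <- function(times, events, group) {
  events <- check_surv(times, events)
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stop("log-rank test needs at least 2 groups")
  if (any(table(group) == 0)) stop("empty group in log-rank test")
  sd <- survival::survdiff(survival::Surv(times, events) ~ group)
  df <- length(sd$n) - 1
  list(chi2 = unname(sd$chisq), df = df,
       p = stats::pchisq(sd$chisq, df = df, lower.tail = FALSE))
}

#' Cox proportional-hazards fit
#'
#' Maximum partial-likelihood estimates with the Efron approximation for tied
#' event times and 95 percent Wald intervals.
#'
#' @param times,events as in [kmEstimate()].
#' @param covariates numeric matrix/data.frame (or single vector), one column
#'   per covariate.
#' @return `data.frame` with one row per covariate: `term`, `loghr`, `hr`,
#'   `se`, `hr_lower`, `hr_upper`, `p`.
#' @export
coxFit <- function(times, events, covariates) {
  events <- check_surv(times, events)
  if (sum(events) == 0) stop("Cox fit requires at least one event")
  X <- as.matrix(covariates)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  fit <- survival::coxph(survival::Surv(times, events) ~ X, ties = "efron")
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(stats::vcov(fit)))
  if (any(abs(beta) > 15)) {
    warning("possible separation: log hazard ratio beyond +/-15")
  }
  z <- beta / se
  data.frame(term = colnames(X), loghr = beta, hr = exp(beta), se = se,
             hr_lower = exp(beta - 1.96 * se),
             hr_upper = exp(beta + 1.96 * se),
             p = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}

#' Harrell's concordance index
#'
#' Fraction of comparable patient pairs in which the patient failing earlier
#' carries the strictly higher risk score; risk ties count 0.5. A pair is
#' comparable when the shorter observed time is an event (pairs with equal
#' times are comparable only when exactly one is an event, the event member
#' being taken as failing first; pairs with equal event times and both events
#' are omitted).
#'
#' @param times,events as in [kmEstimate()].
#' @param risks numeric risk scores aligned with the sample (higher = worse
#'   predicted outcome).
#' @return list with `c` (concordance, `NA` when no comparable pair exists,
#'   flagged via `n_pairs = 0`), `n_pairs`, `concordant`, `tied`.
#' @examples
#' harrellC(c(5, 3, 9), c(TRUE, TRUE, TRUE), risks = c(2, 3, 1))$c  # 1
#' @export
harrellC <- function(times, events, risks) {
  events <- check_surv(times, events)
  stopifnot(length(risks) == length(times))
  n <- length(times)
  ti <- matrix(times, n, n)
  ei <- matrix(events, n, n)
  ri <- matrix(risks, n, n)
  tj <- t(ti); ej <- t(ei); rj <- t(ri)
  # i fails first: t_i < t_j with event_i, or t_i == t_j with only event_i
  comp <- (ti < tj & ei) | (ti == tj & ei & !ej)
  conc <- sum(comp & ri > rj)
  tied <- sum(comp & ri == rj)
  n_pairs <- sum(comp)
  cval <- if (n_pairs == 0) NA_real_ else (conc + 0.5 * tied) / n_pairs
  list(c = cval, n_pairs = n_pairs, concordant = conc, tied = tied)
}
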
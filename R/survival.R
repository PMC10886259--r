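# Kaplan-Meier and log-rank surface. The estimators themselves come from the
# survival package (survfit / survdiff); this module fixes the conventions
# used throughout the trial engine: log-log (Kalbfleisch-Prentice) confidence
# intervals for time-point rates, Brookmeyer-Crowley inversion for median
# CIs, and the "smallest t with S(t) <= 0.5" median tie rule.

#' Kaplan-Meier fit
#'
#' Product-limit estimator with Greenwood variance; ties are handled as
#' simultaneous events at the shared time.
#'
#' @param times Event/censoring times (months), positive.
#' @param observed Logical (or 0/1) event indicators.
#' @return A `km_curve`: list with `time`, `n_risk`, `n_event`, `survival`,
#'   `greenwood_var`, and the underlying `survfit` object (`fit`).
#' @examples
#' km <- km_fit(1:5, rep(TRUE, 5))
#' km$survival[3] # 0.4
#' @export
km_fit <- function(times, observed) {
  if (length(times) == 0) stop("empty input", call. = FALSE)
  if (length(times) != length(observed)) {
    stop("times and observed must have equal length", call. = FALSE)
  }
  if (any(times <= 0)) stop("times must be positive", call. = FALSE)
  fit <- survival::survfit(
    survival::Surv(times, as.integer(observed)) ~ 1,
    conf.type = "log-log")
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, survival = fit$surv,
                 greenwood_var = (fit$std.err * fit$surv)^2,
                 n = length(times), fit = fit),
            class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  med <- km_median(x)
  cat("km_curve:", x$n, "subjects,", sum(x$n_event), "events; median =",
      if (is.na(med)) "not reached" else round(med, 2), "\n")
  invisible(x)
}

#' Median survival time of a Kaplan-Meier curve
#'
#' Smallest time with `S(t) <= 0.5` (so a plateau at exactly 0.5 reports its
#' earliest time); `NA` when the curve never reaches 0.5 ("not reached").
#' With `conf = TRUE`, also returns the Brookmeyer-Crowley 95% CI.
#'
#' @param curve A [km_fit()] object.
#' @param conf Return the confidence interval as well?
#' @return Months (or `NA`); with `conf = TRUE` a list
#'   `(median, lower, upper)`.
#' @export
km_median <- function(curve, conf = FALSE) {
  idx <- which(curve$survival <= 0.5 + 1e-12)
  med <- if (length(idx) == 0) NA_real_ else curve$time[min(idx)]
  if (!conf) return(med)
  tab <- summary(curve$fit)$table
  list(median = med,
       lower = unname(tab["0.95LCL"]),
       upper = unname(tab["0.95UCL"]))
}

#' Survival or cumulative-incidence rate at a time point
#'
#' Evaluates the step function at `t` with a log-log Greenwood 95% CI.
#' `type = "survival"` returns `S(t)` (e.g. a PFS rate);
#' `type = "incidence"` returns `1 - S(t)` (e.g. a cumulative DM rate).
#' Beyond the last follow-up time the last value is carried forward and
#' flagged.
#'
#' @param curve A [km_fit()] object.
#' @param t Time (months), `>= 0`.
#' @param type `"survival"` or `"incidence"`.
#' @return List `(estimate, lower, upper, extrapolated)`, all within
#'   \[0, 1\].
#' @export
km_rate_at <- function(curve, t, type = c("survival", "incidence")) {
  type <- match.arg(type)
  if (t < 0) stop("t must be >= 0", call. = FALSE)
  sm <- summary(curve$fit, times = t, extend = TRUE)
  est <- sm$surv
  lo <- ifelse(is.na(sm$lower), 0, sm$lower)
  hi <- ifelse(is.na(sm$upper), 1, sm$upper)
  extrap <- t > max(curve$fit$time)
  if (type == "incidence") {
    out <- list(estimate = 1 - est, lower = 1 - hi, upper = 1 - lo)
  } else {
    out <- list(estimate = est, lower = lo, upper = hi)
  }
  out$extrapolated <- extrap
  out
}

#' Two-sample log-rank test
#'
#' Standard (unweighted) log-rank with 1 degree of freedom; deterministic
#' given the inputs and symmetric in the group labels.
#'
#' @param a_times,a_observed Event times (months) and indicators, group A.
#' @param b_times,b_observed Same for group B.
#' @return List `(chisq, p)`.
#' @examples
#' lr <- logrank(1:5, rep(TRUE, 5), 1:5, rep(TRUE, 5))
#' lr$p # 1: identical groups
#' @export
logrank <- function(a_times, a_observed, b_times, b_observed) {
  if (length(a_times) == 0 || length(b_times) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  times <- c(a_times, b_times)
  status <- as.integer(c(a_observed, b_observed))
  group <- rep(c("A", "B"), c(length(a_times), length(b_times)))
  if (sum(status) == 0) return(list(chisq = 0, p = 1))
  sd <- survival::survdiff(survival::Surv(times, status) ~ group)
  list(chisq = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Write a Kaplan-Meier curve as CSV
#'
#' Columns: time, at_risk, events, survival, ci_low, ci_high.
#'
#' @param curve A [km_fit()] object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_km_csv <- function(curve, path) {
  utils::write.csv(data.frame(time = curve$time, at_risk = curve$n_risk,
                              events = curve$n_event,
                              survival = curve$survival,
                              ci_low = ifelse(is.na(curve$fit$lower), 0,
                                              curve$fit$lower),
                              ci_high = ifelse(is.na(curve$fit$upper), 1,
                                               curve$fit$upper)),
                   path, row.names = FALSE)
  invisible(path)
}
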
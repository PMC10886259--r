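# Brute-force survival oracles, independent of the survival package and of
# the package's own km_fit/logrank wrappers. Used on small instances only.

# product-limit estimator by direct enumeration of risk sets
km_oracle <- function(times, observed) {
  ev <- sort(unique(times[observed]))
  surv <- numeric(length(ev))
  s <- 1
  for (i in seq_along(ev)) {
    at_risk <- sum(times >= ev[i])
    d <- sum(times == ev[i] & observed)
    s <- s * (1 - d / at_risk)
    surv[i] <- s
  }
  list(time = ev, surv = surv)
}

km_oracle_at <- function(times, observed, t) {
  o <- km_oracle(times, observed)
  if (!any(o$time <= t)) return(1)
  o$surv[max(which(o$time <= t))]
}

# two-sample log-rank by direct evaluation of sum(O - E) and the
# hypergeometric variance at each distinct event time
logrank_oracle <- function(t1, o1, t2, o2) {
  times <- c(t1, t2)
  obs <- c(o1, o2)
  grp <- rep(1:2, c(length(t1), length(t2)))
  ev <- sort(unique(times[obs]))
  OmE <- 0
  V <- 0
  for (tt in ev) {
    n <- sum(times >= tt)
    n1 <- sum(times >= tt & grp == 1)
    d <- sum(times == tt & obs)
    d1 <- sum(times == tt & obs & grp == 1)
    OmE <- OmE + d1 - d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (V > 0) OmE^2 / V else 0
  list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# small random survival instances for oracle comparisons
random_surv_instance <- function(n, p_cens = 0.3) {
  times <- sample(1:6, n, replace = TRUE) + stats::runif(n, 0, 0.1)
  observed <- stats::runif(n) > p_cens
  if (!any(observed)) observed[1] <- TRUE
  list(times = times, observed = observed)
}

# a small cohort reused across test files
test_cohort <- function(n = 200, seed = 42, ...) {
  sample_cohort(cohort_spec(n = n, seed = seed, ...))
}
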
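#' RECIST response-profile target
#'
#' Published response tables are often rounded so the categories need not
#' sum to exactly 1 (the reference Y90 profile 79/20/0/0 sums to 0.99);
#' sums within 2% of 1 are accepted and renormalized.
#'
#' @param cr,pr,sd,pd Category proportions.
#' @return Named numeric vector of class `response_target`, summing to 1.
#' @examples
#' response_target(0.79, 0.20, 0, 0) # the Y90 monotherapy trial profile
#' @export
response_target <- function(cr, pr, sd, pd) {
  x <- c(CR = cr, PR = pr, SD = sd, PD = pd)
  if (any(x < 0) || any(x > 1)) {
    stop("proportions must lie in [0, 1]", call. = FALSE)
  }
  if (abs(sum(x) - 1) > 0.02) {
    stop("proportions must sum to 1 (within rounding)", call. = FALSE)
  }
  structure(x / sum(x), class = c("response_target", "numeric"))
}

#' Simulated RECIST profile under Y90 monotherapy
#'
#' Runs Y90 monotherapy for each patient with a prescribed per-patient
#' effectiveness `q`, classifies the targeted lesion by RECIST at the
#' assessment month, and returns the CR/PR/SD/PD proportions.
#'
#' @param q_values Per-patient Y90 effectiveness, same length as the cohort.
#' @param cohort Data frame from [sample_cohort()].
#' @param dose Prescribed physical dose (Gy), default 400.
#' @param assess_month Assessment time after the first Y90 dose (months).
#' @param p A [model_parameters()] object.
#' @param n_fractions,kappa_blood Passed to [y90_schedule()].
#' @param cr_cell_threshold CR detection floor (cells).
#' @param dt Integration step (days).
#' @return Named numeric vector `c(CR, PR, SD, PD)` summing to 1.
#' @export
simulate_response_profile <- function(q_values, cohort, dose = 400,
                                      assess_month = 6,
                                      p = model_parameters(),
                                      n_fractions = 26, kappa_blood = 0.05,
                                      cr_cell_threshold = 1e8, dt = 0.25) {
  if (length(q_values) != nrow(cohort)) {
    stop("q_values must match the cohort size", call. = FALSE)
  }
  assess_day <- assess_month * DAYS_PER_MONTH
  sched <- y90_schedule(dose, start = 0, q = 1, p = p,
                        n_fractions = n_fractions,
                        kappa_blood = kappa_blood)
  state0 <- cbind(cohort$T0, cohort$TNI0, 0, cohort$L0)
  res <- cpp_batch_endpoints(state0, cohort$alphaT, q_values,
                             rep(0, nrow(cohort)),
                             sched$time, sched$physical_dose, sched$d_lymph,
                             numeric(0), unclass(p),
                             horizon = assess_day, dt = dt,
                             prog_ratio = 1.2^3, dm_thresh = Inf,
                             assess_day = assess_day, prog_nadir = 0L,
                             nadir_floor = 0)
  ti <- res[, "TI_assess"]
  cls <- classify_recist(volume_to_diameter(cohort$T0 / p$tumor_density),
                         volume_to_diameter(ti / p$tumor_density),
                         ti, cr_cell_threshold)
  tab <- table(factor(cls, levels = c("CR", "PR", "SD", "PD")))
  prop <- as.numeric(tab) / nrow(cohort)
  names(prop) <- c("CR", "PR", "SD", "PD")
  prop
}

#' Fit the Y90 effectiveness distribution to a response profile
#'
#' Searches the (mu, sigma) of a \[0, 1\]-truncated normal for the
#' effectiveness `q` so that the simulated 6-month RECIST proportions under
#' Y90 monotherapy match a clinical target profile, minimizing the L1
#' distance between the two category vectors. A coarse grid pass is followed
#' by a Nelder-Mead refinement; every evaluation reuses the same cohort and
#' the same uniform draws mapped through the truncated-normal quantile
#' function (common random numbers), which keeps the objective smooth.
#'
#' @param target A [response_target()].
#' @param cohort Data frame from [sample_cohort()] (at least ~1000 patients
#'   for stable proportions).
#' @param dose Calibration physical dose (Gy), default 400.
#' @param p A [model_parameters()] object.
#' @param mu_grid,sigma_grid Coarse search grids.
#' @param refine Run the Nelder-Mead refinement after the grid pass?
#' @param seed Seed for the shared uniform draws.
#' @param ... Passed to [simulate_response_profile()].
#' @return A `q_fit`: list with `mu`, `sigma`, `proportions` (achieved),
#'   `objective`, `n`, `seed`, `evaluations`.
#' @export
fit_q_distribution <- function(target, cohort, dose = 400,
                               p = model_parameters(),
                               mu_grid = seq(0.02, 0.30, by = 0.02),
                               sigma_grid = seq(0.01, 0.09, by = 0.02),
                               refine = TRUE, seed = 1L, ...) {
  stopifnot(inherits(target, "response_target"))
  if (nrow(cohort) < 2) stop("cohort too small", call. = FALSE)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old), add = TRUE)
  set.seed(seed)
  u <- stats::runif(nrow(cohort))
  evals <- 0L
  objective <- function(par) {
    mu <- par[1]; sigma <- par[2]
    if (mu < 0 || mu > 1 || sigma < 0) return(4 + abs(mu) + abs(sigma))
    qv <- qtnorm(u, mu, sigma, 0, 1)
    prof <- simulate_response_profile(qv, cohort, dose = dose, p = p, ...)
    evals <<- evals + 1L
    sum(abs(prof - unclass(target)))
  }
  grid <- expand.grid(mu = mu_grid, sigma = sigma_grid)
  grid$obj <- apply(grid, 1, function(g) objective(c(g[["mu"]],
                                                     g[["sigma"]])))
  best <- grid[which.min(grid$obj), ]
  par <- c(best$mu, best$sigma)
  obj <- best$obj
  if (refine) {
    opt <- stats::optim(par, objective, method = "Nelder-Mead",
                        control = list(reltol = 1e-3, maxit = 80))
    if (opt$value <= obj) {
      par <- opt$par
      obj <- opt$value
    } else {
      warning("refinement failed to improve on the grid optimum; ",
              "returning the best point found")
    }
  }
  qv <- qtnorm(u, par[1], par[2], 0, 1)
  structure(list(mu = par[1], sigma = par[2],
                 proportions = simulate_response_profile(qv, cohort,
                                                         dose = dose, p = p,
                                                         ...),
                 objective = obj, n = nrow(cohort), seed = seed,
                 evaluations = evals, grid = grid),
            class = "q_fit")
}

#' @export
print.q_fit <- function(x, ...) {
  cat("q_fit: truncated-normal effectiveness, mu =", round(x$mu, 4),
      ", sigma =", round(x$sigma, 4), "\n")
  cat("achieved proportions:",
      paste(names(x$proportions), round(100 * x$proportions, 1),
            sep = "=", collapse = "% "),
      "% (L1 objective", round(x$objective, 4), ",", x$evaluations,
      "evaluations, n =", x$n, ", seed =", x$seed, ")\n")
  invisible(x)
}

#' Write a fitted q distribution as JSON
#'
#' @param fit A `q_fit`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_qfit_json <- function(fit, path) {
  jsonlite::write_json(list(mu = fit$mu, sigma = fit$sigma,
                            proportions = as.list(fit$proportions),
                            objective = fit$objective, n = fit$n,
                            seed = fit$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
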
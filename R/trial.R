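# Five-arm virtual-trial engine. All arms reuse the same cohort (common
# random numbers): the integrator is deterministic given a patient, so arm
# contrasts are within-patient and sweep cells sharing (dose, delta) produce
# identical arm-A trajectories.

# simulate one arm for a whole cohort; returns the per-patient event table
.simulate_arm_events <- function(cohort, arm, dose, delta, interval,
                                 p, horizon_months, dt, n_fractions,
                                 kappa_blood, dm_threshold_cc,
                                 ici_mono_delta = NULL,
                                 y90_mono_dose = NULL,
                                 pd_reference = "nadir",
                                 pd_detect_cells = 1.5e5) {
  n <- nrow(cohort)
  horizon_days <- horizon_months * DAYS_PER_MONTH
  arm_dose <- if (arm == "Y90_mono" && !is.null(y90_mono_dose)) {
    y90_mono_dose
  } else dose
  plan <- build_arm_plan(arm, total_dose = arm_dose, delta = NA,
                         interval = interval, q = 1, p = p,
                         horizon = horizon_days, n_fractions = n_fractions,
                         kappa_blood = kappa_blood)
  delta_vec <- if (arm == "Y90_mono") {
    rep(0, n)
  } else if (arm == "ICI_mono" && is.null(ici_mono_delta)) {
    cohort$delta_durva # monotherapy at the sampled effectiveness
  } else if (arm == "ICI_mono") {
    rep(ici_mono_delta, n)
  } else if (is.null(delta)) {
    cohort$delta_durva
  } else {
    rep(delta, n)
  }
  state0 <- cbind(cohort$T0, cohort$TNI0, 0, cohort$L0)
  ev <- plan$radiation_events
  run_batch <- function(rows) {
    cpp_batch_endpoints(state0[rows, , drop = FALSE], cohort$alphaT[rows],
                        cohort$q[rows], delta_vec[rows],
                        ev$time, ev$physical_dose, ev$d_lymph,
                        plan$ici_dose_times, unclass(p),
                        horizon = horizon_days, dt = dt,
                        prog_ratio = 1.2^3,
                        dm_thresh = dm_threshold_cc * p$tumor_density,
                        assess_day = -1,
                        prog_nadir = if (pd_reference == "nadir") 1L else 0L,
                        nadir_floor = pd_detect_cells)
  }
  res <- tryCatch(run_batch(seq_len(n)), error = function(e) NULL)
  failed <- integer(0)
  if (is.null(res)) {
    # fail-open: isolate failing patients, exclude them, abort above 1%
    res <- matrix(NA_real_, n, 5,
                  dimnames = list(NULL, c("prog_day", "dm_day", "TI_assess",
                                          "TI_end", "L_end")))
    for (i in seq_len(n)) {
      one <- tryCatch(run_batch(i), error = function(e) NULL)
      if (is.null(one)) failed <- c(failed, i) else res[i, ] <- one
    }
    if (length(failed) > 0.01 * n) {
      stop("integration failed for ", length(failed), "/", n,
           " patients in arm ", arm, call. = FALSE)
    }
  }
  ok <- setdiff(seq_len(n), failed)
  prog <- res[ok, "prog_day"]
  dm <- res[ok, "dm_day"]
  data.frame(patient_id = cohort$id[ok], arm = arm,
             pfs_months = ifelse(is.na(prog), horizon_months,
                                 prog / DAYS_PER_MONTH),
             pfs_observed = !is.na(prog),
             dm_months = ifelse(is.na(dm), horizon_months,
                                dm / DAYS_PER_MONTH),
             dm_observed = !is.na(dm),
             dm_evaluable = cohort$TNI0[ok] <=
               dm_threshold_cc * p$tumor_density,
             n_failed = length(failed))
}

.arm_summary <- function(events, horizon_months) {
  pfs <- km_fit(events$pfs_months, events$pfs_observed)
  dm <- km_fit(events$dm_months, events$dm_observed)
  med <- km_median(pfs, conf = TRUE)
  rate <- function(curve, t, type) km_rate_at(curve, t, type)$estimate
  data.frame(n = nrow(events),
             pfs_median = med$median, pfs_lcl = med$lower,
             pfs_ucl = med$upper,
             pfs_rate_1y = rate(pfs, 12, "survival"),
             pfs_rate_3y = rate(pfs, 36, "survival"),
             pfs_rate_5y = rate(pfs, 60, "survival"),
             dm_rate_1y = rate(dm, 12, "incidence"),
             dm_rate_3y = rate(dm, 36, "incidence"),
             dm_rate_5y = rate(dm, 60, "incidence"))
}

#' Run the five-arm virtual clinical trial
#'
#' Simulates every patient of the cohort under every configured arm,
#' converts trajectories to progression (targeted lesion) and
#' distant-metastasis (non-targeted lesion) event times, and summarizes each
#' arm with Kaplan-Meier medians, 1/3/5-year rates and pairwise log-rank
#' tests. Patients whose non-targeted baseline already exceeds the detection
#' threshold count as DM events at the first grid point; `dm_mode =
#' "evaluable"` instead restricts the DM analysis to patients below
#' threshold at baseline (both subsets are flagged in the event table).
#'
#' @param cohort Data frame from [sample_cohort()].
#' @param dose Physical Y90 prescription for the combination arms (Gy).
#' @param delta ICI effectiveness for the combination arms; `NULL` uses each
#'   patient's sampled value.
#' @param interval Days between modalities in arms B and C.
#' @param arms Character vector of arms to run.
#' @param p A [model_parameters()] object.
#' @param horizon_months Follow-up horizon (months), `>= 60` recommended.
#' @param dt Integration step (days).
#' @param n_fractions,kappa_blood Y90 schedule settings.
#' @param dm_threshold_cc DM detection threshold (cc).
#' @param dm_mode `"all"` (default) or `"evaluable"`.
#' @param pd_reference Progression reference: `"nadir"` (default; at least a
#'   20% diameter rise over the smallest size observed so far, as in RECIST
#'   1.1) or `"baseline"` (rise over the pre-treatment size).
#' @param pd_detect_cells Measurement floor (cells) for the nadir reference:
#'   the PD comparison uses the smallest *measurable* size, never less than
#'   this resolution floor. Default 1.5e5 cells (0.15 mm^3 at 1e9
#'   cells/cc).
#' @param ici_mono_delta Fixed effectiveness for the ICI monotherapy arm;
#'   `NULL` (default) uses the sampled per-patient values.
#' @param y90_mono_dose Prescription for the Y90 monotherapy arm; defaults
#'   to `dose`.
#' @return A `trial_result`: list with `events` (per-patient table),
#'   `summary` (per-arm), `km` (per-arm PFS/DM curves), `comparisons`
#'   (pairwise log-rank), and `config`.
#' @export
run_trial <- function(cohort, dose = 400, delta = 0.12, interval = 60,
                      arms = c("Y90_mono", "ICI_mono", "A", "B", "C"),
                      p = model_parameters(), horizon_months = 120,
                      dt = 0.25, n_fractions = 26, kappa_blood = 0.05,
                      dm_threshold_cc = 0.1,
                      dm_mode = c("all", "evaluable"),
                      pd_reference = c("nadir", "baseline"),
                      pd_detect_cells = 1.5e5,
                      ici_mono_delta = NULL, y90_mono_dose = dose) {
  dm_mode <- match.arg(dm_mode)
  pd_reference <- match.arg(pd_reference)
  if (nrow(cohort) == 0) stop("cohort is empty", call. = FALSE)
  events <- do.call(rbind, lapply(arms, function(a) {
    .simulate_arm_events(cohort, a, dose, delta, interval, p,
                         horizon_months, dt, n_fractions, kappa_blood,
                         dm_threshold_cc, ici_mono_delta, y90_mono_dose,
                         pd_reference, pd_detect_cells)
  }))
  dm_events <- if (dm_mode == "evaluable") {
    events[events$dm_evaluable, ]
  } else events
  km <- list()
  summaries <- list()
  for (a in arms) {
    ea <- events[events$arm == a, ]
    da <- dm_events[dm_events$arm == a, ]
    km[[a]] <- list(pfs = km_fit(ea$pfs_months, ea$pfs_observed),
                    dm = km_fit(da$dm_months, da$dm_observed))
    sa <- .arm_summary(ea, horizon_months)
    if (dm_mode == "evaluable") {
      dmc <- km[[a]]$dm
      sa$dm_rate_1y <- km_rate_at(dmc, 12, "incidence")$estimate
      sa$dm_rate_3y <- km_rate_at(dmc, 36, "incidence")$estimate
      sa$dm_rate_5y <- km_rate_at(dmc, 60, "incidence")$estimate
    }
    summaries[[a]] <- cbind(arm = a, sa)
  }
  comparisons <- list()
  if (length(arms) > 1) {
    pairs <- utils::combn(arms, 2, simplify = FALSE)
    comparisons <- lapply(pairs, function(pr) {
      e1 <- events[events$arm == pr[1], ]
      e2 <- events[events$arm == pr[2], ]
      d1 <- dm_events[dm_events$arm == pr[1], ]
      d2 <- dm_events[dm_events$arm == pr[2], ]
      lr_pfs <- logrank(e1$pfs_months, e1$pfs_observed,
                        e2$pfs_months, e2$pfs_observed)
      lr_dm <- logrank(d1$dm_months, d1$dm_observed,
                       d2$dm_months, d2$dm_observed)
      data.frame(arm1 = pr[1], arm2 = pr[2],
                 pfs_chisq = lr_pfs$chisq, pfs_p = lr_pfs$p,
                 dm_chisq = lr_dm$chisq, dm_p = lr_dm$p)
    })
    comparisons <- do.call(rbind, comparisons)
  }
  structure(list(events = events,
                 summary = do.call(rbind, summaries),
                 km = km,
                 comparisons = comparisons,
                 config = list(dose = dose, delta = delta,
                               interval = interval, arms = arms,
                               horizon_months = horizon_months, dt = dt,
                               n_fractions = n_fractions,
                               kappa_blood = kappa_blood,
                               dm_threshold_cc = dm_threshold_cc,
                               dm_mode = dm_mode,
                               pd_reference = pd_reference,
                               pd_detect_cells = pd_detect_cells,
                               n = nrow(cohort),
                               cohort_seed = attr(cohort, "seed"))),
            class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("trial_result:", x$config$n, "patients x",
      length(x$config$arms), "arms (dose", x$config$dose, "Gy, delta",
      x$config$delta, ", interval", x$config$interval, "d)\n")
  print(x$summary, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Dose-grid sweep over the combination arms
#'
#' One virtual trial cell per (dose, delta, arm); the cell payload is the
#' median PFS (months) and the 3-year cumulative DM rate (%).
#'
#' @param cohort Data frame from [sample_cohort()].
#' @param doses Physical Y90 prescriptions (Gy).
#' @param deltas ICI effectiveness values.
#' @param arms Arms to sweep (default A, B, C).
#' @param interval Days between modalities for the sequential arms.
#' @param p,horizon_months,dt,n_fractions,kappa_blood,dm_threshold_cc As in
#'   [run_trial()].
#' @return Data frame with columns dose, delta, arm, median_pfs_months,
#'   dm3y_pct, n, seed.
#' @export
dose_grid_sweep <- function(cohort, doses = c(300, 400, 500),
                            deltas = c(0.08, 0.12, 0.16),
                            arms = c("A", "B", "C"), interval = 60,
                            p = model_parameters(), horizon_months = 120,
                            dt = 0.25, n_fractions = 26, kappa_blood = 0.05,
                            dm_threshold_cc = 0.1,
                            pd_reference = c("nadir", "baseline"),
                            pd_detect_cells = 1.5e5) {
  pd_reference <- match.arg(pd_reference)
  if (length(doses) == 0 || length(deltas) == 0) {
    stop("grids must be non-empty", call. = FALSE)
  }
  grid <- expand.grid(dose = doses, delta = deltas, arm = arms,
                      stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(grid)), function(i) {
    ev <- .simulate_arm_events(cohort, grid$arm[i], grid$dose[i],
                               grid$delta[i], interval, p, horizon_months,
                               dt, n_fractions, kappa_blood,
                               dm_threshold_cc,
                               pd_reference = pd_reference,
                               pd_detect_cells = pd_detect_cells)
    pfs <- km_fit(ev$pfs_months, ev$pfs_observed)
    dm <- km_fit(ev$dm_months, ev$dm_observed)
    data.frame(dose = grid$dose[i], delta = grid$delta[i],
               arm = grid$arm[i],
               median_pfs_months = km_median(pfs),
               dm3y_pct = 100 * km_rate_at(dm, 36, "incidence")$estimate,
               n = nrow(ev),
               seed = if (is.null(attr(cohort, "seed"))) NA_integer_
                      else attr(cohort, "seed"))
  })
  structure(do.call(rbind, out), class = c("sweep_grid", "data.frame"))
}

#' Inter-drug interval sweep for the sequential arms
#'
#' Evaluates arms B (Y90 first) and C (ICI first) at each administration
#' interval, at one or more intensity presets, with the concurrent arm A as
#' the constant reference (reported once per preset with `interval = 0`).
#'
#' @param cohort Data frame from [sample_cohort()].
#' @param intervals Days between modalities (within \[0, 300\]).
#' @param presets Named list of `c(dose, delta)` intensity settings; default
#'   minimum (300 Gy, 0.08), intermediate (400 Gy, 0.12), maximum
#'   (500 Gy, 0.16).
#' @param p,horizon_months,dt,n_fractions,kappa_blood,dm_threshold_cc As in
#'   [run_trial()].
#' @return Data frame with columns preset, dose, delta, interval, arm,
#'   median_pfs_months, dm3y_pct, n, seed.
#' @export
interval_sweep <- function(cohort,
                           intervals = seq(30, 300, by = 30),
                           presets = list(minimum = c(300, 0.08),
                                          intermediate = c(400, 0.12),
                                          maximum = c(500, 0.16)),
                           p = model_parameters(), horizon_months = 120,
                           dt = 0.25, n_fractions = 26, kappa_blood = 0.05,
                           dm_threshold_cc = 0.1,
                           pd_reference = c("nadir", "baseline"),
                           pd_detect_cells = 1.5e5) {
  pd_reference <- match.arg(pd_reference)
  if (any(intervals < 0 | intervals > 300)) {
    stop("intervals must lie in [0, 300] days", call. = FALSE)
  }
  cell <- function(arm, dose, delta, interval, preset) {
    ev <- .simulate_arm_events(cohort, arm, dose, delta, interval, p,
                               horizon_months, dt, n_fractions,
                               kappa_blood, dm_threshold_cc,
                               pd_reference = pd_reference,
                               pd_detect_cells = pd_detect_cells)
    pfs <- km_fit(ev$pfs_months, ev$pfs_observed)
    dm <- km_fit(ev$dm_months, ev$dm_observed)
    data.frame(preset = preset, dose = dose, delta = delta,
               interval = interval, arm = arm,
               median_pfs_months = km_median(pfs),
               dm3y_pct = 100 * km_rate_at(dm, 36, "incidence")$estimate,
               n = nrow(ev),
               seed = if (is.null(attr(cohort, "seed"))) NA_integer_
                      else attr(cohort, "seed"))
  }
  out <- list()
  for (nm in names(presets)) {
    dose <- presets[[nm]][1]; delta <- presets[[nm]][2]
    out[[length(out) + 1]] <- cell("A", dose, delta, 0, nm)
    for (iv in intervals) {
      out[[length(out) + 1]] <- cell("B", dose, delta, iv, nm)
      out[[length(out) + 1]] <- cell("C", dose, delta, iv, nm)
    }
  }
  structure(do.call(rbind, out), class = c("sweep_grid", "data.frame"))
}
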
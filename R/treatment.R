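#' Decay-weighted Y90 dose fractionation
#'
#' Discretizes the exponentially decaying dose delivery of an yttrium-90
#' source into daily instantaneous events. Event `j` (at `start + j - 1`
#' days) carries the fraction of the prescribed physical dose emitted during
#' day `j` of decay, renormalized over `n_fractions` days so the physical
#' doses sum exactly to the prescription; 26 daily fractions (ten half-lives)
#' capture >99.9% of the decay before renormalization. Tumor effective dose
#' is `q` times the physical dose; the circulating-lymphocyte dose per event
#' is `kappa_blood` times the physical dose (only a small fraction of the
#' blood pool transits the perfused territory).
#'
#' @param total_physical_dose Prescribed physical absorbed dose (Gy).
#' @param start First event day.
#' @param q Y90 effectiveness in \[0, 1\].
#' @param p A [model_parameters()] object (uses `t_half_y90`).
#' @param n_fractions Number of daily events (default 26).
#' @param kappa_blood Lymphocyte dose per unit physical dose (default 0.05).
#' @return Data frame with columns `time`, `physical_dose`, `d_tumor`,
#'   `d_lymph` (Gy).
#' @examples
#' sched <- y90_schedule(400, q = 0.12, p = model_parameters())
#' sum(sched$physical_dose) # 400
#' @export
y90_schedule <- function(total_physical_dose, start = 0, q = 1,
                         p = model_parameters(), n_fractions = 26,
                         kappa_blood = 0.05) {
  if (total_physical_dose < 0) stop("dose must be >= 0", call. = FALSE)
  if (q < 0 || q > 1) stop("q must lie in [0, 1]", call. = FALSE)
  if (n_fractions < 1) stop("n_fractions must be >= 1", call. = FALSE)
  lam <- log(2) / p$t_half_y90
  j <- seq_len(n_fractions)
  frac <- (exp(-lam * (j - 1)) - exp(-lam * j)) / (1 - exp(-lam * n_fractions))
  phys <- total_physical_dose * frac
  data.frame(time = start + j - 1,
             physical_dose = phys,
             d_tumor = q * phys,
             d_lymph = kappa_blood * phys)
}

#' Absorbed dose from administered activity
#'
#' Mean absorbed dose under the assumptions of uniformly distributed
#' activity, complete local absorption of the beta energy (no bremsstrahlung
#' escape), and an effective half-life equal to the physical half-life. The
#' cumulated activity is `A0 * t_half / ln 2`.
#'
#' @param A0 Administered activity (GBq).
#' @param m Perfused tissue mass (kg).
#' @param p A [model_parameters()] object (uses `k`, `E_mean`, `t_half_y90`).
#' @return Absorbed dose (Gy).
#' @examples
#' dose_from_activity(1, 1) # about 48.1 Gy per GBq per kg
#' @export
dose_from_activity <- function(A0, m, p = model_parameters()) {
  if (any(A0 < 0)) stop("activity must be >= 0", call. = FALSE)
  if (any(m <= 0)) stop("mass must be positive", call. = FALSE)
  cumulated <- A0 * 1e9 * p$t_half_y90 * 86400 / log(2) # disintegrations
  cumulated * p$E_mean * p$k / m
}

#' Checkpoint-inhibitor immune-kill multiplier
#'
#' The ratio omega1'(t)/omega1 by which the immune-mediated kill rate is
#' boosted: 1 before the first dose, and
#' `1 + delta * Cmax * 2^-((t - t_last)/t_half_ici)` afterwards. Under the
#' default `"reset"` convention the concentration returns to `Cmax` at each
#' administration (`t_last` is the most recent dose at or before `t`); the
#' `"superpose"` mode instead sums the decaying exponentials of all past
#' doses.
#'
#' @param t Time (days); vectorized.
#' @param ici_dose_times Sorted administration days (may be empty).
#' @param delta Checkpoint-inhibitor effectiveness (dimensionless).
#' @param p A [model_parameters()] object.
#' @param mode `"reset"` (default) or `"superpose"`.
#' @return Numeric vector of multipliers, each `>= 1`.
#' @examples
#' p <- model_parameters()
#' ici_multiplier(c(0, 21), 0, delta = 0.12, p = p) # 2.2, 1.6
#' @export
ici_multiplier <- function(t, ici_dose_times, delta,
                           p = model_parameters(),
                           mode = c("reset", "superpose")) {
  mode <- match.arg(mode)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (length(ici_dose_times) == 0 || delta <= 0) {
    return(rep(1, length(t)))
  }
  dose_times <- sort(ici_dose_times)
  lam <- log(2) / p$t_half_ici
  vapply(t, function(ti) {
    past <- dose_times[dose_times <= ti + 1e-9]
    if (length(past) == 0) return(1)
    if (mode == "reset") {
      1 + delta * p$Cmax * exp(-lam * (ti - max(past)))
    } else {
      1 + delta * p$Cmax * sum(exp(-lam * (ti - past)))
    }
  }, numeric(1))
}

#' Build the treatment plan for a trial arm
#'
#' Five arms: `Y90_mono` (radiation only), `ICI_mono` (checkpoint inhibitor
#' only), `A` (concurrent: both start day 0), `B` (Y90 first: radiation day
#' 0, ICI course from day `interval`), and `C` (ICI first: ICI course from
#' day 0, radiation at day `interval`). The ICI course is one dose every 14
#' days, from its start until the end of the trial's 2-year treatment
#' window (a delayed course is a shortened course, as in a protocol that
#' administers all therapy within a fixed window).
#' Radiation events carry the *physical*
#' per-event dose; per-patient effectiveness `q` scales it at simulation
#' time (pass `q` here only to bake a fixed effectiveness into `d_tumor`
#' for inspection).
#'
#' @param arm One of `"Y90_mono"`, `"ICI_mono"`, `"A"`, `"B"`, `"C"`.
#' @param total_dose Prescribed physical Y90 dose (Gy); default 400.
#' @param delta Checkpoint-inhibitor effectiveness for the plan; `NA` means
#'   "use each patient's sampled value".
#' @param interval Days between the two modalities for arms B and C.
#' @param q Effectiveness baked into the plan's `d_tumor` column (default 1).
#' @param p A [model_parameters()] object.
#' @param horizon Simulation horizon (days).
#' @param n_fractions,kappa_blood Passed to [y90_schedule()].
#' @param ici_interval_days,ici_duration_days ICI schedule: dose spacing and
#'   end of the treatment window (trial days).
#' @return A `y90_plan` object.
#' @examples
#' plan <- build_arm_plan("B", interval = 60, delta = 0.12)
#' plan$ici_dose_times[1] # 60
#' @export
build_arm_plan <- function(arm, total_dose = 400, delta = NA,
                           interval = 0, q = 1, p = model_parameters(),
                           horizon = 3652.5, n_fractions = 26,
                           kappa_blood = 0.05,
                           ici_interval_days = 14,
                           ici_duration_days = 730) {
  arms <- c("Y90_mono", "ICI_mono", "A", "B", "C")
  if (!arm %in% arms) {
    stop("unknown arm '", arm, "'; must be one of ",
         paste(arms, collapse = ", "), call. = FALSE)
  }
  if (interval < 0) stop("interval must be >= 0", call. = FALSE)
  y90_start <- switch(arm, Y90_mono = 0, A = 0, B = 0, C = interval,
                      ICI_mono = NA)
  ici_start <- switch(arm, ICI_mono = 0, A = 0, C = 0, B = interval,
                      Y90_mono = NA)
  radiation_events <- if (is.na(y90_start)) {
    data.frame(time = numeric(0), physical_dose = numeric(0),
               d_tumor = numeric(0), d_lymph = numeric(0))
  } else {
    y90_schedule(total_dose, start = y90_start, q = q, p = p,
                 n_fractions = n_fractions, kappa_blood = kappa_blood)
  }
  ici_dose_times <- if (is.na(ici_start) || ici_start > ici_duration_days) {
    numeric(0)
  } else {
    seq(ici_start, ici_duration_days, by = ici_interval_days)
  }
  if (arm == "Y90_mono") delta <- 0
  structure(list(arm_label = arm,
                 radiation_events = radiation_events,
                 ici_dose_times = ici_dose_times,
                 delta_durva = delta,
                 total_dose = if (is.na(y90_start)) 0 else total_dose,
                 interval = interval,
                 horizon = horizon),
            class = "y90_plan")
}

#' @export
print.y90_plan <- function(x, ...) {
  cat("y90_plan, arm", x$arm_label, "-", nrow(x$radiation_events),
      "radiation events (", x$total_dose, "Gy physical ),",
      length(x$ici_dose_times), "ICI doses, delta =", x$delta_durva, "\n")
  invisible(x)
}

#' Write a treatment plan as JSON
#'
#' @param plan A `y90_plan`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_plan_json <- function(plan, path) {
  jsonlite::write_json(list(arm_label = plan$arm_label,
                            radiation_events = plan$radiation_events,
                            ici_dose_times = plan$ici_dose_times,
                            delta_durva = plan$delta_durva,
                            total_dose = plan$total_dose,
                            interval = plan$interval,
                            horizon = plan$horizon),
                       path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
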
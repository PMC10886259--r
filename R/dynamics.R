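#' System state constructor
#'
#' @param TI Targeted tumor cells.
#' @param TNI Non-targeted tumor cells.
#' @param I Inactivated (radiation-killed, antigen-releasing) tumor cells.
#' @param L Circulating lymphocytes.
#' @return Named numeric vector of the four compartments.
#' @export
system_state <- function(TI = 0, TNI = 0, I = 0, L = 0) {
  st <- c(TI = TI, TNI = TNI, I = I, L = L)
  if (any(!is.finite(st)) || any(st < 0)) {
    stop("all compartments must be finite and non-negative", call. = FALSE)
  }
  st
}

#' Continuous right-hand side of the tumor-immune system
#'
#' Returns the instantaneous rates of change (per day) of the four
#' compartments. Tumor compartments grow exponentially and are killed by
#' lymphocytes with a shared geometric saturation in total tumor burden;
#' inactivated cells decay; lymphocytes are recruited by live and inactivated
#' tumor antigen, supplied at a constant rate, and decay. Radiation kill is
#' *not* part of the derivative: it is applied as discrete events at dose
#' instants (see [apply_radiation_event()]).
#'
#' @param state Named non-negative vector as from [system_state()].
#' @param p A [model_parameters()] object.
#' @param ici_multiplier Dimensionless factor `>= 1` scaling immune-mediated
#'   kill (the ratio omega1'(t)/omega1 produced by [ici_multiplier()]).
#' @return Named numeric vector `c(TI, TNI, I, L)` of derivatives (cells/day).
#' @examples
#' p <- model_parameters()
#' derivatives(system_state(L = p$s / p$f), p) # tumor-free steady state: all 0
#' @export
derivatives <- function(state, p, ici_multiplier = 1) {
  if (any(state < 0)) stop("negative state component", call. = FALSE)
  if (ici_multiplier < 1) stop("ici_multiplier must be >= 1", call. = FALSE)
  TI <- state[["TI"]]; TNI <- state[["TNI"]]
  I <- state[["I"]]; L <- state[["L"]]
  den <- p$g + TI + TNI
  kill <- p$omega1 * ici_multiplier * L / den
  c(TI = p$a * TI - kill * TI,
    TNI = p$a * TNI - kill * TNI,
    I = -p$r * I,
    L = p$omega2 * (TI + TNI) * L / den + p$omega3 * I * L / (p$g + I) +
      p$s - p$f * L)
}

#' Apply an instantaneous radiation event
#'
#' Linear-quadratic survival for the targeted tumor (killed cells move to the
#' inactivated compartment, so `TI + I` is conserved by the event) and linear
#' survival for circulating lymphocytes. The non-targeted compartment is
#' outside the irradiated territory and is never exposed.
#'
#' @param state Named state vector.
#' @param d_tumor Effective dose to the targeted tumor at this instant (Gy).
#' @param d_lymph Dose to circulating lymphocytes (Gy).
#' @param p A [model_parameters()] object; uses `alphaT`, `ab_ratio`,
#'   `alphaL`.
#' @return The post-event state.
#' @examples
#' p <- model_parameters()
#' st <- system_state(TI = 1e10, L = 5e9)
#' apply_radiation_event(st, d_tumor = 2, d_lymph = 0, p)
#' @export
apply_radiation_event <- function(state, d_tumor, d_lymph, p) {
  if (d_tumor < 0 || d_lymph < 0) stop("doses must be >= 0", call. = FALSE)
  betaT <- p$alphaT / p$ab_ratio
  sf <- exp(-p$alphaT * d_tumor - betaT * d_tumor^2)
  killed <- state[["TI"]] * (1 - sf)
  state[["I"]] <- state[["I"]] + killed
  state[["TI"]] <- state[["TI"]] - killed
  state[["L"]] <- state[["L"]] * exp(-p$alphaL * d_lymph)
  state
}

#' Simulate one patient under a treatment plan
#'
#' Integrates the continuous dynamics with a fixed-step fourth-order
#' Runge-Kutta scheme, landing exactly on every radiation and ICI dose
#' instant; radiation events are applied at their scheduled times and the
#' checkpoint-inhibitor multiplier is evaluated continuously. The returned
#' trajectory is sampled on a dense (default daily) grid; sampled states are
#' right-continuous at event instants, and the pre-treatment state is kept in
#' `$initial_state`.
#'
#' @param patient A one-row data frame (or list) with fields `T0`, `TNI0`,
#'   `L0`, `alphaT`, `q` as produced by [sample_cohort()]; `q` scales the
#'   plan's physical doses to effective tumor doses.
#' @param plan A [build_arm_plan()] treatment plan.
#' @param p A [model_parameters()] object.
#' @param dt Integration step (days); default 0.25.
#' @param output_times Sampling grid (days); default `0:horizon` daily.
#' @return A `y90_trajectory`: list with `times` (days), `states` (data frame
#'   with columns TI, TNI, I, L), `initial_state`, `events_applied`, `plan`.
#' @export
simulate_patient <- function(patient, plan, p = model_parameters(),
                             dt = 0.25, output_times = NULL) {
  stopifnot(inherits(plan, "y90_plan"))
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (is.null(output_times)) {
    output_times <- unique(c(seq(0, plan$horizon, by = 1), plan$horizon))
  }
  output_times <- sort(unique(as.numeric(output_times)))
  if (any(output_times < 0)) stop("output times must be >= 0", call. = FALSE)
  ev <- plan$radiation_events
  if (nrow(ev) > 0 && max(ev$time) > max(output_times)) {
    stop("plan event times extend beyond the simulation horizon",
         call. = FALSE)
  }
  st0 <- system_state(TI = patient$T0, TNI = patient$TNI0, L = patient$L0)
  q <- if (!is.null(patient$q)) patient$q else p$q
  delta <- plan$delta_durva
  if (is.na(delta)) {
    delta <- if (!is.null(patient$delta_durva)) patient$delta_durva
             else p$delta_durva
  }
  states <- cpp_sim_traj(unname(st0), patient$alphaT, q, delta,
                         ev$time, ev$physical_dose, ev$d_lymph,
                         plan$ici_dose_times, unclass(p), output_times, dt)
  if (any(!is.finite(states))) {
    stop("integration produced non-finite states", call. = FALSE)
  }
  ev_applied <- ev
  if (nrow(ev) > 0) ev_applied$d_tumor <- q * ev$physical_dose
  structure(list(times = output_times,
                 states = as.data.frame(states),
                 initial_state = st0,
                 events_applied = ev_applied,
                 plan = plan),
            class = "y90_trajectory")
}

#' @export
print.y90_trajectory <- function(x, ...) {
  cat("y90_trajectory:", length(x$times), "time points over",
      max(x$times), "days;", nrow(x$events_applied), "radiation events,",
      length(x$plan$ici_dose_times), "ICI doses (arm",
      x$plan$arm_label, ")\n")
  invisible(x)
}

#' @export
as.data.frame.y90_trajectory <- function(x, row.names = NULL,
                                         optional = FALSE, ...,
                                         patient_id = NA, arm = NULL) {
  if (is.null(arm)) arm <- x$plan$arm_label
  data.frame(time_d = x$times, TI = x$states$TI, TNI = x$states$TNI,
             I = x$states$I, L = x$states$L,
             patient_id = patient_id, arm = arm)
}

#' Write a trajectory as tidy CSV
#'
#' Columns: time_d, TI, TNI, I, L, patient_id, arm.
#'
#' @param traj A `y90_trajectory`.
#' @param path Output file.
#' @param patient_id,arm Identifier columns.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path, patient_id = NA, arm = NULL) {
  utils::write.csv(as.data.frame(traj, patient_id = patient_id, arm = arm),
                   path, row.names = FALSE)
  invisible(path)
}
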
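#' Sphere-equivalent diameter of a tumor volume
#'
#' RECIST operates on longest diameters; the model tracks volumes, converted
#' as the diameter of the sphere of equal volume.
#'
#' @param volume_cc Volume (cc).
#' @return Diameter (cm).
#' @examples
#' volume_to_diameter(0.1) # about 0.576 cm
#' @export
volume_to_diameter <- function(volume_cc) {
  if (any(volume_cc < 0)) stop("volume must be >= 0", call. = FALSE)
  (6 * volume_cc / pi)^(1 / 3)
}

#' RECIST 1.1 category from baseline and current lesion size
#'
#' Complete response (CR) when the cell count falls below the detection
#' threshold; otherwise progressive disease (PD) at a rise of at least 20% in
#' diameter over baseline, partial response (PR) at a decrease of at least
#' 30%, stable disease (SD) in between. Boundaries are inclusive, and PD is
#' assessed against the baseline (not the nadir).
#'
#' @param baseline_diam Baseline diameter (cm), positive.
#' @param current_diam Current diameter (cm); vectorized with
#'   `current_cells`.
#' @param current_cells Current cell count.
#' @param cr_cell_threshold Detection floor for CR (cells), default 1e8:
#'   a lesion below 0.1 cc (at 1e9 cells/cc) is unobservable with current
#'   diagnostic imaging, so "removal of all target lesions" means falling
#'   below that limit.
#' @return Character vector in `c("CR", "PR", "SD", "PD")`.
#' @examples
#' classify_recist(5, 3.4, 1e9) # PR: 32% decrease
#' classify_recist(5, 6.0, 1e9) # PD: exactly 20% rise
#' @export
classify_recist <- function(baseline_diam, current_diam, current_cells,
                            cr_cell_threshold = 1e8) {
  if (any(baseline_diam <= 0)) {
    stop("baseline diameter must be positive", call. = FALSE)
  }
  out <- rep("SD", length(current_diam))
  out[current_diam >= 1.2 * baseline_diam] <- "PD"
  out[current_diam <= 0.7 * baseline_diam] <- "PR"
  out[current_cells < cr_cell_threshold] <- "CR"
  out
}

event_time <- function(time, observed) {
  list(time = time, observed = observed)
}

# first time a trajectory column crosses a threshold (linear interpolation
# between sampled points); direction "up" uses >= for inclusivity ("at least
# 20% rise"), "strict_up" uses > (detection: "greater than 0.1 cc").
.first_crossing <- function(times, values, threshold, strict = FALSE) {
  hit <- if (strict) values > threshold else values >= threshold
  if (!any(hit)) return(NA_real_)
  k <- which(hit)[1]
  if (k == 1) return(times[1])
  v0 <- values[k - 1]; v1 <- values[k]
  if (v1 > v0) {
    times[k - 1] + (threshold - v0) / (v1 - v0) * (times[k] - times[k - 1])
  } else {
    times[k]
  }
}

#' Progression time of the targeted tumor
#'
#' First time the targeted-tumor sphere-equivalent diameter reaches 1.2 times
#' its reference value (the RECIST PD rule; a 20% diameter rise is a volume
#' ratio of 1.728); censored at the horizon when no progression occurs.
#' There is no death process, so progression is the only event. With
#' `pd_reference = "nadir"` (default) the reference is the running minimum
#' of the lesion size, floored at the imaging detection limit (a lesion
#' below detection has no measurable diameter), as in RECIST 1.1;
#' `"baseline"` compares against the pre-treatment size throughout.
#'
#' @param traj A [simulate_patient()] trajectory.
#' @param horizon_months Follow-up horizon (months).
#' @param pd_reference `"nadir"` or `"baseline"`.
#' @param pd_detect_cells Detection limit flooring the nadir (cells).
#' @return List with `time` (months) and `observed` (logical).
#' @export
progression_time <- function(traj, horizon_months,
                             pd_reference = c("nadir", "baseline"),
                             pd_detect_cells = 1.5e5) {
  pd_reference <- match.arg(pd_reference)
  horizon_days <- horizon_months * DAYS_PER_MONTH
  if (max(traj$times) < horizon_days - 1e-6) {
    stop("trajectory shorter than the requested horizon", call. = FALSE)
  }
  ti <- traj$states$TI
  if (pd_reference == "baseline") {
    thr <- 1.2^3 * traj$initial_state[["TI"]]
    td <- .first_crossing(traj$times, ti, thr, strict = FALSE)
  } else {
    nadir <- cummin(c(traj$initial_state[["TI"]], ti))[-1]
    ref <- pmax(c(traj$initial_state[["TI"]], nadir[-length(nadir)]),
                pd_detect_cells)
    hit <- which(ti >= 1.2^3 * ref)
    td <- if (length(hit) == 0) NA_real_ else traj$times[hit[1]]
  }
  if (is.na(td) || td > horizon_days) {
    event_time(horizon_months, FALSE)
  } else {
    event_time(max(td, traj$times[2]) / DAYS_PER_MONTH, TRUE)
  }
}

# (event times are floored at the first positive sampled time so censoring
# invariants hold even for degenerate crossings at t = 0)

#' Distant-metastasis time of the non-targeted tumor
#'
#' First time the non-targeted tumor volume exceeds the detection threshold
#' (default 0.1 cc); a baseline already above threshold yields an event at
#' the first sampled time point; censored at the horizon otherwise.
#'
#' @param traj A [simulate_patient()] trajectory.
#' @param threshold_cc Detection threshold (cc).
#' @param horizon_months Follow-up horizon (months).
#' @param p A [model_parameters()] object (for `tumor_density`).
#' @return List with `time` (months) and `observed` (logical).
#' @export
dm_time <- function(traj, threshold_cc = 0.1, horizon_months,
                    p = model_parameters()) {
  horizon_days <- horizon_months * DAYS_PER_MONTH
  if (max(traj$times) < horizon_days - 1e-6) {
    stop("trajectory shorter than the requested horizon", call. = FALSE)
  }
  thr <- threshold_cc * p$tumor_density
  if (traj$initial_state[["TNI"]] > thr) {
    return(event_time(traj$times[2] / DAYS_PER_MONTH, TRUE))
  }
  td <- .first_crossing(traj$times, traj$states$TNI, thr, strict = TRUE)
  if (is.na(td) || td > horizon_days) {
    event_time(horizon_months, FALSE)
  } else {
    event_time(max(td, traj$times[2]) / DAYS_PER_MONTH, TRUE)
  }
}

#' Write a per-patient event table as CSV
#'
#' Columns: patient_id, arm, pfs_months, pfs_observed, dm_months,
#' dm_observed.
#'
#' @param events Data frame in that layout (see [run_trial()]).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_event_csv <- function(events, path) {
  utils::write.csv(events, path, row.names = FALSE)
  invisible(path)
}
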
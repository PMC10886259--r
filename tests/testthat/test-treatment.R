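p <- model_parameters()

test_that("Y90 fractionation follows the decay and sums to the prescription", {
  lam <- log(2) / 2.6
  sched <- y90_schedule(400, q = 0.12, p = p)
  expect_equal(nrow(sched), 26)
  expect_equal(sum(sched$physical_dose), 400, tolerance = 1e-3)
  # day-1 unnormalized decay fraction 1 - e^-lambda = 0.2341
  expect_equal(1 - exp(-lam), 0.2341, tolerance = 1e-3)
  expect_equal(sched$physical_dose[1], 400 * (1 - exp(-lam)) /
                 (1 - exp(-lam * 26)), tolerance = 1e-9)
  expect_equal(sched$d_tumor[1], 0.12 * sched$physical_dose[1])
  expect_equal(sched$d_tumor[1], 11.24, tolerance = 1e-2)
  # 26 daily fractions capture ~99.9% of the decay before renormalization
  expect_equal(1 - exp(-lam * 26), 0.999, tolerance = 1e-3)
  # q = 0: placebo
  expect_true(all(y90_schedule(400, q = 0, p = p)$d_tumor == 0))
  expect_error(y90_schedule(400, q = 1.2, p = p), "\\[0, 1\\]")
  # prescription sum invariant across doses and fraction counts
  for (D in c(0, 55.5, 300, 500)) {
    for (nf in c(1, 5, 26, 40)) {
      expect_equal(sum(y90_schedule(D, p = p, n_fractions = nf)$physical_dose),
                   D, tolerance = 1e-3 * max(D, 1))
    }
  }
})

test_that("absorbed dose from activity follows the cumulated-activity form", {
  expect_equal(dose_from_activity(0, 70, p), 0)
  expect_equal(dose_from_activity(1, 1, p), 48.12, tolerance = 1e-2)
  expect_equal(dose_from_activity(4, 2, p), 2 * dose_from_activity(2, 2, p))
  expect_error(dose_from_activity(1, 0, p), "positive")
})

test_that("ICI multiplier has the published magnitude and decay", {
  expect_equal(ici_multiplier(c(0, 5), numeric(0), 0.12, p), c(1, 1))
  expect_equal(ici_multiplier(0:10, 0, 0, p), rep(1, 11))
  # at the dose instant: 1 + delta * Cmax = 2.2; one half-life later: 1.6
  expect_equal(ici_multiplier(0, 0, 0.12, p), 2.2)
  expect_equal(ici_multiplier(21, 0, 0.12, p), 1.6)
  # reset at a new dose
  expect_equal(ici_multiplier(14, c(0, 14), 0.12, p), 2.2)
  # superposition adds tails of earlier doses
  expect_gt(ici_multiplier(14, c(0, 14), 0.12, p, mode = "superpose"), 2.2)
})

test_that("ICI multiplier is >= 1 and non-increasing between doses", {
  doses <- seq(0, 728, by = 14)
  tt <- seq(0, 900, by = 0.5)
  m <- ici_multiplier(tt, doses, 0.12, p)
  expect_true(all(m >= 1))
  # within each inter-dose window the multiplier only decays
  for (k in which(diff(floor(tt / 14)) == 0)) {
    expect_lte(m[k + 1], m[k] + 1e-12)
  }
})

test_that("arm plans encode the five schedules", {
  a <- build_arm_plan("A", interval = 999, delta = 0.12)
  expect_equal(a$radiation_events$time[1], 0)
  expect_equal(a$ici_dose_times[1], 0)
  b <- build_arm_plan("B", interval = 60, delta = 0.12)
  expect_equal(b$radiation_events$time[1], 0)
  expect_equal(b$ici_dose_times[1], 60)
  cc <- build_arm_plan("C", interval = 60, delta = 0.12)
  expect_equal(cc$ici_dose_times[1], 0)
  expect_equal(cc$radiation_events$time[1], 60)
  ici <- build_arm_plan("ICI_mono", delta = 0.12)
  expect_equal(nrow(ici$radiation_events), 0)
  expect_true(length(ici$ici_dose_times) %in% c(52, 53))
  expect_true(all(diff(ici$ici_dose_times) == 14))
  y90 <- build_arm_plan("Y90_mono")
  expect_equal(length(y90$ici_dose_times), 0)
  expect_error(build_arm_plan("D"), "unknown arm")
})

test_that("arms B and C with a zero interval reduce to arm A", {
  a <- build_arm_plan("A", interval = 0, delta = 0.1)
  for (arm in c("B", "C")) {
    x <- build_arm_plan(arm, interval = 0, delta = 0.1)
    expect_equal(x$radiation_events, a$radiation_events)
    expect_equal(x$ici_dose_times, a$ici_dose_times)
  }
})

test_that("plans round-trip through JSON", {
  plan <- build_arm_plan("B", interval = 60, delta = 0.12)
  f <- tempfile(fileext = ".json")
  write_plan_json(plan, f)
  back <- jsonlite::read_json(f, simplifyVector = TRUE)
  expect_equal(back$arm_label, "B")
  expect_equal(back$ici_dose_times, plan$ici_dose_times)
  expect_equal(back$radiation_events$d_lymph,
               plan$radiation_events$d_lymph)
  unlink(f)
})
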
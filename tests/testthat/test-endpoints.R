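p <- model_parameters()

test_that("volume-to-diameter uses the sphere-equivalent form", {
  expect_equal(volume_to_diameter(0), 0)
  expect_equal(volume_to_diameter(0.1), 0.576, tolerance = 1e-3)
  expect_equal(volume_to_diameter(107), 5.888, tolerance = 1e-3)
  expect_error(volume_to_diameter(-1), ">= 0")
})

test_that("RECIST categories follow the inclusive 30%/20% boundaries", {
  expect_equal(classify_recist(5, 5, 1e10), "SD")
  expect_equal(classify_recist(5, 3.4, 1e10), "PR") # 32% decrease
  expect_equal(classify_recist(5, 3.5, 1e10), "PR") # exactly 30%
  expect_equal(classify_recist(5, 6.0, 1e10), "PD") # exactly 20% rise
  expect_equal(classify_recist(5, 5.9, 1e10), "SD")
  expect_equal(classify_recist(5, 0.1, 1e7), "CR")  # below detection
  # CR takes precedence over the diameter rules
  expect_equal(classify_recist(5, 0.01, 1e7), "CR")
  # scale invariance in (baseline, current)
  set.seed(1)
  for (i in 1:20) {
    b <- runif(1, 1, 10); r <- runif(1, 0.5, 1.5); s <- runif(1, 0.1, 10)
    expect_equal(classify_recist(b, r * b, 1e10),
                 classify_recist(s * b, s * r * b, 1e10))
  }
})

test_that("untreated exponential growth progresses at ln(1.728)/a", {
  # immune-free limit: pure exponential, both PD references coincide
  p0 <- model_parameters(omega1 = 1e-12, omega2 = 0, omega3 = 0, s = 1e-12)
  pat <- list(T0 = 1e10, TNI0 = 1e7, L0 = 1e-9, alphaT = 0.148, q = 0,
              delta_durva = 0)
  plan <- build_arm_plan("Y90_mono", total_dose = 0, p = p0, horizon = 3700)
  tr <- simulate_patient(pat, plan, p0,
                         output_times = seq(0, 3700, by = 0.25))
  pt <- progression_time(tr, horizon_months = 120)
  expect_true(pt$observed)
  expect_equal(pt$time * 30.4375, log(1.2^3) / 0.01, tolerance = 0.005)
  expect_equal(pt$time, 1.8, tolerance = 0.01)
  # both references coincide for a growing tumor (up to grid resolution)
  pt2 <- progression_time(tr, 120, pd_reference = "baseline")
  expect_equal(pt2$time, pt$time, tolerance = 0.01)
})

test_that("controlled or eradicated tumors are censored at the horizon", {
  # strong immune kill: tumor shrinks monotonically
  pstrong <- model_parameters(omega1 = 1.19)
  pat <- list(T0 = 1e10, TNI0 = 1e7, L0 = 5.61e9, alphaT = 0.148, q = 0,
              delta_durva = 0)
  plan <- build_arm_plan("Y90_mono", total_dose = 0, p = pstrong,
                         horizon = 3700)
  tr <- simulate_patient(pat, plan, pstrong,
                         output_times = seq(0, 3700, by = 1))
  pt <- progression_time(tr, 120)
  expect_false(pt$observed)
  expect_equal(pt$time, 120)
  dm <- dm_time(tr, horizon_months = 120, p = pstrong)
  expect_false(dm$observed)
  expect_error(progression_time(tr, 200), "horizon")
})

test_that("distant metastasis crosses the detection threshold on schedule", {
  p0 <- model_parameters(omega1 = 1e-12, omega2 = 0, omega3 = 0, s = 1e-12)
  plan <- build_arm_plan("Y90_mono", total_dose = 0, p = p0, horizon = 3700)
  # TNI0 = 5e7 doubles to 1e8 in ln(2)/0.01 = 69.3 d
  pat <- list(T0 = 1e10, TNI0 = 5e7, L0 = 1e-9, alphaT = 0.148, q = 0,
              delta_durva = 0)
  tr <- simulate_patient(pat, plan, p0,
                         output_times = seq(0, 3700, by = 0.25))
  dm <- dm_time(tr, horizon_months = 120, p = p0)
  expect_true(dm$observed)
  expect_equal(dm$time * 30.4375, log(2) / 0.01, tolerance = 0.005)
  # baseline already above threshold: event at the first sampled point
  pat2 <- list(T0 = 2e11, TNI0 = 2e8, L0 = 1e-9, alphaT = 0.148, q = 0,
               delta_durva = 0)
  tr2 <- simulate_patient(pat2, plan, p0,
                          output_times = seq(0, 3700, by = 0.25))
  dm2 <- dm_time(tr2, horizon_months = 120, p = p0)
  expect_true(dm2$observed)
  expect_equal(dm2$time, tr2$times[2] / 30.4375)
})

test_that("trajectory-level and batch endpoints agree patient by patient", {
  coh <- test_cohort(8, seed = 9)
  for (arm in c("A", "Y90_mono")) {
    ev <- y90ici:::.simulate_arm_events(coh, arm, 400, 0.12, 60, p,
                                        horizon_months = 60, dt = 0.25,
                                        n_fractions = 26,
                                        kappa_blood = 0.05,
                                        dm_threshold_cc = 0.1)
    horizon_days <- 60 * 30.4375
    plan <- build_arm_plan(arm, total_dose = 400, delta = 0.12, p = p,
                           horizon = horizon_days)
    for (i in seq_len(nrow(coh))) {
      tr <- simulate_patient(coh[i, ], plan, p,
                             output_times = seq(0, horizon_days, by = 0.25))
      pt <- progression_time(tr, 60)
      dm <- dm_time(tr, horizon_months = 60, p = p)
      expect_equal(ev$pfs_observed[i], pt$observed)
      expect_equal(ev$pfs_months[i], pt$time, tolerance = 0.02)
      expect_equal(ev$dm_observed[i], dm$observed)
      expect_equal(ev$dm_months[i], dm$time, tolerance = 0.02)
    }
  }
})
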
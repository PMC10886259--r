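p <- model_parameters()

test_that("defaults reproduce the published parameter table", {
  expect_equal(p$a, 0.01)
  expect_equal(p$f, 0.033)
  expect_equal(p$r, 0.14)
  expect_equal(p$omega1, 0.119)
  expect_equal(p$omega2, 0.003)
  expect_equal(p$omega3, 0.009)
  expect_equal(p$g, 7.33e10)
  expect_equal(p$s, 1.47e8)
  expect_equal(p$alphaL, 0.737)
  expect_equal(p$Cmax, 10)
  expect_equal(p$t_half_ici, 21)
  expect_equal(p$t_half_y90, 2.6)
  expect_equal(p$ab_ratio, 10)
  expect_equal(p$tumor_density, 1e9)
  expect_error(model_parameters(a = -1), "positive")
  expect_error(model_parameters(q = 1.5), "\\[0, 1\\]")
})

test_that("tumor-free steady state has zero derivatives at L* = s/f", {
  Lstar <- p$s / p$f
  expect_equal(Lstar, 4.4545454545e9, tolerance = 1e-9)
  d <- derivatives(system_state(L = Lstar), p)
  expect_equal(unname(d), rep(0, 4))
})

test_that("immune-free tumor grows exponentially in the derivative", {
  st <- system_state(TI = 3e10)
  d <- derivatives(st, p)
  expect_equal(d[["TI"]], p$a * 3e10)
  expect_equal(d[["TNI"]], 0)
  expect_error(derivatives(c(TI = -1, TNI = 0, I = 0, L = 0), p),
               "negative")
  expect_error(derivatives(st, p, ici_multiplier = 0.5), ">= 1")
})

test_that("radiation events follow LQ survival and conserve TI + I", {
  st <- system_state(TI = 1e10, TNI = 5e8, I = 1e9, L = 4e9)
  # zero dose: no change
  expect_equal(apply_radiation_event(st, 0, 0, p), st)
  # 2 Gy at alphaT 0.148, alpha/beta 10: SF 0.7010
  out <- apply_radiation_event(st, 2, 0, p)
  sf <- exp(-0.148 * 2 - 0.0148 * 4)
  expect_equal(sf, 0.7010, tolerance = 1e-4)
  expect_equal(out[["TI"]], 1e10 * sf)
  expect_equal(out[["I"]], 1e9 + 1e10 * (1 - sf))
  expect_equal(out[["TNI"]], 5e8) # never irradiated
  # 1 Gy to lymphocytes: survival e^-0.737
  out2 <- apply_radiation_event(st, 0, 1, p)
  expect_equal(out2[["L"]] / 4e9, exp(-0.737), tolerance = 1e-12)
  expect_equal(exp(-0.737), 0.4786, tolerance = 1e-3)
  expect_error(apply_radiation_event(st, -1, 0, p), ">= 0")
})

test_that("conservation and monotonicity hold across random event doses", {
  set.seed(7)
  for (i in 1:50) {
    st <- system_state(TI = 10^runif(1, 6, 11), TNI = 10^runif(1, 5, 9),
                       I = 10^runif(1, 0, 10), L = 10^runif(1, 6, 10))
    d <- runif(1, 0, 60)
    out <- apply_radiation_event(st, d, runif(1, 0, 5), p)
    expect_equal(out[["TI"]] + (out[["I"]] - st[["I"]]), st[["TI"]],
                 tolerance = 1e-12)
    # strict dose-response (checked below underflow of the survival term)
    d2 <- runif(1, 0, 10)
    lo <- apply_radiation_event(st, d2, 0, p)
    hi <- apply_radiation_event(st, d2 + 1, 0, p)
    expect_lt(hi[["TI"]], lo[["TI"]])
    expect_gt(hi[["I"]], lo[["I"]])
  }
})

test_that("integrator matches closed forms in the decoupled limit", {
  # no immune interaction, no supply: pure exponentials
  p0 <- model_parameters(omega1 = 1e-12, omega2 = 0, omega3 = 0)
  pat <- list(T0 = 1e10, TNI0 = 1e7, L0 = 2e9, alphaT = 0.148, q = 0.12,
              delta_durva = 0)
  plan <- build_arm_plan("Y90_mono", total_dose = 0, p = p0, horizon = 365)
  tr <- simulate_patient(pat, plan, p0)
  t <- tr$times
  expect_equal(tr$states$TI, 1e10 * exp(p0$a * t), tolerance = 1e-6)
  expect_equal(tr$states$TNI, 1e7 * exp(p0$a * t), tolerance = 1e-6)
  # L relaxes to s/f: L(t) = s/f + (L0 - s/f) e^(-f t)
  Lstar <- p0$s / p0$f
  expect_equal(tr$states$L, Lstar + (2e9 - Lstar) * exp(-p0$f * t),
               tolerance = 1e-6)
  # doubling time ln(2)/a = 69.3 d
  i2 <- which.min(abs(tr$states$TI - 2e10))
  expect_equal(t[i2], log(2) / 0.01, tolerance = 0.02)
})

test_that("a zero-dose event leaves the trajectory unchanged", {
  pat <- list(T0 = 5e10, TNI0 = 5e7, L0 = 5e9, alphaT = 0.148, q = 0,
              delta_durva = 0)
  plan0 <- build_arm_plan("Y90_mono", total_dose = 0, p = p,
                          horizon = 200, kappa_blood = 0)
  plan1 <- build_arm_plan("Y90_mono", total_dose = 300, q = 0, p = p,
                          horizon = 200, kappa_blood = 0)
  tr0 <- simulate_patient(pat, plan0, p)
  tr1 <- simulate_patient(pat, plan1, p) # q = 0: all tumor doses zero
  expect_equal(tr1$states, tr0$states, tolerance = 1e-12)
})

test_that("growth and radiation kill decouple when the immune term is off", {
  p0 <- model_parameters(a = 1e-12, omega1 = 1e-12, omega2 = 0, omega3 = 0)
  pat <- list(T0 = 1e10, TNI0 = 1e7, L0 = 1e9, alphaT = 0.148, q = 1,
              delta_durva = 0)
  plan <- build_arm_plan("Y90_mono", total_dose = 10, p = p0, horizon = 30,
                         n_fractions = 1, kappa_blood = 0)
  tr <- simulate_patient(pat, plan, p0)
  expect_equal(tr$states$TI[tr$times == 30] / 1e10,
               exp(-0.148 * 10 - 0.0148 * 100), tolerance = 1e-6)
})

test_that("halving the step changes the 5-year state by < 0.5%", {
  pat <- test_cohort(1)[1, ]
  plan <- build_arm_plan("A", total_dose = 400, delta = 0.12, p = p,
                         horizon = 1826)
  tr1 <- simulate_patient(pat, plan, p, dt = 0.25)
  tr2 <- simulate_patient(pat, plan, p, dt = 0.125)
  end1 <- tr1$states$TI[length(tr1$times)]
  end2 <- tr2$states$TI[length(tr2$times)]
  expect_lt(abs(end1 - end2) / max(end2, 1), 0.005)
})

test_that("trajectories are well-formed and written as tidy CSV", {
  pat <- test_cohort(1)[1, ]
  plan <- build_arm_plan("A", total_dose = 400, delta = 0.12, p = p,
                         horizon = 100)
  tr <- simulate_patient(pat, plan, p)
  expect_s3_class(tr, "y90_trajectory")
  expect_true(all(diff(tr$times) > 0))
  expect_true(all(as.matrix(tr$states) >= 0))
  expect_equal(nrow(tr$states), length(tr$times))
  f <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, f, patient_id = 1)
  back <- read.csv(f)
  expect_named(back, c("time_d", "TI", "TNI", "I", "L", "patient_id",
                       "arm"))
  expect_equal(back$TI, tr$states$TI)
  unlink(f)
})
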
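p <- model_parameters()
coh <- test_cohort(300, seed = 17)

test_that("trial runs are deterministic and identical arms test null", {
  e1 <- y90ici:::.simulate_arm_events(coh, "A", 400, 0.12, 60, p, 120,
                                      0.25, 26, 0.05, 0.1)
  e2 <- y90ici:::.simulate_arm_events(coh, "A", 400, 0.12, 60, p, 120,
                                      0.25, 26, 0.05, 0.1)
  expect_identical(e1, e2)
  lr <- logrank(e1$pfs_months, e1$pfs_observed,
                e2$pfs_months, e2$pfs_observed)
  expect_equal(lr$chisq, 0, tolerance = 1e-12)
  expect_equal(lr$p, 1)
})

test_that("an inert arm progresses like the untreated tumor", {
  # q = 0 and delta = 0, immune-free limit: median PFS = ln(1.728)/a
  p0 <- model_parameters(omega1 = 1e-12, omega2 = 0, omega3 = 0, s = 1e-12)
  coh0 <- coh
  coh0$q <- 0
  coh0$L0 <- rep(1e-9, nrow(coh0))
  ev <- y90ici:::.simulate_arm_events(coh0, "A", 400, 0, 60, p0, 120,
                                      0.25, 26, 0, 0.1)
  med <- km_median(km_fit(ev$pfs_months, ev$pfs_observed))
  expect_equal(med, 1.8, tolerance = 0.02)
})

test_that("run_trial assembles events, summaries and comparisons", {
  res <- run_trial(coh, dose = 400, delta = 0.12, interval = 60, p = p,
                   arms = c("Y90_mono", "A", "B"), horizon_months = 84)
  expect_s3_class(res, "trial_result")
  expect_equal(nrow(res$events), 3 * nrow(coh))
  expect_equal(sort(unique(res$events$arm)), c("A", "B", "Y90_mono"))
  # every patient appears exactly once per arm
  expect_true(all(table(res$events$patient_id) == 3))
  expect_equal(nrow(res$summary), 3)
  expect_equal(nrow(res$comparisons), 3)
  expect_true(all(res$comparisons$pfs_p >= 0 & res$comparisons$pfs_p <= 1))
  # combination beats monotherapy on PFS
  medA <- res$summary$pfs_median[res$summary$arm == "A"]
  medY <- res$summary$pfs_median[res$summary$arm == "Y90_mono"]
  expect_true(is.na(medA) || medA > medY)
  # event times within (0, horizon]; censored rows sit at the horizon
  expect_true(all(res$events$pfs_months > 0 &
                    res$events$pfs_months <= 84))
  expect_true(all(res$events$pfs_months[!res$events$pfs_observed] == 84))
})

test_that("evaluable-only DM mode restricts to baseline-negative patients", {
  res <- run_trial(coh, arms = "A", p = p, horizon_months = 60,
                   dm_mode = "evaluable")
  ev <- res$events
  expect_true(any(!ev$dm_evaluable)) # some start above 0.1 cc
  all_mode <- run_trial(coh, arms = "A", p = p, horizon_months = 60)
  r_eval <- res$summary$dm_rate_3y
  r_all <- all_mode$summary$dm_rate_3y
  expect_lt(r_eval, r_all) # immediate events inflate the all-patients rate
})

test_that("a single sweep cell reproduces the plain trial run", {
  g <- dose_grid_sweep(coh, doses = 400, deltas = 0.12, arms = "A",
                       interval = 60, p = p, horizon_months = 84)
  expect_equal(nrow(g), 1)
  res <- run_trial(coh, dose = 400, delta = 0.12, interval = 60, p = p,
                   arms = "A", horizon_months = 84)
  expect_equal(g$median_pfs_months, res$summary$pfs_median)
  expect_equal(g$dm3y_pct, 100 * res$summary$dm_rate_3y)
  expect_equal(g$n, nrow(coh))
})

test_that("interval zero makes the sequential arms coincide with arm A", {
  sw <- interval_sweep(coh, intervals = 0,
                       presets = list(mid = c(400, 0.12)), p = p,
                       horizon_months = 60)
  a <- sw[sw$arm == "A", ]
  b <- sw[sw$arm == "B", ]
  cc <- sw[sw$arm == "C", ]
  expect_equal(b$median_pfs_months, a$median_pfs_months)
  expect_equal(cc$median_pfs_months, a$median_pfs_months)
  expect_equal(b$dm3y_pct, a$dm3y_pct)
})

test_that("longer inter-drug intervals do not improve the Y90-first arm", {
  sw <- interval_sweep(coh, intervals = c(30, 300),
                       presets = list(mid = c(400, 0.12)), p = p,
                       horizon_months = 120)
  b30 <- sw$median_pfs_months[sw$arm == "B" & sw$interval == 30]
  b300 <- sw$median_pfs_months[sw$arm == "B" & sw$interval == 300]
  expect_gte(b30, b300)
})
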
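frozen_trace <- function(rate = 0.03, timing = "first_cycle_undiscounted",
                         horizon = 10) {
  # cohort that never leaves disease-free
  arm <- arm_parameters("frozen", rep(0, horizon), rep(0, horizon),
                        0, 0, 0, 0, 0, horizon)
  mort <- mortality_table(c(50, 55, 60, 65), c(54, 59, 64, 69), rep(0, 4))
  cfg <- model_config(horizon = horizon,
                      discount_rate_benefits = rate,
                      conventions = model_conventions(discount_timing = timing))
  markov_cohort(arm, mort, cfg)
}

test_that("discounted state time matches geometric-series closed forms", {
  expect_equal(unname(discounted_state_time(frozen_trace(0))["disease_free"]), 10)
  # sum_{k=0..9} 1.03^-k and sum_{k=1..10} 1.03^-k
  expect_equal(unname(discounted_state_time(frozen_trace(0.03))["disease_free"]),
               sum(1.03^-(0:9)), tolerance = 1e-12)
  expect_equal(sum(1.03^-(0:9)), 8.7861, tolerance = 1e-4)
  t_end <- frozen_trace(0.03, "end_of_cycle")
  expect_equal(unname(discounted_state_time(t_end)["disease_free"]),
               sum(1.03^-(1:10)), tolerance = 1e-12)
  expect_equal(sum(1.03^-(1:10)), 8.5302, tolerance = 1e-4)
})

test_that("discounting never increases state time; equality at rate zero", {
  p <- apbi_parameters()
  tr <- markov_cohort(p$arms$IORT, p$mortality, p$config)
  t0 <- discounted_state_time(tr, rate = 0)
  t3 <- discounted_state_time(tr, rate = 0.03)
  expect_true(all(t3 <= t0 + 1e-12))
  expect_equal(discounted_state_time(tr, rate = 0), t0)
})

test_that("benefit identities hold on arbitrary traces", {
  p <- apbi_parameters()
  tr <- markov_cohort(p$arms$IORT, p$mortality, p$config)
  b <- arm_benefits(tr, p$utilities)
  expect_equal(b$qarfly, b$rfly * 0.920, tolerance = 1e-15)
  expect_lte(b$rfly, b$ly)
  expect_lte(b$qaly, b$ly)
  # utility-weighted time bounded by extreme utilities
  expect_gte(b$qaly / b$ly, p$utilities$u_metastasis)
  expect_lte(b$qaly / b$ly, p$utilities$u_disease_free)
  # all-ones utilities collapse QALY onto LY
  ones <- utility_set(1, 1, 1)
  b1 <- arm_benefits(tr, ones)
  expect_equal(b1$qaly, b1$ly, tolerance = 1e-15)
  expect_equal(b1$qarfly, b1$rfly, tolerance = 1e-15)
})

test_that("per-patient costs add one-time costs and allocated maintenance", {
  p <- apbi_parameters()
  expect_equal(per_patient_cost(p$arms$IORT, p$config), 418 + 359 + 55344 / 100)
  expect_equal(per_patient_cost(p$arms$IMRT, p$config), 29 + 294)
  cfg <- p$config; cfg$include_maintenance <- FALSE
  expect_equal(per_patient_cost(p$arms$IORT, cfg), 777)
  cfg2 <- p$config; cfg2$maintenance_divisor <- 12
  expect_equal(per_patient_cost(p$arms$IORT, cfg2), 418 + 359 + 55344 / 12)
})

test_that("ICER is the signed ratio of unrounded incrementals", {
  expect_equal(icer(100, 2), 50)
  expect_equal(icer(0, 1), 0)
  expect_true(is.na(icer(5, 0)))
  for (case in list(c(1006, -0.27), c(-3, 0.4), c(12, 7)))
    expect_equal(icer(-case[1], -case[2]), icer(case[1], case[2]))
})

test_that("dominance classification partitions the CE plane", {
  expect_equal(classify_dominance(1006, -0.27), "dominated")
  expect_equal(classify_dominance(-5, 1), "dominant")
  expect_equal(classify_dominance(5, 1), "trade-off")
  expect_equal(classify_dominance(-5, -1), "trade-off")
})

test_that("half-cycle correction averages the cycle boundaries", {
  arm <- arm_parameters("d", rep(0, 1), rep(0, 1), 0, 0, 0, 0, 0, 1)
  mort <- mortality_table(c(50, 55, 60, 65), c(54, 59, 64, 69), rep(0.5, 4))
  cfg <- model_config(horizon = 1, discount_rate_benefits = 0,
                      conventions = model_conventions(half_cycle_correction = TRUE))
  tr <- markov_cohort(arm, mort, cfg)
  # 100 alive at entry, 50 at the end of the single cycle -> 75 person-years
  expect_equal(unname(discounted_state_time(tr)["disease_free"]), 0.75)
})
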
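zero_arm <- function(horizon = 10) arm_parameters(
  "null", rep(0, horizon), rep(0, horizon), 0, 0, 0, 0, 0, horizon)

flat_mortality <- function(p) mortality_table(c(50, 55, 60, 65),
                                              c(54, 59, 64, 69), rep(p, 4))

test_that("zero probabilities give the identity matrix and a frozen cohort", {
  cfg <- model_config()
  m <- build_transition_matrix(zero_arm(), flat_mortality(0), cfg, 1)
  expect_equal(unname(m), diag(4))
  tr <- markov_cohort(zero_arm(), flat_mortality(0), cfg)
  expect_true(all(tr$occupancy[, "disease_free"] == 100))
  expect_true(all(tr$occupancy[, c("local_recurrence", "metastasis", "death")] == 0))
})

test_that("bundled IORT matrices carry the right entries per cycle", {
  p <- apbi_parameters()
  m3 <- build_transition_matrix(p$arms$IORT, p$mortality, p$config, 3)
  # year-3 recurrence 0.018, fixed metastasis 0.006, age 62 all-cause 0.006;
  # breast-cancer death does not apply from disease-free under the defaults
  expect_equal(m3["disease_free", "local_recurrence"], 0.018)
  expect_equal(m3["disease_free", "metastasis"], 0.006)
  expect_equal(m3["disease_free", "death"], 0.006)
  expect_equal(m3["disease_free", "disease_free"], 0.970)
  expect_equal(m3["local_recurrence", "metastasis"], 0.03)
  expect_equal(unname(m3["death", ]), c(0, 0, 0, 1))
  # cycle 6: attained age 65, next mortality band
  m6 <- build_transition_matrix(p$arms$IORT, p$mortality, p$config, 6)
  expect_equal(m6["disease_free", "death"], 0.009)
})

test_that("infeasible outgoing probabilities fail naming state and cycle", {
  arm <- arm_parameters("hot", rep(0.5, 10), rep(0, 10), 0.4, 0.9, 0, 0, 0, 10)
  expect_error(build_transition_matrix(arm, flat_mortality(0.3), model_config(), 2),
               "disease_free.*cycle 2")
})

test_that("a pure death probability of 0.5 halves the cohort each cycle", {
  cfg <- model_config(horizon = 2)
  tr <- markov_cohort(zero_arm(2), flat_mortality(0.5), cfg)
  alive <- rowSums(tr$occupancy[, c("disease_free", "local_recurrence",
                                    "metastasis")])
  expect_equal(unname(alive), c(100, 50, 25))
})

test_that("traces satisfy conservation, monotone death, non-negativity and flow reconciliation", {
  for (seed in 1:20) {
    params <- generate_random_model_spec(seed)
    tr <- markov_cohort(params$arms$A, params$mortality, params$config)
    expect_equal(unname(rowSums(tr$occupancy)),
                 rep(params$config$cohort_size, params$config$horizon + 1),
                 tolerance = 1e-9)
    expect_true(all(diff(tr$occupancy[, "death"]) >= -1e-12))
    expect_true(all(tr$occupancy >= -1e-12))
    for (t in seq_len(params$config$horizon)) {
      expect_equal(unname(colSums(tr$flows[t, , ])),
                   unname(tr$occupancy[t + 1, ]), tolerance = 1e-12)
      expect_equal(unname(rowSums(tr$flows[t, , ])),
                   unname(tr$occupancy[t, ]), tolerance = 1e-12)
    }
    for (t in seq_len(params$config$horizon)) {
      m <- build_transition_matrix(params$arms$A, params$mortality,
                                   params$config, t)
      expect_equal(unname(rowSums(m)), rep(1, 4), tolerance = 1e-12)
      expect_true(all(m >= 0))
    }
  }
})

test_that("per-patient occupancy is invariant to cohort size", {
  p <- apbi_parameters()
  tr100 <- markov_cohort(p$arms$IORT, p$mortality, p$config)
  cfg <- p$config; cfg$cohort_size <- 1000
  tr1000 <- markov_cohort(p$arms$IORT, p$mortality, cfg)
  expect_equal(tr100$occupancy / 100, tr1000$occupancy / 1000,
               tolerance = 1e-12)
})

test_that("raising local-recurrence probabilities never increases disease-free occupancy", {
  for (seed in 1:10) {
    params <- generate_random_model_spec(seed, probability_cap = 0.2)
    lo <- markov_cohort(params$arms$A, params$mortality, params$config)
    bumped <- params$arms$A
    bumped$p_local_recurrence <- pmin(bumped$p_local_recurrence + 0.05, 1)
    hi <- markov_cohort(bumped, params$mortality, params$config)
    expect_true(all(hi$occupancy[, "disease_free"] <=
                      lo$occupancy[, "disease_free"] + 1e-12))
  }
})

test_that("the deterministic trace agrees with a Monte-Carlo microsimulation", {
  for (seed in 1:2)
    expect_microsim_agreement(generate_random_model_spec(seed), "A",
                              n_patients = 1e5, seed = seed + 100)
})

test_that("trace writers emit readable CSV and JSON", {
  p <- apbi_parameters()
  tr <- markov_cohort(p$arms$IORT, p$mortality, p$config)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read.csv(f)
  expect_equal(nrow(back), 4 * (p$config$horizon + 1))
  expect_equal(sum(back$count), 100 * (p$config$horizon + 1), tolerance = 1e-9)
  fj <- withr::local_tempfile(fileext = ".json")
  write_trace(tr, fj)
  expect_true(jsonlite::validate(readChar(fj, file.size(fj))))
})
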
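test_that("bundled parameters match the shipped fixture transcription", {
  p <- apbi_parameters()
  fixture <- yaml::read_yaml(system.file("extdata", "params_base.yaml",
                                         package = "apbicea"))
  for (lab in c("IORT", "IMRT")) {
    for (f in names(fixture$arms[[lab]]))
      expect_identical(p$arms[[lab]][[f]], as.numeric(fixture$arms[[lab]][[f]]),
                       label = paste(lab, f))
  }
  # spot checks on values the model hinges on
  expect_identical(p$arms$IORT$p_local_recurrence[3], 0.018)
  expect_identical(p$arms$IMRT$p_metastasis_from_disease_free, 0.0029)
  expect_identical(p$arms$IORT$cost_annual_maintenance, 55344)
  expect_identical(p$utilities$u_disease_free, 0.920)
  expect_identical(mortality_prob(p$mortality, 64), 0.006)
  expect_identical(mortality_prob(p$mortality, 65), 0.009)
  expect_identical(p$config$cohort_size, 100)
  expect_identical(p$config$discount_rate_benefits, 0.03)
})

test_that("sensitivity variants replace only the stated parameter block", {
  p <- apbi_parameters()
  base <- p$arms$IORT
  lr <- p$arms$IORT_lower_recurrence
  lm <- p$arms$IORT_lower_metastasis
  expect_false(identical(lr$p_local_recurrence, base$p_local_recurrence))
  for (f in setdiff(names(base), c("arm_label", "p_local_recurrence")))
    expect_identical(lr[[f]], base[[f]], label = paste("lower_recurrence", f))
  expect_identical(lm$p_metastasis_from_disease_free, 0.004)
  for (f in setdiff(names(base), c("arm_label", "p_metastasis_from_disease_free")))
    expect_identical(lm[[f]], base[[f]], label = paste("lower_metastasis", f))
})

test_that("serialize then load is the identity on the bundled set", {
  p <- apbi_parameters()
  f <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(p, f)
  p2 <- load_parameters(f)
  expect_equal(p2$arms, p$arms, tolerance = 1e-12)
  expect_equal(p2$mortality$bands, p$mortality$bands)
  expect_equal(unclass(p2$utilities), unclass(p$utilities))
  expect_equal(p2$config$conventions, p$config$conventions)
})

test_that("config schema violations fail with the offending field named", {
  f <- withr::local_tempfile(fileext = ".yaml")
  base <- yaml::read_yaml(system.file("extdata", "params_base.yaml",
                                      package = "apbicea"))
  bad <- base; bad$arms$IORT$p_metastasis_from_disease_free <- 1.2
  yaml::write_yaml(bad, f)
  expect_error(load_parameters(f), "p_metastasis_from_disease_free")

  bad <- base; bad$arms$IORT$p_local_recurrence <- bad$arms$IORT$p_local_recurrence[1:9]
  yaml::write_yaml(bad, f)
  expect_error(load_parameters(f), "length 10")

  bad <- base; bad$arms$IORT$unexpected_knob <- 1
  yaml::write_yaml(bad, f)
  expect_error(load_parameters(f), "unexpected_knob")

  bad <- base; bad$flux_capacitor <- TRUE
  yaml::write_yaml(bad, f)
  expect_error(load_parameters(f), "flux_capacitor")
})

test_that("validate_parameters flags row-sum and cost violations, not valid sets", {
  p <- apbi_parameters()
  expect_length(validate_parameters(p), 0)

  # LR row: 0.99 metastasis + 0.018 bc death + 0.009 all-cause > 1
  bad <- p
  bad$arms$IORT$p_metastasis_from_local_recurrence <- 0.99
  cfg <- p$config
  cfg$conventions <- model_conventions(
    bc_death_sources = c("local_recurrence", "metastasis"),
    death_combination = "additive")
  rep <- validate_parameters(bad, cfg)
  expect_true(any(grepl("local_recurrence", rep) & grepl("sum", rep)))

  bad <- p
  bad$arms$IMRT$cost_treatment <- -5
  expect_true(any(grepl("cost_treatment", validate_parameters(bad))))

  zero <- generate_random_model_spec(1)
  for (a in names(zero$arms)) {
    zero$arms[[a]]$p_local_recurrence[] <- 0
    zero$arms[[a]]$p_bc_death[] <- 0
    zero$arms[[a]]$p_metastasis_from_disease_free <- 0
    zero$arms[[a]]$p_metastasis_from_local_recurrence <- 0
  }
  zero$mortality$bands$p_death[] <- 0
  expect_length(validate_parameters(zero), 0)
})

test_that("mortality table enforces contiguity and covers the cohort's ages", {
  p <- apbi_parameters()
  expect_silent(mortality_prob(p$mortality, 50:69))
  expect_error(mortality_prob(p$mortality, 70), "not covered")
  expect_error(mortality_table(c(50, 56), c(54, 60), c(0.1, 0.1)), "contiguous")
})

test_that("transition-probability CSV round-trips", {
  p <- apbi_parameters()$arms$IORT
  f <- withr::local_tempfile(fileext = ".csv")
  write_transition_csv(p$p_local_recurrence, p$p_bc_death, f)
  back <- read_transition_csv(f)
  expect_equal(back$p_local_recurrence, p$p_local_recurrence)
  expect_equal(back$p_bc_death, p$p_bc_death)
})
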
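#' Transition probabilities and unit costs for one radiotherapy strategy
#'
#' Bundles everything the cohort model needs to know about one treatment
#' arm: the time-dependent annual probabilities of local recurrence and of
#' breast-cancer death (one value per year since surgery), the fixed annual
#' metastasis probabilities from the disease-free and local-recurrence
#' states, and the per-patient and equipment-level unit costs (2021 USD).
#'
#' @param arm_label Character identifier, e.g. `"IORT"` or `"IMRT"`.
#' @param p_local_recurrence Numeric vector of annual local-recurrence
#'   probabilities, indexed by year since surgery; length must equal
#'   `horizon`.
#' @param p_bc_death Annual breast-cancer death probabilities, same
#'   indexing and length.
#' @param p_metastasis_from_disease_free Fixed annual probability of
#'   distant metastasis from the disease-free state.
#' @param p_metastasis_from_local_recurrence Fixed annual probability of
#'   metastasis from the local-recurrence state.
#' @param cost_treatment One-time treatment cost per patient (2021 USD).
#' @param cost_other_direct One-time other direct cost per patient.
#' @param cost_annual_maintenance Equipment maintenance cost per year
#'   (zero where the equipment is shared with other indications and its
#'   upkeep is not attributable to this strategy).
#' @param horizon Model horizon in years; the time-dependent vectors must
#'   cover it exactly.
#' @return An object of class `arm_parameters`.
#' @seealso [apbi_parameters()] for the bundled IORT/IMRT set.
#' @export
arm_parameters <- function(arm_label,
                           p_local_recurrence,
                           p_bc_death,
                           p_metastasis_from_disease_free,
                           p_metastasis_from_local_recurrence,
                           cost_treatment,
                           cost_other_direct,
                           cost_annual_maintenance = 0,
                           horizon = 10) {
  stopifnot(is.character(arm_label), length(arm_label) == 1L)
  check_prob(p_local_recurrence, "p_local_recurrence", horizon)
  check_prob(p_bc_death, "p_bc_death", horizon)
  check_prob(p_metastasis_from_disease_free, "p_metastasis_from_disease_free", 1L)
  check_prob(p_metastasis_from_local_recurrence, "p_metastasis_from_local_recurrence", 1L)
  for (nm in c("cost_treatment", "cost_other_direct", "cost_annual_maintenance")) {
    v <- get(nm)
    check_scalar(v, nm)
    if (v < 0) stopf("'%s' must be non-negative", nm)
  }
  structure(list(
    arm_label = arm_label,
    p_local_recurrence = as.numeric(p_local_recurrence),
    p_bc_death = as.numeric(p_bc_death),
    p_metastasis_from_disease_free = as.numeric(p_metastasis_from_disease_free),
    p_metastasis_from_local_recurrence = as.numeric(p_metastasis_from_local_recurrence),
    cost_treatment = as.numeric(cost_treatment),
    cost_other_direct = as.numeric(cost_other_direct),
    cost_annual_maintenance = as.numeric(cost_annual_maintenance)
  ), class = "arm_parameters")
}

#' @export
print.arm_parameters <- function(x, ...) {
  cat("Arm parameters:", x$arm_label, "\n")
  cat("  annual P(local recurrence): ",
      paste(format(x$p_local_recurrence), collapse = " "), "\n")
  cat("  annual P(breast-cancer death): ",
      paste(format(x$p_bc_death), collapse = " "), "\n")
  cat(sprintf("  P(metastasis | disease-free) = %.4f, P(metastasis | LR) = %.4f\n",
              x$p_metastasis_from_disease_free,
              x$p_metastasis_from_local_recurrence))
  cat(sprintf("  costs (2021 USD): treatment %.2f, other direct %.2f, maintenance/yr %.2f\n",
              x$cost_treatment, x$cost_other_direct, x$cost_annual_maintenance))
  invisible(x)
}

#' Age-banded all-cause mortality table
#'
#' Annual probabilities of death from any cause on contiguous closed age
#' bands, as published in national life tables.
#'
#' @param age_low,age_high Integer vectors of inclusive band bounds.
#' @param p_death Annual all-cause death probability per band.
#' @return An object of class `mortality_table`.
#' @export
mortality_table <- function(age_low, age_high, p_death) {
  stopifnot(length(age_low) == length(age_high),
            length(age_low) == length(p_death))
  check_prob(p_death, "p_death")
  o <- order(age_low)
  age_low <- age_low[o]; age_high <- age_high[o]; p_death <- p_death[o]
  if (any(age_high < age_low))
    stopf("mortality bands must have age_high >= age_low")
  if (length(age_low) > 1L && any(age_low[-1] != age_high[-length(age_high)] + 1L))
    stopf("mortality bands must be contiguous and non-overlapping")
  structure(
    list(bands = data.frame(age_low = age_low, age_high = age_high,
                            p_death = as.numeric(p_death))),
    class = "mortality_table")
}

#' Look up the annual all-cause death probability for an age
#'
#' @param table A [mortality_table()].
#' @param age Age in completed years (vectorised).
#' @return Annual probability of death from any cause.
#' @export
mortality_prob <- function(table, age) {
  stopifnot(inherits(table, "mortality_table"))
  b <- table$bands
  idx <- vapply(age, function(a) {
    i <- which(a >= b$age_low & a <= b$age_high)
    if (length(i) != 1L)
      stopf("age %s is not covered by the mortality table (bands %d-%d)",
            a, min(b$age_low), max(b$age_high))
    i
  }, integer(1))
  b$p_death[idx]
}

#' @export
print.mortality_table <- function(x, ...) {
  cat("All-cause mortality table (annual probabilities):\n")
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Health-state utility weights
#'
#' Quality-of-life weights on the 0 (death) to 1 (perfect health) scale
#' for the three alive states of the model.
#'
#' @param u_disease_free,u_local_recurrence,u_metastasis Utility weights
#'   in `[0, 1]`.
#' @return An object of class `utility_set`.
#' @export
utility_set <- function(u_disease_free, u_local_recurrence, u_metastasis) {
  for (nm in c("u_disease_free", "u_local_recurrence", "u_metastasis"))
    check_prob(get(nm), nm, 1L)
  structure(list(u_disease_free = u_disease_free,
                 u_local_recurrence = u_local_recurrence,
                 u_metastasis = u_metastasis),
            class = "utility_set")
}

#' Modelling conventions the source data leave open
#'
#' A cohort model built from published annual probabilities has to fix a
#' handful of conventions that the probability tables themselves do not
#' determine: from which alive states the breast-cancer-specific death
#' probabilities apply, how cause-specific and all-cause death
#' probabilities combine within a cycle, whether the first cycle is
#' discounted, and whether a half-cycle correction is applied to state
#' occupancy when accruing benefits.  [calibrate_conventions()] searches
#' this space exhaustively; the defaults here are the calibrated winners.
#'
#' @param bc_death_sources Alive states from which the annual
#'   breast-cancer death probability applies.  One of the three presets
#'   `"metastasis"`, `c("local_recurrence", "metastasis")`, or all three
#'   alive states.  All-cause mortality always applies from every alive
#'   state.
#' @param death_combination `"independent"` combines cause-specific and
#'   all-cause death as `1 - (1 - p_bc)(1 - p_ac)`; `"additive"` simply
#'   sums them.  At the probability magnitudes involved the two differ by
#'   less than 1e-4.
#' @param discount_timing `"first_cycle_undiscounted"` weights cycle t by
#'   `(1 + r)^-(t - 1)`; `"end_of_cycle"` by `(1 + r)^-t`.
#' @param half_cycle_correction If `TRUE`, benefits accrue on the average
#'   of the occupancy at the two boundaries of each cycle rather than on
#'   end-of-cycle occupancy.
#' @return An object of class `model_conventions`.
#' @export
model_conventions <- function(bc_death_sources = "metastasis",
                              death_combination = c("independent", "additive"),
                              discount_timing = c("first_cycle_undiscounted",
                                                  "end_of_cycle"),
                              half_cycle_correction = FALSE) {
  bc_death_sources <- match.arg(bc_death_sources, ALIVE_STATES, several.ok = TRUE)
  death_combination <- match.arg(death_combination)
  discount_timing <- match.arg(discount_timing)
  stopifnot(is.logical(half_cycle_correction), length(half_cycle_correction) == 1L)
  structure(list(bc_death_sources = bc_death_sources,
                 death_combination = death_combination,
                 discount_timing = discount_timing,
                 half_cycle_correction = half_cycle_correction),
            class = "model_conventions")
}

#' @export
print.model_conventions <- function(x, ...) {
  cat("Model conventions:\n")
  cat("  breast-cancer death applies from:",
      paste(x$bc_death_sources, collapse = ", "), "\n")
  cat("  death combination:", x$death_combination, "\n")
  cat("  discount timing:", x$discount_timing, "\n")
  cat("  half-cycle correction:", x$half_cycle_correction, "\n")
  invisible(x)
}

#' Global model configuration
#'
#' @param cohort_size Number of women entering the model (all in the
#'   disease-free state).  Per-patient outcomes are invariant to it.
#' @param start_age Age at entry, years.
#' @param horizon Number of annual cycles.
#' @param cycle_length Cycle length in years (the model is annual).
#' @param discount_rate_benefits,discount_rate_costs Annual discount
#'   rates as fractions.
#' @param include_maintenance Include the annual equipment maintenance
#'   cost (allocated over the cohort) in per-patient costs.
#' @param maintenance_divisor Number of patients the annual maintenance
#'   cost is spread over; defaults to `cohort_size`.
#' @param conventions A [model_conventions()] object.
#' @return An object of class `model_config`.
#' @export
model_config <- function(cohort_size = 100,
                         start_age = 60,
                         horizon = 10,
                         cycle_length = 1,
                         discount_rate_benefits = 0.03,
                         discount_rate_costs = 0.03,
                         include_maintenance = TRUE,
                         maintenance_divisor = NULL,
                         conventions = model_conventions()) {
  check_scalar(cohort_size, "cohort_size")
  check_scalar(start_age, "start_age")
  check_scalar(horizon, "horizon")
  if (horizon < 1 || horizon != round(horizon))
    stopf("'horizon' must be a positive integer number of cycles")
  if (cohort_size <= 0) stopf("'cohort_size' must be positive")
  for (nm in c("discount_rate_benefits", "discount_rate_costs")) {
    r <- get(nm)
    check_scalar(r, nm)
    if (r < 0 || r >= 1) stopf("'%s' must lie in [0, 1)", nm)
  }
  stopifnot(inherits(conventions, "model_conventions"),
            is.logical(include_maintenance), length(include_maintenance) == 1L)
  if (!is.null(maintenance_divisor)) {
    check_scalar(maintenance_divisor, "maintenance_divisor")
    if (maintenance_divisor <= 0) stopf("'maintenance_divisor' must be positive")
  }
  structure(list(cohort_size = as.numeric(cohort_size),
                 start_age = as.numeric(start_age),
                 horizon = as.integer(horizon),
                 cycle_length = cycle_length,
                 discount_rate_benefits = discount_rate_benefits,
                 discount_rate_costs = discount_rate_costs,
                 include_maintenance = include_maintenance,
                 maintenance_divisor = maintenance_divisor,
                 conventions = conventions),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("Cohort of %g women aged %g, %d annual cycles\n",
              x$cohort_size, x$start_age, x$horizon))
  cat(sprintf("  discount rates: benefits %.1f%%, costs %.1f%%\n",
              100 * x$discount_rate_benefits, 100 * x$discount_rate_costs))
  cat("  maintenance cost included:", x$include_maintenance, "\n")
  print(x$conventions)
  invisible(x)
}

#' Check a parameter bundle for inconsistencies
#'
#' Collects (rather than throws) violations: outgoing transition
#' probabilities summing above one for any state in any cycle under the
#' configured conventions, negative costs, time-dependent vectors whose
#' length does not match the horizon, probabilities outside `[0, 1]`, and
#' mortality-table gaps over the ages the cohort will reach.
#'
#' @param params A parameter bundle as returned by [apbi_parameters()] or
#'   [load_parameters()].
#' @param config A [model_config()].
#' @return A character vector of violation messages, of class
#'   `validation_report`; empty when the bundle is valid.
#' @export
validate_parameters <- function(params, config = params$config %||% model_config()) {
  viol <- character(0)
  conv <- config$conventions
  ages <- config$start_age + seq_len(config$horizon) - 1
  ac <- tryCatch(mortality_prob(params$mortality, ages),
                 error = function(e) {
                   viol <<- c(viol, conditionMessage(e))
                   rep(0, config$horizon)
                 })
  for (arm in params$arms) {
    lab <- arm$arm_label
    for (nm in c("p_local_recurrence", "p_bc_death")) {
      v <- arm[[nm]]
      if (length(v) != config$horizon)
        viol <- c(viol, sprintf("%s: '%s' has length %d but horizon is %d",
                                lab, nm, length(v), config$horizon))
      if (!is_prob(v))
        viol <- c(viol, sprintf("%s: '%s' outside [0, 1]", lab, nm))
    }
    for (nm in c("cost_treatment", "cost_other_direct", "cost_annual_maintenance"))
      if (arm[[nm]] < 0)
        viol <- c(viol, sprintf("%s: '%s' is negative", lab, nm))
    for (t in seq_len(min(config$horizon, length(arm$p_bc_death),
                          length(arm$p_local_recurrence)))) {
      death <- function(state) compose_death(
        ac[t], if (state %in% conv$bc_death_sources) arm$p_bc_death[t] else 0,
        conv$death_combination)
      sums <- c(
        disease_free = arm$p_local_recurrence[t] +
          arm$p_metastasis_from_disease_free + death("disease_free"),
        local_recurrence = arm$p_metastasis_from_local_recurrence +
          death("local_recurrence"),
        metastasis = death("metastasis"))
      bad <- names(sums)[sums > 1]
      for (s in bad)
        viol <- c(viol, sprintf(
          "%s: outgoing probabilities from state '%s' sum to %.4f > 1 in cycle %d",
          lab, s, sums[[s]], t))
    }
  }
  u <- params$utilities
  if (!is.null(u))
    for (nm in names(u))
      if (!is_prob(u[[nm]]))
        viol <- c(viol, sprintf("utility '%s' outside [0, 1]", nm))
  structure(viol, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (length(x) == 0) cat("Parameter bundle valid: no violations.\n")
  else cat(sprintf("%d violation(s):\n", length(x)),
           paste0("  - ", unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
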
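# Discounted benefit and cost accounting, ICERs and dominance.

discount_factors <- function(rate, horizon, timing) {
  if (timing == "first_cycle_undiscounted") (1 + rate)^-(seq_len(horizon) - 1)
  else (1 + rate)^-seq_len(horizon)
}

#' Discounted person-years per state, per patient
#'
#' Accrues occupancy over the cycles of a trace, discounted at `rate`
#' under the configured timing convention, and divides by cohort size.
#' With the half-cycle correction enabled, each cycle contributes the
#' average of the occupancy at its two boundaries; otherwise end-of-cycle
#' occupancy is used.
#'
#' @param trace A [markov_cohort()] trace.
#' @param rate Annual discount rate (defaults to the trace's configured
#'   benefit rate).
#' @param conventions Conventions controlling discount timing and the
#'   half-cycle correction (default: the trace's).
#' @return Named numeric vector of discounted person-years per patient,
#'   one entry per state.
#' @export
discounted_state_time <- function(trace,
                                  rate = trace$config$discount_rate_benefits,
                                  conventions = trace$config$conventions) {
  stopifnot(inherits(trace, "cohort_trace"))
  H <- trace$config$horizon
  d <- discount_factors(rate, H, conventions$discount_timing)
  occ <- trace$occupancy
  st <- if (conventions$half_cycle_correction)
    (occ[seq_len(H), , drop = FALSE] + occ[seq_len(H) + 1, , drop = FALSE]) / 2
  else occ[seq_len(H) + 1, , drop = FALSE]
  colSums(st * d) / trace$config$cohort_size
}

#' Discounted per-patient benefits for one arm
#'
#' Life-years are the discounted expected time in any alive state;
#' recurrence-free life-years the time in the disease-free state; the
#' quality-adjusted versions weight state time by the health-state
#' utilities (so QARFLY is exactly RFLY times the disease-free utility).
#'
#' @param trace A [markov_cohort()] trace.
#' @param utilities A [utility_set()].
#' @return An object of class `outcome_set`: list with `ly`, `rfly`,
#'   `qaly`, `qarfly` (discounted per-patient person-years) and
#'   `arm_label`.
#' @export
arm_benefits <- function(trace, utilities) {
  stopifnot(inherits(utilities, "utility_set"))
  tm <- discounted_state_time(trace)
  u <- c(disease_free = utilities$u_disease_free,
         local_recurrence = utilities$u_local_recurrence,
         metastasis = utilities$u_metastasis)
  structure(list(
    ly = sum(tm[ALIVE_STATES]),
    rfly = unname(tm["disease_free"]),
    qaly = sum(tm[ALIVE_STATES] * u[ALIVE_STATES]),
    qarfly = unname(tm["disease_free"]) * utilities$u_disease_free,
    arm_label = trace$arm_label
  ), class = "outcome_set")
}

#' @export
print.outcome_set <- function(x, ...) {
  cat(sprintf("%s: LY %.2f, RFLY %.2f, QALY %.2f, QARFLY %.2f (discounted, per patient)\n",
              x$arm_label, x$ly, x$rfly, x$qaly, x$qarfly))
  invisible(x)
}

#' Per-patient cost of one arm
#'
#' Treatment and other direct costs are incurred once, at model entry, so
#' the cost discount rate has no effect on them.  The annual equipment
#' maintenance cost, when included, is allocated over
#' `maintenance_divisor` patients per year (default: the modelled cohort
#' size).
#'
#' @param arm An [arm_parameters()] object.
#' @param config A [model_config()].
#' @return Cost per patient, 2021 USD.
#' @export
per_patient_cost <- function(arm, config = model_config()) {
  maint <- if (config$include_maintenance)
    arm$cost_annual_maintenance / (config$maintenance_divisor %||% config$cohort_size)
  else 0
  arm$cost_treatment + arm$cost_other_direct + maint
}

#' Incremental cost-effectiveness ratio
#'
#' Signed ratio of incremental cost to incremental benefit, always
#' computed from unrounded incrementals.  A zero benefit difference has
#' no defined ICER and returns `NA`; dominance should then be judged on
#' cost alone.
#'
#' @param delta_cost Incremental cost (currency).
#' @param delta_benefit Incremental benefit (person-years).
#' @return Currency per unit benefit, or `NA_real_`.
#' @export
icer <- function(delta_cost, delta_benefit) {
  if (delta_benefit == 0) return(NA_real_)
  delta_cost / delta_benefit
}

#' Dominance classification on the cost-effectiveness plane
#'
#' @param delta_cost,delta_benefit Incrementals of the evaluated strategy
#'   versus its comparator.
#' @return `"dominated"` (costlier and less effective), `"dominant"`
#'   (cheaper and more effective), or `"trade-off"`.
#' @export
classify_dominance <- function(delta_cost, delta_benefit) {
  if (delta_cost > 0 && delta_benefit < 0) "dominated"
  else if (delta_cost < 0 && delta_benefit > 0) "dominant"
  else "trade-off"
}

MEASURES <- c("ly", "rfly", "qaly", "qarfly")

#' Pairwise cost-effectiveness comparison of two arms
#'
#' @param outcome,comparator `outcome_set`s for the evaluated arm and its
#'   comparator (incrementals are evaluated minus comparator).
#' @param cost,cost_comparator Per-patient costs of the two arms.
#' @return An object of class `ce_result`: the two outcome sets and
#'   costs, plus a `table` data frame with one row per benefit measure
#'   (incremental benefit, incremental cost, ICER, dominance label).
#' @export
compare_arms <- function(outcome, comparator, cost, cost_comparator) {
  dc <- cost - cost_comparator
  rows <- lapply(MEASURES, function(m) {
    db <- outcome[[m]] - comparator[[m]]
    data.frame(measure = toupper(m),
               evaluated = outcome[[m]], comparator = comparator[[m]],
               incremental = db, icer = icer(dc, db),
               dominance = classify_dominance(dc, db))
  })
  structure(list(evaluated = outcome, comparator = comparator,
                 cost_evaluated = cost, cost_comparator = cost_comparator,
                 incremental_cost = dc,
                 table = do.call(rbind, rows)),
            class = "ce_result")
}

#' @export
print.ce_result <- function(x, ...) {
  cat(sprintf("Cost-effectiveness: %s vs %s\n",
              x$evaluated$arm_label, x$comparator$arm_label))
  tab <- x$table
  out <- data.frame(measure = tab$measure,
                    evaluated = sprintf("%.2f", tab$evaluated),
                    comparator = sprintf("%.2f", tab$comparator),
                    incremental = sprintf("%.3f", tab$incremental),
                    ICER = ifelse(is.na(tab$icer), "-",
                                  sprintf("%.0f", tab$icer)),
                    dominance = tab$dominance)
  names(out)[2:3] <- c(x$evaluated$arm_label, x$comparator$arm_label)
  print(out, row.names = FALSE)
  cat(sprintf("Costs: %s $%.0f, %s $%.0f, incremental $%.0f\n",
              x$evaluated$arm_label, x$cost_evaluated,
              x$comparator$arm_label, x$cost_comparator,
              x$incremental_cost))
  invisible(x)
}

#' CE-plane coordinates of a comparison
#'
#' One `(incremental benefit, incremental cost)` point per benefit
#' measure, for cost-effectiveness-plane plotting.
#'
#' @param result A `ce_result`.
#' @return Data frame with columns `measure`, `delta_benefit`,
#'   `delta_cost`.
#' @export
ce_plane <- function(result) {
  stopifnot(inherits(result, "ce_result"))
  data.frame(measure = result$table$measure,
             delta_benefit = result$table$incremental,
             delta_cost = result$incremental_cost)
}
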
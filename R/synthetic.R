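# Synthetic data generators: trial-style curves from known hazards and
# random valid parameter bundles for property testing.

#' Specification of a synthetic trial curve pair
#'
#' Describes the data-generating process behind a trial-style cumulative
#' IBTR incidence curve and an overall survival curve: the true annual
#' hazards, optional per-year binomial sampling noise (n subjects at
#' risk, each experiencing the year's event as a Bernoulli draw), and
#' optional rounding to the precision of a published figure.
#'
#' @param hazard_ibtr,hazard_death True annual event hazards, one per
#'   year; equal length.
#' @param n Number of subjects when sampling noise is wanted; `NULL` for
#'   exact (noiseless) curves.
#' @param round_digits Decimal places applied to the reported curve
#'   values (`NULL` = no rounding); published curves typically carry 2-3.
#' @param seed RNG seed; mandatory when `n` is given.
#' @return An object of class `synthetic_trial_spec`.
#' @export
synthetic_trial_spec <- function(hazard_ibtr, hazard_death, n = NULL,
                                 round_digits = NULL, seed = NULL) {
  check_prob(hazard_ibtr, "hazard_ibtr")
  check_prob(hazard_death, "hazard_death", length(hazard_ibtr))
  if (!is.null(n)) {
    check_scalar(n, "n")
    if (n <= 0) stopf("'n' must be positive")
    if (is.null(seed)) stopf("a seed is mandatory when sampling noise is enabled")
  }
  structure(list(hazard_ibtr = hazard_ibtr, hazard_death = hazard_death,
                 n = n, round_digits = round_digits, seed = seed),
            class = "synthetic_trial_spec")
}

simulate_curve <- function(hazard, n, kind) {
  at_risk <- n
  events_cum <- 0
  values <- numeric(length(hazard))
  for (t in seq_along(hazard)) {
    ev <- stats::rbinom(1, at_risk, hazard[t])
    events_cum <- events_cum + ev
    at_risk <- at_risk - ev
    values[t] <- if (kind == "incidence") events_cum / n else at_risk / n
  }
  if (kind == "incidence") c(0, values) else c(1, values)
}

#' Generate a synthetic trial curve pair
#'
#' In noiseless mode the curves are the exact
#' [cumulative_from_annual()] transforms of the true hazards, so
#' [annual_probs()] recovers the hazards to machine precision.  In noisy
#' mode `n` subjects are pushed through per-year Bernoulli events on the
#' shrinking at-risk set (fixed seed) and the empirical curves are
#' returned.  Rounding, when requested, is applied last.
#'
#' @param spec A [synthetic_trial_spec()].
#' @return List with elements `incidence` and `survival`, both
#'   [cumulative_curve()]s.
#' @export
generate_trial_curves <- function(spec) {
  stopifnot(inherits(spec, "synthetic_trial_spec"))
  if (is.null(spec$n)) {
    inc <- cumulative_from_annual(spec$hazard_ibtr, "incidence")$values
    srv <- cumulative_from_annual(spec$hazard_death, "survival")$values
  } else {
    set.seed(spec$seed)
    inc <- simulate_curve(spec$hazard_ibtr, spec$n, "incidence")
    srv <- simulate_curve(spec$hazard_death, spec$n, "survival")
  }
  if (!is.null(spec$round_digits)) {
    inc <- cummax(round(inc, spec$round_digits))  # keep monotone after rounding
    srv <- rev(cummax(rev(round(srv, spec$round_digits))))
  }
  list(incidence = cumulative_curve(inc, "incidence"),
       survival = cumulative_curve(srv, "survival"))
}

#' Generate a random valid parameter bundle
#'
#' Draws a full two-arm parameter bundle -- time-dependent recurrence and
#' breast-cancer death vectors, fixed metastasis probabilities, an
#' age-banded mortality table, ordered utilities and positive costs --
#' constructed so that every per-state outgoing probability sum is at
#' most `3 * probability_cap` (recurrence and metastasis components are
#' capped at `probability_cap`, each death component at half of it, so
#' the additive death term never exceeds the cap).  Used for engine
#' property tests; every bundle passes [validate_parameters()] by
#' construction.
#'
#' @param seed RNG seed (reproducible).
#' @param probability_cap Upper bound for each transition component, in
#'   `(0, 0.3]`.
#' @return An `apbi_parameters` bundle with arms `A` and `B`.
#' @export
generate_random_model_spec <- function(seed, probability_cap = 0.3) {
  check_scalar(probability_cap, "probability_cap")
  if (probability_cap <= 0 || probability_cap > 0.3)
    stopf("'probability_cap' must lie in (0, 0.3]")
  set.seed(seed)
  cap <- probability_cap
  config <- model_config()
  H <- config$horizon
  rand_arm <- function(lab) arm_parameters(
    arm_label = lab,
    p_local_recurrence = stats::runif(H, 0, cap),
    p_bc_death = stats::runif(H, 0, cap / 2),
    p_metastasis_from_disease_free = stats::runif(1, 0, cap),
    p_metastasis_from_local_recurrence = stats::runif(1, 0, cap),
    cost_treatment = stats::runif(1, 1, 5000),
    cost_other_direct = stats::runif(1, 1, 1000),
    cost_annual_maintenance = stats::runif(1, 0, 60000),
    horizon = H)
  arms <- list(A = rand_arm("A"), B = rand_arm("B"))
  ages <- seq(50, 65, by = 5)
  mortality <- mortality_table(ages, ages + 4,
                               stats::runif(length(ages), 0, cap / 2))
  u <- sort(stats::runif(3))
  utilities <- utility_set(u_disease_free = u[3], u_local_recurrence = u[2],
                           u_metastasis = u[1])
  structure(list(arms = arms, mortality = mortality, utilities = utilities,
                 config = config),
            class = "apbi_parameters")
}
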
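# Four-state Markov engine.  State order is fixed for matrix indexing:
# disease_free, local_recurrence, metastasis, death (absorbing).

#' Health states of the cohort model
#'
#' @return Character vector of the four states in fixed matrix order;
#'   death is absorbing.
#' @export
health_states <- function() STATES

compose_death <- function(p_allcause, p_bc, combination) {
  if (combination == "additive") p_allcause + p_bc
  else 1 - (1 - p_allcause) * (1 - p_bc)
}

#' Per-cycle transition matrix
#'
#' Builds the 4x4 row-stochastic matrix for one annual cycle.  Disease
#' progression is one-way: disease-free can move to local recurrence,
#' metastasis or death; local recurrence to metastasis or death;
#' metastasis only to death.  The time-dependent recurrence and
#' breast-cancer death probabilities are indexed by years since surgery
#' (the model cycle), the all-cause mortality by attained age
#' `start_age + cycle - 1`.  Breast-cancer death applies only from the
#' states named in the configured conventions; all-cause mortality from
#' every alive state.  Competing transitions combine additively within a
#' row, with the stay probability as remainder.
#'
#' @param arm An [arm_parameters()] object.
#' @param mortality A [mortality_table()].
#' @param config A [model_config()].
#' @param cycle 1-based year index, `1 <= cycle <= horizon`.
#' @return A 4x4 matrix with `health_states()` dimnames; rows sum to 1.
#' @export
build_transition_matrix <- function(arm, mortality, config, cycle) {
  stopifnot(inherits(arm, "arm_parameters"), inherits(config, "model_config"))
  if (cycle < 1 || cycle > config$horizon)
    stopf("cycle %s outside 1..%d", cycle, config$horizon)
  conv <- config$conventions
  age <- config$start_age + cycle - 1
  p_ac <- mortality_prob(mortality, age)
  p_bc <- arm$p_bc_death[cycle]

  death_from <- function(state) compose_death(
    p_ac, if (state %in% conv$bc_death_sources) p_bc else 0,
    conv$death_combination)

  m <- matrix(0, 4, 4, dimnames = list(STATES, STATES))
  d_df <- death_from("disease_free")
  m["disease_free", "local_recurrence"] <- arm$p_local_recurrence[cycle]
  m["disease_free", "metastasis"] <- arm$p_metastasis_from_disease_free
  m["disease_free", "death"] <- d_df
  m["local_recurrence", "metastasis"] <- arm$p_metastasis_from_local_recurrence
  m["local_recurrence", "death"] <- death_from("local_recurrence")
  m["metastasis", "death"] <- death_from("metastasis")
  m["death", "death"] <- 1
  for (s in ALIVE_STATES) {
    stay <- 1 - sum(m[s, ])
    if (stay < -1e-12)
      stopf("infeasible probabilities: outgoing sum from state '%s' exceeds 1 by %.2e in cycle %d (arm %s)",
            s, -stay, cycle, arm$arm_label)
    m[s, s] <- max(stay, 0)
  }
  m
}

#' Run the deterministic cohort trace for one arm
#'
#' Starts the whole cohort in the disease-free state and propagates it
#' through `horizon` annual cycles: `occupancy[t] = occupancy[t-1] %*%
#' M(t)`.  The per-entry products are retained as transition flows so
#' that incidence-type quantities (e.g. the cumulative probability of
#' ever entering local recurrence) can be read off directly.
#'
#' @inheritParams build_transition_matrix
#' @return An object of class `cohort_trace` with elements
#'   \describe{
#'     \item{occupancy}{`(horizon + 1) x 4` matrix of person-counts at
#'       each cycle boundary; row `"0"` is the initial cohort.}
#'     \item{flows}{`horizon x 4 x 4` array; `flows[t, i, j]` is the
#'       count moving from state i to state j during cycle t (diagonal =
#'       stays).}
#'     \item{arm, mortality, config}{the inputs, retained for methods.}
#'   }
#' @examples
#' p <- apbi_parameters()
#' tr <- markov_cohort(p$arms$IORT, p$mortality, p$config)
#' summary(tr)
#' @export
markov_cohort <- function(arm, mortality, config = model_config()) {
  H <- config$horizon
  occ <- matrix(0, H + 1, 4, dimnames = list(0:H, STATES))
  occ[1, "disease_free"] <- config$cohort_size
  flows <- array(0, c(H, 4, 4), dimnames = list(1:H, STATES, STATES))
  for (t in seq_len(H)) {
    m <- build_transition_matrix(arm, mortality, config, t)
    flows[t, , ] <- occ[t, ] * m
    occ[t + 1, ] <- occ[t, ] %*% m
  }
  structure(list(occupancy = occ, flows = flows, arm = arm,
                 mortality = mortality, config = config,
                 arm_label = arm$arm_label),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, digits = 3, ...) {
  cat(sprintf("Markov cohort trace: arm %s, %g patients, %d annual cycles\n",
              x$arm_label, x$config$cohort_size, x$config$horizon))
  print(round(x$occupancy, digits))
  invisible(x)
}

#' @export
summary.cohort_trace <- function(object, ...) {
  H <- object$config$horizon
  n <- object$config$cohort_size
  v <- validation_metrics(object)
  cat(sprintf("Arm %s after %d years (cohort of %g):\n",
              object$arm_label, H, n))
  cat(sprintf("  alive: %.2f%%  (disease-free %.2f%%, local recurrence %.2f%%, metastasis %.2f%%)\n",
              100 * v$overall_survival_10y,
              100 * object$occupancy[H + 1, "disease_free"] / n,
              100 * object$occupancy[H + 1, "local_recurrence"] / n,
              100 * object$occupancy[H + 1, "metastasis"] / n))
  cat(sprintf("  cumulative local recurrence: %.2f%%\n",
              100 * v$cumulative_lr_10y))
  invisible(v)
}

#' @export
as.data.frame.cohort_trace <- function(x, ...) {
  H <- x$config$horizon
  data.frame(cycle = rep(0:H, times = 4),
             state = rep(STATES, each = H + 1),
             count = as.vector(x$occupancy))
}

#' @export
plot.cohort_trace <- function(x, ...) {
  H <- x$config$horizon
  graphics::matplot(0:H, x$occupancy, type = "l", lty = 1, lwd = 2,
                    col = c("forestgreen", "orange", "firebrick", "grey30"),
                    xlab = "cycle (years since surgery)",
                    ylab = "patients in state",
                    main = paste("Cohort trace:", x$arm_label), ...)
  graphics::legend("left", legend = STATES, lty = 1, lwd = 2,
                   col = c("forestgreen", "orange", "firebrick", "grey30"),
                   bty = "n")
  invisible(x)
}

#' Write a cohort trace to CSV (long format) or JSON
#'
#' @param trace A `cohort_trace`.
#' @param path Output path; `.json` gets the full occupancy-plus-flows
#'   object, anything else a long CSV of `cycle, state, count`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "cohort_trace"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(list(arm = trace$arm_label,
                              occupancy = trace$occupancy,
                              flows = trace$flows),
                         path, digits = NA, matrix = "rowmajor")
  } else {
    utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  }
  invisible(path)
}
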
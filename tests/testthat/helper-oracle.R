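# Independent Monte-Carlo microsimulation oracle.  Deliberately does not
# call the package's transition-matrix builder: transition probabilities
# are composed here from first principles so the deterministic trace and
# the oracle share only the model definition, not code.

oracle_microsim <- function(arm, mortality, config, n_patients, seed) {
  set.seed(seed)
  conv <- config$conventions
  H <- config$horizon
  counts <- c(n_patients, 0, 0, 0)
  occ <- matrix(0, H + 1, 4)
  occ[1, ] <- counts
  bands <- mortality$bands
  for (t in seq_len(H)) {
    age <- config$start_age + t - 1
    pa <- bands$p_death[age >= bands$age_low & age <= bands$age_high]
    bc <- arm$p_bc_death[t]
    death_p <- function(state) {
      pb <- if (state %in% conv$bc_death_sources) bc else 0
      if (conv$death_combination == "additive") pa + pb
      else 1 - (1 - pa) * (1 - pb)
    }
    move <- list(
      c(NA, arm$p_local_recurrence[t], arm$p_metastasis_from_disease_free,
        death_p("disease_free")),
      c(0, NA, arm$p_metastasis_from_local_recurrence,
        death_p("local_recurrence")),
      c(0, 0, NA, death_p("metastasis")),
      c(0, 0, 0, 1))
    nxt <- numeric(4)
    for (s in 1:4) {
      p <- move[[s]]
      if (anyNA(p)) p[is.na(p)] <- 1 - sum(p, na.rm = TRUE)
      if (counts[s] > 0)
        nxt <- nxt + stats::rmultinom(1, counts[s], p)[, 1]
    }
    counts <- nxt
    occ[t + 1, ] <- counts
  }
  occ
}

# Deterministic-vs-microsimulation agreement within k binomial standard
# errors on every state/cycle occupancy proportion.
expect_microsim_agreement <- function(params, arm_name, n_patients = 1e5,
                                      seed = 1, k = 3) {
  arm <- params$arms[[arm_name]]
  trace <- markov_cohort(arm, params$mortality, params$config)
  p_det <- trace$occupancy / params$config$cohort_size
  occ <- oracle_microsim(arm, params$mortality, params$config, n_patients, seed)
  p_sim <- occ / n_patients
  se <- sqrt(p_det * (1 - p_det) / n_patients)
  expect_true(all(abs(p_sim - p_det) <= k * se + 1e-12),
              label = sprintf("microsimulation within %d SE (arm %s)", k, arm_name))
}
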
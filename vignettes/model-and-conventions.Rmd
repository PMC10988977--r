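---
title: "A Markov cohort model for IORT-versus-IMRT disinvestment: structure, conventions, calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Markov cohort model for IORT-versus-IMRT disinvestment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apbicea)
```

## The decision problem and the model

A provider that owns both a dedicated electron-IORT unit and an IMRT
platform faces a disinvestment question: the IORT machine treats a
handful of early-breast-cancer patients per year but costs tens of
thousands of dollars annually to maintain, while the IMRT platform is
shared across indications and has spare capacity. The package answers
it with the standard instrument for this kind of question: a
deterministic Markov cohort model.

Four mutually exclusive health states — disease-free, local
recurrence, metastasis, death — with strictly one-way progression.
There is no salvage-to-remission transition: once a woman has had a
local recurrence she never returns to the disease-free state, and
metastasis only progresses to death. That is a simplification (salvage
mastectomy does return many patients to no-evidence-of-disease), but
no remission state is parameterised by the source trials, and for a
10-year horizon the induced error is second-order relative to the
utility difference between the states.

A cohort (default 100 women aged 60) starts disease-free and is pushed
through annual cycles, `occupancy[t] = occupancy[t-1] %*% P[t]`.
The cycle-dependent matrix `P[t]` mixes three kinds of inputs:

* **time-dependent** annual probabilities of local recurrence and of
  breast-cancer death, indexed by years since surgery (cycle index,
  not time-in-state — they were derived from trial-level curves
  clocked from randomisation);
* **fixed** annual metastasis probabilities: from the disease-free
  state (0.006 IORT / 0.0029 IMRT, the 10-year trial rates converted
  to constant annual probabilities, because no metastasis curve was
  published) and from local recurrence (0.03/yr, memoryless);
* **age-banded** all-cause mortality, looked up at attained age
  `start_age + cycle − 1`; the band switch from 0.006 to 0.009
  happens at cycle 6, when the cohort turns 65. Bands for ages 50–59
  are retained for generality although a 60-year-old cohort never
  consults them.

Competing transitions within a row combine additively and the stay
probability is the remainder; with row sums of at most ≈ 0.06 at the
bundled values, hazard-based rescaling would change nothing material,
and the builder fails loudly (naming state and cycle) if a remainder
ever goes negative.

## Derivation of annual probabilities from curves

Published trials report cumulative curves, not annual probabilities.
The conversion conditions on the at-risk set: for cumulative incidence
`p[t] = (C[t] − C[t−1]) / (1 − C[t−1])`, for overall survival
`p[t] = 1 − S[t]/S[t−1]`. This is the cause-specific, no
competing-risk reading of a published Kaplan–Meier or
cumulative-incidence curve; nothing in the sources supports a
competing-risk correction, so none is applied. `cumulative_from_annual()`
is the exact algebraic inverse, and the round trip is tested to 1e−12.
The bundled parameter set already contains derived annual
probabilities, so in the shipped analyses this module is exercised
through the synthetic-data generator rather than on raw curves.

## What the tables leave open: conventions and calibration

Annual probability tables underdetermine a cohort model. Four choices
matter here and are made explicit in `model_conventions()`:

* **bc_death_sources** — from which alive states the time-dependent
  breast-cancer death probability applies (all-cause mortality always
  applies everywhere). Candidates: {LR, M}, all alive states, {M}.
* **death_combination** — additive `p_ac + p_bc` versus independent
  `1 − (1−p_ac)(1−p_bc)`; at these magnitudes they differ by < 1e−4.
* **discount_timing** — cycle t weighted by `(1+r)^−(t−1)`
  (first cycle undiscounted) or `(1+r)^−t`.
* **half_cycle_correction** — accrue end-of-cycle occupancy, or the
  average of the two cycle boundaries.

Rather than hard-coding a guess, `calibrate_conventions()` enumerates
the full 3 × 2 × 2 × 2 = 24 space, runs both arms under each
configuration, and scores each by the summed relative error against
the published per-arm expected benefits, costs and validation metrics
(`benchmark_results()`). The search is deterministic and the score
table is part of the returned object (`write_calibration()` archives
it). The winner — breast-cancer death applied from the metastasis
state only, independent combination, first cycle undiscounted, no
half-cycle correction — is wired in as the package default. Two
observations make this winner interpretable rather than a black-box
fit: applying breast-cancer death from the disease-free state would
drive 10-year survival to ≈ 90.8%, well below the published ≈ 92.6%,
so the published model cannot have done that; and confining it to the
metastasis state reads naturally as "breast-cancer deaths occur in
women whose disease has disseminated", avoiding double-counting
cause-specific mortality in states that already feed the metastasis
state. The {LR, M} variant is a close runner-up and remains available.

Discounting uses 3%/yr for both benefits and costs. All costs are
incurred once at model entry (follow-up and complication costs are
excluded as equal between arms), so the cost discount rate, while
implemented, has no effect on the bundled runs. The first-cycle-
undiscounted timing means a frozen cohort accrues
`Σ_{k=0..9} 1.03^−k ≈ 8.786` discounted years over the horizon; the
end-of-cycle alternative gives ≈ 8.530. Both closed forms are pinned
in the tests.

## Costs

Per patient: one-time treatment cost plus one-time other direct costs,
plus — for IORT only — the annual equipment maintenance divided by a
divisor that defaults to the cohort size (100), giving
55,344/100 ≈ 553 USD/patient. The published per-patient cost of
$1,330 = 418 + 359 + 553 reconciles exactly with that allocation, even
though the narrative mentions 10–12 IORT patients treated per year;
`maintenance_divisor` exposes the per-actual-throughput alternative
(55,344/12 ≈ 4,612/patient), under which the disinvestment conclusion
only strengthens. IMRT maintenance is zero by assumption: the platform
is shared with other indications and absorbing the IORT patients does
not increase its upkeep. The no-maintenance scenario
(`run_scenario_no_maintenance()`) removes the allocation entirely and
leaves benefits untouched.

## Validation metrics and the reporting surface

`validation_metrics()` reports the 10-year cumulative local-recurrence
rate as the *incidence of ever entering* the LR state — summed
DF → LR transition flows per patient — rather than terminal state
occupancy, because the published comparators are trial IBTR rates,
which are incidence quantities. Overall survival is the alive fraction
at the end of cycle 10. Both are computed for the IORT arm by default
(its published comparators are IORT-based studies) and for both arms in
the suite object. ICERs are always computed from unrounded
incrementals; the LY-denominated ICER divides by a ΔLY of order 0.002
and is therefore numerically fragile — the package reports it but the
tests treat it as a sign-and-magnitude check only.

## The synthetic-data generator

`generate_trial_curves()` emulates what a trial publication actually
provides: a cumulative IBTR incidence curve and an overall survival
curve generated from known annual hazards, optionally with per-year
binomial events on the shrinking at-risk set (n subjects, fixed seed)
and rounding to published-figure precision (2–3 decimals). That makes
the curve → annual-probability stage testable by round trip: exact
recovery in noiseless mode, recovery within three binomial standard
errors in noisy mode. `generate_random_model_spec()` draws full
two-arm parameter bundles with each transition component capped (0.3
by default, each death component at half the cap) so every per-state
outgoing sum stays at or below 0.9; these drive the engine property
tests (row-stochasticity, conservation, flow reconciliation,
monotonicity, microsimulation agreement). What the generator does *not*
emulate: censoring, competing risks within one curve, correlation
between the recurrence and survival curves of one trial, or
interval-censored event times. Passing tests therefore certify the
arithmetic pipeline, not the epidemiological fidelity of any
particular published curve.

The deterministic trace is cross-checked against an independent
Monte-Carlo microsimulation oracle (10^5 patients, multinomial draws
per state and cycle, agreement within 3 standard errors on every
state/cycle occupancy) that composes its transition probabilities from
first principles in the test helpers, sharing no code with the engine.

## Numerical choices and test problem sizes

All arithmetic is double-precision dense 4 × 4 linear algebra; no
tolerance tuning is needed beyond 1e−12 for algebraic identities and
1e−9 for cohort conservation. Degenerate inputs are handled
explicitly: zero probabilities give the identity matrix and a frozen
cohort; a cumulative curve touching 1 (incidence) or 0 (survival) is
only an error if it subsequently moves; a zero benefit difference
yields an undefined ICER (`NA`) with dominance judged on cost alone.
The property suites run 100 random bundles for the structural
invariants and 10 bundles for the microsimulation cross-check —
sizes chosen to exercise the parameter space densely while keeping the
whole suite in the tens-of-seconds range on a single core, which is
ample for a model whose production run is a 10-step 4-state recursion.

## Known limitations

* No probabilistic sensitivity analysis, willingness-to-pay decision
  rules, net monetary benefit or EVPI: the reporting surface is
  expected values, ICERs and dominance.
* No tunnel states or time-in-state dependence; recurrence and
  breast-cancer death clocks both run from surgery.
* Utilities come from a patient-preference study in a different
  jurisdiction; only the quality-adjusted outcomes inherit that
  uncertainty.
* The horizon is 10 years with no extrapolation; the model says
  nothing beyond it.
* The lower-bound sensitivity variants replace the IORT parameter
  block with the published lower-confidence-limit values as printed
  (3-decimal annual probabilities); conclusions (dominance) are robust
  to that precision, but ICER magnitudes in the lower-metastasis
  variant are sensitive to the third decimal of the annual metastasis
  probability.
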
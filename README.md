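# apbicea

Markov cohort cost-effectiveness analysis of two accelerated partial
breast irradiation (APBI) strategies after breast-conserving surgery in
early breast cancer: electron-based intraoperative radiotherapy (IORT,
a single dose delivered to the tumour bed during surgery) versus
intensity-modulated radiotherapy (IMRT, conformal external-beam
radiotherapy delivered over a few fractions). The comparison is framed
as a **disinvestment** question for a provider that already owns both
machines: is it worth paying the annual maintenance of the dedicated
IORT unit, or should those patients be moved onto the IMRT platform?
The package is aimed at health-economics and HTA analysts who want the
whole pipeline — parameters, cohort engine, outcome accounting,
sensitivity analyses, validation — as tested, configurable code rather
than a spreadsheet.

## The model

A deterministic four-state Markov cohort model with annual cycles:

* states *disease-free* (DF), *local recurrence* (LR), *metastasis*
  (M), *death* (D, absorbing), with one-way progression
  DF → {LR, M, D}, LR → {M, D}, M → D;
* a cohort of 100 women aged 60 enters in DF and is propagated for a
  10-year horizon by `x_t = x_{t-1} P_t`, where the cycle-dependent
  transition matrix `P_t` is assembled from annual probabilities:
  time-dependent P(LR) and P(breast-cancer death) indexed by years
  since surgery (derived from trial cumulative-incidence and overall
  survival curves via `p_t = (C_t − C_{t−1})/(1 − C_{t−1})` and
  `p_t = 1 − S_t/S_{t−1}`), fixed annual metastasis probabilities, and
  age-banded all-cause mortality;
* discounted benefits per patient at rate r = 3%:
  LY (time alive), RFLY (time in DF), and their quality-adjusted
  versions QALY and QARFLY using health-state utilities
  u(DF) = 0.920, u(LR) = 0.779, u(M) = 0.685;
* per-patient costs (2021 USD): one-time treatment and other direct
  costs, plus the annual IORT equipment maintenance allocated over the
  cohort;
* results as incremental cost-effectiveness ratios
  `ICER = ΔC / ΔE` (IORT − IMRT, unrounded incrementals) with
  dominance classification on the cost-effectiveness plane.

Conventions that published probability tables leave open — from which
alive states the breast-cancer death probabilities apply, how they
combine with all-cause mortality, discount timing, half-cycle
correction — are first-class (`model_conventions()`) and are pinned
down by an exhaustive 24-configuration calibration
(`calibrate_conventions()`) against the published per-arm expected
values; the calibrated winners are the package defaults.

## Worked example

```r
library(apbicea)
suite <- apbi_cea()        # bundled parameters, calibrated conventions
suite$base_case
#> Cost-effectiveness: IORT vs IMRT
#>  measure IORT IMRT incremental    ICER dominance
#>       LY 8.47 8.48      -0.005 -187207 dominated
#>     RFLY 7.92 8.19      -0.266   -3788 dominated
#>     QALY 7.69 7.75      -0.054  -18572 dominated
#>   QARFLY 7.29 7.54      -0.245   -4117 dominated
#> Costs: IORT $1330, IMRT $323, incremental $1007
```

Read: per patient, IORT buys no additional benefit on any measure (for
example 7.92 vs 8.19 discounted recurrence-free life-years) while
costing $1,007 more, mostly the maintenance allocation
($55,344 / 100 patients); every ICER is negative with positive
incremental cost, i.e. IORT is *dominated*. `print(suite)` adds the two
one-way sensitivity analyses (IORT recurrence and metastasis
probabilities at their lower confidence bounds) and the scenario
without maintenance costs — IORT remains dominated throughout — plus
the validation metrics (10-year cumulative local recurrence and
overall survival). `plot(suite)` draws the cost-effectiveness plane,
`write_suite(suite, "out/")` the CSV/JSON artifacts, and
`inst/cli/apbicea.R` wraps the same calls for the shell.

Custom parameter sets are YAML/JSON documents (see
`inst/extdata/params_base.yaml`) loaded with `load_parameters()`;
synthetic trial curves and random-but-valid parameter bundles for
testing come from `generate_trial_curves()` and
`generate_random_model_spec()`.

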
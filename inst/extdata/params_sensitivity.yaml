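# One-way sensitivity variants for the IORT arm: annual local-recurrence
# probabilities re-derived from the lower confidence bound of the trial
# recurrence curve, and the metastasis probability from the lower bound of
# the 10-year distant-metastasis rate.  Costs and all other fields equal
# the base-case IORT arm.
arms:
  IORT_lower_recurrence:
    p_local_recurrence: [0.000, 0.000, 0.010, 0.008, 0.006, 0.011, 0.002, 0.010, 0.008, 0.005]
    p_bc_death:         [0.003, 0.002, 0.006, 0.008, 0.017, 0.018, 0.006, 0.011, 0.008, 0.018]
    p_metastasis_from_disease_free: 0.006
    p_metastasis_from_local_recurrence: 0.03
    cost_treatment: 418
    cost_other_direct: 359
    cost_annual_maintenance: 55344
  IORT_lower_metastasis:
    p_local_recurrence: [0.000, 0.001, 0.018, 0.009, 0.005, 0.016, 0.001, 0.012, 0.010, 0.006]
    p_bc_death:         [0.003, 0.002, 0.006, 0.008, 0.017, 0.018, 0.006, 0.011, 0.008, 0.018]
    p_metastasis_from_disease_free: 0.004
    p_metastasis_from_local_recurrence: 0.03
    cost_treatment: 418
    cost_other_direct: 359
    cost_annual_maintenance: 55344
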
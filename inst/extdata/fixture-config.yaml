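# Surrogate calibration for the three-arm first-line advanced RCC
# cost-utility model. Curve evidence: reference (sunitinib) PFS Weibull
# calibrated to its published 9.2-month median (shape 1.2), reference OS
# exponential anchored to 2.83 discounted life-years over the 5-year
# horizon; comparator curves are proportional-hazards shifts by the
# published hazard ratios. Costs/utilities/proportions follow the published
# input table; grade >= 3 adverse-event incidences are NOT published in
# that table and the values below are synthetic placeholders of plausible
# magnitude (they contribute only a one-off entry cost/disutility).
model:
  cycle_length_days: 21
  horizon_years: 5
  discount_rate: 0.05
  gdp_per_capita: 217341
  ae_duration_weeks: 4

reference: sunitinib

curves:
  sunitinib:
    pfs: {source: weibull_median, median_months: 9.2, shape: 1.2}
    os: {source: exponential_ly_anchor, discounted_ly: 2.83}
  lenv_ever:
    pfs: {source: hazard_ratio, reference: sunitinib, hr: 0.65}
    os: {source: hazard_ratio, reference: sunitinib, hr: 1.15}
  lenv_pemb:
    pfs: {source: hazard_ratio, reference: sunitinib, hr: 0.39}
    os: {source: hazard_ratio, reference: sunitinib, hr: 0.66}

strategies:
  sunitinib:
    label: Sunitinib
    # 50 mg once daily, 4 weeks on / 2 weeks off -> dosed-day fraction 28/42;
    # units chosen so the dosed-day acquisition cost is 392 RMB/day
    oral:
      - {price_param: price_sunitinib, units_per_day: 4}
    dosed_day_fraction: 0.6666667
    subsequent_cost_param: subs_cost_sunitinib
    subsequent_prop_param: subs_prop_sunitinib
    u_pfs_param: u_pfs_sunitinib
    discontinuation_param: disc_ae_sunitinib
    ae_incidence: # synthetic placeholders, grade >= 3
      diarrhea: 0.05
      hypertension: 0.19
      decreased_appetite: 0.01
      nausea: 0.02
      vomiting: 0.02
      proteinuria: 0.03
      palmar_plantar: 0.04
      rash: 0.02
  lenv_ever:
    label: Lenvatinib + Everolimus
    # lenvatinib 18 mg (486 RMB/day) + everolimus 5 mg (130 RMB/day)
    oral:
      - {price_param: price_lenvatinib, units_per_day: 4.5}
      - {price_param: price_everolimus, units_per_day: 1}
    subsequent_cost_param: subs_cost_lenv_ever
    subsequent_prop_param: subs_prop_lenv_ever
    u_pfs_param: u_pfs
    discontinuation_param: disc_ae_lenv_ever
    ae_incidence: # synthetic placeholders, grade >= 3
      diarrhea: 0.12
      hypertension: 0.22
      decreased_appetite: 0.06
      nausea: 0.05
      vomiting: 0.03
      proteinuria: 0.08
      palmar_plantar: 0.02
      rash: 0.02
  lenv_pemb:
    label: Lenvatinib + Pembrolizumab
    # lenvatinib 20 mg (540 RMB/day); pembrolizumab 200 mg per 21-day
    # administration (the trial regimen; see the methods vignette on why
    # the acquisition dose is 200 mg)
    oral:
      - {price_param: price_lenvatinib, units_per_day: 5}
    infusion: {price_param: price_pembrolizumab, mg_per_administration: 200}
    subsequent_cost_param: subs_cost_lenv_pemb
    subsequent_prop_param: subs_prop_lenv_pemb
    u_pfs_param: u_pfs
    discontinuation_param: disc_ae_lenv_pemb
    ae_incidence: # synthetic placeholders, grade >= 3
      diarrhea: 0.10
      hypertension: 0.28
      decreased_appetite: 0.04
      nausea: 0.03
      vomiting: 0.03
      proteinuria: 0.08
      palmar_plantar: 0.04
      rash: 0.04

followup_params: [fu_blood_count, fu_ct, fu_biochemistry, fu_urine, fu_consultation]
management_params: [mgmt_bed, mgmt_care, mgmt_hosp_exam, mgmt_transport, mgmt_preparation]
ae_cost_params:
  diarrhea: ae_cost_diarrhea
  hypertension: ae_cost_hypertension
  decreased_appetite: ae_cost_decreased_appetite
  nausea: ae_cost_nausea
  vomiting: ae_cost_vomiting
  proteinuria: ae_cost_proteinuria
  palmar_plantar: ae_cost_palmar_plantar
  rash: ae_cost_rash

parameters:
  # drug acquisition prices (RMB per unit)
  - {name: price_pembrolizumab, base: 179.18, low: 143.34, high: 215.02, dist: gamma}
  - {name: price_lenvatinib, base: 108, low: 86.4, high: 129.6, dist: gamma}
  - {name: price_everolimus, base: 130, low: 104, high: 156, dist: gamma}
  - {name: price_sunitinib, base: 98, low: 78.4, high: 117.6, dist: gamma}
  # subsequent treatment cost per cycle (RMB)
  - {name: subs_cost_lenv_pemb, base: 6416, low: 5132, high: 7699, dist: gamma}
  - {name: subs_cost_lenv_ever, base: 16301, low: 13040, high: 19561, dist: gamma}
  - {name: subs_cost_sunitinib, base: 17461, low: 13969, high: 20953, dist: gamma}
  # subsequent treatment proportions
  - {name: subs_prop_lenv_pemb, base: 0.549, low: 0.44, high: 0.66, dist: beta}
  - {name: subs_prop_lenv_ever, base: 0.682, low: 0.55, high: 0.82, dist: beta}
  - {name: subs_prop_sunitinib, base: 0.71, low: 0.57, high: 0.85, dist: beta}
  # probability of treatment discontinuation due to AEs (carried, not
  # applied in the base case)
  - {name: disc_ae_lenv_pemb, base: 0.372, low: 0.298, high: 0.446, dist: beta}
  - {name: disc_ae_lenv_ever, base: 0.27, low: 0.216, high: 0.324, dist: beta}
  - {name: disc_ae_sunitinib, base: 0.144, low: 0.115, high: 0.173, dist: beta}
  # follow-up cost per cycle (RMB)
  - {name: fu_blood_count, base: 18, low: 14, high: 21, dist: gamma}
  - {name: fu_ct, base: 220, low: 176, high: 264, dist: gamma}
  - {name: fu_biochemistry, base: 214, low: 171, high: 257, dist: gamma}
  - {name: fu_urine, base: 10, low: 8, high: 12, dist: gamma}
  - {name: fu_consultation, base: 12, low: 9.6, high: 14.4, dist: gamma}
  # hospital management cost per cycle (RMB)
  - {name: mgmt_bed, base: 50, low: 40, high: 60, dist: gamma}
  - {name: mgmt_care, base: 27, low: 21.6, high: 32.4, dist: gamma}
  - {name: mgmt_hosp_exam, base: 15, low: 12, high: 18, dist: gamma}
  - {name: mgmt_transport, base: 10, low: 8, high: 12, dist: gamma}
  - {name: mgmt_preparation, base: 40, low: 32, high: 48, dist: gamma}
  # supportive / end-of-life care (terminal range set to +/-20% of base)
  - {name: bsc_cost, base: 353, low: 282, high: 423, dist: gamma}
  - {name: terminal_care_cost, base: 12721, low: 10176.8, high: 15265.2, dist: gamma}
  # grade >= 3 adverse-event management cost per episode (RMB)
  - {name: ae_cost_diarrhea, base: 276, low: 220, high: 331, dist: gamma}
  - {name: ae_cost_hypertension, base: 80.4, low: 64, high: 96, dist: gamma}
  - {name: ae_cost_decreased_appetite, base: 705.4, low: 564, high: 846, dist: gamma}
  - {name: ae_cost_nausea, base: 298, low: 238, high: 357, dist: gamma}
  - {name: ae_cost_vomiting, base: 298, low: 238, high: 357, dist: gamma}
  - {name: ae_cost_proteinuria, base: 775, low: 620, high: 930, dist: gamma}
  - {name: ae_cost_palmar_plantar, base: 102, low: 82, high: 122, dist: gamma}
  - {name: ae_cost_rash, base: 294, low: 235, high: 352, dist: gamma}
  # utilities
  - {name: u_pfs, base: 0.82, low: 0.656, high: 0.984, dist: beta}
  - {name: u_pfs_sunitinib, base: 0.73, low: 0.584, high: 0.876, dist: beta}
  - {name: u_pd, base: 0.66, low: 0.528, high: 0.792, dist: beta}
  - {name: ae_disutility, base: 0.157, low: 0.126, high: 0.188, dist: beta}
  # discount rate: varied one-way, fixed in PSA
  - {name: discount_rate, base: 0.05, low: 0, high: 0.08, dist: fixed}

psa:
  n_iterations: 10000
  wtp_max: 1000000
  wtp_step: 10000

scenarios:
  horizons: [5, 10, 20]
  pembrolizumab_price_scales: [1, 0.75, 0.5, 0.25, 0]

# Demonstration subgroups: subgroup-specific trial hazard ratios are not
# published in the source input table, so these are synthetic examples.
subgroups:
  - {label: synthetic_favourable, hr_pfs: 0.45, hr_os: 0.75}
  - {label: synthetic_poor_risk, hr_pfs: 0.30, hr_os: 0.50}

simulation:
  enabled: false
  n_per_arm: 355
  accrual_months: 12
  max_followup_months: 36
  risk_grid_step_months: 3
  pfs_shape: 1.2
  criterion: aic
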
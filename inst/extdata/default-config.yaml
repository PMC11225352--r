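# Default structural constants and study-design settings.
# All values are configuration, not hard-coded: silk_config() reads this file
# and user overrides merge over it.

model:
  f_ab40: 0.1          # stoichiometric fraction of APP processed to Abeta40
  tau_delay: 3.0       # labeling/processing delay, h
  phi_CR: 0.75         # fraction of CSF absorbed via the cranial SAS
  k_t: 15.0            # ISF -> ventricular transport, equivalent flow mL/h
  V_ISF: 250.0         # interstitial fluid volume, mL
  n_leu: 1             # leucine residues counted in the labeled fraction
  mw_ab40_ng_per_nmol: 4329.9   # Abeta40 molar mass (ng per nmol)
  # CSF compartment volumes (mL) as a + b * age, scaled by f_VCSF; the
  # coefficients give V_V + V_CIS + V_CR = 150 mL at age 70.
  csf_volume_coefficients:
    ventricular: {a: 9.0,  b: 0.30}
    cisternal:   {a: 13.0, b: 0.10}
    cranial:     {a: 44.0, b: 0.80}

nominal:                # reference adjustable-parameter values (fit starts)
  k_BPD40: 0.125        # 1/h, midpoint of the lower regime
  Q_CSF: 20.0           # mL/h
  Q_osc: 30.0           # mL/h
  SF_40: 1.0
  R_APP: 0.75           # nmol/h

infusion:
  bolus_mg_per_kg: 3.0
  rate_mg_per_kg_h: 2.0
  duration_h: 9.0
  e_ss: 0.12            # plateau plasma leucine enrichment
  k_rise: 2.0           # 1/h (primed -> fast approach to plateau)
  k_decay: 0.7          # 1/h post-infusion washout

schedule:
  times_start: 0.0
  times_end: 36.0
  times_step: 2.0
  draw_volume_ml: 6.0

grid:
  f_VCSF_values: [0.5, 0.75, 1.0, 1.25]
  V_SP_values: [40.0, 60.0, 80.0, 100.0]
  Q_leak_values: [0.0, 5.0, 10.0, 15.0]
  k_BPD40_ranges: [[0.05, 0.2], [0.2, 0.35]]
  penalty_ratio_cap: 10.0
  penalty_weight_factor: 1000.0
  acceptance_band: 0.20
  conc_fit_window: [0.0, 15.0]
  clock_filter_min: 660        # 11:00 local, minutes since midnight
  max_iter: 2000
  rel_tol: 1.0e-8

grid_test:               # reduced preset for fast runs
  f_VCSF_values: [0.75, 1.0]
  V_SP_values: [60.0, 80.0]
  Q_leak_values: [0.0, 5.0]
  k_BPD40_ranges: [[0.05, 0.2]]

cohort:
  n_per_cohort: 8            # one dose cohort = one permuted block
  allocation_active: 5
  allocation_placebo: 3
  block_size: 8
  sites: [site01, site02]
  arms: [QD60, BID120, TID180]   # sequential active-dose cohorts
  dose_effect:                   # fractional reduction of R_APP per arm
    placebo: 0.0
    QD60: 0.10
    BID120: 0.20
    TID180: 0.30
  r_app_median: 0.75        # nmol/h, between-subject lognormal median
  r_app_cv: 0.25            # between-subject CV (prior-study FSR CV ~26%)
  true_V_SP: 60.0
  true_Q_leak: 0.0
  true_f_VCSF: 1.0
  silk_noise_cv: 0.075
  conc_noise_cv: 0.075
  missingness: 0.1825       # 1 - observed CSF sample completeness (81.75%)
  eligibility_ratio: 0.131  # CSF Abeta42/40 amyloid-positivity cutoff
  ab42_40_mean: 0.105
  ab42_40_sd: 0.02
  start_clock_min: [540, 660]   # confinement starts between 09:00 and 11:00
  biomarker_noise_cv: 0.10
  screening_noise_cv: 0.10

drug_pk:                 # one-compartment oral, steady state at confinement
  dose_mg: 60
  Posiphen: {ka: 1.5, ke: 0.198, cl_f: 283.0, csf_ratio: 0.064}
  N1:       {ka: 0.198, ke: 0.35, cl_f: 1200.0, csf_ratio: 0.11}
  N8:       {ka: 0.198, ke: 0.30, cl_f: 700.0, csf_ratio: 0.12}
  lloq_ng_ml: 0.05
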
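# Base-case assumptions for a repurposed rare-disease compound (U.S. market).
# Costs in $M, durations in years, price in $/patient/year.
schema: orphanval/scenario/v1
name: rett_base
plan:
  phases:
    - name: "Discovery, preclinical development, and phase 1"
      pos: 0.67
      cost: {min: 1, mode: 4, max: 7}
      duration: {min: 1, mode: 1, max: 1}
    - name: "Phase 2"
      pos: 0.53
      cost: {min: 9, mode: 14, max: 40}
      duration: {min: 1, mode: 2, max: 3}
    - name: "Phase 3"
      pos: 0.69
      cost: {min: 22, mode: 35, max: 99}
      duration: {min: 1, mode: 2, max: 3}
    - name: "FDA submission-to-launch"
      pos: 0.94
      cost: {min: 37, mode: 37, max: 37}
      duration: {min: 1, mode: 1, max: 1}
commercial:
  price: 40000
  price_ci: [30000, 50000]
  adoption:
    peak_rate: 0.50
    peak_rate_ci: [0.35, 0.65]
    ramp: [0.333333333333333, 0.666666666666667, 1.0]
    groups:
      - {label: "0 to 12 years",  population: 25770, prevalence: 0.125, multiplier: 1.0}
      - {label: "12 to 24 years", population: 25313, prevalence: 0.120, multiplier: 0.75}
      - {label: "24 to 48 years", population: 51749, prevalence: 0.115, multiplier: 0.50}
      - {label: "48 to 85 years", population: 64090, prevalence: 0.060, multiplier: 0.0}
  cogs_frac: 0.10
  sga_frac: 0.30
  rnd_frac: 0.05
  prerevenue_sga_of_rnd: 0.40
  tax_rate: 0.20
  exclusivity_years: 14.0
  patent_term_years: 20
  orphan_exclusivity_years: 7
  discount_rate: 0.13
  tax_credit_rate: 0.25
  prv_value: 100
  prv_year: 3
  pdufa_waiver: 2.9   # already netted from the FDA-phase cost above
correlations:
  phase23_time_cost_rho: 0.5
  cross_drug_rho: 0.2
flags:
  include_tax_credit: false
  include_prv: false
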
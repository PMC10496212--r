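---
title: "Valuing rare-disease drug compounds and portfolios with orphanval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing rare-disease drug compounds and portfolios with orphanval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orphanval)
```

## The valuation problem

Early-stage rare-disease compounds — particularly repurposed drugs filed
through abbreviated regulatory pathways — are hard to finance because a
single program is very likely to lose money even when its expected value
is positive. `orphanval` implements a three-layer valuation framework
for this setting:

1. a deterministic **risk-adjusted NPV (rNPV)** over a configurable
   phase plan and commercial model,
2. a **multi-stage Monte Carlo** simulation of a single compound, and
3. a **portfolio simulator** for several pairwise-correlated compounds.

The shipped fixtures (`scenario_fixture("rett_base")` and its bound and
follow-on variants) describe a repurposed compound for Rett syndrome, a
rare neurodevelopmental disorder affecting mostly girls, developed
through four consolidated phases: discovery-through-phase-1, phase 2,
phase 3, and regulatory submission-to-launch.

## The rNPV model

Each phase \(k\) carries a probability of success \(p_k\), a cost
\(C_k\) ($M) and a duration \(T_k\) (years), each given as a
(min, mode, max) triple. With arrival probabilities
\(a_k = \prod_{j<k} p_j\) and approval probability
\(a^* = \prod_k p_k\), the overall value at project start is

\[
\mathrm{rNPV} \;=\; -\sum_k a_k \, \mathrm{PV}\!\big[(1+s)\,C_k\big]
\;+\; a^* \, \mathrm{PV}\big[\text{revenue over exclusivity}\big],
\]

where \(s\) is the pre-revenue SG&A load (40% of each phase's
development cost, incurred contemporaneously — the commercial
assumptions give this as a ratio of R&D, not a schedule). Development
losses generate no tax shield; the optional 25% R&D credit (below) is
the only pre-revenue tax offset. Revenue in post-launch year \(y\) is
`patients × price × (1 − COGS − SG&A − R&D) × (1 − tax)`, with patients
built from an age-stratified population (population × prevalence per
stratum), stratum multipliers relative to the youngest group, and an
adoption ramp (1/3, 2/3, then 1 of peak from year 3 onward, held through
exclusivity). The exclusivity window is recomputed as
`patent term − launch time`, floored at the 7-year orphan exclusivity,
so slower sampled programs earn revenue for fewer years.

`value_after_phase[k]` is the value of the *remaining* project at the
end of phase \(k\), conditional on having just completed it: future
cash flows reweighted by \(a_j / a_{k+1}\) and re-discounted to that
time. These conditional values increase along the phase sequence — each
cleared hurdle removes risk and brings revenue closer.

## Discounting convention

The engine supports two conventions and defaults to **annual
end-of-period bucketing**: every cash flow accrues uniformly in
continuous time, is allocated to calendar-year buckets \((k-1, k]\),
and each bucket settles at its year end, discounted by \((1+r)^{-k}\).
Revenue year \(y\) settles at `launch + y` (a fractional final year
settles at its earned fraction). The alternative `"continuous"`
convention discounts every instant exactly via
\(\mathrm{PV} = A\,\frac{(1+r)^{-t_0} - (1+r)^{-t_1}}{(t_1-t_0)\ln(1+r)}\).

Both handle non-integer phase durations, which the simulator needs. The
annual convention is the default because the framework is calibrated
under it: on the base fixture at \(r = 13\%\) it yields an overall rNPV
of 14.17&nbsp;$M and conditional phase values of
(32.3, 117.1, 292.4, 406.6)&nbsp;$M, and at \(r = 11\%\) an overall
23.26&nbsp;$M — the values this class of spreadsheet-based industry
valuations produces for these assumptions. The continuous convention
gives systematically richer values (about 6% on this fixture) because
mid-year cash flows are discounted less; the choice is a reporting
convention, not a modeling claim.

## Add-on benefits

* **R&D tax credit** (`apply_tax_credit()`): adds
  `rate × Σ a_k PV(C_k)` over the pre-submission phases. The credit
  applies to the development cost itself, not the SG&A load. On the
  base fixture it lifts the overall value to 18.59&nbsp;$M.
* **Priority review voucher** (`apply_prv()`): a transferable voucher
  granted for qualifying rare-pediatric approvals. It is modeled as
  `P(completing the phase in progress during the grant year) × value`,
  monetized at the *start* of the grant year. For the base fixture
  (granted in year 3, during phase 2) that is
  \(0.67 \times 0.53 \times 100 \times 1.13^{-2} = 27.8\)&nbsp;$M,
  lifting the credited value to 46.40&nbsp;$M. Gating on phase-2
  completion reflects that a voucher only materializes if the program
  remains viable through its pivotal efficacy readout; both this
  reading and the flag combination (credit on top) are design choices
  recorded in the run manifest.

## The Monte Carlo layer

Per path:

* **Phase outcomes**: sequential Bernoulli trials at the per-phase
  success probabilities; a phase is attempted only if all prior phases
  succeeded.
* **Costs and durations**: classical PERT draws (λ = 4 Beta rescaling
  of the three-point estimate — the universal default when a PERT is
  named without parameters). The four margins belonging to the two
  pivotal clinical phases (duration and cost of each) are coupled by a
  Gaussian copula with exchangeable correlation 0.5; the stated
  pairwise time/cost correlation fixes only the phase-2/phase-3 pairs,
  so extending the same value to the within-phase time–cost pairs (the
  exchangeable completion) is a documented assumption, overridable via
  `correlation_settings()`. Phase outcomes are independent of cost and
  duration draws — no such coupling is specified.
* **Price and peak adoption**: normal draws calibrated so their 95% CI
  spans the scenario bounds (`normal_from_ci()`), truncated at 0 (and 1
  for adoption) by inverse-CDF restriction; drawn once per path, since
  one price assumption underlies a valuation, not one per year.
* **Timeline**: sampled durations re-time everything — launch shifts
  and exclusivity is recomputed.

Each path records the conditional value at every completed phase and
two year-0 net-value accountings:

* **invested basis** — discounted sale proceeds minus development
  outlays at face value ("did the exit return the cash put in");
* **discounted basis** — proceeds minus the discounted PV of outlays.

Both are always computed; which one a report quotes is part of its
manifest. The invested basis is the default for single-compound risk
headlines: under it the simulated probability of a negative overall
NPV on the base fixture is ≈ 0.80 (the cumulative failure probability
0.77 plus approved-but-unprofitable paths), which is the convention
under which published headline figures for this compound class are
defined. Under the fully discounted basis the same probability is
≈ 0.77, because an approved program essentially always clears its
discounted costs.

### The log-normal value model

`lognormal_loss_profile()` is a two-stage estimator of the
sale-at-loss probabilities: per-phase conditional values are drawn from
log-normals moment-matched to the full simulation
(`calibrate_lognormal()`: \(\sigma^2 = \ln(1 + s^2/m^2)\),
\(\mu = \ln m - \sigma^2/2\)), while outcomes, durations and sunk costs
are re-simulated. A log-normal is the natural parametric family here —
phase values are positive and right-skewed — and it thins the heavy
left tail that the raw difference of (right-skewed) cost draws imposes
on early-phase values. On the base fixture the two-stage estimator
gives sale-at-loss probabilities of ≈ (0.39, 0.66, 0.78) for phases
1–3 on the invested basis, a few points below/above the purely
empirical estimates; both are reported so users can see the effect of
the parametric assumption.

## Portfolio simulation and diversification

`simulate_portfolio()` draws all drugs jointly: within each phase the
drugs' latent success variables follow a Gaussian copula with
exchangeable pairwise correlation `cross_drug_rho`; costs, durations,
price and adoption are independent per drug. Aggregate values sum
across drugs per phase, deliberately ignoring inter-drug timing
differences. Loss probabilities are computed on the aggregate exactly
as for one compound. In `"lognormal"` mode the per-drug values come
from the calibrated log-normals, with the value draws sharing the same
cross-drug correlation (so the comonotone limit ρ → 1 recovers the
single-compound profile, a tested property).

Portfolio risk metrics are quoted on the **discounted basis**. On the
invested basis the expected per-drug overall value of the base fixture
is negative (face-value costs exceed the risk-weighted discounted
revenue), so the portfolio's negative-NPV probability exceeds 0.72 for
*any* correlation — no diversification story exists on that basis.
This asymmetry between the bases is a genuine finding of the
reimplementation: the single-compound and portfolio headline risk
figures circulating for this compound class are internally consistent
only if the single-compound figures use face-value costs and the
portfolio figures discounted costs.

`cross_drug_rho` defaults to 0.2 — "moderately correlated" is the most
one can defend for mechanistically unrelated monogenic diseases — and
every portfolio output echoes it as an assumption. Because the true
pairwise structure is rarely observable, `calibrate_cross_drug_rho()`
fits the exchangeable correlation to an external headline (bisection
with common random numbers; the downside probability is monotone in ρ,
a tested invariant) and reports the fitted value. Fitting ρ to a
portfolio-level negative-NPV headline of 0.561 for eight drugs yields
ρ ≈ 0.72, at which the phase-3 aggregate sale-loss probability also
matches (≈ 0.55) — but the phase-1 and phase-2 aggregate loss
probabilities then overshoot (≈ 0.20 and ≈ 0.45 against published
values near 0.11 and 0.39). No single exchangeable success-correlation
reproduces the whole profile: matching it phase by phase would require
the cross-drug correlation to *increase* with phase (roughly 0.3 / 0.5
/ 0.7), i.e. late-stage and market risks are more shared across
programs than early biology risk. The package exposes only the
exchangeable structure and reports the discrepancy rather than
overfitting per-phase correlations to four numbers.

## What the generator emulates — and what it does not

The simulator reproduces the *study conditions* of a desk valuation:
fixed per-phase success probabilities, three-point cost/duration
estimates, a single U.S. market with a stylized adoption ramp, constant
real price, no competition, no post-exclusivity tail, no capital
structure. Passing tests therefore show internal consistency of the
framework and faithful reproduction of the published case — not that
real Rett-syndrome programs have a 23% approval probability. In
particular: success probabilities are treated as known constants (no
parameter uncertainty); price and adoption are drawn once per path;
failure timing within a phase is not modeled (a failed phase still pays
its full cost); and portfolio correlation is an assumption, not an
estimate.

## Numerical choices

* Patient counts are carried unrounded (the printed peak of 4237
  patients arises from unrounded intermediates); rounding happens only
  at display. Recomputing the lower-bound peak from the population
  table gives 2966 patients (0.35 × 8475), not the 2996 sometimes
  printed alongside these assumptions — the engine reports the
  computed value.
* Truncating the price/adoption normals by inverse-CDF restriction
  keeps the per-path random-number consumption fixed, which makes a
  1-drug portfolio bit-identical to the single-compound simulator
  (tested) and keeps seeds reproducible.
* Degenerate PERT triples (min = max) are point masses and consume no
  random numbers.
* The correlation matrix sampler falls back to an eigendecomposition
  square root for PSD-but-singular matrices, so the comonotone limit
  ρ = 0.999…1 remains usable.
* Problem sizes: 10,000 paths for single-compound summaries (standard
  for this class of model; binomial SE ≈ 0.4 points on an 80%
  probability) and 100,000 for portfolio headline probabilities;
  the correlation calibration bisects at 20,000 paths with common
  random numbers.
* Empty conditional sets (no path completed a phase) report `NA`
  statistics, never zero.

## Limitations

The model prices a stylized single-market launch; list-price erosion,
ex-U.S. revenue, competitive entry before exclusivity lapse, and
financing structure are all out of scope. The log-normal value model
and the exchangeable cross-drug copula are parametric conveniences —
both are exposed so users can swap in their own calibrations. All
headline numbers in this vignette are recomputed by the package's test
suite and by `scripts/acceptance.R`; none are hard-coded.
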
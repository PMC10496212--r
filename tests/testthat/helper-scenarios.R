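# shared fixtures: load once per test run
base_scn <- scenario_fixture("rett_base")
lower_scn <- scenario_fixture("rett_lower")
upper_scn <- scenario_fixture("rett_upper")
metoo_scn <- scenario_fixture("me_too")

# a degenerate scenario: certain success, constant costs/durations/price
degenerate_scenario <- function(pos = 1) {
  plan <- phase_plan(
    phase_spec("a", pos, c(5, 5, 5), c(1, 1, 1)),
    phase_spec("b", pos, c(10, 10, 10), c(2, 2, 2)))
  groups <- list(age_group("kids", 1000, 1, 1))
  ad <- adoption_model(0.5, 0.4, 0.6, c(0.5, 1), groups)
  cm <- commercial_model(price = 1e5, price_lo = 9e4, price_hi = 1.1e5,
                         adoption = ad, cogs_frac = 0, sga_frac = 0,
                         rnd_frac = 0, prerevenue_sga_of_rnd = 0,
                         tax_rate = 0, exclusivity_years = 5,
                         discount_rate = 0.1)
  # negligible price/adoption spread so paths are near-identical
  cm$price_lo <- 1e5 - 1e-6; cm$price_hi <- 1e5 + 1e-6
  cm$adoption$peak_rate_lo <- 0.5 - 1e-12; cm$adoption$peak_rate_hi <- 0.5 + 1e-12
  scenario(plan, cm, name = "degenerate")
}
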
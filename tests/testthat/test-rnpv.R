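# deterministic discounting and rNPV engine

test_that("uniform-stream discounting matches quadrature and limits", {
  # oracle: numerical integration of the discount factor over the window
  num <- integrate(function(t) 100 * 1.13^(-t), 0, 1)$value
  expect_equal(discount_uniform_stream(100, 0, 1, 0.13), num, tolerance = 1e-8)
  expect_equal(discount_uniform_stream(100, 0, 1, 0.13), 94.13, tolerance = 1e-4)
  # amount spread over the window: integrate the flow rate amount/(t1-t0)
  num2 <- integrate(function(t) 50 / 2.25 * 1.08^(-t), 2.25, 4.5)$value
  expect_equal(discount_uniform_stream(50, 2.25, 4.5, 0.08), num2, tolerance = 1e-8)
  # r -> 0 returns the undiscounted amount
  expect_equal(discount_uniform_stream(7, 1, 3, 0), 7)
  expect_equal(discount_annual_stream(7, 1, 3, 0), 7)
  expect_error(discount_uniform_stream(1, 2, 2, 0.1), "t1 > t0")
  # annual buckets: one-year window settles at the year end
  expect_equal(discount_annual_stream(100, 0, 1, 0.13), 100 / 1.13)
  # split windows are additive under both conventions
  expect_equal(discount_annual_stream(10, 0.5, 2.5, 0.1),
               discount_annual_stream(5, 0.5, 1.5, 0.1) +
                 discount_annual_stream(5, 1.5, 2.5, 0.1))
})

# independent spreadsheet-style oracle for the base case: explicit
# year-by-year sums under annual end-of-period discounting
oracle_rnpv <- function(r) {
  v <- 1 / (1 + r)
  pos <- c(0.67, 0.53, 0.69, 0.94)
  arr <- c(1, cumprod(pos)[1:3])
  cost <- c(4, 14, 35, 37) * 1.4
  # per-phase yearly outlays: years 1 | 2,3 | 4,5 | 6
  pv_cost <- c(cost[1] * v,
               cost[2] / 2 * (v^2 + v^3),
               cost[3] / 2 * (v^4 + v^5),
               cost[4] * v^6)
  patients <- c(25770 * 0.125, 25313 * 0.120, 51749 * 0.115, 64090 * 0.060)
  peak_patients <- sum(patients * c(1, 0.75, 0.5, 0)) * 0.5
  cf <- peak_patients * 40000 * 0.55 * 0.8 / 1e6
  ramp <- c(1/3, 2/3, rep(1, 12))
  pv_rev <- sum(cf * ramp * v^(6 + 1:14))
  -sum(arr * pv_cost) + prod(pos) * pv_rev
}

test_that("the engine agrees with an independent year-by-year computation", {
  expect_equal(rnpv(base_scn)$rnpv_overall, oracle_rnpv(0.13), tolerance = 1e-9)
  expect_equal(rnpv(base_scn, discount_rate = 0.11)$rnpv_overall,
               oracle_rnpv(0.11), tolerance = 1e-9)
})

test_that("valuation limits and degenerate plans behave", {
  # certain success, r -> 0: rNPV = undiscounted revenue minus costs
  scn <- base_scn
  for (k in 1:4) scn$plan[[k]]$pos <- 1
  scn$commercial$discount_rate <- 1e-9
  v <- rnpv(scn)
  undisc_cost <- sum(c(4, 14, 35, 37) * 1.4)
  patients <- sum(c(3221.25, 3037.56, 5951.135) * c(1, 0.75, 0.5)) * 0.5
  undisc_rev <- patients * 40000 * 0.55 * 0.8 / 1e6 * (1/3 + 2/3 + 12)
  expect_equal(v$rnpv_overall, undisc_rev - undisc_cost, tolerance = 1e-5)

  # forced failure in phase 1: value is minus the phase-1 outlay PV
  s0 <- base_scn
  s0$plan[[1]]$pos <- 1e-12
  v0 <- rnpv(s0)
  expect_equal(v0$rnpv_overall,
               -discount_annual_stream(4 * 1.4, 0, 1, 0.13), tolerance = 1e-6)

  # zero-cost certain plan: overall equals the discounted revenue PV
  s1 <- base_scn
  for (k in 1:4) { s1$plan[[k]]$pos <- 1; s1$plan[[k]]$cost <- c(0, 0, 0) }
  v1 <- rnpv(s1)
  expect_equal(v1$rnpv_overall, v1$components$revenue_pv, tolerance = 1e-10)
})

test_that("conditional phase values increase along the phase sequence", {
  va <- rnpv(base_scn)$value_after_phase
  expect_true(all(diff(va) > 0))
  va11 <- rnpv(base_scn, discount_rate = 0.11)$value_after_phase
  expect_true(all(va11 > va))   # cheaper capital raises every value
})

test_that("rNPV is monotone in the headline drivers", {
  base <- rnpv(base_scn)$rnpv_overall
  up <- function(param, values)
    sensitivity_grid(base_scn, param, values)$rnpv_overall
  expect_true(all(diff(up("price", c(30000, 40000, 50000))) > 0))
  expect_true(all(diff(up("peak_adoption", c(0.35, 0.5, 0.65))) > 0))
  expect_true(all(diff(up("pos_2", c(0.3, 0.53, 0.8))) > 0))
  expect_true(all(diff(up("exclusivity", c(7, 14, 20))) > 0))
  expect_true(all(diff(up("cost_3", c(22, 35, 99))) < 0))
  expect_true(all(diff(up("discount_rate", c(0.11, 0.13, 0.15))) < 0))
})

test_that("the tax credit adds the credit on pre-submission development PV", {
  v <- rnpv(base_scn)
  vt <- apply_tax_credit(v, base_scn)
  arr <- unname(arrival_probabilities(base_scn$plan))[1:3]
  pv_rnd <- c(discount_annual_stream(4, 0, 1, 0.13),
              discount_annual_stream(14, 1, 3, 0.13),
              discount_annual_stream(35, 3, 5, 0.13))
  expect_equal(vt$rnpv_overall - v$rnpv_overall, 0.25 * sum(arr * pv_rnd),
               tolerance = 1e-10)
  # zero rate leaves the value unchanged
  s0 <- base_scn; s0$commercial$tax_credit_rate <- 0
  expect_equal(apply_tax_credit(rnpv(s0), s0)$rnpv_overall,
               rnpv(s0)$rnpv_overall)
  # zero costs leave the value unchanged
  sz <- base_scn
  for (k in 1:4) sz$plan[[k]]$cost <- c(0, 0, 0)
  expect_equal(apply_tax_credit(rnpv(sz), sz)$rnpv_overall,
               rnpv(sz)$rnpv_overall)
  expect_error(apply_tax_credit(vt, base_scn), "already applied")
})

test_that("the voucher adds its survival-weighted discounted value", {
  v <- rnpv(base_scn)
  vp <- apply_prv(v, base_scn)
  # granted during phase 2 (year 3): weighted by completing phase 2,
  # monetized at the start of the grant year
  expect_equal(vp$rnpv_overall - v$rnpv_overall,
               0.67 * 0.53 * 100 * 1.13^(-2), tolerance = 1e-10)
  s0 <- base_scn; s0$commercial$prv_value <- 0
  expect_equal(apply_prv(rnpv(s0), s0)$rnpv_overall, rnpv(s0)$rnpv_overall)
  # beyond-timeline grant year rejected
  sl <- base_scn; sl$commercial$prv_year <- 30
  expect_error(apply_prv(rnpv(sl), sl), "beyond the development timeline")
  # flags on the scenario fold the add-ons into rnpv() directly
  sf <- base_scn; sf$include_tax_credit <- TRUE; sf$include_prv <- TRUE
  both <- rnpv(sf)
  expect_equal(both$rnpv_overall,
               apply_prv(apply_tax_credit(v, base_scn), base_scn)$rnpv_overall)
})

test_that("sampled timelines shift launch and exclusivity coherently", {
  v <- rnpv(base_scn, durations = c(1, 3, 3, 1))
  expect_equal(v$timeline$launch, 8)
  expect_equal(v$timeline$exclusivity, 12)   # patent term 20 minus launch
  expect_lt(v$rnpv_overall, rnpv(base_scn)$rnpv_overall)
  # orphan floor binds for very slow programs
  v2 <- rnpv(base_scn, durations = c(4, 4, 4, 2))
  expect_equal(v2$timeline$exclusivity, 7)
})
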
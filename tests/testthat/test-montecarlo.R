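# single-compound Monte Carlo simulation

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_compound(base_scn, 500, seed = 42)
  b <- simulate_compound(base_scn, 500, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  sa <- summarize_paths(a)
  sb <- summarize_paths(b)
  expect_identical(sa$by_phase, sb$by_phase)
  expect_identical(sa$overall, sb$overall)
  c <- simulate_compound(base_scn, 500, seed = 43)
  expect_false(identical(a$overall_inv, c$overall_inv))
})

test_that("path outcomes are consistent with the phase plan", {
  paths <- simulate_compound(base_scn, 10000, seed = 7)
  p <- cumulative_pos(base_scn)
  expect_lt(abs(mean(paths$approved) - p), 3 * sqrt(p * (1 - p) / 10000))
  # sampled quantities respect their supports
  expect_true(all(paths$cost_2 >= 9 & paths$cost_2 <= 40))
  expect_true(all(paths$dur_3 >= 1 & paths$dur_3 <= 3))
  expect_true(all(paths$price > 0))
  expect_true(all(paths$peak_rate >= 0 & paths$peak_rate <= 1))
  # launch equals the summed durations; exclusivity from the patent term
  durs <- paths$dur_1 + paths$dur_2 + paths$dur_3 + paths$dur_4
  expect_equal(paths$launch, durs)
  expect_equal(paths$exclusivity, pmax(20 - paths$launch, 7))
  # the phase-2/3 copula correlates costs across phases
  expect_gt(cor(paths$cost_2, paths$cost_3, method = "spearman"), 0.35)
})

test_that("a degenerate certain scenario collapses to identical paths", {
  scn <- degenerate_scenario()
  paths <- simulate_compound(scn, 200, seed = 1)
  expect_true(all(paths$approved))
  expect_lt(diff(range(paths$overall_inv)), 1e-4)
  expect_equal(loss_probabilities(paths)$negative_overall, 0)
})

test_that("failed paths carry sunk costs; completed ones sale proceeds", {
  paths <- simulate_compound(base_scn, 5000, seed = 8)
  fail1 <- paths$att_1 & !paths$succ_1
  # invested basis: phase-1 failures lose the nominal phase-1 outlay
  expect_equal(paths$sale_inv_1[fail1], -(paths$cost_1 * 1.4)[fail1])
  # all failures are losses at every later sale point
  expect_true(all(paths$sale_inv_3[fail1] < 0))
  expect_true(all(paths$sale_dcf_3[fail1] < 0))
  # discounted proceeds of completers: value discounted minus sunk PV
  ok4 <- paths$succ_4
  expect_equal(paths$overall_inv[ok4],
               paths$pv_revenue[ok4] -
                 1.4 * (paths$cost_1 + paths$cost_2 + paths$cost_3 + paths$cost_4)[ok4])
})

test_that("conditional value distributions shift upward with phase", {
  paths <- simulate_compound(base_scn, 10000, seed = 9)
  q <- sapply(1:4, function(k)
    quantile(paths[[paste0("value_after_", k)]][paths[[paste0("succ_", k)]]],
             c(0.25, 0.5, 0.75)))
  expect_true(all(diff(t(q)[, 1]) > 0))
  expect_true(all(diff(t(q)[, 2]) > 0))
  expect_true(all(diff(t(q)[, 3]) > 0))
  # the simulated conditional mean at approval sits near the modal value
  s <- summarize_paths(paths)
  expect_equal(s$by_phase$mean_value[4], s$by_phase$expected_rnpv[4],
               tolerance = 0.05)
  # time-0 positive-sale probability at the last phase converges toward
  # the cumulative PoS
  p_pos <- mean(paths$sale_dcf_4 > 0)
  expect_lt(abs(p_pos - cumulative_pos(base_scn)), 0.03)
})

test_that("empty conditional sets give NA statistics, not zeros", {
  scn <- base_scn
  scn$plan[[4]]$pos <- 1e-9
  paths <- simulate_compound(scn, 300, seed = 10)
  s <- summarize_paths(paths)
  expect_true(is.na(s$by_phase$mean_value[4]))
  expect_identical(s$by_phase$n_completed[4], 0L)
})

test_that("the sensitivity grid recomputes the deterministic valuation", {
  g <- sensitivity_grid(base_scn, "discount_rate", c(0.13, 0.11))
  expect_equal(g$rnpv_overall[1], rnpv(base_scn)$rnpv_overall)
  expect_gt(g$rnpv_overall[2], g$rnpv_overall[1])
  gp <- sensitivity_grid(base_scn, "price", c(30000, 40000, 50000))
  expect_true(all(diff(gp$rnpv_overall) > 0))
  # forcing a mid-plan failure leaves only the sunk risk-adjusted costs
  g0 <- sensitivity_grid(base_scn, "pos_2", 0)
  expect_equal(g0$rnpv_overall,
               -(discount_annual_stream(4 * 1.4, 0, 1, 0.13) +
                   0.67 * discount_annual_stream(14 * 1.4, 1, 3, 0.13)),
               tolerance = 1e-9)
  expect_error(sensitivity_grid(base_scn, "nonsense", 1), "unknown sensitivity")
})

test_that("the lognormal two-stage profile tracks the empirical one", {
  paths <- simulate_compound(base_scn, 10000, seed = 11)
  s <- summarize_paths(paths)
  prof <- lognormal_loss_profile(base_scn, s, 10000, seed = 12)
  emp <- loss_probabilities(paths, "invested")
  # same failure floor; parametric values thin the left tail, so the
  # two estimates agree within a few points everywhere
  expect_true(all(abs(prof$sale_loss - emp$sale_loss) < 0.08))
  expect_lt(abs(prof$negative_overall - emp$negative_overall), 0.03)
  # calibration identity: fitted lognormal reproduces the moments
  cal <- calibrate_lognormal(401.78, 96.35)
  expect_equal(exp(cal$meanlog + cal$sdlog^2 / 2), 401.78)
  expect_equal(sqrt((exp(cal$sdlog^2) - 1)) * 401.78, 96.35, tolerance = 1e-10)
  m <- calibrate_lognormal(10, 5)
  expect_equal(m$meanlog, log(10) - 0.5 * log(1.25))
  expect_equal(m$sdlog, sqrt(log(1.25)))
  expect_error(calibrate_lognormal(-1, 2), "positive mean")
})
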
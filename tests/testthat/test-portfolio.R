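# portfolio aggregation, diversification, correlation calibration

test_that("a one-drug portfolio reduces exactly to the single simulation", {
  spec <- portfolio_spec(base_scn, n_drugs = 1, cross_drug_rho = 0)
  pf <- simulate_portfolio(spec, 3000, seed = 5)
  single <- simulate_compound(base_scn, 3000, seed = 5)
  expect_equal(pf$aggregate$overall_inv, single$overall_inv)
  expect_equal(pf$aggregate$overall_dcf, single$overall_dcf)
  for (k in 1:4)
    expect_equal(pf$aggregate[[paste0("sale_dcf_", k)]],
                 single[[paste0("sale_dcf_", k)]])
})

test_that("portfolio means scale linearly with the number of drugs", {
  spec4 <- portfolio_spec(base_scn, n_drugs = 4, cross_drug_rho = 0.3)
  pf4 <- simulate_portfolio(spec4, 20000, seed = 6)
  spec1 <- portfolio_spec(base_scn, n_drugs = 1, cross_drug_rho = 0.3)
  pf1 <- simulate_portfolio(spec1, 20000, seed = 6)
  m4 <- mean(pf4$aggregate$overall_dcf)
  m1 <- mean(pf1$aggregate$overall_dcf)
  se <- sd(pf4$aggregate$overall_dcf) / sqrt(20000) +
    4 * sd(pf1$aggregate$overall_dcf) / sqrt(20000)
  expect_lt(abs(m4 - 4 * m1), 3 * se)
})

test_that("independent drugs add variances in lognormal mode", {
  s <- summarize_paths(simulate_compound(base_scn, 10000, seed = 1))
  sp4 <- portfolio_spec(base_scn, 4, cross_drug_rho = 0, mode = "lognormal",
                        calibration = s)
  sp1 <- portfolio_spec(base_scn, 1, cross_drug_rho = 0, mode = "lognormal",
                        calibration = s)
  v4 <- var(simulate_portfolio(sp4, 30000, seed = 2)$aggregate$overall_dcf)
  v1 <- var(simulate_portfolio(sp1, 30000, seed = 3)$aggregate$overall_dcf)
  expect_equal(v4 / v1, 4, tolerance = 0.12)
})

test_that("downside risk is nondecreasing in the cross-drug correlation", {
  probs <- vapply(c(0, 0.4, 0.8), function(rho) {
    spec <- portfolio_spec(base_scn, n_drugs = 8, cross_drug_rho = rho)
    simulate_portfolio(spec, 8000, seed = 7)$summary$prob_negative_dcf
  }, numeric(1))
  expect_true(all(diff(probs) > 0))
  # diversification: the portfolio is safer than a single compound
  single_p <- loss_probabilities(simulate_compound(base_scn, 8000, seed = 7),
                                 "discounted")$negative_overall
  expect_lt(probs[1], single_p)
  expect_lt(probs[2], single_p)
})

test_that("the comonotone limit recovers the single-compound profile", {
  s <- summarize_paths(simulate_compound(base_scn, 10000, seed = 1))
  single <- lognormal_loss_profile(base_scn, s, 20000, seed = 8)
  spec <- portfolio_spec(base_scn, n_drugs = 8, cross_drug_rho = 0.999,
                         mode = "lognormal", calibration = s)
  pf <- simulate_portfolio(spec, 20000, seed = 8)
  expect_true(all(abs(pf$summary$prob_sale_loss_inv - single$sale_loss) < 0.025))
  expect_lt(abs(pf$summary$prob_negative_inv - single$negative_overall), 0.025)
})

test_that("rho calibration brackets and hits an attainable target", {
  spec <- portfolio_spec(base_scn, n_drugs = 8)
  fit <- calibrate_cross_drug_rho(spec, target = 0.50, n_paths = 4000,
                                  seed = 9, tol = 0.01)
  expect_gt(fit$rho, 0)
  expect_lt(fit$rho, 0.98)
  expect_lt(abs(fit$achieved - 0.50), 0.01)
  # unattainably low targets clamp to the independence end
  lowfit <- calibrate_cross_drug_rho(spec, target = 0.01, n_paths = 2000, seed = 9)
  expect_equal(lowfit$rho, 0)
})

test_that("the diversification report contrasts the two profiles", {
  paths <- simulate_compound(base_scn, 5000, seed = 10)
  s <- summarize_paths(paths)
  spec <- portfolio_spec(base_scn, n_drugs = 8, cross_drug_rho = 0.3)
  pf <- simulate_portfolio(spec, 5000, seed = 10)
  rep <- diversification_report(s, pf)
  expect_equal(nrow(rep), 5)
  expect_equal(rep$delta, rep$portfolio - rep$single)
  # pooling eight drugs cuts every loss probability at moderate correlation
  expect_true(all(rep$delta < 0))
})
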
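# samplers: PERT, CI-calibrated normal, Gaussian copula, phase chain

test_that("PERT moments match the three-point closed forms", {
  cases <- list(c(4, 6, 8), c(9, 14, 40), c(1, 4, 7), c(22, 35, 99))
  set.seed(101)
  for (tr in cases) {
    # oracle: numerical integration of the scaled Beta density
    a <- 1 + 4 * (tr[2] - tr[1]) / (tr[3] - tr[1])
    b <- 1 + 4 * (tr[3] - tr[2]) / (tr[3] - tr[1])
    dens <- function(x) dbeta((x - tr[1]) / (tr[3] - tr[1]), a, b) / (tr[3] - tr[1])
    m_num <- integrate(function(x) x * dens(x), tr[1], tr[3])$value
    expect_equal(pert_mean(tr[1], tr[2], tr[3]), m_num, tolerance = 1e-6)
    v_num <- integrate(function(x) (x - m_num)^2 * dens(x), tr[1], tr[3])$value
    expect_equal(pert_var(tr[1], tr[2], tr[3]), v_num, tolerance = 1e-6)

    x <- rpert(2e5, tr[1], tr[2], tr[3])
    expect_true(all(x >= tr[1] & x <= tr[3]))
    expect_equal(mean(x), pert_mean(tr[1], tr[2], tr[3]),
                 tolerance = 4 * sqrt(pert_var(tr[1], tr[2], tr[3]) / 2e5) /
                   pert_mean(tr[1], tr[2], tr[3]))
    expect_equal(var(x), pert_var(tr[1], tr[2], tr[3]), tolerance = 0.05)
  }
  expect_equal(pert_mean(4, 6, 8), 6)
  expect_equal(pert_mean(9, 14, 40), 17.5)
})

test_that("degenerate PERT returns the constant and invalid triples error", {
  expect_equal(rpert(10, 5, 5, 5), rep(5, 10))
  expect_equal(qpert(c(0.1, 0.9), 3, 3, 3), c(3, 3))
  expect_error(rpert(1, 2, 1, 3), "min <= mode <= max")
})

test_that("normal_from_ci calibrates to the 95% interval", {
  p <- normal_from_ci(40000, 30000, 50000)
  expect_equal(unname(p["mean"]), 40000)
  expect_equal(unname(p["sd"]), 10000 / qnorm(0.975), tolerance = 1e-10)
  expect_equal(unname(p["sd"]), 5102.1, tolerance = 1e-4)
  p2 <- normal_from_ci(0.50, 0.35, 0.65)
  expect_equal(unname(p2["sd"]), 0.0765, tolerance = 1e-3)
  expect_error(normal_from_ci(5, 5, 6), "lo < center < hi")
  expect_error(normal_from_ci(5, 4, 5.5), "not symmetric")
})

test_that("copula sampling preserves marginals and correlation structure", {
  n <- 4e4
  # independence: near-zero correlation
  sp0 <- copula_spec(diag(2),
                     list(list(type = "pert", min = 1, mode = 2, max = 3),
                          list(type = "pert", min = 22, mode = 35, max = 99)))
  x0 <- copula_sample(sp0, n, seed = 11)
  expect_lt(abs(cor(x0[, 1], x0[, 2])), 0.02)

  # Gaussian margins recover rho exactly
  spn <- copula_spec(matrix(c(1, .5, .5, 1), 2),
                     list(list(type = "normal", mean = 0, sd = 1),
                          list(type = "normal", mean = 0, sd = 1)))
  xn <- copula_sample(spn, n, seed = 12)
  expect_equal(cor(xn[, 1], xn[, 2]), 0.5, tolerance = 0.03)

  # rank correlation identity for arbitrary continuous margins
  spp <- copula_spec(matrix(c(1, .5, .5, 1), 2),
                     list(list(type = "pert", min = 1, mode = 2, max = 3),
                          list(type = "pert", min = 22, mode = 35, max = 99)))
  xp <- copula_sample(spp, n, seed = 13)
  rho_s <- cor(xp[, 1], xp[, 2], method = "spearman")
  expect_equal(rho_s, (6 / pi) * asin(0.5 / 2), tolerance = 0.03)

  # marginal preservation under correlation (KS distance)
  ks <- suppressWarnings(
    stats::ks.test(xp[, 2], function(q) ppert(q, 22, 35, 99)))
  expect_lt(unname(ks$statistic), 2.2 / sqrt(n))

  # Bernoulli margin realizes its success probability
  spb <- copula_spec(matrix(c(1, .5, .5, 1), 2),
                     list(list(type = "bernoulli", pos = 0.53),
                          list(type = "pert", min = 1, mode = 2, max = 3)))
  xb <- copula_sample(spb, n, seed = 14)
  expect_equal(mean(xb[, 1]), 0.53, tolerance = 3 * sqrt(0.53 * 0.47 / n) / 0.53)
})

test_that("non-PSD correlation matrices are rejected with the eigenvalue", {
  bad <- matrix(c(1, 0.9, -0.9, 0.9, 1, 0.9, -0.9, 0.9, 1), 3)
  expect_error(copula_spec(bad, rep(list(list(type = "normal", mean = 0, sd = 1)), 3)),
               "positive semi-definite")
})

test_that("phase chains are sequential Bernoulli trials", {
  plan <- base_scn$plan
  ch <- sample_phase_chain(plan, 2e4, seed = 21)
  # attempted only after all prior successes
  expect_true(all(ch$attempted[, 1]))
  for (k in 2:4)
    expect_true(all(ch$attempted[, k] ==
                      (ch$attempted[, k - 1] & ch$succeeded[, k - 1])))
  # completion fraction near the cumulative PoS
  p <- cumulative_pos(plan)
  se <- sqrt(p * (1 - p) / 2e4)
  expect_lt(abs(mean(ch$succeeded[, 4]) - p), 3 * se)
  # fraction reaching phase 3 near the product of the first two PoS
  p3 <- prod(vapply(plan[1:2], `[[`, numeric(1), "pos"))
  expect_lt(abs(mean(ch$attempted[, 3]) - p3), 3 * sqrt(p3 * (1 - p3) / 2e4))
  # certain plan: everything succeeds
  sure <- phase_plan(phase_spec("a", 1, c(1, 1, 1), c(1, 1, 1)),
                     phase_spec("b", 1, c(1, 1, 1), c(1, 1, 1)))
  chs <- sample_phase_chain(sure, 100, seed = 22)
  expect_true(all(chs$succeeded))
})

test_that("samplers are reproducible under a fixed seed", {
  set.seed(33); a <- rpert(50, 1, 4, 7)
  set.seed(33); b <- rpert(50, 1, 4, 7)
  expect_identical(a, b)
  sp <- copula_spec(matrix(c(1, .5, .5, 1), 2),
                    list(list(type = "pert", min = 1, mode = 2, max = 3),
                         list(type = "normal", mean = 0, sd = 1)))
  expect_identical(copula_sample(sp, 100, seed = 7),
                   copula_sample(sp, 100, seed = 7))
})
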
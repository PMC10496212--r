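#' Sample sequential phase outcomes
#'
#' Models the development process as a sequence of Bernoulli trials: a
#' phase is attempted only if all prior phases succeeded, and succeeds
#' with its probability of success.
#'
#' @param plan a `phase_plan` or `scenario`.
#' @param n number of outcome vectors.
#' @param seed optional integer seed.
#' @return list of two `n x nphases` logical matrices, `attempted` and
#'   `succeeded`.
#' @examples
#' ch <- sample_phase_chain(example_plan(), 1000, seed = 1)
#' mean(ch$succeeded[, 4])   # close to the cumulative PoS
#' @export
sample_phase_chain <- function(plan, n, seed = NULL) {
  plan <- as_plan(plan)
  if (!is.null(seed)) set.seed(seed)
  pos <- vapply(plan, `[[`, numeric(1), "pos")
  u <- matrix(runif(n * length(pos)), n, length(pos))
  chain_from_uniforms(u, pos)
}

chain_from_uniforms <- function(u, pos) {
  nph <- length(pos)
  succ <- sweep(u, 2, pos, "<")
  att <- matrix(TRUE, nrow(u), nph)
  if (nph > 1)
    for (k in 2:nph) att[, k] <- att[, k - 1] & succ[, k - 1]
  succ <- succ & att
  list(attempted = att, succeeded = succ)
}

# ---- internal sampling core ---------------------------------------------
# Draw order is fixed so that a 1-drug portfolio consumes the RNG stream
# identically to simulate_compound: (1) copula block for the interior
# (pivotal clinical) phases' durations and costs, (2) remaining phases'
# durations then costs in phase order, (3) price, (4) peak adoption.

draw_drug_inputs <- function(scn, n) {
  plan <- scn$plan
  nph <- length(plan)
  interior <- if (nph >= 3) 2:(nph - 1) else integer(0)
  D <- matrix(NA_real_, n, nph)
  C <- matrix(NA_real_, n, nph)
  if (length(interior)) {
    rho <- scn$correlations$phase23_time_cost_rho
    U <- pnorm(latent_normals(n, exchangeable_corr(2 * length(interior), rho)))
    for (i in seq_along(interior)) {
      k <- interior[i]
      D[, k] <- qpert(U[, 2 * i - 1], plan[[k]]$duration[1],
                      plan[[k]]$duration[2], plan[[k]]$duration[3])
      C[, k] <- qpert(U[, 2 * i], plan[[k]]$cost[1],
                      plan[[k]]$cost[2], plan[[k]]$cost[3])
    }
  }
  for (k in setdiff(seq_len(nph), interior)) {
    dtr <- plan[[k]]$duration
    ctr <- plan[[k]]$cost
    D[, k] <- if (dtr[1] == dtr[3]) rep(dtr[1], n) else rpert(n, dtr[1], dtr[2], dtr[3])
    C[, k] <- if (ctr[1] == ctr[3]) rep(ctr[1], n) else rpert(n, ctr[1], ctr[2], ctr[3])
  }
  cm <- scn$commercial
  pp <- normal_from_ci(cm$price, cm$price_lo, cm$price_hi)
  price <- trunc_normal(n, pp["mean"], pp["sd"], lower = 0)
  ap <- normal_from_ci(cm$adoption$peak_rate, cm$adoption$peak_rate_lo,
                       cm$adoption$peak_rate_hi)
  peak <- trunc_normal(n, ap["mean"], ap["sd"], lower = 0, upper = 1)
  list(D = D, C = C, price = price, peak = peak)
}

# inverse-CDF truncated normal: consumes exactly n uniforms
trunc_normal <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# All per-path valuation quantities for one drug. succ/att are n x nph
# logical; D, C are n x nph; price, peak length n.
path_values <- function(scn, att, succ, D, C, price, peak,
                        convention = "annual") {
  cm <- scn$commercial
  r <- cm$discount_rate
  plan <- scn$plan
  nph <- length(plan)
  n <- nrow(D)
  pos <- vapply(plan, `[[`, numeric(1), "pos")
  arr <- c(1, cumprod(pos))

  ends <- D
  for (k in seq_len(nph)) ends[, k] <- if (k == 1) D[, 1] else ends[, k - 1] + D[, k]
  starts <- cbind(0, ends[, -nph, drop = FALSE])
  launch <- ends[, nph]
  excl <- if (is.null(cm$patent_term_years)) rep(cm$exclusivity_years, n)
          else pmax(cm$patent_term_years - launch, cm$orphan_exclusivity_years)

  load <- 1 + cm$prerevenue_sga_of_rnd
  pv_cost <- matrix(0, n, nph)
  for (k in seq_len(nph))
    pv_cost[, k] <- pv_stream(C[, k] * load, starts[, k], ends[, k], r, convention)
  nom_cost <- C * load

  # after-tax cash flow at full peak ($M/yr), path-specific price/adoption
  pc <- patient_counts(cm$adoption$groups)
  mult <- vapply(cm$adoption$groups, `[[`, numeric(1), "multiplier")
  base_patients <- sum(pc$patients * mult)
  atcf_peak <- after_tax_cashflow(base_patients * peak, price, cm) / 1e6
  pv_rev <- pv_revenue(atcf_peak, cm$adoption$ramp, launch, excl, r, convention)

  # conditional value of the remaining project at each phase end
  V <- matrix(NA_real_, n, nph)
  for (k in seq_len(nph)) {
    if (arr[k + 1] == 0) next
    val <- arr[nph + 1] / arr[k + 1] * pv_rev
    if (k < nph) {
      future <- (k + 1):nph
      for (j in future) val <- val - arr[j] / arr[k + 1] * pv_cost[, j]
    }
    V[, k] <- val * (1 + r)^(ends[, k])
  }

  pv_cum <- t(apply(pv_cost, 1, cumsum))
  nom_cum <- t(apply(nom_cost, 1, cumsum))
  if (nph == 1) { pv_cum <- pv_cost; nom_cum <- nom_cost }

  sale_inv <- matrix(NA_real_, n, nph)
  sale_dcf <- matrix(NA_real_, n, nph)
  for (k in seq_len(nph)) {
    si <- numeric(n); sdc <- numeric(n)
    for (j in seq_len(k)) {
      fj <- att[, j] & !succ[, j]
      si[fj] <- -nom_cum[fj, j]
      sdc[fj] <- -pv_cum[fj, j]
    }
    ck <- att[, k] & succ[, k]
    proceeds <- V[ck, k] * (1 + r)^(-ends[ck, k])
    si[ck] <- proceeds - nom_cum[ck, k]
    sdc[ck] <- proceeds - pv_cum[ck, k]
    sale_inv[, k] <- si
    sale_dcf[, k] <- sdc
  }

  approved <- att[, nph] & succ[, nph]
  inc_nom <- rowSums(nom_cost * att)
  inc_pv <- rowSums(pv_cost * att)
  overall_inv <- -inc_nom + ifelse(approved, pv_rev, 0)
  overall_dcf <- -inc_pv + ifelse(approved, pv_rev, 0)
  overall_rnpv <- -as.vector(pv_cost %*% arr[seq_len(nph)]) + arr[nph + 1] * pv_rev

  list(ends = ends, launch = launch, exclusivity = excl,
       pv_cost = pv_cost, nom_cost = nom_cost, pv_rev = pv_rev,
       value_after = V, sale_invested = sale_inv, sale_discounted = sale_dcf,
       overall_invested = overall_inv, overall_discounted = overall_dcf,
       overall_rnpv = overall_rnpv, approved = approved)
}

#' Multi-stage Monte Carlo simulation of a single compound
#'
#' Each path draws: sequential Bernoulli phase outcomes; PERT-distributed
#' phase durations and costs, with the pivotal clinical phases' four
#' margins (duration and cost of each) coupled through a Gaussian copula
#' at the scenario's `phase23_time_cost_rho`; and a price and peak
#' adoption rate from normal distributions calibrated to the scenario's
#' 95% confidence intervals (truncated at zero, and at one for
#' adoption). The path's timeline re-times all later cash flows: launch
#' shifts with sampled durations and the exclusivity window is
#' recomputed from the patent term.
#'
#' Two year-0 net-value accountings are carried per path and phase:
#'
#' * **invested basis**: sale proceeds (the compound's conditional value
#'   at the phase end, discounted to year 0) minus development outlays
#'   at face value — "did the exit recover the cash invested";
#' * **discounted basis**: the same proceeds minus the discounted present
#'   value of the outlays — a fully discounted NPV.
#'
#' Paths that fail before a phase carry their sunk outlays and zero
#' proceeds in both accountings.
#'
#' @param scn a `scenario`.
#' @param n_paths number of Monte Carlo paths.
#' @param seed integer seed; identical seeds give bit-identical results.
#' @param convention discounting convention, see [rnpv()].
#' @return an `ov_paths` data.frame, one row per path, with per-phase
#'   columns (`succ_k`, `att_k`, `dur_k`, `cost_k`, `value_after_k`,
#'   `sale_inv_k`, `sale_dcf_k`) and path columns (`price`, `peak_rate`,
#'   `launch`, `exclusivity`, `pv_revenue`, `overall_inv`, `overall_dcf`,
#'   `overall_rnpv`, `approved`).
#' @seealso [summarize_paths()], [loss_probabilities()]
#' @examples
#' paths <- simulate_compound(scenario_fixture("rett_base"), 2000, seed = 1)
#' mean(paths$overall_inv < 0)   # probability of a negative overall NPV
#' @export
simulate_compound <- function(scn, n_paths = 10000, seed = 1,
                              convention = c("annual", "continuous")) {
  stopifnot(inherits(scn, "scenario"), n_paths >= 1)
  convention <- match.arg(convention)
  set.seed(seed)
  nph <- length(scn$plan)
  pos <- vapply(scn$plan, `[[`, numeric(1), "pos")
  # chain latents phase-by-phase (shared layout with the portfolio sampler)
  u <- matrix(NA_real_, n_paths, nph)
  for (k in seq_len(nph)) u[, k] <- pnorm(rnorm(n_paths))
  ch <- chain_from_uniforms(u, pos)
  inp <- draw_drug_inputs(scn, n_paths)
  pv <- path_values(scn, ch$attempted, ch$succeeded, inp$D, inp$C,
                    inp$price, inp$peak, convention)
  assemble_paths(scn, ch, inp, pv, seed, convention)
}

assemble_paths <- function(scn, ch, inp, pv, seed, convention) {
  nph <- length(scn$plan)
  df <- data.frame(row.names = seq_len(nrow(inp$D)))
  for (k in seq_len(nph)) {
    df[[paste0("att_", k)]] <- ch$attempted[, k]
    df[[paste0("succ_", k)]] <- ch$succeeded[, k]
    df[[paste0("dur_", k)]] <- inp$D[, k]
    df[[paste0("cost_", k)]] <- inp$C[, k]
    df[[paste0("value_after_", k)]] <- pv$value_after[, k]
    df[[paste0("sale_inv_", k)]] <- pv$sale_invested[, k]
    df[[paste0("sale_dcf_", k)]] <- pv$sale_discounted[, k]
  }
  df$price <- inp$price
  df$peak_rate <- inp$peak
  df$launch <- pv$launch
  df$exclusivity <- pv$exclusivity
  df$pv_revenue <- pv$pv_rev
  df$overall_inv <- pv$overall_invested
  df$overall_dcf <- pv$overall_discounted
  df$overall_rnpv <- pv$overall_rnpv
  df$approved <- pv$approved
  structure(df, class = c("ov_paths", "data.frame"),
            scenario = scn, seed = seed, convention = convention,
            phase_names = vapply(scn$plan, `[[`, character(1), "name"))
}
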
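#' Calibrate a log-normal distribution by moment matching
#'
#' Fits the log-normal whose mean and standard deviation equal the given
#' values: `sigma^2 = log(1 + sd^2 / mean^2)`,
#' `mu = log(mean) - sigma^2 / 2`. Used to turn the simulated
#' conditional-value distribution of a compound at each phase into a
#' parametric stand-in for portfolio work.
#'
#' @param mean,sd target mean and standard deviation (`mean > 0`,
#'   `sd >= 0`; `sd = 0` gives a point mass).
#' @return an `ov_lognormal`: list with `meanlog`, `sdlog`, `mean`, `sd`.
#' @examples
#' cal <- calibrate_lognormal(401.78, 96.35)
#' exp(cal$meanlog + cal$sdlog^2 / 2)   # recovers the mean
#' @export
calibrate_lognormal <- function(mean, sd) {
  if (!is.finite(mean) || mean <= 0)
    stop("log-normal calibration needs a positive mean", call. = FALSE)
  if (!is.finite(sd) || sd < 0)
    stop("log-normal calibration needs sd >= 0", call. = FALSE)
  s2 <- log(1 + sd^2 / mean^2)
  structure(list(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2),
                 mean = mean, sd = sd),
            class = "ov_lognormal")
}

# per-phase calibrations from a risk summary (conditional value moments)
calibration_from_summary <- function(summary) {
  stopifnot(inherits(summary, "ov_risk_summary"))
  lapply(seq_len(nrow(summary$by_phase)), function(k)
    calibrate_lognormal(summary$by_phase$mean_value[k],
                        summary$by_phase$sd_value[k]))
}

#' Loss probabilities under the log-normal value model
#'
#' A two-stage risk estimator: the conditional value of the compound at
#' each phase end is modeled as log-normal (calibrated by moment
#' matching from a full simulation, see [calibrate_lognormal()]), while
#' phase outcomes, durations and sunk development costs are re-simulated
#' as in [simulate_compound()]. Year-0 sale values are then the
#' discounted log-normal value draw minus the sunk outlays; failed paths
#' carry sunk outlays and no proceeds.
#'
#' This parametric treatment of the value distribution is the standard
#' shortcut for portfolio work, where only the value moments of each
#' compound are carried; modeling the value as log-normal thins the
#' (unrealistic) extreme-left tail that a normal approximation would
#' imply for a quantity that is bounded below by construction.
#'
#' @param scn a `scenario`.
#' @param calibration per-phase value distributions: an
#'   `ov_risk_summary`, or a list of `ov_lognormal` (one per phase).
#' @param n_paths,seed simulation controls.
#' @param basis accounting basis for sunk outlays, see
#'   [simulate_compound()].
#' @param convention discounting convention for the discounted basis.
#' @return list with `sale_loss` (per phase), `negative_overall`,
#'   `basis`, `n_paths`, `seed`.
#' @examples
#' scn <- scenario_fixture("rett_base")
#' paths <- simulate_compound(scn, 2000, seed = 1)
#' prof <- lognormal_loss_profile(scn, summarize_paths(paths), 2000, seed = 2)
#' @export
lognormal_loss_profile <- function(scn, calibration, n_paths = 10000, seed = 1,
                                   basis = c("invested", "discounted"),
                                   convention = c("annual", "continuous")) {
  stopifnot(inherits(scn, "scenario"), n_paths >= 1)
  basis <- match.arg(basis)
  convention <- match.arg(convention)
  if (inherits(calibration, "ov_risk_summary"))
    calibration <- calibration_from_summary(calibration)
  nph <- length(scn$plan)
  if (length(calibration) != nph)
    stop("need one value calibration per phase", call. = FALSE)

  set.seed(seed)
  pos <- vapply(scn$plan, `[[`, numeric(1), "pos")
  u <- matrix(runif(n_paths * nph), n_paths, nph)
  ch <- chain_from_uniforms(u, pos)
  inp <- draw_drug_inputs(scn, n_paths)
  V <- vapply(calibration, function(cal)
    rlnorm(n_paths, cal$meanlog, cal$sdlog), numeric(n_paths))

  lp <- lognormal_path_losses(scn, ch, inp, V, basis, convention)
  sale <- colMeans(lp$sale < 0)
  names(sale) <- vapply(scn$plan, `[[`, character(1), "name")
  list(sale_loss = sale, negative_overall = mean(lp$overall < 0),
       basis = basis, n_paths = n_paths, seed = seed)
}

# year-0 sale values and overall NPV when phase-end values are draws V
lognormal_path_losses <- function(scn, ch, inp, V, basis, convention) {
  cm <- scn$commercial
  r <- cm$discount_rate
  nph <- length(scn$plan)
  n <- nrow(inp$D)
  att <- ch$attempted; succ <- ch$succeeded
  ends <- inp$D
  for (k in seq_len(nph)) ends[, k] <- if (k == 1) inp$D[, 1] else ends[, k - 1] + inp$D[, k]
  starts <- cbind(0, ends[, -nph, drop = FALSE])
  load <- 1 + cm$prerevenue_sga_of_rnd
  sunk <- if (basis == "invested") {
    inp$C * load
  } else {
    m <- matrix(0, n, nph)
    for (k in seq_len(nph))
      m[, k] <- pv_stream(inp$C[, k] * load, starts[, k], ends[, k], r, convention)
    m
  }
  sunk_cum <- t(apply(sunk, 1, cumsum))
  if (nph == 1) sunk_cum <- sunk

  sale <- matrix(NA_real_, n, nph)
  for (k in seq_len(nph)) {
    s <- numeric(n)
    for (j in seq_len(k)) {
      fj <- att[, j] & !succ[, j]
      s[fj] <- -sunk_cum[fj, j]
    }
    ck <- att[, k] & succ[, k]
    s[ck] <- V[ck, k] * (1 + r)^(-ends[ck, k]) - sunk_cum[ck, k]
    sale[, k] <- s
  }
  overall <- sale[, nph]   # sell at approval, at the approved-compound value
  list(sale = sale, overall = overall, ends = ends)
}
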
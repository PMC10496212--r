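#' Risk-adjusted net present value of a development scenario
#'
#' Computes the deterministic rNPV of a compound at project start and
#' the conditional value at the end of each development phase. Cash
#' flows are risk-weighted by the probability of reaching them:
#' a phase's outflow (its development cost plus the pre-revenue SG&A
#' load) is weighted by the probability of arriving at that phase, the
#' commercial revenue stream by the cumulative probability of approval.
#' Outflows accrue uniformly over their phase; revenue is earned for the
#' exclusivity period after launch, ramping to peak adoption.
#'
#' `value_after_phase[k]` is the value of the remaining project at the
#' end of phase k, conditional on having just completed phase k
#' successfully: later cash flows are reweighted by conditional arrival
#' probabilities and re-discounted to that time.
#'
#' When the scenario's `include_tax_credit` / `include_prv` flags are
#' set, the corresponding add-ons (see [apply_tax_credit()] and
#' [apply_prv()]) are folded into the overall value.
#'
#' @param scn a `scenario`.
#' @param durations,costs optional per-phase overrides (defaults: modal
#'   values of each phase's three-point estimate).
#' @param price,peak_rate optional commercial overrides.
#' @param discount_rate optional override of the scenario's rate.
#' @param convention `"annual"` (calendar-year buckets discounted at
#'   year end; the calibrated default) or `"continuous"` (exact
#'   uniform-stream discounting).
#' @return an `ov_valuation`: list with `rnpv_overall` ($M at time 0),
#'   `value_after_phase` ($M at each phase end), `components` (risk-
#'   adjusted cost and revenue PVs, add-ons), `timeline`, and the
#'   conventions used.
#' @examples
#' scn <- scenario_fixture("rett_base")
#' v <- rnpv(scn)
#' v$rnpv_overall                      # ~14.2 $M
#' rnpv(scn, discount_rate = 0.11)$rnpv_overall   # ~23.3 $M
#' @export
rnpv <- function(scn, durations = NULL, costs = NULL, price = NULL,
                 peak_rate = NULL, discount_rate = NULL,
                 convention = c("annual", "continuous")) {
  stopifnot(inherits(scn, "scenario"))
  convention <- match.arg(convention)
  cm <- scn$commercial
  r <- discount_rate %||% cm$discount_rate
  nph <- length(scn$plan)
  durations <- durations %||% vapply(scn$plan, function(p) p$duration[2], numeric(1))
  costs <- costs %||% vapply(scn$plan, function(p) p$cost[2], numeric(1))
  stopifnot(length(durations) == nph, length(costs) == nph)
  price <- price %||% cm$price
  peak <- peak_rate %||% cm$adoption$peak_rate

  ends <- cumsum(durations)
  starts <- c(0, ends[-nph])
  launch <- ends[nph]
  excl <- exclusivity_at(cm, launch)

  pos <- vapply(scn$plan, `[[`, numeric(1), "pos")
  arr <- c(1, cumprod(pos))   # arr[k] = P(reach phase k); arr[nph+1] = P(approval)

  outflow <- costs * (1 + cm$prerevenue_sga_of_rnd)
  pv_cost <- vapply(seq_len(nph), function(k)
    pv_stream(outflow[k], starts[k], ends[k], r, convention), numeric(1))
  pv_rev <- pv_revenue(peak_atcf(cm, price, peak), cm$adoption$ramp,
                       launch, excl, r, convention)

  overall <- -sum(arr[seq_len(nph)] * pv_cost) + arr[nph + 1] * pv_rev

  value_after <- vapply(seq_len(nph), function(k) {
    if (arr[k + 1] == 0) return(NA_real_)
    val <- arr[nph + 1] / arr[k + 1] * pv_rev
    if (k < nph) {
      future <- (k + 1):nph
      val <- val - sum(arr[future] / arr[k + 1] * pv_cost[future])
    }
    val * (1 + r)^(ends[k])
  }, numeric(1))
  names(value_after) <- vapply(scn$plan, `[[`, character(1), "name")

  out <- structure(list(
    scenario = scn$name,
    rnpv_overall = overall,
    value_after_phase = value_after,
    components = list(cost_pv = pv_cost, cost_pv_risk_adjusted = arr[seq_len(nph)] * pv_cost,
                      revenue_pv = pv_rev,
                      revenue_pv_risk_adjusted = arr[nph + 1] * pv_rev,
                      addons = list()),
    timeline = list(phase_starts = starts, phase_ends = ends,
                    launch = launch, exclusivity = excl),
    inputs = list(durations = durations, costs = costs, price = price,
                  peak_rate = peak, discount_rate = r),
    convention = convention
  ), class = "ov_valuation")

  if (scn$include_tax_credit) out <- apply_tax_credit(out, scn)
  if (scn$include_prv) out <- apply_prv(out, scn)
  out
}

# exclusivity window at a given launch date: patent life net of the
# development time, floored at the regulatory exclusivity minimum
exclusivity_at <- function(cm, launch) {
  if (is.null(cm$patent_term_years)) return(cm$exclusivity_years)
  max(cm$patent_term_years - launch, cm$orphan_exclusivity_years)
}

# after-tax cash flow at full peak adoption, $M/year
peak_atcf <- function(cm, price, peak_rate) {
  pc <- patient_counts(cm$adoption$groups)
  mult <- vapply(cm$adoption$groups, `[[`, numeric(1), "multiplier")
  treated <- sum(pc$patients * mult) * peak_rate
  after_tax_cashflow(treated, price, cm) / 1e6
}

#' Add-on benefits: R&D tax credit and priority review voucher
#'
#' `apply_tax_credit()` adds back `tax_credit_rate` times the
#' risk-adjusted present value of development costs through the last
#' pre-submission phase (the credit applies to the R&D cost itself, not
#' the SG&A load). `apply_prv()` adds the expected discounted value of a
#' priority review voucher granted during development year `prv_year`:
#' the voucher value is risk-weighted by the probability of successfully
#' completing the phase in progress during that year and monetized at
#' the start of the year.
#'
#' @param result an `ov_valuation` from [rnpv()].
#' @param scn the scenario it was computed from.
#' @return the updated `ov_valuation` (overall value increased; the
#'   add-on recorded under `components$addons`).
#' @export
apply_tax_credit <- function(result, scn) {
  stopifnot(inherits(result, "ov_valuation"), inherits(scn, "scenario"))
  if (!is.null(result$components$addons$tax_credit))
    stop("tax credit already applied to this result", call. = FALSE)
  cm <- scn$commercial
  nph <- length(scn$plan)
  eligible <- seq_len(max(nph - 1, 1))   # through the last pre-submission phase
  r <- result$inputs$discount_rate
  arr <- arrival_probabilities(scn$plan)
  tl <- result$timeline
  pv_rnd <- vapply(eligible, function(k)
    pv_stream(result$inputs$costs[k], tl$phase_starts[k], tl$phase_ends[k],
              r, result$convention), numeric(1))
  credit <- cm$tax_credit_rate * sum(arr[eligible] * pv_rnd)
  result$components$addons$tax_credit <- credit
  result$rnpv_overall <- result$rnpv_overall + credit
  result
}

#' @rdname apply_tax_credit
#' @export
apply_prv <- function(result, scn) {
  stopifnot(inherits(result, "ov_valuation"), inherits(scn, "scenario"))
  if (!is.null(result$components$addons$prv))
    stop("voucher already applied to this result", call. = FALSE)
  cm <- scn$commercial
  if (cm$prv_value == 0) return(result)
  if (is.na(cm$prv_year)) stop("scenario has no prv_year", call. = FALSE)
  tl <- result$timeline
  if (cm$prv_year > ceiling(tl$launch))
    stop(sprintf("prv_year %g lies beyond the development timeline (launch at %g years)",
                 cm$prv_year, tl$launch), call. = FALSE)
  # phase in progress during calendar year prv_year
  k <- which(tl$phase_starts < cm$prv_year & cm$prv_year <= tl$phase_ends)[1]
  pos <- vapply(scn$plan, `[[`, numeric(1), "pos")
  p_complete <- prod(pos[seq_len(k)])
  r <- result$inputs$discount_rate
  addon <- p_complete * cm$prv_value * (1 + r)^(-(cm$prv_year - 1))
  result$components$addons$prv <- addon
  result$rnpv_overall <- result$rnpv_overall + addon
  result
}

#' @export
print.ov_valuation <- function(x, ...) {
  cat(sprintf("<rNPV valuation: %s (%s discounting, r = %.1f%%)>\n",
              x$scenario, x$convention, 100 * x$inputs$discount_rate))
  cat(sprintf("  overall rNPV at project start: %.1f $M\n", x$rnpv_overall))
  for (ad in names(x$components$addons))
    cat(sprintf("    includes %s: +%.1f $M\n", ad, x$components$addons[[ad]]))
  cat("  conditional value at end of each phase ($M):\n")
  va <- x$value_after_phase
  for (i in seq_along(va))
    cat(sprintf("    %-45s %8.1f\n", names(va)[i], va[i]))
  invisible(x)
}
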
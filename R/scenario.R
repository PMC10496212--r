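#' Development-phase assumptions
#'
#' `phase_spec()` describes one development phase: its probability of
#' success and three-point (min / mode / max) estimates of out-of-pocket
#' cost (in $M) and duration (in years). `phase_plan()` strings phases
#' together in development order. The shipped fixtures use the four-phase
#' consolidation typical of repurposed compounds filed under an
#' abbreviated pathway (discovery through phase 1 collapsed into one
#' phase, then phase 2, phase 3, and regulatory submission-to-launch),
#' but the engine accepts any ordered phase list.
#'
#' @param name phase label.
#' @param pos probability of success, in (0, 1].
#' @param cost numeric triple `c(min, mode, max)`, $M.
#' @param duration numeric triple `c(min, mode, max)`, years.
#' @return `phase_spec()` a `phase_spec` object; `phase_plan()` a
#'   `phase_plan` (list of phases).
#' @examples
#' p <- phase_spec("phase 2", 0.53, c(9, 14, 40), c(1, 2, 3))
#' @export
phase_spec <- function(name, pos, cost, duration) {
  if (!is.character(name) || length(name) != 1L)
    stop_field("name", "must be a single string")
  check_number(pos, paste0(name, ".pos"), 0, 1, strict_lo = TRUE)
  check_triple(cost, paste0(name, ".cost"))
  check_triple(duration, paste0(name, ".duration"), strictly_positive = TRUE)
  structure(list(name = name, pos = pos,
                 cost = as.numeric(cost), duration = as.numeric(duration)),
            class = "phase_spec")
}

check_triple <- function(x, field, strictly_positive = FALSE) {
  if (!is.numeric(x) || length(x) != 3L || any(!is.finite(x)))
    stop_field(field, "must be a numeric triple c(min, mode, max)")
  if (!(x[1] <= x[2] && x[2] <= x[3]))
    stop_field(field, sprintf("needs min <= mode <= max, got (%g, %g, %g)",
                              x[1], x[2], x[3]))
  lo_ok <- if (strictly_positive) x[1] > 0 else x[1] >= 0
  if (!lo_ok) stop_field(field, "values must be positive")
  invisible(x)
}

#' @rdname phase_spec
#' @param ... `phase_spec` objects (or a single list of them).
#' @export
phase_plan <- function(...) {
  phases <- list(...)
  if (length(phases) == 1L && !inherits(phases[[1]], "phase_spec"))
    phases <- phases[[1]]
  if (!length(phases)) stop("a phase plan needs at least one phase", call. = FALSE)
  for (p in phases)
    if (!inherits(p, "phase_spec")) stop("all elements must be phase_spec objects", call. = FALSE)
  structure(phases, class = "phase_plan")
}

#' Cumulative and per-phase arrival probabilities
#'
#' `cumulative_pos()` is the probability that a compound clears every
#' phase of the plan: the product of the per-phase success probabilities.
#' `arrival_probabilities()` gives, for each phase, the probability of
#' arriving at (i.e. starting) that phase: 1 for the first phase, then
#' the running product of the preceding success probabilities.
#'
#' @param plan a `phase_plan` (or a `scenario`, whose plan is used).
#' @return a single probability, or a vector with one entry per phase.
#' @examples
#' plan <- example_plan()
#' cumulative_pos(plan)          # ~0.23 for the base fixture
#' arrival_probabilities(plan)   # 1.00 0.67 0.36 0.25 (rounded)
#' @export
cumulative_pos <- function(plan) {
  plan <- as_plan(plan)
  prod(vapply(plan, `[[`, numeric(1), "pos"))
}

#' @rdname cumulative_pos
#' @export
arrival_probabilities <- function(plan) {
  plan <- as_plan(plan)
  pos <- vapply(plan, `[[`, numeric(1), "pos")
  out <- c(1, cumprod(pos)[-length(pos)])
  names(out) <- vapply(plan, `[[`, character(1), "name")
  out
}

as_plan <- function(x) {
  if (inherits(x, "scenario")) x <- x$plan
  if (!inherits(x, "phase_plan")) stop("expected a phase_plan or scenario", call. = FALSE)
  x
}

#' Patient population and adoption assumptions
#'
#' `age_group()` describes one age stratum of the addressable population:
#' its size (thousands of persons), disease prevalence (cases per 1,000)
#' and a peak-adoption multiplier relative to the reference (youngest)
#' group. `adoption_model()` combines the strata with the reference
#' group's peak adoption rate (with its 95% CI) and a ramp of per-year
#' fractions of peak; the ramp holds at its final value from the peak
#' year through the end of exclusivity.
#'
#' @param label group label.
#' @param population persons, thousands.
#' @param prevalence cases per 1,000 persons.
#' @param multiplier fraction of the reference group's peak rate, in \[0, 1\].
#' @export
age_group <- function(label, population, prevalence, multiplier) {
  check_number(population, paste0(label, ".population"), 0)
  check_number(prevalence, paste0(label, ".prevalence"), 0)
  check_fraction(multiplier, paste0(label, ".multiplier"))
  structure(list(label = label, population = population,
                 prevalence = prevalence, multiplier = multiplier),
            class = "age_group")
}

#' @rdname age_group
#' @param peak_rate peak adoption fraction for the reference group.
#' @param peak_rate_lo,peak_rate_hi 95% CI bounds on `peak_rate`.
#' @param ramp per-year fractions of peak adoption (year 1, 2, ...);
#'   values in \[0, 1\], held at the last value afterwards.
#' @param groups list of `age_group` objects.
#' @export
adoption_model <- function(peak_rate, peak_rate_lo, peak_rate_hi, ramp, groups) {
  check_fraction(peak_rate, "adoption.peak_rate")
  check_fraction(peak_rate_lo, "adoption.peak_rate_lo")
  check_fraction(peak_rate_hi, "adoption.peak_rate_hi")
  if (!(peak_rate_lo <= peak_rate && peak_rate <= peak_rate_hi))
    stop_field("adoption.peak_rate", "CI bounds must bracket the peak rate")
  if (!is.numeric(ramp) || !length(ramp) || any(ramp < 0 | ramp > 1))
    stop_field("adoption.ramp", "must be fractions in [0, 1]")
  for (g in groups)
    if (!inherits(g, "age_group")) stop("groups must be age_group objects", call. = FALSE)
  structure(list(peak_rate = peak_rate, peak_rate_lo = peak_rate_lo,
                 peak_rate_hi = peak_rate_hi, ramp = as.numeric(ramp),
                 groups = groups),
            class = "adoption_model")
}

#' Commercial-stage assumptions
#'
#' Bundles everything that turns an approved compound into cash flows:
#' annual list price (with 95% CI), the adoption model, operating-cost
#' fractions of sales (COGS, SG&A, R&D), the pre-revenue SG&A load as a
#' share of development spend, the tax rate, exclusivity and patent
#' terms, the discount rate, and optional add-on benefits (R&D tax
#' credit through the last pre-submission phase, priority review
#' voucher).
#'
#' @param price annual list price, $ per patient per year.
#' @param price_lo,price_hi 95% CI bounds on `price`.
#' @param adoption an `adoption_model`.
#' @param cogs_frac,sga_frac,rnd_frac cost fractions of sales.
#' @param prerevenue_sga_of_rnd SG&A during development, as a fraction of
#'   each phase's development cost.
#' @param tax_rate corporate tax rate applied to positive operating income.
#' @param exclusivity_years revenue-earning years after launch.
#' @param patent_term_years patent life from project start; when supplied,
#'   the engine recomputes exclusivity as `patent_term_years - launch`,
#'   floored at `orphan_exclusivity_years`.
#' @param orphan_exclusivity_years regulatory exclusivity floor, years.
#' @param discount_rate annual discount rate.
#' @param tax_credit_rate credit rate on development costs through the
#'   last pre-submission phase.
#' @param prv_value priority review voucher value, $M.
#' @param prv_year calendar year of development in which the voucher is
#'   granted (monetized at the start of that year).
#' @param pdufa_waiver regulatory fee waiver, $M; metadata only — fixture
#'   costs are already net of it.
#' @export
commercial_model <- function(price, price_lo, price_hi, adoption,
                             cogs_frac, sga_frac, rnd_frac,
                             prerevenue_sga_of_rnd, tax_rate,
                             exclusivity_years, patent_term_years = NULL,
                             orphan_exclusivity_years = 7,
                             discount_rate,
                             tax_credit_rate = 0, prv_value = 0, prv_year = NA,
                             pdufa_waiver = 0) {
  check_number(price, "commercial.price", 0, strict_lo = TRUE)
  check_number(price_lo, "commercial.price_lo", 0)
  check_number(price_hi, "commercial.price_hi", 0)
  if (!(price_lo <= price && price <= price_hi))
    stop_field("commercial.price", "CI bounds must bracket the price")
  if (!inherits(adoption, "adoption_model"))
    stop_field("commercial.adoption", "must be an adoption_model")
  for (f in c("cogs_frac", "sga_frac", "rnd_frac", "prerevenue_sga_of_rnd",
              "tax_rate", "tax_credit_rate"))
    check_fraction(get(f), paste0("commercial.", f))
  if (cogs_frac + sga_frac + rnd_frac > 1)
    stop_field("commercial", "cost fractions of sales sum above 1")
  check_number(exclusivity_years, "commercial.exclusivity_years", 0, strict_lo = TRUE)
  if (!is.null(patent_term_years))
    check_number(patent_term_years, "commercial.patent_term_years", 0, strict_lo = TRUE)
  check_number(orphan_exclusivity_years, "commercial.orphan_exclusivity_years", 0)
  check_number(discount_rate, "commercial.discount_rate", 0, strict_lo = TRUE)
  check_number(prv_value, "commercial.prv_value", 0)
  structure(list(price = price, price_lo = price_lo, price_hi = price_hi,
                 adoption = adoption, cogs_frac = cogs_frac,
                 sga_frac = sga_frac, rnd_frac = rnd_frac,
                 prerevenue_sga_of_rnd = prerevenue_sga_of_rnd,
                 tax_rate = tax_rate,
                 exclusivity_years = exclusivity_years,
                 patent_term_years = patent_term_years,
                 orphan_exclusivity_years = orphan_exclusivity_years,
                 discount_rate = discount_rate,
                 tax_credit_rate = tax_credit_rate,
                 prv_value = prv_value, prv_year = prv_year,
                 pdufa_waiver = pdufa_waiver),
            class = "commercial_model")
}

#' Correlation settings
#'
#' @param phase23_time_cost_rho Gaussian-copula correlation applied
#'   pairwise among the durations and costs of the two pivotal clinical
#'   phases (phases 2 and 3 in the fixtures), in \[-1, 1\].
#' @param cross_drug_rho pairwise correlation of phase-success latent
#'   variables across drugs in a portfolio, in \[0, 1).
#' @export
correlation_settings <- function(phase23_time_cost_rho = 0.5,
                                 cross_drug_rho = 0.2) {
  check_number(phase23_time_cost_rho, "correlations.phase23_time_cost_rho", -1, 1)
  check_number(cross_drug_rho, "correlations.cross_drug_rho", 0, 1, strict_hi = TRUE)
  structure(list(phase23_time_cost_rho = phase23_time_cost_rho,
                 cross_drug_rho = cross_drug_rho),
            class = "correlation_settings")
}

#' Assemble a valuation scenario
#'
#' A `scenario` is a complete single-compound valuation case: the phase
#' plan, the commercial model, correlation settings, and flags selecting
#' optional add-on benefits.
#'
#' @param plan a `phase_plan`.
#' @param commercial a `commercial_model`.
#' @param correlations a `correlation_settings`.
#' @param include_tax_credit,include_prv logical flags; when set, the
#'   corresponding add-on is folded into [rnpv()] results.
#' @param name scenario label.
#' @return a `scenario` object.
#' @seealso [load_scenario()], [scenario_fixture()]
#' @export
scenario <- function(plan, commercial,
                     correlations = correlation_settings(),
                     include_tax_credit = FALSE, include_prv = FALSE,
                     name = "scenario") {
  if (!inherits(plan, "phase_plan")) stop_field("plan", "must be a phase_plan")
  if (!inherits(commercial, "commercial_model"))
    stop_field("commercial", "must be a commercial_model")
  if (!inherits(correlations, "correlation_settings"))
    stop_field("correlations", "must be correlation_settings")
  structure(list(name = name, plan = plan, commercial = commercial,
                 correlations = correlations,
                 include_tax_credit = isTRUE(include_tax_credit),
                 include_prv = isTRUE(include_prv)),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat(sprintf("<scenario: %s>\n", x$name))
  pos <- vapply(x$plan, `[[`, numeric(1), "pos")
  cat(sprintf("  %d phases, per-phase PoS: %s; cumulative PoS %.3f\n",
              length(x$plan), paste(format(pos), collapse = ", "),
              cumulative_pos(x$plan)))
  cat(sprintf("  price $%s/yr, discount rate %.0f%%, exclusivity %g y\n",
              format(x$commercial$price, big.mark = ","),
              100 * x$commercial$discount_rate,
              x$commercial$exclusivity_years))
  cat(sprintf("  add-ons: tax credit %s, PRV %s\n",
              if (x$include_tax_credit) "on" else "off",
              if (x$include_prv) "on" else "off"))
  invisible(x)
}

#' Phase-plan summary table
#'
#' One row per phase: success probability, arrival probability and the
#' three-point cost and duration estimates. Suitable for CSV export.
#'
#' @param plan a `phase_plan` or `scenario`.
#' @return a data.frame.
#' @export
phase_table <- function(plan) {
  plan <- as_plan(plan)
  data.frame(
    phase = vapply(plan, `[[`, character(1), "name"),
    pos = vapply(plan, `[[`, numeric(1), "pos"),
    arrival = unname(arrival_probabilities(plan)),
    cost_min = vapply(plan, function(p) p$cost[1], numeric(1)),
    cost_mode = vapply(plan, function(p) p$cost[2], numeric(1)),
    cost_max = vapply(plan, function(p) p$cost[3], numeric(1)),
    dur_min = vapply(plan, function(p) p$duration[1], numeric(1)),
    dur_mode = vapply(plan, function(p) p$duration[2], numeric(1)),
    dur_max = vapply(plan, function(p) p$duration[3], numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' @rdname cumulative_pos
#' @export
example_plan <- function() {
  scenario_fixture("rett_base")$plan
}
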
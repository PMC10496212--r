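#' One-way sensitivity analysis of the deterministic rNPV
#'
#' Recomputes [rnpv()] over a grid of values for one registered tunable,
#' holding every other assumption at its scenario value.
#'
#' Registered parameter names:
#' `"price"`, `"peak_adoption"`, `"discount_rate"`, `"exclusivity"`,
#' and the per-phase families `"pos_<k>"`, `"cost_<k>"` (modal cost) and
#' `"duration_<k>"` (modal duration), with `<k>` a phase index.
#'
#' @param scn a `scenario`.
#' @param param parameter name (see above).
#' @param values numeric grid.
#' @param convention discounting convention, see [rnpv()].
#' @return data.frame with columns `param`, `value`, `rnpv_overall`.
#' @examples
#' scn <- scenario_fixture("rett_base")
#' sensitivity_grid(scn, "discount_rate", c(0.13, 0.11))
#' @export
sensitivity_grid <- function(scn, param, values,
                             convention = c("annual", "continuous")) {
  stopifnot(inherits(scn, "scenario"))
  convention <- match.arg(convention)
  scn <- strip_flags(scn)
  out <- vapply(values, function(v)
    rnpv(set_scenario_param(scn, param, v), convention = convention)$rnpv_overall,
    numeric(1))
  data.frame(param = param, value = values, rnpv_overall = out,
             stringsAsFactors = FALSE)
}

set_scenario_param <- function(scn, param, value) {
  phase_of <- function(prefix) {
    k <- suppressWarnings(as.integer(sub(prefix, "", param)))
    if (is.na(k) || k < 1 || k > length(scn$plan))
      stop(sprintf("unknown sensitivity parameter '%s'", param), call. = FALSE)
    k
  }
  if (param == "price") {
    scn$commercial$price <- value
    scn$commercial$price_lo <- min(scn$commercial$price_lo, value)
    scn$commercial$price_hi <- max(scn$commercial$price_hi, value)
  } else if (param == "peak_adoption") {
    scn$commercial$adoption$peak_rate <- value
    scn$commercial$adoption$peak_rate_lo <- min(scn$commercial$adoption$peak_rate_lo, value)
    scn$commercial$adoption$peak_rate_hi <- max(scn$commercial$adoption$peak_rate_hi, value)
  } else if (param == "discount_rate") {
    scn$commercial$discount_rate <- value
  } else if (param == "exclusivity") {
    scn$commercial$exclusivity_years <- value
    scn$commercial$patent_term_years <- NULL   # direct override
  } else if (startsWith(param, "pos_")) {
    scn$plan[[phase_of("pos_")]]$pos <- value
  } else if (startsWith(param, "cost_")) {
    k <- phase_of("cost_")
    tr <- scn$plan[[k]]$cost
    scn$plan[[k]]$cost <- c(min(tr[1], value), value, max(tr[3], value))
  } else if (startsWith(param, "duration_")) {
    k <- phase_of("duration_")
    tr <- scn$plan[[k]]$duration
    scn$plan[[k]]$duration <- c(min(tr[1], value), value, max(tr[3], value))
  } else {
    stop(sprintf("unknown sensitivity parameter '%s'", param), call. = FALSE)
  }
  scn
}
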
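#' Addressable patient population by age group
#'
#' Patient counts per group are `population` (thousands of persons)
#' times `prevalence` (cases per 1,000), so the two unit factors cancel
#' and the result is a number of patients. Counts are carried unrounded;
#' round only for display.
#'
#' @param groups list of [age_group()] objects, or an [adoption_model()],
#'   or a `scenario`.
#' @return data.frame with one row per group plus a `total` attribute.
#' @examples
#' scn <- scenario_fixture("rett_base")
#' pc <- patient_counts(scn)
#' round(sum(pc$patients))   # total addressable patients
#' @export
patient_counts <- function(groups) {
  groups <- as_groups(groups)
  df <- data.frame(
    group = vapply(groups, `[[`, character(1), "label"),
    population = vapply(groups, `[[`, numeric(1), "population"),
    prevalence = vapply(groups, `[[`, numeric(1), "prevalence"),
    stringsAsFactors = FALSE
  )
  df$patients <- df$population * df$prevalence
  attr(df, "total") <- sum(df$patients)
  df
}

as_groups <- function(x) {
  if (inherits(x, "scenario")) x <- x$commercial$adoption
  if (inherits(x, "adoption_model")) x <- x$groups
  if (!is.list(x) || !all(vapply(x, inherits, logical(1), "age_group")))
    stop("expected age_group objects, an adoption_model, or a scenario", call. = FALSE)
  x
}

#' Treated patients in a given post-launch year
#'
#' Treated patients in group g, year y equal
#' `patients_g * peak_rate * multiplier_g * ramp(y)`, where the ramp is
#' the per-year fraction of peak adoption; beyond the ramp's length it
#' holds at its final value, so adoption plateaus from the peak year
#' through the end of exclusivity.
#'
#' @param adoption an [adoption_model()] (or a `scenario`).
#' @param year post-launch year (1-based). Vectorized.
#' @param peak_rate optional override of the model's peak adoption rate.
#' @return for a single year, a data.frame of per-group treated counts
#'   with a `total` attribute; for several years, a numeric vector of
#'   totals.
#' @examples
#' scn <- scenario_fixture("rett_base")
#' round(treated_patients(scn, year = 1:3))  # 1412 2825 4237
#' @export
treated_patients <- function(adoption, year, peak_rate = NULL) {
  if (inherits(adoption, "scenario")) adoption <- adoption$commercial$adoption
  if (!inherits(adoption, "adoption_model"))
    stop("expected an adoption_model or scenario", call. = FALSE)
  stopifnot(all(year >= 1))
  peak <- peak_rate %||% adoption$peak_rate
  pc <- patient_counts(adoption$groups)
  mult <- vapply(adoption$groups, `[[`, numeric(1), "multiplier")
  ramp <- adoption$ramp[pmin(year, length(adoption$ramp))]
  if (length(year) > 1L)
    return(vapply(ramp, function(f) sum(pc$patients * mult * peak * f), numeric(1)))
  df <- data.frame(group = pc$group,
                   treated = pc$patients * mult * peak * ramp,
                   stringsAsFactors = FALSE)
  attr(df, "total") <- sum(df$treated)
  df
}

#' After-tax cash flow from treated patients
#'
#' Revenue is `treated * price`; operating income nets out COGS, SG&A
#' and R&D as fractions of sales; tax applies only to positive operating
#' income (development losses carry no tax shield in this model).
#'
#' @param treated_total treated patients (vectorized).
#' @param price annual list price, $ per patient per year.
#' @param cm a [commercial_model()] (or a `scenario`).
#' @return after-tax cash flow in $ per year.
#' @export
after_tax_cashflow <- function(treated_total, price, cm) {
  if (inherits(cm, "scenario")) cm <- cm$commercial
  stopifnot(inherits(cm, "commercial_model"), all(treated_total >= 0))
  op_margin <- 1 - cm$cogs_frac - cm$sga_frac - cm$rnd_frac
  operating <- treated_total * price * op_margin
  ifelse(operating > 0, operating * (1 - cm$tax_rate), operating)
}

#' Per-year commercial revenue schedule
#'
#' Expands a scenario's market assumptions into a year-by-year table of
#' treated patients, gross revenue and after-tax cash flow over the
#' exclusivity window.
#'
#' @param scn a `scenario`.
#' @param years number of post-launch years; defaults to the scenario's
#'   exclusivity period (rounded up).
#' @param price,peak_rate optional overrides.
#' @param file optional path; when given the table is also written as CSV.
#' @return data.frame with columns `year`, one column per age group,
#'   `total_treated`, `gross_revenue`, `after_tax_cashflow` ($).
#' @examples
#' head(revenue_schedule(scenario_fixture("rett_base")), 3)
#' @export
revenue_schedule <- function(scn, years = NULL, price = NULL, peak_rate = NULL,
                             file = NULL) {
  stopifnot(inherits(scn, "scenario"))
  cm <- scn$commercial
  years <- years %||% ceiling(cm$exclusivity_years)
  price <- price %||% cm$price
  rows <- lapply(seq_len(years), function(y) {
    tp <- treated_patients(cm$adoption, y, peak_rate = peak_rate)
    tot <- attr(tp, "total")
    row <- c(list(year = y), as.list(setNames(tp$treated, make.names(tp$group))),
             list(total_treated = tot,
                  gross_revenue = tot * price,
                  after_tax_cashflow = after_tax_cashflow(tot, price, cm)))
    as.data.frame(row, check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
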
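#' Read and write scenario files
#'
#' Scenarios are stored as flat, explicitly-united YAML or JSON documents
#' (`schema: orphanval/scenario/v1`). Costs are in $M, durations in
#' years, price in $ per patient per year. Unknown keys are rejected and
#' every structural invariant is checked on load, so a scenario that
#' loads is valid by construction.
#'
#' @param path file path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @param scn a `scenario`.
#' @return `load_scenario()` returns a validated `scenario`;
#'   `save_scenario()` returns `path` invisibly.
#' @examples
#' scn <- scenario_fixture("rett_base")
#' f <- tempfile(fileext = ".yaml")
#' save_scenario(scn, f)
#' identical_fields <- all.equal(load_scenario(f), scn)
#' @export
load_scenario <- function(path) {
  if (!file.exists(path)) stop(sprintf("scenario file not found: %s", path), call. = FALSE)
  doc <- read_doc(path)
  check_names(doc, c("schema", "name", "plan", "commercial", "correlations", "flags"),
              "scenario document")
  schema <- doc$schema %||% ""
  if (!identical(schema, "orphanval/scenario/v1"))
    stop_field("schema", sprintf("expected 'orphanval/scenario/v1', got '%s'", schema))
  if (is.null(doc$plan$phases)) stop_field("plan.phases", "missing")
  check_names(doc$plan, "phases", "plan")

  phases <- lapply(doc$plan$phases, function(p) {
    check_names(p, c("name", "pos", "cost", "duration"), "plan.phases[]")
    phase_spec(p$name %||% stop_field("phase.name", "missing"),
               p$pos %||% stop_field("phase.pos", "missing"),
               triple_from(p$cost, "cost"), triple_from(p$duration, "duration"))
  })

  cm <- doc$commercial
  check_names(cm, c("price", "price_ci", "adoption", "cogs_frac", "sga_frac",
                    "rnd_frac", "prerevenue_sga_of_rnd", "tax_rate",
                    "exclusivity_years", "patent_term_years",
                    "orphan_exclusivity_years", "discount_rate",
                    "tax_credit_rate", "prv_value", "prv_year", "pdufa_waiver"),
              "commercial")
  ad <- cm$adoption
  check_names(ad, c("peak_rate", "peak_rate_ci", "ramp", "groups"), "commercial.adoption")
  groups <- lapply(ad$groups, function(g) {
    check_names(g, c("label", "population", "prevalence", "multiplier"),
                "adoption.groups[]")
    age_group(g$label, g$population, g$prevalence, g$multiplier)
  })
  adoption <- adoption_model(ad$peak_rate,
                             ad$peak_rate_ci[[1]], ad$peak_rate_ci[[2]],
                             unlist(ad$ramp), groups)
  commercial <- commercial_model(
    price = cm$price, price_lo = cm$price_ci[[1]], price_hi = cm$price_ci[[2]],
    adoption = adoption,
    cogs_frac = cm$cogs_frac, sga_frac = cm$sga_frac, rnd_frac = cm$rnd_frac,
    prerevenue_sga_of_rnd = cm$prerevenue_sga_of_rnd, tax_rate = cm$tax_rate,
    exclusivity_years = cm$exclusivity_years,
    patent_term_years = cm$patent_term_years,
    orphan_exclusivity_years = cm$orphan_exclusivity_years %||% 7,
    discount_rate = cm$discount_rate,
    tax_credit_rate = cm$tax_credit_rate %||% 0,
    prv_value = cm$prv_value %||% 0, prv_year = cm$prv_year %||% NA,
    pdufa_waiver = cm$pdufa_waiver %||% 0)

  co <- doc$correlations %||% list()
  check_names(co, c("phase23_time_cost_rho", "cross_drug_rho"), "correlations")
  correlations <- correlation_settings(co$phase23_time_cost_rho %||% 0.5,
                                       co$cross_drug_rho %||% 0.2)

  fl <- doc$flags %||% list()
  check_names(fl, c("include_tax_credit", "include_prv"), "flags")

  scenario(phase_plan(phases), commercial, correlations,
           include_tax_credit = fl$include_tax_credit %||% FALSE,
           include_prv = fl$include_prv %||% FALSE,
           name = doc$name %||% sub("\\.[^.]+$", "", basename(path)))
}

triple_from <- function(x, field) {
  if (is.list(x)) {
    check_names(x, c("min", "mode", "max"), field)
    x <- c(x$min, x$mode, x$max)
  }
  if (length(x) != 3L) stop_field(field, "needs min / mode / max")
  as.numeric(x)
}

read_doc <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = FALSE)
  else stop(sprintf("unsupported scenario format '.%s'", ext), call. = FALSE)
}

#' @rdname load_scenario
#' @export
save_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "scenario"))
  doc <- list(
    schema = "orphanval/scenario/v1",
    name = scn$name,
    plan = list(phases = lapply(scn$plan, function(p) list(
      name = p$name, pos = p$pos,
      cost = list(min = p$cost[1], mode = p$cost[2], max = p$cost[3]),
      duration = list(min = p$duration[1], mode = p$duration[2], max = p$duration[3])
    ))),
    commercial = local({
      cm <- scn$commercial
      ad <- cm$adoption
      out <- list(
        price = cm$price, price_ci = c(cm$price_lo, cm$price_hi),
        adoption = list(
          peak_rate = ad$peak_rate,
          peak_rate_ci = c(ad$peak_rate_lo, ad$peak_rate_hi),
          ramp = ad$ramp,
          groups = lapply(ad$groups, function(g) list(
            label = g$label, population = g$population,
            prevalence = g$prevalence, multiplier = g$multiplier))),
        cogs_frac = cm$cogs_frac, sga_frac = cm$sga_frac, rnd_frac = cm$rnd_frac,
        prerevenue_sga_of_rnd = cm$prerevenue_sga_of_rnd, tax_rate = cm$tax_rate,
        exclusivity_years = cm$exclusivity_years,
        orphan_exclusivity_years = cm$orphan_exclusivity_years,
        discount_rate = cm$discount_rate,
        tax_credit_rate = cm$tax_credit_rate,
        prv_value = cm$prv_value, prv_year = cm$prv_year,
        pdufa_waiver = cm$pdufa_waiver)
      if (!is.null(cm$patent_term_years))
        out$patent_term_years <- cm$patent_term_years
      out
    }),
    correlations = list(
      phase23_time_cost_rho = scn$correlations$phase23_time_cost_rho,
      cross_drug_rho = scn$correlations$cross_drug_rho),
    flags = list(include_tax_credit = scn$include_tax_credit,
                 include_prv = scn$include_prv)
  )
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(doc, path, precision = 15)
  else if (ext == "json")
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  else stop(sprintf("unsupported scenario format '.%s'", ext), call. = FALSE)
  invisible(path)
}

#' Shipped scenario fixtures
#'
#' The package ships four ready-made scenarios for a repurposed
#' rare-disease (Rett syndrome) compound: the base case, lower- and
#' upper-bound parameter sets, and a follow-on ("me-too") variant with
#' elevated success probabilities.
#'
#' @param name one of `"rett_base"`, `"rett_lower"`, `"rett_upper"`,
#'   `"me_too"`, or the path of any scenario file.
#' @return a validated `scenario`.
#' @examples
#' scn <- scenario_fixture("rett_base")
#' cumulative_pos(scn)
#' @export
scenario_fixture <- function(name = c("rett_base", "rett_lower", "rett_upper", "me_too")) {
  if (file.exists(name[1])) return(load_scenario(name[1]))
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".yaml"), package = "orphanval",
                      mustWork = TRUE)
  load_scenario(path)
}
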
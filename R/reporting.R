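#' Run manifest
#'
#' Every report written by the package embeds a manifest identifying the
#' scenario (path and MD5 when read from a file), the seed, path count,
#' engine version and the convention flags in force, so any output can
#' be reproduced bit-for-bit from its manifest.
#'
#' @param scenario_path scenario file path, or `NA` for in-memory
#'   scenarios.
#' @param seed,n_paths simulation controls (may be `NA` for
#'   deterministic runs).
#' @param convention discounting convention.
#' @param upper_prob upper-bound percentile used in summaries.
#' @param loss_basis accounting basis of loss probabilities.
#' @param cross_drug_rho portfolio correlation assumption, if any.
#' @return named list (class `ov_manifest`).
#' @export
run_manifest <- function(scenario_path = NA, seed = NA, n_paths = NA,
                         convention = "annual", upper_prob = 0.95,
                         loss_basis = "invested", cross_drug_rho = NULL) {
  md5 <- if (!is.na(scenario_path) && file.exists(scenario_path))
    unname(tools::md5sum(scenario_path)) else NA
  m <- list(scenario_file = scenario_path, scenario_md5 = md5,
            seed = seed, n_paths = n_paths,
            engine_version = as.character(utils::packageVersion("orphanval")),
            conventions = list(discounting = convention,
                               upper_bound = sprintf("p%g", 100 * upper_prob),
                               loss_basis = loss_basis),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (!is.null(cross_drug_rho)) m$cross_drug_rho <- cross_drug_rho
  structure(m, class = "ov_manifest")
}

#' Render a risk summary as a CSV table
#'
#' Produces the standard phase-by-statistic report: one row per phase
#' plus an Overall row, monetary values in $M rounded to two decimals
#' (internal arithmetic is unrounded). The `"portfolio"` layout reports
#' aggregate loss probabilities and echoes the cross-drug correlation
#' assumption in the header.
#'
#' @param summary an `ov_risk_summary` or (for the portfolio layout) an
#'   `ov_portfolio`.
#' @param layout `"phases"` (per-phase conditional values and loss
#'   probabilities) or `"portfolio"`.
#' @param file optional output path; when given the CSV text is written
#'   there.
#' @return the CSV text, invisibly when written to a file.
#' @export
render_table <- function(summary, layout = c("phases", "portfolio"), file = NULL) {
  layout <- match.arg(layout)
  fmt <- function(x) ifelse(is.na(x), "NA", sprintf("%.2f", x))
  if (layout == "phases") {
    if (!inherits(summary, "ov_risk_summary"))
      stop("'phases' layout needs an ov_risk_summary", call. = FALSE)
    bp <- summary$by_phase
    hdr <- sprintf("# scenario: %s; paths: %d; seed: %s; units: $M",
                   summary$scenario, summary$n_paths, format(summary$seed))
    upper_lab <- sprintf("upper_p%g", 100 * summary$upper_prob)
    lines <- c(hdr,
               paste("phase", "expected_rnpv", "mean_rnpv", "sd_rnpv",
                     upper_lab, "prob_sale_loss", sep = ","),
               vapply(seq_len(nrow(bp)), function(i)
                 paste(csv_quote(bp$phase[i]), fmt(bp$expected_rnpv[i]),
                       fmt(bp$mean_value[i]), fmt(bp$sd_value[i]),
                       fmt(bp$upper_value[i]), sprintf("%.4f", bp$prob_sale_loss_inv[i]),
                       sep = ","), character(1)),
               paste("Overall", fmt(summary$overall$expected_rnpv),
                     fmt(summary$overall$mean_rnpv), fmt(summary$overall$sd_rnpv),
                     fmt(summary$overall$upper_rnpv),
                     sprintf("%.4f", summary$overall$prob_negative_inv), sep = ","))
  } else {
    if (!inherits(summary, "ov_portfolio"))
      stop("'portfolio' layout needs an ov_portfolio", call. = FALSE)
    s <- summary$summary
    hdr <- sprintf("# portfolio: %d drugs x %s; paths: %d; seed: %s; cross_drug_rho: %.4f (assumption); mode: %s",
                   summary$n_drugs, summary$scenario, summary$n_paths,
                   format(summary$seed), summary$cross_drug_rho, summary$mode)
    nph <- length(s$prob_sale_loss_dcf)
    lines <- c(hdr,
               "phase,mean_aggregate_value,prob_sale_loss_discounted,prob_sale_loss_invested",
               vapply(seq_len(nph), function(k)
                 paste(k, fmt(s$mean_value_after[k]),
                       sprintf("%.4f", s$prob_sale_loss_dcf[k]),
                       sprintf("%.4f", s$prob_sale_loss_inv[k]), sep = ","),
                 character(1)),
               paste("Overall", fmt(s$mean_overall_dcf),
                     sprintf("%.4f", s$prob_negative_dcf),
                     sprintf("%.4f", s$prob_negative_inv), sep = ","))
  }
  text <- paste(lines, collapse = "\n")
  if (!is.null(file)) {
    writeLines(text, file)
    return(invisible(text))
  }
  text
}

csv_quote <- function(x) {
  needs <- grepl("[,\"]", x)
  x[needs] <- paste0('"', gsub('"', '""', x[needs]), '"')
  x
}

#' Write a valuation result as a JSON report
#'
#' @param result an `ov_valuation` from [rnpv()].
#' @param file output path.
#' @param manifest an [run_manifest()] to embed.
#' @return `file`, invisibly.
#' @export
write_valuation_json <- function(result, file, manifest = run_manifest()) {
  stopifnot(inherits(result, "ov_valuation"))
  doc <- list(
    manifest = unclass(manifest),
    scenario = result$scenario,
    rnpv_overall = result$rnpv_overall,
    value_after_phase = as.list(result$value_after_phase),
    components = result$components,
    timeline = result$timeline,
    inputs = result$inputs,
    convention = result$convention)
  jsonlite::write_json(doc, file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(file)
}

#' Histogram-ready CSV export
#'
#' Bins a simulated value vector into fixed-width intervals and writes
#' (or returns) the bin table, so plotting tools can reproduce the
#' distribution without the raw paths.
#'
#' @param x numeric vector (e.g. a column of an `ov_paths`).
#' @param breaks number of bins or a vector of break points.
#' @param file optional output path.
#' @return data.frame with `bin_lo`, `bin_hi`, `count`.
#' @export
histogram_csv <- function(x, breaks = 50, file = NULL) {
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  out <- data.frame(bin_lo = head(h$breaks, -1), bin_hi = tail(h$breaks, -1),
                    count = h$counts)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}
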
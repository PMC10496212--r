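#' Summarize Monte Carlo paths into a risk report
#'
#' Per phase: the deterministic conditional rNPV at the phase end (from
#' [rnpv()] at modal assumptions), and the mean, standard deviation and
#' upper percentile of the simulated conditional value across paths that
#' completed the phase successfully; plus the probability of selling the
#' project at a loss at the end of that phase under both accounting
#' bases (see [simulate_compound()]). The "Overall" row summarizes the
#' per-path risk-adjusted overall rNPV and the probability of a negative
#' realized overall NPV.
#'
#' Statistics over an empty conditional set (no path completed the
#' phase) are reported as `NA`, not zero.
#'
#' @param paths an `ov_paths` from [simulate_compound()].
#' @param upper_prob percentile reported as the distribution's upper
#'   bound (default 0.95).
#' @return an `ov_risk_summary`: list with `by_phase` (data.frame),
#'   `overall` (list), `n_paths`, `seed`, `upper_prob`, `convention`.
#' @examples
#' paths <- simulate_compound(scenario_fixture("rett_base"), 2000, seed = 1)
#' summarize_paths(paths)
#' @export
summarize_paths <- function(paths, upper_prob = 0.95) {
  stopifnot(inherits(paths, "ov_paths"))
  scn <- attr(paths, "scenario")
  nph <- length(scn$plan)
  det <- rnpv(strip_flags(scn), convention = attr(paths, "convention"))

  stat_or_na <- function(x, f) if (length(x)) f(x) else NA_real_
  rows <- lapply(seq_len(nph), function(k) {
    ok <- paths[[paste0("succ_", k)]]
    v <- paths[[paste0("value_after_", k)]][ok]
    data.frame(
      phase = attr(paths, "phase_names")[k],
      expected_rnpv = det$value_after_phase[[k]],
      mean_value = stat_or_na(v, mean),
      sd_value = stat_or_na(v, sd),
      upper_value = stat_or_na(v, function(x) unname(quantile(x, upper_prob))),
      n_completed = sum(ok),
      prob_sale_loss_inv = mean(paths[[paste0("sale_inv_", k)]] < 0),
      prob_sale_loss_dcf = mean(paths[[paste0("sale_dcf_", k)]] < 0),
      stringsAsFactors = FALSE)
  })
  by_phase <- do.call(rbind, rows)

  overall <- list(
    expected_rnpv = det$rnpv_overall,
    mean_rnpv = mean(paths$overall_rnpv),
    sd_rnpv = sd(paths$overall_rnpv),
    upper_rnpv = unname(quantile(paths$overall_rnpv, upper_prob)),
    prob_negative_inv = mean(paths$overall_inv < 0),
    prob_negative_dcf = mean(paths$overall_dcf < 0))

  structure(list(by_phase = by_phase, overall = overall,
                 n_paths = nrow(paths), seed = attr(paths, "seed"),
                 upper_prob = upper_prob,
                 convention = attr(paths, "convention"),
                 scenario = scn$name),
            class = "ov_risk_summary")
}

strip_flags <- function(scn) {
  scn$include_tax_credit <- FALSE
  scn$include_prv <- FALSE
  scn
}

#' @export
print.ov_risk_summary <- function(x, ...) {
  cat(sprintf("<risk summary: %s, %d paths, seed %s>\n",
              x$scenario, x$n_paths, format(x$seed)))
  bp <- x$by_phase
  cat(sprintf("  %-45s %9s %9s %8s %9s\n", "phase", "expected", "mean",
              "sd", sprintf("p%d", round(100 * x$upper_prob))))
  for (i in seq_len(nrow(bp)))
    cat(sprintf("  %-45s %9.2f %9.2f %8.2f %9.2f\n", bp$phase[i],
                bp$expected_rnpv[i], bp$mean_value[i], bp$sd_value[i],
                bp$upper_value[i]))
  ov <- x$overall
  cat(sprintf("  %-45s %9.2f %9.2f %8.2f %9.2f\n", "Overall",
              ov$expected_rnpv, ov$mean_rnpv, ov$sd_rnpv, ov$upper_rnpv))
  cat(sprintf("  P(negative overall NPV): %.3f (invested) / %.3f (discounted)\n",
              ov$prob_negative_inv, ov$prob_negative_dcf))
  cat(sprintf("  P(sale at loss) by phase (invested): %s\n",
              paste(sprintf("%.3f", bp$prob_sale_loss_inv), collapse = " ")))
  invisible(x)
}

#' Empirical loss probabilities from simulated paths
#'
#' @param paths an `ov_paths`.
#' @param basis `"invested"` (outlays at face value) or `"discounted"`.
#' @return list with `sale_loss` (per-phase probability of a negative
#'   year-0 sale value) and `negative_overall`.
#' @export
loss_probabilities <- function(paths, basis = c("invested", "discounted")) {
  stopifnot(inherits(paths, "ov_paths"))
  basis <- match.arg(basis)
  suffix <- if (basis == "invested") "inv" else "dcf"
  nph <- length(attr(paths, "scenario")$plan)
  sale <- vapply(seq_len(nph), function(k)
    mean(paths[[paste0("sale_", suffix, "_", k)]] < 0), numeric(1))
  names(sale) <- attr(paths, "phase_names")
  list(sale_loss = sale,
       negative_overall = mean(paths[[paste0("overall_", suffix)]] < 0),
       basis = basis)
}
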
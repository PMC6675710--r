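# End-to-end report bundle: score, classify, concordance, outcomes, cost,
# written as CSV/JSON plus a short markdown summary. The thin command-line
# wrapper in inst/cli/romma.R exposes the same steps as subcommands.

#' Run the full analysis pipeline and write a report bundle
#'
#' Scores the cohort, classifies it, and writes: the scored cohort CSV, the
#' calls CSV, the category-frequency JSON, the band-agreement and screening
#' 2x2 concordance tables, outcome tables when outcome fields are present,
#' the cost summary, and a markdown overview. Identical inputs and config
#' produce identical outputs; inputs are never mutated.
#'
#' @param cohort A cohort data frame (see [read_cohort()]).
#' @param output_dir Directory to write into (created if needed).
#' @param equations,thresholds Scoring and classification rules.
#' @param scenario A [cost_scenario()]; its `frac_low`/`frac_high` are
#'   replaced by the cohort's realized fractions before extrapolation.
#' @param amms_cutoff,odx_cutoff Screening thresholds for the 2x2 table.
#' @return Invisibly, a list with every table in the bundle.
#' @export
run_report <- function(cohort, output_dir,
                       equations = magee_equations(),
                       thresholds = romma_thresholds(),
                       scenario = cost_scenario(),
                       amms_cutoff = 18, odx_cutoff = 26) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  validation <- validate_cohort(cohort)
  scored <- score_magee(cohort, equations, unscorable = "keep")
  calls <- romma_classify(dplyr::filter(scored, !is.na(.data$amms)),
                          thresholds)
  summ <- romma_summary(calls)

  write_cohort(scored, file.path(output_dir, "scored.csv"))
  readr::write_csv(
    dplyr::select(calls, dplyr::any_of(c(
      "case_id", "patient_id", "amms", "n_equations_used", "category",
      "histologic_low_risk", "predicted_odx_band", "send_for_odx",
      "rationale"))),
    file.path(output_dir, "calls.csv"))
  jsonlite::write_json(
    list(categories = summ,
         low_risk_total = attr(summ, "low_risk_total"),
         low_risk_total_pct = attr(summ, "low_risk_total_pct")),
    file.path(output_dir, "frequencies.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)

  out <- list(validation = validation, summary = summ)

  if ("odx_rs" %in% names(calls) && any(!is.na(calls$odx_rs))) {
    agreement <- band_agreement(calls, thresholds = thresholds)
    tab <- two_by_two(calls, amms_cutoff, odx_cutoff)
    metrics <- diagnostic_metrics(tab)
    disc <- discordance_report(calls)
    readr::write_csv(agreement, file.path(output_dir, "band_agreement.csv"))
    readr::write_csv(glance(metrics), file.path(output_dir, "screening_metrics.csv"))
    readr::write_csv(
      dplyr::count(disc, .data$discordance),
      file.path(output_dir, "discordance.csv"))
    out$band_agreement <- agreement
    out$screening <- metrics
    out$discordance <- disc
  }

  if ("recurred" %in% names(calls) && any(!is.na(calls$recurred))) {
    patients <- collapse_to_patients(calls)
    strata <- recurrence_by_stratum(patients, .data$category)
    readr::write_csv(strata, file.path(output_dir, "recurrence_by_category.csv"))
    out$recurrence <- strata
  }

  scenario$frac_low <- attr(summ, "low_risk_total") / nrow(calls)
  scenario$frac_high <- sum(calls$category == "high_risk") / nrow(calls)
  scenario$cohort_n <- nrow(calls)
  n_avoided <- attr(summ, "low_risk_total") +
    sum(calls$category == "high_risk")
  cost <- tibble(
    n_avoided = n_avoided,
    institutional_savings_usd = institutional_savings(
      n_avoided, scenario$list_price_usd)
  )
  cost <- dplyr::bind_cols(cost, national_extrapolation(scenario))
  readr::write_csv(cost, file.path(output_dir, "cost_summary.csv"))
  out$cost <- cost

  md <- c(
    "# RoMMa report", "",
    sprintf("Cases: %d (%d usable, %d flagged)", validation$n,
            validation$n_usable, validation$n_flagged),
    sprintf("Low risk (incl. lowest): %d (%.1f%%); high risk: %d (%.1f%%)",
            attr(summ, "low_risk_total"), attr(summ, "low_risk_total_pct"),
            summ$n[summ$category == "high_risk"],
            summ$pct[summ$category == "high_risk"]),
    sprintf("Send-out avoided: %d cases, institutional savings $%s",
            n_avoided, format(cost$institutional_savings_usd[1],
                              big.mark = ",", scientific = FALSE)),
    ""
  )
  writeLines(md, file.path(output_dir, "report.md"))
  invisible(out)
}
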
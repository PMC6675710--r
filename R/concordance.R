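# Agreement between the average modified Magee score and the Oncotype DX
# recurrence score: cumulative band-agreement tables, 2x2 diagnostic
# accuracy with Fisher exact association, discordance grading, and
# population-comparison tests.

#' Oncotype DX recurrence-score bands
#'
#' The standard ODX risk bands: low (< 18), intermediate (18-30), high
#' (> 30); < 26 is the TAILORx lower-risk band and < 11 the band the AJCC
#' prognostic-stage rule uses.
#'
#' @param odx_rs Integer vector of recurrence scores in 0-100.
#' @return Factor with levels `low`, `intermediate`, `high`.
#' @export
odx_band <- function(odx_rs) {
  bad <- !is.na(odx_rs) & (odx_rs < 0 | odx_rs > 100)
  if (any(bad)) abort("odx_rs must be in [0, 100]")
  cut(odx_rs, breaks = c(-Inf, 17.5, 30.5, Inf),
      labels = c("low", "intermediate", "high"))
}

#' Cumulative band-agreement table
#'
#' For a sequence of cumulative amMs groups (at or below rising cutoffs, as
#' reported for the validation of the algorithm), counts the ODX risk bands
#' within each group and the percent falling in the concordant band: ODX low
#' for the low-score groups, ODX high for the amMs > 30 group. A row for the
#' histologic low-risk criterion is included when the cohort carries the
#' histologic inputs. Cases without an ODX score are excluded and counted in
#' the `n_excluded` attribute.
#'
#' @param scored A scored cohort with `amms` and `odx_rs` (and the histologic
#'   columns for the histologic row).
#' @param groups Named numeric vector of cutoffs; names ending `<` mark a
#'   strict cutoff. Default mirrors the usual report: `<9`, `<=10`, `<=11`,
#'   `<=12`, `<=14`, `<=15`, `<18`, histologic criteria, `>30`.
#' @param thresholds [romma_thresholds()], for the histologic row and the
#'   high cutoff.
#' @return A tibble with `group`, `n`, `odx_high`, `odx_intermediate`,
#'   `odx_low`, `pct_concordant`.
#' @export
#' @examples
#' band_agreement(example_validation_scores())
band_agreement <- function(scored,
                           groups = c("amMs <9" = 9, "amMs <=10" = 10,
                                      "amMs <=11" = 11, "amMs <=12" = 12,
                                      "amMs <=14" = 14, "amMs <=15" = 15,
                                      "amMs <18" = 18),
                           thresholds = romma_thresholds()) {
  scored <- as_tibble(scored)
  if (!all(c("amms", "odx_rs") %in% names(scored))) {
    abort("band_agreement needs columns amms and odx_rs")
  }
  n_excluded <- sum(is.na(scored$odx_rs) | is.na(scored$amms))
  scored <- dplyr::filter(scored, !is.na(.data$odx_rs), !is.na(.data$amms))
  if (nrow(scored) == 0) abort("no cases with paired amms and odx_rs")
  band <- odx_band(scored$odx_rs)

  row_for <- function(label, sel, concordant_band) {
    counts <- table(band[sel])
    n <- sum(sel)
    tibble(
      group = label, n = n,
      odx_high = as.integer(counts[["high"]]),
      odx_intermediate = as.integer(counts[["intermediate"]]),
      odx_low = as.integer(counts[["low"]]),
      pct_concordant = if (n == 0) NA_real_ else
        100 * as.integer(counts[[concordant_band]]) / n
    )
  }

  strict <- grepl("<[0-9]", names(groups)) & !grepl("<=", names(groups))
  rows <- purrr::pmap(
    list(names(groups), unname(groups), strict),
    function(label, cutoff, is_strict) {
      sel <- if (is_strict) scored$amms < cutoff else scored$amms <= cutoff
      row_for(label, sel, "low")
    }
  )
  rows <- dplyr::bind_rows(rows)

  if (all(c("nottingham_score", "er_h_score", "pr_h_score", "ki67_pct") %in%
          names(scored))) {
    hist_sel <- as.logical(histologic_low_risk(scored, thresholds))
    rows <- dplyr::bind_rows(
      rows, row_for("histologic low risk", hist_sel, "low"))
  }
  rows <- dplyr::bind_rows(
    rows,
    row_for(sprintf("amMs >%s", thresholds$high_cutoff),
            scored$amms > thresholds$high_cutoff, "high")
  )
  attr(rows, "n_excluded") <- n_excluded
  rows
}

#' Build a 2x2 contingency table from paired scores
#'
#' Cross-classifies cases by the surrogate test rule (amMs at or below
#' `amms_cutoff`) against the reference rule (ODX RS strictly below
#' `odx_cutoff`). With the defaults this is the screening question "does an
#' amMs of 18 or less predict an ODX recurrence score under 26?"; tp counts
#' cases positive on both.
#'
#' @param scored A data frame with `amms` and `odx_rs`.
#' @param amms_cutoff Test rule: positive iff `amms <= amms_cutoff`.
#' @param odx_cutoff Reference rule: positive iff `odx_rs < odx_cutoff`.
#' @return A `contingency_2x2` object (named integer counts tp, fp, fn, tn
#'   with the rules recorded as attributes).
#' @export
#' @examples
#' two_by_two(example_screening_scores())
two_by_two <- function(scored, amms_cutoff = 18, odx_cutoff = 26) {
  scored <- dplyr::filter(as_tibble(scored),
                          !is.na(.data$amms), !is.na(.data$odx_rs))
  if (nrow(scored) == 0) abort("no cases with paired amms and odx_rs")
  test <- scored$amms <= amms_cutoff
  ref <- scored$odx_rs < odx_cutoff
  contingency_2x2(
    tp = sum(test & ref), fp = sum(test & !ref),
    fn = sum(!test & ref), tn = sum(!test & !ref),
    test_label = sprintf("amMs <= %s", amms_cutoff),
    ref_label = sprintf("ODX RS < %s", odx_cutoff)
  )
}

#' @param tp,fp,fn,tn Non-negative integer cell counts (rows = test
#'   condition, columns = reference condition).
#' @param test_label,ref_label Optional labels for printing.
#' @rdname two_by_two
#' @export
contingency_2x2 <- function(tp, fp, fn, tn, test_label = "test+",
                            ref_label = "reference+") {
  cells <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != round(cells))) {
    abort("2x2 cells must be non-negative integers")
  }
  if (sum(cells) == 0) abort("all-zero 2x2 table")
  structure(as.integer(round(cells)),
            names = names(cells),
            test_label = test_label, ref_label = ref_label,
            class = "contingency_2x2")
}

#' @export
print.contingency_2x2 <- function(x, ...) {
  m <- matrix(unclass(x)[c("tp", "fp", "fn", "tn")], 2, 2, byrow = TRUE,
              dimnames = list(
                c(attr(x, "test_label"), "complement"),
                c(attr(x, "ref_label"), "complement")))
  print(m)
  invisible(x)
}

#' Diagnostic accuracy metrics for a 2x2 table
#'
#' Sensitivity tp/(tp+fn), specificity tn/(fp+tn), PPV tp/(tp+fp), NPV
#' tn/(fn+tn), the cross-product odds ratio (tp*tn)/(fp*fn), a two-sided
#' Fisher exact p-value for association, and a Woolf (log-normal) 95% CI for
#' the odds ratio. A zero off-diagonal product yields an infinite (or zero)
#' odds ratio, reported as such with a note rather than silently adjusted.
#'
#' @param table A `contingency_2x2` from [two_by_two()] or
#'   [contingency_2x2()].
#' @return An object of class `diagnostic_metrics`; use [tidy()] for a
#'   metric/estimate tibble or [glance()] for a one-row summary.
#' @export
#' @examples
#' diagnostic_metrics(contingency_2x2(524, 13, 233, 133))
diagnostic_metrics <- function(table) {
  stopifnot(inherits(table, "contingency_2x2"))
  tp <- table[["tp"]]; fp <- table[["fp"]]
  fn <- table[["fn"]]; tn <- table[["tn"]]
  rate <- function(num, den) if (den == 0) NA_real_ else num / den
  or_note <- NULL
  if (fp * fn == 0 && tp * tn == 0) {
    or <- NA_real_
    or_note <- "odds ratio undefined (zero numerator and denominator)"
  } else if (fp * fn == 0) {
    or <- Inf
    or_note <- "infinite odds ratio: zero discordant product (fp*fn = 0)"
  } else {
    or <- (tp * tn) / (fp * fn)
    if (tp * tn == 0) or_note <- "zero odds ratio: tp*tn = 0"
  }
  m <- matrix(c(tp, fn, fp, tn), 2, 2)
  fisher_p <- fisher.test(m)$p.value
  ci <- if (all(c(tp, fp, fn, tn) > 0)) {
    se <- sqrt(1 / tp + 1 / fp + 1 / fn + 1 / tn)
    exp(log(or) + c(-1, 1) * 1.96 * se)
  } else {
    c(NA_real_, NA_real_)
  }
  structure(
    list(
      table = table,
      sensitivity = rate(tp, tp + fn),
      specificity = rate(tn, fp + tn),
      ppv = rate(tp, tp + fp),
      npv = rate(tn, fn + tn),
      odds_ratio = or,
      or_ci95 = ci,
      p_value = fisher_p,
      note = or_note
    ),
    class = "diagnostic_metrics"
  )
}

#' @export
print.diagnostic_metrics <- function(x, ...) {
  print(x$table)
  cat(sprintf(
    "Sensitivity: %.3f\nSpecificity: %.3f\nPositive predictive value: %.3f\nNegative predictive value: %.3f\nOdds ratio: %.1f (95%% CI %.1f-%.1f), Fisher exact P = %.3g\n",
    x$sensitivity, x$specificity, x$ppv, x$npv, x$odds_ratio,
    x$or_ci95[1], x$or_ci95[2], x$p_value))
  if (!is.null(x$note)) cat("Note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Grade amMs vs ODX discordance case by case
#'
#' Places the amMs and the ODX recurrence score each into the ODX risk bands
#' (low < 18, intermediate 18-30, high > 30) and grades each case
#' concordant, one-step, or two-step discordant (low on one system, high on
#' the other). Two-step cases are the clinically alarming ones and carry the
#' full record for review.
#'
#' @param scored A data frame with `amms` and `odx_rs`.
#' @return A tibble with `amms_band`, `odx_band`, `steps`, and `discordance`
#'   (`concordant` / `one_step` / `two_step`); attribute `two_step_cases`
#'   holds the full rows of two-step cases.
#' @export
discordance_report <- function(scored) {
  scored <- dplyr::filter(as_tibble(scored),
                          !is.na(.data$amms), !is.na(.data$odx_rs))
  band_of_amms <- factor(
    dplyr::case_when(scored$amms < 18 ~ "low",
                     scored$amms > 30 ~ "high",
                     .default = "intermediate"),
    levels = c("low", "intermediate", "high"))
  out <- scored
  out$amms_band <- band_of_amms
  out$odx_band <- odx_band(scored$odx_rs)
  out$steps <- abs(as.integer(out$amms_band) - as.integer(out$odx_band))
  out$discordance <- c("concordant", "one_step", "two_step")[out$steps + 1]
  attr(out, "two_step_cases") <- dplyr::filter(out, .data$steps == 2)
  out
}

#' Compare score-group frequency distributions between two populations
#'
#' Pearson correlation between two populations' score-group frequency
#' vectors (are the cohorts distributed the same way across amMs groups?),
#' and, when 2x2 threshold-split counts are supplied, a chi-squared test of
#' independence (does the fraction above a threshold differ between the
#' populations?).
#'
#' @param freq_a,freq_b Equal-length numeric frequency vectors.
#' @param split_counts Optional 2x2 matrix of counts (populations x
#'   threshold split) for the chi-squared test.
#' @param correct Continuity correction for the chi-squared test.
#' @return A list with `pearson` (estimate, p.value) and, if requested,
#'   `chisq` (statistic, df, p.value).
#' @export
distribution_tests <- function(freq_a, freq_b, split_counts = NULL,
                               correct = FALSE) {
  if (length(freq_a) != length(freq_b)) {
    abort("frequency vectors must have equal length")
  }
  if (stats::sd(freq_a) == 0 || stats::sd(freq_b) == 0) {
    degenerate <- if (stats::sd(freq_a) == 0) "freq_a" else "freq_b"
    abort(paste0("zero-variance frequency vector: ", degenerate))
  }
  ct <- cor.test(freq_a, freq_b, method = "pearson")
  out <- list(pearson = list(estimate = unname(ct$estimate),
                             p.value = ct$p.value))
  if (!is.null(split_counts)) {
    if (!all(dim(split_counts) == c(2, 2))) {
      abort("split_counts must be a 2x2 matrix")
    }
    cs <- suppressWarnings(chisq.test(split_counts, correct = correct))
    out$chisq <- list(statistic = unname(cs$statistic),
                      df = unname(cs$parameter), p.value = cs$p.value)
  }
  out
}
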
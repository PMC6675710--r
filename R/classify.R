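# RoMMa decision rules: threshold bands on the average modified Magee score
# plus a histologic low-risk criterion, yielding a four-level risk category
# and a send-for-Oncotype-DX recommendation.

romma_categories <- c("lowest_risk", "low_risk", "intermediate", "high_risk")
odx_band_levels <- c("low", "below_26", "indeterminate", "high")

#' RoMMa thresholds
#'
#' Cutoffs on the average modified Magee score (amMs) and the histologic
#' low-risk criterion. Defaults pin the published algorithm: amMs <= 9 is
#' lowest risk, <= 12 low risk, > 30 high risk; amMs <= 18 predicts an
#' Oncotype DX recurrence score < 26; the histologic rule is Nottingham
#' score < 6 with both modified ER and PR H-scores >= 150 and Ki-67 < 10%.
#'
#' @param lowest_cutoff amMs at or below which a case is lowest risk.
#' @param low_cutoff amMs at or below which a case is low risk.
#' @param odx26_cutoff amMs at or below which an ODX RS < 26 is predicted.
#' @param high_cutoff amMs above which a case is high risk.
#' @param histologic_ns_max Nottingham score must be strictly below this.
#' @param histologic_h_min ER and PR H-scores must be at least this.
#' @param histologic_ki67_max Ki-67 must be strictly below this (percent).
#' @return A list of class `romma_thresholds`.
#' @export
romma_thresholds <- function(lowest_cutoff = 9, low_cutoff = 12,
                             odx26_cutoff = 18, high_cutoff = 30,
                             histologic_ns_max = 6, histologic_h_min = 150,
                             histologic_ki67_max = 10) {
  if (!(lowest_cutoff <= low_cutoff && low_cutoff <= odx26_cutoff &&
        odx26_cutoff < high_cutoff)) {
    abort("thresholds must satisfy lowest <= low <= odx26 < high")
  }
  structure(
    list(lowest_cutoff = lowest_cutoff, low_cutoff = low_cutoff,
         odx26_cutoff = odx26_cutoff, high_cutoff = high_cutoff,
         histologic_ns_max = histologic_ns_max,
         histologic_h_min = histologic_h_min,
         histologic_ki67_max = histologic_ki67_max),
    class = "romma_thresholds"
  )
}

#' Histologic low-risk criterion
#'
#' TRUE iff Nottingham score < 6, modified ER H-score >= 150, modified PR
#' H-score >= 150, and Ki-67 < 10% (all four, the ER and PR bounds both
#' required). Cases missing ER, PR, or Ki-67 evaluate FALSE and are flagged
#' indeterminate rather than guessed.
#'
#' @param cohort A cohort data frame with `nottingham_score`, `er_h_score`,
#'   `pr_h_score`, `ki67_pct`.
#' @param thresholds A [romma_thresholds()] object.
#' @return Logical vector with attribute `indeterminate` (logical vector).
#' @export
histologic_low_risk <- function(cohort, thresholds = romma_thresholds()) {
  cohort <- as_tibble(cohort)
  g <- function(nm) if (nm %in% names(cohort)) as.numeric(cohort[[nm]]) else
    rep(NA_real_, nrow(cohort))
  ns <- g("nottingham_score"); er <- g("er_h_score")
  pr <- g("pr_h_score"); ki <- g("ki67_pct")
  if (all(is.na(ns))) abort("histologic rule requires nottingham_score")
  indeterminate <- is.na(er) | is.na(pr) | is.na(ki) | is.na(ns)
  ok <- !indeterminate &
    ns < thresholds$histologic_ns_max &
    er >= thresholds$histologic_h_min &
    pr >= thresholds$histologic_h_min &
    ki < thresholds$histologic_ki67_max
  attr(ok, "indeterminate") <- indeterminate
  ok
}

#' Classify scored cases with the RoMMa algorithm
#'
#' Applies the decision rules to the unrounded amMs of each case: amMs at or
#' below the lowest cutoff is lowest risk; otherwise at or below the low
#' cutoff, or meeting the histologic low-risk criterion, is low risk;
#' otherwise above the high cutoff is high risk; everything else is
#' intermediate and is the only category recommended for send-out Oncotype
#' DX testing. The predicted ODX band is `high` (> 30) for high risk, `low`
#' (< 18) for amMs at or below the low cutoff, `below_26` for any other case
#' with amMs at or below the ODX-26 cutoff, else `indeterminate`.
#'
#' @param scored A cohort scored by [score_magee()] (must carry `amms`), or a
#'   raw cohort, in which case it is scored first with `equations`.
#' @param thresholds A [romma_thresholds()] object.
#' @param equations Passed to [score_magee()] when scoring is needed.
#' @return A tibble of class `romma_calls`: the input plus `category`
#'   (ordered factor lowest_risk < low_risk < intermediate < high_risk),
#'   `histologic_low_risk`, `histologic_indeterminate`, `predicted_odx_band`,
#'   `send_for_odx`, and `rationale` (the fired rules, comma-separated).
#' @export
#' @examples
#' calls <- romma_classify(simulate_cohort(100, seed = 1))
#' romma_summary(calls)
romma_classify <- function(scored, thresholds = romma_thresholds(),
                           equations = magee_equations()) {
  scored <- as_tibble(scored)
  if (nrow(scored) == 0) abort("empty cohort")
  if (!"amms" %in% names(scored)) {
    scored <- score_magee(scored, equations)
  }
  if (any(is.na(scored$amms))) {
    abort(paste0("cases without an amMs cannot be classified: ",
                 paste(head(scored$case_id[is.na(scored$amms)], 5),
                       collapse = ", ")))
  }
  amms <- scored$amms
  hist_low <- histologic_low_risk(scored, thresholds)
  indet <- attr(hist_low, "indeterminate")

  category <- dplyr::case_when(
    amms <= thresholds$lowest_cutoff ~ "lowest_risk",
    amms <= thresholds$low_cutoff | hist_low ~ "low_risk",
    amms > thresholds$high_cutoff ~ "high_risk",
    .default = "intermediate"
  )
  band <- dplyr::case_when(
    category == "high_risk" ~ "high",
    amms <= thresholds$low_cutoff ~ "low",
    amms <= thresholds$odx26_cutoff ~ "below_26",
    .default = "indeterminate"
  )
  rationale <- purrr::pmap_chr(
    list(amms, hist_low, category),
    function(a, h, cat) {
      rules <- c(
        if (a <= thresholds$lowest_cutoff)
          sprintf("amms<=%s", thresholds$lowest_cutoff),
        if (a <= thresholds$low_cutoff && a > thresholds$lowest_cutoff)
          sprintf("amms<=%s", thresholds$low_cutoff),
        if (h) "histologic_low_risk",
        if (a > thresholds$high_cutoff) sprintf("amms>%s", thresholds$high_cutoff),
        if (cat == "intermediate") "default_intermediate"
      )
      paste(rules, collapse = ",")
    }
  )
  out <- scored
  out$category <- factor(category, levels = romma_categories, ordered = TRUE)
  out$histologic_low_risk <- as.logical(hist_low)
  out$histologic_indeterminate <- indet
  out$predicted_odx_band <- factor(band, levels = odx_band_levels)
  out$send_for_odx <- category == "intermediate"
  out$rationale <- rationale
  class(out) <- c("romma_calls", class(out))
  out
}

#' Category frequencies for a classified cohort
#'
#' Counts and percentages per RoMMa category. The headline low-risk fraction
#' reported alongside (`low_risk_total`) folds the lowest-risk cases into low
#' risk, matching how the algorithm's low-risk yield is usually quoted.
#'
#' @param calls A `romma_calls` tibble from [romma_classify()].
#' @return A tibble with `category`, `n`, `pct`, plus attributes
#'   `low_risk_total` and `low_risk_total_pct`.
#' @export
romma_summary <- function(calls) {
  if (nrow(calls) == 0) abort("empty cohort")
  counts <- table(factor(calls$category, levels = romma_categories))
  out <- tibble(
    category = romma_categories,
    n = as.integer(counts),
    pct = 100 * as.integer(counts) / nrow(calls)
  )
  low_total <- sum(out$n[out$category %in% c("lowest_risk", "low_risk")])
  attr(out, "low_risk_total") <- low_total
  attr(out, "low_risk_total_pct") <- 100 * low_total / nrow(calls)
  out
}

#' Score and classify a raw cohort in one step
#'
#' Convenience wrapper: [score_magee()] then [romma_classify()], with a
#' frequency summary attached.
#'
#' @inheritParams romma_classify
#' @param cohort A raw cohort data frame.
#' @param unscorable Passed to [score_magee()].
#' @return A `romma_calls` tibble (see [romma_classify()]); the summary is
#'   available via [romma_summary()].
#' @export
classify_cohort <- function(cohort, equations = magee_equations(),
                            thresholds = romma_thresholds(),
                            unscorable = "error") {
  scored <- score_magee(cohort, equations, unscorable = unscorable)
  romma_classify(scored, thresholds)
}

#' Collapse case-level calls to patient level
#'
#' A patient with multiple tumors takes the highest-risk call among them;
#' scoring and concordance statistics stay case-level while outcome
#' statistics run on patients.
#'
#' @param calls A `romma_calls` tibble.
#' @return One row per `patient_id`, carrying the highest-risk case.
#' @export
collapse_to_patients <- function(calls) {
  calls |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::arrange(dplyr::desc(.data$category), dplyr::desc(.data$amms),
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}
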
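# Recurrence-outcome statistics: stratum rates, covariate odds ratios,
# group-mean comparisons. These run at patient level; collapse case-level
# calls first with collapse_to_patients().

#' Recurrence rate by stratum
#'
#' Counts recurrences per stratum of a grouping variable (a RoMMa category,
#' an ODX band, a covariate level, ...) with the mean and range of follow-up.
#' Optional filter expressions (for example restricting to patients who
#' received hormonal therapy, or excluding chemotherapy-treated
#' non-recurrers) are applied first and echoed in the `filters` attribute so
#' a report always states the denominator it used. Empty strata are reported
#' with `n = 0`, not dropped.
#'
#' @param patients A patient-level data frame with a logical `recurred`
#'   column (and `followup_years` if available).
#' @param stratum Column (unquoted) defining the strata.
#' @param ... Optional filter expressions evaluated in the data, e.g.
#'   `hormonal_therapy | recurred`.
#' @return A tibble with `stratum`, `n`, `n_recurred`, `rate`, `pct`,
#'   `mean_followup`, `min_followup`, `max_followup`.
#' @export
#' @examples
#' calls <- collapse_to_patients(romma_classify(simulate_cohort(300, seed = 2)))
#' recurrence_by_stratum(calls, category)
recurrence_by_stratum <- function(patients, stratum, ...) {
  patients <- as_tibble(patients)
  if (!"recurred" %in% names(patients)) abort("patients need a recurred column")
  filters <- rlang::enquos(...)
  if (length(filters) > 0) patients <- dplyr::filter(patients, !!!filters)
  patients <- dplyr::filter(patients, !is.na(.data$recurred))
  has_fu <- "followup_years" %in% names(patients)
  out <- patients |>
    dplyr::group_by(stratum = {{ stratum }}, .drop = FALSE) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_recurred = sum(.data$recurred),
      rate = ifelse(dplyr::n() == 0, NA_real_,
                    sum(.data$recurred) / dplyr::n()),
      mean_followup = if (has_fu) mean(.data$followup_years, na.rm = TRUE)
                      else NA_real_,
      min_followup = if (has_fu) suppressWarnings(
        min(.data$followup_years, na.rm = TRUE)) else NA_real_,
      max_followup = if (has_fu) suppressWarnings(
        max(.data$followup_years, na.rm = TRUE)) else NA_real_,
      .groups = "drop"
    ) |>
    dplyr::mutate(pct = 100 * .data$rate, .after = "rate")
  attr(out, "filters") <- unname(purrr::map_chr(filters, rlang::as_label))
  out
}

#' Odds ratio of recurrence for a binary covariate
#'
#' Cross-tabulates a binary covariate (for example lymphovascular invasion
#' or nodal involvement) against recurrence and returns the cross-product
#' odds ratio with a two-sided Fisher exact p-value, reusing
#' [diagnostic_metrics()]. `unknown` and `suspicious` covariate levels are
#' excluded from the denominators, never imputed.
#'
#' @param patients A patient-level data frame.
#' @param covariate Column (unquoted); logical, or a status column where
#'   `positive_level` marks the exposed level.
#' @param positive_level For character/factor covariates, the exposed level
#'   (e.g. `"identified"` for LVI, `"positive"` for LN).
#' @param exclude Levels dropped from the analysis (default `unknown`,
#'   `suspicious`).
#' @return A `diagnostic_metrics` object; `odds_ratio` is the recurrence
#'   odds ratio for the exposed level.
#' @export
#' @examples
#' fx <- example_outcome_tables()
#' covariate_odds_ratio_counts(fx$lvi)
covariate_odds_ratio <- function(patients, covariate, positive_level = NULL,
                                 exclude = c("unknown", "suspicious")) {
  patients <- as_tibble(patients)
  cov <- dplyr::pull(patients, {{ covariate }})
  rec <- patients$recurred
  keep <- !is.na(cov) & !is.na(rec)
  if (!is.logical(cov)) {
    keep <- keep & !cov %in% exclude
    if (is.null(positive_level)) {
      abort("positive_level is required for a non-logical covariate")
    }
    cov <- cov == positive_level
  }
  cov <- cov[keep]; rec <- rec[keep]
  if (length(unique(cov)) < 2) {
    abort("covariate has a single level among analyzable patients")
  }
  covariate_odds_ratio_counts(c(
    exposed_recurred = sum(cov & rec),
    unexposed_recurred = sum(!cov & rec),
    exposed_not_recurred = sum(cov & !rec),
    unexposed_not_recurred = sum(!cov & !rec)
  ))
}

#' @param counts Named integer vector with `exposed_recurred`,
#'   `unexposed_recurred`, `exposed_not_recurred`, `unexposed_not_recurred`.
#' @rdname covariate_odds_ratio
#' @export
covariate_odds_ratio_counts <- function(counts) {
  tab <- contingency_2x2(
    tp = counts[["exposed_recurred"]],
    fp = counts[["exposed_not_recurred"]],
    fn = counts[["unexposed_recurred"]],
    tn = counts[["unexposed_not_recurred"]],
    test_label = "exposed", ref_label = "recurred"
  )
  diagnostic_metrics(tab)
}

#' Welch two-sample comparison of a continuous covariate between outcomes
#'
#' Compares the mean of a continuous covariate (Ki-67, PR H-score, ...)
#' between recurred and non-recurred patients using Welch's unequal-variance
#' t-test, the robust default when the groups are badly unbalanced.
#'
#' @param patients A patient-level data frame.
#' @param covariate Column (unquoted), numeric.
#' @param group Grouping column (unquoted, default `recurred`), two levels.
#' @return A tibble with group means and n, the t statistic, df, and
#'   p-value.
#' @export
group_mean_test <- function(patients, covariate, group = recurred) {
  patients <- as_tibble(patients)
  x <- dplyr::pull(patients, {{ covariate }})
  g <- dplyr::pull(patients, {{ group }})
  keep <- !is.na(x) & !is.na(g)
  x <- x[keep]; g <- as.character(g[keep])
  lv <- sort(unique(g))
  if (length(lv) != 2) abort("group must have exactly two levels")
  n1 <- sum(g == lv[1]); n2 <- sum(g == lv[2])
  if (n1 < 2 || n2 < 2) {
    abort(paste0("insufficient observations in group ",
                 if (n1 < 2) lv[1] else lv[2]))
  }
  tt <- t.test(x[g == lv[1]], x[g == lv[2]], var.equal = FALSE)
  tibble(
    group1 = lv[1], group2 = lv[2],
    n1 = n1, n2 = n2,
    mean1 = mean(x[g == lv[1]]), mean2 = mean(x[g == lv[2]]),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p_value = tt$p.value
  )
}
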
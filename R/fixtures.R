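# Worked-example fixtures: per-case score pairs reconstructed in code from
# the published RoMMa validation-study summary tables. These are synthetic
# reconstructions -- each summary count becomes that many cases carrying a
# representative score inside the relevant band -- so every band-agreement
# count, diagnostic metric, and odds ratio recomputed from them reproduces
# the printed figures exactly, while no per-patient data are shipped.

#' Reconstructed validation-population score pairs
#'
#' A 584-case scored cohort (the validation cases with an available Ki-67)
#' whose cumulative amMs-group by ODX-band counts reproduce the published
#' band-agreement table, including the histologic low-risk row (67
#' qualifying cases: 48 with amMs <= 12 and 19 above) and the single
#' two-step discordant case (an amMs in the 14-15 group with an ODX
#' recurrence score of 31). Representative amMs and ODX values are placed
#' inside each band; clinicopathologic columns are nominal and chosen only
#' so the histologic criterion fires for the right cases.
#'
#' @return A scored cohort tibble with `amms`, `odx_rs`, and the histologic
#'   input columns.
#' @export
#' @examples
#' band_agreement(example_validation_scores())
example_validation_scores <- function() {
  # per amMs-increment counts: odx band x histologic yes/no
  # columns: amms value, n by (band, histologic)
  block <- function(amms, odx, n, hist) {
    if (n == 0) return(NULL)
    tibble(
      amms = rep(amms, n),
      odx_rs = rep(as.integer(odx), n),
      histologic = rep(hist, n)
    )
  }
  spec <- list(
    # interval amMs < 9
    list(a = 7.0,  low = 4,   low_h = 4,  int = 0,  int_h = 0, high = 0),
    # 9 <= amMs <= 10
    list(a = 9.5,  low = 18,  low_h = 14, int = 2,  int_h = 1, high = 0),
    # 10 < amMs <= 11
    list(a = 10.5, low = 23,  low_h = 13, int = 5,  int_h = 1, high = 0),
    # 11 < amMs <= 12
    list(a = 11.5, low = 39,  low_h = 13, int = 6,  int_h = 2, high = 0),
    # 12 < amMs <= 14
    list(a = 13.0, low = 41,  low_h = 6,  int = 9,  int_h = 3, high = 0),
    # 14 < amMs <= 15 (carries the two-step discordant case)
    list(a = 14.9, low = 81,  low_h = 6,  int = 14, int_h = 4, high = 1),
    # 15 < amMs < 18
    list(a = 16.0, low = 55,  low_h = 0,  int = 27, int_h = 0, high = 0),
    # 18 <= amMs <= 30 filler (not a reported row)
    list(a = 24.0, low = 82,  low_h = 0,  int = 160, int_h = 0, high = 0),
    # amMs > 30
    list(a = 33.0, low = 0,   low_h = 0,  int = 0,  int_h = 0, high = 17)
  )
  rows <- purrr::map(spec, function(s) {
    dplyr::bind_rows(
      block(s$a, 10, s$low - s$low_h, FALSE),
      block(s$a, 10, s$low_h, TRUE),
      block(s$a, 22, s$int - s$int_h, FALSE),
      block(s$a, 22, s$int_h, TRUE),
      block(s$a, 31, s$high, FALSE)
    )
  })
  out <- dplyr::bind_rows(rows)
  n <- nrow(out)
  out$case_id <- sprintf("val_%04d", seq_len(n))
  out$patient_id <- sprintf("valpt_%04d", seq_len(n))
  out$nottingham_score <- ifelse(out$histologic, 5L, 6L)
  out$er_h_score <- 200L
  out$pr_h_score <- ifelse(out$histologic, 180L, 100L)
  out$ki67_pct <- ifelse(out$histologic, 5, 20)
  out$her2_ihc <- 1L
  out$tumor_size_cm <- 1.5
  dplyr::select(out, -"histologic")
}

#' Reconstructed total-population screening pairs
#'
#' A 903-case cohort of (amMs, ODX recurrence score) pairs reproducing the
#' published screening 2x2: 524 cases with amMs <= 18 and ODX RS < 26, 13
#' with amMs <= 18 and ODX RS >= 26, 233 with amMs > 18 and ODX RS < 26, and
#' 133 with both above threshold.
#'
#' @return A tibble with `case_id`, `amms`, `odx_rs`.
#' @export
#' @examples
#' diagnostic_metrics(two_by_two(example_screening_scores()))
example_screening_scores <- function() {
  cells <- tibble(
    amms = c(10, 10, 25, 25),
    odx_rs = c(10L, 30L, 12L, 40L),
    n = c(524L, 13L, 233L, 133L)
  )
  out <- tidyr::uncount(cells, weights = .data$n)
  out$case_id <- sprintf("tot_%04d", seq_len(nrow(out)))
  dplyr::relocate(out, "case_id")
}

#' Published outcome-analysis counts
#'
#' The printed outcome-association inputs: the LVI-by-recurrence and
#' LN-by-recurrence 2x2 counts, the per-stratum recurrence counts, and the
#' filtered low-risk comparison (patients on appropriate hormonal therapy,
#' non-recurring chemotherapy-treated patients excluded).
#'
#' @return A list with `lvi` and `ln` (named count vectors for
#'   [covariate_odds_ratio_counts()]), `strata` (a tibble of per-stratum
#'   recurrence counts), and `low_risk_filtered`.
#' @export
#' @examples
#' covariate_odds_ratio_counts(example_outcome_tables()$lvi)
example_outcome_tables <- function() {
  list(
    # 7/17 recurred patients had LVI; 28/276 non-recurred patients had LVI
    lvi = c(exposed_recurred = 7L, unexposed_recurred = 10L,
            exposed_not_recurred = 28L, unexposed_not_recurred = 248L),
    # 5/18 recurred patients were node-positive; 47/270 non-recurred
    ln = c(exposed_recurred = 5L, unexposed_recurred = 13L,
           exposed_not_recurred = 47L, unexposed_not_recurred = 223L),
    strata = tibble(
      stratum = c("amMs <=12 (low risk)", "histologic low risk",
                  "ODX <11", "ODX 11-17", "ODX 18-30", "ODX <26", "ODX >30"),
      n_recurred = c(1L, 1L, 1L, 9L, 5L, 12L, 3L),
      n = c(55L, 38L, 49L, 117L, 112L, 258L, 23L)
    ),
    low_risk_filtered = tibble(
      classifier = c("romma_low", "odx_low"),
      n_recurred = c(1L, 8L),
      n = c(45L, 116L)
    )
  )
}

#' Published band-agreement summaries for both study populations
#'
#' The cumulative amMs-group concordance percentages and the amMs-18
#' threshold split counts for the validation population (620 cases) and the
#' original test population (283 cases), as inputs for
#' [distribution_tests()].
#'
#' @return A list with `pct_concordant` (a tibble with one row per group and
#'   one percentage column per population) and `split_lt18` (a 2x2 count
#'   matrix, populations x amMs <18 / >=18).
#' @export
example_band_counts <- function() {
  list(
    pct_concordant = tibble(
      group = c("amMs <9", "amMs <=10", "amMs <=11", "amMs <=12",
                "amMs <=14", "amMs <=15", "amMs <18",
                "histologic low risk", "amMs >30"),
      validation = c(100.0, 91.7, 86.5, 86.6, 85.0, 84.8, 80.3, 83.6, 100.0),
      original = c(100.0, 91.3, 86.1, 82.7, 83.6, 78.7, 73.4, 89.5, 100.0)
    ),
    split_lt18 = matrix(
      c(325, 295, 158, 125), nrow = 2, byrow = TRUE,
      dimnames = list(population = c("validation", "original"),
                      amms = c("<18", ">=18"))
    )
  )
}
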
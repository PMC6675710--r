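# Cost-avoidance modeling for multigene-assay triage: cases meeting the
# algorithmic low- or high-risk criteria would not be sent out for Oncotype
# DX testing, avoiding the list price per case.

#' Cost-avoidance scenario
#'
#' Parameters of the avoided-test calculation. Defaults pin the published
#' scenario: a $4,620 list price (Genomic Health 2017 annual report), 126,740
#' test reports delivered nationally, of which about 85% are invasive breast
#' carcinoma, and the study's algorithmic fractions of 20.8% low risk and
#' 2.8% high risk.
#'
#' @param list_price_usd List price per test, USD.
#' @param cohort_n Institutional cohort size.
#' @param frac_low,frac_high Fractions of cases meeting low / high risk
#'   criteria (must sum to at most 1).
#' @param national_reports National test reports delivered per year.
#' @param breast_fraction Fraction of national reports that are invasive
#'   breast carcinoma.
#' @return A list of class `cost_scenario`.
#' @export
cost_scenario <- function(list_price_usd = 4620, cohort_n = 903,
                          frac_low = 0.208, frac_high = 0.028,
                          national_reports = 126740,
                          breast_fraction = 0.85) {
  if (list_price_usd <= 0) abort("list_price_usd must be positive")
  for (f in c(frac_low, frac_high, breast_fraction)) {
    if (is.na(f) || f < 0 || f > 1) abort("fractions must lie in [0, 1]")
  }
  if (frac_low + frac_high > 1) abort("frac_low + frac_high must be <= 1")
  structure(
    list(list_price_usd = list_price_usd, cohort_n = cohort_n,
         frac_low = frac_low, frac_high = frac_high,
         national_reports = national_reports,
         breast_fraction = breast_fraction),
    class = "cost_scenario"
  )
}

#' Institutional cost avoidance
#'
#' Exact product of the number of avoided send-outs and the list price.
#'
#' @param n_avoided Number of cases not sent out (non-negative integer).
#' @param list_price_usd List price per test, USD.
#' @return USD amount (numeric, exact for integer-cent prices).
#' @export
#' @examples
#' institutional_savings(213)  # $984,060
institutional_savings <- function(n_avoided, list_price_usd = 4620) {
  if (is.na(n_avoided) || n_avoided < 0) abort("n_avoided must be >= 0")
  n_avoided * list_price_usd
}

#' National cost-avoidance extrapolation
#'
#' Scales the institutional low/high-risk fractions to the national testing
#' volume: `candidate_pool = round(national_reports * breast_fraction)` is
#' the national pool of breast cases tested; `n_avoidable` rounds
#' `candidate_pool * (frac_low + frac_high)`; the dollar savings keeps the
#' unrounded avoidable-case count in the product with the list price and
#' rounds only the final dollar figure (rounding the case count first loses
#' about $200 on the default scenario).
#'
#' @param scenario A [cost_scenario()].
#' @return A tibble with `candidate_pool`, `n_avoidable`, `savings_usd`.
#' @export
#' @examples
#' national_extrapolation(cost_scenario())
national_extrapolation <- function(scenario = cost_scenario()) {
  stopifnot(inherits(scenario, "cost_scenario"))
  pool <- round(scenario$national_reports * scenario$breast_fraction)
  frac <- scenario$frac_low + scenario$frac_high
  avoidable_exact <- pool * frac
  tibble(
    candidate_pool = pool,
    n_avoidable = round(avoidable_exact),
    savings_usd = round(avoidable_exact * scenario$list_price_usd)
  )
}
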
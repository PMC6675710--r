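# Seeded synthetic-cohort generator. Candidate cases are drawn from
# realistic clinicopathologic marginals, scored with the real Magee
# equations, and quota-sampled so the realized RoMMa stratum fractions hit
# the targets; the ODX recurrence score is a linear-Gaussian function of the
# amMs and recurrence follows a logistic model on Ki-67, PR, LN, and LVI.

#' Synthetic cohort specification
#'
#' Targets and model knobs for [simulate_cohort()]. Defaults emulate an
#' ER-positive, Oncotype-DX-tested institutional cohort: 20.8% of cases meet
#' algorithmic low-risk criteria and 2.8% high-risk; the score link maps
#' amMs to the ODX recurrence score with unit slope, small intercept, and
#' Gaussian noise tight enough that nearly all amMs <= 18 cases score below
#' 26; the recurrence model has a roughly 6% base rate with higher risk for
#' high Ki-67, low PR, nodal involvement, and lymphovascular invasion; Ki-67
#' is missing in 5.9% of cases and tumor size in 0.3%.
#'
#' @param target_low,target_high Target fractions of cases meeting low-risk
#'   (including lowest-risk and histologic) and high-risk criteria.
#' @param link_slope,link_intercept,link_sd Score link: `odx_rs =
#'   round(link_slope * amms + link_intercept + N(0, link_sd))`, clipped to
#'   0-100.
#' @param outcome_coef Named numeric vector of logistic coefficients for
#'   recurrence: `intercept`, `ki67_pct` (per point), `pr_h_score` (per
#'   point), `ln_positive`, `lvi_identified`.
#' @param missing_ki67,missing_size Missingness rates injected into Ki-67
#'   and tumor size (never both in one case, so every case stays scorable).
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(target_low = 0.208, target_high = 0.028,
                        link_slope = 1.0, link_intercept = 1.0,
                        link_sd = 4.0,
                        outcome_coef = c(intercept = -2.94, ki67_pct = 0.05,
                                         pr_h_score = -0.005,
                                         ln_positive = 0.7,
                                         lvi_identified = 1.8),
                        missing_ki67 = 0.059, missing_size = 0.003) {
  if (target_low < 0 || target_high < 0 || target_low + target_high > 1) {
    abort("target fractions must be non-negative and sum to <= 1")
  }
  if (link_sd <= 0) abort("link_sd must be positive")
  structure(
    list(target_low = target_low, target_high = target_high,
         link_slope = link_slope, link_intercept = link_intercept,
         link_sd = link_sd, outcome_coef = outcome_coef,
         missing_ki67 = missing_ki67, missing_size = missing_size),
    class = "cohort_spec"
  )
}

# One batch of candidate clinicopathologic records (no ODX, no outcomes).
draw_candidates <- function(m, spec) {
  ns <- sample(3:9, m, replace = TRUE,
               prob = c(0.06, 0.12, 0.20, 0.24, 0.19, 0.13, 0.06))
  er <- as.integer(round(300 * rbeta(m, 4, 0.6)))
  pr <- as.integer(round(300 * rbeta(m, 1.4, 0.7)))
  ihc <- sample(0:3, m, replace = TRUE, prob = c(0.29, 0.44, 0.266, 0.004))
  fish <- ifelse(ihc == 2L,
                 ifelse(runif(m) < 0.06, "amplified", "not_amplified"),
                 NA_character_)
  ki <- round(pmin(95, rgamma(m, shape = 1.8, scale = 9)), 1)
  sz <- pmax(0.1, round(pmin(8, rlnorm(m, log(1.5), 0.45)), 1))
  miss_ki <- runif(m) < spec$missing_ki67
  miss_sz <- runif(m) < spec$missing_size & !miss_ki
  ki[miss_ki] <- NA_real_
  sz[miss_sz] <- NA_real_
  tibble(
    nottingham_score = as.integer(ns), er_h_score = er, pr_h_score = pr,
    her2_ihc = as.integer(ihc), her2_fish = fish,
    ki67_pct = ki, tumor_size_cm = sz
  )
}

#' Generate a synthetic cohort
#'
#' Deterministic given `seed`. Candidate cases are drawn, scored with the
#' real equations, classified, and quota-sampled until the realized RoMMa
#' stratum counts equal `round(n_cases * target)`; the ODX recurrence score
#' and outcome fields are then generated from the spec's link and logistic
#' models. About 1.5% of patients carry two tumors, so patient-level
#' analyses have something to collapse.
#'
#' @param n_cases Number of cases (> 0).
#' @param seed Integer seed; the only source of randomness.
#' @param spec A [cohort_spec()].
#' @param equations,thresholds Scoring and classification rules used while
#'   quota-sampling.
#' @return A cohort tibble in the standard column schema (see
#'   [read_cohort()]), including `odx_rs` and outcome fields.
#' @export
#' @examples
#' cohort <- simulate_cohort(200, seed = 42)
#' romma_summary(romma_classify(cohort))
simulate_cohort <- function(n_cases, seed, spec = cohort_spec(),
                            equations = magee_equations(),
                            thresholds = romma_thresholds()) {
  if (is.na(n_cases) || n_cases <= 0) abort("n_cases must be positive")
  withr::local_seed(as.integer(seed))

  n_low <- round(n_cases * spec$target_low)
  n_high <- round(n_cases * spec$target_high)
  n_int <- n_cases - n_low - n_high

  got <- list(low = NULL, high = NULL, intermediate = NULL)
  need <- c(low = n_low, high = n_high, intermediate = n_int)
  batch <- max(2000, 2 * n_cases)
  for (iter in seq_len(60)) {
    have <- vapply(got, NROW, integer(1))
    if (all(have >= need[names(got)])) break
    cand <- draw_candidates(batch, spec)
    scored <- score_magee(cand, equations, unscorable = "keep")
    calls <- romma_classify(
      dplyr::filter(scored, !is.na(.data$amms)), thresholds)
    grp <- dplyr::case_when(
      calls$category %in% c("lowest_risk", "low_risk") ~ "low",
      calls$category == "high_risk" ~ "high",
      .default = "intermediate"
    )
    for (k in names(got)) {
      short <- need[[k]] - NROW(got[[k]])
      if (short > 0) {
        pick <- which(grp == k)
        pick <- pick[seq_len(min(short, length(pick)))]
        got[[k]] <- dplyr::bind_rows(got[[k]], calls[pick, ])
      }
    }
  }
  if (any(vapply(names(need), function(k) NROW(got[[k]]), 1L) < need)) {
    abort("could not fill stratum quotas; marginals too far from targets")
  }

  cohort <- dplyr::bind_rows(got)[sample(n_cases), ]
  amms <- cohort$amms

  # score link: linear-Gaussian, rounded and clipped to the 0-100 scale
  odx <- round(spec$link_slope * amms + spec$link_intercept +
                 rnorm(n_cases, 0, spec$link_sd))
  cohort$odx_rs <- as.integer(pmin(100, pmax(0, odx)))

  cohort$ln_status <- sample(c("negative", "positive", "unknown"), n_cases,
                             replace = TRUE, prob = c(0.77, 0.155, 0.075))
  cohort$lvi_status <- sample(
    c("identified", "not_identified", "suspicious", "unknown"), n_cases,
    replace = TRUE, prob = c(0.118, 0.852, 0.013, 0.017))

  b <- spec$outcome_coef
  ki_for_model <- ifelse(is.na(cohort$ki67_pct), 16, cohort$ki67_pct)
  lp <- b[["intercept"]] + b[["ki67_pct"]] * ki_for_model +
    b[["pr_h_score"]] * cohort$pr_h_score +
    b[["ln_positive"]] * (cohort$ln_status == "positive") +
    b[["lvi_identified"]] * (cohort$lvi_status == "identified")
  cohort$recurred <- rbinom(n_cases, 1, stats::plogis(lp)) == 1
  cohort$followup_years <- round(
    ifelse(cohort$recurred, runif(n_cases, 2, 11), runif(n_cases, 5, 11)), 1)
  chemo_p <- c(lowest_risk = 0.03, low_risk = 0.05, intermediate = 0.2,
               high_risk = 0.7)[as.character(cohort$category)]
  cohort$hormonal_therapy <- runif(n_cases) < 0.8
  cohort$chemotherapy <- runif(n_cases) < chemo_p
  cohort$radiation <- runif(n_cases) < 0.52
  cohort$age_years <- as.integer(pmin(90, pmax(25, round(rnorm(n_cases, 59, 12)))))

  # identifiers; ~1.5% of patients contribute two tumors
  n_multi <- floor(0.015 * n_cases)
  n_pat <- n_cases - n_multi
  pat_idx <- c(seq_len(n_pat),
               if (n_multi > 0) sample(seq_len(n_pat), n_multi))
  cohort$case_id <- sprintf("case_%05d", seq_len(n_cases))
  cohort$patient_id <- sprintf("pt_%05d", sample(pat_idx))

  dplyr::select(cohort, dplyr::all_of(names(cohort_columns())))
}

#' Recover the score-link parameters from a generated cohort
#'
#' Parameter-recovery harness: ordinary least squares of the ODX recurrence
#' score on the amMs, returning slope/intercept estimates with standard
#' errors and the residual standard deviation. On a cohort from
#' [simulate_cohort()] with a known spec, the estimates should sit within a
#' few standard errors of the truth.
#'
#' @param cohort A cohort with `odx_rs` (scored or raw; scored if needed).
#' @param equations Used if the cohort lacks an `amms` column.
#' @return An object of class `romma_link` wrapping the [lm()] fit; use
#'   [tidy()] / [glance()].
#' @export
recover_link <- function(cohort, equations = magee_equations()) {
  cohort <- as_tibble(cohort)
  if (!"amms" %in% names(cohort)) cohort <- score_magee(cohort, equations)
  cohort <- dplyr::filter(cohort, !is.na(.data$amms), !is.na(.data$odx_rs))
  if (nrow(cohort) < 3) abort("need at least 3 paired cases to fit the link")
  fit <- lm(odx_rs ~ amms, data = cohort)
  structure(list(fit = fit,
                 slope = unname(coef(fit)[["amms"]]),
                 intercept = unname(coef(fit)[["(Intercept)"]]),
                 sigma = summary(fit)$sigma,
                 slope_se = summary(fit)$coefficients["amms", "Std. Error"],
                 n = nrow(cohort)),
            class = "romma_link")
}

#' @export
print.romma_link <- function(x, ...) {
  cat(sprintf(
    "Score link (ODX RS ~ amMs), n = %d\n  slope %.3f (SE %.3f), intercept %.3f, residual SD %.3f\n",
    x$n, x$slope, x$slope_se, x$intercept, x$sigma))
  invisible(x)
}
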
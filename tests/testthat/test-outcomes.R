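# Expand printed per-stratum counts into a per-patient tibble.
expand_strata <- function(strata) {
  purrr::pmap_dfr(strata, function(stratum, n_recurred, n) {
    tibble::tibble(
      patient_id = paste0(stratum, "_", seq_len(n)),
      stratum = stratum,
      recurred = c(rep(TRUE, n_recurred), rep(FALSE, n - n_recurred)),
      followup_years = 6.5
    )
  })
}

test_that("stratum recurrence rates match their defining counts", {
  fx <- example_outcome_tables()
  patients <- expand_strata(fx$strata)
  res <- recurrence_by_stratum(patients, stratum)
  r12 <- res[res$stratum == "amMs <=12 (low risk)", ]
  expect_equal(c(r12$n, r12$n_recurred), c(55, 1))
  expect_equal(round(r12$pct), 2)
  r30 <- res[res$stratum == "ODX >30", ]
  expect_equal(round(r30$pct), 13)

  # the filtered low-risk comparison endpoints
  filt <- expand_strata(dplyr::rename(fx$low_risk_filtered,
                                      stratum = classifier))
  res_f <- recurrence_by_stratum(filt, stratum)
  romma_low <- res_f[res_f$stratum == "romma_low", ]
  expect_equal(c(romma_low$n, romma_low$n_recurred), c(45, 1))
  expect_equal(round(romma_low$pct, 1), 2.2)
  odx_low <- res_f[res_f$stratum == "odx_low", ]
  expect_equal(c(odx_low$n, odx_low$n_recurred), c(116, 8))

  # toy strata
  all_rec <- tibble::tibble(stratum = "x", recurred = rep(TRUE, 4))
  expect_equal(recurrence_by_stratum(all_rec, stratum)$rate, 1.0)
})

test_that("strata partition the filtered cohort and ignore patient order", {
  calls <- collapse_to_patients(romma_classify(simulate_cohort(400, seed = 2)))
  res <- recurrence_by_stratum(calls, category)
  expect_equal(sum(res$n), nrow(calls))

  res_shuffled <- recurrence_by_stratum(calls[sample(nrow(calls)), ], category)
  expect_equal(res, res_shuffled, ignore_attr = TRUE)

  # filters are applied and recorded
  res_f <- recurrence_by_stratum(calls, category, hormonal_therapy)
  expect_equal(sum(res_f$n), sum(calls$hormonal_therapy))
  expect_equal(attr(res_f, "filters"), "hormonal_therapy")
})

test_that("the LVI odds ratio reproduces the published association", {
  fx <- example_outcome_tables()
  m <- covariate_odds_ratio_counts(fx$lvi)
  expect_equal(round(m$odds_ratio, 1), 6.2)
  expect_lt(m$p_value, 0.01)

  # LN association is weaker and, computed from its counts, below the
  # printed 2.0 (the counts give ~1.8)
  ln <- covariate_odds_ratio_counts(fx$ln)
  expect_equal(round(ln$odds_ratio, 1), 1.8)
  expect_gt(ln$p_value, 0.05)
})

test_that("covariate odds ratios are symmetric and match the cross-product", {
  # independent covariate: OR 1 in a balanced table
  bal <- covariate_odds_ratio_counts(c(
    exposed_recurred = 10L, unexposed_recurred = 10L,
    exposed_not_recurred = 30L, unexposed_not_recurred = 30L))
  expect_equal(bal$odds_ratio, 1.0)

  set.seed(23)
  for (i in 1:10) {
    cells <- sample(1:20, 4)
    names(cells) <- c("exposed_recurred", "unexposed_recurred",
                      "exposed_not_recurred", "unexposed_not_recurred")
    m <- covariate_odds_ratio_counts(cells)
    expect_equal(m$odds_ratio,
                 cells[[1]] * cells[[4]] / (cells[[2]] * cells[[3]]))
    # 2x2 OR symmetry: swap covariate and outcome roles
    swapped <- c(exposed_recurred = cells[[1]],
                 unexposed_recurred = cells[[3]],
                 exposed_not_recurred = cells[[2]],
                 unexposed_not_recurred = cells[[4]])
    expect_equal(covariate_odds_ratio_counts(swapped)$odds_ratio,
                 m$odds_ratio)
  }
})

test_that("status covariates exclude unknown and suspicious levels", {
  patients <- tibble::tibble(
    patient_id = as.character(1:10),
    lvi_status = c("identified", "identified", "not_identified",
                   "not_identified", "not_identified", "not_identified",
                   "suspicious", "unknown", "identified", "not_identified"),
    recurred = c(TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, TRUE,
                 FALSE, FALSE)
  )
  m <- covariate_odds_ratio(patients, lvi_status,
                            positive_level = "identified")
  # 8 analyzable patients: LVI 2/3 recurred vs no-LVI 1/5
  expect_equal(sum(unclass(m$table)), 8L)
  expect_equal(m$odds_ratio, (2 * 4) / (1 * 1))

  one_level <- tibble::tibble(patient_id = "1", lvi_status = "identified",
                              recurred = TRUE)
  expect_error(covariate_odds_ratio(one_level, lvi_status,
                                    positive_level = "identified"),
               "single level")
})

test_that("group mean comparisons use Welch's test", {
  same <- tibble::tibble(x = rep(c(1, 2, 3), 2),
                         recurred = rep(c(TRUE, FALSE), each = 3))
  res <- group_mean_test(same, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(29)
  sep <- tibble::tibble(
    x = c(rnorm(20, 30, 5), rnorm(200, 10, 5)),
    recurred = rep(c(TRUE, FALSE), c(20, 200))
  )
  res <- group_mean_test(sep, x)
  expect_lt(res$p_value, 1e-4)
  expect_gt(abs(res$mean1 - res$mean2), 15)

  # location invariance
  shifted <- dplyr::mutate(sep, x = x + 100)
  expect_equal(group_mean_test(shifted, x)$statistic, res$statistic)

  tiny <- tibble::tibble(x = c(1, 2, 3), recurred = c(TRUE, FALSE, FALSE))
  expect_error(group_mean_test(tiny, x), "insufficient")
})
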
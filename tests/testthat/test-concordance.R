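test_that("band agreement reproduces the validation-population table", {
  agreement <- band_agreement(example_validation_scores())
  row <- function(g) agreement[agreement$group == g, ]

  r12 <- row("amMs <=12")
  expect_equal(c(r12$odx_high, r12$odx_intermediate, r12$odx_low),
               c(0L, 13L, 84L))
  expect_equal(round(r12$pct_concordant, 1), 86.6)

  r30 <- row("amMs >30")
  expect_equal(c(r30$odx_high, r30$odx_intermediate, r30$odx_low),
               c(17L, 0L, 0L))
  expect_equal(r30$pct_concordant, 100)

  rh <- row("histologic low risk")
  expect_equal(rh$n, 67L)
  expect_equal(round(rh$pct_concordant, 1), 83.6)

  expect_equal(round(row("amMs <9")$pct_concordant, 1), 100)
  expect_equal(round(row("amMs <=15")$pct_concordant, 1), 84.8)
  expect_equal(round(row("amMs <18")$pct_concordant, 1), 80.3)
})

test_that("a uniformly low cohort is 100% concordant in every low group", {
  co <- tibble::tibble(case_id = as.character(1:30), amms = 5, odx_rs = 5L,
                       nottingham_score = 5L, er_h_score = 200L,
                       pr_h_score = 200L, ki67_pct = 5)
  agreement <- band_agreement(co)
  low_rows <- agreement$group != "amMs >30"
  expect_true(all(agreement$pct_concordant[low_rows] == 100))
})

test_that("cumulative groups are consistent with their increments", {
  co <- simulate_cohort(800, seed = 31)
  scored <- score_magee(co)
  agreement <- band_agreement(scored)
  r11 <- agreement[agreement$group == "amMs <=11", ]
  r12 <- agreement[agreement$group == "amMs <=12", ]
  inc <- dplyr::filter(scored, !is.na(.data$odx_rs),
                       .data$amms > 11, .data$amms <= 12)
  inc_band <- table(odx_band(inc$odx_rs))
  expect_equal(r12$odx_low, r11$odx_low + unname(inc_band[["low"]]))
  expect_equal(r12$odx_high, r11$odx_high + unname(inc_band[["high"]]))
  expect_equal(r12$n, r11$n + nrow(inc))
})

test_that("the screening 2x2 counts cases by both rules and keeps totals", {
  tab <- two_by_two(example_screening_scores())
  expect_equal(unclass(tab)[c("tp", "fp", "fn", "tn")],
               c(tp = 524L, fp = 13L, fn = 233L, tn = 133L))
  expect_equal(sum(unclass(tab)), 903L)

  one <- two_by_two(tibble::tibble(amms = 10, odx_rs = 10L))
  expect_equal(unclass(one)[c("tp", "fp", "fn", "tn")],
               c(tp = 1L, fp = 0L, fn = 0L, tn = 0L))

  # totals preserved for any threshold pair
  co <- simulate_cohort(300, seed = 7)
  scored <- score_magee(co)
  for (t in c(10, 18, 25)) {
    for (r in c(18, 26, 31)) {
      expect_equal(sum(unclass(two_by_two(scored, t, r))),
                   sum(!is.na(scored$amms) & !is.na(scored$odx_rs)))
    }
  }
})

test_that("diagnostic metrics match their defining ratios and identities", {
  m <- diagnostic_metrics(contingency_2x2(524, 13, 233, 133))
  expect_equal(round(m$sensitivity, 3), 0.692)
  expect_equal(round(m$specificity, 3), 0.911)
  expect_equal(round(m$ppv, 3), 0.976)
  expect_equal(round(m$npv, 3), 0.363)
  expect_equal(round(m$odds_ratio, 1), 23.0)
  expect_lt(m$p_value, 0.0001)

  # symmetric table
  s <- diagnostic_metrics(contingency_2x2(4, 4, 4, 4))
  expect_equal(s$odds_ratio, 1)
  expect_equal(c(s$sensitivity, s$specificity, s$ppv, s$npv),
               rep(0.5, 4))

  # exact identity and scale invariance of the rates
  set.seed(13)
  for (i in 1:10) {
    cells <- sample(1:30, 4)
    m1 <- diagnostic_metrics(do.call(contingency_2x2, as.list(cells)))
    expect_equal(m1$ppv * (cells[1] + cells[2]), cells[1])
    m3 <- diagnostic_metrics(do.call(contingency_2x2, as.list(cells * 3L)))
    expect_equal(
      c(m1$sensitivity, m1$specificity, m1$ppv, m1$npv, m1$odds_ratio),
      c(m3$sensitivity, m3$specificity, m3$ppv, m3$npv, m3$odds_ratio))
  }
})

test_that("zero cells give explicit infinite or undefined odds ratios", {
  m <- diagnostic_metrics(contingency_2x2(5, 0, 3, 4))
  expect_equal(m$odds_ratio, Inf)
  expect_match(m$note, "infinite")
  expect_error(contingency_2x2(0, 0, 0, 0), "all-zero")
})

test_that("odds ratio and Fisher p agree with hypergeometric enumeration", {
  set.seed(17)
  for (i in 1:25) {
    cells <- sample(0:6, 4, replace = TRUE)
    if (sum(cells) == 0) cells[1] <- 1L
    m <- diagnostic_metrics(do.call(contingency_2x2, as.list(cells)))
    expect_equal(m$p_value,
                 fisher_p_oracle(cells[1], cells[2], cells[3], cells[4]),
                 tolerance = 1e-7)
    if (all(cells > 0)) {
      expect_equal(m$odds_ratio, cells[1] * cells[4] / (cells[2] * cells[3]))
    }
  }
})

test_that("discordance grading flags the single two-step validation case", {
  rep <- discordance_report(
    tibble::tibble(case_id = c("a", "b"), amms = c(15.4, 20),
                   odx_rs = c(31L, 20L)))
  expect_equal(rep$discordance, c("two_step", "concordant"))

  val <- discordance_report(example_validation_scores())
  expect_equal(sum(val$discordance == "two_step"), 1)
  expect_equal(nrow(attr(val, "two_step_cases")), 1)
  expect_equal(attr(val, "two_step_cases")$odx_rs, 31L)
})

test_that("population distribution comparisons behave sanely", {
  x <- c(10, 20, 30, 40)
  expect_equal(distribution_tests(x, x)$pearson$estimate, 1.0)

  bands <- example_band_counts()
  res <- distribution_tests(bands$pct_concordant$validation,
                            bands$pct_concordant$original,
                            split_counts = bands$split_lt18)
  expect_gt(res$pearson$estimate, 0.8)
  expect_lt(res$pearson$p.value, 0.05)
  expect_gt(res$chisq$p.value, 0.05)  # populations distribute alike

  # identical row proportions: no association
  even <- matrix(c(20, 40, 10, 20), 2, byrow = TRUE)
  expect_gt(distribution_tests(x, x + 1, split_counts = even)$chisq$p.value,
            0.99)

  expect_error(distribution_tests(c(1, 1, 1), c(1, 2, 3)), "freq_a")
  expect_error(distribution_tests(1:3, 1:4), "equal length")
})

test_that("chi-squared p agrees with a permutation null on a small table", {
  # tolerance covers Monte-Carlo error plus the asymptotic-vs-conditional gap
  m <- matrix(c(30, 20, 18, 32), 2, byrow = TRUE)
  res <- distribution_tests(c(1, 2, 3), c(2, 3, 5), split_counts = m)
  set.seed(41)
  p_perm <- chisq_perm_oracle(m, n_perm = 4000)
  expect_lt(abs(res$chisq$p.value - p_perm), 0.02)
})
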
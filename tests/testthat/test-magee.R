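test_that("equation evaluation is intercept plus weighted predictors", {
  const <- load_test_equations(list(eq1 = list(
    intercept = 17.5,
    coefficients = list(nottingham_score = 0, er_h_score = 0),
    required = list("nottingham_score", "er_h_score")
  )))
  expect_equal(score_equation(base_record(), const$eq1), 17.5)

  unit <- load_test_equations(list(eq1 = unit_equation()))
  rec <- base_record(nottingham_score = 7L, er_h_score = 200L,
                     pr_h_score = 100L, her2_ihc = 1L, ki67_pct = 20,
                     tumor_size_cm = 2)
  # 7 + 200 + 100 + 0 (HER-2 negative) + 2 + 20
  expect_equal(score_equation(rec, unit$eq1), 329)
})

test_that("a missing required predictor or unresolved HER-2 blocks an equation", {
  unit <- load_test_equations(list(eq1 = unit_equation()))
  expect_true(is.na(score_equation(base_record(ki67_pct = NA), unit$eq1)))
  expect_true(is.na(score_equation(base_record(her2_ihc = 2L), unit$eq1)))
  # resolved equivocal scores fine
  expect_false(is.na(score_equation(
    base_record(her2_ihc = 2L, her2_fish = "not_amplified"), unit$eq1)))
})

test_that("the average uses exactly the computable equations", {
  eqs <- magee_equations()
  co <- dplyr::bind_rows(
    base_record(case_id = "full"),
    base_record(case_id = "no_ki", ki67_pct = NA),
    base_record(case_id = "no_size", tumor_size_cm = NA)
  )
  scored <- score_magee(co, eqs)
  per_eq <- as.matrix(scored[, c("eq1", "eq2", "eq3")])

  expect_equal(scored$n_equations_used, c(3L, 1L, 1L))
  # oracle: direct arithmetic mean over the computable subset
  expect_equal(scored$amms,
               apply(per_eq, 1, function(r) mean(r, na.rm = TRUE)))
  # ki67 missing leaves only eq2; size missing leaves only eq3
  expect_true(is.na(scored$eq1[2]) && is.na(scored$eq3[2]))
  expect_true(is.na(scored$eq1[3]) && is.na(scored$eq2[3]))
  expect_match(scored$missing_inputs[2], "ki67_pct")

  # idempotent mean: equal per-equation scores average to themselves
  two <- load_test_equations(list(a = unit_equation(), b = unit_equation()))
  s2 <- score_magee(base_record(), two)
  expect_equal(s2$amms, s2$a)
})

test_that("a case no equation can score raises an unscorable error", {
  eqs <- magee_equations()
  hopeless <- base_record(case_id = "bad", ki67_pct = NA,
                          tumor_size_cm = NA, her2_ihc = 2L)
  expect_error(score_magee(hopeless, eqs), "bad.*her2_term|bad.*missing")
  expect_silent(s <- score_magee(hopeless, eqs, unscorable = "keep"))
  expect_true(is.na(s$amms))
})

test_that("scoring is linear in every predictor", {
  eqs <- magee_equations()
  set.seed(5)
  for (i in 1:10) {
    rec <- base_record(
      nottingham_score = sample(3:9, 1), er_h_score = sample(0:300, 1),
      pr_h_score = sample(0:300, 1), ki67_pct = runif(1, 0, 60),
      tumor_size_cm = runif(1, 0.3, 5)
    )
    for (eq in eqs) {
      for (nm in setdiff(names(eq$coefficients), "her2_term")) {
        delta <- runif(1, 0.5, 3)
        bumped <- rec
        bumped[[nm]] <- bumped[[nm]] + delta
        expect_equal(
          score_equation(bumped, eq) - score_equation(rec, eq),
          eq$coefficients[[nm]] * delta,
          tolerance = 1e-10
        )
      }
    }
  }
})

test_that("the average lies within the per-equation range and ignores row order", {
  eqs <- magee_equations()
  co <- simulate_cohort(60, seed = 9)
  scored <- score_magee(co, eqs)
  per_eq <- as.matrix(scored[, c("eq1", "eq2", "eq3")])
  lo <- apply(per_eq, 1, min, na.rm = TRUE)
  hi <- apply(per_eq, 1, max, na.rm = TRUE)
  expect_true(all(scored$amms >= lo - 1e-12 & scored$amms <= hi + 1e-12))

  shuffled <- score_magee(co[sample(nrow(co)), ], eqs)
  merged <- dplyr::left_join(scored[, c("case_id", "amms")],
                             shuffled[, c("case_id", "amms")],
                             by = "case_id")
  expect_equal(merged$amms.x, merged$amms.y)
})

test_that("the default config loads three equations and round-trips", {
  eqs <- magee_equations()
  expect_length(eqs, 3)
  for (eq in eqs) {
    expect_true(is.numeric(eq$intercept))
    expect_gte(length(eq$coefficients), 4)
  }
  path <- withr::local_tempfile(fileext = ".yaml")
  write_magee_equations(eqs, path)
  reloaded <- magee_equations(path)
  for (id in names(eqs)) {
    expect_equal(reloaded[[id]]$intercept, eqs[[id]]$intercept)
    expect_equal(reloaded[[id]]$coefficients, eqs[[id]]$coefficients)
    expect_equal(reloaded[[id]]$required, eqs[[id]]$required)
  }
})

test_that("malformed configs are rejected by schema validation", {
  expect_error(
    load_test_equations(list(eq1 = list(
      intercept = 1, coefficients = list(grade4 = 2), required = list("grade4")
    ))),
    "unknown predictor"
  )
  expect_error(
    load_test_equations(list(eq1 = list(
      intercept = 1, coefficients = list(her2_term = 1),
      her2_term_values = list(negative = 0),
      required = list("her2_term")
    ))),
    "her2_term_values"
  )
  expect_error(
    load_test_equations(list(eq1 = list(
      coefficients = list(er_h_score = 1), required = list("er_h_score")
    ))),
    "intercept"
  )
  expect_error(magee_equations("/nonexistent/eq.yaml"), "not found")
})
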
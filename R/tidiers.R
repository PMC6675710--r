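# broom-style tidiers for the package's result objects.

#' Tidy a diagnostic_metrics object
#'
#' @param x A [diagnostic_metrics()] object.
#' @param ... Unused.
#' @return One row per metric with `metric`, `estimate`, and for the odds
#'   ratio its 95% CI bounds.
#' @export
tidy.diagnostic_metrics <- function(x, ...) {
  tibble(
    metric = c("sensitivity", "specificity", "ppv", "npv", "odds_ratio"),
    estimate = c(x$sensitivity, x$specificity, x$ppv, x$npv, x$odds_ratio),
    conf.low = c(NA, NA, NA, NA, x$or_ci95[1]),
    conf.high = c(NA, NA, NA, NA, x$or_ci95[2])
  )
}

#' @rdname tidy.diagnostic_metrics
#' @export
glance.diagnostic_metrics <- function(x, ...) {
  tibble(
    sensitivity = x$sensitivity, specificity = x$specificity,
    ppv = x$ppv, npv = x$npv, odds_ratio = x$odds_ratio,
    or_conf.low = x$or_ci95[1], or_conf.high = x$or_ci95[2],
    p.value = x$p_value, n = sum(unclass(x$table))
  )
}

#' Tidy a contingency_2x2 object
#'
#' @param x A [contingency_2x2()] object.
#' @param ... Unused.
#' @return One row per cell with `test`, `reference`, `n`.
#' @export
tidy.contingency_2x2 <- function(x, ...) {
  tibble(
    test = c(TRUE, TRUE, FALSE, FALSE),
    reference = c(TRUE, FALSE, TRUE, FALSE),
    n = as.integer(unclass(x)[c("tp", "fp", "fn", "tn")])
  )
}

#' Tidy a fitted score link
#'
#' @param x A [recover_link()] object.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient with estimate and standard
#'   error; `glance()`: one-row fit summary.
#' @export
tidy.romma_link <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "slope"),
    estimate = s[c("(Intercept)", "amms"), "Estimate"],
    std.error = s[c("(Intercept)", "amms"), "Std. Error"]
  )
}

#' @rdname tidy.romma_link
#' @export
glance.romma_link <- function(x, ...) {
  tibble(
    slope = x$slope, slope_se = x$slope_se, intercept = x$intercept,
    sigma = x$sigma, r.squared = summary(x$fit)$r.squared, n = x$n
  )
}
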
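# Modified Magee scoring: three published linear equations on routine
# clinicopathologic variables, averaged per case into the amMs.

valid_predictors <- c("nottingham_score", "er_h_score", "pr_h_score",
                      "her2_term", "tumor_size_cm", "ki67_pct")
her2_statuses <- c("negative", "equivocal", "positive")

#' Load, validate, or write Magee equation specifications
#'
#' The three Magee equations are linear models of the Oncotype DX recurrence
#' score built from Nottingham score, ER/PR H-scores, a HER-2 status term,
#' tumor size, and Ki-67; each equation uses a different predictor subset.
#' Coefficients are never hard-coded: they live in a YAML config
#' (the packaged default transcribes the publicly posted equations, with
#' provenance recorded in the file header) so the arithmetic stays auditable
#' and upgradable.
#'
#' @param path Path to a YAML config; `NULL` loads the packaged default.
#' @return For `magee_equations()`, an object of class `magee_equations`: a
#'   named list of equation specs, each with `intercept`, `coefficients`,
#'   `her2_term_values`, and `required`.
#' @export
#' @examples
#' eqs <- magee_equations()
#' names(eqs)
#' eqs$eq1$intercept
magee_equations <- function(path = NULL) {
  path <- path %||% system.file("extdata", "magee_equations.yaml",
                                package = "romma")
  if (!file.exists(path)) abort(paste0("equation config not found: ", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw$equations) || length(raw$equations) == 0) {
    abort("equation config has no 'equations' entry")
  }
  specs <- purrr::imap(raw$equations, function(eq, id) {
    validate_equation_spec(eq, id)
  })
  structure(specs, version = raw$version %||% "unversioned",
            class = "magee_equations")
}

validate_equation_spec <- function(eq, id) {
  if (is.null(eq$intercept) || !is.numeric(eq$intercept)) {
    abort(paste0(id, ": missing numeric intercept"))
  }
  coefs <- unlist(eq$coefficients)
  unknown <- setdiff(names(coefs), valid_predictors)
  if (length(unknown) > 0) {
    abort(paste0(id, ": coefficient for unknown predictor: ",
                 paste(unknown, collapse = ", ")))
  }
  required <- unlist(eq$required)
  if (!all(required %in% names(coefs))) {
    abort(paste0(id, ": required predictors must have coefficients"))
  }
  if ("her2_term" %in% required) {
    h <- unlist(eq$her2_term_values)
    if (!all(her2_statuses %in% names(h))) {
      abort(paste0(id, ": her2_term_values must cover ",
                   paste(her2_statuses, collapse = ", ")))
    }
    eq$her2_term_values <- as.list(h[her2_statuses])
  }
  list(
    equation_id = id,
    intercept = as.numeric(eq$intercept),
    coefficients = as.list(coefs),
    her2_term_values = eq$her2_term_values,
    required = required
  )
}

#' @param equations A `magee_equations` object.
#' @rdname magee_equations
#' @export
write_magee_equations <- function(equations, path) {
  out <- list(
    version = attr(equations, "version"),
    equations = purrr::map(unclass(equations), function(eq) {
      list(intercept = eq$intercept,
           coefficients = eq$coefficients,
           her2_term_values = eq$her2_term_values,
           required = as.list(eq$required))
    })
  )
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @export
print.magee_equations <- function(x, ...) {
  cat("Magee equations (version ", attr(x, "version"), "):\n", sep = "")
  for (eq in x) {
    cat("  ", eq$equation_id, ": intercept ", eq$intercept, "; predictors ",
        paste(names(eq$coefficients), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# Predictor matrix for one equation; NA where a required input is missing or
# HER-2 is unresolved equivocal.
equation_terms <- function(cohort, spec) {
  her2 <- rep(NA_character_, nrow(cohort))
  has_any <- (("her2_ihc" %in% names(cohort)) & !is.na(cohort$her2_ihc)) |
    (("her2_fish" %in% names(cohort)) & !is.na(cohort$her2_fish))
  if (any(has_any)) {
    her2[has_any] <- normalize_her2(
      if ("her2_ihc" %in% names(cohort)) cohort$her2_ihc[has_any] else NA,
      if ("her2_fish" %in% names(cohort)) cohort$her2_fish[has_any] else NA
    )
  }
  fetch <- function(nm) {
    if (nm == "her2_term") {
      vals <- unlist(spec$her2_term_values)
      out <- unname(vals[her2])
      out[is.na(her2) | her2 == "equivocal"] <- NA_real_
      if (!"equivocal" %in% names(vals)) out[her2 == "equivocal"] <- NA_real_
      return(out)
    }
    if (nm %in% names(cohort)) as.numeric(cohort[[nm]]) else
      rep(NA_real_, nrow(cohort))
  }
  out <- vapply(names(spec$coefficients), fetch, numeric(nrow(cohort)))
  if (nrow(cohort) == 1) {
    out <- matrix(out, nrow = 1, dimnames = list(NULL, names(spec$coefficients)))
  }
  out
}

#' Evaluate one Magee equation over a cohort
#'
#' Returns `intercept + sum(coefficient * predictor)` per case, with the
#' HER-2 term contributed by its status-mapped value. A case is not
#' computable (NA) when any required predictor is missing or its HER-2
#' status is an unresolved equivocal.
#'
#' @param cohort A cohort data frame.
#' @param spec A single equation spec from [magee_equations()].
#' @return Numeric vector, NA where not computable.
#' @export
score_equation <- function(cohort, spec) {
  cohort <- as_tibble(cohort)
  terms <- equation_terms(cohort, spec)
  if (nrow(cohort) == 0) return(numeric(0))
  coefs <- unlist(spec$coefficients)[colnames(terms)]
  req <- colnames(terms) %in% spec$required
  incomplete <- rowSums(is.na(terms[, req, drop = FALSE])) > 0
  # optional predictors with NA contribute 0
  terms[is.na(terms)] <- 0
  score <- spec$intercept + drop(terms %*% coefs)
  score[incomplete] <- NA_real_
  unname(score)
}

#' Score a cohort with the Magee equations and average them
#'
#' Adds one column per equation plus the average modified Magee score
#' (`amms`), the arithmetic mean over the equations computable for each case.
#' Equations disqualified by a missing input (for example a missing Ki-67 or
#' tumor size, or an unresolved HER-2) simply drop out of the mean;
#' `n_equations_used` and `missing_inputs` record the provenance. Scores are
#' carried unrounded; round only for display.
#'
#' @param cohort A cohort data frame.
#' @param equations A [magee_equations()] object.
#' @param unscorable What to do with cases where no equation is computable:
#'   `"error"` (default) aborts naming the cases and their missing inputs,
#'   `"keep"` leaves them with `amms = NA`, `"drop"` removes them.
#' @return The cohort tibble with columns `eq1`, `eq2`, `eq3` (per config),
#'   `amms`, `n_equations_used`, and `missing_inputs` appended.
#' @export
#' @examples
#' score_magee(simulate_cohort(5, seed = 1))[, c("case_id", "amms")]
score_magee <- function(cohort, equations = magee_equations(),
                        unscorable = c("error", "keep", "drop")) {
  unscorable <- arg_match(unscorable)
  cohort <- as_tibble(cohort)
  if (nrow(cohort) == 0) abort("empty cohort")
  score_mat <- vapply(equations, function(spec) score_equation(cohort, spec),
                      numeric(nrow(cohort)))
  if (nrow(cohort) == 1) score_mat <- matrix(score_mat, nrow = 1,
                                             dimnames = list(NULL, names(equations)))
  n_used <- rowSums(!is.na(score_mat))
  amms <- ifelse(n_used > 0, rowMeans(score_mat, na.rm = TRUE), NA_real_)

  miss <- missing_inputs_per_case(cohort, equations)
  out <- dplyr::bind_cols(cohort, as_tibble(score_mat))
  out$amms <- amms
  out$n_equations_used <- as.integer(n_used)
  out$missing_inputs <- miss
  if (any(n_used == 0)) {
    bad <- which(n_used == 0)
    msg <- paste0("unscorable case(s), no equation computable: ",
                  paste(head(paste0(cohort$case_id[bad], " (missing: ",
                                    miss[bad], ")"), 5), collapse = "; "))
    if (unscorable == "error") abort(msg)
    if (unscorable == "drop") {
      warn(msg)
      out <- out[-bad, ]
    }
  }
  out
}

missing_inputs_per_case <- function(cohort, equations) {
  needed <- unique(unlist(purrr::map(equations, "required")))
  miss <- matrix(FALSE, nrow(cohort), length(needed),
                 dimnames = list(NULL, needed))
  for (nm in needed) {
    if (nm == "her2_term") {
      ihc <- if ("her2_ihc" %in% names(cohort)) cohort$her2_ihc else NA
      fish <- if ("her2_fish" %in% names(cohort)) cohort$her2_fish else NA
      ihc <- rep_len(ihc, nrow(cohort)); fish <- rep_len(fish, nrow(cohort))
      miss[, nm] <- (is.na(ihc) & is.na(fish)) |
        (!is.na(ihc) & ihc == 2 & is.na(fish))
    } else {
      v <- if (nm %in% names(cohort)) cohort[[nm]] else NA
      miss[, nm] <- is.na(rep_len(v, nrow(cohort)))
    }
  }
  apply(miss, 1, function(r) paste(needed[r], collapse = ","))
}
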
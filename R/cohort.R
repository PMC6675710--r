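# Cohort data model: column schema, CSV I/O, HER-2 normalization, validation.

# Canonical column order and types for a cohort file. Empty CSV fields are NA.
cohort_columns <- function() {
  c(
    case_id = "c", patient_id = "c",
    nottingham_score = "i", er_h_score = "i", pr_h_score = "i",
    her2_ihc = "i", her2_fish = "c",
    ki67_pct = "d", tumor_size_cm = "d",
    odx_rs = "i", age_years = "i",
    ln_status = "c", lvi_status = "c",
    recurred = "l", followup_years = "d",
    hormonal_therapy = "l", chemotherapy = "l", radiation = "l"
  )
}

ln_levels  <- c("negative", "positive", "unknown")
lvi_levels <- c("identified", "not_identified", "suspicious", "unknown")
fish_levels <- c("amplified", "not_amplified")

#' Read or write a cohort CSV
#'
#' A cohort file holds one row per tumor (case) with the columns documented in
#' the package's JSON schema (`system.file("extdata", "cohort-schema.json",
#' package = "romma")`): identifiers, Nottingham score, modified ER/PR
#' H-scores, HER-2 IHC score and FISH result, Ki-67 percentage, tumor size,
#' and the optional Oncotype DX recurrence score and outcome fields. Missing
#' values are empty fields; extra columns are preserved.
#'
#' @param path Path to a CSV file.
#' @return A tibble with one row per case.
#' @export
#' @examples
#' cohort <- simulate_cohort(20, seed = 1)
#' tmp <- tempfile(fileext = ".csv")
#' write_cohort(cohort, tmp)
#' read_cohort(tmp)
read_cohort <- function(path) {
  spec <- cohort_columns()
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(c("case_id", "patient_id", "nottingham_score",
                            "er_h_score", "pr_h_score"), names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort file lacks required column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  for (nm in intersect(names(spec), names(x))) {
    x[[nm]] <- switch(spec[[nm]],
      c = as.character(x[[nm]]),
      i = as.integer(x[[nm]]),
      d = as.numeric(x[[nm]]),
      l = as.logical(x[[nm]])
    )
  }
  as_tibble(x)
}

#' @param cohort A cohort data frame.
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  ord <- intersect(names(cohort_columns()), names(cohort))
  cohort <- dplyr::relocate(as_tibble(cohort), dplyr::all_of(ord))
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Resolve HER-2 status from IHC score and FISH result
#'
#' Deterministic three-level resolution used throughout the package:
#' IHC 0/1+ is negative, IHC 3+ is positive, and an equivocal IHC 2+ is
#' resolved by FISH (amplified = positive, not amplified = negative), the FISH
#' result taking precedence over IHC whenever both are present. An IHC 2+
#' with no FISH remains `"equivocal"` (unresolvable) and downstream scoring
#' treats the case as missing its HER-2 input rather than guessing.
#'
#' @param her2_ihc Integer vector of IHC scores in 0..3 (NA allowed).
#' @param her2_fish Character vector, `"amplified"` / `"not_amplified"`
#'   (NA allowed).
#' @param case_id Optional case identifiers used in error messages.
#' @return Character vector: `"negative"`, `"equivocal"`, or `"positive"`.
#' @export
#' @examples
#' normalize_her2(c(0, 1, 2, 2, 3, NA),
#'                c(NA, NA, "not_amplified", NA, NA, "amplified"))
normalize_her2 <- function(her2_ihc, her2_fish, case_id = NULL) {
  n <- max(length(her2_ihc), length(her2_fish))
  her2_ihc <- rep_len(as.integer(her2_ihc), n)
  her2_fish <- rep_len(as.character(her2_fish), n)
  bad_fish <- !is.na(her2_fish) & !her2_fish %in% fish_levels
  if (any(bad_fish)) {
    abort(paste0("invalid her2_fish value(s): ",
                 paste(unique(her2_fish[bad_fish]), collapse = ", ")))
  }
  bad_ihc <- !is.na(her2_ihc) & !her2_ihc %in% 0:3
  if (any(bad_ihc)) {
    abort(paste0("her2_ihc must be in 0..3; got ",
                 paste(unique(her2_ihc[bad_ihc]), collapse = ", ")))
  }
  both_absent <- is.na(her2_ihc) & is.na(her2_fish)
  if (any(both_absent)) {
    who <- if (is.null(case_id)) paste0("row ", which(both_absent)) else
      case_id[both_absent]
    abort(paste0("HER-2 status requires an IHC score or a FISH result; ",
                 "missing for: ", paste(head(who, 5), collapse = ", ")))
  }
  # FISH wins whenever present; IHC decides only 0/1 -> neg, 3 -> pos.
  dplyr::case_when(
    her2_fish == "amplified" ~ "positive",
    her2_fish == "not_amplified" ~ "negative",
    her2_ihc %in% c(0L, 1L) ~ "negative",
    her2_ihc == 3L ~ "positive",
    .default = "equivocal"
  )
}

#' Validate a cohort and account for every record
#'
#' Checks ranges and completeness case by case. Every record is either usable
#' for full scoring or carries at least one named flag, so the usable and
#' flagged counts always partition the cohort. Records flagged only for a
#' missing Ki-67 or tumor size remain scorable by the equations that do not
#' require the missing input; out-of-range records are not scorable at all.
#'
#' @param cohort A cohort data frame (see [read_cohort()]).
#' @return An object of class `romma_validation`: a list with `cases` (a
#'   tibble of per-case flags), `summary` (counts per flag reason), `n`,
#'   `n_usable`, and `n_flagged`.
#' @export
#' @examples
#' v <- validate_cohort(simulate_cohort(50, seed = 1))
#' v$summary
validate_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  if (nrow(cohort) == 0) abort("empty cohort")
  if (anyDuplicated(cohort$case_id)) {
    dup <- unique(cohort$case_id[duplicated(cohort$case_id)])
    abort(paste0("duplicate case_id: ", paste(head(dup, 5), collapse = ", ")))
  }
  get0n <- function(nm) {
    if (nm %in% names(cohort)) cohort[[nm]] else rep(NA, nrow(cohort))
  }
  ns <- get0n("nottingham_score"); er <- get0n("er_h_score")
  pr <- get0n("pr_h_score"); ki <- get0n("ki67_pct")
  sz <- get0n("tumor_size_cm"); odx <- get0n("odx_rs")
  ihc <- get0n("her2_ihc"); fish <- get0n("her2_fish")

  out_of_range <-
    (!is.na(ns) & (ns < 3 | ns > 9)) |
    (!is.na(er) & (er < 0 | er > 300)) |
    (!is.na(pr) & (pr < 0 | pr > 300)) |
    (!is.na(ki) & (ki < 0 | ki > 100)) |
    (!is.na(sz) & sz <= 0) |
    (!is.na(odx) & (odx < 0 | odx > 100)) |
    (!is.na(ihc) & !ihc %in% 0:3) |
    (!is.na(fish) & !fish %in% fish_levels)

  her2_unresolved <- (is.na(ihc) & is.na(fish)) |
    (!is.na(ihc) & ihc == 2L & is.na(fish))

  flags <- tibble(
    case_id = cohort$case_id,
    missing_nottingham = is.na(ns),
    missing_er = is.na(er),
    missing_pr = is.na(pr),
    missing_ki67 = is.na(ki),
    missing_size = is.na(sz),
    unresolved_her2 = her2_unresolved,
    out_of_range = out_of_range
  )
  flag_mat <- as.matrix(flags[-1])
  flags$flagged <- rowSums(flag_mat) > 0
  summary <- tibble(
    reason = colnames(flag_mat),
    n = colSums(flag_mat)
  )
  structure(
    list(
      cases = flags,
      summary = summary,
      n = nrow(cohort),
      n_usable = sum(!flags$flagged),
      n_flagged = sum(flags$flagged)
    ),
    class = "romma_validation"
  )
}

#' @export
print.romma_validation <- function(x, ...) {
  cat("Cohort validation: ", x$n, " cases; ", x$n_usable, " usable, ",
      x$n_flagged, " flagged\n", sep = "")
  bad <- dplyr::filter(x$summary, .data$n > 0)
  if (nrow(bad) > 0) print(bad)
  invisible(x)
}
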
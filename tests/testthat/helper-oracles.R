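# Independent oracles and small builders used across the suite.

# Two-sided Fisher exact p-value by exhaustive hypergeometric enumeration
# over all 2x2 tables with the observed margins, using choose() directly.
fisher_p_oracle <- function(tp, fp, fn, tn) {
  n <- tp + fp + fn + tn
  row1 <- tp + fp
  col1 <- tp + fn
  ks <- max(0, row1 + col1 - n):min(row1, col1)
  probs <- choose(col1, ks) * choose(n - col1, row1 - ks) / choose(n, row1)
  obs <- probs[ks == tp]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Uncorrected Pearson chi-squared statistic for a 2x2 count matrix.
chisq_stat <- function(m) {
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Monte-Carlo permutation p-value for independence in a 2x2 table: expand to
# individual observations, permute the outcome labels.
chisq_perm_oracle <- function(m, n_perm = 20000) {
  g <- rep(c(1, 1, 2, 2), as.vector(t(m)))
  y <- rep(c(1, 2, 1, 2), as.vector(t(m)))
  obs <- chisq_stat(m)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    yp <- sample(y)
    mp <- table(g, yp)
    if (chisq_stat(mp) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# A minimal complete scorable record.
base_record <- function(...) {
  defaults <- list(
    case_id = "c1", patient_id = "p1",
    nottingham_score = 6L, er_h_score = 200L, pr_h_score = 150L,
    her2_ihc = 1L, her2_fish = NA_character_,
    ki67_pct = 15, tumor_size_cm = 1.5
  )
  args <- list(...)
  defaults[names(args)] <- args
  tibble::as_tibble(defaults)
}

# A scored row ready for romma_classify (amms supplied directly).
scored_record <- function(amms, ns = 8L, er = 100L, pr = 50L, ki = 20,
                          id = "c1") {
  tibble::tibble(
    case_id = id, patient_id = id, amms = amms,
    nottingham_score = ns, er_h_score = er, pr_h_score = pr, ki67_pct = ki
  )
}

# Write a one-off equation config and load it.
load_test_equations <- function(equations_list, version = "test") {
  path <- withr::local_tempfile(fileext = ".yaml",
                                .local_envir = parent.frame())
  yaml::write_yaml(list(version = version, equations = equations_list), path)
  magee_equations(path)
}

unit_equation <- function(required = c("nottingham_score", "er_h_score",
                                       "pr_h_score", "her2_term",
                                       "tumor_size_cm", "ki67_pct"),
                          intercept = 0) {
  list(
    intercept = intercept,
    coefficients = list(nottingham_score = 1, er_h_score = 1, pr_h_score = 1,
                        her2_term = 1, tumor_size_cm = 1, ki67_pct = 1),
    her2_term_values = list(negative = 0, equivocal = 0.5, positive = 10),
    required = as.list(required)
  )
}
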
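# The preregistered (H1-H5) and exploratory analysis suites over a
# participant analysis table.

#' Run the preregistered confirmatory analyses (H1-H5)
#'
#' * H1: simple regression of AUDIT on the reward discounting parameter
#'   `log_kappa_R` (with the zero-order correlation).
#' * H2: correlation of AUDIT with the loss parameter `log_kappa_L`; the
#'   follow-up regression runs only if that correlation is significant.
#' * H3: multiple regression of `log_kappa_R` on education and individual
#'   income.
#' * H4: multiple regression of AUDIT on education and individual income.
#' * H5: hierarchical regression of AUDIT on education + income, then adding
#'   `log_kappa_R`, with the block F-test on the R-squared increment.
#'
#' All tests are two-tailed; each analysis uses its own complete cases.
#'
#' @param table Analysis tibble (see [build_analysis_table]).
#' @param alpha Significance level for the H2 gate and the summary.
#' @return List of class `confirmatory_report` with elements `h1`...`h5` and
#'   a `summary` tibble of the headline p-values.
#' @export
run_confirmatory_suite <- function(table, alpha = 0.05) {
  required <- c(
    "audit_sum", "log_kappa_R", "log_kappa_L", "education_num",
    "income_individual_num"
  )
  missing_cols <- setdiff(required, names(table))
  if (length(missing_cols) > 0L) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }

  h1_cor <- pearson_with_ci(table$audit_sum, table$log_kappa_R)
  h1_reg <- simple_regression(table, "audit_sum", "log_kappa_R")

  h2_cor <- pearson_with_ci(table$audit_sum, table$log_kappa_L)
  h2_reg <- if (h2_cor$p < alpha) {
    simple_regression(table, "audit_sum", "log_kappa_L")
  } else {
    NULL
  }

  h3 <- multiple_regression(
    table, "log_kappa_R", c("education_num", "income_individual_num")
  )
  h4 <- multiple_regression(
    table, "audit_sum", c("education_num", "income_individual_num")
  )
  h5 <- hierarchical_regression(
    table, "audit_sum", c("education_num", "income_individual_num"),
    "log_kappa_R"
  )

  summary <- tibble::tibble(
    hypothesis = c("H1", "H2", "H3", "H4", "H5"),
    statistic = c("F", "r", "F", "F", "F_block"),
    value = c(h1_reg$f, h2_cor$r, h3$f, h4$f, h5$f_block),
    p = c(h1_reg$p, h2_cor$p, h3$p, h4$p, h5$p_block),
    n = c(h1_reg$n, h2_cor$n, h3$n, h4$n, h5$n),
    significant = c(
      h1_reg$p < alpha, h2_cor$p < alpha, h3$p < alpha, h4$p < alpha,
      h5$p_block < alpha
    )
  )
  structure(
    list(
      h1 = list(correlation = h1_cor, regression = h1_reg),
      h2 = list(correlation = h2_cor, regression = h2_reg,
                gated = is.null(h2_reg)),
      h3 = h3, h4 = h4, h5 = h5, alpha = alpha, summary = summary
    ),
    class = "confirmatory_report"
  )
}

#' @export
print.confirmatory_report <- function(x, ...) {
  cat("<confirmatory_report> preregistered hypotheses\n")
  print(x$summary)
  if (x$h2$gated) {
    cat("  (H2 regression not computed: correlation gate not passed)\n")
  }
  invisible(x)
}

# Correlation matrix with CIs over the named columns, complete pairs.
correlation_table <- function(table, vars, level = 0.95) {
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    res <- tryCatch(
      pearson_with_ci(table[[pr[1]]], table[[pr[2]]], level),
      error = function(e) NULL
    )
    if (is.null(res)) return(NULL)
    cbind(tibble::tibble(var1 = pr[1], var2 = pr[2]), res)
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Run the exploratory analyses
#'
#' Produces the full pairwise correlation matrix with CIs; gender t-tests on
#' alcohol use, discounting, impulsivity, education and income; the gender
#' moderation model for AUDIT on `log_kappa_R`; nondiscounter-vs-discounter
#' comparisons in the loss condition; the loss-discounting correlation with
#' AUDIT after excluding nondiscounters; the age + education hierarchical
#' model; the impulsivity (BIS-15) + `log_kappa_R` model; and repeats of the
#' H4/H5 hierarchical model with the secondary discounting indices (relative
#' discounting frequency, one-year discount factor) in place of
#' `log_kappa_R`. Analyses whose columns are absent or degenerate are skipped
#' and listed in `skipped`.
#'
#' @param table Analysis tibble.
#' @param alpha Significance level.
#' @return List of class `exploratory_report`.
#' @export
run_exploratory_suite <- function(table, alpha = 0.05) {
  skipped <- character(0)
  note_skip <- function(what, e) {
    skipped <<- c(skipped, paste0(what, " (", conditionMessage(e), ")"))
    NULL
  }
  try_run <- function(what, expr) {
    tryCatch(expr, error = function(e) note_skip(what, e))
  }

  numeric_vars <- intersect(
    c(
      "audit_sum", "weekly_units", "log_kappa_R", "log_kappa_L",
      "rel_freq_R", "rel_freq_L", "discount_factor_R", "discount_factor_L",
      "education_num", "income_individual_num", "income_household_num",
      "parental_education_num", "subjective_ses", "adolescent_wellbeing",
      "age", "bis15_sum"
    ),
    names(table)
  )
  correlations <- try_run(
    "correlation matrix", correlation_table(table, numeric_vars)
  )

  gender_vars <- intersect(
    c(
      "audit_sum", "weekly_units", "log_kappa_R", "log_kappa_L", "bis15_sum",
      "education_num", "income_individual_num", "income_household_num"
    ),
    names(table)
  )
  gender_tests <- NULL
  if ("gender_dummy" %in% names(table)) {
    rows <- lapply(gender_vars, function(v) {
      res <- try_run(
        paste("gender t-test:", v),
        group_ttest(table[[v]], table$gender_dummy)
      )
      if (is.null(res)) return(NULL)
      cbind(tibble::tibble(variable = v), res)
    })
    gender_tests <- tibble::as_tibble(do.call(rbind, rows))
  } else {
    skipped <- c(skipped, "gender t-tests (no gender_dummy column)")
  }

  gender_moderation <- try_run(
    "gender moderation model",
    moderation_model(table, "audit_sum", "log_kappa_R", "gender_dummy")
  )

  nondiscounter_tests <- NULL
  if ("nondiscounter_L" %in% names(table) &&
      length(unique(stats::na.omit(table$nondiscounter_L))) == 2L) {
    nd_vars <- intersect(
      c("age", "bis15_sum", "audit_sum", "weekly_units",
        "income_individual_num", "education_num"),
      names(table)
    )
    rows <- lapply(nd_vars, function(v) {
      res <- try_run(
        paste("nondiscounter comparison:", v),
        group_ttest(table[[v]], as.integer(table$nondiscounter_L))
      )
      if (is.null(res)) return(NULL)
      cbind(tibble::tibble(variable = v), res)
    })
    nondiscounter_tests <- tibble::as_tibble(do.call(rbind, rows))
  } else {
    skipped <- c(skipped, "nondiscounter comparisons (no two-level nondiscounter_L)")
  }

  h2_without_nondiscounters <- if (!all(c("nondiscounter_L", "log_kappa_L",
                                          "audit_sum") %in% names(table))) {
    skipped <- c(skipped,
                 "loss correlation excluding nondiscounters (missing columns)")
    NULL
  } else {
    try_run(
      "loss correlation excluding nondiscounters",
      {
        sub <- table[!is.na(table$nondiscounter_L) & !table$nondiscounter_L, ]
        pearson_with_ci(sub$audit_sum, sub$log_kappa_L)
      }
    )
  }

  age_education_model <- try_run(
    "age + education hierarchical model",
    hierarchical_regression(
      table, "audit_sum", c("age", "education_num"), "log_kappa_R"
    )
  )

  bis_model <- try_run(
    "BIS-15 + log_kappa_R model",
    multiple_regression(table, "audit_sum", c("bis15_sum", "log_kappa_R"))
  )

  secondary_indices <- list()
  for (idx in c("rel_freq_R", "discount_factor_R")) {
    secondary_indices[[idx]] <- try_run(
      paste("secondary-index hierarchical model:", idx),
      hierarchical_regression(
        table, "audit_sum", c("education_num", "income_individual_num"), idx
      )
    )
  }

  structure(
    list(
      correlations = correlations,
      gender_tests = gender_tests,
      gender_moderation = gender_moderation,
      nondiscounter_tests = nondiscounter_tests,
      h2_without_nondiscounters = h2_without_nondiscounters,
      age_education_model = age_education_model,
      bis_model = bis_model,
      secondary_indices = secondary_indices,
      alpha = alpha, skipped = skipped
    ),
    class = "exploratory_report"
  )
}

#' @export
print.exploratory_report <- function(x, ...) {
  cat("<exploratory_report>\n")
  if (!is.null(x$correlations)) {
    cat(sprintf("  %d pairwise correlations\n", nrow(x$correlations)))
  }
  if (length(x$skipped) > 0L) {
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  }
  invisible(x)
}
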
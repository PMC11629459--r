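# End-to-end pipeline: design -> simulate -> fit -> preprocess -> analyze,
# with provenance and deterministic seed derivation.

#' Pipeline configuration
#'
#' One master seed deterministically derives the seeds of every stage.
#'
#' @param design A [design_config].
#' @param cohort A [cohort_config].
#' @param fit A [fit_config].
#' @param alpha Significance level for the analysis suites.
#' @param suites Which suites to run: `"confirmatory"`, `"exploratory"`,
#'   both, or `NULL` to stop after preprocessing.
#' @param seed Master seed; overrides the seeds inside `design` and `cohort`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(design = design_config(), cohort = cohort_config(),
                       fit = fit_config(), alpha = 0.05,
                       suites = c("confirmatory", "exploratory"),
                       seed = 1L) {
  suites <- if (is.null(suites)) {
    character(0)
  } else {
    match.arg(suites, c("confirmatory", "exploratory"), several.ok = TRUE)
  }
  design$seed <- derive_seed(seed, 1L)
  cohort$seed <- derive_seed(seed, 2L)
  structure(
    list(
      design = design, cohort = cohort, fit = fit, alpha = alpha,
      suites = suites, seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

serialize_config <- function(config) {
  jsonlite::toJSON(
    list(
      seed = config$seed, alpha = config$alpha, suites = config$suites,
      design = list(
        delays = config$design$delays,
        delayed_amounts = config$design$delayed_amounts,
        hypothetical_kappas = vapply(
          config$design$hypothetical_params, function(p) p$kappa, numeric(1)
        ),
        target_probabilities = config$design$target_probabilities,
        rounding_increment = config$design$rounding_increment,
        clamp = config$design$clamp
      ),
      cohort = list(
        n = config$cohort$n,
        loss_nondiscounter_weight = config$cohort$loss_nondiscounter_weight,
        artifact_rates = config$cohort$artifact_rates,
        missing_rates = config$cohort$missing_rates,
        bis_reverse_key = config$cohort$bis_reverse_key
      )
    ),
    auto_unbox = TRUE, digits = NA
  )
}

#' Run the full analysis pipeline
#'
#' Generates the design, simulates the synthetic cohort, fits the discounting
#' model to every participant and condition, applies quality control, builds
#' the analysis table, and runs the requested statistical suites. When
#' `out_dir` is given, writes the trial/participant/fit/analysis tables as
#' CSV, the reports as JSON, and the serialized configuration for provenance.
#'
#' @param config A [run_config].
#' @param out_dir Optional output directory.
#' @return List of class `pipeline_result` with `cohort`, `fits`, `qc`,
#'   `analysis_table`, `confirmatory`, `exploratory`, `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  cohort <- generate_cohort(config$cohort, config$design)
  fits <- fit_cohort(cohort$trials, config$fit)
  qc <- apply_qc(
    cohort$trials,
    scheduled_per_condition = nrow(generate_design(config$design)) / 2L
  )
  table <- build_analysis_table(
    cohort$participants, fits, cohort$trials, qc,
    bis_reverse_key = config$cohort$bis_reverse_key
  )
  confirmatory <- if ("confirmatory" %in% config$suites) {
    run_confirmatory_suite(table, config$alpha)
  }
  exploratory <- if ("exploratory" %in% config$suites) {
    run_exploratory_suite(table, config$alpha)
  }

  result <- structure(
    list(
      cohort = cohort, fits = fits, qc = qc, analysis_table = table,
      confirmatory = confirmatory, exploratory = exploratory, config = config
    ),
    class = "pipeline_result"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(
      cohort$participants, file.path(out_dir, "participants.csv"),
      row.names = FALSE
    )
    utils::write.csv(
      cohort$trials, file.path(out_dir, "trials.csv"), row.names = FALSE
    )
    utils::write.csv(
      cohort$ground_truth, file.path(out_dir, "ground_truth.csv"),
      row.names = FALSE
    )
    utils::write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE)
    utils::write.csv(qc, file.path(out_dir, "qc.csv"), row.names = FALSE)
    utils::write.csv(
      table, file.path(out_dir, "analysis_table.csv"), row.names = FALSE
    )
    writeLines(
      as.character(serialize_config(config)),
      file.path(out_dir, "config.json")
    )
    if (!is.null(confirmatory)) {
      jsonlite::write_json(
        confirmatory$summary, file.path(out_dir, "confirmatory_summary.json"),
        auto_unbox = TRUE, digits = NA
      )
    }
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> seed %d: %d participants, %d retained after QC\n",
    x$config$seed, nrow(x$cohort$participants), nrow(x$analysis_table)
  ))
  if (!is.null(x$confirmatory)) print(x$confirmatory)
  invisible(x)
}

#' Read a long-format trial CSV
#'
#' Validates the trial schema used throughout the package (one row per
#' trial: participant, condition, design magnitudes, choice, reaction time).
#'
#' @param path CSV path.
#' @return Trial tibble.
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c(
    "participant_id", "condition", "delay_days", "immediate_amount",
    "delayed_amount", "chosen"
  )
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("trial CSV lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad <- !df$condition %in% c("reward", "loss")
  if (any(bad)) {
    stop("invalid condition at row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  }
  tibble::as_tibble(df)
}
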
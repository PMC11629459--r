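# Preregistered exclusion rules and construction of the participant-level
# analysis table from raw questionnaire and trial data.

#' Apply trial-level quality control
#'
#' A participant is excluded when any of the preregistered rules fire:
#' completion below 80% of the scheduled trials in either condition (strict),
#' a stereotypical key-press pattern (exactly one distinct key across all
#' non-missing trials of the session, despite randomized option sides), or a
#' mean reaction time below 500 ms (strict) over the non-missing discounting
#' trials of both conditions pooled.
#'
#' @param trials Long-format trial tibble (all participants).
#' @param scheduled_per_condition Number of scheduled trials per condition
#'   used as the completion denominator (default 96).
#' @return Tibble with one row per participant: `participant_id`, `excluded`,
#'   `reasons` (comma-separated codes among `incomplete`,
#'   `stereotypical_keys`, `fast_rt`, `no_trials`), completion fractions and
#'   mean RT.
#' @export
apply_qc <- function(trials, scheduled_per_condition = 96L) {
  ids <- unique(trials$participant_id)
  rows <- lapply(ids, function(id) {
    tr <- trials[trials$participant_id == id, , drop = FALSE]
    reasons <- character(0)
    ok <- !is.na(tr$chosen) & tr$chosen != "missing"
    if (!any(ok)) {
      return(tibble::tibble(
        participant_id = id, excluded = TRUE, reasons = "no_trials",
        completion_reward = 0, completion_loss = 0, mean_rt = NA_real_
      ))
    }
    comp <- function(cond) {
      sum(ok & tr$condition == cond) / scheduled_per_condition
    }
    comp_r <- comp("reward")
    comp_l <- comp("loss")
    if (comp_r < 0.8 || comp_l < 0.8) reasons <- c(reasons, "incomplete")
    keys <- unique(tr$key[ok])
    if (length(setdiff(keys, "none")) == 1L) {
      reasons <- c(reasons, "stereotypical_keys")
    }
    mean_rt <- mean(tr$rt_ms[ok], na.rm = TRUE)
    if (is.finite(mean_rt) && mean_rt < 500) reasons <- c(reasons, "fast_rt")
    tibble::tibble(
      participant_id = id, excluded = length(reasons) > 0L,
      reasons = paste(reasons, collapse = ","),
      completion_reward = comp_r, completion_loss = comp_l, mean_rt = mean_rt
    )
  })
  tibble::as_tibble(do.call(rbind, rows))
}

#' Score the AUDIT questionnaire
#'
#' Sum of the ten item responses (items 1-8 scored 0-4; items 9-10 scored
#' 0, 2, or 4). Range 0-40; higher scores indicate more problematic use.
#'
#' @param items Integer vector of length 10.
#' @return Integer sum.
#' @export
score_audit <- function(items) {
  stopifnot(length(items) == 10L, !anyNA(items))
  if (any(items[1:8] < 0 | items[1:8] > 4) ||
      any(!items[9:10] %in% c(0, 2, 4))) {
    stop("AUDIT item out of range (items 1-8: 0-4; items 9-10: 0/2/4)")
  }
  as.integer(sum(items))
}

#' Score the BIS-15 impulsiveness scale
#'
#' Reverse-keyed items are mapped `x -> 5 - x`, then all fifteen items are
#' summed. Range 15-60.
#'
#' @param items Integer vector of length 15, each in 1-4.
#' @param reverse_key Indices of reverse-keyed items.
#' @return Integer sum.
#' @export
score_bis15 <- function(items, reverse_key = c(1, 4, 5, 6, 9, 11)) {
  stopifnot(length(items) == 15L, !anyNA(items))
  if (any(items < 1 | items > 4)) stop("BIS-15 item out of range (1-4)")
  scored <- items
  scored[reverse_key] <- 5 - items[reverse_key]
  as.integer(sum(scored))
}

#' Weekly drinking from DDQ daily units
#'
#' Sum of the seven average daily standard-unit counts.
#'
#' @param daily Numeric vector of length 7, nonnegative.
#' @return Weekly UK alcohol units.
#' @export
ddq_weekly_units <- function(daily) {
  stopifnot(length(daily) == 7L, !anyNA(daily))
  if (any(daily < 0)) stop("daily units must be nonnegative")
  sum(daily)
}

#' Convert weekly UK units to grams of ethanol per day
#'
#' One UK alcohol unit is 8 g of pure ethanol, so
#' `grams/day = weekly_units * 8 / 7`.
#'
#' @param weekly_units Weekly UK units (vectorized, `NA` passes through).
#' @return Grams of ethanol per day.
#' @examples
#' units_to_grams_per_day(24.43) # 27.92
#' @export
units_to_grams_per_day <- function(weekly_units) {
  if (any(weekly_units < 0, na.rm = TRUE)) {
    stop("weekly_units must be nonnegative")
  }
  weekly_units * 8 / 7
}

income_midpoint_table <- function() {
  mids <- c(5000, seq(15000, 95000, 10000), 125000, 175000, 225000, 250000)
  names(mids) <- INCOME_LABELS
  mids
}

normalize_income_label <- function(label) {
  x <- gsub("£", "", label)          # pound sign optional
  x <- gsub("–|—", "-", x)      # en/em dash -> hyphen
  x <- gsub("\\s+", " ", trimws(tolower(x)))
  x
}

#' Midpoint coding of an income band
#'
#' Maps the categorical income bands (GBP 10,000 increments to 100,000, then
#' 50,000 increments to 250,000) to their midpoints. The open-ended bands are
#' coded 5,000 ("less than 10,000") and 250,000 ("more than 250,000",
#' top-coded). Labels are matched case-insensitively, with or without the
#' pound sign, and with hyphen or en-dash ranges. `NA` passes through.
#'
#' @param label Character vector of band labels.
#' @return Numeric midpoints (GBP/year).
#' @examples
#' income_midpoint("10,000-20,000") # 15000
#' @export
income_midpoint <- function(label) {
  mids <- income_midpoint_table()
  keys <- normalize_income_label(names(mids))
  idx <- match(normalize_income_label(label), keys)
  bad <- !is.na(label) & is.na(idx)
  if (any(bad)) {
    stop("unknown income label(s): ", paste(unique(label[bad]), collapse = "; "))
  }
  unname(mids[idx])
}

#' Average parental education
#'
#' Mean of the available caregivers' ISCED levels (a single caregiver yields
#' that caregiver's level; both absent yields `NA`).
#'
#' @param primary,secondary ISCED levels 0-7, possibly `NA`.
#' @return Mean level or `NA`.
#' @export
parental_education <- function(primary, secondary = NA) {
  vals <- c(primary, secondary)
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0L) return(NA_real_)
  if (any(vals < 0 | vals > 7)) stop("ISCED levels must lie in 0-7")
  mean(vals)
}

#' Build the participant-level analysis table
#'
#' Joins questionnaire scores, transformed socioeconomic variables,
#' demographics, and per-condition discounting measures into one row per
#' QC-retained participant. Missing questionnaire entries propagate as `NA`
#' and are excluded per-analysis downstream, not listwise.
#'
#' @param participants Item-level participant tibble (schema of
#'   [sample_covariates]).
#' @param fits Per-participant/condition fit tibble from [fit_cohort].
#' @param trials Long-format trial tibble (for discounting frequencies).
#' @param qc QC tibble from [apply_qc]; excluded participants are dropped.
#' @param bis_reverse_key Reverse-keyed BIS-15 items used for scoring.
#' @return Analysis tibble with one row per retained participant.
#' @export
build_analysis_table <- function(participants, fits, trials, qc,
                                 bis_reverse_key = c(1, 4, 5, 6, 9, 11)) {
  if (anyDuplicated(participants$participant_id)) {
    stop("duplicate participant_id in `participants`")
  }
  keep <- participants
  if (!is.null(qc)) {
    excluded <- qc$participant_id[qc$excluded]
    keep <- keep[!keep$participant_id %in% excluded, , drop = FALSE]
  }
  if (nrow(keep) == 0L) {
    return(tibble::tibble(participant_id = character(0)))
  }

  audit_items <- as.matrix(keep[, sprintf("audit_%d", 1:10)])
  bis_items <- as.matrix(keep[, sprintf("bis_%d", 1:15)])
  ddq <- as.matrix(keep[, grep("^ddq_", names(keep))])
  weekly <- apply(ddq, 1, ddq_weekly_units)

  get_fit <- function(cond, col) {
    idx <- match(
      paste(keep$participant_id, cond),
      paste(fits$participant_id, fits$condition)
    )
    fits[[col]][idx]
  }
  rel_freq <- function(cond) {
    vapply(keep$participant_id, function(id) {
      tr <- trials[trials$participant_id == id & trials$condition == cond, ,
                   drop = FALSE]
      out <- tryCatch(
        relative_discounting_frequency(tr), error = function(e) NA_real_
      )
      out
    }, numeric(1), USE.NAMES = FALSE)
  }
  rf_R <- rel_freq("reward")
  rf_L <- rel_freq("loss")

  kappa_R <- get_fit("reward", "kappa")
  s_R <- get_fit("reward", "s")
  kappa_L <- get_fit("loss", "kappa")
  s_L <- get_fit("loss", "s")

  tibble::tibble(
    participant_id = keep$participant_id,
    audit_sum = apply(audit_items, 1, score_audit),
    bis15_sum = apply(bis_items, 1, score_bis15,
                      reverse_key = bis_reverse_key),
    weekly_units = weekly,
    grams_per_day = units_to_grams_per_day(weekly),
    education_num = as.numeric(keep$education),
    income_individual_num = income_midpoint(keep$income_individual_cat),
    income_household_num = income_midpoint(keep$income_household_cat),
    parental_education_num = mapply(
      parental_education, keep$parental_primary, keep$parental_secondary
    ),
    subjective_ses = keep$subjective_ses,
    adolescent_wellbeing = keep$adolescent_wellbeing,
    age = as.numeric(keep$age),
    gender_dummy = keep$gender,
    log_kappa_R = get_fit("reward", "log_kappa"),
    log_kappa_L = get_fit("loss", "log_kappa"),
    rel_freq_R = rf_R,
    rel_freq_L = rf_L,
    discount_factor_R = 1 / (1 + kappa_R * 365^s_R),
    discount_factor_L = 1 / (1 + kappa_L * 365^s_L),
    nondiscounter_R = classify_nondiscounter(ifelse(is.na(rf_R), 0, rf_R)) &
      !is.na(rf_R),
    nondiscounter_L = classify_nondiscounter(ifelse(is.na(rf_L), 0, rf_L)) &
      !is.na(rf_L),
    qc_excluded = FALSE
  )
}
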
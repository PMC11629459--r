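# Synthetic cohort generator: Gaussian-copula covariates matched to published
# marginal and correlation targets, ground-truth discounting parameters,
# simulated trial-level choices, and configurable response artifacts.

COPULA_VARS <- c(
  "log_kappa_R", "log_kappa_L", "audit", "weekly_units", "education",
  "income_individual", "income_household", "age", "bis15", "subjective_ses",
  "gender"
)

LOG_KAPPA_RANGE <- c(log(LOG_KAPPA_OFFSET), log(1000 + LOG_KAPPA_OFFSET))

INCOME_LABELS <- c(
  "less than 10,000",
  paste0(
    formatC(seq(10000, 90000, 10000), format = "d", big.mark = ","), "-",
    formatC(seq(20000, 100000, 10000), format = "d", big.mark = ",")
  ),
  "100,000-150,000", "150,000-200,000", "200,000-250,000",
  "more than 250,000"
)

income_band_pmf <- function(meanlog, sdlog) {
  edges <- c(0, seq(10000, 100000, 10000), 150000, 200000, 250000, Inf)
  p <- diff(stats::plnorm(edges, meanlog, sdlog))
  p / sum(p)
}

#' Default correlation targets for the synthetic cohort
#'
#' Pairwise Pearson targets among the latent copula variables. Nonzero
#' entries reproduce published associations between discounting, alcohol use,
#' socioeconomic status, age, and impulsivity in frequent drinkers; the
#' AUDIT-weekly-units entry ties the two alcohol measures together; all other
#' pairs default to zero. The matrix is repaired to the nearest positive
#' semi-definite correlation matrix before use.
#'
#' @return Named 11 x 11 correlation matrix over `log_kappa_R`,
#'   `log_kappa_L`, `audit`, `weekly_units`, `education`,
#'   `income_individual`, `income_household`, `age`, `bis15`,
#'   `subjective_ses`, `gender`.
#' @export
default_correlation_targets <- function() {
  R <- diag(length(COPULA_VARS))
  dimnames(R) <- list(COPULA_VARS, COPULA_VARS)
  set_r <- function(a, b, r) {
    R[a, b] <<- r
    R[b, a] <<- r
  }
  set_r("log_kappa_R", "audit", 0.15)
  set_r("log_kappa_R", "education", -0.19)
  set_r("log_kappa_R", "income_individual", -0.10)
  set_r("log_kappa_R", "log_kappa_L", 0.25)
  set_r("audit", "education", -0.15)
  set_r("audit", "income_individual", -0.12)
  set_r("education", "income_individual", 0.26)
  set_r("age", "log_kappa_R", -0.20)
  set_r("age", "audit", -0.22)
  set_r("bis15", "log_kappa_R", 0.17)
  set_r("bis15", "audit", 0.36)
  set_r("audit", "weekly_units", 0.60)
  R
}

#' Cohort generator configuration
#'
#' Defaults emulate the study conditions: n = 341 UK moderate-to-heavy
#' drinkers with gender-balanced sampling, the published covariate marginals,
#' the published correlation structure, and a 29.7% nondiscounter mixture in
#' the loss condition. Artifact rates are zero by default; raise them to
#' exercise quality-control screening downstream.
#'
#' @param n Number of participants.
#' @param correlation_targets Correlation matrix over the copula variables
#'   (see [default_correlation_targets]).
#' @param loss_nondiscounter_weight Probability that an agent's loss-side
#'   discount rate is replaced by the lower bound `kappa = 0`.
#' @param artifact_rates List with elements `stereotypical` (participant
#'   presses a single key throughout), `fast_rt` (participant responds with
#'   mean RT under 500 ms), `missing_trial` (per-trial non-response rate).
#' @param missing_rates Per-variable questionnaire missingness
#'   (`income_individual`, `income_household`, `parental_education`).
#' @param bis_reverse_key Indices of reverse-keyed BIS-15 items; the
#'   generator emits raw responses consistent with this key.
#' @param seed Master seed; every downstream draw derives from it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n = 341,
                          correlation_targets = default_correlation_targets(),
                          loss_nondiscounter_weight = 0.297,
                          artifact_rates = list(
                            stereotypical = 0, fast_rt = 0, missing_trial = 0
                          ),
                          missing_rates = list(
                            income_individual = 11 / 341,
                            income_household = 12 / 341,
                            parental_education = 23 / 341
                          ),
                          bis_reverse_key = c(1, 4, 5, 6, 9, 11),
                          seed = 1L) {
  stopifnot(
    n >= 2,
    identical(sort(rownames(correlation_targets)), sort(COPULA_VARS)),
    loss_nondiscounter_weight >= 0, loss_nondiscounter_weight <= 1,
    all(unlist(artifact_rates) >= 0), all(unlist(artifact_rates) <= 1)
  )
  structure(
    list(
      n = as.integer(n),
      correlation_targets =
        correlation_targets[COPULA_VARS, COPULA_VARS, drop = FALSE],
      loss_nondiscounter_weight = loss_nondiscounter_weight,
      artifact_rates = artifact_rates,
      missing_rates = missing_rates,
      bis_reverse_key = as.integer(bis_reverse_key),
      seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# Decompose an AUDIT sum into 10 item responses (items 1-8: 0..4,
# items 9-10: 0/2/4). Any allocation meeting the sum is valid; sums are the
# only quantity analyzed.
decompose_audit <- function(total, u) {
  stopifnot(total >= 0, total <= 40)
  i9 <- pick_from(intersect(c(0L, 2L, 4L), seq.int(max(0L, total - 36L), min(4L, total))), u[1])
  rem <- total - i9
  i10 <- pick_from(intersect(c(0L, 2L, 4L), seq.int(max(0L, rem - 32L), min(4L, rem))), u[2])
  rem <- rem - i10
  c(allocate_integer_sum(rem, 8L, 0L, 4L, u[3:10]), i9, i10)
}

# Decompose a scored BIS-15 sum (15..60) into raw 1..4 item responses under
# the reverse key.
decompose_bis15 <- function(total, reverse_key, u) {
  stopifnot(total >= 15, total <= 60)
  scored <- 1L + allocate_integer_sum(total - 15L, 15L, 0L, 3L, u)
  raw <- scored
  raw[reverse_key] <- 5L - scored[reverse_key]
  raw
}

# Split weekly units into a weekend-heavy daily profile
# (Mon..Thu 1, Fri 2, Sat 3, Sun 2), rounded to 0.1 units.
decompose_ddq <- function(weekly) {
  w <- c(1, 1, 1, 1, 2, 3, 2)
  round(weekly * w / sum(w), 1)
}

#' Sample cohort covariates from the Gaussian copula
#'
#' Draws a latent multivariate normal with the (PSD-repaired) target
#' correlation matrix and maps each margin by quantile transform: truncated
#' normals for age, AUDIT, BIS-15 and the latent log discount rates, a gamma
#' for weekly drinking, discretized categorical distributions for education,
#' income bands and subjective SES. Gender is assigned by latent rank so the
#' split is exactly balanced. Questionnaire sums are decomposed into
#' item-level responses; weekly units into a weekend-heavy daily profile.
#'
#' @param config A [cohort_config].
#' @return List with `participants` (item-level covariate tibble) and
#'   `latents` (tibble with `participant_id`, `log_kappa_R_latent`,
#'   `log_kappa_L_latent`).
#' @export
sample_covariates <- function(config = cohort_config()) {
  n <- config$n
  R <- psd_repair(config$correlation_targets)
  rng <- local_rng(derive_seed(config$seed, 11L))

  Z <- matrix(rng$rnorm(n * ncol(R)), nrow = n) %*% chol(R)
  colnames(Z) <- COPULA_VARS
  U <- stats::pnorm(Z)

  lat_R <- qtruncnorm(U[, "log_kappa_R"], -3.44, 3.40,
                      LOG_KAPPA_RANGE[1], LOG_KAPPA_RANGE[2])
  lat_L <- qtruncnorm(U[, "log_kappa_L"], -5.99, 3.77,
                      LOG_KAPPA_RANGE[1], LOG_KAPPA_RANGE[2])

  audit_sum <- as.integer(round(qtruncnorm(U[, "audit"], 11.76, 6.06, 0, 40)))
  gshape <- (24.43 / 18.48)^2
  weekly <- stats::qgamma(U[, "weekly_units"], shape = gshape,
                          rate = gshape / 24.43)
  education <- quantile_categorical(
    U[, "education"], discretized_normal_pmf(0:7, 4.31, 1.57)
  ) - 1L
  inc_ind <- quantile_categorical(
    U[, "income_individual"], income_band_pmf(9.9934, 0.70)
  )
  inc_hh <- quantile_categorical(
    U[, "income_household"], income_band_pmf(10.66, 0.67)
  )
  age <- as.integer(round(qtruncnorm(U[, "age"], 43.48, 11.90, 19, 65)))
  bis_sum <- as.integer(round(qtruncnorm(U[, "bis15"], 30.65, 6.65, 15, 60)))
  ses <- quantile_categorical(
    U[, "subjective_ses"], discretized_normal_pmf(1:10, 5.53, 1.63)
  )

  # exact gender balance via latent rank (male = 1 for the upper half)
  gender <- integer(n)
  gender[order(Z[, "gender"])] <- rep(
    c(0L, 1L), c(floor(n / 2), ceiling(n / 2))
  )

  um <- matrix(rng$runif(n * 40L), nrow = n)
  audit_items <- t(vapply(
    seq_len(n), function(i) decompose_audit(audit_sum[i], um[i, 1:10]),
    integer(10)
  ))
  bis_items <- t(vapply(
    seq_len(n),
    function(i) decompose_bis15(bis_sum[i], config$bis_reverse_key, um[i, 11:25]),
    integer(15)
  ))
  ddq <- t(vapply(seq_len(n), function(i) decompose_ddq(weekly[i]), numeric(7)))

  household <- quantile_categorical(
    rng$runif(n), discretized_normal_pmf(1:7, 2.60, 1.25)
  )
  wellbeing <- quantile_categorical(
    rng$runif(n), discretized_normal_pmf(0:4, 1.77, 0.93)
  ) - 1L
  par_pmf <- discretized_normal_pmf(0:7, 2.43, 1.73)
  par_primary <- quantile_categorical(rng$runif(n), par_pmf) - 1L
  par_secondary <- quantile_categorical(rng$runif(n), par_pmf) - 1L
  par_secondary[rng$runif(n) < 0.15] <- NA_integer_

  # questionnaire missingness (both caregivers missing -> parental NA)
  inc_ind_lab <- INCOME_LABELS[inc_ind]
  inc_hh_lab <- INCOME_LABELS[inc_hh]
  inc_ind_lab[rng$runif(n) < config$missing_rates$income_individual] <- NA
  inc_hh_lab[rng$runif(n) < config$missing_rates$income_household] <- NA
  par_na <- rng$runif(n) < config$missing_rates$parental_education
  par_primary[par_na] <- NA_integer_
  par_secondary[par_na] <- NA_integer_

  ids <- sprintf("P%04d", seq_len(n))
  participants <- tibble::tibble(
    participant_id = ids,
    age = age, gender = gender, education = education,
    income_individual_cat = inc_ind_lab, income_household_cat = inc_hh_lab,
    household_members = household, subjective_ses = ses,
    adolescent_wellbeing = wellbeing,
    parental_primary = par_primary, parental_secondary = par_secondary
  )
  colnames(audit_items) <- sprintf("audit_%d", 1:10)
  colnames(bis_items) <- sprintf("bis_%d", 1:15)
  colnames(ddq) <- paste0(
    "ddq_", c("mon", "tue", "wed", "thu", "fri", "sat", "sun")
  )
  participants <- tibble::as_tibble(
    cbind(participants, audit_items, bis_items, ddq)
  )
  latents <- tibble::tibble(
    participant_id = ids,
    log_kappa_R_latent = lat_R,
    log_kappa_L_latent = lat_L
  )
  list(participants = participants, latents = latents)
}

#' Derive ground-truth discounting parameters from copula latents
#'
#' The latent log discount rates invert the analysis transform,
#' `kappa = exp(latent) - 0.0001` (clipped to the bounds); scaling exponents
#' are uniform on `[0, 1]` and inverse temperatures uniform on `[0.5, 2]`.
#' With probability `loss_nondiscounter_weight` an agent's loss-side rate is
#' replaced by the lower bound `kappa = 0`, creating the nondiscounter
#' subgroup seen in the loss condition.
#'
#' @param latents Latent tibble from [sample_covariates].
#' @param config A [cohort_config].
#' @return Tibble with per-agent true parameters for both conditions and the
#'   `nondiscounter_L_true` flag.
#' @export
derive_true_params <- function(latents, config = cohort_config()) {
  rng <- local_rng(derive_seed(config$seed, 23L))
  n <- nrow(latents)
  clip_kappa <- function(lat) {
    pmin(pmax(exp(lat) - LOG_KAPPA_OFFSET, KAPPA_BOUNDS[1]), KAPPA_BOUNDS[2])
  }
  kappa_R <- clip_kappa(latents$log_kappa_R_latent)
  kappa_L <- clip_kappa(latents$log_kappa_L_latent)
  nondisc <- rng$runif(n) < config$loss_nondiscounter_weight
  kappa_L[nondisc] <- 0
  tibble::tibble(
    participant_id = latents$participant_id,
    kappa_R = kappa_R,
    s_R = rng$runif(n),
    beta_R = rng$runif(n, 0.5, 2),
    kappa_L = kappa_L,
    s_L = rng$runif(n),
    beta_L = rng$runif(n, 0.5, 2),
    nondiscounter_L_true = nondisc
  )
}

# Map a choice and the immediate option's side to the pressed key
# (Q = left option, P = right option).
choice_to_key <- function(chosen, immediate_side) {
  ifelse(
    chosen == "immediate",
    ifelse(immediate_side == "left", "Q", "P"),
    ifelse(immediate_side == "left", "P", "Q")
  )
}

# Draw truncated-lognormal reaction times (resampling above the cap).
draw_rt <- function(rng, n, meanlog, sdlog, cap = 10000) {
  rt <- rng$rlnorm(n, meanlog, sdlog)
  while (any(bad <- rt > cap)) rt[bad] <- rng$rlnorm(sum(bad), meanlog, sdlog)
  rt
}

#' Simulate one participant's trial-level choices
#'
#' Each trial's choice is Bernoulli with the immediate-choice probability
#' implied by the agent's condition-specific true parameters; reaction times
#' are lognormal (median 1500 ms, sigma 0.4) truncated to 10 s; the pressed
#' key follows from the choice and the side of the immediate option.
#'
#' @param agent One row of the ground-truth tibble from
#'   [derive_true_params].
#' @param plan Session plan from [randomize_blocks].
#' @param seed Integer seed.
#' @return Trial tibble in the long-format schema (`participant_id`,
#'   `condition`, `block`, `trial_id`, `delay_days`, `immediate_amount`,
#'   `delayed_amount`, `immediate_side`, `key`, `chosen`, `rt_ms`).
#' @export
simulate_participant_choices <- function(agent, plan, seed = 1L) {
  rng <- local_rng(seed)
  is_loss <- plan$condition == "loss"
  kappa <- ifelse(is_loss, agent$kappa_L, agent$kappa_R)
  s <- ifelse(is_loss, agent$s_L, agent$s_R)
  beta <- ifelse(is_loss, agent$beta_L, agent$beta_R)
  sgn <- ifelse(is_loss, -1, 1)
  v1 <- sgn * plan$immediate_amount
  v2 <- sgn * hyperboloid_value(kappa, s, plan$delayed_amount, plan$delay_days)
  p1 <- p_immediate(beta, v1, v2)
  chosen <- ifelse(rng$runif(nrow(plan)) < p1, "immediate", "delayed")
  tibble::tibble(
    participant_id = agent$participant_id,
    condition = plan$condition,
    block = plan$block,
    trial_id = plan$trial_id,
    delay_days = plan$delay_days,
    immediate_amount = plan$immediate_amount,
    delayed_amount = plan$delayed_amount,
    immediate_side = plan$immediate_side,
    key = choice_to_key(chosen, plan$immediate_side),
    chosen = chosen,
    rt_ms = draw_rt(rng, nrow(plan), log(1500), 0.4)
  )
}

#' Inject response artifacts into simulated trials
#'
#' Applies the ground-truth artifact flags: stereotypical agents press a
#' single key throughout (choices re-derived from the option sides), fast-RT
#' agents get reaction times resampled with mean below 500 ms, and a
#' per-trial missingness rate blanks the response.
#'
#' @param trials Simulated trial tibble.
#' @param flags Tibble with `participant_id`, `stereotypical`, `fast_rt`.
#' @param config A [cohort_config] (supplies the `missing_trial` rate).
#' @param seed Integer seed.
#' @return The trial tibble with artifacts applied.
#' @export
inject_artifacts <- function(trials, flags, config = cohort_config(),
                             seed = 1L) {
  rng <- local_rng(seed)
  out <- trials
  stereo_ids <- flags$participant_id[flags$stereotypical]
  for (id in stereo_ids) {
    idx <- which(out$participant_id == id)
    key <- c("Q", "P")[rng$sample_int(2L)[1]]
    out$key[idx] <- key
    side_of_key <- if (key == "Q") "left" else "right"
    out$chosen[idx] <- ifelse(
      out$immediate_side[idx] == side_of_key, "immediate", "delayed"
    )
  }
  fast_ids <- flags$participant_id[flags$fast_rt]
  for (id in fast_ids) {
    idx <- which(out$participant_id == id)
    out$rt_ms[idx] <- draw_rt(rng, length(idx), log(350), 0.3)
  }
  rate <- config$artifact_rates$missing_trial
  if (rate > 0) {
    miss <- rng$runif(nrow(out)) < rate
    out$chosen[miss] <- "missing"
    out$key[miss] <- "none"
    out$rt_ms[miss] <- NA_real_
  }
  out
}

#' Generate a complete synthetic cohort
#'
#' End-to-end composition: covariates and latents from the copula, true
#' discounting parameters, a per-participant randomized session over the
#' task design, simulated choices, and artifact injection. Fully reproducible
#' from the master seed.
#'
#' @param config A [cohort_config].
#' @param design_cfg A [design_config] for the trial structure.
#' @return List of class `synthetic_cohort` with `participants` (item-level
#'   covariates), `trials` (long-format choice rows), `ground_truth` (true
#'   parameters, latents, artifact flags), and the two configs.
#' @export
generate_cohort <- function(config = cohort_config(),
                            design_cfg = design_config()) {
  cov <- sample_covariates(config)
  truth <- derive_true_params(cov$latents, config)

  rng <- local_rng(derive_seed(config$seed, 37L))
  n <- config$n
  flags <- tibble::tibble(
    participant_id = truth$participant_id,
    stereotypical = rng$runif(n) < config$artifact_rates$stereotypical,
    fast_rt = rng$runif(n) < config$artifact_rates$fast_rt
  )

  design <- generate_design(design_cfg)
  trials <- vector("list", n)
  for (i in seq_len(n)) {
    plan <- randomize_blocks(design, seed = derive_seed(config$seed, 100L + i))
    trials[[i]] <- simulate_participant_choices(
      truth[i, ], plan, seed = derive_seed(config$seed, 5000L + i)
    )
  }
  trials <- tibble::as_tibble(do.call(rbind, trials))
  trials <- inject_artifacts(
    trials, flags, config, seed = derive_seed(config$seed, 53L)
  )

  ground_truth <- tibble::as_tibble(cbind(
    truth,
    cov$latents[match(truth$participant_id, cov$latents$participant_id),
                c("log_kappa_R_latent", "log_kappa_L_latent")],
    flags[match(truth$participant_id, flags$participant_id),
          c("stereotypical", "fast_rt")]
  ))
  structure(
    list(
      participants = cov$participants, trials = trials,
      ground_truth = ground_truth, config = config, design_config = design_cfg
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf(
    "<synthetic_cohort> %d participants, %d trial rows (seed %d)\n",
    nrow(x$participants), nrow(x$trials), x$config$seed
  ))
  invisible(x)
}

#' Covariate-level analysis table with ground-truth discounting
#'
#' Builds a participant analysis table directly from the generator's
#' covariates and true parameters, bypassing choice simulation and model
#' fitting. Intended for calibration studies of the statistical suite, where
#' thousands of cohorts are needed and fitting noise is not under study.
#'
#' @param cohort A `synthetic_cohort`, or the list returned by
#'   [sample_covariates] combined with [derive_true_params] ground truth.
#' @return A participant analysis tibble (see [build_analysis_table]).
#' @export
cohort_truth_table <- function(cohort) {
  p <- cohort$participants
  g <- cohort$ground_truth
  stopifnot(identical(p$participant_id, g$participant_id))
  audit_items <- as.matrix(p[, sprintf("audit_%d", 1:10)])
  bis_items <- as.matrix(p[, sprintf("bis_%d", 1:15)])
  ddq <- as.matrix(p[, grep("^ddq_", names(p))])
  weekly <- rowSums(ddq)
  reverse_key <- cohort$config$bis_reverse_key
  tibble::tibble(
    participant_id = p$participant_id,
    audit_sum = apply(audit_items, 1, score_audit),
    bis15_sum = apply(bis_items, 1, score_bis15, reverse_key = reverse_key),
    weekly_units = weekly,
    grams_per_day = units_to_grams_per_day(weekly),
    education_num = as.numeric(p$education),
    income_individual_num = income_midpoint(p$income_individual_cat),
    income_household_num = income_midpoint(p$income_household_cat),
    parental_education_num = mapply(
      parental_education, p$parental_primary, p$parental_secondary
    ),
    subjective_ses = p$subjective_ses,
    adolescent_wellbeing = p$adolescent_wellbeing,
    age = as.numeric(p$age),
    gender_dummy = p$gender,
    log_kappa_R = log_kappa(g$kappa_R),
    log_kappa_L = log_kappa(g$kappa_L),
    rel_freq_R = NA_real_,
    rel_freq_L = NA_real_,
    discount_factor_R = 1 / (1 + g$kappa_R * 365^g$s_R),
    discount_factor_L = 1 / (1 + g$kappa_L * 365^g$s_L),
    nondiscounter_R = FALSE,
    nondiscounter_L = g$kappa_L == 0,
    qc_excluded = FALSE
  )
}
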
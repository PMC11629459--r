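# Gaussian-copula cohort generator: marginals, correlation fidelity,
# ground-truth parameters, choice simulation, artifacts.

observed_copula_frame <- function(cov, reverse_key) {
  p <- cov$participants
  data.frame(
    log_kappa_R = cov$latents$log_kappa_R_latent,
    log_kappa_L = cov$latents$log_kappa_L_latent,
    audit = rowSums(p[, sprintf("audit_%d", 1:10)]),
    weekly_units = rowSums(p[, grep("^ddq_", names(p))]),
    education = p$education,
    income_individual = income_midpoint(p$income_individual_cat),
    income_household = income_midpoint(p$income_household_cat),
    age = p$age,
    bis15 = apply(p[, sprintf("bis_%d", 1:15)], 1, score_bis15,
                  reverse_key = reverse_key),
    subjective_ses = p$subjective_ses,
    gender = p$gender
  )
}

test_that("copula draws reproduce the target correlation structure", {
  cfg <- cohort_config(n = 5000, seed = 2025)
  cov <- sample_covariates(cfg)
  obs <- observed_copula_frame(cov, cfg$bis_reverse_key)
  target <- discountr:::psd_repair(cfg$correlation_targets)
  emp <- cor(obs, use = "pairwise.complete.obs")
  expect_lt(max(abs(emp[colnames(target), colnames(target)] - target)), 0.04)
})

test_that("independence targets yield near-zero empirical correlations", {
  R <- diag(11)
  dimnames(R) <- dimnames(default_correlation_targets())
  cfg <- cohort_config(n = 341, correlation_targets = R, seed = 31)
  cov <- sample_covariates(cfg)
  obs <- observed_copula_frame(cov, cfg$bis_reverse_key)
  emp <- cor(obs, use = "pairwise.complete.obs")
  diag(emp) <- 0
  expect_lt(max(abs(emp)), 0.15)
})

test_that("covariate marginals respect their published ranges and gender is balanced", {
  cfg <- cohort_config(n = 341, seed = 8)
  cov <- sample_covariates(cfg)
  p <- cov$participants
  expect_equal(nrow(p), 341L)
  expect_lte(abs(sum(p$gender == 0) - sum(p$gender == 1)), 1L)
  audit <- rowSums(p[, sprintf("audit_%d", 1:10)])
  expect_true(all(audit >= 0 & audit <= 40))
  expect_true(all(as.matrix(p[, sprintf("audit_%d", 1:8)]) %in% 0:4))
  expect_true(all(as.matrix(p[, c("audit_9", "audit_10")]) %in% c(0, 2, 4)))
  expect_true(all(as.matrix(p[, sprintf("bis_%d", 1:15)]) %in% 1:4))
  bis <- apply(p[, sprintf("bis_%d", 1:15)], 1, score_bis15,
               reverse_key = cfg$bis_reverse_key)
  expect_true(all(bis >= 15 & bis <= 60))
  expect_true(all(p$age >= 19 & p$age <= 65))
  expect_true(all(p$education %in% 0:7))
  expect_true(all(p$subjective_ses %in% 1:10))
  ddq <- as.matrix(p[, grep("^ddq_", names(p))])
  expect_true(all(ddq >= 0))
  # weekend-heavy profile: Saturday at least the weekday average
  expect_true(all(ddq[, "ddq_sat"] >= ddq[, "ddq_mon"]))
  # latent log kappas inside the transform's range
  expect_true(all(cov$latents$log_kappa_R_latent >= log(1e-4) &
                    cov$latents$log_kappa_R_latent <= log(1000.0001)))
})

test_that("true parameters invert the log transform and mix in nondiscounters", {
  cfg <- cohort_config(n = 341, seed = 1)
  cov <- sample_covariates(cfg)
  truth <- derive_true_params(cov$latents, cfg)
  # bound latents map back to the kappa bounds
  lat <- tibble::tibble(
    participant_id = c("A", "B"),
    log_kappa_R_latent = c(log(1e-4), log(1000.0001)),
    log_kappa_L_latent = c(log(1e-4), log(1000.0001))
  )
  tp <- derive_true_params(lat, cohort_config(n = 2, loss_nondiscounter_weight = 0, seed = 3))
  expect_equal(tp$kappa_R, c(0, 1000), tolerance = 1e-10)
  # interior latents round-trip through log_kappa
  mid <- truth$kappa_R[truth$kappa_R > 0 & truth$kappa_R < 1000]
  lat_mid <- cov$latents$log_kappa_R_latent[truth$kappa_R > 0 & truth$kappa_R < 1000]
  expect_equal(log_kappa(mid), lat_mid, tolerance = 1e-8)
  # parameters respect their bounds
  expect_true(all(truth$s_R >= 0 & truth$s_R <= 1))
  expect_true(all(truth$beta_R >= 0.5 & truth$beta_R <= 2))
  # loss-side nondiscounter mixture near its configured weight
  frac <- mean(truth$kappa_L == 0)
  expect_gt(frac, 0.297 - 0.05)
  expect_lt(frac, 0.297 + 0.05)
  expect_true(all(truth$kappa_L[truth$nondiscounter_L_true] == 0))
})

test_that("choice simulation follows the generating probabilities", {
  # a patient agent (kappa_R = 0) with decisive beta on a design solved for a
  # steeper hypothetical discounter chooses delayed almost always
  dcfg <- design_config(
    hypothetical_params = rep(list(discounting_params(0.01, 1, 1)), 4)
  )
  plan <- randomize_blocks(generate_design(dcfg), seed = 5)
  agent <- tibble::tibble(
    participant_id = "A", kappa_R = 0, s_R = 0.5, beta_R = 2,
    kappa_L = 0, s_L = 0.5, beta_L = 2
  )
  tr <- simulate_participant_choices(agent, plan, seed = 21)
  rw <- tr[tr$condition == "reward", ]
  expect_gt(mean(rw$chosen == "delayed"), 0.90)
  # determinism
  tr2 <- simulate_participant_choices(agent, plan, seed = 21)
  expect_identical(tr, tr2)
  # keys are consistent with choices and sides
  expect_true(all(
    tr$key == ifelse(
      (tr$chosen == "immediate") == (tr$immediate_side == "left"), "Q", "P"
    )
  ))
  expect_true(all(tr$rt_ms > 0 & tr$rt_ms <= 10000))
})

test_that("a flat choice rule pulls responding toward chance regardless of kappa", {
  # at beta = 0.01 the largest value difference the design can produce
  # (about 49 GBP) maps to a logit of only ~0.5, so the immediate-choice
  # rate collapses toward 0.5 whatever kappa is; the residual deviation is
  # the analytic mean of the flattened sigmoid over the design
  dcfg <- design_config(
    hypothetical_params = rep(list(discounting_params(0.01, 1, 1)), 40)
  )
  plan <- randomize_blocks(generate_design(dcfg), seed = 6)
  rw <- plan[plan$condition == "reward", ]
  for (kappa in c(0, 5)) {
    v2 <- rw$delayed_amount / (1 + kappa * rw$delay_days^0.5)
    analytic <- mean(plogis(-0.01 * (v2 - rw$immediate_amount)))
    agent <- tibble::tibble(
      participant_id = "A", kappa_R = kappa, s_R = 0.5, beta_R = 0.01,
      kappa_L = kappa, s_L = 0.5, beta_L = 0.01
    )
    tr <- simulate_participant_choices(agent, plan, seed = 9)
    rate <- mean(tr$chosen[tr$condition == "reward"] == "immediate")
    expect_lt(abs(rate - analytic), 0.03)
    expect_lt(abs(rate - 0.5), 0.10)
    # decisive choices under the same values would sit far from chance
    agent$beta_R <- 2
    tr2 <- simulate_participant_choices(agent, plan, seed = 9)
    rate2 <- mean(tr2$chosen[tr2$condition == "reward"] == "immediate")
    expect_gt(abs(rate2 - 0.5), abs(rate - 0.5))
  }
})

test_that("artifact injection matches its flags and leaves clean data alone", {
  cfg <- cohort_config(n = 6, seed = 13)
  ch <- generate_cohort(cfg, small_design_config())
  flags <- tibble::tibble(
    participant_id = unique(ch$trials$participant_id),
    stereotypical = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    fast_rt = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)
  )
  out <- inject_artifacts(ch$trials, flags, cfg, seed = 2)
  for (i in seq_len(nrow(flags))) {
    rows <- out[out$participant_id == flags$participant_id[i], ]
    if (flags$stereotypical[i]) {
      expect_length(unique(rows$key), 1L)
    }
    if (flags$fast_rt[i]) {
      expect_lt(mean(rows$rt_ms), 500)
    }
  }
  # rates zero and no flags: unchanged rows
  noflags <- flags
  noflags$stereotypical <- FALSE
  noflags$fast_rt <- FALSE
  expect_identical(inject_artifacts(ch$trials, noflags, cfg, seed = 2), ch$trials)
})

test_that("generate_cohort is reproducible and correctly shaped", {
  cfg <- cohort_config(n = 10, seed = 77)
  a <- generate_cohort(cfg, small_design_config())
  b <- generate_cohort(cfg, small_design_config())
  expect_identical(a$participants, b$participants)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ground_truth, b$ground_truth)
  expect_equal(nrow(a$participants), 10L)
  counts <- table(a$trials$participant_id, a$trials$condition)
  expect_true(all(counts == 8L))
  expect_setequal(
    names(a$ground_truth),
    c("participant_id", "kappa_R", "s_R", "beta_R", "kappa_L", "s_L",
      "beta_L", "nondiscounter_L_true", "log_kappa_R_latent",
      "log_kappa_L_latent", "stereotypical", "fast_rt")
  )
})

test_that("fitting a simulated cohort recovers the configured alcohol association", {
  cfg <- cohort_config(n = 80, seed = 19)
  ch <- generate_cohort(cfg)
  rw <- ch$trials[ch$trials$condition == "reward", ]
  fits <- fit_cohort(rw)
  tt <- cohort_truth_table(ch)
  m <- match(tt$participant_id, fits$participant_id)
  fitted_logk <- fits$log_kappa[m]
  # recovery: fitted log kappa tracks the generating latent
  expect_gt(cor(fitted_logk, ch$ground_truth$log_kappa_R_latent), 0.8)
  # the H1 association lands inside the Fisher-z 95% sampling band of the
  # configured target r = 0.15 at this n
  r_obs <- cor(fitted_logk, tt$audit_sum)
  band <- tanh(atanh(0.15) + c(-1, 1) * qnorm(0.975) / sqrt(80 - 3))
  expect_gt(r_obs, band[1])
  expect_lt(r_obs, band[2])
})
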
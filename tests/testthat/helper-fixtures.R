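# Shared fixtures built in code at test time.

# A compact design for fast fitting tests (8 trials per condition).
small_design_config <- function() {
  design_config(
    delays = c(30, 365),
    delayed_amounts = c(10, 50),
    hypothetical_params = list(
      discounting_params(0.01, 1, 1), discounting_params(0.1, 1, 1)
    )
  )
}

# One simulated participant's reward-condition trials under known parameters.
simulate_reward_trials <- function(kappa, s, beta, seed,
                                   design_cfg = design_config()) {
  d <- generate_design(design_cfg)
  plan <- randomize_blocks(d, seed = seed)
  agent <- tibble::tibble(
    participant_id = "SIM", kappa_R = kappa, s_R = s, beta_R = beta,
    kappa_L = kappa, s_L = s, beta_L = beta
  )
  tr <- simulate_participant_choices(agent, plan, seed = seed + 1L)
  tr[tr$condition == "reward", , drop = FALSE]
}

# Minimal hand-built trial table for QC tests: `pattern` controls chosen/key.
manual_trials <- function(id, n_reward = 96, n_loss = 96, rt = 900,
                          missing_loss = 0, single_key = FALSE) {
  n <- n_reward + n_loss
  cond <- c(rep("reward", n_reward), rep("loss", n_loss))
  side <- rep(c("left", "right"), length.out = n)
  chosen <- rep(c("immediate", "delayed", "delayed", "immediate"),
                length.out = n)
  key <- ifelse(
    (chosen == "immediate") == (side == "left"), "Q", "P"
  )
  if (single_key) {
    key <- rep("Q", n)
    chosen <- ifelse(side == "left", "immediate", "delayed")
  }
  tr <- tibble::tibble(
    participant_id = id, condition = cond, block = 1L,
    trial_id = sprintf("T%03d", seq_len(n)), delay_days = 30,
    immediate_amount = 5, delayed_amount = 10, immediate_side = side,
    key = key, chosen = chosen, rt_ms = rt
  )
  if (missing_loss > 0) {
    idx <- which(tr$condition == "loss")[seq_len(missing_loss)]
    tr$chosen[idx] <- "missing"
    tr$key[idx] <- "none"
    tr$rt_ms[idx] <- NA_real_
  }
  tr
}

# Item-level participant rows with controllable sums, for table-building
# tests (uses all-zero AUDIT items shifted to hit the target).
manual_participants <- function(ids, audit_sums = 10, seed = 1) {
  set.seed(seed)
  n <- length(ids)
  audit_sums <- rep_len(audit_sums, n)
  base <- tibble::tibble(
    participant_id = ids,
    age = sample(20:64, n, replace = TRUE),
    gender = rep_len(c(0L, 1L), n),
    education = sample(1:7, n, replace = TRUE),
    income_individual_cat = rep_len("10,000-20,000", n),
    income_household_cat = rep_len("20,000-30,000", n),
    household_members = 2L, subjective_ses = 5L, adolescent_wellbeing = 2L,
    parental_primary = 3L, parental_secondary = 4L
  )
  audit <- t(vapply(as.integer(audit_sums), function(s) {
    items <- integer(10)
    for (j in 1:8) {
      items[j] <- as.integer(min(4L, s))
      s <- s - items[j]
    }
    items[9] <- as.integer(min(4L, s - s %% 2L))
    s <- s - items[9]
    items[10] <- as.integer(min(4L, s))
    items
  }, integer(10)))
  colnames(audit) <- sprintf("audit_%d", 1:10)
  bis <- matrix(2L, n, 15, dimnames = list(NULL, sprintf("bis_%d", 1:15)))
  ddq <- matrix(2, n, 7, dimnames = list(
    NULL, paste0("ddq_", c("mon", "tue", "wed", "thu", "fri", "sat", "sun"))
  ))
  tibble::as_tibble(cbind(base, audit, bis, ddq))
}
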
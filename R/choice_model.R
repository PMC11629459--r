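# Hyperboloid intertemporal-choice model: value function, sigmoid choice rule,
# likelihood, and bounded multi-start maximum-likelihood fitting.

KAPPA_BOUNDS <- c(0, 1000)
S_BOUNDS <- c(0, 1)
BETA_BOUNDS <- c(0.01, 2)
LOG_KAPPA_OFFSET <- 1e-4
NLL_CLIP_EPS <- 1e-12

#' Discounting parameter set
#'
#' Bundles the three parameters of the modified hyperboloid choice model for
#' one task condition: the discount rate `kappa` (value halves over
#' `1/kappa` days when `s = 1`), the temporal scaling exponent `s`, and the
#' inverse temperature `beta` of the sigmoid choice rule (high `beta` means
#' near-deterministic value-based choice, low `beta` means random choice).
#'
#' @param kappa Discount rate, in `[0, 1000]` (units day^-s).
#' @param s Temporal scaling exponent, in `[0, 1]` (dimensionless).
#' @param beta Inverse temperature of the choice rule, in `[0.01, 2]`.
#' @param condition `"reward"` or `"loss"`.
#' @return An object of class `discounting_params`.
#' @examples
#' discounting_params(kappa = 0.01, s = 1, beta = 1)
#' @export
discounting_params <- function(kappa, s, beta, condition = c("reward", "loss")) {
  condition <- match.arg(condition)
  stopifnot(
    is.numeric(kappa), length(kappa) == 1L, is.finite(kappa),
    is.numeric(s), length(s) == 1L, is.finite(s),
    is.numeric(beta), length(beta) == 1L, is.finite(beta)
  )
  if (kappa < KAPPA_BOUNDS[1] || kappa > KAPPA_BOUNDS[2]) {
    stop("`kappa` must lie in [", KAPPA_BOUNDS[1], ", ", KAPPA_BOUNDS[2], "]")
  }
  if (s < S_BOUNDS[1] || s > S_BOUNDS[2]) {
    stop("`s` must lie in [", S_BOUNDS[1], ", ", S_BOUNDS[2], "]")
  }
  if (beta < BETA_BOUNDS[1] || beta > BETA_BOUNDS[2]) {
    stop("`beta` must lie in [", BETA_BOUNDS[1], ", ", BETA_BOUNDS[2], "]")
  }
  structure(
    list(kappa = kappa, s = s, beta = beta, condition = condition),
    class = "discounting_params"
  )
}

#' @export
print.discounting_params <- function(x, ...) {
  cat(sprintf(
    "<discounting_params> %s: kappa = %.4g, s = %.3f, beta = %.3f\n",
    x$condition, x$kappa, x$s, x$beta
  ))
  invisible(x)
}

# Discounted present value of the delayed amount (unsigned magnitude).
# Vectorized over delay/r2.
hyperboloid_value <- function(kappa, s, delayed_amount, delay_days) {
  delayed_amount / (1 + kappa * delay_days^s)
}

#' Subjective value of one option in a trial
#'
#' Immediate options are valued at face value; delayed options are discounted
#' hyperboloidally, `V = r2 / (1 + kappa * D^s)`. In the loss condition both
#' options carry negative sign, so the steeper the discounting the *less*
#' aversive the delayed loss appears.
#'
#' @param params A [discounting_params] object.
#' @param trial A list or one-row data frame with `delay_days`,
#'   `immediate_amount`, `delayed_amount`.
#' @param option `"immediate"` or `"delayed"`.
#' @return Signed subjective value (same monetary units as the amounts).
#' @examples
#' p <- discounting_params(0.01, 1, 1)
#' trial <- list(delay_days = 365, immediate_amount = 10, delayed_amount = 50)
#' subjective_value(p, trial, "delayed") # 50 / (1 + 0.01 * 365)
#' @export
subjective_value <- function(params, trial, option) {
  if (!option %in% c("immediate", "delayed")) {
    stop("`option` must be \"immediate\" or \"delayed\"")
  }
  sgn <- if (params$condition == "loss") -1 else 1
  if (option == "immediate") {
    return(sgn * trial$immediate_amount)
  }
  sgn * hyperboloid_value(params$kappa, params$s, trial$delayed_amount, trial$delay_days)
}

# Probability of the immediate option from signed values, vectorized.
# p(a1) = 1 / (1 + exp(beta * (V2 - V1))); plogis keeps the exponent safe.
p_immediate <- function(beta, v_immediate, v_delayed) {
  p <- stats::plogis(-beta * (v_delayed - v_immediate))
  # stay strictly inside (0, 1) even at sigmoid saturation
  pmin(pmax(p, .Machine$double.xmin), 1 - .Machine$double.eps / 2)
}

#' Probability of choosing the immediate option
#'
#' Sigmoid choice rule `p(a1) = 1 / (1 + exp(beta * (V_a2 - V_a1)))` applied
#' to the signed subjective values of the two options.
#'
#' @inheritParams subjective_value
#' @return Probability in (0, 1). `1 - p` is the delayed-choice probability.
#' @export
choice_probability <- function(params, trial) {
  v1 <- subjective_value(params, trial, "immediate")
  v2 <- subjective_value(params, trial, "delayed")
  p_immediate(params$beta, v1, v2)
}

# Internal vectorized NLL over raw columns; params need not respect bounds
# exactly (finite-difference gradients probe just outside them).
nll_core <- function(kappa, s, beta, condition, delay_days, immediate_amount,
                     delayed_amount, chose_immediate, eps = NLL_CLIP_EPS) {
  sgn <- ifelse(condition == "loss", -1, 1)
  v1 <- sgn * immediate_amount
  v2 <- sgn * hyperboloid_value(kappa, s, delayed_amount, delay_days)
  p1 <- stats::plogis(-beta * (v2 - v1))
  p <- ifelse(chose_immediate, p1, 1 - p1)
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(log(p))
}

check_one_condition <- function(choices) {
  cond <- unique(choices$condition)
  if (length(cond) > 1L) {
    stop("`choices` must all come from one condition; found: ",
         paste(cond, collapse = ", "))
  }
  cond
}

#' Negative log-likelihood of a choice sequence
#'
#' Sum over non-missing trials of `-log` of the probability assigned to the
#' observed choice. Probabilities are clipped to `[1e-12, 1 - 1e-12]` so the
#' result is always finite. Missing trials are skipped, not imputed.
#'
#' @param params A [discounting_params] object.
#' @param choices Data frame of trial rows from one condition with columns
#'   `condition`, `delay_days`, `immediate_amount`, `delayed_amount`, `chosen`
#'   (`"immediate"`, `"delayed"`, or `"missing"`/`NA`).
#' @return Nonnegative scalar. An empty or all-missing input returns 0 with a
#'   warning and attribute `all_missing = TRUE`.
#' @export
negative_log_likelihood <- function(params, choices) {
  if (nrow(choices) > 0L) check_one_condition(choices)
  keep <- !is.na(choices$chosen) & choices$chosen != "missing"
  if (!any(keep)) {
    warning("no non-missing trials; returning 0")
    return(structure(0, all_missing = TRUE))
  }
  ch <- choices[keep, , drop = FALSE]
  nll_core(
    params$kappa, params$s, params$beta, params$condition,
    ch$delay_days, ch$immediate_amount, ch$delayed_amount,
    ch$chosen == "immediate"
  )
}

#' Log-transformed discount rate
#'
#' Natural log after adding a constant of 0.0001, so that `kappa = 0` (no
#' discounting, the lower optimization bound) maps to a finite value:
#' `log_kappa(0) = -9.21`, `log_kappa(1000) = 6.91`.
#'
#' @param kappa Discount rate(s), each in `[0, 1000]`.
#' @return `log(kappa + 0.0001)`.
#' @export
log_kappa <- function(kappa) {
  if (any(kappa < 0)) stop("`kappa` must be nonnegative")
  log(kappa + LOG_KAPPA_OFFSET)
}

#' Discount factor at a one-year delay
#'
#' The fraction of face value retained by a delayed outcome at D = 365 days:
#' `1 / (1 + kappa * 365^s)`. One of the model-free-facing summary indices of
#' discounting steepness (1 = no devaluation).
#'
#' @param params A [discounting_params] object.
#' @return Value in (0, 1].
#' @export
discount_factor_one_year <- function(params) {
  1 / (1 + params$kappa * 365^params$s)
}

#' Relative frequency of discounted choices
#'
#' Percentage of non-missing trials on which the participant made the
#' "discounting" choice: the immediate option in the reward condition, the
#' delayed (larger-later) loss in the loss condition.
#'
#' @param choices Trial rows from one condition (see
#'   [negative_log_likelihood]).
#' @return Percent in `[0, 100]`.
#' @export
relative_discounting_frequency <- function(choices) {
  cond <- check_one_condition(choices)
  keep <- !is.na(choices$chosen) & choices$chosen != "missing"
  if (!any(keep)) stop("no non-missing trials")
  chosen <- choices$chosen[keep]
  discounted <- if (cond == "loss") chosen == "delayed" else chosen == "immediate"
  100 * mean(discounted)
}

#' Classify a participant as a nondiscounter
#'
#' Nondiscounters are participants whose relative discounting frequency is
#' strictly below 5%.
#'
#' @param freq Percent in `[0, 100]`.
#' @return Logical.
#' @export
classify_nondiscounter <- function(freq) {
  stopifnot(all(freq >= 0 & freq <= 100))
  freq < 5
}

#' Fitting configuration for [fit_discounting]
#'
#' The likelihood is multimodal in (kappa, s), so fitting uses a fixed 3x3x3
#' start grid plus two boundary-profile candidates with kappa pinned at each
#' of its bounds (where the MLE lies for all-immediate / all-delayed
#' responders and a box-constrained quasi-Newton run can stall on the flat
#' approach). Everything is deterministic.
#'
#' @param start_log_kappa,start_s,start_beta Start-grid coordinates.
#' @param eps Probability clipping constant inside the likelihood.
#' @param boundary_profiles Evaluate kappa-bound profile candidates.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(start_log_kappa = c(-7, -3, 1),
                       start_s = c(0.2, 0.5, 0.9),
                       start_beta = c(0.1, 1.0, 1.9),
                       eps = NLL_CLIP_EPS,
                       boundary_profiles = TRUE) {
  structure(
    list(
      start_log_kappa = start_log_kappa, start_s = start_s,
      start_beta = start_beta, eps = eps,
      boundary_profiles = boundary_profiles
    ),
    class = "fit_config"
  )
}

#' Fit the hyperboloid discounting model by maximum likelihood
#'
#' Bounded (L-BFGS-B) minimization of the negative log-likelihood over
#' `kappa` in `[0, 1000]`, `s` in `[0, 1]`, `beta` in `[0.01, 2]`, from every
#' point of the start grid in `config`, plus profile candidates with kappa
#' fixed at each bound. The candidate with the lowest NLL wins; exact ties are
#' broken by smaller kappa, then smaller s.
#'
#' @param choices Trial rows from one condition with at least one non-missing
#'   trial (see [negative_log_likelihood]).
#' @param config A [fit_config].
#' @return A list of class `discounting_fit` with elements `params`
#'   ([discounting_params]), `nll`, `log_kappa`, `n_trials_used`, `converged`,
#'   `n_starts`.
#' @export
fit_discounting <- function(choices, config = fit_config()) {
  cond <- check_one_condition(choices)
  keep <- !is.na(choices$chosen) & choices$chosen != "missing"
  if (!any(keep)) stop("cannot fit: all trials missing")
  ch <- choices[keep, , drop = FALSE]

  delay <- ch$delay_days
  r1 <- ch$immediate_amount
  r2 <- ch$delayed_amount
  imm <- ch$chosen == "immediate"
  objective <- function(par) {
    nll_core(par[1], par[2], par[3], cond, delay, r1, r2, imm, eps = config$eps)
  }

  lower <- c(KAPPA_BOUNDS[1], S_BOUNDS[1], BETA_BOUNDS[1])
  upper <- c(KAPPA_BOUNDS[2], S_BOUNDS[2], BETA_BOUNDS[2])

  starts <- expand.grid(
    kappa = exp(config$start_log_kappa),
    s = config$start_s,
    beta = config$start_beta,
    KEEP.OUT.ATTRS = FALSE
  )

  candidates <- vector("list", nrow(starts))
  for (i in seq_len(nrow(starts))) {
    res <- tryCatch(
      stats::optim(
        par = as.numeric(starts[i, ]), fn = objective, method = "L-BFGS-B",
        lower = lower, upper = upper
      ),
      error = function(e) NULL
    )
    if (is.null(res)) {
      par0 <- as.numeric(starts[i, ])
      res <- list(par = par0, value = objective(par0), convergence = 1L)
    }
    candidates[[i]] <- res
  }

  if (isTRUE(config$boundary_profiles)) {
    for (k_fixed in KAPPA_BOUNDS) {
      prof_obj <- function(par) objective(c(k_fixed, par[1], par[2]))
      best_prof <- NULL
      for (j in seq_along(config$start_s)) {
        res <- tryCatch(
          stats::optim(
            par = c(config$start_s[j], config$start_beta[j]), fn = prof_obj,
            method = "L-BFGS-B", lower = lower[2:3], upper = upper[2:3]
          ),
          error = function(e) NULL
        )
        if (!is.null(res) &&
            (is.null(best_prof) || res$value < best_prof$value)) {
          best_prof <- res
        }
      }
      if (!is.null(best_prof)) {
        candidates[[length(candidates) + 1L]] <- list(
          par = c(k_fixed, best_prof$par), value = best_prof$value,
          convergence = best_prof$convergence
        )
      }
    }
  }

  vals <- vapply(candidates, function(cnd) cnd$value, numeric(1))
  kap <- vapply(candidates, function(cnd) cnd$par[1], numeric(1))
  ss <- vapply(candidates, function(cnd) cnd$par[2], numeric(1))
  best <- candidates[[order(vals, kap, ss)[1]]]

  par <- pmin(pmax(best$par, lower), upper)
  params <- discounting_params(par[1], par[2], par[3], cond)
  structure(
    list(
      params = params,
      nll = best$value,
      log_kappa = log_kappa(par[1]),
      n_trials_used = nrow(ch),
      converged = identical(best$convergence, 0L),
      n_starts = nrow(starts)
    ),
    class = "discounting_fit"
  )
}

#' @export
print.discounting_fit <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<discounting_fit> %s: kappa = %.4g (log kappa = %.3f), s = %.3f, ",
      "beta = %.3f\n  NLL = %.4f over %d trials (%d starts%s)\n"
    ),
    x$params$condition, x$params$kappa, x$log_kappa, x$params$s,
    x$params$beta, x$nll, x$n_trials_used, x$n_starts,
    if (x$converged) ", converged" else ", NOT converged"
  ))
  invisible(x)
}

#' Fit every participant/condition in a trial table
#'
#' Convenience wrapper mapping [fit_discounting] over the groups of a
#' long-format trial table.
#'
#' @param trials Trial table with `participant_id`, `condition`, and the
#'   columns required by [negative_log_likelihood].
#' @param config A [fit_config].
#' @return A tibble with one row per participant x condition: `participant_id`,
#'   `condition`, `kappa`, `s`, `beta`, `log_kappa`, `nll`, `n_trials_used`,
#'   `converged`. Groups whose trials are all missing yield `NA` estimates.
#' @export
fit_cohort <- function(trials, config = fit_config()) {
  groups <- split(
    trials,
    list(trials$participant_id, trials$condition),
    drop = TRUE
  )
  rows <- lapply(groups, function(g) {
    base <- tibble::tibble(
      participant_id = g$participant_id[1], condition = g$condition[1]
    )
    fit <- tryCatch(fit_discounting(g, config), error = function(e) NULL)
    if (is.null(fit)) {
      return(cbind(base, tibble::tibble(
        kappa = NA_real_, s = NA_real_, beta = NA_real_, log_kappa = NA_real_,
        nll = NA_real_, n_trials_used = 0L, converged = FALSE
      )))
    }
    cbind(base, tibble::tibble(
      kappa = fit$params$kappa, s = fit$params$s, beta = fit$params$beta,
      log_kappa = fit$log_kappa, nll = fit$nll,
      n_trials_used = fit$n_trials_used, converged = fit$converged
    ))
  })
  out <- tibble::as_tibble(do.call(rbind, rows))
  out[order(out$participant_id, out$condition), ]
}
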
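# Intertemporal-choice design generation: solve immediate amounts at target
# choice probabilities under hypothetical discounting parameters, then
# randomize into alternating reward/loss blocks.

#' Design configuration
#'
#' The default design crosses 6 delays x 4 delayed amounts x 4 hypothetical
#' discounting parameter sets x 1 target choice probability = 96 trials per
#' condition. The hypothetical parameter grid spans discount rates from very
#' shallow (kappa = 0.001) to very steep (kappa = 1), so that the solved
#' immediate amounts sample informative decisions across plausible behavior.
#'
#' @param delays Delays in days.
#' @param delayed_amounts Larger-later magnitudes (GBP).
#' @param hypothetical_params List of [discounting_params] used to solve the
#'   immediate amounts a priori.
#' @param target_probabilities Intended immediate-choice probabilities, each
#'   in (0, 1).
#' @param rounding_increment Monetary rounding step for solved amounts (GBP).
#' @param clamp Two fractions of the delayed amount bracketing admissible
#'   immediate amounts.
#' @param seed Integer seed used by [randomize_blocks] when none is passed.
#' @return A list of class `design_config`.
#' @export
design_config <- function(delays = c(7, 30, 90, 180, 365, 1095),
                          delayed_amounts = c(5, 10, 20, 50),
                          hypothetical_params = default_hypothetical_params(),
                          target_probabilities = 0.5,
                          rounding_increment = 0.10,
                          clamp = c(0.02, 0.98),
                          seed = 1L) {
  stopifnot(
    all(delays > 0), all(delays == round(delays)),
    all(delayed_amounts > 0),
    length(hypothetical_params) >= 1L,
    all(target_probabilities > 0 & target_probabilities < 1),
    rounding_increment > 0,
    length(clamp) == 2L, clamp[1] > 0, clamp[2] < 1, clamp[1] < clamp[2]
  )
  structure(
    list(
      delays = delays, delayed_amounts = delayed_amounts,
      hypothetical_params = hypothetical_params,
      target_probabilities = target_probabilities,
      rounding_increment = rounding_increment, clamp = clamp,
      seed = as.integer(seed)
    ),
    class = "design_config"
  )
}

#' Default hypothetical parameter grid
#'
#' Four log-spaced discount rates (0.001, 0.01, 0.1, 1) with `s = 1` and
#' `beta = 1`, giving 96 trials with the default delay and amount sets.
#'
#' @return List of four [discounting_params].
#' @export
default_hypothetical_params <- function() {
  lapply(c(0.001, 0.01, 0.1, 1), function(k) discounting_params(k, 1, 1))
}

#' Solve the immediate amount for a target choice probability
#'
#' Closed-form inversion of the sigmoid choice rule: with
#' `V2 = r2 / (1 + kappa * D^s)`, the immediate amount at which a
#' hypothetical decision maker chooses the immediate option with probability
#' `p` is `r1 = V2 - log(1/p - 1) / beta`. The result is clamped into
#' `clamp * r2` and, if `rounding_increment` is not `NULL`, rounded to that
#' increment.
#'
#' @param hyp A [discounting_params] object (the hypothetical agent).
#' @param delay_days Delay in days.
#' @param delayed_amount Larger-later magnitude `r2`.
#' @param p_target Target immediate-choice probability in (0, 1).
#' @param clamp Admissible fraction range of `r2`.
#' @param rounding_increment Monetary rounding step, or `NULL` for the exact
#'   pre-rounding value.
#' @return Immediate amount `r1` with `0 < r1 < r2`. Attribute `clamped` is
#'   `TRUE` when the clamp was active.
#' @export
solve_immediate_amount <- function(hyp, delay_days, delayed_amount, p_target,
                                   clamp = c(0.02, 0.98),
                                   rounding_increment = 0.10) {
  stopifnot(hyp$beta > 0, p_target > 0, p_target < 1)
  v2 <- hyperboloid_value(hyp$kappa, hyp$s, delayed_amount, delay_days)
  r1 <- v2 - log(1 / p_target - 1) / hyp$beta
  lo <- clamp[1] * delayed_amount
  hi <- clamp[2] * delayed_amount
  if (lo > hi) stop("empty clamp interval")
  clamped <- r1 < lo || r1 > hi
  r1 <- min(max(r1, lo), hi)
  if (!is.null(rounding_increment)) {
    r1 <- round(r1 / rounding_increment) * rounding_increment
  }
  if (r1 <= 0 || r1 >= delayed_amount) {
    stop("solved immediate amount out of (0, r2); check clamp/rounding settings")
  }
  structure(r1, clamped = clamped)
}

#' Generate the full-factorial trial design
#'
#' Crosses delays, delayed amounts, hypothetical parameter sets, and target
#' probabilities; solves each immediate amount; and duplicates the identical
#' magnitude structure for the reward and loss conditions.
#'
#' @param config A [design_config].
#' @return Tibble with one row per trial and condition: `condition`,
#'   `trial_id`, `delay_days`, `immediate_amount` (rounded),
#'   `immediate_amount_exact` (pre-rounding, for round-trip checks),
#'   `delayed_amount`, `hyp_index`, `p_target`, `clamped`.
#' @export
generate_design <- function(config = design_config()) {
  grid <- expand.grid(
    delay_days = config$delays,
    delayed_amount = config$delayed_amounts,
    hyp_index = seq_along(config$hypothetical_params),
    p_target = config$target_probabilities,
    KEEP.OUT.ATTRS = FALSE
  )
  exact <- numeric(nrow(grid))
  rounded <- numeric(nrow(grid))
  clamped <- logical(nrow(grid))
  for (i in seq_len(nrow(grid))) {
    hyp <- config$hypothetical_params[[grid$hyp_index[i]]]
    e <- solve_immediate_amount(
      hyp, grid$delay_days[i], grid$delayed_amount[i], grid$p_target[i],
      clamp = config$clamp, rounding_increment = NULL
    )
    exact[i] <- as.numeric(e)
    clamped[i] <- attr(e, "clamped")
    rounded[i] <- round(exact[i] / config$rounding_increment) *
      config$rounding_increment
  }
  if (any(rounded <= 0 | rounded >= grid$delayed_amount)) {
    stop("rounding pushed an immediate amount outside (0, r2)")
  }
  n <- nrow(grid)
  one_condition <- function(cond, tag) {
    tibble::tibble(
      condition = cond,
      trial_id = sprintf("%s%03d", tag, seq_len(n)),
      delay_days = grid$delay_days,
      immediate_amount = rounded,
      immediate_amount_exact = exact,
      delayed_amount = grid$delayed_amount,
      hyp_index = grid$hyp_index,
      p_target = grid$p_target,
      clamped = clamped
    )
  }
  rbind(one_condition("reward", "R"), one_condition("loss", "L"))
}

#' Randomize trials into an alternating-block session plan
#'
#' Each condition's trials are permuted and split into two equal blocks;
#' reward and loss blocks alternate, with the starting condition drawn at
#' random. Each trial's immediate option is assigned to the left or right
#' side uniformly at random.
#'
#' @param design Output of [generate_design].
#' @param seed Integer seed; the whole session plan is a deterministic
#'   function of it.
#' @return The design rows in presentation order with added columns `block`
#'   (session block 1..4), `trial_in_block`, `session_order`, and
#'   `immediate_side`.
#' @export
randomize_blocks <- function(design, seed = 1L) {
  conds <- unique(design$condition)
  counts <- table(design$condition)
  if (any(counts %% 2L != 0L)) stop("trial count per condition must be even")
  rng <- local_rng(seed)
  per_cond <- lapply(conds, function(cond) {
    rows <- design[design$condition == cond, , drop = FALSE]
    rows <- rows[rng$sample_int(nrow(rows)), , drop = FALSE]
    half <- nrow(rows) / 2L
    split(rows, rep(1:2, each = half))
  })
  names(per_cond) <- conds
  first <- conds[rng$sample_int(length(conds))[1]]
  order_conds <- if (length(conds) == 2L) {
    c(first, setdiff(conds, first))
  } else {
    conds
  }
  blocks <- list(
    per_cond[[order_conds[1]]][[1]], per_cond[[order_conds[2]]][[1]],
    per_cond[[order_conds[1]]][[2]], per_cond[[order_conds[2]]][[2]]
  )
  out <- do.call(rbind, lapply(seq_along(blocks), function(b) {
    blk <- blocks[[b]]
    blk$block <- b
    blk$trial_in_block <- seq_len(nrow(blk))
    blk
  }))
  out$session_order <- seq_len(nrow(out))
  out$immediate_side <- c("left", "right")[rng$sample_int_n(2L, nrow(out))]
  tibble::as_tibble(out)
}
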
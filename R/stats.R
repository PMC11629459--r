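# Statistical machinery: Pearson correlations with Fisher-z CIs, simple /
# multiple / hierarchical OLS with standardized weights and squared
# semipartials, Alf-Graf asymptotic confidence intervals, Fisher-z
# comparison of independent correlations, t-tests, and power for r.

#' Pearson correlation with Fisher-z confidence interval
#'
#' Two-tailed p from `t = r * sqrt((n - 2) / (1 - r^2))`; the CI from
#' `atanh(r) +/- z * 1/sqrt(n - 3)`, back-transformed. Incomplete pairs are
#' dropped.
#'
#' @param x,y Paired numeric vectors.
#' @param level Confidence level.
#' @return One-row tibble: `r`, `n`, `ci_lower`, `ci_upper`, `p`.
#' @export
pearson_with_ci <- function(x, y, level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in `x` or `y`")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    # degenerate perfectly linear data: point interval, p = 0
    return(tibble::tibble(r = r, n = n, ci_lower = r, ci_upper = r, p = 0))
  }
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  z <- atanh(r)
  ci <- tanh(z + c(-1, 1) * zcrit / sqrt(n - 3))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  tibble::tibble(r = r, n = n, ci_lower = ci[1], ci_upper = ci[2], p = p)
}

# ---- OLS internals -------------------------------------------------------

# Asymptotic CI for R^2 (Olkin-Finn variance with df adjustment), clamped to
# [0, 1].
r2_ci <- function(r2, n, k, level = 0.95) {
  v <- 4 * r2 * (1 - r2)^2 * (n - k - 1)^2 / ((n^2 - 1) * (n + 3))
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  half <- zcrit * sqrt(max(v, 0))
  c(max(0, r2 - half), min(1, r2 + half))
}

# Alf-Graf asymptotic variance of R2_full - R2_reduced for nested OLS fits
# on the same sample, through the correlations r1 = cor(y, yhat_full),
# r2 = cor(y, yhat_red), r3 = cor(yhat_full, yhat_red):
#   var(r^2)   = 4 r^2 (1 - r^2)^2 / n
#   cov(r1,r2) = [r3 (1 - r1^2 - r2^2)
#                 - (r1 r2 / 2) (1 - r1^2 - r2^2 - r3^2)] / n
#   cov(r1^2, r2^2) = 4 r1 r2 cov(r1, r2)
delta_r2_variance <- function(y, yhat_full, yhat_red) {
  n <- length(y)
  r1 <- stats::cor(y, yhat_full)
  r2 <- if (stats::sd(yhat_red) == 0) 0 else stats::cor(y, yhat_red)
  r3 <- if (stats::sd(yhat_red) == 0) 0 else stats::cor(yhat_full, yhat_red)
  v1 <- 4 * r1^2 * (1 - r1^2)^2 / n
  v2 <- 4 * r2^2 * (1 - r2^2)^2 / n
  cov12 <- (r3 * (1 - r1^2 - r2^2) -
              (r1 * r2 / 2) * (1 - r1^2 - r2^2 - r3^2)) / n
  v1 + v2 - 2 * (4 * r1 * r2 * cov12)
}

#' Alf-Graf confidence interval for a squared-semipartial or delta-R-squared
#'
#' Asymptotic normal-theory interval for the difference of squared multiple
#' correlations of two nested OLS fits on the same sample. The interval may
#' include zero even when the block F-test is significant: the sampling
#' variance of an R-squared difference near zero is large relative to the
#' F-test's precision.
#'
#' @param y Outcome vector (complete cases).
#' @param yhat_full,yhat_red Fitted values from the full and reduced models.
#' @param level Confidence level.
#' @return Numeric interval `c(lower, upper)` for
#'   `R2_full - R2_reduced`.
#' @export
alf_graf_ci <- function(y, yhat_full, yhat_red, level = 0.95) {
  n <- length(y)
  if (n < 10) stop("sample too small for the asymptotic variance")
  r2f <- stats::cor(y, yhat_full)^2
  r2r <- if (stats::sd(yhat_red) == 0) 0 else stats::cor(y, yhat_red)^2
  v <- delta_r2_variance(y, yhat_full, yhat_red)
  zcrit <- stats::qnorm(1 - (1 - level) / 2)
  (r2f - r2r) + c(-1, 1) * zcrit * sqrt(max(v, 0))
}

# Fit OLS of y on the named predictors of `data` and report the Table-4
# quantities: b and CI, standardized beta and CI, sr^2 with Alf-Graf CI,
# zero-order r, R^2 with CI.
ols_report <- function(data, outcome, predictors, level = 0.95) {
  cols <- c(outcome, predictors)
  cc <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
             drop = FALSE]
  n <- nrow(cc)
  if (n <= length(predictors) + 1L) stop("too few complete cases")
  for (v in predictors) {
    if (stats::sd(cc[[v]]) == 0) stop("constant predictor: ", v)
  }
  fml <- stats::as.formula(
    paste(outcome, "~", paste(predictors, collapse = " + "))
  )
  fit <- stats::lm(fml, data = cc)
  qr_rank <- fit$rank
  if (qr_rank < length(predictors) + 1L) {
    alias <- predictors[is.na(stats::coef(fit)[predictors])]
    stop("rank-deficient model; collinear term(s): ",
         paste(alias, collapse = ", "))
  }
  smry <- summary(fit)
  bhat <- stats::coef(fit)
  bci <- stats::confint(fit, level = level)
  sdy <- stats::sd(cc[[outcome]])
  yhat_full <- stats::fitted(fit)

  rows <- lapply(c("(Intercept)", predictors), function(term) {
    if (term == "(Intercept)") {
      return(tibble::tibble(
        term = term, b = bhat[[term]], b_ci_lower = bci[term, 1],
        b_ci_upper = bci[term, 2], beta = NA_real_, beta_ci_lower = NA_real_,
        beta_ci_upper = NA_real_, sr2 = NA_real_, sr2_ci_lower = NA_real_,
        sr2_ci_upper = NA_real_, r_zero_order = NA_real_,
        t = smry$coefficients[term, "t value"],
        p = smry$coefficients[term, "Pr(>|t|)"]
      ))
    }
    sdx <- stats::sd(cc[[term]])
    scale_f <- sdx / sdy
    others <- setdiff(predictors, term)
    yhat_red <- if (length(others) == 0L) {
      rep(mean(cc[[outcome]]), n)
    } else {
      stats::fitted(stats::lm(
        stats::as.formula(
          paste(outcome, "~", paste(others, collapse = " + "))
        ),
        data = cc
      ))
    }
    sr2 <- stats::cor(cc[[outcome]], yhat_full)^2 -
      (if (stats::sd(yhat_red) == 0) 0 else stats::cor(cc[[outcome]], yhat_red)^2)
    sr2_ci <- alf_graf_ci(cc[[outcome]], yhat_full, yhat_red, level)
    tibble::tibble(
      term = term, b = bhat[[term]], b_ci_lower = bci[term, 1],
      b_ci_upper = bci[term, 2], beta = bhat[[term]] * scale_f,
      beta_ci_lower = bci[term, 1] * scale_f,
      beta_ci_upper = bci[term, 2] * scale_f,
      sr2 = sr2, sr2_ci_lower = sr2_ci[1], sr2_ci_upper = sr2_ci[2],
      r_zero_order = stats::cor(cc[[outcome]], cc[[term]]),
      t = smry$coefficients[term, "t value"],
      p = smry$coefficients[term, "Pr(>|t|)"]
    )
  })
  r2 <- smry$r.squared
  ci <- r2_ci(r2, n, length(predictors), level)
  structure(
    list(
      terms = tibble::as_tibble(do.call(rbind, rows)),
      r_squared = r2, r2_ci_lower = ci[1], r2_ci_upper = ci[2],
      f = unname(smry$fstatistic["value"]),
      df1 = unname(smry$fstatistic["numdf"]),
      df2 = unname(smry$fstatistic["dendf"]),
      p = stats::pf(smry$fstatistic["value"], smry$fstatistic["numdf"],
                    smry$fstatistic["dendf"], lower.tail = FALSE)[[1]],
      n = n, outcome = outcome, predictors = predictors, fit = fit
    ),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression_report> %s ~ %s\n  R^2 = %.4f [%.3f, %.3f], F(%d, %d) = %.3f, p = %.4g, n = %d\n",
    x$outcome, paste(x$predictors, collapse = " + "), x$r_squared,
    x$r2_ci_lower, x$r2_ci_upper, x$df1, x$df2, x$f, x$p, x$n
  ))
  print(x$terms[, c("term", "b", "beta", "sr2", "p")])
  invisible(x)
}

#' Simple linear regression report
#'
#' OLS of `y` on a single predictor, with the same report shape as
#' [multiple_regression]. `R^2` equals the squared Pearson correlation.
#'
#' @param data Data frame.
#' @param outcome,predictor Column names.
#' @param level Confidence level.
#' @return A `regression_report`.
#' @export
simple_regression <- function(data, outcome, predictor, level = 0.95) {
  ols_report(data, outcome, predictor, level)
}

#' Multiple linear regression report
#'
#' OLS with unstandardized and standardized weights, squared semipartials
#' with Alf-Graf CIs, zero-order correlations, and the model R-squared with
#' its asymptotic CI. Standardized weights are computed on the complete-case
#' sample (`beta = b * sd(x) / sd(y)`), with CIs scaled from the
#' unstandardized ones.
#'
#' @param data Data frame.
#' @param outcome Column name of the dependent variable.
#' @param predictors Character vector of predictor column names.
#' @param level Confidence level.
#' @return A `regression_report`.
#' @export
multiple_regression <- function(data, outcome, predictors, level = 0.95) {
  ols_report(data, outcome, predictors, level)
}

#' Hierarchical regression with a block F-test
#'
#' Fits the step-1 model (`step1` predictors) and the step-2 model (`step1`
#' plus `step2` predictors) on the complete cases of the *larger* model, so
#' both steps use an identical sample. Reports both fits, the R-squared
#' increment, its Alf-Graf CI, and the block F-test
#' `F = (dR2/q) / ((1 - R2_full) / (n - p_full - 1))`.
#'
#' @param data Data frame.
#' @param outcome Column name of the dependent variable.
#' @param step1,step2 Character vectors of predictor names; `step2` are the
#'   added predictors.
#' @param level Confidence level.
#' @return A list of class `hierarchical_report`: `step1`, `step2`
#'   (`regression_report`s), `delta_r2`, `delta_r2_ci_lower/upper`, `f_block`,
#'   `df1`, `df2`, `p_block`, `n`.
#' @export
hierarchical_regression <- function(data, outcome, step1, step2,
                                    level = 0.95) {
  if (any(step2 %in% step1)) {
    stop("rank-deficient model; collinear term(s): ",
         paste(intersect(step2, step1), collapse = ", "))
  }
  cols <- c(outcome, step1, step2)
  cc <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
             drop = FALSE]
  rep1 <- ols_report(cc, outcome, step1, level)
  rep2 <- ols_report(cc, outcome, c(step1, step2), level)
  stopifnot(rep1$n == rep2$n)
  n <- rep2$n
  q <- length(step2)
  p_full <- length(step1) + length(step2)
  delta <- rep2$r_squared - rep1$r_squared
  f_block <- (delta / q) / ((1 - rep2$r_squared) / (n - p_full - 1))
  p_block <- stats::pf(f_block, q, n - p_full - 1, lower.tail = FALSE)
  ci <- alf_graf_ci(
    cc[[outcome]], stats::fitted(rep2$fit), stats::fitted(rep1$fit), level
  )
  structure(
    list(
      step1 = rep1, step2 = rep2, delta_r2 = delta,
      delta_r2_ci_lower = ci[1], delta_r2_ci_upper = ci[2],
      f_block = f_block, df1 = q, df2 = n - p_full - 1, p_block = p_block,
      n = n
    ),
    class = "hierarchical_report"
  )
}

#' @export
print.hierarchical_report <- function(x, ...) {
  cat("Step 1:\n")
  print(x$step1)
  cat("Step 2:\n")
  print(x$step2)
  cat(sprintf(
    "  dR^2 = %.4f [%.3f, %.3f], F(%d, %d) = %.3f, p = %.4g\n",
    x$delta_r2, x$delta_r2_ci_lower, x$delta_r2_ci_upper, x$df1, x$df2,
    x$f_block, x$p_block
  ))
  invisible(x)
}

#' Compare two independent correlations by Fisher's z
#'
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`, two-tailed p.
#'
#' @param r1,r2 Correlations from independent samples, `|r| < 1`.
#' @param n1,n2 Sample sizes (each at least 4).
#' @return List with `z` and `p`.
#' @export
fisher_z_compare <- function(r1, n1, r2, n2) {
  stopifnot(n1 >= 4, n2 >= 4)
  if (abs(r1) >= 1 || abs(r2) >= 1) stop("|r| must be < 1")
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Two-group t-test
#'
#' Welch's unequal-variance test for independent groups (the default), or the
#' classic paired test.
#'
#' @param values Numeric vector.
#' @param groups Two-level grouping vector (ignored when `paired` and
#'   `values2` is given).
#' @param paired Paired test instead of independent-samples.
#' @param values2 Second measurement for the paired test.
#' @return One-row tibble: `t`, `df`, `p`, `mean_1`, `mean_2`, `n_1`, `n_2`.
#' @export
group_ttest <- function(values, groups = NULL, paired = FALSE,
                        values2 = NULL) {
  if (paired) {
    stopifnot(!is.null(values2), length(values) == length(values2))
    ok <- stats::complete.cases(values, values2)
    if (sum(ok) < 2) stop("need at least 2 complete pairs")
    d <- values[ok] - values2[ok]
    n <- length(d)
    se <- stats::sd(d) / sqrt(n)
    # identically zero differences: no effect, t = 0 by convention
    tstat <- if (se == 0 && mean(d) == 0) 0 else mean(d) / se
    return(tibble::tibble(
      t = tstat, df = n - 1,
      p = 2 * stats::pt(-abs(tstat), n - 1),
      mean_1 = mean(values[ok]), mean_2 = mean(values2[ok]),
      n_1 = n, n_2 = n
    ))
  }
  ok <- stats::complete.cases(values, groups)
  values <- values[ok]
  groups <- groups[ok]
  lev <- sort(unique(groups))
  if (length(lev) != 2L) stop("`groups` must have exactly two levels")
  g1 <- values[groups == lev[1]]
  g2 <- values[groups == lev[2]]
  if (length(g1) < 2 || length(g2) < 2) stop("each group needs n >= 2")
  ht <- stats::t.test(g1, g2, var.equal = FALSE)
  tibble::tibble(
    t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
    mean_1 = mean(g1), mean_2 = mean(g2),
    n_1 = length(g1), n_2 = length(g2)
  )
}

#' Moderation model with a dummy-coded moderator
#'
#' OLS of `y` on the focal predictor, a 0/1 dummy, and their product. The
#' product is computed without centering, matching a plain interaction
#' contrast against the dummy's reference group.
#'
#' @param data Data frame.
#' @param outcome,predictor,dummy Column names; `dummy` must be 0/1 with both
#'   levels present.
#' @param level Confidence level.
#' @return A `regression_report` with terms `predictor`, `dummy`, and
#'   `interaction`.
#' @export
moderation_model <- function(data, outcome, predictor, dummy, level = 0.95) {
  cols <- c(outcome, predictor, dummy)
  cc <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
             drop = FALSE]
  dvals <- unique(cc[[dummy]])
  if (!all(dvals %in% c(0, 1)) || length(dvals) != 2L) {
    stop("`dummy` must take both values 0 and 1")
  }
  cc$interaction <- cc[[predictor]] * cc[[dummy]]
  ols_report(cc, outcome, c(predictor, dummy, "interaction"), level)
}

#' Sample size for detecting a correlation
#'
#' Fisher-z approximation:
#' `n = ceil(((z_{1-alpha/sides} + z_{power}) / atanh(r))^2 + 3)`.
#'
#' @param r True correlation in (0, 1).
#' @param power Target power in (0, 1).
#' @param alpha Significance level.
#' @param sides 1 or 2.
#' @return Integer sample size.
#' @examples
#' power_n_for_r(0.14, 0.8, 0.05, sides = 2)
#' @export
power_n_for_r <- function(r, power = 0.8, alpha = 0.05, sides = 2) {
  stopifnot(r > 0, r < 1, power > 0, power < 1, sides %in% c(1, 2))
  za <- stats::qnorm(1 - alpha / sides)
  zb <- stats::qnorm(power)
  as.integer(ceiling(((za + zb) / atanh(r))^2 + 3))
}
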
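# Independent oracles, coded from the formulas without touching package
# internals, for cross-checking likelihoods, regressions, and magnitudes.

# Per-trial negative log-likelihood by plain summation.
oracle_nll <- function(kappa, s, beta, cond, trials) {
  total <- 0
  for (i in seq_len(nrow(trials))) {
    ch <- trials$chosen[i]
    if (is.na(ch) || ch == "missing") next
    sgn <- if (cond == "loss") -1 else 1
    v1 <- sgn * trials$immediate_amount[i]
    v2 <- sgn * trials$delayed_amount[i] /
      (1 + kappa * trials$delay_days[i]^s)
    p1 <- 1 / (1 + exp(beta * (v2 - v1)))
    p <- if (ch == "immediate") p1 else 1 - p1
    p <- min(max(p, 1e-12), 1 - 1e-12)
    total <- total - log(p)
  }
  total
}

# Minimum NLL over a full grid of the bounded parameter cube.
oracle_grid_min_nll <- function(trials, cond, n_grid = 20) {
  kappas <- seq(0, 1000, length.out = n_grid)
  ss <- seq(0, 1, length.out = n_grid)
  betas <- seq(0.01, 2, length.out = n_grid)
  best <- Inf
  keep <- !is.na(trials$chosen) & trials$chosen != "missing"
  tr <- trials[keep, , drop = FALSE]
  sgn <- if (cond == "loss") -1 else 1
  for (k in kappas) {
    for (s in ss) {
      v1 <- sgn * tr$immediate_amount
      v2 <- sgn * tr$delayed_amount / (1 + k * tr$delay_days^s)
      dv <- v2 - v1
      for (b in betas) {
        p1 <- 1 / (1 + exp(b * dv))
        p <- ifelse(tr$chosen == "immediate", p1, 1 - p1)
        p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
        nll <- -sum(log(p))
        if (nll < best) best <- nll
      }
    }
  }
  best
}

# OLS coefficients and R^2 by the normal equations.
oracle_ols <- function(y, X) {
  Xd <- cbind(1, as.matrix(X))
  b <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  yhat <- Xd %*% b
  r2 <- 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
  list(b = drop(b), r2 = r2, yhat = drop(yhat))
}

# Welch t statistic from the textbook formula.
oracle_welch_t <- function(g1, g2) {
  se <- sqrt(var(g1) / length(g1) + var(g2) / length(g2))
  (mean(g1) - mean(g2)) / se
}

# Build paired data with an exact sample correlation r.
make_exact_correlation <- function(r, n, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  e <- rnorm(n)
  e <- residuals(lm(e ~ x))
  x <- as.numeric(scale(x))
  e <- as.numeric(scale(e))
  list(x = x, y = r * x + sqrt(1 - r^2) * e)
}
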
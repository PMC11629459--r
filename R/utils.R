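# Internal helpers: seeded RNG streams that do not disturb the caller's RNG,
# truncated-normal quantiles, discretized categorical marginals, PSD repair.

# A self-contained RNG stream. Each returned function runs its draw under the
# stream's own state and restores the caller's .Random.seed afterwards.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  wrap <- function(f) {
    function(...) {
      old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
      if (is.null(env$state)) {
        set.seed(seed)
      } else {
        assign(".Random.seed", env$state, envir = globalenv())
      }
      on.exit({
        env$state <- get(".Random.seed", envir = globalenv())
        if (is.null(old)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", old, envir = globalenv())
        }
      })
      f(...)
    }
  }
  list(
    sample_int = wrap(function(n) sample.int(n)),
    sample_int_n = wrap(function(k, n) sample.int(k, n, replace = TRUE)),
    runif = wrap(stats::runif),
    rnorm = wrap(stats::rnorm),
    rlnorm = wrap(stats::rlnorm),
    rbinom = wrap(stats::rbinom),
    draw = wrap(function(expr_fun) expr_fun())
  )
}

# Deterministic stage seeds derived from one master seed; kept within
# 32-bit integer range.
derive_seed <- function(master, offset) {
  as.integer((as.numeric(master) %% 1000003) * 1009 + offset) %% .Machine$integer.max
}

# Quantile function of a normal truncated to [lo, hi].
qtruncnorm <- function(p, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  q <- stats::qnorm(plo + p * (phi - plo), mean, sd)
  pmin(pmax(q, lo), hi)
}

# Probability mass over integer-spaced category values from a discretized
# normal (mass of [v - step/2, v + step/2]).
discretized_normal_pmf <- function(values, mean, sd, step = 1) {
  p <- stats::pnorm(values + step / 2, mean, sd) -
    stats::pnorm(values - step / 2, mean, sd)
  p / sum(p)
}

# Map uniforms to categories by the inverse CDF of a pmf.
quantile_categorical <- function(u, probs) {
  findInterval(u, cumsum(probs), left.open = TRUE) + 1L
}

# Repair a correlation matrix to the nearest positive semi-definite one.
psd_repair <- function(R, tol = 1e-8) {
  stopifnot(isSymmetric(unname(R)), all(diag(R) == 1), all(abs(R) <= 1))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= tol) return(R)
  out <- as.matrix(Matrix::nearPD(R, corr = TRUE, posd.tol = tol)$mat)
  dimnames(out) <- dimnames(R)
  ev2 <- eigen(out, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev2) < -tol) stop("correlation target matrix could not be repaired to PSD")
  out
}

# Uniformly sample one value from a small feasible set (deterministic when
# the set has one element). `u` is a uniform draw in [0, 1).
pick_from <- function(set, u) set[1L + floor(u * length(set)) %% length(set)]

# Allocate integer total over `m` slots with per-slot range [lo, hi],
# sampling each slot uniformly over its feasible range given the remainder.
allocate_integer_sum <- function(total, m, lo, hi, u) {
  out <- integer(m)
  rem <- total
  for (j in seq_len(m)) {
    left <- m - j
    lo_j <- max(lo, rem - hi * left)
    hi_j <- min(hi, rem - lo * left)
    out[j] <- pick_from(seq.int(lo_j, hi_j), u[j])
    rem <- rem - out[j]
  }
  stopifnot(rem == 0L)
  out
}
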
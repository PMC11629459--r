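# Correlation/regression machinery against independent oracles.

test_that("Fisher-z correlation CIs reproduce published-style intervals", {
  d <- make_exact_correlation(0.15, 341, seed = 3)
  res <- pearson_with_ci(d$x, d$y)
  expect_equal(res$r, 0.15, tolerance = 1e-10)
  expect_equal(round(res$ci_lower, 2), 0.04)
  expect_equal(round(res$ci_upper, 2), 0.25)
  expect_lt(res$p, 0.01)

  d2 <- make_exact_correlation(0.26, 330, seed = 4)
  res2 <- pearson_with_ci(d2$x, d2$y)
  expect_equal(round(res2$ci_lower, 2), 0.16)
  expect_equal(round(res2$ci_upper, 2), 0.36)
})

test_that("correlation reports agree with cor.test on random fixtures", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(10:200, 1)
    x <- rnorm(n)
    y <- 0.3 * x + rnorm(n)
    res <- pearson_with_ci(x, y)
    ct <- cor.test(x, y)
    expect_equal(res$r, unname(ct$estimate), tolerance = 1e-12)
    expect_equal(res$p, ct$p.value, tolerance = 1e-12)
    expect_equal(res$ci_lower, ct$conf.int[1], tolerance = 1e-9)
    expect_equal(res$ci_upper, ct$conf.int[2], tolerance = 1e-9)
  }
  # incomplete pairs are dropped
  x <- c(rnorm(50), NA)
  y <- c(rnorm(50), 1)
  expect_equal(pearson_with_ci(x, y)$n, 50L)
  # degenerate inputs
  expect_error(pearson_with_ci(1:3, 3:1), "4 complete")
  expect_error(pearson_with_ci(rep(1, 10), rnorm(10)), "variance")
  perfect <- pearson_with_ci(1:20, 2 * (1:20) + 3)
  expect_equal(perfect$r, 1)
  expect_equal(perfect$ci_lower, 1)
})

test_that("regression quantities match the normal-equations oracle", {
  set.seed(21)
  for (i in 1:10) {
    n <- sample(30:100, 1)
    dat <- data.frame(
      x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n)
    )
    dat$y <- 1 + 0.5 * dat$x1 - 0.3 * dat$x2 + rnorm(n)
    rep3 <- multiple_regression(dat, "y", c("x1", "x2", "x3"))
    orc <- oracle_ols(dat$y, dat[, c("x1", "x2", "x3")])
    expect_equal(rep3$terms$b, unname(orc$b), tolerance = 1e-10)
    expect_equal(rep3$r_squared, orc$r2, tolerance = 1e-10)
    # standardized betas equal coefficients of the z-scored fit
    zdat <- as.data.frame(scale(dat))
    zfit <- lm(y ~ x1 + x2 + x3, data = zdat)
    expect_equal(
      rep3$terms$beta[-1], unname(coef(zfit))[-1], tolerance = 1e-10
    )
    # sr^2: squared correlation between y and each predictor's unique part
    for (j in 1:3) {
      v <- c("x1", "x2", "x3")[j]
      others <- setdiff(c("x1", "x2", "x3"), v)
      ux <- residuals(lm(reformulate(others, v), data = dat))
      expect_equal(
        rep3$terms$sr2[j + 1], cor(dat$y, ux)^2, tolerance = 1e-8
      )
    }
  }
  # simple regression: R^2 is the squared Pearson correlation
  d <- data.frame(x = rnorm(60))
  d$y <- 0.4 * d$x + rnorm(60)
  expect_equal(
    simple_regression(d, "y", "x")$r_squared, cor(d$x, d$y)^2,
    tolerance = 1e-12
  )
  expect_equal(simple_regression(d, "y", "x")$df2, 58)
  # y = x exactly
  expect_equal(
    suppressWarnings(
      simple_regression(data.frame(x = 1:30, y = 1:30), "y", "x")$r_squared
    ), 1
  )
  expect_error(simple_regression(data.frame(x = rep(1, 30), y = rnorm(30)), "y", "x"),
               "constant")
})

test_that("hierarchical regression matches the two-fit oracle and the F = t^2 identity", {
  set.seed(31)
  n <- 50
  dat <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  dat$y <- 0.3 * dat$a - 0.2 * dat$b + 0.4 * dat$c + rnorm(n)
  h <- hierarchical_regression(dat, "y", c("a", "b"), "c")
  o1 <- oracle_ols(dat$y, dat[, c("a", "b")])
  o2 <- oracle_ols(dat$y, dat[, c("a", "b", "c")])
  delta <- o2$r2 - o1$r2
  expect_equal(h$delta_r2, delta, tolerance = 1e-10)
  f_oracle <- (delta / 1) / ((1 - o2$r2) / (n - 3 - 1))
  expect_equal(h$f_block, f_oracle, tolerance = 1e-10)
  expect_gte(h$delta_r2, 0)
  # single added predictor: block F equals the squared t of its coefficient
  tc <- h$step2$terms$t[h$step2$terms$term == "c"]
  expect_equal(h$f_block, tc^2, tolerance = 1e-8)
  # p-value consistency with anova()
  a <- anova(lm(y ~ a + b, dat), lm(y ~ a + b + c, dat))
  expect_equal(h$p_block, a$`Pr(>F)`[2], tolerance = 1e-10)
  # invariant chain: 0 <= sr2 <= R2 <= 1
  expect_true(all(h$step2$terms$sr2[-1] >= 0))
  expect_true(all(h$step2$terms$sr2[-1] <= h$step2$r_squared))
  # duplicated predictors are rejected
  expect_error(hierarchical_regression(dat, "y", c("a", "b"), "a"),
               "collinear")
})

test_that("a population-orthogonal added block contributes almost nothing", {
  set.seed(41)
  n <- 10000
  dat <- data.frame(x = rnorm(n), z = rnorm(n))
  dat$y <- 0.5 * dat$x + rnorm(n)
  h <- hierarchical_regression(dat, "y", "x", "z")
  expect_lt(h$delta_r2, 0.001)
})

test_that("Alf-Graf intervals agree with a bootstrap oracle and cover", {
  # fixture with a genuine added effect: away from the delta-R2 = 0 boundary
  # the statistic is asymptotically normal and the bootstrap and Alf-Graf
  # intervals must agree closely
  set.seed(51)
  n <- 300
  dat <- data.frame(x1 = rnorm(n), x2 = rnorm(n))
  dat$x3 <- 0.5 * dat$x1 + rnorm(n)
  dat$y <- 0.4 * dat$x1 + 0.2 * dat$x2 + 0.3 * dat$x3 + rnorm(n)
  h <- hierarchical_regression(dat, "y", c("x1", "x2"), "x3")
  boot <- replicate(2000, {
    idx <- sample.int(n, replace = TRUE)
    d <- dat[idx, ]
    f1 <- lm(y ~ x1 + x2, d)
    f2 <- lm(y ~ x1 + x2 + x3, d)
    summary(f2)$r.squared - summary(f1)$r.squared
  })
  bci <- quantile(boot, c(0.025, 0.975))
  expect_lt(abs(h$delta_r2_ci_lower - bci[[1]]), 0.02)
  expect_lt(abs(h$delta_r2_ci_upper - bci[[2]]), 0.02)

  # population-zero increment at large n: the CI covers 0
  set.seed(52)
  big <- data.frame(x = rnorm(5000), z = rnorm(5000))
  big$y <- 0.3 * big$x + rnorm(5000)
  h0 <- hierarchical_regression(big, "y", "x", "z")
  expect_lte(h0$delta_r2_ci_lower, 0)
  expect_gte(h0$delta_r2_ci_upper, 0)
})

test_that("Alf-Graf sr2 intervals achieve near-nominal coverage at n = 341", {
  # y = 0.3 x1 + 0.2 x2 + e: population sr2 of x1 is 0.09 / 1.13
  true_sr2 <- 0.09 / 1.13
  set.seed(53)
  hits <- 0
  reps <- 500
  for (i in seq_len(reps)) {
    n <- 341
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    y <- 0.3 * x1 + 0.2 * x2 + rnorm(n)
    dat <- data.frame(x1 = x1, x2 = x2, y = y)
    rep2 <- multiple_regression(dat, "y", c("x1", "x2"))
    lo <- rep2$terms$sr2_ci_lower[rep2$terms$term == "x1"]
    hi <- rep2$terms$sr2_ci_upper[rep2$terms$term == "x1"]
    if (true_sr2 >= lo && true_sr2 <= hi) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.93)
})

test_that("Fisher z comparison of independent correlations", {
  expect_equal(fisher_z_compare(0.4, 100, 0.4, 80)$z, 0)
  expect_equal(fisher_z_compare(0.5, 100, 0.5, 50)$z, 0)
  z <- fisher_z_compare(0.25, 171, 0.05, 170)
  expect_equal(round(z$z, 2), 1.88)
  expect_gt(z$p, 0.05)
  expect_error(fisher_z_compare(1, 100, 0.5, 100), "< 1")
  expect_error(fisher_z_compare(0.5, 3, 0.5, 100))
})

test_that("group t-tests follow the Welch formula; paired tests handle zero differences", {
  set.seed(61)
  g <- rep(c(0, 1), c(40, 60))
  v <- rnorm(100) + 0.5 * g
  res <- group_ttest(v, g)
  expect_equal(res$t, oracle_welch_t(v[g == 0], v[g == 1]), tolerance = 1e-10)
  ct <- t.test(v[g == 0], v[g == 1])
  expect_equal(res$p, ct$p.value, tolerance = 1e-12)
  expect_equal(res$df, unname(ct$parameter), tolerance = 1e-10)
  # identical groups: t = 0
  same <- group_ttest(c(1:5, 1:5), rep(c(0, 1), each = 5))
  expect_equal(same$t, 0)
  # paired with zero differences
  paired <- group_ttest(1:10 + 0.5, paired = TRUE, values2 = 1:10 + 0.5)
  expect_equal(paired$t, 0)
  x1 <- rnorm(10)
  x2 <- rnorm(10)
  paired2 <- group_ttest(x1, paired = TRUE, values2 = x2)
  ct2 <- t.test(x1, x2, paired = TRUE)
  expect_equal(paired2$t, unname(ct2$statistic), tolerance = 1e-12)
  expect_equal(paired2$p, ct2$p.value, tolerance = 1e-12)
  expect_error(group_ttest(rnorm(10), rep(0, 10)), "two levels")
})

test_that("the moderation model uses an uncentered product term", {
  set.seed(71)
  n <- 200
  dat <- data.frame(x = rnorm(n), g = rep(c(0, 1), n / 2))
  dat$y <- 0.3 * dat$x + 0.5 * dat$g + 0.4 * dat$x * dat$g + rnorm(n)
  m <- moderation_model(dat, "y", "x", "g")
  ofit <- lm(y ~ x * g, data = dat)
  expect_equal(m$terms$b, unname(coef(ofit)), tolerance = 1e-10)
  expect_error(
    moderation_model(data.frame(x = rnorm(10), g = 0, y = rnorm(10)),
                     "y", "x", "g"),
    "dummy"
  )
  # population-zero interaction at large n
  set.seed(72)
  big <- data.frame(x = rnorm(10000), g = rep(c(0, 1), 5000))
  big$y <- 0.3 * big$x + 0.2 * big$g + rnorm(10000)
  m0 <- moderation_model(big, "y", "x", "g")
  expect_lt(abs(m0$terms$beta[m0$terms$term == "interaction"]), 0.05)
})

test_that("sample-size planning follows the Fisher-z power formula", {
  n1 <- power_n_for_r(0.14, 0.8, 0.05, sides = 1)
  n2 <- power_n_for_r(0.14, 0.8, 0.05, sides = 2)
  expect_equal(n1, 315L)
  expect_equal(n2, 399L)
  expect_gt(n2, n1)
  # monotone in power and in r
  expect_gt(power_n_for_r(0.14, 0.9), power_n_for_r(0.14, 0.8))
  expect_lt(power_n_for_r(0.3, 0.8), power_n_for_r(0.14, 0.8))
  # simulation oracle: empirical power at the returned n reaches the target
  set.seed(81)
  r <- 0.14
  reject <- replicate(2000, {
    d <- MASS::mvrnorm(n1, c(0, 0), matrix(c(1, r, r, 1), 2))
    ct <- cor.test(d[, 1], d[, 2], alternative = "greater")
    ct$p.value < 0.05
  })
  expect_gte(mean(reject), 0.77)
})
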
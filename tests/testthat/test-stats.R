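test_that("paired t matches the textbook formula and handles degeneracy", {
  x <- c(1.2, 1.8, 1.1, 2.4, 1.9)
  y <- c(1.0, 1.5, 1.3, 1.9, 1.6)
  r <- paired_t(x, y)
  expect_equal(r$t, oracle_paired_t(x, y), tolerance = 1e-10)
  expect_equal(r$df, 4)
  expect_equal(r$p, 2 * stats::pt(-abs(r$t), 4), tolerance = 1e-12)

  same <- paired_t(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  d <- paired_t(x + 1, x)  # constant non-zero differences
  expect_true(d$degenerate)
  expect_equal(d$p, 0)
})

test_that("GG epsilon is 1 for two conditions and under compound symmetry", {
  set.seed(5)
  Y2 <- matrix(rnorm(20), 10, 2)
  expect_equal(rm_anova_gg(Y2)$epsilon, 1)

  # compound-symmetric data: subject effect + iid noise, population epsilon 1;
  # test on an exactly compound-symmetric covariance via a linear construction
  k <- 4; n <- 8
  L <- chol(diag(k) * 0.5 + 0.5)
  Yc <- matrix(rnorm(n * k), n, k) %*% L
  eps_pop <- {
    S <- diag(k) * 0.5 + 0.5  # the population covariance is c-symmetric
    C <- qr.Q(qr(stats::contr.helmert(k)))
    M <- t(C) %*% S %*% C
    sum(diag(M))^2 / ((k - 1) * sum(M^2))
  }
  expect_equal(eps_pop, 1, tolerance = 1e-9)
})

test_that("F and epsilon match the direct-formula oracle on random data", {
  set.seed(17)
  for (rep in 1:5) {
    Y <- matrix(rnorm(21, sd = 1) + rep(c(0, 0.5, 0.2), each = 7), 7, 3)
    r <- rm_anova_gg(Y)
    expect_equal(r$F, oracle_rm_F(Y), tolerance = 1e-8)
    expect_equal(r$epsilon, min(1, max(0.5, oracle_gg_epsilon(Y))),
                 tolerance = 1e-8)
    expect_equal(r$df1, r$epsilon * 2)
    expect_equal(r$df2, r$epsilon * 12)
    expect_true(r$epsilon >= 1 / 2 && r$epsilon <= 1)
  }
  # epsilon bounds hold across many shapes
  for (k in 3:5) for (rep in 1:10) {
    Y <- matrix(rnorm(8 * k), 8, k)
    e <- rm_anova_gg(Y)$epsilon
    expect_true(e >= 1 / (k - 1) - 1e-12 && e <= 1 + 1e-12)
  }
  # constant data is flagged
  expect_true(rm_anova_gg(matrix(3, 5, 3))$flagged)
})

test_that("Tukey comparisons control the null and detect large effects", {
  set.seed(23)
  null_hits <- vapply(1:200, function(i) {
    Y <- matrix(rnorm(21), 7, 3) + rnorm(7)  # subject effect, no condition
    any(tukey_hsd(Y)$p_adj < 0.05)
  }, logical(1))
  expect_gte(mean(!null_hits), 0.92)  # nominal 5% family-wise error

  # two conditions give exactly one pair
  expect_equal(nrow(tukey_hsd(matrix(rnorm(12), 6, 2))), 1)

  # injected effect of 10 sigma is always detected
  for (s in 1:50) {
    set.seed(s)
    Y <- matrix(rnorm(21), 7, 3) + rnorm(7)
    Y[, 2] <- Y[, 2] + 10
    tk <- tukey_hsd(Y)
    expect_lt(tk$p_adj[tk$i == 1 & tk$j == 2], 0.001)
  }
})

test_that("Pearson r-squared matches the covariance-ratio formula", {
  x <- c(70, 80, 95); y <- c(0.2, 0.5, 0.9)
  r <- pearson_log(x, y)
  expect_equal(r$r2, oracle_r2(x, y), tolerance = 1e-12)

  xl <- seq(60, 100, length.out = 10)
  expect_equal(pearson_log(xl, 0.01 * xl - 2)$r2, 1, tolerance = 1e-12)

  set.seed(31)
  nulls <- vapply(1:40, function(i)
    pearson_log(rnorm(1000), rnorm(1000))$r2, numeric(1))
  expect_gte(mean(nulls < 0.01), 0.95)

  expect_true(pearson_log(rep(1, 5), rnorm(5))$flagged)
})
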
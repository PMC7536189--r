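test_that("t-tests match closed-form hand calculation to 1e-10", {
  # paired: textbook set {(1,2),(2,4),(3,6)}
  x <- c(1, 2, 3); y <- c(2, 4, 6)
  d <- x - y
  t_hand <- mean(d) / (sd(d) / sqrt(3))
  p_hand <- 2 * pt(-abs(t_hand), 2)
  res <- paired_t(x, y)
  expect_equal(res$statistic, t_hand, tolerance = 1e-10)
  expect_equal(res$p_value, p_hand, tolerance = 1e-10)
  expect_equal(res$df, 2)

  # unpaired, pooled variance
  set.seed(2); a <- rnorm(8); b <- rnorm(10, 0.5)
  sp2 <- ((7 * var(a) + 9 * var(b)) / 16)
  t_un <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 8 + 1 / 10))
  res_u <- unpaired_t(a, b)
  expect_equal(res_u$statistic, t_un, tolerance = 1e-10)
  expect_equal(res_u$p_value, 2 * pt(-abs(t_un), 16), tolerance = 1e-10)

  # identical paired samples
  same <- paired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # argument swap negates the statistic, keeps p
  sw <- unpaired_t(b, a)
  expect_equal(sw$statistic, -res_u$statistic, tolerance = 1e-12)
  expect_equal(sw$p_value, res_u$p_value, tolerance = 1e-12)

  expect_error(unpaired_t(rep(1, 5), rep(2, 5)), "degenerate test")
  expect_error(paired_t(c(1, 2), c(2, 3)), "degenerate test")
})

test_that("repeated-measures ANOVA matches the sums-of-squares oracle", {
  set.seed(42)
  n <- 10; k <- 3
  dat <- matrix(rnorm(n * k), n, k) +
    matrix(rep(c(0, 0.5, 1), each = n), n, k)
  res <- rm_anova(dat)

  grand <- mean(dat)
  ss_cond <- n * sum((colMeans(dat) - grand)^2)
  ss_err <- sum((dat - outer(rowMeans(dat), colMeans(dat), "+") + grand)^2)
  f_or <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  S <- cov(dat); C <- diag(k) - 1 / k
  D <- C %*% S %*% C
  eps_or <- sum(diag(D))^2 / ((k - 1) * sum(D * D))
  expect_equal(res$statistic, f_or, tolerance = 1e-10)
  expect_equal(res$gg_epsilon, eps_or, tolerance = 1e-10)
})

test_that("two-condition RM-ANOVA equals the squared paired t", {
  set.seed(7)
  dat <- matrix(rnorm(20), 10, 2)
  res <- rm_anova(dat)
  tt <- paired_t(dat[, 1], dat[, 2])
  expect_equal(res$statistic, tt$statistic^2, tolerance = 1e-10)
  expect_equal(res$p_value, tt$p_value, tolerance = 1e-10)
})

test_that("degenerate and corrected RM-ANOVA branches behave", {
  flat <- matrix(rep(rnorm(5), 3), 5, 3)
  r0 <- rm_anova(flat)
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  expect_error(rm_anova(matrix(c(1, NA, 2, 3, 4, 5), 3, 2)),
               "unbalanced design")

  # strongly heteroscedastic differences force a sphericity violation
  set.seed(11)
  n <- 20
  base <- rnorm(n)
  dat <- cbind(base + rnorm(n, 0, 0.05),
               base + rnorm(n, 0.3, 0.05),
               base + rnorm(n, 0.5, 3))
  res <- rm_anova(dat)
  expect_lt(res$mauchly_p, 0.05)
  expect_equal(res$correction, "greenhouse_geisser")
  expect_lt(res$df[1], res$df_uncorrected[1])
  expect_true(res$gg_epsilon > 0 && res$gg_epsilon <= 1)
})

test_that("Pearson correlation matches its closed form and limits", {
  x <- c(1.2, 2.3, 3.1, 4.8, 5.5, 7.1)
  y <- 0.7 * x + c(0.1, -0.2, 0.05, 0.3, -0.1, 0)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t_hand <- r_hand * sqrt((6 - 2) / (1 - r_hand^2))
  res <- pearson_r(x, y)
  expect_equal(res$r, r_hand, tolerance = 1e-10)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 4), tolerance = 1e-10)

  expect_equal(pearson_r(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_r(x, -x)$r, -1, tolerance = 1e-12)
  expect_error(pearson_r(x, rep(1, 6)), "degenerate correlation")
})

test_that("Bonferroni adjustment is min(1, m p) with family-size checks", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.9, 3), 1)
  expect_equal(bonferroni(c(0.2, 0.04)), c(0.4, 0.08))
  expect_equal(bonferroni(0.2, 1), 0.2)
  expect_error(bonferroni(c(0.1, 0.2, 0.3), 2), "invalid family size")
  expect_error(bonferroni(1.4, 2), "\\[0,1\\]")
})

test_that("Shapiro-Wilk p-values are uniform under the null and the test
           rejects exponential data", {
  set.seed(101)
  p_null <- replicate(600, shapiro_wilk(rnorm(20))$p)
  ks <- stats::ks.test(p_null, "punif")
  expect_gt(ks$p.value, 0.01)

  p_exp <- replicate(300, shapiro_wilk(rexp(20))$p)
  expect_gte(mean(p_exp < 0.05), 0.5)

  expect_error(shapiro_wilk(rep(2, 10)), "degenerate sample")
  expect_error(shapiro_wilk(c(1, 2)), "degenerate sample")
})

test_that("group difference detection matches analytic power and the null
           holds its size", {
  set.seed(202)
  n <- 10; delta <- 1.5
  an_power <- stats::power.t.test(n = n, delta = delta, sd = 1,
                                  type = "two.sample")$power
  rej <- replicate(300, unpaired_t(rnorm(n, delta), rnorm(n))$p_value < 0.05)
  se <- sqrt(an_power * (1 - an_power) / 300)
  expect_lt(abs(mean(rej) - an_power), 4 * se)

  rej0 <- replicate(600, unpaired_t(rnorm(n), rnorm(n))$p_value < 0.05)
  se0 <- sqrt(0.05 * 0.95 / 600)
  expect_lt(abs(mean(rej0) - 0.05), 3 * se0)
})
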
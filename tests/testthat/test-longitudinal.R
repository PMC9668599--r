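test_that("paired t-test matches the closed-form oracle", {
  set.seed(17)
  for (i in 1:10) {
    n <- sample(5:40, 1)
    x1 <- rnorm(n); x2 <- x1 + rnorm(n, 0.1, 0.4)
    res <- paired_t(x1, x2)
    d <- x2 - x1
    t_oracle <- mean(d) / (sd(d) / sqrt(n))
    expect_equal(res$t, t_oracle, tolerance = 1e-12)
    expect_equal(res$df, n - 1)
    expect_equal(res$p, 2 * pt(-abs(t_oracle), n - 1), tolerance = 1e-12)
  }
})

test_that("paired t degenerate cases", {
  res <- paired_t(c(1, 2, 3), c(0, 2, 4))   # differences -1, 0, 1
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  expect_warning(res2 <- paired_t(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_true(is.infinite(res2$t))
})

test_that("paired t from summary statistics reproduces a worked value", {
  res <- paired_t_from_summary(0.47, 1.05, 62)
  expect_equal(round(res$t, 2), 3.52)
  expect_lt(res$p, 0.001)
})

test_that("mixed model covers a known time effect and a null", {
  gen <- function(n, beta, resid_sd = 0.01) {
    b0 <- rnorm(n, 3.8, 0.15)
    data.frame(subject = rep(sprintf("S%02d", 1:n), 2),
               time = rep(c(0, 1), each = n),
               age = rep(rnorm(n, 38, 10), 2),
               sex = rep(sample(c("F", "M"), n, TRUE), 2),
               dmt = rep(sample(c(TRUE, FALSE), n, TRUE), 2),
               lesion_load = rep(rexp(n, 2), 2),
               value = rep(b0, 2) + beta * rep(c(0, 1), each = n) +
                 rnorm(2 * n, 0, resid_sd))
  }
  set.seed(18)
  covered <- vapply(1:100, function(i) {
    d <- gen(30, beta = 0.005)
    r <- fit_lmm(d)
    abs(r$beta_time - 0.005) <= 1.96 * r$se
  }, logical(1))
  expect_gte(mean(covered), 0.90)

  set.seed(19)
  null_t <- vapply(1:50, function(i) fit_lmm(gen(30, beta = 0))$t, numeric(1))
  expect_gte(mean(abs(null_t) < 2), 0.80)
})

test_that("mixed model drops constant covariates instead of failing", {
  set.seed(20)
  n <- 12
  d <- data.frame(subject = rep(sprintf("S%02d", 1:n), 2),
                  time = rep(c(0, 1), each = n),
                  age = rep(rnorm(n, 38, 5), 2),
                  sex = "F", dmt = FALSE,
                  lesion_load = rep(rexp(n), 2),
                  value = rnorm(2 * n, 3.8, 0.1))
  r <- fit_lmm(d)
  expect_true(is.finite(r$p))
})

test_that("marginal R-squared follows the variance-component definition", {
  expect_equal(nakagawa_r2(1, 1, 2), 0.25)
  expect_equal(nakagawa_r2(0, 1, 1), 0)
  set.seed(21)
  # strong time effect, known components: R2m from the fit is sane
  n <- 200
  d <- data.frame(subject = rep(sprintf("S%03d", 1:n), 2),
                  time = rep(c(0, 1), each = n),
                  age = rep(rnorm(n), 2), sex = rep(sample(c("F", "M"), n,
                                                           TRUE), 2),
                  dmt = rep(sample(c(TRUE, FALSE), n, TRUE), 2),
                  lesion_load = rep(rexp(n), 2))
  d$value <- 2 * d$time + rep(rnorm(n, 0, 1), 2) + rnorm(2 * n, 0, 1)
  r <- fit_lmm(d, covariates = character())
  # var(fixed) ~ 1 (time effect 2 on a 0/1 regressor), sigma_r ~ 1, sigma_e ~ 1
  expect_equal(r$marginal_r2,
               r$sigma2_fixed /
                 (r$sigma2_fixed + r$sigma2_random + r$sigma2_resid))
  expect_equal(r$marginal_r2, 1 / 3, tolerance = 0.3)
})

test_that("BH adjustment matches hand computation and brute force", {
  expect_equal(fdr_adjust(0.03), 0.03)
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  bh_oracle <- function(p) {
    m <- length(p); o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(22)
  base <- c(0.001, 0.04, 0.2, 0.5, 0.8, 0.049)
  perms <- replicate(30, sample(base), simplify = FALSE)
  for (p in c(perms, list(runif(6), runif(3))))
    expect_equal(fdr_adjust(p), bh_oracle(p), tolerance = 1e-12)
  q <- fdr_adjust(runif(6))
  expect_true(all(q <= 1) && all(q >= 0))
  expect_error(fdr_adjust(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("change correlations match direct formula evaluation", {
  a <- c(1, 2, 3, 4); b <- c(2, 4, 5, 9)
  res <- change_correlation(a, b)
  r_oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(res$r, r_oracle, tolerance = 1e-12)
  expect_equal(res$r2, r_oracle^2, tolerance = 1e-12)
  expect_equal(change_correlation(a, 3 * a + 1)$r2, 1)
  set.seed(23)
  big <- change_correlation(rnorm(1e4), rnorm(1e4))
  expect_lt(abs(big$r), 0.03)
  expect_error(change_correlation(a, rep(1, 4)), "zero-variance")
})

test_that("Welch test matches the oracle and reduces to pooled df", {
  set.seed(24)
  x <- rnorm(15, 0, 1); y <- rnorm(12, 0.8, 2)
  res <- subgroup_welch(c(x, y), rep(c("a", "b"), c(15, 12)))
  se <- sqrt(var(x) / 15 + var(y) / 12)
  t_oracle <- (mean(x) - mean(y)) / se
  df_oracle <- se^4 / ((var(x) / 15)^2 / 14 + (var(y) / 12)^2 / 11)
  expect_equal(res$t, t_oracle, tolerance = 1e-12)
  expect_equal(res$df, df_oracle, tolerance = 1e-12)
  # equal variances and n: Satterthwaite df collapses to 2n - 2
  x2 <- c(1, 2, 3, 4); y2 <- c(2, 3, 4, 5)   # identical spread
  expect_equal(subgroup_welch(c(x2, y2), rep(1:2, each = 4))$df, 6)
  expect_equal(subgroup_welch(c(x2, x2), rep(1:2, each = 4))$t, 0)
})

test_that("exclusion tallies track the remaining sample", {
  flow <- exclusion_tally(100, c(a = 5, b = 3))
  expect_equal(flow$remaining, c(95, 92))
  expect_error(exclusion_tally(5, c(a = 10)), "exceed")
})
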
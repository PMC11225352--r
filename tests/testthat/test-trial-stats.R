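test_that("uncorrected chi-squared reproduces the baseline-table p-values", {
  res <- pearson_chi2_2x2(matrix(c(2, 5, 9, 3), 2, 2, byrow = TRUE))
  expect_equal(round(res$p, 3), 0.048)
  res2 <- pearson_chi2_2x2(matrix(c(3, 4, 2, 10), 2, 2, byrow = TRUE))
  expect_equal(round(res2$p, 2), 0.21)
  flat <- pearson_chi2_2x2(matrix(c(5, 5, 5, 5), 2, 2))
  expect_equal(flat$chi2, 0); expect_equal(flat$p, 1)
  # transpose invariance and agreement with the standard implementation
  set.seed(10)
  for (i in 1:20) {
    m <- matrix(rpois(4, 6) + 1, 2, 2)
    a <- pearson_chi2_2x2(m); b <- pearson_chi2_2x2(t(m))
    expect_equal(a$chi2, b$chi2, tolerance = 1e-12)
    ref <- suppressWarnings(chisq.test(m, correct = FALSE))
    expect_equal(a$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(a$p, ref$p.value, tolerance = 1e-12)
  }
  expect_error(pearson_chi2_2x2(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               class = "silkfit_numeric_error")
})

test_that("Fisher exact matches hypergeometric enumeration on small tables", {
  expect_equal(fisher_exact_2x2(matrix(c(3, 4, 6, 6), 2, 2, byrow = TRUE)),
               1.0, tolerance = 1e-12)
  # exhaustive check of the 2/0/0/2 support: k in {0, 1, 2}
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 0, 2), 2, 2)), 1 / 3,
               tolerance = 1e-12)
  # a table equal to its expected counts has p = 1
  expect_equal(fisher_exact_2x2(matrix(c(4, 2, 8, 4), 2, 2, byrow = TRUE)), 1,
               tolerance = 1e-12)
  # equality with the reference implementation over random tables, n <= 30
  set.seed(12)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    a <- rmultinom(1, n, rep(0.25, 4))
    m <- matrix(a, 2, 2)
    expect_equal(fisher_exact_2x2(m), fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("pooled t from summaries reproduces the MMSE row and the oracle", {
  res <- pooled_t_from_summary(24, 4.4, 7, 24.5, 2.7, 12)
  expect_equal(round(res$p, 2), 0.76)
  expect_equal(res$df, 17)
  # hand-computed oracle
  sp2 <- (6 * 4.4^2 + 11 * 2.7^2) / 17
  t_hand <- (24 - 24.5) / sqrt(sp2 * (1 / 7 + 1 / 12))
  expect_equal(res$t, t_hand, tolerance = 1e-12)
  expect_equal(res$p, 2 * pt(-abs(t_hand), 17), tolerance = 1e-12)
  id <- pooled_t_from_summary(5, 1, 6, 5, 1, 6)
  expect_equal(id$t, 0); expect_equal(id$p, 1)
  zz <- pooled_t_from_summary(5, 0, 6, 5, 0, 6)
  expect_equal(zz$t, 0); expect_equal(zz$p, 1)
})

test_that("the change ANCOVA solves the normal equations", {
  d <- data.frame(change = c(1.2, 0.8, 1.9, 2.3, 0.4, 1.1, 2.8, 1.7),
                  treatment = rep(c("placebo", "posiphen"), 4),
                  age = c(70, 75, 61, 66, 80, 72, 59, 68),
                  sex = rep(c("female", "male"), each = 4))
  res <- ancova_change(d)
  X <- cbind(1, d$treatment == "posiphen", d$age, d$sex == "male")
  beta <- solve(t(X) %*% X, t(X) %*% d$change)
  expect_equal(res$difference, beta[2], tolerance = 1e-10)
  resid <- d$change - X %*% beta
  s2 <- sum(resid^2) / (8 - 4)
  se_hand <- sqrt(s2 * solve(t(X) %*% X)[2, 2])
  expect_equal(res$se, se_hand, tolerance = 1e-10)
  expect_equal(res$df, 4)
  # identical outcomes: difference 0, p 1
  d0 <- d; d0$change <- 2
  res0 <- ancova_change(d0)
  expect_equal(res0$difference, 0, tolerance = 1e-12)
  expect_equal(res0$p, 1, tolerance = 1e-12)
})

test_that("with constant covariates the ANCOVA collapses to the pooled t", {
  set.seed(13)
  d <- data.frame(change = rnorm(16), treatment = rep(c("a", "b"), each = 8),
                  age = 70, sex = "female")
  res <- ancova_change(d)
  g1 <- d$change[1:8]; g2 <- d$change[9:16]
  tt <- pooled_t_from_summary(mean(g2), sd(g2), 8, mean(g1), sd(g1), 8)
  expect_equal(res$t, tt$t, tolerance = 1e-10)
  expect_equal(res$p, tt$p, tolerance = 1e-10)
})

test_that("the treatment-effect estimator is unbiased under injected effects", {
  set.seed(14)
  delta <- 1.5
  est <- replicate(500, {
    n <- 24
    trt <- rep(c("placebo", "posiphen"), each = n / 2)
    age <- rnorm(n, 70, 8)
    sex <- sample(c("female", "male"), n, replace = TRUE)
    ch <- 0.05 * age + 0.3 * (sex == "male") + delta * (trt == "posiphen") +
      rnorm(n)
    ancova_change(data.frame(change = ch, treatment = trt, age = age,
                             sex = sex))$difference
  })
  expect_lt(abs(mean(est) - delta), 4 * sd(est) / sqrt(500))
})

test_that("dose-response contrasts recover a production reduction", {
  # fixed toy table against the normal equations
  d <- data.frame(r_app = c(1.0, 1.1, 0.8, 0.85, 0.7, 0.72),
                  arm = rep(c("placebo", "BID120", "TID180"), each = 2),
                  baseline_ab40 = c(5, 5.5, 4.2, 4.4, 3.9, 4.0))
  res <- dose_response_ancova(d)
  X <- cbind(1, d$arm == "BID120", d$arm == "TID180", d$baseline_ab40)
  beta <- solve(t(X) %*% X, t(X) %*% d$r_app)
  expect_equal(res$estimate[res$arm == "BID120"], beta[2], tolerance = 1e-10)
  expect_equal(res$estimate[res$arm == "TID180"], beta[3], tolerance = 1e-10)
  # direction: simulated 20% reduction at top dose, covariate correlated
  set.seed(15)
  hits <- replicate(500, {
    base <- rlnorm(20, 0, 0.2)
    arm <- rep(c("placebo", "TID180"), each = 10)
    r <- base * ifelse(arm == "TID180", 0.8, 1) * rlnorm(20, 0, 0.05)
    out <- dose_response_ancova(
      data.frame(r_app = r, arm = arm, baseline_ab40 = base * 5))
    out$estimate[out$arm == "TID180"] < 0
  })
  expect_gte(mean(hits), 0.95)
})

test_that("noncentral-t power matches simulation and its limits", {
  expect_equal(power_two_sample(5, 9, 0, 0.0361, 0.00954), 0.05,
               tolerance = 1e-10)
  p1 <- power_two_sample(5, 9, 27, 0.0361, 0.00954)
  p2 <- power_two_sample(10, 9, 27, 0.0361, 0.00954)
  p3 <- power_two_sample(20, 9, 27, 0.0361, 0.00954)
  expect_true(p1 < p2 && p2 < p3)            # increasing in n1
  # Monte-Carlo oracle at 1e5 replicates
  set.seed(16)
  n1 <- 5; n2 <- 9; mu <- 0.0361; sdv <- 0.00954; pct <- 27
  m1 <- matrix(rnorm(1e5 * n1, mu * (1 + pct / 100), sdv), ncol = n1)
  m2 <- matrix(rnorm(1e5 * n2, mu, sdv), ncol = n2)
  x1 <- rowMeans(m1); x2 <- rowMeans(m2)
  v1 <- apply(m1, 1, var); v2 <- apply(m2, 1, var)
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  tstat <- (x1 - x2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  mc <- mean(abs(tstat) > qt(0.975, n1 + n2 - 2))
  expect_lt(abs(power_two_sample(n1, n2, pct, mu, sdv) - mc), 0.01)
})
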
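mk_silk <- function(t, y, id = "s1") silk_series(id, "Ab40", t, y)

test_that("fixed-window FSR equals the closed-form OLS slope over plateau", {
  t <- seq(0, 36, 2)
  # exact line inside the window: slope 0.005/h, plateau 0.10 -> FSR 0.05
  y <- pmin(pmax(0.001 + 0.005 * t, 0), 1)
  r <- fsr_fixed_window(mk_silk(t, y), plateau = 0.10)
  expect_equal(r$fsr, 0.05, tolerance = 1e-12)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$n_points, 6L)          # hours 6..16 on the 2-h grid
  # constant series: zero slope, zero FSR
  rc <- fsr_fixed_window(mk_silk(t, rep(0.02, 19)), plateau = 0.10)
  expect_equal(rc$fsr, 0)
  # noisy line against hand-solved normal equations
  set.seed(3)
  yn <- 0.01 + 0.004 * t + rnorm(19, 0, 1e-3)
  yn <- pmin(pmax(yn, 0), 1)
  rn <- fsr_fixed_window(mk_silk(t, yn), plateau = 0.12)
  w <- t >= 6 & t <= 16
  tx <- t[w]; yx <- yn[w]
  slope_hand <- (sum(tx * yx) - length(tx) * mean(tx) * mean(yx)) /
    (sum(tx^2) - length(tx) * mean(tx)^2)
  expect_equal(rn$slope, slope_hand, tolerance = 1e-12)
  expect_equal(rn$fsr, slope_hand / 0.12, tolerance = 1e-12)
})

test_that("FSR scales with the series and inversely with the plateau", {
  t <- seq(0, 36, 2)
  set.seed(5)
  y <- pmin(pmax(0.002 + 0.004 * t + rnorm(19, 0, 5e-4), 0), 1)
  base <- fsr_fixed_window(mk_silk(t, y), 0.1)$fsr
  expect_equal(fsr_fixed_window(mk_silk(t, 2 * y), 0.1)$fsr, 2 * base,
               tolerance = 1e-12)
  expect_equal(fsr_fixed_window(mk_silk(t, y), 0.2)$fsr, base / 2,
               tolerance = 1e-12)
  # guards
  expect_error(fsr_fixed_window(mk_silk(t, y), 0),
               class = "silkfit_normalization_error")
  expect_error(fsr_fixed_window(mk_silk(c(0, 8, 20), y[1:3]), 0.1),
               class = "silkfit_insufficient_data_error")
})

test_that("the automated window brackets a constructed monotone upslope", {
  t <- seq(0, 36, 2)
  y <- ifelse(t <= 20, pmax(t - 4, 0) * 0.004, 0.064 - (t - 20) * 0.002)
  w <- detect_upslope(mk_silk(t, y))
  expect_gte(w[1], 4); expect_lte(w[2], 20)
  steepest <- t[which.max(diff(y))]
  expect_true(w[1] <= steepest && steepest <= w[2])
  expect_error(detect_upslope(mk_silk(t, seq(0.9, 0.1, length.out = 19))),
               class = "silkfit_detection_error")
})

test_that("automated and fixed windows agree on noise-free model output", {
  sub <- noise_free_subject()
  plateau <- plateau_enrichment(sub$enrichment)
  fx <- fsr_fixed_window(sub$silk, plateau)
  fa <- fsr_auto_window(sub$silk, plateau)
  expect_gt(fx$fsr, 0)
  expect_lt(abs(fa$fsr - fx$fsr) / fx$fsr, 0.20)
  # reproducible to within floating noise across runs
  expect_identical(fx$fsr, fsr_fixed_window(sub$silk, plateau)$fsr)
})

test_that("newly synthesized series integrates by the trapezoid rule", {
  t <- seq(0, 36, 2)
  r <- newly_synthesized_series(10, mk_silk(t, rep(0.1, 19)))
  expect_equal(unique(r$values), 1.0)
  expect_equal(r$auc, 36, tolerance = 1e-12)
  expect_equal(newly_synthesized_series(10, mk_silk(t, rep(0, 19)))$auc, 0)
  set.seed(8)
  y <- runif(19, 0, 0.1)
  r2 <- newly_synthesized_series(25, mk_silk(t, y))
  auc_hand <- sum(diff(t) * (head(25 * y, -1) + tail(25 * y, -1)) / 2)
  expect_equal(r2$auc, auc_hand, tolerance = 1e-12)
})

test_that("one-way ANOVA on FSR matches the sums-of-squares decomposition", {
  tab <- data.frame(fsr = c(1, 2, 3, 4, 5, 6),
                    arm = rep(c("placebo", "QD60"), each = 3))
  res <- compare_fsr_groups(tab)
  # brute-force decomposition
  g1 <- c(1, 2, 3); g2 <- c(4, 5, 6); gm <- mean(c(g1, g2))
  ssb <- 3 * (mean(g1) - gm)^2 + 3 * (mean(g2) - gm)^2
  ssw <- sum((g1 - mean(g1))^2) + sum((g2 - mean(g2))^2)
  f_hand <- (ssb / 1) / (ssw / 4)
  expect_equal(res$F, f_hand, tolerance = 1e-12)
  expect_equal(res$p, pf(f_hand, 1, 4, lower.tail = FALSE), tolerance = 1e-12)
  # degenerate equal-means zero-variance guard
  flat <- data.frame(fsr = rep(2, 6), arm = rep(c("a", "b"), each = 3))
  res0 <- compare_fsr_groups(flat)
  expect_equal(res0$F, 0); expect_equal(res0$p, 1)
  expect_error(compare_fsr_groups(data.frame(fsr = 1:3, arm = c("a", "a", "b"))),
               class = "silkfit_degrees_of_freedom_error")
})

test_that("isoform FSR correlations match the covariance formula", {
  x <- c(0.03, 0.035, 0.04, 0.05, 0.028, 0.045)
  tab <- data.frame(subject_id = rep(sprintf("s%d", 1:6), 2),
                    isoform = rep(c("Ab38", "Ab40"), each = 6),
                    fsr = c(2 * x, x))
  res <- isoform_correlation(tab)
  expect_equal(res$r, 1, tolerance = 1e-12)
  set.seed(9)
  y <- x + rnorm(6, 0, 0.01)
  tab2 <- tab; tab2$fsr <- c(y, x)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(isoform_correlation(tab2)$r, r_hand, tolerance = 1e-12)
  expect_error(isoform_correlation(
    within(tab, fsr[1:6] <- 0.5)), class = "silkfit_numeric_error")
})
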
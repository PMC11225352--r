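# Baseline-table tests, covariate-adjusted change models, dose-response
# contrasts and the two-sample power computation.

as_2x2 <- function(table) {
  m <- matrix(as.numeric(table), 2, 2)
  if (any(m < 0) || any(m != round(m))) {
    abort_silkfit("2x2 table needs nonnegative integer counts",
                  "silkfit_validation_error")
  }
  m
}

#' Pearson chi-squared test for a 2x2 table
#'
#' Classic closed form `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))` without
#' continuity correction, with the p-value from the chi-squared upper tail
#' on 1 degree of freedom.
#'
#' @param table 2x2 matrix of counts (rows = arm, columns = trait).
#' @return List with `chi2`, `df`, `p`.
#' @export
pearson_chi2_2x2 <- function(table) {
  m <- as_2x2(table)
  a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) {
    abort_silkfit("chi-squared undefined with a zero margin",
                  "silkfit_numeric_error")
  }
  n <- sum(m)
  chi2 <- n * (a * d - b * c)^2 / prod(margins)
  list(chi2 = chi2, df = 1L, p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Fisher exact test for a 2x2 table (two-sided)
#'
#' Sums the hypergeometric probabilities of all tables with the observed
#' margins whose probability does not exceed that of the observed table.
#'
#' @param table 2x2 matrix of counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  m <- as_2x2(table)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (n < 1) abort_silkfit("empty table", "silkfit_validation_error")
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(support, c1, n - c1, r1)
  p_obs <- stats::dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

#' Pooled-variance two-sample t test from summary statistics
#'
#' @param mean1,sd1,n1 Group 1 summary.
#' @param mean2,sd2,n2 Group 2 summary.
#' @return List with `t`, `df`, `p` (two-sided).
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2 || n2 < 2) {
    abort_silkfit("each group needs n >= 2", "silkfit_degrees_of_freedom_error")
  }
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  if (se == 0) {
    t <- if (mean1 == mean2) 0 else Inf * sign(mean1 - mean2)
  } else {
    t <- (mean1 - mean2) / se
  }
  p <- if (is.finite(t)) 2 * stats::pt(-abs(t), df) else 0
  list(t = t, df = df, p = p)
}

#' Covariate-adjusted analysis of biomarker change
#'
#' Ordinary least squares of change on treatment with age and sex (and
#' optionally baseline MMSE) as covariates.  Reports least-squares mean
#' change per group (prediction at covariate means), the treatment
#' difference with its standard error, t and two-sided p.
#'
#' @param data Data frame with columns `change`, `treatment` (two levels;
#'   the second level's coefficient is reported), `age`, `sex`, and
#'   optionally `mmse_baseline`.
#' @param include_mmse Add baseline MMSE as a covariate (default FALSE,
#'   matching the reported covariate set of age and sex).
#' @return Object of class `ancova_result`: `ls_means` (named), `difference`,
#'   `se`, `t`, `df`, `p`, and the fitted `lm`.
#' @export
ancova_change <- function(data, include_mmse = FALSE) {
  data$treatment <- factor(data$treatment)
  if (nlevels(data$treatment) != 2) {
    abort_silkfit("treatment must have exactly two levels",
                  "silkfit_validation_error")
  }
  data$sex <- factor(data$sex)
  # constant covariates carry no information and would alias the intercept
  rhs <- "treatment"
  if (stats::var(data$age) > 0) rhs <- c(rhs, "age")
  if (nlevels(data$sex) > 1) rhs <- c(rhs, "sex")
  if (include_mmse && stats::var(data$mmse_baseline) > 0) {
    rhs <- c(rhs, "mmse_baseline")
  }
  form <- stats::reformulate(rhs, response = "change")
  if (nrow(data) <= length(rhs) + 1) {
    abort_silkfit("more coefficients than observations",
                  "silkfit_validation_error")
  }
  fit <- stats::lm(form, data = data)
  if (fit$rank < length(stats::coef(fit))) {
    aliased <- names(which(is.na(stats::coef(fit))))
    abort_silkfit(sprintf("singular design: aliased column(s) %s",
                          paste(aliased, collapse = ", ")),
                  "silkfit_singular_design_error")
  }
  sm <- summary(fit)
  co <- sm$coefficients
  trt_row <- grep("^treatment", rownames(co))
  est <- co[trt_row, "Estimate"]; se <- co[trt_row, "Std. Error"]
  # LS means: prediction at the covariate means for each treatment level
  nd <- data.frame(treatment = levels(data$treatment),
                   age = mean(data$age))
  nd$sex <- factor(levels(data$sex)[1], levels = levels(data$sex))
  if (include_mmse) nd$mmse_baseline <- mean(data$mmse_baseline)
  ls0 <- stats::predict(fit, newdata = nd)
  if (nlevels(data$sex) > 1) {   # average over the sex factor proportions
    nd2 <- nd; nd2$sex <- factor(levels(data$sex)[2],
                                 levels = levels(data$sex))
    w <- mean(data$sex == levels(data$sex)[2])
    ls0 <- (1 - w) * ls0 + w * stats::predict(fit, newdata = nd2)
  }
  names(ls0) <- levels(data$treatment)
  df <- fit$df.residual
  if (se < .Machine$double.eps^0.5 && abs(est) < .Machine$double.eps^0.5) {
    tval <- 0; pval <- 1       # perfectly flat outcome
  } else {
    tval <- est / se
    pval <- 2 * stats::pt(-abs(tval), df)
  }
  structure(list(ls_means = ls0, difference = unname(est), se = unname(se),
                 t = unname(tval), df = df, p = unname(pval), fit = fit),
            class = "ancova_result")
}

#' Dose-response model with pre-treatment concentration covariate
#'
#' Linear model of the production-rate estimate on dose-arm indicators with
#' the pre-drug lumbar concentration as covariate; reports each arm's
#' adjusted contrast versus placebo.
#'
#' @param data Data frame with columns `r_app`, `arm` (factor or character;
#'   `"placebo"` is the reference), `baseline_ab40`.
#' @return Data frame with one row per non-placebo arm: `arm`, `estimate`,
#'   `se`, `t`, `p`; attribute `fit` holds the `lm`.
#' @export
dose_response_ancova <- function(data) {
  lv <- unique(as.character(data$arm))
  if (length(lv) < 2) {
    abort_silkfit("dose-response needs >= 2 dose levels",
                  "silkfit_validation_error")
  }
  ref <- if ("placebo" %in% lv) "placebo" else lv[1]
  data$arm <- stats::relevel(factor(data$arm), ref = ref)
  fit <- stats::lm(r_app ~ arm + baseline_ab40, data = data)
  if (fit$rank < length(stats::coef(fit))) {
    abort_silkfit("singular dose-response design",
                  "silkfit_singular_design_error")
  }
  co <- summary(fit)$coefficients
  rows <- grep("^arm", rownames(co))
  out <- data.frame(arm = sub("^arm", "", rownames(co)[rows]),
                    estimate = co[rows, "Estimate"],
                    se = co[rows, "Std. Error"],
                    t = co[rows, "t value"],
                    p = co[rows, "Pr(>|t|)"], row.names = NULL)
  attr(out, "fit") <- fit
  out
}

#' Power of a two-sided pooled-variance t test
#'
#' For detecting a `percent_change` shift of `reference_mean` against
#' residual spread `reference_sd`, with the noncentral-t distribution at
#' `n1 + n2 - 2` degrees of freedom.
#'
#' @param n1,n2 Group sizes.
#' @param percent_change Detectable change as a percentage of
#'   `reference_mean` (e.g. 27).
#' @param reference_mean,reference_sd Reference mean and SD of the outcome.
#' @param alpha Two-sided significance level.
#' @return Power in (0, 1).
#' @export
power_two_sample <- function(n1, n2, percent_change, reference_mean,
                             reference_sd, alpha = 0.05) {
  if (reference_sd <= 0) {
    abort_silkfit("reference_sd must be > 0", "silkfit_validation_error")
  }
  if (alpha <= 0 || alpha >= 1) {
    abort_silkfit("alpha must lie in (0, 1)", "silkfit_validation_error")
  }
  delta <- percent_change / 100 * reference_mean / reference_sd
  ncp <- delta * sqrt(n1 * n2 / (n1 + n2))
  df <- n1 + n2 - 2
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(tcrit, df, ncp = ncp, lower.tail = FALSE) +
    stats::pt(-tcrit, df, ncp = ncp, lower.tail = TRUE)
}
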
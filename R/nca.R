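# Noncompartmental pharmacokinetics: AUC0-24, Cmax/Tmax, terminal slope,
# derived parameters, and the geometric summary conventions used for
# reporting (geometric mean, % geometric CV, median (min-max) for Tmax).

nca_points <- function(series) {
  keep <- !series$missing_mask & !is.na(series$values)
  list(t = series$times[keep], y = series$values[keep])
}

#' Restrict a concentration series to a time window
#'
#' Used to evaluate single-interval PK conventions (e.g. the 0-24 h dosing
#' day) on longer sampling spans.
#'
#' @param series A [concentration_series()].
#' @param lo,hi Window bounds, h (inclusive).
#' @return A [concentration_series()] with only the in-window samples.
#' @export
window_series <- function(series, lo = 0, hi = 24) {
  keep <- series$times >= lo & series$times <= hi
  concentration_series(series$subject_id, series$analyte, series$matrix,
                       series$times[keep], series$values[keep],
                       series$clock_times[keep], series$missing_mask[keep])
}

#' Area under the concentration-time curve, 0-24 h
#'
#' Linear trapezoid over the observed non-missing points within `[0, 24]`;
#' no extrapolation beyond the last observed point.
#'
#' @param series A [concentration_series()].
#' @return AUC in h x (concentration unit).
#' @export
auc_0_24 <- function(series) {
  p <- nca_points(series)
  keep <- p$t >= 0 & p$t <= 24
  if (sum(keep) < 2) {
    abort_silkfit("AUC needs >= 2 observed points in [0, 24]",
                  "silkfit_insufficient_data_error")
  }
  pracma::trapz(p$t[keep], p$y[keep])
}

#' Maximum observed concentration and its time
#'
#' Ties take the earliest time.
#'
#' @param series A [concentration_series()].
#' @return List with `cmax` and `tmax`.
#' @export
cmax_tmax <- function(series) {
  p <- nca_points(series)
  if (!length(p$y)) {
    abort_silkfit("no observed concentrations", "silkfit_insufficient_data_error")
  }
  i <- which(p$y == max(p$y))[1]
  list(cmax = p$y[i], tmax = p$t[i])
}

#' Terminal elimination rate constant
#'
#' Log-linear regression over candidate terminal point sets (all suffixes of
#' at least 3 positive concentrations strictly after Tmax), choosing the
#' suffix with maximal adjusted r-squared; `lambda_z` is the negative slope
#' and must be positive, otherwise the terminal phase is undefined (as when
#' accumulation flattens the profile).
#'
#' @param series A [concentration_series()].
#' @return List with `lambda_z` (1/h), `t_half` (h), `n_points`,
#'   `r2_adj`; `lambda_z = NA` when undefined.
#' @export
lambda_z <- function(series) {
  p <- nca_points(series)
  ct <- cmax_tmax(series)
  keep <- p$t > ct$tmax & p$y > 0
  t <- p$t[keep]; y <- p$y[keep]
  undefined <- list(lambda_z = NA_real_, t_half = NA_real_,
                    n_points = 0L, r2_adj = NA_real_)
  if (length(t) < 3) return(undefined)
  best <- NULL
  for (i in seq_len(length(t) - 2)) {       # suffixes t[i..n]
    tt <- t[i:length(t)]; ly <- log(y[i:length(t)])
    fit <- stats::lm(ly ~ tt)
    slope <- unname(stats::coef(fit)["tt"])
    if (!is.finite(slope) || slope >= -1e-9) next   # flat phase: undefined
    r2a <- summary(fit)$adj.r.squared
    if (is.null(best) || r2a > best$r2_adj + 1e-12) {
      best <- list(lambda_z = -slope, t_half = log(2) / (-slope),
                   n_points = length(tt), r2_adj = r2a)
    }
  }
  best %||% undefined
}

#' Dose-normalized derived PK parameters
#'
#' `Cl/F = dose / AUC0-24` (mg and h.ng/mL reconciled to L/h),
#' `Vz/F = Cl/F / lambda_z`, `t1/2 = ln 2 / lambda_z`.  When the terminal
#' slope is undefined, `vz_f` and `t_half` are omitted (NA).
#'
#' @param dose_mg Dose in mg over the AUC interval.
#' @param auc AUC0-24 in h.ng/mL (> 0).
#' @param lz `lambda_z` in 1/h, possibly NA.
#' @return List with `cl_f` (L/h), `vz_f` (L), `t_half` (h).
#' @export
derived_params <- function(dose_mg, auc, lz = NA_real_) {
  if (!is.numeric(auc) || auc <= 0) {
    abort_silkfit("AUC must be > 0", "silkfit_validation_error")
  }
  cl_f <- dose_mg * 1e6 / auc / 1e3        # mg -> ng, then mL -> L
  if (is.na(lz) || lz <= 0) {
    return(list(cl_f = cl_f, vz_f = NA_real_, t_half = NA_real_))
  }
  list(cl_f = cl_f, vz_f = cl_f / lz, t_half = log(2) / lz)
}

#' Full per-series noncompartmental analysis
#'
#' @param series A [concentration_series()] for a drug analyte.
#' @param dose_mg Administered dose, mg (optional; enables `cl_f`, `vz_f`).
#' @return One-row data frame (an NCA result).
#' @export
nca_analyze <- function(series, dose_mg = NA_real_) {
  auc <- auc_0_24(series)
  ct <- cmax_tmax(series)
  lz <- lambda_z(series)
  dp <- if (!is.na(dose_mg) && auc > 0) {
    derived_params(dose_mg, auc, lz$lambda_z)
  } else list(cl_f = NA_real_, vz_f = NA_real_, t_half = lz$t_half)
  data.frame(subject_id = series$subject_id, analyte = series$analyte,
             matrix = series$matrix, auc_0_24 = auc, cmax = ct$cmax,
             tmax = ct$tmax, lambda_z = lz$lambda_z, t_half = lz$t_half,
             vz_f = dp$vz_f, cl_f = dp$cl_f,
             n_lambda_points = lz$n_points, lambda_r2_adj = lz$r2_adj)
}

#' Geometric summary of positive values
#'
#' Geometric mean `exp(mean(log x))` and percent geometric coefficient of
#' variation `100 * sqrt(exp(s2) - 1)` with `s2` the sample variance of the
#' logs — the reporting convention for PK parameters.
#'
#' @param values Positive numeric vector.
#' @return List with `n`, `geo_mean`, `pct_gcv`.
#' @export
geo_summary <- function(values) {
  bad <- which(!is.finite(values) | values <= 0)
  if (length(bad)) {
    abort_silkfit(sprintf("nonpositive value(s) at position(s) %s",
                          paste(bad, collapse = ", ")),
                  "silkfit_validation_error")
  }
  lx <- log(values)
  s2 <- if (length(lx) > 1) stats::var(lx) else 0
  list(n = length(values), geo_mean = exp(mean(lx)),
       pct_gcv = 100 * sqrt(exp(s2) - 1))
}

#' Median (min-max) summary for Tmax
#'
#' @param values Numeric vector of Tmax values.
#' @return List with `median`, `min`, `max`, and a formatted string.
#' @export
tmax_summary <- function(values) {
  list(median = stats::median(values), min = min(values), max = max(values),
       label = sprintf("%g (%g-%g)", stats::median(values), min(values),
                       max(values)))
}

#' Spearman correlation of plasma and CSF exposure
#'
#' @param auc_table Data frame with columns `analyte`, `auc_plasma`,
#'   `auc_csf` (one row per subject x analyte).
#' @return Data frame with `analyte`, `rho`, `n` (average ranks on ties).
#' @export
plasma_csf_correlation <- function(auc_table) {
  do.call(rbind, lapply(split(auc_table, auc_table$analyte), function(d) {
    ok <- stats::complete.cases(d$auc_plasma, d$auc_csf)
    if (sum(ok) < 4) {
      abort_silkfit("Spearman correlation needs >= 4 pairs",
                    "silkfit_insufficient_data_error")
    }
    x <- d$auc_plasma[ok]; y <- d$auc_csf[ok]
    if (stats::var(x) == 0 || stats::var(y) == 0) {
      abort_silkfit("Spearman correlation undefined for constant input",
                    "silkfit_numeric_error")
    }
    data.frame(analyte = d$analyte[1],
               rho = stats::cor(x, y, method = "spearman"), n = sum(ok))
  }))
}
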
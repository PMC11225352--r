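# Fractional synthesis rate estimation from SILK labeled-fraction curves.
#
# FSR = (OLS slope of the labeled fraction over the upslope window) divided
# by the plasma leucine plateau enrichment.  The prespecified window is
# hours 6-16; a post-hoc automated detector finds the upslope from the
# smoothed first differences.

#' Plateau plasma leucine enrichment
#'
#' Mean plasma enrichment over the plateau window (default hours 4-9 of the
#' infusion), the precursor normalization used by FSR.
#'
#' @param leucine A [concentration_series()] with analyte
#'   `leucine_enrichment`, or an `enrichment_curve`.
#' @param window Plateau window, h.
#' @return Mean enrichment (unitless).
#' @export
plateau_enrichment <- function(leucine, window = c(4, 9)) {
  if (inherits(leucine, "enrichment_curve")) {
    tt <- seq(window[1], window[2], by = 0.25)
    return(mean(eval_enrichment(leucine, tt)))
  }
  stopifnot(inherits(leucine, "concentration_series"))
  keep <- !leucine$missing_mask & leucine$times >= window[1] &
    leucine$times <= window[2]
  if (!any(keep)) {
    abort_silkfit("no plasma enrichment samples in the plateau window",
                  "silkfit_insufficient_data_error")
  }
  mean(leucine$values[keep])
}

#' Fixed-window fractional synthesis rate
#'
#' OLS slope of the labeled fraction against time over the window (default
#' the prespecified hours 6-16), normalized by the plateau precursor
#' enrichment.  Missing draws inside the window are dropped.
#'
#' @param silk A [silk_series()].
#' @param plateau Plateau plasma leucine enrichment (> 0), see
#'   [plateau_enrichment()].
#' @param window Upslope window `[h, h]`.
#' @return Object of class `fsr_result`: list with `subject_id`, `isoform`,
#'   `window`, `slope` (fraction/h), `normalization`, `fsr` (1/h),
#'   `r_squared`, `n_points`.
#' @export
fsr_fixed_window <- function(silk, plateau, window = c(6, 16)) {
  stopifnot(inherits(silk, "silk_series"))
  if (!is.numeric(plateau) || plateau <= 0) {
    abort_silkfit("plateau enrichment must be > 0", "silkfit_normalization_error")
  }
  keep <- !silk$missing_mask & silk$times >= window[1] & silk$times <= window[2]
  if (sum(keep) < 3) {
    abort_silkfit(sprintf("subject %s: %d points in window (< 3)",
                          silk$subject_id, sum(keep)),
                  "silkfit_insufficient_data_error")
  }
  t <- silk$times[keep]; y <- silk$labeled_fraction[keep]
  fit <- stats::lm(y ~ t)
  slope <- unname(stats::coef(fit)["t"])
  r2 <- if (stats::var(y) > 0) summary(fit)$r.squared else NA_real_
  structure(list(subject_id = silk$subject_id, isoform = silk$isoform,
                 window = window, slope = slope, normalization = plateau,
                 fsr = slope / plateau, r_squared = r2,
                 n_points = sum(keep)), class = "fsr_result")
}

#' Automated upslope window detection
#'
#' Smooths the labeled-fraction series with a 3-point running median, takes
#' first differences, and returns the longest contiguous run of positive
#' differences containing the maximum difference (earliest run on ties),
#' extended symmetrically to cover at least 4 points.
#'
#' @param silk A [silk_series()] with at least 6 non-missing points.
#' @return Window `c(t_start, t_end)` in hours.
#' @export
detect_upslope <- function(silk) {
  stopifnot(inherits(silk, "silk_series"))
  keep <- !silk$missing_mask
  if (sum(keep) < 6) {
    abort_silkfit("upslope detection needs >= 6 points",
                  "silkfit_insufficient_data_error")
  }
  t <- silk$times[keep]; y <- silk$labeled_fraction[keep]
  ys <- stats::runmed(y, 3, endrule = "keep")
  d <- diff(ys)
  # count a difference as rising only when its slope is material relative to
  # the steepest rise, so a long near-flat lead-in does not stretch the window
  pos <- d > 0 & d > 0.1 * max(d)
  if (!any(pos)) {
    abort_silkfit("no positive upslope run detected", "silkfit_detection_error")
  }
  runs <- rle(pos)
  ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1L
  pos_runs <- which(runs$values & runs$lengths >= 3L)
  if (!length(pos_runs)) {
    abort_silkfit("no positive upslope run of length >= 3",
                  "silkfit_detection_error")
  }
  # the admissible (length >= 3) run holding the steepest rise; earliest wins
  run_max <- vapply(pos_runs, function(r) max(d[starts[r]:ends[r]]),
                    numeric(1))
  run <- pos_runs[which.max(run_max)]
  i0 <- starts[run]; i1 <- ends[run] + 1L    # diff index -> point index
  while (i1 - i0 + 1L < 4L) {                # enforce >= 4 points
    if (i0 > 1L) i0 <- i0 - 1L
    if (i1 - i0 + 1L < 4L && i1 < length(t)) i1 <- i1 + 1L
  }
  c(t[i0], t[i1])
}

#' Automated-window fractional synthesis rate
#'
#' @inheritParams fsr_fixed_window
#' @return An `fsr_result`, with the detected window.
#' @export
fsr_auto_window <- function(silk, plateau) {
  fsr_fixed_window(silk, plateau, window = detect_upslope(silk))
}

#' Newly synthesized amyloid-beta series and its exposure
#'
#' Multiplies the concentration at catheter placement by the labeled
#' fraction at each time point, giving the concentration-equivalent of newly
#' synthesized peptide; the area under this curve (linear trapezoid over the
#' observed span) summarizes 36-h new synthesis.
#'
#' @param conc_at_t0 Concentration at time 0, pg/mL (>= 0).
#' @param silk A [silk_series()].
#' @return List with `times`, `values` (pg/mL) and `auc` (pg h/mL).
#' @export
newly_synthesized_series <- function(conc_at_t0, silk) {
  stopifnot(conc_at_t0 >= 0, inherits(silk, "silk_series"))
  keep <- !silk$missing_mask
  t <- silk$times[keep]; y <- conc_at_t0 * silk$labeled_fraction[keep]
  auc <- if (length(t) >= 2) pracma::trapz(t, y) else 0
  list(times = t, values = y, auc = auc)
}

#' One-way ANOVA of FSR by treatment arm
#'
#' @param fsr_table Data frame with columns `fsr` and `arm`.
#' @return List with `F`, `df1`, `df2`, `p` and the `stats::aov` table.
#' @export
compare_fsr_groups <- function(fsr_table) {
  arm <- factor(fsr_table$arm)
  if (nlevels(arm) < 2) {
    abort_silkfit("ANOVA needs >= 2 groups", "silkfit_validation_error")
  }
  if (any(table(arm) < 2)) {
    abort_silkfit("each group needs >= 2 observations",
                  "silkfit_degrees_of_freedom_error")
  }
  fit <- stats::aov(fsr ~ arm, data = data.frame(fsr = fsr_table$fsr, arm = arm))
  tab <- summary(fit)[[1]]
  ss_between <- tab["arm", "Sum Sq"]
  # flat data: both sums of squares are rounding dust relative to the scale
  if (ss_between <= 1e-12 * max(sum(fsr_table$fsr^2), .Machine$double.xmin)) {
    return(list(F = 0, df1 = tab["arm", "Df"], df2 = tab["Residuals", "Df"],
                p = 1, table = tab))
  }
  list(F = tab["arm", "F value"], df1 = tab["arm", "Df"],
       df2 = tab["Residuals", "Df"], p = tab["arm", "Pr(>F)"], table = tab)
}

#' Pairwise Pearson correlation of FSR between isoforms
#'
#' @param fsr_table Data frame with columns `subject_id`, `isoform`, `fsr`.
#' @return Data frame with one row per isoform pair: `isoform1`, `isoform2`,
#'   `r`, `p`, `n`.
#' @export
isoform_correlation <- function(fsr_table) {
  wide <- stats::reshape(fsr_table[, c("subject_id", "isoform", "fsr")],
                         idvar = "subject_id", timevar = "isoform",
                         direction = "wide")
  isos <- sub("^fsr\\.", "", setdiff(names(wide), "subject_id"))
  pairs <- utils::combn(isos, 2, simplify = FALSE)
  do.call(rbind, lapply(pairs, function(pr) {
    x <- wide[[paste0("fsr.", pr[1])]]; y <- wide[[paste0("fsr.", pr[2])]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 4) {
      abort_silkfit("isoform correlation needs >= 4 paired observations",
                    "silkfit_insufficient_data_error")
    }
    if (stats::var(x[ok]) == 0 || stats::var(y[ok]) == 0) {
      abort_silkfit("correlation undefined for a constant FSR vector",
                    "silkfit_numeric_error")
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(isoform1 = pr[1], isoform2 = pr[2],
               r = unname(ct$estimate), p = ct$p.value, n = sum(ok))
  }))
}
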
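# Grid-multistart estimation of the APP production rate.
#
# For each combination of the systematically varied parameters (f_VCSF,
# V_SP, Q_leak, k_BPD40 regime) a constrained simplex optimization fits the
# adjustable parameters to the SILK labeled-fraction data and the early
# (0-15 h, post-11:00) lumbar concentration data; combinations whose block
# sum-of-squares both fall within the acceptance band of the best values are
# averaged to give the subject's production-rate estimate.

#' Grid configuration for the fitting procedure
#'
#' The default grid is 4 f_VCSF x 4 V_SP x 4 Q_leak x 2 k_BPD40 regimes =
#' 128 optimizations per subject; the `"test"` preset is a reduced
#' 2 x 2 x 2 x 1 grid (8 optimizations) for fast runs.
#'
#' @param preset `"default"` or `"test"`.
#' @param config Configuration list, see [silk_config()].
#' @return Object of class `grid_config` with the grid values, penalty and
#'   band settings, and `n_combinations`.
#' @export
grid_config <- function(preset = c("default", "test"), config = silk_config()) {
  preset <- match.arg(preset)
  g <- config$grid
  if (preset == "test") g <- merge_config(g, config$grid_test)
  g$k_BPD40_ranges <- lapply(g$k_BPD40_ranges, as.numeric)
  g$n_combinations <- length(g$f_VCSF_values) * length(g$V_SP_values) *
    length(g$Q_leak_values) * length(g$k_BPD40_ranges)
  if (g$acceptance_band <= 0) {
    abort_silkfit("acceptance_band must be > 0", "silkfit_validation_error")
  }
  g$preset <- preset
  structure(g, class = "grid_config")
}

#' Assemble the fit dataset for one subject
#'
#' SILK points: all non-missing draws over 0-36 h.  Concentration points:
#' non-missing, within the early-time window (default 0-15 h) and drawn at
#' or after 11:00 local time (morning samples are confounded by the previous
#' night's sleep); points without a recorded clock time are not clock-filtered.
#'
#' @param silk A [silk_series()] (Ab40).
#' @param conc A [concentration_series()] (Ab40, CSF) whose `clock_times`
#'   carry minutes since midnight.
#' @param grid A [grid_config()].
#' @param enrichment Plasma leucine `enrichment_curve` for the subject.
#' @param schedule The sampling [sample_schedule()].
#' @param age Subject age in years (sets the CSF compartment volumes).
#' @param config Configuration list.
#' @return Object of class `fit_data`.
#' @export
prepare_fit_data <- function(silk, conc, grid = grid_config(),
                             enrichment = default_enrichment(),
                             schedule = default_schedule(), age = 70,
                             config = silk_config()) {
  stopifnot(inherits(silk, "silk_series"),
            inherits(conc, "concentration_series"))
  if (silk$subject_id != conc$subject_id) {
    abort_silkfit("SILK and concentration series belong to different subjects",
                  "silkfit_validation_error")
  }
  keep_s <- !silk$missing_mask & silk$times >= 0 & silk$times <= 36
  if (sum(keep_s) < 6) {
    abort_silkfit(sprintf("subject %s: %d usable SILK points (< 6)",
                          silk$subject_id, sum(keep_s)),
                  "silkfit_insufficient_data_error")
  }
  w <- grid$conc_fit_window
  keep_c <- !conc$missing_mask & conc$times >= w[1] & conc$times <= w[2]
  # first-morning filter: drop draws taken before 11:00 on the starting day
  # (sleep the previous night confounds them); post-midnight samples of the
  # same experiment are governed by the time window, not the clock
  clk <- conc$clock_times
  keep_c <- keep_c &
    (is.na(clk) | clk >= grid$clock_filter_min | conc$times >= 12)
  structure(list(
    subject_id = silk$subject_id,
    silk_times = silk$times[keep_s],
    silk_obs = silk$labeled_fraction[keep_s],
    conc_times = conc$times[keep_c],
    conc_obs = conc$values[keep_c],
    enrichment = enrichment, schedule = schedule, age = age,
    lab = label_curve_terms(enrichment, config$model$tau_delay,
                            config$model$n_leu),
    config = config), class = "fit_data")
}

# objective pieces for one parameter vector; R_APP profiled by linear least
# squares on the concentration block (the system is linear in production)
eval_objective <- function(theta, fd, gp, grid, sf_40 = 1) {
  k_lo <- gp$k_range[1]; k_hi <- gp$k_range[2]
  k_BPD40 <- k_lo + (k_hi - k_lo) * stats::plogis(theta[1])
  Q_CSF <- exp(theta[2]); Q_osc <- exp(theta[3])
  params <- tryCatch(
    kinetic_parameters(R_APP = 1, k_BPD40 = k_BPD40, Q_CSF = Q_CSF,
                       Q_osc = Q_osc, SF_40 = sf_40, Q_leak = gp$Q_leak,
                       f_VCSF = gp$f_VCSF, V_SP = gp$V_SP, age = fd$age,
                       config = fd$config),
    error = function(e) NULL)
  if (is.null(params)) return(list(J = 1e10))
  out <- tryCatch(simulate_model(params, fd$enrichment, fd$schedule,
                                 .lab = fd$lab),
                  error = function(e) NULL)
  if (is.null(out)) return(list(J = 1e10))
  is_ <- match(fd$silk_times, out$times)
  ic_ <- match(fd$conc_times, out$times)
  pred_frac <- out$labeled_fraction[is_]
  pred_conc_unit <- out$lumbar_concentration[ic_]   # at R_APP = 1
  ssr_silk <- sum((pred_frac - fd$silk_obs)^2)
  # profile the amplitude (SF_40 fixed at its gauge; R_APP carries the scale)
  denom <- sum(pred_conc_unit^2)
  r_app <- if (denom > 0) max(sum(fd$conc_obs * pred_conc_unit) / denom, 1e-9)
           else 1e-9
  ssr_conc <- sum((r_app * pred_conc_unit - fd$conc_obs)^2)
  # each block enters the objective dimensionless (scaled by its mean
  # observation) so labeled fractions and pg/mL concentrations weigh equally
  scale_s <- mean(fd$silk_obs)^2
  scale_c <- mean(fd$conc_obs)^2
  pen_w <- grid$penalty_weight_factor * mean(fd$silk_obs^2)
  excess <- max(0, out$isf_lumbar_ratio - grid$penalty_ratio_cap)
  penalty <- pen_w * excess^2
  nu_s <- length(fd$silk_obs); nu_c <- max(length(fd$conc_obs), 1L)
  list(J = ssr_silk / scale_s / nu_s + ssr_conc / scale_c / nu_c +
         penalty / scale_s,
       ssr_silk = ssr_silk, ssr_conc = ssr_conc, penalty = penalty,
       R_APP = r_app, k_BPD40 = k_BPD40, Q_CSF = Q_CSF, Q_osc = Q_osc,
       isf_lumbar_ratio = out$isf_lumbar_ratio)
}

#' Fit the adjustable parameters for one grid combination
#'
#' Minimizes `ssr_silk/nu_s + ssr_conc/nu_c + penalty` over
#' (`k_BPD40` logit-constrained to its regime, `log Q_CSF`, `log Q_osc`)
#' with a Nelder-Mead simplex; the production rate is profiled analytically
#' from the concentration amplitude at each evaluation, and the penalty is
#' `penalty_weight * max(0, isf_lumbar_ratio - cap)^2`.
#'
#' @param fd A `fit_data` from [prepare_fit_data()].
#' @param grid_point List with `f_VCSF`, `V_SP`, `Q_leak`, `k_range`
#'   (length-2 numeric), `k_range_index`.
#' @param grid A [grid_config()].
#' @param start Optional named start values (`Q_CSF`, `Q_osc`); `k_BPD40`
#'   starts at the lower and upper quartiles of its regime (the flat
#'   clearance-flow trade-off leaves noise-induced local minima at both ends
#'   of a regime, so a single midpoint start anchors the estimate).
#' @param sf_40 Measurement scaling factor; fixed gauge 1 unless a known
#'   calibration factor is supplied (it is not separable from the production
#'   rate within a single study).
#' @return One-row data frame (a fit record).
#' @export
fit_one_combo <- function(fd, grid_point, grid = grid_config(),
                          start = NULL, sf_40 = 1) {
  nom <- fd$config$nominal
  q_csf0 <- start$Q_CSF %||% nom$Q_CSF
  q_osc0 <- start$Q_osc %||% nom$Q_osc
  obj <- function(th) eval_objective(th, fd, grid_point, grid, sf_40)$J
  opt <- NULL; n_eval <- 0L
  for (z0 in stats::qlogis(c(0.25, 0.75))) {   # regime quartile starts
    o <- stats::optim(c(z0, log(q_csf0), log(q_osc0)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = grid$max_iter,
                                     reltol = grid$rel_tol))
    n_eval <- n_eval + unname(o$counts["function"])
    if (is.null(opt) || o$value < opt$value) opt <- o
  }
  opt$counts["function"] <- n_eval
  ev <- eval_objective(opt$par, fd, grid_point, grid, sf_40)
  data.frame(
    f_VCSF = grid_point$f_VCSF, V_SP = grid_point$V_SP,
    Q_leak = grid_point$Q_leak,
    k_range_index = grid_point$k_range_index,
    k_range_lo = grid_point$k_range[1], k_range_hi = grid_point$k_range[2],
    k_BPD40 = ev$k_BPD40, SF_40 = sf_40, Q_CSF = ev$Q_CSF, Q_osc = ev$Q_osc,
    R_APP = ev$R_APP, ssr_silk = ev$ssr_silk, ssr_conc = ev$ssr_conc,
    penalty = ev$penalty, isf_lumbar_ratio = ev$isf_lumbar_ratio,
    objective = ev$J, converged = opt$convergence == 0,
    n_iter = unname(opt$counts["function"]))
}

#' Run the full optimization grid for one subject
#'
#' One constrained optimization per grid combination, in lexicographic order
#' over (f_VCSF, V_SP, Q_leak, k_BPD40 regime); the default grid gives 128
#' records.
#'
#' @inheritParams fit_one_combo
#' @return Data frame of fit records, class `fit_records`.
#' @export
fit_subject_grid <- function(fd, grid = grid_config(), sf_40 = 1) {
  stopifnot(inherits(fd, "fit_data"))
  recs <- list()
  i <- 0L
  for (fv in sort(grid$f_VCSF_values)) {
    for (vs in sort(grid$V_SP_values)) {
      for (ql in sort(grid$Q_leak_values)) {
        for (kr in seq_along(grid$k_BPD40_ranges)) {
          i <- i + 1L
          gp <- list(f_VCSF = fv, V_SP = vs, Q_leak = ql,
                     k_range = grid$k_BPD40_ranges[[kr]], k_range_index = kr)
          recs[[i]] <- fit_one_combo(fd, gp, grid, sf_40 = sf_40)
        }
      }
    }
  }
  out <- do.call(rbind, recs)
  out$subject_id <- fd$subject_id
  class(out) <- c("fit_records", "data.frame")
  out
}

#' Band-filter and average the grid fits
#'
#' Keeps converged records whose SILK and concentration sums of squares both
#' lie within the acceptance band (default 20%) of the respective best
#' values, and averages their production-rate estimates.  If no record
#' satisfies both bands, the record with the smallest total objective is
#' used and flagged.
#'
#' @param records `fit_records` from [fit_subject_grid()].
#' @param grid A [grid_config()].
#' @return List of class `subject_fit_summary`: `subject_id`, `R_APP`
#'   (averaged), `n_kept`, `best_ssr_silk`, `best_ssr_conc`, `kept`
#'   (logical per record), `fallback`.
#' @export
select_and_average <- function(records, grid = grid_config()) {
  conv <- records[records$converged, , drop = FALSE]
  if (nrow(conv) == 0) {
    abort_silkfit("no converged fit record", "silkfit_validation_error")
  }
  band <- 1 + grid$acceptance_band
  bs <- min(conv$ssr_silk); bc <- min(conv$ssr_conc)
  keep <- records$converged & records$ssr_silk <= band * bs &
    records$ssr_conc <= band * bc
  fallback <- FALSE
  if (!any(keep)) {
    fallback <- TRUE
    keep <- seq_len(nrow(records)) == which.min(records$objective)
  }
  structure(list(
    subject_id = records$subject_id[1] %||% NA_character_,
    R_APP = mean(records$R_APP[keep]),
    n_kept = sum(keep), best_ssr_silk = bs, best_ssr_conc = bc,
    kept = keep, fallback = fallback), class = "subject_fit_summary")
}

#' Fit one subject end to end
#'
#' Convenience wrapper: [prepare_fit_data()], [fit_subject_grid()],
#' [select_and_average()].
#'
#' @inheritParams prepare_fit_data
#' @inheritParams fit_one_combo
#' @return List with `records` and `summary`.
#' @export
fit_subject <- function(silk, conc, grid = grid_config(),
                        enrichment = default_enrichment(),
                        schedule = default_schedule(), age = 70,
                        config = silk_config(), sf_40 = 1) {
  fd <- prepare_fit_data(silk, conc, grid, enrichment, schedule, age, config)
  records <- fit_subject_grid(fd, grid, sf_40 = sf_40)
  list(records = records, summary = select_and_average(records, grid))
}
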
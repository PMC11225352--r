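# End-to-end orchestration: baseline table, FSR + ANOVA, NCA summaries,
# biomarker-change ANCOVA, grid fits and dose-response, with CSV outputs and
# a JSON manifest.

#' Baseline characteristics table with group statistics
#'
#' Placebo versus pooled active: continuous rows by pooled-variance t from
#' the group summaries, binary rows by Pearson chi-squared (uncorrected) and
#' Fisher exact (both reported, as neither uniformly reproduces small-sample
#' practice).
#'
#' @param subjects A `subject_table` (see [read_long_table()]).
#' @return Data frame with one row per characteristic.
#' @export
make_table1 <- function(subjects) {
  grp <- ifelse(subjects$arm == "placebo", "placebo", "active")
  if (length(unique(grp)) < 2) {
    abort_silkfit("table 1 needs both placebo and active subjects",
                  "silkfit_validation_error")
  }
  pl <- subjects[grp == "placebo", ]; ac <- subjects[grp == "active", ]
  cont_row <- function(name, x_pl, x_ac) {
    tt <- pooled_t_from_summary(mean(x_pl), stats::sd(x_pl), length(x_pl),
                                mean(x_ac), stats::sd(x_ac), length(x_ac))
    data.frame(characteristic = name, type = "continuous",
               placebo = sprintf("%.1f ± %.1f", mean(x_pl), stats::sd(x_pl)),
               active = sprintf("%.1f ± %.1f", mean(x_ac), stats::sd(x_ac)),
               p_chi2 = NA_real_, p_fisher = NA_real_, p_t = tt$p)
  }
  bin_row <- function(name, b_pl, b_ac) {
    tab <- matrix(c(sum(b_pl), sum(!b_pl), sum(b_ac), sum(!b_ac)), 2, 2,
                  byrow = TRUE)
    chi <- tryCatch(pearson_chi2_2x2(tab)$p, error = function(e) NA_real_)
    data.frame(characteristic = name, type = "binary",
               placebo = sprintf("%d (%.0f%%)", sum(b_pl),
                                 100 * mean(b_pl)),
               active = sprintf("%d (%.0f%%)", sum(b_ac), 100 * mean(b_ac)),
               p_chi2 = chi, p_fisher = fisher_exact_2x2(tab), p_t = NA_real_)
  }
  rbind(cont_row("age", pl$age, ac$age),
        bin_row("sex_female", pl$sex == "female", ac$sex == "female"),
        cont_row("education", pl$education, ac$education),
        cont_row("mmse", pl$mmse_baseline, ac$mmse_baseline),
        bin_row("achei", pl$on_achei, ac$on_achei),
        bin_row("memantine", pl$on_memantine, ac$on_memantine),
        bin_row("antidepressant", pl$on_antidepressant, ac$on_antidepressant))
}

#' FSR table for a study
#'
#' Fixed-window (hours 6-16) and automated-window FSR for every
#' subject x isoform, normalized by each subject's plasma leucine plateau.
#'
#' @param study A `synthetic_study` (or list with `silk`, `conc`, `subjects`).
#' @return Data frame: `subject_id`, `isoform`, `arm`, `fsr_fixed`,
#'   `fsr_auto`, `r_squared`, `plateau`.
#' @export
compute_fsr_table <- function(study) {
  series <- split_silk_series(study$silk)
  leu <- split_concentration_series(
    study$conc[study$conc$analyte == "leucine_enrichment", ])
  arm_of <- stats::setNames(study$subjects$arm, study$subjects$subject_id)
  rows <- lapply(series, function(s) {
    lkey <- paste(s$subject_id, "leucine_enrichment", "plasma", sep = "/")
    plateau <- plateau_enrichment(leu[[lkey]])
    fx <- tryCatch(fsr_fixed_window(s, plateau), error = function(e) NULL)
    fa <- tryCatch(fsr_auto_window(s, plateau), error = function(e) NULL)
    if (is.null(fx)) return(NULL)
    data.frame(subject_id = s$subject_id, isoform = s$isoform,
               arm = unname(arm_of[s$subject_id]), fsr_fixed = fx$fsr,
               fsr_auto = if (is.null(fa)) NA_real_ else fa$fsr,
               r_squared = fx$r_squared, plateau = plateau)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(out) <- NULL
  out
}

#' Noncompartmental PK tables for a study
#'
#' Per-subject NCA for the drug analytes in plasma and CSF (placebo
#' subjects, having no measurable drug, are skipped), geometric summaries
#' per arm x analyte x matrix, and plasma-CSF Spearman correlations of AUC.
#'
#' @param study A `synthetic_study`.
#' @param config Configuration list (dose under `drug_pk`).
#' @return List with `nca` (per subject), `summary` (per arm), `spearman`.
#' @export
compute_nca_tables <- function(study, config = silk_config()) {
  drugs <- c("Posiphen", "N1", "N8")
  cs <- split_concentration_series(
    study$conc[study$conc$analyte %in% drugs, ])
  arm_of <- stats::setNames(study$subjects$arm, study$subjects$subject_id)
  rows <- lapply(cs, function(s) {
    if (arm_of[s$subject_id] == "placebo") return(NULL)
    if (all(s$values[!s$missing_mask] == 0)) return(NULL)
    s <- window_series(s, 0, 24)        # PK conventions on the dosing day
    res <- tryCatch(nca_analyze(s, dose_mg = config$drug_pk$dose_mg),
                    error = function(e) NULL)
    if (!is.null(res)) res$arm <- unname(arm_of[s$subject_id])
    res
  })
  nca <- do.call(rbind, Filter(Negate(is.null), rows))
  rownames(nca) <- NULL
  summ <- NULL
  if (!is.null(nca) && nrow(nca)) {
    grp <- split(nca, list(nca$arm, nca$analyte, nca$matrix), drop = TRUE)
    summ <- do.call(rbind, lapply(grp, function(d) {
      pos <- d$auc_0_24 > 0 & d$cmax > 0
      if (!any(pos)) return(NULL)
      ga <- geo_summary(d$auc_0_24[pos]); gc <- geo_summary(d$cmax[pos])
      tm <- tmax_summary(d$tmax[pos])
      data.frame(arm = d$arm[1], analyte = d$analyte[1], matrix = d$matrix[1],
                 n = sum(pos), auc_geo_mean = ga$geo_mean,
                 auc_pct_gcv = ga$pct_gcv, cmax_geo_mean = gc$geo_mean,
                 cmax_pct_gcv = gc$pct_gcv, tmax_median = tm$median,
                 tmax_min = tm$min, tmax_max = tm$max)
    }))
    rownames(summ) <- NULL
  }
  sp <- NULL
  if (!is.null(nca) && nrow(nca)) {
    wide <- merge(
      stats::setNames(nca[nca$matrix == "plasma",
                          c("subject_id", "analyte", "auc_0_24")],
                      c("subject_id", "analyte", "auc_plasma")),
      stats::setNames(nca[nca$matrix == "CSF",
                          c("subject_id", "analyte", "auc_0_24")],
                      c("subject_id", "analyte", "auc_csf")))
    sp <- tryCatch(plasma_csf_correlation(wide), error = function(e) NULL)
    if (!is.null(sp)) rownames(sp) <- NULL
  }
  list(nca = nca, summary = summ, spearman = sp)
}

#' Biomarker-change ANCOVA table
#'
#' Change (confinement minus screening) per analyte, treatment (pooled
#' active vs placebo) adjusted for age and sex.
#'
#' @param study A `synthetic_study`.
#' @param include_mmse Also adjust for baseline MMSE.
#' @return Data frame: analyte, LS mean changes, difference, SE, t, df, p.
#' @export
compute_biomarker_changes <- function(study, include_mmse = FALSE) {
  bm <- merge(study$biomarkers, study$subjects[
    , c("subject_id", "arm", "age", "sex", "mmse_baseline")])
  bm$change <- bm$confinement - bm$screening
  bm$treatment <- factor(ifelse(bm$arm == "placebo", "placebo", "posiphen"),
                         levels = c("placebo", "posiphen"))
  out <- do.call(rbind, lapply(split(bm, bm$analyte), function(d) {
    res <- ancova_change(d, include_mmse = include_mmse)
    data.frame(analyte = d$analyte[1],
               ls_mean_placebo = res$ls_means[["placebo"]],
               ls_mean_posiphen = res$ls_means[["posiphen"]],
               difference = res$difference, se = res$se, t = res$t,
               df = res$df, p = res$p)
  }))
  rownames(out) <- NULL
  out
}

#' Grid-fit production estimates for a study
#'
#' Runs the grid procedure on each requested subject's Ab40 SILK and lumbar
#' concentration series.
#'
#' @param study A `synthetic_study`.
#' @param grid A [grid_config()]; the reduced `"test"` preset is the
#'   practical choice for whole-study refits.
#' @param subject_ids Subjects to fit (default all).
#' @param config Configuration list.
#' @return List with `summaries` (data frame) and `records` (list).
#' @export
compute_grid_fits <- function(study, grid = grid_config("test"),
                              subject_ids = NULL, config = silk_config()) {
  silk <- split_silk_series(study$silk)
  conc <- split_concentration_series(
    study$conc[study$conc$analyte == "Ab40" & study$conc$matrix == "CSF", ])
  ids <- subject_ids %||% study$subjects$subject_id
  age_of <- stats::setNames(study$subjects$age, study$subjects$subject_id)
  records <- list(); rows <- list()
  for (id in ids) {
    s <- silk[[paste(id, "Ab40", sep = "/")]]
    k <- conc[[paste(id, "Ab40", "CSF", sep = "/")]]
    enr <- study$enrichments[[id]] %||% default_enrichment(config)
    res <- tryCatch(
      fit_subject(s, k, grid, enrichment = enr, age = unname(age_of[id]),
                  config = config),
      error = function(e) NULL)
    if (is.null(res)) next
    records[[id]] <- res$records
    rows[[id]] <- data.frame(subject_id = id, r_app = res$summary$R_APP,
                             n_kept = res$summary$n_kept,
                             best_ssr_silk = res$summary$best_ssr_silk,
                             best_ssr_conc = res$summary$best_ssr_conc,
                             fallback = res$summary$fallback)
  }
  summaries <- do.call(rbind, rows)
  rownames(summaries) <- NULL
  list(summaries = summaries, records = records)
}

#' Run the full pipeline and write a report bundle
#'
#' Generates (or takes) a study, computes the baseline table, FSR table with
#' ANOVA, NCA tables, biomarker-change ANCOVA, grid-fit summaries and the
#' dose-response model, writes all tables as CSV plus a JSON manifest with
#' content hashes, and returns the results invisibly.
#'
#' @param output_dir Output directory (created if needed).
#' @param study A `synthetic_study`; if NULL one is generated from `seed`.
#' @param seed Seed for study generation.
#' @param grid_preset `"test"` (default, 8 combinations) or `"default"`
#'   (128 combinations).
#' @param fit_subjects Subjects to grid-fit (default all); `character(0)`
#'   skips the fitting stage.
#' @param config Configuration list.
#' @return Invisibly, a list with every computed table and the manifest.
#' @export
run_end_to_end <- function(output_dir, study = NULL, seed = 1L,
                           grid_preset = "test", fit_subjects = NULL,
                           config = silk_config()) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  study <- study %||% generate_cohort(config, seed)

  table1 <- make_table1(study$subjects)
  fsr <- compute_fsr_table(study)
  fsr40 <- fsr[fsr$isoform == "Ab40" & !is.na(fsr$fsr_fixed), ]
  fsr_anova <- compare_fsr_groups(
    data.frame(fsr = fsr40$fsr_fixed, arm = fsr40$arm))
  nca <- compute_nca_tables(study, config)
  biomarkers <- compute_biomarker_changes(study)

  fits <- NULL; dose_response <- NULL
  ids <- fit_subjects %||% study$subjects$subject_id
  if (length(ids)) {
    fits <- compute_grid_fits(study, grid_config(grid_preset, config), ids,
                              config)
    scr40 <- study$biomarkers[study$biomarkers$analyte == "Ab40",
                              c("subject_id", "screening")]
    dd <- merge(merge(fits$summaries, scr40),
                study$subjects[, c("subject_id", "arm")])
    n_arms <- length(unique(dd$arm))
    if (n_arms >= 2 && nrow(dd) > n_arms + 1) {
      dose_response <- dose_response_ancova(
        data.frame(r_app = dd$r_app, arm = dd$arm,
                   baseline_ab40 = dd$screening))
    }
  }

  write_long_table(study$subjects, file.path(output_dir, "subjects.csv"),
                   "subjects")
  write_long_table(study$silk, file.path(output_dir, "silk.csv"), "silk")
  write_long_table(study$conc, file.path(output_dir, "concentrations.csv"),
                   "concentration")
  out_csv <- function(df, name) {
    if (is.null(df)) return(invisible(NULL))
    utils::write.csv(df, file.path(output_dir, name), row.names = FALSE)
  }
  out_csv(table1, "table1.csv")
  out_csv(fsr, "fsr.csv")
  out_csv(nca$nca, "nca_subject.csv")
  out_csv(nca$summary, "nca_summary.csv")
  out_csv(nca$spearman, "nca_spearman.csv")
  out_csv(biomarkers, "biomarker_changes.csv")
  out_csv(study$truth, "truth.csv")
  if (!is.null(fits)) {
    out_csv(fits$summaries, "grid_fit_summaries.csv")
    out_csv(do.call(rbind, fits$records), "grid_fit_records.csv")
    out_csv(dose_response, "dose_response.csv")
  }
  jsonlite::write_json(
    list(fsr_anova = fsr_anova[c("F", "df1", "df2", "p")],
         seed = study$log$seed, n_randomized = study$log$n_randomized),
    file.path(output_dir, "stats.json"), auto_unbox = TRUE, digits = NA)

  files <- sort(list.files(output_dir, full.names = FALSE))
  files <- setdiff(files, "manifest.json")
  manifest <- list(files = as.list(stats::setNames(
    unname(tools::md5sum(file.path(output_dir, files))), files)),
    seed = study$log$seed)
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(study = study, table1 = table1, fsr = fsr,
                 fsr_anova = fsr_anova, nca = nca, biomarkers = biomarkers,
                 fits = fits, dose_response = dose_response,
                 manifest = manifest))
}
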
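# Synthetic study generator: subjects, stratified permuted-block
# randomization, leucine enrichment, model-driven SILK and concentration
# series, steady-state drug PK, biomarker changes and draw-level missingness.
#
# The generator's defaults are the study conditions (19 x 2-h draws of 6 mL
# over 36 h, 9-h primed infusion, sequential dose cohorts of 8 randomized
# 5:3, amyloid-positive eligibility, ~18% missing CSF draws) so every
# pipeline stage runs without subject-level data; a truth table is retained
# for recovery experiments.

BIOMARKER_REF <- c(Ab38 = 2000, Ab42 = 350, sAPPa = 120000, sAPPb = 150000,
                   tTau = 60000)   # reference CSF levels, pg/mL

# mean-one multiplicative lognormal noise
ln_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdl <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdl^2 / 2, sdlog = sdl)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

#' Site-stratified permuted-block randomization
#'
#' Within each site stratum, subjects are assigned in permuted blocks that
#' realize the active:placebo allocation (default 5:3 in blocks of 8)
#' exactly per completed block.
#'
#' @param subjects Data frame with `subject_id` and `site_id`.
#' @param active_label Arm label for active assignments.
#' @param config Configuration list (allocation and block size under
#'   `cohort`).
#' @param seed Optional integer seed (restores the RNG state afterwards is
#'   not attempted; call inside your own seeded context or pass `seed`).
#' @return The subjects data frame with an `arm` column (active label or
#'   `"placebo"`), in the input row order.
#' @export
randomize_blocks <- function(subjects, active_label = "QD60",
                             config = silk_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cc <- config$cohort
  if (cc$block_size %% (cc$allocation_active + cc$allocation_placebo) != 0) {
    abort_silkfit("block size must be divisible by the allocation ratio sum",
                  "silkfit_validation_error")
  }
  reps <- cc$block_size / (cc$allocation_active + cc$allocation_placebo)
  arm <- character(nrow(subjects))
  for (site in unique(subjects$site_id)) {
    idx <- which(subjects$site_id == site)
    if (!length(idx)) next
    n_blocks <- ceiling(length(idx) / cc$block_size)
    seq_arm <- unlist(lapply(seq_len(n_blocks), function(b) {
      sample(rep(c(rep(active_label, cc$allocation_active),
                   rep("placebo", cc$allocation_placebo)), reps))
    }))
    arm[idx] <- seq_arm[seq_along(idx)]
  }
  subjects$arm <- arm
  subjects
}

#' Simulate a subject's plasma leucine enrichment curve
#'
#' A primed (bolus + constant-rate) infusion per the protocol (3 mg/kg
#' bolus then 2 mg/kg/h for the remainder of 9 h) yields a near-immediate
#' plateau; the per-kg dosing makes the plateau largely weight-independent,
#' so weight enters only through a mild subject-level wobble of the plateau.
#'
#' @param weight_kg Subject weight (> 0).
#' @param config Configuration list (infusion spec under `infusion`).
#' @param seed Optional integer seed.
#' @return An [enrichment_infusion()] curve.
#' @export
simulate_leucine_enrichment <- function(weight_kg, config = silk_config(),
                                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot_scalar_number(weight_kg, "weight_kg", lower = 1e-9)
  inf <- config$infusion
  e_ss <- min(inf$e_ss * ln_noise(1, 0.05), 0.99)
  enrichment_infusion(e_ss = e_ss, k_rise = inf$k_rise,
                      k_decay = inf$k_decay, t_infusion = inf$duration_h)
}

# steady-state multiple-dose one-compartment oral profile, ng/mL
drug_profile <- function(t, dose_mg, ka, ke, cl_f, interval_h) {
  v_l <- cl_f / ke                       # V/F in L
  coef <- dose_mg * 1e6 * ka / (v_l * 1e3 * (ka - ke))   # ng/mL
  tau <- t %% interval_h
  coef * (exp(-ke * tau) / (1 - exp(-ke * interval_h)) -
            exp(-ka * tau) / (1 - exp(-ka * interval_h)))
}

arm_interval <- function(arm) {
  switch(arm, QD60 = 24, BID120 = 12, TID180 = 8, NA_real_)
}

#' Simulate all series for one subject
#'
#' Runs the compartment model at the subject's true production rate reduced
#' by the arm's dose effect, adds multiplicative lognormal noise, applies
#' draw-level missingness to the CSF samples, and generates steady-state
#' drug PK profiles (QD / BID q12h / TID q8h) with parent-to-metabolite
#' scaling.
#'
#' @param subject One-row data frame of subject metadata (needs
#'   `subject_id`, `age`, `weight_kg`, `arm`).
#' @param truth Named list of true parameters (`R_APP` base, `k_BPD40`,
#'   `Q_CSF`, `Q_osc`).
#' @param config Configuration list.
#' @param seed Integer seed for this subject's noise streams.
#' @return List with `silk` (data frame rows), `conc` (data frame rows),
#'   `biomarkers` (screening/confinement values), `enrichment` (curve),
#'   `truth` (updated with the applied dose effect), `start_clock_min`.
#' @export
simulate_subject <- function(subject, truth, config = silk_config(),
                             seed = 1L) {
  set.seed(seed)
  cc <- config$cohort
  arm <- subject$arm
  effect <- cc$dose_effect[[arm]] %||% 0
  r_app_true <- truth$R_APP * (1 - effect)

  enr <- simulate_leucine_enrichment(subject$weight_kg, config)
  sch <- default_schedule(config)
  params <- kinetic_parameters(
    R_APP = r_app_true, k_BPD40 = truth$k_BPD40, Q_CSF = truth$Q_CSF,
    Q_osc = truth$Q_osc, Q_leak = cc$true_Q_leak, f_VCSF = cc$true_f_VCSF,
    V_SP = cc$true_V_SP, age = subject$age, config = config)
  out <- simulate_model(params, enr, sch)
  nt <- length(sch$times)

  start_clock <- round(stats::runif(1, cc$start_clock_min[[1]],
                                    cc$start_clock_min[[2]]))
  clock <- (start_clock + 60 * sch$times) %% 1440
  miss_draw <- stats::runif(nt) < cc$missingness

  noisy_frac <- function(f, cv) pmin(pmax(f * ln_noise(nt, cv), 0), 1)
  frac40 <- noisy_frac(out$labeled_fraction, cc$silk_noise_cv)
  frac38 <- noisy_frac(out$labeled_fraction * ln_noise(1, 0.03),
                       cc$silk_noise_cv)
  # Ab42 kinetics are plaque-modified in vivo; emulate as an attenuated,
  # distorted copy so its FSR decouples from Ab40
  warp <- stats::runif(1, 0.6, 1.1)
  frac42 <- noisy_frac(out$labeled_fraction * warp, 3 * cc$silk_noise_cv)

  silk_rows <- do.call(rbind, Map(function(iso, fr) {
    data.frame(subject_id = subject$subject_id, isoform = iso,
               time_h = sch$times,
               labeled_fraction = ifelse(miss_draw, NA_real_, fr),
               missing = miss_draw)
  }, c("Ab38", "Ab40", "Ab42"), list(frac38, frac40, frac42)))

  conc40 <- out$lumbar_concentration * ln_noise(nt, cc$conc_noise_cv)
  conc_rows <- data.frame(
    subject_id = subject$subject_id, analyte = "Ab40", matrix = "CSF",
    time_h = sch$times, value = ifelse(miss_draw, NA_real_, conc40),
    clock_min = clock, missing = miss_draw)
  leu <- eval_enrichment(enr, sch$times)
  conc_rows <- rbind(conc_rows, data.frame(
    subject_id = subject$subject_id, analyte = "leucine_enrichment",
    matrix = "plasma", time_h = sch$times,
    value = pmin(leu * ln_noise(nt, 0.02), 1), clock_min = clock,
    missing = FALSE))

  pk <- config$drug_pk
  interval <- arm_interval(arm)
  for (an in c("Posiphen", "N1", "N8")) {
    pp <- pk[[an]]
    plasma <- if (arm == "placebo") rep(0, nt) else {
      pmax(drug_profile(sch$times, pk$dose_mg, pp$ka, pp$ke, pp$cl_f,
                        interval) * ln_noise(nt, 0.15), 0)
    }
    csf <- plasma * pp$csf_ratio * ln_noise(nt, 0.15)
    plasma[plasma < pk$lloq_ng_ml] <- 0
    csf[csf < pk$lloq_ng_ml] <- 0
    conc_rows <- rbind(
      conc_rows,
      data.frame(subject_id = subject$subject_id, analyte = an,
                 matrix = "plasma", time_h = sch$times, value = plasma,
                 clock_min = clock, missing = FALSE),
      data.frame(subject_id = subject$subject_id, analyte = an,
                 matrix = "CSF", time_h = sch$times,
                 value = ifelse(miss_draw, NA_real_, csf),
                 clock_min = clock, missing = miss_draw))
  }

  # screening (pre-drug) vs confinement (on-drug) CSF biomarkers; APP
  # metabolite concentrations track production in this model, other
  # analytes carry noise only
  ss_pre <- steady_state(kinetic_parameters(
    R_APP = truth$R_APP, k_BPD40 = truth$k_BPD40, Q_CSF = truth$Q_CSF,
    Q_osc = truth$Q_osc, Q_leak = cc$true_Q_leak, f_VCSF = cc$true_f_VCSF,
    V_SP = cc$true_V_SP, age = subject$age, config = config))
  ab40_pre <- unname(ss_pre["SP"]) * config$model$mw_ab40_ng_per_nmol * 1e3
  bm <- data.frame(
    subject_id = subject$subject_id,
    analyte = c("Ab38", "Ab40", "Ab42", "sAPPa", "sAPPb", "tTau"),
    screening = NA_real_, confinement = NA_real_)
  base_lvl <- c(BIOMARKER_REF["Ab38"], ab40_pre, BIOMARKER_REF["Ab42"],
                BIOMARKER_REF[c("sAPPa", "sAPPb", "tTau")])
  drug_scale <- c(1 - effect, 1 - effect, 1 - effect, 1, 1, 1)
  bm$screening <- base_lvl * ln_noise(6, cc$screening_noise_cv)
  bm$confinement <- base_lvl * drug_scale * ln_noise(6, cc$biomarker_noise_cv)

  truth$arm <- arm; truth$dose_effect <- effect
  truth$R_APP_true <- r_app_true
  list(silk = silk_rows, conc = conc_rows, biomarkers = bm,
       enrichment = enr, truth = truth, start_clock_min = start_clock)
}

#' Generate a full synthetic study
#'
#' Draws eligible subjects (amyloid-positive CSF ratio below the cutoff;
#' failures are recorded and excluded before randomization), randomizes
#' sequential dose cohorts 5:3 within site strata, and simulates every
#' series.  Fully reproducible from `seed`.
#'
#' @param config Configuration list, see [silk_config()].
#' @param seed Integer seed.
#' @return Object of class `synthetic_study`: `subjects`, `silk`, `conc`
#'   (classed tables), `biomarkers`, `truth`, `enrichments` (per subject),
#'   `excluded`, `log`.
#' @export
generate_cohort <- function(config = silk_config(), seed = 1L) {
  set.seed(seed)
  cc <- config$cohort
  arms <- unlist(cc$arms)
  n_total <- cc$n_per_cohort * length(arms)

  draw_subject <- function(i) {
    data.frame(
      subject_id = sprintf("S%03d", i),
      site_id = sample(unlist(cc$sites), 1),
      age = round(rtrunc_norm(1, 72, 8, 55, 89)),
      sex = sample(c("female", "male"), 1),
      education = round(rtrunc_norm(1, 15, 3, 8, 22)),
      mmse_baseline = round(rtrunc_norm(1, 24, 3, 17, 30)),
      arm = NA_character_,
      on_achei = stats::runif(1) < 0.5,
      on_memantine = stats::runif(1) < 0.25,
      on_antidepressant = stats::runif(1) < 0.5,
      csf_ab42_40 = rtrunc_norm(1, cc$ab42_40_mean, cc$ab42_40_sd, 0.01, 0.3),
      weight_kg = round(rtrunc_norm(1, 75, 12, 45, 110), 1))
  }

  enrolled <- list(); excluded <- list(); i <- 0
  while (length(enrolled) < n_total) {
    i <- i + 1
    s <- draw_subject(i)
    if (s$csf_ab42_40 < cc$eligibility_ratio) {
      enrolled[[length(enrolled) + 1]] <- s
    } else {
      excluded[[length(excluded) + 1]] <- s
    }
  }
  subjects <- do.call(rbind, enrolled)

  # sequential dose cohorts of n_per_cohort, each randomized 5:3 by site
  assigned <- list()
  for (k in seq_along(arms)) {
    idx <- ((k - 1) * cc$n_per_cohort + 1):(k * cc$n_per_cohort)
    assigned[[k]] <- randomize_blocks(subjects[idx, ], active_label = arms[k],
                                      config = config)
  }
  subjects <- do.call(rbind, assigned)

  bundles <- vector("list", nrow(subjects))
  for (j in seq_len(nrow(subjects))) {
    truth <- list(
      subject_id = subjects$subject_id[j],
      R_APP = cc$r_app_median * ln_noise(1, cc$r_app_cv),
      k_BPD40 = min(max(0.1 * ln_noise(1, 0.15), 0.06), 0.19),
      Q_CSF = config$nominal$Q_CSF * ln_noise(1, 0.15),
      Q_osc = config$nominal$Q_osc * ln_noise(1, 0.20))
    bundles[[j]] <- simulate_subject(subjects[j, ], truth, config,
                                     seed = seed + 7919L * j)
  }
  silk <- validate_long_table(do.call(rbind, lapply(bundles, `[[`, "silk")),
                              "silk")
  conc <- validate_long_table(do.call(rbind, lapply(bundles, `[[`, "conc")),
                              "concentration")
  truth <- do.call(rbind, lapply(bundles, function(b) {
    as.data.frame(b$truth[c("subject_id", "arm", "R_APP", "R_APP_true",
                            "dose_effect", "k_BPD40", "Q_CSF", "Q_osc")])
  }))
  biomarkers <- do.call(rbind, lapply(bundles, `[[`, "biomarkers"))
  rownames(subjects) <- rownames(truth) <- rownames(biomarkers) <- NULL
  enrichments <- stats::setNames(lapply(bundles, `[[`, "enrichment"),
                                 subjects$subject_id)
  structure(list(
    subjects = validate_long_table(subjects, "subjects"),
    silk = silk, conc = conc, biomarkers = biomarkers, truth = truth,
    enrichments = enrichments,
    excluded = if (length(excluded)) do.call(rbind, excluded) else NULL,
    log = list(seed = seed, n_randomized = nrow(subjects),
               n_excluded = length(excluded),
               arms = table(subjects$arm))), class = "synthetic_study")
}
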
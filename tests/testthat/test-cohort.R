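test_that("permuted blocks realize the 5:3 allocation exactly", {
  subj <- data.frame(subject_id = sprintf("S%02d", 1:8), site_id = "site01")
  a <- randomize_blocks(subj, "QD60", seed = 1)
  expect_equal(sum(a$arm == "QD60"), 5)
  expect_equal(sum(a$arm == "placebo"), 3)
  subj16 <- data.frame(subject_id = sprintf("S%02d", 1:16), site_id = "site01")
  a16 <- randomize_blocks(subj16, "QD60", seed = 2)
  expect_equal(sum(a16$arm == "QD60"), 10)
  expect_equal(sum(a16$arm == "placebo"), 6)
  # per completed block, not just overall
  expect_equal(sum(a16$arm[1:8] == "QD60"), 5)
  # determinism under a fixed seed
  expect_identical(randomize_blocks(subj16, "QD60", seed = 9)$arm,
                   randomize_blocks(subj16, "QD60", seed = 9)$arm)
})

test_that("a subject simulated without noise reproduces the model exactly", {
  cfg <- silk_config(list(cohort = list(silk_noise_cv = 0, conc_noise_cv = 0,
                                        missingness = 0)))
  subj <- data.frame(subject_id = "S001", age = 70, weight_kg = 75,
                     arm = "TID180")
  truth <- list(R_APP = 0.9, k_BPD40 = 0.1, Q_CSF = 20, Q_osc = 30)
  b <- simulate_subject(subj, truth, cfg, seed = 5)
  # dose effect 0.30 at TID: truth table carries the reduced rate
  expect_equal(b$truth$R_APP_true, 0.9 * 0.7, tolerance = 1e-12)
  params <- kinetic_parameters(R_APP = 0.63, k_BPD40 = 0.1, Q_CSF = 20,
                               Q_osc = 30, V_SP = cfg$cohort$true_V_SP,
                               age = 70, config = cfg)
  out <- simulate_model(params, b$enrichment, default_schedule(cfg))
  got40 <- b$silk[b$silk$isoform == "Ab40", ]
  expect_equal(got40$labeled_fraction, out$labeled_fraction, tolerance = 1e-12)
  conc40 <- b$conc[b$conc$analyte == "Ab40" & b$conc$matrix == "CSF", ]
  expect_equal(conc40$value, out$lumbar_concentration, tolerance = 1e-12)
  expect_false(any(got40$missing))
})

test_that("placebo subjects have no measurable drug", {
  st <- test_cohort()
  pl <- st$subjects$subject_id[st$subjects$arm == "placebo"]
  drug <- st$conc[st$conc$analyte %in% c("Posiphen", "N1", "N8") &
                    st$conc$subject_id %in% pl, ]
  expect_true(all(drug$value[!drug$missing] == 0))
})

test_that("active drug exposure lands near the intended plasma scale", {
  st <- test_cohort()
  qd <- st$subjects$subject_id[st$subjects$arm == "QD60"]
  pp <- st$conc[st$conc$analyte == "Posiphen" & st$conc$matrix == "plasma" &
                  st$conc$subject_id %in% qd & st$conc$time_h <= 24, ]
  mean24 <- mean(pp$value[!pp$missing])
  expect_gt(mean24, 7.16 / 2)
  expect_lt(mean24, 7.16 * 2)
})

test_that("the default study design is reproduced and reproducible", {
  st <- test_cohort()
  expect_equal(nrow(st$subjects), 24)                 # pre-planned cohorts
  expect_setequal(unique(st$subjects$arm),
                  c("placebo", "QD60", "BID120", "TID180"))
  expect_true(all(st$subjects$csf_ab42_40 < 0.131))   # amyloid-positive only
  if (!is.null(st$excluded)) {
    expect_true(all(st$excluded$csf_ab42_40 >= 0.131))
  }
  st2 <- generate_cohort(seed = 20260929L)
  expect_identical(st2$silk, st$silk)
  expect_identical(st2$conc, st$conc)
  expect_identical(st2$truth, st$truth)
  st3 <- generate_cohort(seed = 7L)
  expect_false(identical(st3$silk, st$silk))
})

test_that("every generated series passes table validation", {
  st <- test_cohort()
  expect_s3_class(validate_long_table(as.data.frame(st$silk), "silk"),
                  "silk_table")
  expect_s3_class(validate_long_table(as.data.frame(st$conc), "concentration"),
                  "concentration_table")
  expect_s3_class(validate_long_table(as.data.frame(st$subjects), "subjects"),
                  "subject_table")
  leu <- st$conc[st$conc$analyte == "leucine_enrichment", ]
  expect_true(all(leu$value >= 0 & leu$value <= 1))
})
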
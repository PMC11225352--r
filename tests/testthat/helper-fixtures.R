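# Shared fixtures, built in code.

# one noise-free simulated subject at known parameters (memoised)
noise_free_subject <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    p <- kinetic_parameters(R_APP = 0.8, k_BPD40 = 0.1, Q_CSF = 22,
                            Q_osc = 35, Q_leak = 0, f_VCSF = 1, V_SP = 60,
                            age = 70)
    enr <- default_enrichment()
    sch <- default_schedule()
    out <- simulate_model(p, enr, sch)
    silk <- silk_series("s1", "Ab40", out$times, out$labeled_fraction)
    conc <- concentration_series("s1", "Ab40", "CSF", out$times,
                                 out$lumbar_concentration,
                                 clock_times = (600 + 60 * out$times) %% 1440)
    cache <<- list(params = p, enrichment = enr, schedule = sch, out = out,
                   silk = silk, conc = conc)
    cache
  }
})

# one shared synthetic cohort (memoised; seed fixed)
test_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_cohort(seed = 20260929L)
    cache
  }
})

# random admissible kinetic parameter set
random_params <- function() {
  kinetic_parameters(
    R_APP = runif(1, 0.2, 2),
    k_BPD40 = runif(1, 0.05, 0.35),
    Q_CSF = runif(1, 5, 40),
    Q_osc = runif(1, 0.5, 200),
    Q_leak = runif(1, 0, 15),
    f_VCSF = runif(1, 0.5, 1.25),
    V_SP = runif(1, 40, 100),
    age = round(runif(1, 55, 89)))
}
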
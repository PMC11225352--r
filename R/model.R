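# Compartmental model of Abeta40 production, interstitial clearance and CSF
# transport with serial lumbar withdrawals.
#
# Compartments (concentrations, nmol/mL): ISF, ventricles (V), cisterna
# (CIS), cranial SAS (CR), spinal SAS (SP).  Abeta40 is produced into ISF at
# f_ab40 * R_APP (split labeled/unlabeled by the labeled production
# fraction), cleared from ISF at first order k_BPD40 (blood efflux plus
# proteolysis, lumped), exchanged ISF <-> ventricles by an equivalent flow
# k_t, advected ventricles -> cisterna -> {cranial, spinal} SAS by Q_CSF
# (split phi_CR / 1 - phi_CR, with the catheter leak Q_leak routed through
# the spinal path), mixed by a symmetric oscillatory exchange flow Q_osc on
# cisterna <-> cranial and cisterna <-> spinal, and absorbed from the cranial
# (phi_CR * Q_CSF - Q_leak) and spinal ((1 - phi_CR) * Q_CSF) SAS plus lost
# through the leak.  The fluid imbalance created by the leak is absorbed by
# reducing cranial absorption (volumes stay fixed).
#
# The state system is linear with piecewise exponential/linear forcing, so
# trajectories are propagated exactly segment by segment (eigendecomposition
# plus closed-form particular solutions) with stop-and-restart withdrawal
# events at the sampling times; no step-size or tolerance enters the result.

COMPARTMENTS <- c("ISF", "V", "CIS", "CR", "SP")

#' Age-based CSF compartment volumes
#'
#' Each volume is `f_VCSF * (a + b * age)` with coefficients from the shipped
#' configuration (total reference volume 150 mL at age 70).
#'
#' @param age Age in years, within 40-100.
#' @param f_VCSF CSF-volume error multiplier (> 0); the grid procedure varies
#'   it over 0.5-1.25.
#' @param config Configuration list, see [silk_config()].
#' @return Named vector with `V_V`, `V_CIS`, `V_CR` in mL.
#' @export
estimate_csf_volumes <- function(age, f_VCSF = 1, config = silk_config()) {
  stopifnot_scalar_number(age, "age", 40, 100)
  stopifnot_scalar_number(f_VCSF, "f_VCSF", lower = 1e-9)
  cc <- config$model$csf_volume_coefficients
  v <- f_VCSF * c(
    V_V = cc$ventricular$a + cc$ventricular$b * age,
    V_CIS = cc$cisternal$a + cc$cisternal$b * age,
    V_CR = cc$cranial$a + cc$cranial$b * age)
  if (any(v <= 0)) {
    abort_silkfit("CSF volumes must be positive", "silkfit_parameter_error")
  }
  v
}

#' Full kinetic parameter vector of the compartment model
#'
#' Bundles adjustable parameters (`k_BPD40`, `SF_40`, `Q_CSF`, `Q_osc`),
#' systematically varied parameters (`f_VCSF`, `V_SP`, `Q_leak`), and the
#' structural constants taken from configuration.
#'
#' @param R_APP APP production rate, nmol/h.
#' @param k_BPD40 First-order Abeta40 clearance from ISF, 1/h (in `[0.05, 0.35]`).
#' @param Q_CSF CSF production/clearance flow, mL/h.
#' @param Q_osc SAS oscillatory mixing exchange flow, mL/h.
#' @param SF_40 Measurement scaling factor (> 0).
#' @param Q_leak Catheter leak flow, mL/h.
#' @param f_VCSF CSF-volume error multiplier.
#' @param V_SP Spinal SAS volume, mL.
#' @param age Subject age (years), used for the age-based volumes.
#' @param f_ab40,tau_delay,phi_CR,k_t,V_ISF,n_leu Structural constants;
#'   defaults from `config`.
#' @param config Configuration list.
#' @return Object of class `kinetic_parameters`.
#' @export
kinetic_parameters <- function(R_APP, k_BPD40 = NULL, Q_CSF = NULL,
                               Q_osc = NULL, SF_40 = NULL, Q_leak = 0,
                               f_VCSF = 1, V_SP = 60, age = 70,
                               f_ab40 = NULL, tau_delay = NULL, phi_CR = NULL,
                               k_t = NULL, V_ISF = NULL, n_leu = NULL,
                               config = silk_config()) {
  m <- config$model; nom <- config$nominal
  p <- list(
    R_APP = R_APP,
    k_BPD40 = k_BPD40 %||% nom$k_BPD40,
    Q_CSF = Q_CSF %||% nom$Q_CSF,
    Q_osc = Q_osc %||% nom$Q_osc,
    SF_40 = SF_40 %||% nom$SF_40,
    Q_leak = Q_leak, f_VCSF = f_VCSF, V_SP = V_SP, age = age,
    f_ab40 = f_ab40 %||% m$f_ab40,
    tau_delay = tau_delay %||% m$tau_delay,
    phi_CR = phi_CR %||% m$phi_CR,
    k_t = k_t %||% m$k_t,
    V_ISF = V_ISF %||% m$V_ISF,
    n_leu = as.integer(n_leu %||% m$n_leu),
    mw_ab40 = m$mw_ab40_ng_per_nmol)
  stopifnot_scalar_number(p$R_APP, "R_APP", lower = 0)
  stopifnot_scalar_number(p$k_BPD40, "k_BPD40", 0.05, 0.35)
  stopifnot_scalar_number(p$Q_CSF, "Q_CSF", lower = 0)
  stopifnot_scalar_number(p$Q_osc, "Q_osc", lower = 0)
  stopifnot_scalar_number(p$SF_40, "SF_40", lower = 1e-12)
  stopifnot_scalar_number(p$Q_leak, "Q_leak", lower = 0)
  stopifnot_scalar_number(p$V_SP, "V_SP", lower = 1e-9)
  if (p$phi_CR <= 0 || p$phi_CR >= 1) {
    abort_silkfit("phi_CR must lie in (0, 1)", "silkfit_parameter_error")
  }
  vols <- estimate_csf_volumes(p$age, p$f_VCSF, config)
  p$V_V <- unname(vols["V_V"]); p$V_CIS <- unname(vols["V_CIS"])
  p$V_CR <- unname(vols["V_CR"])
  structure(p, class = "kinetic_parameters")
}

# rate matrix A (dC/dt = A C + u(t) e1 / V_ISF) and absorption flows
model_matrix <- function(p) {
  V <- c(p$V_ISF, p$V_V, p$V_CIS, p$V_CR, p$V_SP)
  Q <- p$Q_CSF; L <- p$Q_leak; phi <- p$phi_CR
  cr_abs <- max(phi * Q - L, 0)        # cranial absorption flow, mL/h
  sp_out <- (1 - phi) * Q + L          # spinal absorption + leak, mL/h
  A <- matrix(0, 5, 5, dimnames = list(COMPARTMENTS, COMPARTMENTS))
  A[1, 1] <- -(p$k_BPD40 * p$V_ISF + p$k_t)
  A[1, 2] <- p$k_t
  A[2, 1] <- p$k_t
  A[2, 2] <- -(p$k_t + Q)
  A[3, 2] <- Q
  A[3, 3] <- -(Q + L + 2 * p$Q_osc)
  A[3, 4] <- p$Q_osc
  A[3, 5] <- p$Q_osc
  A[4, 3] <- phi * Q + p$Q_osc
  A[4, 4] <- -(cr_abs + p$Q_osc)
  A[5, 3] <- sp_out + p$Q_osc
  A[5, 5] <- -(sp_out + p$Q_osc)
  A <- A / V                            # row i divided by V_i
  list(A = A, V = V, cr_abs = cr_abs, sp_out = sp_out)
}

#' Pre-infusion steady state of the compartment model
#'
#' Solves the linear balance (production = clearance; no withdrawals, no
#' label) for the unlabeled concentrations in each compartment.
#'
#' @param params A [kinetic_parameters()] object.
#' @return Named vector of concentrations, nmol/mL.
#' @export
steady_state <- function(params) {
  mm <- model_matrix(params)
  prod_rate <- params$f_ab40 * params$R_APP   # nmol/h
  if (prod_rate == 0) {
    return(stats::setNames(numeric(5), COMPARTMENTS))
  }
  b <- c(prod_rate / params$V_ISF, 0, 0, 0, 0)
  x <- tryCatch(solve(-mm$A, b), error = function(e) {
    abort_silkfit("steady state is singular: no clearance path with R_APP > 0",
                  "silkfit_numeric_error")
  })
  stats::setNames(x, COMPARTMENTS)
}

# --- exact linear propagation ----------------------------------------------

expm_eig <- function(cache, dt) {
  key <- sprintf("%.12g", dt)
  if (!is.null(cache$E[[key]])) return(cache$E[[key]])
  E <- if (cache$ok) {
    Re(cache$Vmat %*% (exp(cache$lambda * dt) * cache$Vinv))
  } else {
    expm_ss(cache$A * dt)
  }
  cache$E[[key]] <- E
  E
}

# scaling-and-squaring Taylor fallback for defective matrices
expm_ss <- function(M) {
  k <- max(0, ceiling(log2(max(1, norm(M, "1")))) + 4)
  Ms <- M / 2^k
  E <- diag(nrow(M)); term <- diag(nrow(M))
  for (i in 1:20) {
    term <- term %*% Ms / i
    E <- E + term
  }
  for (i in seq_len(k)) E <- E %*% E
  E
}

solve_mu <- function(cache, mu) {
  key <- sprintf("%.12g", mu)
  if (!is.null(cache$S[[key]])) return(cache$S[[key]])
  n <- nrow(cache$A)
  M <- mu * diag(n) - cache$A
  w <- tryCatch(solve(M, cache$e1), error = function(e) {
    solve(M + 1e-10 * diag(n), cache$e1)   # mu collides with an eigenvalue
  })
  cache$S[[key]] <- w
  w
}

make_prop_cache <- function(A) {
  cache <- new.env(parent = emptyenv())
  cache$A <- A
  cache$e1 <- c(1, 0, 0, 0, 0)
  cache$E <- list(); cache$S <- list()
  ev <- eigen(A)
  cache$ok <- FALSE
  kp <- tryCatch(kappa(ev$vectors, exact = FALSE), error = function(e) Inf)
  if (is.finite(kp) && kp < 1e9) {
    cache$Vmat <- ev$vectors
    cache$Vinv <- solve(ev$vectors)
    cache$lambda <- ev$values
    cache$ok <- TRUE
  }
  cache
}

# particular-solution basis for x' = A x + s(t) * e1 with s a term sum:
# xp(t) = W %*% (t^pow * exp(mu * t)) for column-wise (mu, pow)
particular_basis <- function(cache, terms) {
  nt <- if (is.null(terms)) 0L else nrow(terms)
  if (nt == 0L) return(NULL)
  W <- NULL; mu_out <- numeric(0); pow_out <- numeric(0)
  n <- nrow(cache$A)
  for (i in seq_len(nt)) {
    cval <- terms[i, 1]; mu <- terms[i, 2]; p <- terms[i, 3]
    if (p == 0) {
      W <- cbind(W, solve_mu(cache, mu) * cval)
      mu_out <- c(mu_out, mu); pow_out <- c(pow_out, 0)
    } else if (mu == 0) {
      b0 <- -solve(cache$A, cache$e1) * cval
      a0 <- solve(cache$A, b0)
      W <- cbind(W, a0, b0)
      mu_out <- c(mu_out, 0, 0); pow_out <- c(pow_out, 0, 1)
    } else {
      w2 <- solve_mu(cache, mu) * cval
      w1 <- solve(mu * diag(n) - cache$A, -w2)
      W <- cbind(W, w1, w2)
      mu_out <- c(mu_out, mu, mu); pow_out <- c(pow_out, 0, 1)
    }
  }
  list(W = W, mu = mu_out, pow = pow_out)
}

basis_at <- function(pb, t1, scale) {
  if (is.null(pb) || scale == 0) return(numeric(5))
  drop(pb$W %*% (t1^pb$pow * exp(pb$mu * t1))) * scale
}

# propagate x' = A x + scale * s(t) * e1 from (t0, x0) to t1
propagate_segment <- function(cache, x0, t0, t1, terms, scale) {
  pb <- particular_basis(cache, terms)
  xp0 <- basis_at(pb, t0, scale); xp1 <- basis_at(pb, t1, scale)
  E <- expm_eig(cache, t1 - t0)
  drop(E %*% (x0 - xp0)) + xp1
}

#' Simulate the compartment model over a sampling schedule
#'
#' Integrates labeled and unlabeled Abeta40 from the pre-infusion steady
#' state, applying a 6-mL-style withdrawal event at every schedule time
#' (the spinal compartment is refilled from the cisternal side), and returns
#' the model state at each scheduled draw (recorded before the draw).
#' Propagation is exact for the linear system, so results are deterministic
#' and tolerance-free.
#'
#' @param params A [kinetic_parameters()] object.
#' @param enrichment An `enrichment_curve` (see [enrichment_infusion()]).
#' @param schedule A [sample_schedule()]; set `draw_volume = 0` via
#'   `withdrawals = FALSE` to simulate without draws.
#' @param withdrawals Apply withdrawal events (default TRUE).
#' @return Object of class `model_output`: list with `times`, matrices
#'   `labeled` and `unlabeled` (times x compartments, nmol/mL),
#'   `lumbar_concentration` (measured scale, pg/mL, = `SF_40` x total spinal
#'   concentration), `labeled_fraction` (spinal), and `isf_lumbar_ratio`
#'   (pre-infusion steady state ISF:spinal concentration ratio).
#' @export
simulate_model <- function(params, enrichment, schedule = default_schedule(),
                           withdrawals = TRUE, engine = c("cpp", "r"),
                           .lab = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(params, "kinetic_parameters"),
            inherits(enrichment, "enrichment_curve"),
            inherits(schedule, "sample_schedule"))
  mm <- model_matrix(params)
  prod_rate <- params$f_ab40 * params$R_APP / params$V_ISF  # forcing scale
  lab <- .lab %||%
    label_curve_terms(enrichment, params$tau_delay, params$n_leu)

  x_ss <- steady_state(params)
  tt <- schedule$times
  nt <- length(tt)
  frac_draw <- if (withdrawals) schedule$draw_volume / params$V_SP else 0

  # all propagation pieces (schedule times + label breakpoints), built once
  t_end <- tt[nt]
  brks <- lab$breaks
  cuts <- sort(unique(c(0, tt, brks[brks > 0 & brks < t_end])))
  mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
  seg_idx <- findInterval(mids, brks)
  seg_idx[mids < brks[1]] <- 0L
  one <- es_terms(1, 0, 0L)
  lab_terms <- c(list(es_empty()), lab$segments)   # slot 1 = pre-label
  unl_terms <- c(list(one), lab$unlabeled)

  if (engine == "cpp") {
    res <- sim_core(mm$A, prod_rate, as.numeric(x_ss), cuts,
                    as.integer(seg_idx), lab_terms, unl_terms, tt, frac_draw)
    Lm <- res$labeled; Um <- res$unlabeled
    colnames(Lm) <- colnames(Um) <- COMPARTMENTS
  } else {
    cache <- make_prop_cache(mm$A)
    x_u <- as.numeric(x_ss); x_l <- numeric(5)
    Lm <- matrix(0, nt, 5, dimnames = list(NULL, COMPARTMENTS))
    Um <- matrix(0, nt, 5, dimnames = list(NULL, COMPARTMENTS))
    pb_l <- lapply(lab_terms, particular_basis, cache = cache)
    pb_u <- lapply(unl_terms, particular_basis, cache = cache)
    k_out <- 1L
    if (cuts[1] == tt[1]) {    # sample at t = 0: record, then draw
      Lm[1, ] <- x_l; Um[1, ] <- x_u
      if (frac_draw > 0) {
        x_l[5] <- x_l[5] + frac_draw * (x_l[3] - x_l[5])
        x_u[5] <- x_u[5] + frac_draw * (x_u[3] - x_u[5])
      }
      k_out <- 2L
    }
    for (i in seq_along(mids)) {
      a <- cuts[i]; b <- cuts[i + 1]
      E <- expm_eig(cache, b - a)
      s <- seg_idx[i] + 1L
      xp0 <- basis_at(pb_l[[s]], a, prod_rate)
      xp1 <- basis_at(pb_l[[s]], b, prod_rate)
      x_l <- (E %*% (x_l - xp0))[, 1] + xp1
      xp0 <- basis_at(pb_u[[s]], a, prod_rate)
      xp1 <- basis_at(pb_u[[s]], b, prod_rate)
      x_u <- (E %*% (x_u - xp0))[, 1] + xp1
      if (k_out <= nt && b == tt[k_out]) {
        x_l[x_l < 0] <- 0; x_u[x_u < 0] <- 0
        Lm[k_out, ] <- x_l; Um[k_out, ] <- x_u
        if (frac_draw > 0) {
          x_l[5] <- x_l[5] + frac_draw * (x_l[3] - x_l[5])
          x_u[5] <- x_u[5] + frac_draw * (x_u[3] - x_u[5])
        }
        k_out <- k_out + 1L
      }
    }
  }
  total_sp <- Lm[, "SP"] + Um[, "SP"]
  frac <- ifelse(total_sp > 0, Lm[, "SP"] / total_sp, 0)
  ratio <- if (x_ss["SP"] > 0) unname(x_ss["ISF"] / x_ss["SP"]) else 0
  structure(list(
    times = tt, labeled = Lm, unlabeled = Um,
    lumbar_concentration = params$SF_40 * total_sp * params$mw_ab40 * 1e3,
    labeled_fraction = pmin(pmax(frac, 0), 1),
    isf_lumbar_ratio = ratio,
    steady_state = x_ss, params = params),
    class = "model_output")
}

#' Steady-state mass balance of the compartment model
#'
#' Sums all clearance fluxes (ISF first-order clearance, cranial and spinal
#' CSF absorption, catheter leak) at the unlabeled steady state and compares
#' them with the production flux `f_ab40 * R_APP`.
#'
#' @param params A [kinetic_parameters()] object.
#' @return List with `production`, `clearance` (both nmol/h) and
#'   `relative_error`.
#' @export
mass_balance <- function(params) {
  x <- steady_state(params)
  mm <- model_matrix(params)
  clearance <- params$k_BPD40 * params$V_ISF * x["ISF"] +
    mm$cr_abs * x["CR"] + mm$sp_out * x["SP"]
  production <- params$f_ab40 * params$R_APP
  rel <- if (production > 0) abs(clearance - production) / production else 0
  list(production = unname(production), clearance = unname(clearance),
       relative_error = unname(rel))
}
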
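# Plasma leucine enrichment curves.
#
# Curves are stored as piecewise sums of terms c * t^p * exp(mu*t) (p in
# {0,1}), which the compartment model propagates in closed form.  The primed
# infusion curve (bolus + constant-rate over 9 h) is exactly of this class;
# sampled curves are represented piecewise-linearly.

# terms are plain 3-column matrices (coef, rate, pow) for speed
es_terms <- function(coef, rate = 0, pow = 0L) {
  m <- cbind(coef, rate, pow)
  colnames(m) <- c("coef", "rate", "pow")
  m
}

es_empty <- function() es_terms(numeric(0), numeric(0), integer(0))

es_collapse <- function(terms) {
  if (is.null(terms) || nrow(terms) == 0) return(es_empty())
  key <- paste(signif(terms[, 2], 15), terms[, 3])
  coef <- rowsum(terms[, 1], key, reorder = FALSE)
  m <- match(rownames(coef), key)
  out <- es_terms(as.numeric(coef), terms[m, 2], terms[m, 3])
  out[abs(out[, 1]) > 0, , drop = FALSE]
}

es_add <- function(a, b) es_collapse(rbind(a, b))

es_scale <- function(a, k) { a[, 1] <- a[, 1] * k; a }

es_mul <- function(a, b) {
  out <- do.call(rbind, lapply(seq_len(nrow(a)), function(i) {
    pow <- a[i, 3] + b[, 3]
    if (any(pow > 1L)) {
      abort_silkfit("enrichment algebra: polynomial degree > 1 not supported (use n_leu = 1 with sampled curves)",
                    "silkfit_numeric_error")
    }
    es_terms(a[i, 1] * b[, 1], a[i, 2] + b[, 2], pow)
  }))
  es_collapse(out)
}

es_pow <- function(a, n) {
  out <- es_terms(1, 0, 0L)
  for (i in seq_len(n)) out <- es_mul(out, a)
  out
}

es_eval <- function(terms, t) {
  vapply(t, function(tt) {
    sum(terms[, 1] * tt^terms[, 3] * exp(terms[, 2] * tt))
  }, numeric(1))
}

# shift terms: s(t - tau) expressed in global time t
es_shift <- function(terms, tau) {
  out <- do.call(rbind, lapply(seq_len(nrow(terms)), function(i) {
    c0 <- terms[i, 1] * exp(-terms[i, 2] * tau)
    if (terms[i, 3] == 0) {
      es_terms(c0, terms[i, 2], 0L)
    } else {
      rbind(es_terms(c0, terms[i, 2], 1L),
            es_terms(-c0 * tau, terms[i, 2], 0L))
    }
  }))
  es_collapse(out)
}

new_piecewise_curve <- function(breaks, segments, meta = list()) {
  structure(list(breaks = breaks, segments = segments, meta = meta),
            class = "enrichment_curve")
}

#' Parametric plasma leucine enrichment curve for a primed infusion
#'
#' Models the labeled mole fraction of plasma leucine during and after a
#' primed (bolus + constant-rate) infusion: a fast mono-exponential approach
#' to the plateau `e_ss` while the infusion runs, then mono-exponential
#' washout.
#'
#' @param e_ss Plateau enrichment (labeled mole fraction) during infusion.
#' @param k_rise Rise rate constant, 1/h (primed infusions equilibrate fast).
#' @param k_decay Post-infusion washout rate constant, 1/h.
#' @param t_infusion Infusion duration, h.
#' @return An `enrichment_curve`.
#' @export
enrichment_infusion <- function(e_ss = 0.12, k_rise = 2, k_decay = 0.7,
                                t_infusion = 9) {
  stopifnot_scalar_number(e_ss, "e_ss", 0, 1)
  stopifnot_scalar_number(k_rise, "k_rise", 1e-9)
  stopifnot_scalar_number(k_decay, "k_decay", 1e-9)
  stopifnot_scalar_number(t_infusion, "t_infusion", 1e-9)
  e_end <- e_ss * (1 - exp(-k_rise * t_infusion))
  new_piecewise_curve(
    breaks = c(0, t_infusion, Inf),
    segments = list(
      rbind(es_terms(e_ss, 0, 0L), es_terms(-e_ss, -k_rise, 0L)),
      es_terms(e_end * exp(k_decay * t_infusion), -k_decay, 0L)
    ),
    meta = list(kind = "infusion", e_ss = e_ss, k_rise = k_rise,
                k_decay = k_decay, t_infusion = t_infusion))
}

#' Piecewise-linear enrichment curve from sampled values
#'
#' @param times Sampling times, h (strictly increasing, first >= 0).
#' @param values Enrichment in `[0, 1]`; held constant after the last sample.
#' @return An `enrichment_curve`.
#' @export
enrichment_from_samples <- function(times, values) {
  if (any(diff(times) <= 0) || times[1] < 0) {
    abort_silkfit("enrichment times must be strictly increasing and >= 0",
                  "silkfit_validation_error")
  }
  if (any(values < 0 | values > 1)) {
    abort_silkfit("enrichment values must lie in [0, 1]",
                  "silkfit_validation_error")
  }
  n <- length(times)
  segs <- vector("list", n)
  brks <- c(times, Inf)
  if (times[1] > 0) {           # ramp from 0 at t = 0
    brks <- c(0, brks)
    segs <- c(list(NULL), segs)
    times0 <- c(0, times); values0 <- c(0, values)
  } else {
    times0 <- times; values0 <- values
  }
  for (i in seq_len(length(brks) - 2L)) {
    slope <- (values0[i + 1] - values0[i]) / (times0[i + 1] - times0[i])
    segs[[i]] <- es_collapse(rbind(
      es_terms(values0[i] - slope * times0[i], 0, 0L),
      es_terms(slope, 0, 1L)))
  }
  segs[[length(brks) - 1L]] <- es_terms(values0[length(values0)], 0, 0L)
  new_piecewise_curve(brks, segs, meta = list(kind = "sampled"))
}

#' Evaluate an enrichment curve
#'
#' @param curve An `enrichment_curve`.
#' @param t Times, h; values for `t < 0` are 0.
#' @return Numeric vector of enrichments.
#' @export
eval_enrichment <- function(curve, t) {
  stopifnot(inherits(curve, "enrichment_curve"))
  out <- numeric(length(t))
  for (k in seq_along(curve$segments)) {
    inside <- t >= curve$breaks[k] & t < curve$breaks[k + 1]
    if (any(inside)) out[inside] <- es_eval(curve$segments[[k]], t[inside])
  }
  pmin(pmax(out, 0), 1)
}

#' Labeled fraction of newly produced peptide
#'
#' A peptide carrying `n_leu` leucine residues is labeled if at least one
#' residue is labeled, so the labeled production fraction at time `t` is
#' `1 - (1 - e(t - tau_delay))^n_leu`, with the precursor enrichment `e`
#' taken as 0 for negative arguments.
#'
#' @param enrichment An `enrichment_curve`.
#' @param t Time(s), h.
#' @param tau_delay Labeling/processing delay, h.
#' @param n_leu Number of leucine residues considered (default 1, making the
#'   fraction the normalized tracer-to-tracee ratio assumed by FSR).
#' @return Labeled production fraction(s) in `[0, 1]`.
#' @export
labeled_production_fraction <- function(enrichment, t, tau_delay = 0,
                                        n_leu = 1L) {
  stopifnot(all(t >= 0))
  e <- eval_enrichment(enrichment, t - tau_delay)
  e[t - tau_delay < 0] <- 0
  1 - (1 - e)^n_leu
}

# piecewise terms of the labeled production fraction in global time,
# plus the complementary unlabeled-production terms per segment
label_curve_terms <- function(enrichment, tau_delay, n_leu = 1L) {
  brks <- enrichment$breaks + tau_delay
  segs <- lapply(enrichment$segments, es_shift, tau = tau_delay)
  one <- es_terms(1, 0, 0L)
  if (n_leu != 1L) {
    segs <- lapply(segs, function(s) {
      es_add(one, es_scale(es_pow(es_add(one, es_scale(s, -1)), n_leu), -1))
    })
  }
  list(breaks = brks, segments = segs,
       unlabeled = lapply(segs, function(s) es_add(one, es_scale(s, -1))))
}
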
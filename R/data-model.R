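# Domain types and CSV readers/writers for the study tables.
#
# All tables are long (tidy): one row per sample.  Missing samples are kept as
# rows with an empty value and missing = TRUE, never dropped, so that schedule
# accounting (fraction of draws obtained) is well defined.

SILK_COLS <- c("subject_id", "isoform", "time_h", "labeled_fraction", "missing")
CONC_COLS <- c("subject_id", "analyte", "matrix", "time_h", "value",
               "clock_min", "missing")
SUBJ_COLS <- c("subject_id", "site_id", "age", "sex", "education",
               "mmse_baseline", "arm", "on_achei", "on_memantine",
               "on_antidepressant", "csf_ab42_40", "weight_kg")

ISOFORMS <- c("Ab38", "Ab40", "Ab42")
ANALYTES <- c("Posiphen", "N1", "N8", "Ab38", "Ab40", "Ab42",
              "sAPPa", "sAPPb", "tTau", "leucine_enrichment")
MATRICES <- c("plasma", "CSF")
ARMS     <- c("placebo", "QD60", "BID120", "TID180")

#' Sampling schedule for serial lumbar CSF collection
#'
#' The default schedule is the study design: a draw every 2 h for 36 h
#' (19 time points) of `draw_volume` mL each.
#'
#' @param times Sampling times in hours since catheter placement, strictly
#'   increasing.
#' @param draw_volume CSF volume removed per draw, mL (> 0).
#' @return An object of class `sample_schedule`.
#' @export
sample_schedule <- function(times = seq(0, 36, by = 2), draw_volume = 6) {
  if (!is.numeric(times) || length(times) < 1L || anyNA(times)) {
    abort_silkfit("schedule times must be a non-empty numeric vector",
                  "silkfit_validation_error")
  }
  if (any(diff(times) <= 0)) {
    abort_silkfit("schedule times must be strictly increasing",
                  "silkfit_validation_error")
  }
  stopifnot_scalar_number(draw_volume, "draw_volume", lower = 1e-12)
  structure(list(times = as.numeric(times), draw_volume = draw_volume),
            class = "sample_schedule")
}

#' Per-subject labeled-fraction time course
#'
#' One SILK series: the tracer-to-tracee labeled mole fraction of one
#' amyloid-beta isoform in lumbar CSF over the sampling schedule.
#'
#' @param subject_id,isoform Identifiers; `isoform` one of Ab38, Ab40, Ab42.
#' @param times Hours since catheter placement.
#' @param labeled_fraction Labeled mole fraction in `[0, 1]` (NA where missing).
#' @param missing_mask Logical; TRUE where the draw was not obtained.
#' @return Object of class `silk_series`.
#' @export
silk_series <- function(subject_id, isoform, times, labeled_fraction,
                        missing_mask = is.na(labeled_fraction)) {
  isoform <- match.arg(isoform, ISOFORMS)
  if (any(diff(times) <= 0)) {
    abort_silkfit(sprintf("subject %s: SILK times must be strictly increasing",
                          subject_id), "silkfit_validation_error")
  }
  bad <- which(!missing_mask &
                 (is.na(labeled_fraction) | labeled_fraction < 0 |
                    labeled_fraction > 1))
  if (length(bad)) {
    abort_silkfit(sprintf(
      "subject %s: labeled_fraction outside [0, 1] at row(s) %s",
      subject_id, paste(bad, collapse = ", ")), "silkfit_validation_error")
  }
  structure(list(subject_id = as.character(subject_id), isoform = isoform,
                 times = as.numeric(times),
                 labeled_fraction = as.numeric(labeled_fraction),
                 missing_mask = as.logical(missing_mask)),
            class = "silk_series")
}

#' Per-subject analyte concentration time course
#'
#' @param subject_id Subject identifier.
#' @param analyte One of Posiphen, N1, N8, Ab38, Ab40, Ab42, sAPPa, sAPPb,
#'   tTau, leucine_enrichment.
#' @param matrix `"plasma"` or `"CSF"`.
#' @param times Hours since catheter placement.
#' @param values ng/mL for drug analytes, pg/mL for biomarkers, mole fraction
#'   for leucine enrichment; NA where missing.
#' @param clock_times Local clock time per sample, minutes since midnight
#'   (needed only for the morning-sample concentration filter); NA allowed.
#' @param missing_mask Logical missing indicator.
#' @return Object of class `concentration_series`.
#' @export
concentration_series <- function(subject_id, analyte, matrix, times, values,
                                 clock_times = rep(NA_real_, length(times)),
                                 missing_mask = is.na(values)) {
  analyte <- match.arg(analyte, ANALYTES)
  matrix <- match.arg(matrix, MATRICES)
  if (any(diff(times) <= 0)) {
    abort_silkfit(sprintf("subject %s/%s: times must be strictly increasing",
                          subject_id, analyte), "silkfit_validation_error")
  }
  bad <- which(!missing_mask & (is.na(values) | values < 0))
  if (length(bad)) {
    abort_silkfit(sprintf("subject %s/%s: negative concentration at row(s) %s",
                          subject_id, analyte, paste(bad, collapse = ", ")),
                  "silkfit_validation_error")
  }
  if (analyte == "leucine_enrichment") {
    bad <- which(!missing_mask & values > 1)
    if (length(bad)) {
      abort_silkfit(sprintf(
        "subject %s: leucine enrichment > 1 at row(s) %s",
        subject_id, paste(bad, collapse = ", ")), "silkfit_validation_error")
    }
  }
  structure(list(subject_id = as.character(subject_id), analyte = analyte,
                 matrix = matrix, times = as.numeric(times),
                 values = as.numeric(values),
                 clock_times = as.numeric(clock_times),
                 missing_mask = as.logical(missing_mask)),
            class = "concentration_series")
}

validate_subjects <- function(df) {
  msgs <- character(0)
  chk <- function(cond, what) {
    bad <- which(!(cond | is.na(cond) & FALSE))
    bad <- which(!cond)
    if (length(bad)) {
      msgs <<- c(msgs, sprintf("%s at row(s) %s", what,
                               paste(bad, collapse = ", ")))
    }
  }
  chk(df$age >= 55 & df$age <= 89, "age outside [55, 89]")
  chk(df$mmse_baseline >= 17 & df$mmse_baseline <= 30,
      "mmse_baseline outside [17, 30]")
  chk(df$arm %in% ARMS, "unknown arm")
  chk(df$sex %in% c("female", "male"), "unknown sex")
  chk(df$csf_ab42_40 > 0, "csf_ab42_40 must be > 0")
  if (length(msgs)) {
    abort_silkfit(paste(msgs, collapse = "; "), "silkfit_validation_error")
  }
  df
}

canonical_order <- function(df, kind) {
  key <- switch(kind,
    silk = order(df$subject_id, df$isoform, df$time_h),
    concentration = order(df$subject_id, df$analyte, df$matrix, df$time_h),
    subjects = order(df$subject_id))
  df[key, , drop = FALSE]
}

#' Read a long-format study table
#'
#' Reads and validates one of the three table kinds: `"silk"` (labeled
#' fractions), `"concentration"` (analyte concentrations and leucine
#' enrichment), or `"subjects"` (metadata).  Rows failing a type or bound
#' check are reported with their row index.
#'
#' @param path CSV file path.
#' @param kind Table kind.
#' @return A validated data frame in canonical row order, with class
#'   `silk_table`, `concentration_table` or `subject_table`.
#' @export
read_long_table <- function(path, kind = c("silk", "concentration", "subjects")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) {
    abort_silkfit(sprintf("file not found: %s", path), "silkfit_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_long_table(df, kind)
}

#' Validate an in-memory long-format study table
#'
#' @param df Data frame with the documented columns for `kind`.
#' @inheritParams read_long_table
#' @return The validated, canonically ordered data frame (classed).
#' @export
validate_long_table <- function(df, kind = c("silk", "concentration", "subjects")) {
  kind <- match.arg(kind)
  need <- switch(kind, silk = SILK_COLS, concentration = CONC_COLS,
                 subjects = SUBJ_COLS)
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort_silkfit(sprintf("missing required column(s): %s",
                          paste(miss, collapse = ", ")), "silkfit_schema_error")
  }
  df <- df[, need, drop = FALSE]
  if (kind == "silk") {
    df$missing <- as.logical(df$missing)
    bad <- which(!df$missing & (is.na(df$labeled_fraction) |
                                  df$labeled_fraction < 0 |
                                  df$labeled_fraction > 1))
    if (length(bad)) {
      abort_silkfit(sprintf("labeled_fraction outside [0, 1] at row(s) %s",
                            paste(bad, collapse = ", ")),
                    "silkfit_validation_error")
    }
    bad <- which(!df$isoform %in% ISOFORMS)
    if (length(bad)) {
      abort_silkfit(sprintf("unknown isoform at row(s) %s",
                            paste(bad, collapse = ", ")),
                    "silkfit_validation_error")
    }
    check_monotone(df, c("subject_id", "isoform"))
    df <- canonical_order(df, kind)
    class(df) <- c("silk_table", "data.frame")
  } else if (kind == "concentration") {
    df$missing <- as.logical(df$missing)
    bad <- which(!df$missing & (is.na(df$value) | df$value < 0))
    if (length(bad)) {
      abort_silkfit(sprintf("negative/missing value at row(s) %s",
                            paste(bad, collapse = ", ")),
                    "silkfit_validation_error")
    }
    bad <- which(!df$analyte %in% ANALYTES)
    if (length(bad)) {
      abort_silkfit(sprintf("unknown analyte at row(s) %s",
                            paste(bad, collapse = ", ")),
                    "silkfit_validation_error")
    }
    check_monotone(df, c("subject_id", "analyte", "matrix"))
    df <- canonical_order(df, kind)
    class(df) <- c("concentration_table", "data.frame")
  } else {
    df <- validate_subjects(df)
    df <- canonical_order(df, kind)
    class(df) <- c("subject_table", "data.frame")
  }
  rownames(df) <- NULL
  df
}

check_monotone <- function(df, by) {
  key <- do.call(paste, c(df[by], sep = "\r"))
  for (k in unique(key)) {
    tt <- df$time_h[key == k]
    if (any(diff(tt[order(tt)]) == 0) ||
        any(duplicated(tt))) {
      abort_silkfit(sprintf("duplicate time points within %s",
                            gsub("\r", "/", k)), "silkfit_validation_error")
    }
  }
  invisible(df)
}

#' Write a long-format study table
#'
#' Row and column order are canonical (subject, analyte, time) so writes are
#' byte-stable across runs and independent of input row order.
#'
#' @param df Table (validated or raw with documented columns).
#' @param path Output CSV path.
#' @param kind Table kind, see [read_long_table()].
#' @return `path`, invisibly.
#' @export
write_long_table <- function(df, path,
                             kind = c("silk", "concentration", "subjects")) {
  kind <- match.arg(kind)
  df <- validate_long_table(as.data.frame(df), kind)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Split a SILK table into per-subject series objects
#'
#' @param df A `silk_table`.
#' @return Named list of [silk_series()] objects (`subject/isoform` keys).
#' @export
split_silk_series <- function(df) {
  key <- paste(df$subject_id, df$isoform, sep = "/")
  lapply(split(seq_len(nrow(df)), key), function(i) {
    d <- df[i, ][order(df$time_h[i]), ]
    silk_series(d$subject_id[1], d$isoform[1], d$time_h, d$labeled_fraction,
                d$missing)
  })
}

#' Split a concentration table into per-subject series objects
#'
#' @param df A `concentration_table`.
#' @return Named list of [concentration_series()] objects.
#' @export
split_concentration_series <- function(df) {
  key <- paste(df$subject_id, df$analyte, df$matrix, sep = "/")
  lapply(split(seq_len(nrow(df)), key), function(i) {
    d <- df[i, ][order(df$time_h[i]), ]
    concentration_series(d$subject_id[1], d$analyte[1], d$matrix[1],
                         d$time_h, d$value, d$clock_min, d$missing)
  })
}

#' Account a series against its sampling schedule
#'
#' Reports how many of the scheduled draws are present, mirroring the
#' study's sample-completeness feasibility metric.
#'
#' @param series A [silk_series()] or [concentration_series()].
#' @param schedule A [sample_schedule()].
#' @return List with `n_expected`, `n_present`, `n_missing`, `extra_times`
#'   (observed times not on the schedule) and `fraction_present`.
#' @export
validate_against_schedule <- function(series, schedule) {
  stopifnot(inherits(schedule, "sample_schedule"))
  times <- series$times
  miss <- series$missing_mask
  on_sched <- times %in% schedule$times
  present_times <- times[!miss & on_sched]
  n_expected <- length(schedule$times)
  n_present <- sum(schedule$times %in% present_times)
  list(n_expected = n_expected,
       n_present = n_present,
       n_missing = n_expected - n_present,
       extra_times = times[!on_sched],
       fraction_present = if (n_expected > 0) n_present / n_expected else NA_real_)
}
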
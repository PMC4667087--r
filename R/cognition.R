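#' @name cognition
#' @title Compound cognitive domain scores
#'
#' @description Three equal-weight compound measures are built from
#' baseline-standardized subtest z-scores:
#' speed and motor control = (Trail Making A + maze + digit
#' cancellation) / 3; executive functions = ((Stroop III - II) +
#' (Trail Making B - A) + Symbol Digit Modalities + verbal fluency) / 4;
#' memory = (immediate word recall + delayed recall + word recognition +
#' digit span) / 4. Timed measures (Trail A, Trail B - A, Stroop
#' III - II, maze) are sign-flipped so that a higher compound always
#' means better performance. All visits are standardized against the
#' baseline cohort mean/SD, so cohort-level decline appears as negative
#' drift in follow-up compounds.
NULL

# derived-measure definitions: name, sign (-1 for timed), domain
compound_measures <- function() {
  data.frame(
    measure = c("trail_a", "maze", "digit_cancellation",
                "stroop_diff", "trail_diff", "symbol_digit", "verbal_fluency",
                "word_recall_immediate", "word_recall_delayed",
                "word_recognition", "digit_span"),
    sign = c(-1, -1, +1,
             -1, -1, +1, +1,
             +1, +1, +1, +1),
    domain = c("speed", "speed", "speed",
               "executive", "executive", "executive", "executive",
               "memory", "memory", "memory", "memory"),
    stringsAsFactors = FALSE)
}

# add the timed-difference measures; inputs may be missing -> NA result
derive_difference_measures <- function(records) {
  raw <- c("trail_a", "trail_b", "stroop_ii", "stroop_iii")
  miss <- setdiff(raw, names(records))
  if (length(miss) > 0) stopf("missing subtest column: %s", miss[1])
  records$stroop_diff <- records$stroop_iii - records$stroop_ii
  records$trail_diff <- records$trail_b - records$trail_a
  records
}

#' Fit baseline standardization norms
#'
#' Computes the mean and sample SD of every derived measure over the
#' baseline (visit 0) rows only; follow-up visits are later scored
#' against these same norms.
#'
#' @param records data.frame with `visit_year` and the subtest columns
#'   (`trail_a`, `trail_b`, `maze`, `digit_cancellation`, `stroop_ii`,
#'   `stroop_iii`, `symbol_digit`, `verbal_fluency`,
#'   `word_recall_immediate`, `word_recall_delayed`, `word_recognition`,
#'   `digit_span`).
#' @return `baseline_norms`: data.frame of measure, mean, sd, sign,
#'   domain.
#' @export
fit_baseline_norms <- function(records) {
  stopifnot(is.data.frame(records), "visit_year" %in% names(records))
  base <- derive_difference_measures(records[records$visit_year == 0, , drop = FALSE])
  cm <- compound_measures()
  for (msr in cm$measure)
    if (!msr %in% names(base)) stopf("missing subtest column: %s", msr)
  cm$mean <- NA_real_; cm$sd <- NA_real_
  for (i in seq_len(nrow(cm))) {
    v <- base[[cm$measure[i]]]
    v <- v[is.finite(v)]
    if (length(v) < 2)
      stopf("need >= 2 baseline observations of '%s'", cm$measure[i])
    cm$mean[i] <- mean(v)
    cm$sd[i] <- sd(v)
    if (cm$sd[i] == 0)
      stopf("zero baseline SD for measure '%s'; cannot standardize", cm$measure[i])
  }
  structure(cm, class = c("baseline_norms", "data.frame"))
}

#' Compute compound domain scores
#'
#' Standardizes every derived measure against its baseline norm, applies
#' the sign convention (timed measures negated), and averages within
#' each domain with equal weights. A compound is set to missing whenever
#' any of its constituents is missing; nothing is imputed.
#'
#' @param records data.frame of subject-visit rows with subtest columns.
#' @param norms a [fit_baseline_norms()] result.
#' @return `records` with added columns `compound_speed`,
#'   `compound_executive`, `compound_memory`.
#' @export
compute_compound_scores <- function(records, norms) {
  stopifnot(inherits(norms, "baseline_norms"))
  rec <- derive_difference_measures(records)
  z <- matrix(NA_real_, nrow(rec), nrow(norms),
              dimnames = list(NULL, norms$measure))
  for (i in seq_len(nrow(norms)))
    z[, i] <- norms$sign[i] * (rec[[norms$measure[i]]] - norms$mean[i]) / norms$sd[i]
  for (dom in c("speed", "executive", "memory")) {
    cols <- norms$measure[norms$domain == dom]
    records[[paste0("compound_", dom)]] <- rowMeans(z[, cols, drop = FALSE])
  }
  n_miss <- sum(!complete.cases(z))
  if (n_miss > 0)
    message(sprintf("compute_compound_scores: %d row(s) with missing constituents; their compounds set to NA", n_miss))
  records
}
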
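# Annual fruit-and-vegetable consumption (AFVC) from food-frequency
# questionnaire fields, and median/threshold stratification of a cohort.

#' Annual fruit and vegetable consumption from FFQ fields
#'
#' For each questionnaire item the intake is `times_per_month *
#' grams_per_time`, i.e. grams per month; summing over items and converting
#' (12 months/year, 1000 g/kg) gives
#' `AFVC = sum(times_per_month * grams_per_time) * 12 / 1000` kg/year.
#' A `literal` mode multiplies by 1000 instead of dividing — the form some
#' questionnaire write-ups print — and is kept only for traceability; it does
#' not yield kg/year.
#'
#' @param times_per_month Numeric vector, intake frequency per item.
#' @param grams_per_time Numeric vector, portion mass per item (g).
#' @param literal Use the printed `x 1000 x 12` form instead of the
#'   dimensionally consistent `x 12 / 1000`.
#' @return AFVC in kg/year (unless `literal = TRUE`).
#' @examples
#' compute_afvc(30, 250)  # 90 kg/year
#' @export
compute_afvc <- function(times_per_month, grams_per_time, literal = FALSE) {
  if (length(times_per_month) != length(grams_per_time)) {
    abort_arg("`times_per_month` and `grams_per_time` must have equal length")
  }
  if (any(times_per_month < 0) || any(grams_per_time < 0)) {
    abort_arg("FFQ entries must be >= 0")
  }
  monthly_g <- sum(times_per_month * grams_per_time)
  if (literal) monthly_g * 1000 * 12 else monthly_g * 12 / 1000
}

# AFVC per row of a cohort table, from an explicit column or the FFQ columns.
cohort_afvc <- function(cohort) {
  if ("afvc_kg_year" %in% names(cohort)) return(cohort$afvc_kg_year)
  tcols <- grep("^ffq_times_per_month_", names(cohort), value = TRUE)
  gcols <- grep("^ffq_grams_per_time_", names(cohort), value = TRUE)
  if (length(tcols) == 0L || length(tcols) != length(gcols)) {
    abort_arg("cohort needs an `afvc_kg_year` column or paired FFQ columns")
  }
  vapply(seq_len(nrow(cohort)), function(i) {
    compute_afvc(as.numeric(cohort[i, tcols]), as.numeric(cohort[i, gcols]))
  }, numeric(1))
}

#' Stratify a cohort at an AFVC threshold
#'
#' Labels each participant `"high"` if their AFVC is greater than or equal
#' to the threshold (inclusive boundary) and `"low"` otherwise, and reports
#' per-group sizes and crude dementia incidence (cases / group size). The
#' default threshold is the cohort median. Formal survival comparisons
#' (Kaplan-Meier, log-rank) are left to the standard survival machinery;
#' only the crude incidence is computed here.
#'
#' @param cohort A data.frame with a `dementia` logical column and either an
#'   `afvc_kg_year` column or FFQ item columns (as from [gen_cohort()]).
#' @param threshold AFVC cut point in kg/year; `NULL` uses the median.
#' @return A list with `labels` (factor high/low per participant), `threshold`,
#'   and `groups` (data.frame: group, n, cases, incidence).
#' @export
stratify <- function(cohort, threshold = NULL) {
  stopifnot(is.data.frame(cohort), nrow(cohort) >= 1L)
  check_columns(cohort, "dementia", "cohort table")
  afvc <- cohort_afvc(cohort)
  if (is.null(threshold)) threshold <- stats::median(afvc)
  labels <- factor(ifelse(afvc >= threshold, "high", "low"),
                   levels = c("high", "low"))
  groups <- do.call(rbind, lapply(levels(labels), function(g) {
    idx <- labels == g
    data.frame(group = g, n = sum(idx),
               cases = sum(cohort$dementia[idx]),
               incidence = if (sum(idx) > 0) mean(cohort$dementia[idx])
                           else NA_real_,
               stringsAsFactors = FALSE)
  }))
  list(labels = labels, threshold = threshold, groups = groups)
}
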
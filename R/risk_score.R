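#' Z-score standardisation over a cohort
#'
#' Centres and scales to sample mean 0 and sample SD 1 (denominator n - 1).
#'
#' @param x Numeric vector with at least two values.
#' @param name Variable name used in error messages.
#' @return Standardised numeric vector.
#' @export
zscore <- function(x, name = deparse(substitute(x))) {
  if (length(x) < 2L) abort(sprintf("`%s`: need at least 2 values to standardise.", name))
  if (anyNA(x)) abort(sprintf("`%s` contains missing values.", name))
  s <- sd(x)
  if (!is.finite(s) || s == 0) {
    abort(sprintf("`%s` has zero variance; cannot standardise.", name))
  }
  (x - mean(x)) / s
}

#' Reversed cardiometabolic composite score
#'
#' Combines five risk factors -- waist circumference, systolic blood
#' pressure, total-cholesterol-to-HDL ratio, triglycerides and HbA1c -- into
#' a single cohort-standardised score.  So that dyslipidaemia carries the
#' same influence as central obesity, hypertension and hyperglycaemia, the
#' two lipid variables are first averaged on the Z-scale:
#' \deqn{lipid = (z(TC/HDL) + z(TG)) / 2}
#' \deqn{CS = -( z(waist) + z(HbA1c) + z(SBP) + lipid ) / 4}
#' The sign reversal makes a positive score represent better cardiometabolic
#' health.  Z-scores are computed on the analysed sample after exclusions, so
#' the score is sample-specific and not comparable across cohorts.
#'
#' @param panel Tibble with columns `subject_id`, `waist` (cm), `sbp` (mmHg),
#'   `tc`, `hdl`, `tg` (mmol/L), `hba1c` (mmol/mol).  Additional columns are
#'   ignored.  Subjects with any missing risk factor are dropped with a
#'   message (complete-case analysis).
#' @return Tibble with `subject_id` and `cs`; `cs` has cohort mean 0.
#' @examples
#' panel <- tibble::tibble(
#'   subject_id = c("a", "b", "c"),
#'   waist = c(80, 95, 110), sbp = c(110, 125, 135),
#'   tc = c(4.5, 5.5, 6.5), hdl = c(1.9, 1.5, 1.1),
#'   tg = c(0.8, 1.2, 2.1), hba1c = c(31, 35, 41)
#' )
#' composite_score(panel)
#' @export
composite_score <- function(panel) {
  needed <- c("subject_id", "waist", "sbp", "tc", "hdl", "tg", "hba1c")
  missing_cols <- setdiff(needed, names(panel))
  if (length(missing_cols)) {
    abort(paste0("Panel is missing columns: ", paste(missing_cols, collapse = ", ")))
  }
  panel <- as_tibble(panel)
  complete <- stats::complete.cases(panel[needed])
  if (!all(complete)) {
    inform(sprintf(
      "Excluding %d subject(s) with incomplete risk-factor data: %s",
      sum(!complete), paste(panel$subject_id[!complete], collapse = ", ")
    ))
    panel <- panel[complete, , drop = FALSE]
  }
  if (nrow(panel) < 2L) abort("Need at least 2 complete subjects.")
  if (any(panel$hdl <= 0)) abort("HDL must be positive (TC:HDL ratio undefined).")
  lipid <- (zscore(panel$tc / panel$hdl, "tc_hdl") + zscore(panel$tg, "tg")) / 2
  cs <- -(zscore(panel$waist, "waist") + zscore(panel$hba1c, "hba1c") +
            zscore(panel$sbp, "sbp") + lipid) / 4
  tibble(subject_id = panel$subject_id, cs = cs)
}
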
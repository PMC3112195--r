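# Fasting-time correction of non-fasting triglycerides: eligibility window,
# correction subgroup, and the per-hour correction itself.

#' Correction model: per-hour factors and full-fast targets
#'
#' The published per-hour correction factors are 3.7% for the whole
#' population, 4.3% for healthy subjects and 6.5% for severe obesity
#' (BMI > 35), applied until 8 hours of fasting in men and 7 in women.
#'
#' @param factors named per-hour proportions, all in (0, 1), with entries
#'   `all`, `healthy`, `bmi_gt_35`.
#' @param target_fast_hours full-fast hours by sex (positive integers).
#' @param form `"compound"` (default) multiplies by `(1 - factor)^delta`;
#'   `"linear"` divides by `1 + factor * delta`.
#' @return an object of class `correction_model`.
#' @export
correction_model <- function(factors = c(all = 0.037, healthy = 0.043,
                                         bmi_gt_35 = 0.065),
                             target_fast_hours = c(male = 8, female = 7),
                             form = c("compound", "linear")) {
  form <- match.arg(form)
  if (any(factors <= 0 | factors >= 1))
    stop("correction factors must lie strictly in (0, 1)")
  if (!all(c("all", "healthy", "bmi_gt_35") %in% names(factors)))
    stop("`factors` needs entries named all, healthy and bmi_gt_35")
  if (any(target_fast_hours <= 0) ||
      any(target_fast_hours != round(target_fast_hours)))
    stop("`target_fast_hours` must be positive integers")
  structure(list(factors = factors, target_fast_hours = target_fast_hours,
                 form = form),
            class = "correction_model")
}

#' Eligibility rule for the non-fasting visit
#'
#' Subjects are analysed if they reported fasting at least 2 and at most
#' 8 hours (men) or 7 hours (women) at the survey visit, and if serum Tg did
#' not exceed 10 mmol/L at either visit.
#'
#' @param min_fast_hours lower fasting bound, hours (inclusive).
#' @param max_fast_hours_by_sex upper fasting bound by sex (inclusive).
#' @param tg_exclusion_threshold Tg above which a subject is excluded, mmol/L.
#' @return an object of class `eligibility_rule`.
#' @export
eligibility_rule <- function(min_fast_hours = 2,
                             max_fast_hours_by_sex = c(male = 8, female = 7),
                             tg_exclusion_threshold = 10) {
  if (any(min_fast_hours >= max_fast_hours_by_sex))
    stop("`min_fast_hours` must be below each sex's maximum")
  structure(list(min_fast_hours = min_fast_hours,
                 max_fast_hours_by_sex = max_fast_hours_by_sex,
                 tg_exclusion_threshold = tg_exclusion_threshold),
            class = "eligibility_rule")
}

#' Eligibility of each cohort row, with reason codes
#'
#' @param cohort cohort `data.frame` with columns `sex`, `v1_fasting_hours`,
#'   `v1_tg` and `v2_tg`.
#' @param rule an [eligibility_rule()].
#' @return `data.frame` with logical `eligible` and character `reason`, one
#'   of `"ok"`, `"window"` (fasting hours outside the sex-specific window),
#'   `"tg_exclusion"` (Tg above the threshold at either visit) or
#'   `"missing"` (a required field absent).
#' @export
is_eligible <- function(cohort, rule = eligibility_rule()) {
  h <- cohort$v1_fasting_hours
  hi <- rule$max_fast_hours_by_sex[cohort$sex]
  miss <- is.na(h) | is.na(cohort$v1_tg) | is.na(cohort$v2_tg) |
    is.na(cohort$sex)
  window_ok <- !is.na(h) & !is.na(hi) & h >= rule$min_fast_hours & h <= hi
  tg_ok <- !is.na(cohort$v1_tg) & !is.na(cohort$v2_tg) &
    cohort$v1_tg <= rule$tg_exclusion_threshold &
    cohort$v2_tg <= rule$tg_exclusion_threshold
  reason <- rep("ok", nrow(cohort))
  reason[!tg_ok] <- "tg_exclusion"
  reason[!window_ok] <- "window"
  reason[miss] <- "missing"
  data.frame(eligible = reason == "ok", reason = reason,
             stringsAsFactors = FALSE)
}

#' Assign each subject to a correction subgroup
#'
#' Severe obesity (`bmi_gt_35`, BMI > 35) takes precedence. `healthy`
#' requires BMI <= 35, alcohol consumption below the sex-specific 90th
#' percentile, no diagnosed cardiovascular disease, diabetes or cancer, no
#' lipid-lowering medication, and normal blood pressure (below 140/90 mmHg
#' and no antihypertensive treatment). Everyone else is `all`. Missing flags
#' disqualify from `healthy`; a missing BMI cannot be classified and falls
#' back to `all` with a warning.
#'
#' @param cohort cohort `data.frame` (columns `sex`, `bmi`, `alcohol`, the
#'   diagnosis/medication flags, `sbp`, `dbp`).
#' @param alcohol_p90_by_sex named vector of sex-specific 90th percentiles
#'   of alcohol consumption, grams/week; computed from the cohort when `NULL`.
#' @return character vector of `"all"`, `"healthy"`, `"bmi_gt_35"`.
#' @export
assign_subgroup <- function(cohort, alcohol_p90_by_sex = NULL) {
  if (is.null(alcohol_p90_by_sex)) {
    alcohol_p90_by_sex <- vapply(
      c(male = "male", female = "female"),
      function(s) quantile(cohort$alcohol[cohort$sex == s], 0.9,
                           na.rm = TRUE, names = FALSE),
      numeric(1))
  }
  bmi_missing <- is.na(cohort$bmi)
  if (any(bmi_missing))
    warning(sum(bmi_missing),
            " record(s) with missing BMI assigned to subgroup 'all'")
  no_na <- function(x) !is.na(x) & x          # NA counts as disqualifying
  normal_bp <- no_na(cohort$sbp < 140) & no_na(cohort$dbp < 90) &
    no_na(!cohort$bp_treated)
  healthy <- no_na(cohort$bmi <= 35) &
    no_na(cohort$alcohol < alcohol_p90_by_sex[cohort$sex]) &
    no_na(!cohort$cvd_dx) & no_na(!cohort$diabetes_dx) &
    no_na(!cohort$cancer_dx) & no_na(!cohort$lipid_treated) &
    normal_bp
  out <- ifelse(no_na(cohort$bmi > 35), "bmi_gt_35",
                ifelse(healthy, "healthy", "all"))
  out[bmi_missing] <- "all"
  out
}

#' Convert a non-fasting triglyceride to its fasting-equivalent value
#'
#' Applies the per-hour correction over the fasting shortfall
#' `delta = max(0, target - fasting_hours)`: compound form
#' `tg_obs * (1 - factor)^delta`, linear form `tg_obs / (1 + factor * delta)`.
#' Values measured at or beyond the sex-specific full fast are returned
#' unchanged; the correction is never extrapolated past the target.
#'
#' @param tg_obs observed (non-fasting) Tg, mmol/L, strictly positive.
#' @param fasting_hours reported hours since the last meal, whole hours.
#'   Fractional values are rejected unless `allow_fractional = TRUE`, in
#'   which case they are truncated toward zero.
#' @param sex `"male"` / `"female"` vector.
#' @param factor per-hour correction proportion in (0, 1); use the factor of
#'   the subject's subgroup (see [correction_model()], [assign_subgroup()]).
#' @param form `"compound"` or `"linear"`.
#' @param target_fast_hours full-fast hours by sex.
#' @param allow_fractional accept non-integer fasting hours (truncated).
#' @return corrected Tg, mmol/L; always positive and no larger than `tg_obs`.
#' @examples
#' correct_tg(1.18, 5, "male")                    # 1.18 * 0.963^3
#' correct_tg(1.18, 4, "female", form = "linear") # 1.18 / (1 + 0.037 * 3)
#' @export
correct_tg <- function(tg_obs, fasting_hours, sex,
                       factor = 0.037,
                       form = c("compound", "linear"),
                       target_fast_hours = c(male = 8, female = 7),
                       allow_fractional = FALSE) {
  form <- match.arg(form)
  if (any(tg_obs <= 0, na.rm = TRUE))
    stop("`tg_obs` must be strictly positive")
  if (any(factor <= 0 | factor >= 1))
    stop("correction `factor` must lie strictly in (0, 1)")
  frac <- !is.na(fasting_hours) & fasting_hours != trunc(fasting_hours)
  if (any(frac)) {
    if (!allow_fractional)
      stop("`fasting_hours` must be whole hours; ",
           "set allow_fractional = TRUE to truncate")
    message(sum(frac), " fractional fasting-hour value(s) truncated")
    fasting_hours <- trunc(fasting_hours)
  }
  delta <- pmax(0, target_fast_hours[sex] - fasting_hours)
  out <- switch(form,
                compound = tg_obs * (1 - factor)^delta,
                linear   = tg_obs / (1 + factor * delta))
  unname(out)
}

#' Correct the visit-1 triglycerides of a whole cohort
#'
#' Assigns each subject a correction subgroup, looks up the subgroup's
#' per-hour factor, and applies [correct_tg()] to the visit-1 Tg.
#'
#' @param cohort cohort `data.frame`.
#' @param model a [correction_model()].
#' @param subgroup optional precomputed subgroup labels; computed with
#'   [assign_subgroup()] when `NULL`.
#' @return the cohort with columns `subgroup` and `tg_corrected` added.
#' @export
correct_cohort <- function(cohort, model = correction_model(),
                           subgroup = NULL) {
  if (!inherits(model, "correction_model"))
    stop("`model` must be created by correction_model()")
  if (is.null(subgroup)) subgroup <- assign_subgroup(cohort)
  cohort$subgroup <- subgroup
  cohort$tg_corrected <- correct_tg(
    cohort$v1_tg, cohort$v1_fasting_hours, cohort$sex,
    factor = unname(model$factors[subgroup]),
    form = model$form,
    target_fast_hours = model$target_fast_hours)
  cohort
}
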
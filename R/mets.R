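# Metabolic syndrome classification under three guideline definitions:
# MS-ATP (NCEP ATP III, 2005 revision), MS-IDF (IDF 2005, waist mandatory)
# and MS-IDFTF (2009 harmonized Task Force definition).

#' Threshold sets for the three metabolic syndrome definitions
#'
#' Shared component cut-offs: Tg >= 1.7 mmol/L, HDL-C < 1.03 (men) /
#' < 1.30 (women) mmol/L, blood pressure >= 130 systolic or >= 85 diastolic,
#' fasting glucose >= 5.6 mmol/L; drug treatment counts as positive for the
#' corresponding component (lipid-lowering medication for the Tg and HDL
#' components, antihypertensives for blood pressure, diagnosed diabetes for
#' glucose). The definitions differ in the waist component:
#' \describe{
#'   \item{MS-ATP}{waist > 102 cm (men) / > 88 cm (women), strict; any 3 of
#'     5 components.}
#'   \item{MS-IDF}{waist >= 94 / >= 80 cm (Europid), mandatory, plus at
#'     least 2 of the other 4.}
#'   \item{MS-IDFTF}{waist >= 94 / >= 80 cm (European), any 3 of 5.}
#' }
#'
#' @param name `"atp"`, `"idf"` or `"idftf"`.
#' @param waist_cut,waist_strict,waist_mandatory,tg_cut,hdl_cut,sbp_cut,dbp_cut,glucose_cut,n_required
#'   overrides for individual thresholds, so alternative dialects (other
#'   ethnicity-specific waist cuts, stricter glucose) remain testable.
#' @return an object of class `mets_thresholds`.
#' @export
mets_thresholds <- function(name = c("atp", "idf", "idftf"),
                            waist_cut = NULL, waist_strict = NULL,
                            waist_mandatory = NULL,
                            tg_cut = 1.7,
                            hdl_cut = c(male = 1.03, female = 1.30),
                            sbp_cut = 130, dbp_cut = 85,
                            glucose_cut = 5.6, n_required = 3) {
  name <- match.arg(name)
  defaults <- switch(name,
    atp   = list(label = "MS-ATP", waist_cut = c(male = 102, female = 88),
                 waist_strict = TRUE, waist_mandatory = FALSE),
    idf   = list(label = "MS-IDF", waist_cut = c(male = 94, female = 80),
                 waist_strict = FALSE, waist_mandatory = TRUE),
    idftf = list(label = "MS-IDFTF", waist_cut = c(male = 94, female = 80),
                 waist_strict = FALSE, waist_mandatory = FALSE))
  th <- list(
    name = defaults$label,
    waist_cut = if (is.null(waist_cut)) defaults$waist_cut else waist_cut,
    waist_strict = if (is.null(waist_strict)) defaults$waist_strict
                   else waist_strict,
    waist_mandatory = if (is.null(waist_mandatory)) defaults$waist_mandatory
                      else waist_mandatory,
    tg_cut = tg_cut, hdl_cut = hdl_cut,
    sbp_cut = sbp_cut, dbp_cut = dbp_cut,
    glucose_cut = glucose_cut, n_required = n_required)
  if (th$n_required < 2 || th$n_required > 5)
    stop("`n_required` must lie in 2..5")
  if (any(unlist(th[c("waist_cut", "tg_cut", "hdl_cut", "sbp_cut",
                      "dbp_cut", "glucose_cut")]) <= 0))
    stop("all cut-offs must be positive")
  structure(th, class = "mets_thresholds")
}

#' Classify metabolic syndrome with an explicitly supplied triglyceride
#'
#' The Tg value is passed separately from the cohort row so that the three
#' Tg treatments (raw non-fasting, fasting-time-corrected, true fasting) can
#' be compared on otherwise identical covariates. HDL-C likewise defaults to
#' the fasting-visit value, and glucose is the fasting measurement, so only
#' the Tg component differs between treatments.
#'
#' Missing components are resolved as early as the outcome is forced: a
#' subject with enough positive components is positive even if others are
#' missing, and negative when the missing components could no longer reach
#' the required count; otherwise the status is `NA`.
#'
#' @param cohort cohort `data.frame` (columns `sex`, `waist`, `sbp`, `dbp`,
#'   `glucose_fasting`, `bp_treated`, `lipid_treated`, `diabetes_dx`).
#' @param tg_value triglyceride vector, mmol/L (recycled if length 1).
#' @param thresholds a [mets_thresholds()] object.
#' @param hdl_value HDL-C vector, mmol/L; defaults to the fasting visit's.
#' @return `data.frame` with the five logical components (`waist_pos`,
#'   `tg_pos`, `hdl_pos`, `bp_pos`, `glucose_pos`), `n_positive`,
#'   `n_missing`, and the logical `status`.
#' @examples
#' coh <- generate_cohort(cohort_config(n_subjects = 5, seed = 1))
#' classify_mets(coh, coh$v2_tg, mets_thresholds("atp"))$status
#' @export
classify_mets <- function(cohort, tg_value, thresholds = mets_thresholds("atp"),
                          hdl_value = cohort$v2_hdl_chol) {
  if (!inherits(thresholds, "mets_thresholds"))
    stop("`thresholds` must be created by mets_thresholds()")
  n <- nrow(cohort)
  tg_value <- rep_len(tg_value, n)
  hdl_value <- rep_len(hdl_value, n)
  wcut <- thresholds$waist_cut[cohort$sex]
  waist_pos <- if (thresholds$waist_strict) cohort$waist > wcut
               else cohort$waist >= wcut
  # `|` keeps NA | TRUE == TRUE: drug treatment decides even if the
  # measurement is missing
  tg_pos <- (tg_value >= thresholds$tg_cut) | cohort$lipid_treated
  hdl_pos <- (hdl_value < thresholds$hdl_cut[cohort$sex]) |
    cohort$lipid_treated
  bp_pos <- (cohort$sbp >= thresholds$sbp_cut) |
    (cohort$dbp >= thresholds$dbp_cut) | cohort$bp_treated
  glucose_pos <- (cohort$glucose_fasting >= thresholds$glucose_cut) |
    cohort$diabetes_dx

  comp <- cbind(waist_pos, tg_pos, hdl_pos, bp_pos, glucose_pos)
  n_pos <- rowSums(comp, na.rm = TRUE)
  n_miss <- rowSums(is.na(comp))

  if (!thresholds$waist_mandatory) {
    req <- thresholds$n_required
    status <- ifelse(n_pos >= req, TRUE,
                     ifelse(n_pos + n_miss < req, FALSE, NA))
  } else {
    others <- comp[, -1, drop = FALSE]
    pos_o <- rowSums(others, na.rm = TRUE)
    miss_o <- rowSums(is.na(others))
    status <- rep(NA, n)
    status[pos_o + miss_o < 2] <- FALSE              # others can't reach 2
    status[!is.na(waist_pos) & !waist_pos] <- FALSE  # mandatory waist fails
    forced_pos <- !is.na(waist_pos) & waist_pos & pos_o >= 2
    status[forced_pos] <- TRUE
  }
  data.frame(waist_pos = unname(waist_pos), tg_pos = unname(tg_pos),
             hdl_pos = unname(hdl_pos), bp_pos = unname(bp_pos),
             glucose_pos = unname(glucose_pos),
             n_positive = unname(n_pos), n_missing = unname(n_miss),
             status = unname(status))
}

#' Metabolic syndrome prevalence under one triglyceride treatment
#'
#' @param cohort cohort `data.frame`; `tg_source = "visit1_corrected"`
#'   requires the `tg_corrected` column added by [correct_cohort()].
#' @param tg_source which Tg enters the classification: `"visit1_raw"`
#'   (non-fasting), `"visit1_corrected"`, or `"visit2"` (true fasting).
#' @param thresholds a [mets_thresholds()] object.
#' @return list with `label`, `tg_source`, `prevalence` (percent of
#'   decidable subjects), `n_positive`, `n_decidable`, `n_total`. The
#'   denominator is always reported alongside the prevalence.
#' @export
mets_prevalence <- function(cohort, tg_source = c("visit1_raw",
                                                  "visit1_corrected",
                                                  "visit2"),
                            thresholds = mets_thresholds("atp")) {
  tg_source <- match.arg(tg_source)
  tg <- switch(tg_source,
               visit1_raw = cohort$v1_tg,
               visit1_corrected = cohort$tg_corrected,
               visit2 = cohort$v2_tg)
  if (is.null(tg))
    stop("cohort lacks the Tg column for source '", tg_source, "'")
  status <- classify_mets(cohort, tg, thresholds)$status
  n_dec <- sum(!is.na(status))
  if (n_dec == 0) stop("no decidable subjects: prevalence undefined")
  list(label = thresholds$name, tg_source = tg_source,
       prevalence = 100 * sum(status, na.rm = TRUE) / n_dec,
       n_positive = sum(status, na.rm = TRUE),
       n_decidable = n_dec, n_total = length(status))
}
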
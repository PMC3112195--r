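# Friedewald LDL-cholesterol and the high-LDL-C classification.

#' Calculated LDL-cholesterol by the Friedewald formula
#'
#' `LDL-C = total cholesterol - HDL-C - Tg / 2.2` (all mmol/L). The formula
#' is not applied above a triglyceride validity limit (default 4.5 mmol/L),
#' and a negative computed value is flagged invalid rather than clamped — it
#' is an arithmetic artifact, not a concentration.
#'
#' @param total_chol,hdl_chol,tg serum concentrations, mmol/L. Vectorised;
#'   `NA` inputs yield reason `"missing_input"`.
#' @param tg_limit triglyceride validity limit, mmol/L.
#' @return `data.frame` with columns `ldl` (mmol/L, `NA` when invalid),
#'   logical `valid`, and `reason` in `"ok"`, `"tg_too_high"`,
#'   `"negative_result"`, `"missing_input"`.
#' @examples
#' friedewald_ldl(5.5, 1.3, 2.2)  # 3.2 mmol/L
#' friedewald_ldl(5.5, 1.3, 5.0)  # invalid: Tg above the limit
#' @export
friedewald_ldl <- function(total_chol, hdl_chol, tg, tg_limit = 4.5) {
  if (any(total_chol < 0 | hdl_chol < 0 | tg < 0, na.rm = TRUE))
    stop("concentrations must be non-negative")
  n <- max(length(total_chol), length(hdl_chol), length(tg))
  total_chol <- rep_len(total_chol, n)
  hdl_chol <- rep_len(hdl_chol, n)
  tg <- rep_len(tg, n)
  ldl_raw <- total_chol - hdl_chol - tg / 2.2
  reason <- rep("ok", n)
  reason[!is.na(ldl_raw) & ldl_raw < 0] <- "negative_result"
  reason[!is.na(tg) & tg > tg_limit] <- "tg_too_high"
  reason[is.na(total_chol) | is.na(hdl_chol) | is.na(tg)] <- "missing_input"
  valid <- reason == "ok"
  data.frame(ldl = ifelse(valid, ldl_raw, NA_real_),
             valid = valid, reason = reason, stringsAsFactors = FALSE)
}

#' Classify high LDL-cholesterol
#'
#' High LDL-C is a calculated LDL-C at or above the cut-off (boundary
#' inclusive, default 3.00 mmol/L). Invalid LDL results propagate as `NA`.
#'
#' @param ldl_result a `data.frame` from [friedewald_ldl()], or a bare
#'   numeric vector of LDL-C values.
#' @param cutoff decision threshold, mmol/L.
#' @return logical vector (`NA` where LDL-C is unavailable).
#' @export
classify_high_ldl <- function(ldl_result, cutoff = 3.00) {
  if (is.data.frame(ldl_result)) {
    ifelse(ldl_result$valid, ldl_result$ldl >= cutoff, NA)
  } else {
    ldl_result >= cutoff
  }
}
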
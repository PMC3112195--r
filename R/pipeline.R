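# Pipeline orchestration: cohort IO, run configuration, and the full
# simulate -> correct -> LDL -> MetS -> agreement run.

.cohort_required_cols <- c(
  "subject_id", "sex", "age", "bmi", "waist", "sbp", "dbp",
  "glucose_fasting", "bp_treated", "lipid_treated", "diabetes_dx",
  "cvd_dx", "cancer_dx", "alcohol",
  "v1_total_chol", "v1_hdl_chol", "v1_tg", "v1_fasting_hours",
  "v2_total_chol", "v2_hdl_chol", "v2_tg", "v2_fasting_hours")

#' Read and write cohort tables
#'
#' The on-disk format is comma-separated text with a header row, UTF-8,
#' `.` decimal separator, one row per subject with both visits' lipid panels
#' in wide format (`v1_*`, `v2_*` columns). Missing values are empty fields;
#' no sentinel numbers. Unknown extra columns are preserved. Writing then
#' reading a cohort reproduces all documented fields.
#'
#' @param path file path.
#' @param cohort cohort `data.frame`.
#' @return `read_cohort()` returns the cohort `data.frame`;
#'   `write_cohort()` returns `path` invisibly.
#' @export
read_cohort <- function(path) {
  df <- read.csv(path, na.strings = "", stringsAsFactors = FALSE,
                 fileEncoding = "UTF-8")
  missing_cols <- setdiff(.cohort_required_cols, names(df))
  if (length(missing_cols))
    stop("cohort file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  num_cols <- setdiff(.cohort_required_cols, c("subject_id", "sex"))
  for (cl in num_cols) {
    v <- df[[cl]]
    if (cl %in% c("bp_treated", "lipid_treated", "diabetes_dx",
                  "cvd_dx", "cancer_dx")) {
      df[[cl]] <- as.logical(v)
    } else if (!is.numeric(v)) {
      conv <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(conv))
      if (length(bad))
        stop("malformed numeric field '", cl, "' in ", path,
             " at data line(s) ", paste(utils::head(bad, 5), collapse = ", "))
      df[[cl]] <- conv
    }
  }
  df$subject_id <- as.character(df$subject_id)
  df
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "",
            fileEncoding = "UTF-8")
  invisible(path)
}

#' Configuration of a full pipeline run
#'
#' Bundles every tunable of the pipeline; all thresholds default to the
#' published values (per-hour correction factors 3.7/4.3/6.5%, full fast
#' 8 h men / 7 h women, Tg exclusion 10 mmol/L, LDL-C cut-off 3.00 mmol/L,
#' Friedewald validity limit 4.5 mmol/L, guideline MetS cuts).
#'
#' @param cohort a [cohort_config()]; its `seed` drives all randomness.
#' @param correction a [correction_model()].
#' @param eligibility an [eligibility_rule()].
#' @param ldl_cutoff high-LDL-C decision threshold, mmol/L.
#' @param ldl_tg_limit Friedewald triglyceride validity limit, mmol/L.
#' @param criteria character vector of MetS criteria names to evaluate.
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            correction = correction_model(),
                            eligibility = eligibility_rule(),
                            ldl_cutoff = 3.00,
                            ldl_tg_limit = 4.5,
                            criteria = c("atp", "idf", "idftf")) {
  criteria <- match.arg(criteria, several.ok = TRUE)
  structure(list(cohort = cohort, correction = correction,
                 eligibility = eligibility, ldl_cutoff = ldl_cutoff,
                 ldl_tg_limit = ldl_tg_limit, criteria = criteria),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file mirrors [pipeline_config()]: top-level keys `cohort`,
#' `correction`, `eligibility`, `ldl_cutoff`, `ldl_tg_limit`, `criteria`,
#' each holding the corresponding constructor's arguments (sex-keyed values
#' as `male:`/`female:` maps). Omitted keys keep their defaults.
#'
#' @param path YAML file path.
#' @param seed optional seed overriding the file's `cohort: seed`.
#' @return a `pipeline_config` object.
#' @export
read_run_config <- function(path, seed = NULL) {
  y <- yaml::read_yaml(path)
  named <- function(x) if (is.list(x)) unlist(x) else x
  coh_args <- y$cohort
  if (!is.null(coh_args)) {
    for (k in c("fasting_hours_visit1", "target_fast_hours"))
      if (!is.null(coh_args[[k]])) coh_args[[k]] <- named(coh_args[[k]])
    if (!is.null(coh_args$covariates))
      coh_args$covariates <- modifyList(covariate_defaults(),
                                        lapply(coh_args$covariates, named))
  }
  if (!is.null(seed)) coh_args$seed <- seed
  cor_args <- y$correction
  if (!is.null(cor_args))
    for (k in c("factors", "target_fast_hours"))
      if (!is.null(cor_args[[k]])) cor_args[[k]] <- named(cor_args[[k]])
  eli_args <- y$eligibility
  if (!is.null(eli_args) && !is.null(eli_args$max_fast_hours_by_sex))
    eli_args$max_fast_hours_by_sex <- named(eli_args$max_fast_hours_by_sex)
  args <- list(cohort = do.call(cohort_config, as.list(coh_args)),
               correction = do.call(correction_model, as.list(cor_args)),
               eligibility = do.call(eligibility_rule, as.list(eli_args)))
  for (k in c("ldl_cutoff", "ldl_tg_limit", "criteria"))
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  do.call(pipeline_config, args)
}

prevalence_block <- function(status_by_source) {
  counts <- lapply(status_by_source, function(s)
    list(n_positive = sum(s, na.rm = TRUE),
         n_decidable = sum(!is.na(s))))
  prev <- vapply(counts, function(cn)
    100 * cn$n_positive / cn$n_decidable, numeric(1))
  pairs <- list(c("visit1_raw", "visit2"),
                c("visit1_corrected", "visit2"),
                c("visit1_raw", "visit1_corrected"))
  diffs <- list(); tests <- list()
  for (p in pairs) {
    key <- paste(p, collapse = "_vs_")
    diffs[[key]] <- prev[[p[1]]] - prev[[p[2]]]
    tests[[key]] <- chi2_prevalence(
      counts[[p[1]]]$n_positive, counts[[p[1]]]$n_decidable,
      counts[[p[2]]]$n_positive, counts[[p[2]]]$n_decidable)$p_value
  }
  list(prevalences = as.list(prev), counts = counts,
       pairwise_diff_pp = diffs, test_p = tests)
}

#' Run the full analysis pipeline
#'
#' Simulates (or takes) a paired-visit cohort, applies the eligibility
#' window, assigns correction subgroups, corrects the visit-1 triglycerides,
#' computes Friedewald LDL-C and high-LDL-C status and metabolic syndrome
#' status under each requested criteria set for all three Tg treatments, and
#' assembles the agreement statistics: Tg distribution summaries, the
#' Bland-Altman comparison of corrected vs. true-fasting Tg, duplicate-based
#' CVs, Wilcoxon signed-rank p-values, prevalences with pairwise differences
#' and chi-square p-values. Deterministic given the cohort seed.
#'
#' @param config a [pipeline_config()].
#' @param cohort optional pre-built cohort `data.frame`; when `NULL` one is
#'   generated from `config$cohort`.
#' @param out_dir optional directory; when given, the eligible analysis
#'   table (`analysis.csv`), the full cohort (`cohort.csv`) and the report
#'   (`report.json`) are written there.
#' @param verbose emit per-stage record counts with [message()].
#' @return list with `cohort` (all generated rows), `analysis` (eligible
#'   rows with `subgroup`, `tg_corrected`, LDL and status columns added),
#'   and `report` (nested list of all summary statistics).
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         out_dir = NULL, verbose = FALSE) {
  if (!inherits(config, "pipeline_config"))
    stop("`config` must be created by pipeline_config()")
  say <- function(...) if (verbose) message(...)

  if (is.null(cohort)) cohort <- generate_cohort(config$cohort)
  say("generated: ", nrow(cohort), " subjects")

  elig <- is_eligible(cohort, config$eligibility)
  excl <- table(elig$reason[!elig$eligible])
  say("eligible: ", sum(elig$eligible), "; excluded: ",
      paste(sprintf("%s=%d", names(excl), excl), collapse = ", "))
  an <- cohort[elig$eligible, , drop = FALSE]
  if (!nrow(an)) stop("pipeline stage 'eligibility': no eligible subjects")

  an <- correct_cohort(an, config$correction)

  ldl_of <- function(tc, hdl, tg) friedewald_ldl(tc, hdl, tg,
                                                 tg_limit = config$ldl_tg_limit)
  ldl_raw <- ldl_of(an$v1_total_chol, an$v1_hdl_chol, an$v1_tg)
  ldl_cor <- ldl_of(an$v1_total_chol, an$v1_hdl_chol, an$tg_corrected)
  ldl_v2 <- ldl_of(an$v2_total_chol, an$v2_hdl_chol, an$v2_tg)
  an$ldl_visit1_raw <- ldl_raw$ldl
  an$ldl_visit1_corrected <- ldl_cor$ldl
  an$ldl_visit2 <- ldl_v2$ldl
  an$high_ldl_visit1_raw <- classify_high_ldl(ldl_raw, config$ldl_cutoff)
  an$high_ldl_visit1_corrected <- classify_high_ldl(ldl_cor, config$ldl_cutoff)
  an$high_ldl_visit2 <- classify_high_ldl(ldl_v2, config$ldl_cutoff)

  tg_cols <- c(visit1_raw = "v1_tg", visit1_corrected = "tg_corrected",
               visit2 = "v2_tg")
  mets_status <- list()
  for (cr in config$criteria) {
    th <- mets_thresholds(cr)
    for (src in names(tg_cols)) {
      st <- classify_mets(an, an[[tg_cols[src]]], th)$status
      an[[paste0("mets_", cr, "_", src)]] <- st
      mets_status[[cr]][[src]] <- st
    }
  }

  report <- list(
    seed = config$cohort$seed,
    n_generated = nrow(cohort),
    n_eligible = nrow(an),
    excluded = as.list(excl),
    subgroups = as.list(table(an$subgroup)),
    tg_summary = lapply(tg_cols, function(cl)
      as.list(quantile_summary(an[[cl]]))),
    wilcoxon_p = list(
      visit1_raw_vs_visit2 =
        wilcoxon_signed_rank(an$v1_tg, an$v2_tg)$p_value,
      visit1_corrected_vs_visit2 =
        wilcoxon_signed_rank(an$tg_corrected, an$v2_tg)$p_value),
    bland_altman = local({
      ba <- bland_altman(an$tg_corrected, an$v2_tg)
      ba[c("bias", "sd_d", "loa_low", "loa_high", "ci_bias",
           "ci_loa_low", "ci_loa_high", "n", "denominator_mode")]
    }),
    cv = list(
      visit1_raw_vs_visit2 =
        unclass(duplicate_cv(an$v1_tg, an$v2_tg, config$cohort$cv_anal)),
      visit1_corrected_vs_visit2 =
        unclass(duplicate_cv(an$tg_corrected, an$v2_tg,
                             config$cohort$cv_anal))),
    prevalence = c(
      list(high_ldl = prevalence_block(list(
        visit1_raw = an$high_ldl_visit1_raw,
        visit1_corrected = an$high_ldl_visit1_corrected,
        visit2 = an$high_ldl_visit2))),
      lapply(mets_status, prevalence_block))
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    write_cohort(an, file.path(out_dir, "analysis.csv"))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    say("wrote cohort.csv, analysis.csv, report.json to ", out_dir)
  }
  list(cohort = cohort, analysis = an, report = report)
}
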
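# tgcorrect

Fasting-time correction of non-fasting serum triglycerides, and its effect
on lipid and metabolic syndrome classification in population surveys.

## The problem

Large health examination surveys usually cannot obtain fully fasting blood
samples; participants report 2–8 hours since their last meal. Serum
triglyceride (Tg) is elevated after meals, which biases two standard
survey endpoints computed from it:

* **Friedewald LDL-cholesterol**, `LDL-C = TC − HDL-C − Tg/2.2` (mmol/L):
  an elevated Tg *lowers* calculated LDL-C, so a non-fasting survey
  under-counts people with LDL-C ≥ 3.00 mmol/L.
* **Metabolic syndrome**: the Tg ≥ 1.7 mmol/L component turns positive too
  often, so a non-fasting survey *over*-counts the syndrome.

`tgcorrect` converts each non-fasting Tg to a fasting-equivalent value with
published per-hour correction factors,

    tg_corrected = tg_obs × (1 − f)^Δ,   Δ = max(0, target − hours fasted)

with `f` = 3.7%/h (whole population), 4.3%/h (healthy subgroup), 6.5%/h
(BMI > 35), and a full-fast target of 8 h for men and 7 h for women (a
linear form `tg_obs / (1 + fΔ)` is also available). It then recomputes
LDL-C and metabolic syndrome status under three guideline definitions
(NCEP ATP III 2005, IDF 2005, harmonized 2009) for the raw, corrected and
true-fasting Tg, and quantifies agreement and misclassification:
Bland-Altman bias with 95% limits of agreement, duplicate-based
intraindividual CV with the decomposition `CV_tb² = CV_anal² + CV_biol²`,
Wilcoxon signed-rank and chi-square comparisons, and prevalence differences
in percentage points.

A synthetic paired-visit cohort generator with known latent fasting Tg
makes the whole pipeline testable end to end; no individual-level survey
data are required or included.

## Worked example

```r
library(tgcorrect)

# one subject: 1.18 mmol/L measured after a 5 h fast (male, 3 h short)
correct_tg(1.18, 5, "male")
#> [1] 1.053806

friedewald_ldl(5.5, 1.3, 2.2)
#>   ldl valid reason
#> 1 3.2  TRUE     ok

# full pipeline on a simulated survey of 10,000 subjects
cfg <- pipeline_config(cohort = cohort_config(n_subjects = 10000, seed = 1))
rep <- run_pipeline(cfg)$report

round(unlist(rep$prevalence$atp$prevalences), 1)
#>       visit1_raw visit1_corrected           visit2
#>             37.8             35.7             36.0
```

Reading the output: under the MS-ATP definition the non-fasting visit
overstates the true-fasting metabolic syndrome prevalence (36.0%) by 1.8
percentage points, and the correction shrinks that misclassification to
0.3 points — the qualitative result the method exists to deliver. The same
report carries the high-LDL-C prevalences (here 52.3% raw / 54.9%
corrected / 54.0% fasting: the raw deficit of 1.7 points shrinks to 0.9),
the Tg distribution summaries, Wilcoxon and chi-square p-values, the
duplicate-based CVs (total ≈ 17% between visits months apart), and the
Bland-Altman comparison of corrected vs. true-fasting Tg:

```r
rep$bland_altman$bias          # +3.8% with the true-fasting denominator
rep$cv$visit1_corrected_vs_visit2$cv_tb_mean   # 16.8
```

The methods vignette (`vignettes/fasting-tg-correction.Rmd`) explains the
model, the generator's calibration, and why a positive Bland-Altman bias
of a few percent appears even under a perfectly matched correction.

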
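# Shared fixtures and independent oracles for the test suite.

# Small cohort configuration shortcut.
quick_config <- function(n = 200, seed = 1, ...) {
  cohort_config(n_subjects = n, seed = seed, ...)
}

# Configuration with every noise source switched off, so observed values are
# deterministic functions of the latent fasting Tg.
zero_noise_config <- function(n = 200, seed = 1, ...) {
  cov <- covariate_defaults()
  cov$chol_cv_biol <- 0
  cohort_config(n_subjects = n, seed = seed, cv_biol = 0, cv_anal = 0,
                covariates = cov, ...)
}

# One-row cohort data.frame with explicit covariates, for hand-constructed
# metabolic syndrome cases.
make_subject <- function(sex = "male", waist = 100, sbp = 120, dbp = 75,
                         glucose = 5.0, hdl = 1.5,
                         bp_treated = FALSE, lipid_treated = FALSE,
                         diabetes_dx = FALSE) {
  data.frame(sex = sex, waist = waist, sbp = sbp, dbp = dbp,
             glucose_fasting = glucose, v2_hdl_chol = hdl,
             bp_treated = bp_treated, lipid_treated = lipid_treated,
             diabetes_dx = diabetes_dx, stringsAsFactors = FALSE)
}

# Independent oracle: exact two-sided signed-rank p-value by exhaustive
# enumeration of all 2^n sign assignments (symmetric-tail definition; the
# null distribution of W is symmetric about n(n+1)/4).
wilcoxon_exact_enum <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  W <- as.vector(signs %*% r)
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  mean(abs(W - mu) >= abs(w - mu) - 1e-9)
}
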
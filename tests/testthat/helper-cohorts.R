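## Shared fixture builders: everything is generated in code at test time.

## Included (filtered) synthetic cohort for one sex stratum.
gen_included <- function(sex, n, seed, null = FALSE, ...) {
  cfg <- cohort_config(sex, n = n, seed = seed, ...)
  coh <- if (null) generate_null_cohort(cfg) else generate_cohort(cfg)
  apply_inclusion(coh)
}

## Fast fit of the known true male structure (no selection).
fit_male_fixed <- function(coh) {
  mfp_logit(died ~ fp(bmi, powers = c(-2, -2)) + fp(age, powers = 2) +
              ever_smoker,
            data = coh, weights = weight)
}

## Full MFP selection fit with the study's default formula.
fit_mfp_default <- function(coh, alpha = 0.05) {
  mfp_logit(died ~ fp(bmi, degree = 2) + fp(age, degree = 1) + ever_smoker,
            data = coh, weights = weight, alpha = alpha)
}
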
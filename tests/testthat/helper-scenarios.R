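# Shared simulation scenarios and analysis formulas used across test files.

# Fixed exposure contrast (25th/75th percentile of the default exposure
# distribution, precomputed) so estimators and truth oracles share the units.
STUDY_CONTRAST <- c(105.16, 122.69)
STUDY_DELTA <- diff(STUDY_CONTRAST)

FULL_FORMULA <- outcome ~ exposure_o3 + maternal_age_y + infant_sex +
  temperature_c + occupation + gestational_diabetes + husband_smoking

# parameter-recovery scenario: planted total effect 1.5 per IQR contrast,
# proportion mediated ~20%, outcome prevalence 1%
cfg_recovery <- function(n, seed) {
  sim_config(
    n_subjects = n, seed = seed,
    mediator = list(exposure = 0.03793),
    outcome = list(mediator = log(6.499),
                   exposure = log(1.5^0.8) / STUDY_DELTA,
                   prevalence = 0.01)
  )
}

# bootstrap-coverage scenario: same planted effects with null covariate
# slopes, so the crude exposure-only analysis model is exactly specified
# and each replicate is cheap
cfg_coverage <- function(n, seed) {
  sim_config(
    n_subjects = n, seed = seed,
    mediator = list(exposure = 0.03793, covariates = c(maternal_age_c = 0)),
    outcome = list(mediator = log(6.499),
                   exposure = log(1.5^0.8) / STUDY_DELTA,
                   prevalence = 0.01,
                   covariates = c(maternal_age_c = 0))
  )
}

# covariate-driven-selection scenario for the weighting bias-reduction check:
# temperature drives selection, is correlated with exposure (r = 0.75), and
# affects the outcome, so the crude complete-case estimate is biased while
# moderate selection keeps the 99th-percentile weight cap benign
cfg_selection_bias <- function(n, seed) {
  sim_config(
    n_subjects = n, seed = seed,
    outcome = list(covariates = c(maternal_age_c = -0.005, female = 0.47,
                                  gdm = -0.25, temperature_c = 0.25),
                   prevalence = 0.10),
    selection = list(intercept = 0.0, covariates = c(temperature_c = -0.5))
  )
}

# a single fixed covariate row for conditional (closed-form) evaluations
fixed_covariate_row <- function() {
  data.frame(maternal_age_y = 30, infant_sex = "male", occupation = "clerk",
             gestational_diabetes = 0L, husband_smoking = 0L,
             temperature_c = 14.58, stringsAsFactors = FALSE)
}
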
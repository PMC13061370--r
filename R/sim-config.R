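# Covariate design columns shared by the generative and analysis models.
# Continuous covariates enter centered so intercepts are interpretable as
# log-odds at the reference covariate pattern.
COVARIATE_TERMS <- c(
  "maternal_age_c", "female",
  "occ_farmer", "occ_housewife", "occ_worker", "occ_other",
  "gdm", "husband_smoking", "temperature_c"
)

#' Simulation configuration for a synthetic birth cohort
#'
#' Builds the full generative specification used by [generate_cohort()]:
#' a truncated-normal whole-pregnancy ozone exposure correlated with
#' pregnancy-mean temperature, demographic covariates, a logistic model for
#' the binary mediator (gestational hypertension), a logistic model for the
#' rare binary outcome (term low birth weight) with optional
#' exposure-mediator interaction, auxiliary birth weight / gestational age
#' models, and a logistic selection (inclusion) model.
#'
#' Defaults emulate a large Chinese registry birth cohort: exposure mean
#' 113.90 and SD 13.03 ug/m3 supported on \[62.35, 157.58\], mediator
#' prevalence 3.05\%, outcome prevalence 0.89\%, a mediator odds ratio of
#' 1.162 per IQR (19.93 ug/m3) of ozone, a mediator-outcome odds ratio of
#' 6.499, and a direct exposure-outcome odds ratio of 1.034 per IQR.
#' Model intercepts are calibrated numerically at construction so that the
#' analytic prevalences (the average of the inverse-logit over the covariate
#' distribution) match the configured targets.
#'
#' @param n_subjects number of births to generate.
#' @param seed root seed; all generator stages derive child seeds from it.
#' @param exposure,covariates,mediator,outcome,birthweight,gestational_age,selection,daily_series
#'   named lists overriding entries of the corresponding default component
#'   (see Details in the package vignette); unnamed entries are an error.
#' @param calibrate_intercepts if `TRUE` (default), solve the mediator and
#'   outcome intercepts to hit the configured target prevalences; if `FALSE`
#'   the intercepts supplied in `mediator$intercept` / `outcome$intercept`
#'   are used as-is.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 10000L, seed = 1L,
                       exposure = list(), covariates = list(),
                       mediator = list(), outcome = list(),
                       birthweight = list(), gestational_age = list(),
                       selection = list(), daily_series = list(),
                       calibrate_intercepts = TRUE) {
  iqr_ref <- 19.93  # reference IQR (ug/m3) used to express planted per-IQR effects

  cfg <- list(
    n_subjects = n_subjects,
    seed = seed,
    exposure = list(
      mean = 113.90, sd = 13.03, min = 62.35, max = 157.58,
      temperature_cor = 0.75
    ),
    covariates = list(
      maternal_age = list(mean = 30.0, sd = 4.8, min = 20, max = 45),
      p_female = 0.476,
      occupation = c(clerk = 0.166, farmer = 0.330, housewife = 0.110,
                     worker = 0.065, other = 0.329),
      p_gdm = 0.103,
      p_husband_smoking = 0.034,
      temperature = list(mean = 14.58, sd = 3.06)
    ),
    mediator = list(
      intercept = NA_real_,
      exposure = log(1.162) / iqr_ref,
      covariates = c(maternal_age_c = 0.04, occ_farmer = 0.05,
                     occ_housewife = 0.05, gdm = 0.45,
                     husband_smoking = 0.05, temperature_c = -0.01),
      prevalence = 103443 / 3394739
    ),
    outcome = list(
      intercept = NA_real_,
      exposure = log(1.034) / iqr_ref,
      mediator = log(6.499),
      interaction = 0,
      covariates = c(maternal_age_c = -0.005, female = 0.47,
                     occ_farmer = 0.05, occ_housewife = 0.10,
                     occ_worker = -0.05, gdm = -0.25,
                     husband_smoking = 0.08, temperature_c = 0.01),
      prevalence = 30145 / 3394739
    ),
    birthweight = list(mean = 3350, sd = 420, exposure_slope = -0.5,
                       mediator_shift = -150),
    gestational_age = list(mean = 39.0, sd = 1.1, min = 30, max = 45),
    selection = list(
      intercept = 1.0,
      covariates = c(maternal_age_c = -0.01, female = 0.02,
                     gdm = -0.05, husband_smoking = -0.05)
    ),
    daily_series = list(enabled = FALSE, season_amplitude = 20,
                        ar1_coefficient = 0.6, daily_noise_sd = 10)
  )

  merge_component <- function(name, user) {
    if (length(user) == 0L) return(invisible())
    if (is.null(names(user)) || any(names(user) == ""))
      stop_config(name, "overrides must be a fully named list")
    bad <- setdiff(names(user), names(cfg[[name]]))
    if (length(bad))
      stop_config(name, paste("unknown entries:", paste(bad, collapse = ", ")))
    cfg[[name]] <<- utils::modifyList(cfg[[name]], user)
  }
  merge_component("exposure", exposure)
  merge_component("covariates", covariates)
  merge_component("mediator", mediator)
  merge_component("outcome", outcome)
  merge_component("birthweight", birthweight)
  merge_component("gestational_age", gestational_age)
  merge_component("selection", selection)
  merge_component("daily_series", daily_series)

  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
  if (calibrate_intercepts) cfg <- calibrate_config_intercepts(cfg)
  cfg$fingerprint <- config_fingerprint(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  if (!is.numeric(cfg$n_subjects) || length(cfg$n_subjects) != 1L ||
      is.na(cfg$n_subjects) || cfg$n_subjects < 0 ||
      cfg$n_subjects != floor(cfg$n_subjects))
    stop_config("n_subjects", "must be a single non-negative integer")
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L || !is.finite(cfg$seed))
    stop_config("seed", "must be a single finite number")
  if (cfg$exposure$sd <= 0) stop_config("exposure$sd", "must be > 0")
  if (cfg$exposure$min >= cfg$exposure$max)
    stop_config("exposure$min", "truncation bounds must satisfy min < max")
  if (abs(cfg$exposure$temperature_cor) >= 1)
    stop_config("exposure$temperature_cor", "must lie in (-1, 1)")
  probs <- c(p_female = cfg$covariates$p_female,
             p_gdm = cfg$covariates$p_gdm,
             p_husband_smoking = cfg$covariates$p_husband_smoking)
  for (nm in names(probs))
    if (probs[[nm]] < 0 || probs[[nm]] > 1)
      stop_config(paste0("covariates$", nm), "must be a probability in [0, 1]")
  occ <- cfg$covariates$occupation
  if (any(occ < 0) || abs(sum(occ) - 1) > 1e-6)
    stop_config("covariates$occupation", "category probabilities must be >= 0 and sum to 1")
  ar1 <- cfg$daily_series$ar1_coefficient
  if (abs(ar1) >= 1)
    stop_config("daily_series$ar1_coefficient", "must lie in (-1, 1)")
  for (comp in c("mediator", "outcome", "selection")) {
    sl <- cfg[[comp]]$covariates
    bad <- setdiff(names(sl), COVARIATE_TERMS)
    if (length(bad))
      stop_config(paste0(comp, "$covariates"),
                  paste("unknown design terms:", paste(bad, collapse = ", ")))
  }
  for (p in c("mediator", "outcome")) {
    pv <- cfg[[p]]$prevalence
    if (!is.null(pv) && (pv <= 0 || pv >= 1))
      stop_config(paste0(p, "$prevalence"), "must lie in (0, 1)")
  }
  invisible(cfg)
}

config_fingerprint <- function(cfg) {
  core <- cfg[setdiff(names(cfg), "fingerprint")]
  flat <- paste(deparse(core, control = "all"), collapse = "")
  # short content hash; md5 of the deparsed configuration
  f <- tempfile(); on.exit(unlink(f))
  writeLines(flat, f)
  unname(tools::md5sum(f))
}

# Full slope vector over COVARIATE_TERMS (unnamed terms get slope 0).
full_slopes <- function(sl) {
  out <- stats::setNames(numeric(length(COVARIATE_TERMS)), COVARIATE_TERMS)
  out[names(sl)] <- sl
  out
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  n_subjects: %d   seed: %s\n", x$n_subjects, format(x$seed)))
  cat(sprintf("  exposure: TN(mean %.2f, sd %.2f) on [%.2f, %.2f], cor(T) = %.2f\n",
              x$exposure$mean, x$exposure$sd, x$exposure$min, x$exposure$max,
              x$exposure$temperature_cor))
  cat(sprintf("  mediator: b0 = %.4f, b_A = %.6f (target prevalence %.4f)\n",
              x$mediator$intercept, x$mediator$exposure, x$mediator$prevalence))
  cat(sprintf("  outcome:  t0 = %.4f, t_A = %.6f, t_M = %.4f, t_AM = %.6f (target prevalence %.4f)\n",
              x$outcome$intercept, x$outcome$exposure, x$outcome$mediator,
              x$outcome$interaction, x$outcome$prevalence))
  cat(sprintf("  daily series: %s\n",
              if (isTRUE(x$daily_series$enabled)) "on" else "off"))
  invisible(x)
}

# ---- covariate and exposure draws (shared by generator and truth oracle) ----

draw_covariates <- function(cfg, n) {
  cc <- cfg$covariates
  occ_levels <- names(cc$occupation)
  data.frame(
    maternal_age_y = round(rtruncnorm(n, cc$maternal_age$mean, cc$maternal_age$sd,
                                      cc$maternal_age$min, cc$maternal_age$max), 1),
    infant_sex = ifelse(stats::runif(n) < cc$p_female, "female", "male"),
    occupation = occ_levels[1L + findInterval(stats::runif(n),
                                              cumsum(cc$occupation))],
    gestational_diabetes = as.integer(stats::runif(n) < cc$p_gdm),
    husband_smoking = as.integer(stats::runif(n) < cc$p_husband_smoking),
    temperature_c = round(stats::rnorm(n, cc$temperature$mean, cc$temperature$sd), 2),
    stringsAsFactors = FALSE
  )
}

# Design matrix over COVARIATE_TERMS for generative linear predictors.
covariate_design <- function(cov, cfg) {
  cc <- cfg$covariates
  cbind(
    maternal_age_c = cov$maternal_age_y - cc$maternal_age$mean,
    female = as.numeric(cov$infant_sex == "female"),
    occ_farmer = as.numeric(cov$occupation == "farmer"),
    occ_housewife = as.numeric(cov$occupation == "housewife"),
    occ_worker = as.numeric(cov$occupation == "worker"),
    occ_other = as.numeric(cov$occupation == "other"),
    gdm = as.numeric(cov$gestational_diabetes),
    husband_smoking = as.numeric(cov$husband_smoking),
    temperature_c = cov$temperature_c - cc$temperature$mean
  )
}

draw_exposure <- function(cfg, temperature_c, n) {
  ex <- cfg$exposure
  tsd <- cfg$covariates$temperature$sd
  slope <- ex$temperature_cor * ex$sd / tsd
  mu <- ex$mean + slope * (temperature_c - cfg$covariates$temperature$mean)
  resid_sd <- ex$sd * sqrt(1 - ex$temperature_cor^2)
  round(rtruncnorm(n, mu, resid_sd, ex$min, ex$max), 2)
}

# Linear predictors of the generative models -----------------------------------

mediator_linpred <- function(cfg, a, X) {
  cfg$mediator$intercept + cfg$mediator$exposure * a +
    drop(X %*% full_slopes(cfg$mediator$covariates))
}

outcome_linpred <- function(cfg, a, m, X) {
  cfg$outcome$intercept + cfg$outcome$exposure * a +
    cfg$outcome$mediator * m + cfg$outcome$interaction * a * m +
    drop(X %*% full_slopes(cfg$outcome$covariates))
}

selection_linpred <- function(cfg, X) {
  cfg$selection$intercept + drop(X %*% full_slopes(cfg$selection$covariates))
}

# Solve intercepts so the analytic prevalence (mean expit over the covariate
# and exposure distribution) matches the target. Uses a fixed internal draw,
# independent of the user's seed, so calibration is deterministic.
calibrate_config_intercepts <- function(cfg, n_int = 20000L) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(760451L)
  cov <- draw_covariates(cfg, n_int)
  a <- draw_exposure(cfg, cov$temperature_c, n_int)
  X <- covariate_design(cov, cfg)

  med_off <- cfg$mediator$exposure * a + drop(X %*% full_slopes(cfg$mediator$covariates))
  cfg$mediator$intercept <- stats::uniroot(
    function(b0) mean(expit(b0 + med_off)) - cfg$mediator$prevalence,
    c(-30, 10), tol = 1e-10
  )$root

  p_m <- expit(cfg$mediator$intercept + med_off)
  out_off0 <- cfg$outcome$exposure * a + drop(X %*% full_slopes(cfg$outcome$covariates))
  out_off1 <- out_off0 + cfg$outcome$mediator + cfg$outcome$interaction * a
  cfg$outcome$intercept <- stats::uniroot(
    function(t0) mean((1 - p_m) * expit(t0 + out_off0) + p_m * expit(t0 + out_off1)) -
      cfg$outcome$prevalence,
    c(-30, 10), tol = 1e-10
  )$root
  cfg
}
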
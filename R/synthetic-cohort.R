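#' Generate a synthetic birth cohort
#'
#' Draws a cohort with the statistical structure the downstream analysis
#' assumes: a whole-pregnancy ozone exposure summary (optionally with a
#' matching daily series), demographic covariates, a binary mediator
#' (gestational hypertension) from a logistic model, a rare binary outcome
#' from a logistic model with optional exposure-mediator interaction, and
#' auxiliary birth weight / gestational age / date fields so the cohort can
#' also be pushed through the eligibility and outcome-derivation stages.
#'
#' Reproducibility contract: the same configuration and seed produce a
#' byte-identical record table. Each generator stage (covariates, exposure,
#' mediator, outcome, anthropometrics, selection, daily series) draws from
#' its own child seed of `config$seed`, so enabling a later stage never
#' perturbs earlier draws.
#'
#' @param config a [sim_config()] object.
#' @return an object of class `synthetic_cohort`: a list with `records`
#'   (data frame, one row per birth), `daily` (long-format daily exposure
#'   series or `NULL`), and `config_fingerprint`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(config$n_subjects)
  seeds <- child_seeds(config$seed, 8L)

  if (n == 0L) {
    rec <- empty_cohort_frame()
    return(structure(list(records = rec, daily = NULL,
                          config_fingerprint = config$fingerprint),
                     class = "synthetic_cohort"))
  }

  set.seed(seeds[1L]); cov <- draw_covariates(config, n)
  set.seed(seeds[2L]); o3 <- draw_exposure(config, cov$temperature_c, n)
  X <- covariate_design(cov, config)

  set.seed(seeds[3L])
  p_med <- expit(mediator_linpred(config, o3, X))
  m <- as.integer(stats::runif(n) < p_med)

  set.seed(seeds[4L])
  p_out <- expit(outcome_linpred(config, o3, m, X))
  y <- as.integer(stats::runif(n) < p_out)

  set.seed(seeds[5L])
  ga <- config$gestational_age
  gestational_age_wk <- round(rtruncnorm(n, ga$mean, ga$sd, ga$min, ga$max), 1)
  bw <- config$birthweight
  birth_weight_g <- round(stats::rnorm(
    n,
    bw$mean + bw$exposure_slope * (o3 - config$exposure$mean) + bw$mediator_shift * m,
    bw$sd
  ))
  delivery_date <- as.Date("2016-01-01") +
    sample.int(as.integer(as.Date("2022-12-31") - as.Date("2016-01-01")) + 1L, n,
               replace = TRUE) - 1L
  lmp_date <- delivery_date - round(gestational_age_wk * 7)

  records <- data.frame(
    subject_id = sprintf("S%07d", seq_len(n)),
    lmp_date = lmp_date,
    delivery_date = delivery_date,
    gestational_age_wk = gestational_age_wk,
    birth_weight_g = birth_weight_g,
    plurality = 1L,
    birth_order = 1L,
    maternal_age_y = cov$maternal_age_y,
    marital_status = "married",
    infant_sex = cov$infant_sex,
    occupation = cov$occupation,
    husband_smoking = cov$husband_smoking,
    gestational_diabetes = cov$gestational_diabetes,
    gestational_hypertension = m,
    temperature_c = cov$temperature_c,
    exposure_o3 = o3,
    outcome = y,
    stringsAsFactors = FALSE
  )

  daily <- NULL
  if (isTRUE(config$daily_series$enabled)) {
    set.seed(seeds[7L])
    daily <- build_daily_series(records, config)
  }

  structure(list(records = records, daily = daily,
                 config_fingerprint = config$fingerprint),
            class = "synthetic_cohort")
}

empty_cohort_frame <- function() {
  data.frame(
    subject_id = character(), lmp_date = as.Date(character()),
    delivery_date = as.Date(character()), gestational_age_wk = numeric(),
    birth_weight_g = numeric(), plurality = integer(), birth_order = integer(),
    maternal_age_y = numeric(), marital_status = character(),
    infant_sex = character(), occupation = character(),
    husband_smoking = integer(), gestational_diabetes = integer(),
    gestational_hypertension = integer(), temperature_c = numeric(),
    exposure_o3 = numeric(), outcome = integer(), stringsAsFactors = FALSE
  )
}

# Per-subject daily series: seasonal cycle + AR(1) noise, then shifted so the
# pregnancy mean reproduces the stored exposure summary exactly.
build_daily_series <- function(records, config) {
  ds <- config$daily_series
  out <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    dates <- seq(records$lmp_date[i], records$delivery_date[i], by = "day")
    nd <- length(dates)
    doy <- as.integer(format(dates, "%j"))
    season <- ds$season_amplitude * sin(2 * pi * (doy - 105) / 365.25)
    eps <- as.numeric(stats::arima.sim(
      list(ar = ds$ar1_coefficient), nd,
      sd = ds$daily_noise_sd * sqrt(1 - ds$ar1_coefficient^2)
    ))
    vals <- season + eps
    # unrounded: the pregnancy mean must reproduce the summary exactly
    vals <- vals - mean(vals) + records$exposure_o3[i]
    out[[i]] <- data.frame(subject_id = records$subject_id[i],
                           date = dates, o3_ugm3 = vals,
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d births", nrow(x$records)))
  if (nrow(x$records)) {
    cat(sprintf(" | O3 mean %.2f | mediator %.2f%% | outcome %.2f%%",
                mean(x$records$exposure_o3),
                100 * mean(x$records$gestational_hypertension),
                100 * mean(x$records$outcome)))
  }
  cat("\n")
  invisible(x)
}

#' Apply the covariate-dependent selection model to a synthetic cohort
#'
#' Each record gains its inclusion probability
#' `expit(selection intercept + slopes . covariates)` and a drawn inclusion
#' flag. The full cohort is retained (flags, not subsetting) so that
#' selection-weighting can be validated against the full-cohort truth.
#'
#' @param cohort a `synthetic_cohort`.
#' @param config the [sim_config()] that generated it.
#' @return the cohort with `selection_probability` and `included` columns
#'   added to `records`.
#' @export
apply_selection <- function(cohort, config) {
  stopifnot(inherits(cohort, "synthetic_cohort"), inherits(config, "sim_config"))
  rec <- cohort$records
  if (nrow(rec) == 0L) {
    rec$selection_probability <- numeric()
    rec$included <- integer()
    cohort$records <- rec
    return(cohort)
  }
  X <- covariate_design(rec, config)
  p <- expit(selection_linpred(config, X))
  seeds <- child_seeds(config$seed, 8L)
  set.seed(seeds[6L])
  rec$selection_probability <- p
  rec$included <- as.integer(stats::runif(nrow(rec)) < p)
  cohort$records <- rec
  cohort
}

#' Ground-truth mediation effects of a simulation configuration
#'
#' Evaluates the true total, natural direct, and natural indirect effects (on
#' the odds-ratio scale, standardized over the covariate distribution) implied
#' by a generative configuration, for an exposure contrast `a_star -> a`.
#'
#' Default evaluation is Monte Carlo: draw covariates and exposure-model
#' inputs, set exposure to `a` or `a_star`, draw the mediator under the
#' indicated exposure, average the exact model outcome probabilities, and form
#' odds ratios of the averaged counterfactual risks. Delta-method Monte-Carlo
#' standard errors for the log effects are returned. An exact closed-form
#' evaluation (mixture odds, no approximation) is available when the outcome
#' model has no exposure-mediator interaction and covariates are held fixed.
#'
#' @param config a [sim_config()].
#' @param contrast numeric length-2 `c(a_star, a)`; default the 25th and 75th
#'   percentile of the configured exposure distribution (evaluated by
#'   simulation under a fixed internal stream of `seed`).
#' @param n_mc Monte-Carlo draws (values below 1000 flag the result).
#' @param seed seed for the Monte-Carlo stream.
#' @param method `"monte_carlo"` or `"closed_form"`.
#' @param at_covariates single-row data frame of covariates at which to
#'   evaluate conditionally (required for `"closed_form"`; when supplied with
#'   `"monte_carlo"` the covariates are held fixed at that row).
#' @return an object of class `true_effects` with elements `te_or`, `nde_or`,
#'   `nie_or`, `pm_pct`, `contrast`, `method`, and (Monte Carlo) `se_log`
#'   (named SEs of log TE/NDE/NIE).
#' @export
true_mediation_effects <- function(config, contrast = NULL, n_mc = 2e5,
                                   seed = 1L,
                                   method = c("monte_carlo", "closed_form"),
                                   at_covariates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  method <- match.arg(method)
  seeds <- child_seeds(seed, 4L)

  if (is.null(contrast)) {
    set.seed(seeds[1L])
    cov0 <- draw_covariates(config, 100000L)
    a_mc <- draw_exposure(config, cov0$temperature_c, 100000L)
    contrast <- quantile7(a_mc, c(0.25, 0.75))
  }
  a_star <- contrast[1L]; a <- contrast[2L]

  if (method == "closed_form") {
    if (config$outcome$interaction != 0)
      stop("closed-form evaluation requires no exposure-mediator interaction")
    if (is.null(at_covariates))
      stop("closed-form evaluation requires 'at_covariates' (fixed covariates)")
    # exact mixture-odds evaluation (no rare-outcome approximation): the
    # counterfactual risk integrates the outcome model against the mediator
    # model at the fixed covariates, and odds ratios are formed from risks
    X <- covariate_design(at_covariates, config)[1L, , drop = FALSE]
    q_exact <- function(a_y, a_m) {
      pm1 <- expit(mediator_linpred(config, a_m, X))
      (1 - pm1) * expit(outcome_linpred(config, a_y, 0, X)) +
        pm1 * expit(outcome_linpred(config, a_y, 1, X))
    }
    q_base <- q_exact(a_star, a_star)
    q_nde <- q_exact(a, a_star)
    q_te <- q_exact(a, a)
    if (any(c(q_base, q_nde, q_te) <= 0) || any(c(q_base, q_nde, q_te) >= 1))
      stop("degenerate counterfactual outcome probability (0 or 1); check coefficients")
    nde <- unname(odds(q_nde) / odds(q_base))
    nie <- unname(odds(q_te) / odds(q_nde))
    te <- nde * nie
    return(structure(list(
      te_or = te, nde_or = nde, nie_or = nie,
      pm_pct = if (te != 1) 100 * log(nie) / log(te) else NA_real_,
      contrast = c(a_star = unname(a_star), a = unname(a)),
      method = "closed_form", n_mc = NA_integer_, se_log = NULL,
      low_precision = FALSE
    ), class = "true_effects"))
  }

  n_mc <- as.integer(n_mc)
  low_precision <- n_mc < 1000L
  set.seed(seeds[2L])
  if (is.null(at_covariates)) {
    cov <- draw_covariates(config, n_mc)
  } else {
    cov <- at_covariates[rep(1L, n_mc), , drop = FALSE]
  }
  X <- covariate_design(cov, config)

  # mediator draws under each exposure level, comonotone-coupled through a
  # shared uniform: when the exposure does not move the mediator (or the
  # contrast is null) the two counterfactual draws coincide exactly, so
  # NIE = 1 holds exactly rather than up to Monte-Carlo noise
  p_m_star <- expit(mediator_linpred(config, a_star, X))
  p_m_a <- expit(mediator_linpred(config, a, X))
  set.seed(seeds[3L])
  u_m <- stats::runif(n_mc)
  m_star <- as.integer(u_m < p_m_star)
  m_a <- as.integer(u_m < p_m_a)

  # exact counterfactual outcome probabilities per draw
  y_base <- expit(outcome_linpred(config, a_star, m_star, X)) # Y(a*, M(a*))
  y_nde  <- expit(outcome_linpred(config, a,      m_star, X)) # Y(a,  M(a*))
  y_te   <- expit(outcome_linpred(config, a,      m_a,    X)) # Y(a,  M(a))

  q <- c(base = mean(y_base), nde = mean(y_nde), te = mean(y_te))
  if (any(q <= 0) || any(q >= 1))
    stop("degenerate counterfactual outcome probability (0 or 1); check coefficients")

  nde <- odds(q["nde"]) / odds(q["base"])
  nie <- odds(q["te"]) / odds(q["nde"])
  te <- nde * nie

  # delta-method MC SEs of the log effects: d log odds(q) / dq = 1/(q(1-q))
  S <- stats::cov(cbind(y_base, y_nde, y_te)) / n_mc
  g <- 1 / (q * (1 - q))
  v_log <- function(w) max(drop(t(w * g) %*% S %*% (w * g)), 0)
  se_log <- c(
    te  = sqrt(v_log(c(-1, 0, 1))),
    nde = sqrt(v_log(c(-1, 1, 0))),
    nie = sqrt(v_log(c(0, -1, 1)))
  )

  structure(list(
    te_or = unname(te), nde_or = unname(nde), nie_or = unname(nie),
    pm_pct = if (te != 1) unname(100 * log(nie) / log(te)) else NA_real_,
    contrast = c(a_star = unname(a_star), a = unname(a)),
    method = "monte_carlo", n_mc = n_mc, se_log = se_log,
    low_precision = low_precision
  ), class = "true_effects")
}

#' @export
print.true_effects <- function(x, ...) {
  cat(sprintf("<true_effects> (%s) contrast %.2f -> %.2f ug/m3\n",
              x$method, x$contrast[1L], x$contrast[2L]))
  cat(sprintf("  TE %.4f  NDE %.4f  NIE %.4f  PM %.2f%%\n",
              x$te_or, x$nde_or, x$nie_or, x$pm_pct))
  if (!is.null(x$se_log))
    cat(sprintf("  MC SE(log): te %.2e, nde %.2e, nie %.2e (n_mc = %d)\n",
                x$se_log["te"], x$se_log["nde"], x$se_log["nie"], x$n_mc))
  if (isTRUE(x$low_precision)) cat("  note: n_mc < 1000, low precision\n")
  invisible(x)
}

#' Write a synthetic cohort to delimited text
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "cohort.tsv")
  utils::write.table(cohort$records, paths[1L], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(cohort$daily)) {
    p2 <- file.path(dir, "daily_series.tsv")
    utils::write.table(cohort$daily, p2, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p2)
  }
  invisible(paths)
}
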
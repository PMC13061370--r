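#' Published summary tables of the motivating registry cohort
#'
#' Loads the published summary statistics of a province-wide Chinese registry
#' birth cohort (Shandong, 2016-2022; ~3.39 million singleton term births)
#' that this package's reporting layer is validated against: the eligibility
#' flowchart counts, descriptive characteristic counts, the exposure
#' distribution summary, and the published mediation decompositions. These
#' printed numbers are inputs for arithmetic-identity checks (flowchart
#' conservation, prevalence ratios, product decompositions, proportion
#' mediated); the underlying registry records are not distributed.
#'
#' @return named list of data frames: `flowchart`, `table1_counts`,
#'   `exposure_summary`, `mediation_estimates`.
#' @export
study_reference_tables <- function() {
  path <- function(f) system.file("extdata", f, package = "ozmediate", mustWork = TRUE)
  rd <- function(f) utils::read.delim(path(f), stringsAsFactors = FALSE)
  list(
    flowchart = rd("study_flowchart.tsv"),
    table1_counts = rd("study_table1_counts.tsv"),
    exposure_summary = rd("study_exposure_summary.tsv"),
    mediation_estimates = rd("study_mediation_estimates.tsv")
  )
}

#' Default end-to-end run configuration
#'
#' @param n_subjects synthetic cohort size.
#' @param seed root seed for every stochastic stage.
#' @param n_boot bootstrap replications for the mediation stage.
#' @param variants mediation variants to run.
#' @param out_dir output directory.
#' @param sim overrides passed through to [sim_config()].
#' @return a `run_config` list.
#' @export
run_config <- function(n_subjects = 50000L, seed = 1L, n_boot = 200L,
                       variants = c("four_step", "counterfactual",
                                    "counterfactual_interaction", "cox"),
                       out_dir = tempfile("ozmediate_run_"), sim = list()) {
  structure(list(n_subjects = n_subjects, seed = seed, n_boot = n_boot,
                 variants = variants, out_dir = out_dir, sim = sim),
            class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file whose top-level keys match the arguments of
#'   [run_config()].
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML run configurations",
         call. = FALSE)
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

analysis_covariates <- c("maternal_age_y", "infant_sex", "temperature_c",
                         "occupation", "gestational_diabetes", "husband_smoking")

analysis_formula <- function(outcome = "outcome",
                             covariates = analysis_covariates,
                             extra = character()) {
  stats::reformulate(c("exposure_o3", covariates, extra), response = outcome)
}

age_band <- function(age) cut(age, c(20, 25, 30, 35, 40, 45.01),
                              right = FALSE, include.lowest = TRUE)

#' Run the full synthetic-cohort analysis pipeline
#'
#' Simulate -> select -> eligibility -> outcomes -> weights -> per-IQR
#' regressions -> mediation decompositions, writing a descriptive summary
#' table, an adjusted-effects table (main, Cox, mediator-adjusted, weighted
#' rows), a mediation table, and a machine-readable run manifest (stage
#' record counts, config fingerprint, seed, file hashes) to
#' `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with every intermediate object and the output
#'   directory.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  sim <- stage("simulate", do.call(sim_config, c(
    list(n_subjects = config$n_subjects, seed = config$seed), config$sim)))
  cohort <- stage("simulate", apply_selection(generate_cohort(sim), sim))

  elig <- stage("build-cohort", apply_eligibility(cohort$records))
  eligible <- stage("build-cohort",
                    derive_outcomes(elig$records, make_growth_reference()))
  analytic <- eligible[eligible$included == 1L, , drop = FALSE]
  scale <- stage("build-cohort", compute_iqr_scale(analytic$exposure_o3))

  # composite weights on the analytic sample: raking to eligible-population
  # margins x IPSW from the selection model fitted at eligibility level
  wts <- stage("weights", {
    targets <- list(
      age_band = prop.table(table(age_band(eligible$maternal_age_y))),
      infant_sex = prop.table(table(eligible$infant_sex)),
      ga_week = prop.table(table(floor(eligible$gestational_age_wk)))
    )
    targets <- lapply(targets, function(t) stats::setNames(as.numeric(t), names(t)))
    adf <- analytic
    adf$age_band <- as.character(age_band(adf$maternal_age_y))
    adf$ga_week <- as.character(floor(adf$gestational_age_wk))
    cal <- calibrate_raking(adf, targets, tol = 1e-8)
    sel <- fit_selection_ipsw(eligible, inclusion = "included")
    ipsw <- sel$ipsw[eligible$included == 1L]
    compose_weights(cal$weights, ipsw)
  })

  fits <- stage("fit", {
    prev <- mean(analytic$outcome)
    main <- fit_logistic(analysis_formula(), analytic)
    adj <- fit_logistic(analysis_formula(extra = "gestational_hypertension"),
                        analytic)
    wtd <- fit_logistic(analysis_formula(), analytic,
                        weights = wts$final_weight)
    cox <- fit_cox(stats::as.formula(paste(
      "survival::Surv(gestational_age_wk, outcome) ~",
      paste(c("exposure_o3", analysis_covariates), collapse = " + "))), analytic)
    effects <- rbind(
      cbind(model = "main", rr_per_iqr(main, scale$iqr, "exposure_o3", prev)),
      cbind(model = "cox", rr_per_iqr(cox, scale$iqr, "exposure_o3", prev)),
      cbind(model = "mediator_adjusted",
            rr_per_iqr(adj, scale$iqr, "exposure_o3", prev)),
      cbind(model = "weighted", rr_per_iqr(wtd, scale$iqr, "exposure_o3", prev))
    )
    list(main = main, adjusted = adj, weighted = wtd, cox = cox,
         effects = effects)
  })

  med <- stage("mediate", {
    out <- list()
    for (v in config$variants) {
      out[[v]] <- o3_mediate(
        analysis_formula(), analytic, mediator = "gestational_hypertension",
        variant = switch(v, counterfactual_interaction = "counterfactual",
                         counterfactual = "counterfactual", v),
        interaction = identical(v, "counterfactual_interaction"),
        contrast = c(scale$q25, scale$q75),
        n_boot = config$n_boot, seed = config$seed)
    }
    out
  })

  paths <- stage("report", {
    desc <- data.frame(
      quantity = c("n_analytic", "o3_mean", "o3_sd", "o3_q25", "o3_q75",
                   "o3_iqr", "pct_female", "pct_mediator", "pct_outcome"),
      value = c(nrow(analytic), mean(analytic$exposure_o3),
                stats::sd(analytic$exposure_o3), scale$q25, scale$q75,
                scale$iqr, 100 * mean(analytic$infant_sex == "female"),
                100 * mean(analytic$gestational_hypertension),
                100 * mean(analytic$outcome))
    )
    med_tab <- do.call(rbind, lapply(names(med), function(v) {
      s <- summary(med[[v]])$table
      cbind(variant = med[[v]]$variant, s)
    }))
    p <- c(
      descriptive = write_tsv(desc, config$out_dir, "table1_descriptive.tsv"),
      eligibility = write_tsv(as.data.frame(elig$report), config$out_dir,
                              "eligibility_report.tsv"),
      effects = write_tsv(fits$effects, config$out_dir, "table3_effects.tsv"),
      mediation = write_tsv(med_tab, config$out_dir, "table4_mediation.tsv")
    )
    manifest <- data.frame(
      file = basename(p),
      md5 = unname(tools::md5sum(p)),
      stringsAsFactors = FALSE
    )
    attr_lines <- c(
      sprintf("seed\t%s", format(config$seed)),
      sprintf("n_subjects\t%d", config$n_subjects),
      sprintf("n_boot\t%d", config$n_boot),
      sprintf("config_fingerprint\t%s", sim$fingerprint),
      sprintf("package_version\t%s", as.character(utils::packageVersion("ozmediate")))
    )
    mp <- file.path(config$out_dir, "manifest.tsv")
    writeLines(c(attr_lines, "file\tmd5",
                 sprintf("%s\t%s", manifest$file, manifest$md5)), mp)
    c(p, manifest = mp)
  })

  invisible(list(config = config, sim = sim, cohort = cohort,
                 eligibility = elig$report, analytic = analytic,
                 iqr_scale = scale, weights = wts, fits = fits,
                 mediation = med, paths = paths, out_dir = config$out_dir))
}

write_tsv <- function(df, dir, name) {
  p <- file.path(dir, name)
  df_out <- df
  num <- vapply(df_out, is.numeric, logical(1))
  df_out[num] <- lapply(df_out[num], function(x) formatC(x, digits = 10, format = "g"))
  utils::write.table(df_out, p, sep = "\t", quote = FALSE, row.names = FALSE)
  p
}
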
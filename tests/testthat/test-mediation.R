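test_that("proportion mediated follows the log-ratio definition", {
  expect_equal(proportion_mediated(1.055, 1.021), 100 * log(1.021) / log(1.055))
  expect_equal(proportion_mediated(2, 1), 0)
  expect_error(proportion_mediated(1, 1.02), "undefined")
  expect_error(proportion_mediated(0.9, -1), "positive")
})

test_that("Sobel statistic matches direct hand evaluation", {
  # beta1 = 0.15 (SE 0.01), theta2 = 1.87 (SE 0.016)
  z_hand <- (0.15 * 1.87) / sqrt(1.87^2 * 0.01^2 + 0.15^2 * 0.016^2)
  s <- sobel_test(0.15, 0.01, 1.87, 0.016)
  expect_equal(s$z, z_hand)
  expect_equal(s$p, 2 * stats::pnorm(-abs(z_hand)))
})

test_that("counterfactual point estimates satisfy the product identity", {
  for (seed in c(3, 17, 29)) {
    d <- generate_cohort(sim_config(n_subjects = 30000, seed = seed))$records
    for (intx in c(FALSE, TRUE)) {
      m <- o3_mediate(FULL_FORMULA, d, mediator = "gestational_hypertension",
                      variant = "counterfactual", interaction = intx)
      est <- coef(m)
      expect_lt(abs(est[["te"]] - est[["direct"]] * est[["indirect"]]) /
                  est[["te"]], 1e-12)
      expect_equal(est[["pm_pct"]],
                   proportion_mediated(est[["te"]], est[["indirect"]]))
    }
  }
})

test_that("estimates recover generative truth at large n", {
  cfg <- sim_config(n_subjects = 200000, seed = 3)
  d <- generate_cohort(cfg)$records
  m <- o3_mediate(FULL_FORMULA, d, mediator = "gestational_hypertension",
                  variant = "counterfactual", contrast = STUDY_CONTRAST)
  tr <- true_mediation_effects(cfg, contrast = STUDY_CONTRAST, n_mc = 2e5,
                               seed = 77)
  # indirect path is precisely estimated; direct path has sampling noise
  # of order 0.09 on the log scale at ~1800 cases
  expect_lt(abs(log(coef(m)[["indirect"]]) - log(tr$nie_or)), 0.01)
  expect_lt(abs(log(coef(m)[["te"]]) - log(tr$te_or)), 0.1)
})

test_that("fully mediated and unmediated limits are respected", {
  # theta1 = 0: NDE ~ 1 and pm ~ 100%
  cfg_full <- sim_config(n_subjects = 150000, seed = 41,
                         outcome = list(exposure = 0))
  d <- generate_cohort(cfg_full)$records
  m <- o3_mediate(FULL_FORMULA, d, mediator = "gestational_hypertension",
                  variant = "counterfactual", contrast = STUDY_CONTRAST)
  expect_lt(abs(log(coef(m)[["direct"]])), 0.12)  # ~1.5 SE of the direct path
  # beta1 = 0: estimated NIE concentrates at 1
  cfg_none <- sim_config(n_subjects = 150000, seed = 42,
                         mediator = list(exposure = 0))
  d2 <- generate_cohort(cfg_none)$records
  m2 <- o3_mediate(FULL_FORMULA, d2, mediator = "gestational_hypertension",
                   variant = "counterfactual", contrast = STUDY_CONTRAST)
  expect_lt(abs(log(coef(m2)[["indirect"]])), 0.01)
})

test_that("four-step decomposition is internally consistent", {
  # the redistribution total effect agrees with the step-1 per-IQR OR up to
  # the rare-outcome collapsibility error, O(prevalence) ~ 1e-3 in this
  # regime; averaged over replicates to separate it from sampling noise
  gap <- numeric(5)
  for (i in seq_along(gap)) {
    d <- generate_cohort(sim_config(n_subjects = 100000, seed = 18 + i))$records
    m <- o3_mediate(FULL_FORMULA, d, mediator = "gestational_hypertension",
                    variant = "four_step")
    est <- coef(m)
    # product identity is exact by construction
    expect_equal(est[["te"]], est[["direct"]] * est[["indirect"]],
                 tolerance = 1e-12)
    gap[i] <- log(est[["te"]]) - log(est[["te_step1"]])
    # Sobel output present and finite
    expect_true(is.finite(m$sobel$z) && m$sobel$p >= 0 && m$sobel$p <= 1)
    # both proportion-mediated readings emitted
    expect_true(all(c("pm_pct", "pm_excess_pct") %in% names(est)))
  }
  expect_lt(abs(mean(gap)), 2e-3)
})

test_that("a null mediator-outcome path yields a null Sobel test", {
  ok <- logical(15)
  for (r in seq_along(ok)) {
    cfg <- sim_config(n_subjects = 20000, seed = 600 + r,
                      outcome = list(mediator = 0))
    d <- generate_cohort(cfg)$records
    m <- o3_mediate(outcome ~ exposure_o3 + maternal_age_y + temperature_c,
                    d, mediator = "gestational_hypertension",
                    variant = "four_step")
    ok[r] <- m$sobel$p > 0.05
  }
  expect_gte(mean(ok), 0.8)
})

test_that("interaction and no-interaction variants agree when no interaction is planted", {
  d <- generate_cohort(sim_config(n_subjects = 200000, seed = 55))$records
  m0 <- o3_mediate(FULL_FORMULA, d, mediator = "gestational_hypertension",
                   variant = "counterfactual", contrast = STUDY_CONTRAST)
  m1 <- o3_mediate(FULL_FORMULA, d, mediator = "gestational_hypertension",
                   variant = "counterfactual", interaction = TRUE,
                   contrast = STUDY_CONTRAST)
  expect_lt(abs(log(coef(m1)[["indirect"]]) - log(coef(m0)[["indirect"]])), 0.01)
  expect_lt(abs(log(coef(m1)[["direct"]]) - log(coef(m0)[["direct"]])), 0.02)
  expect_identical(m0$variant, "counterfactual_no_interaction")
  expect_identical(m1$variant, "counterfactual_interaction")
})

test_that("Cox-framework decomposition concords with the logistic variant under rarity", {
  d <- generate_cohort(sim_config(n_subjects = 150000, seed = 23))$records
  ml <- o3_mediate(FULL_FORMULA, d, mediator = "gestational_hypertension",
                   variant = "counterfactual", contrast = STUDY_CONTRAST)
  mc <- o3_mediate(FULL_FORMULA, d, mediator = "gestational_hypertension",
                   variant = "cox", contrast = STUDY_CONTRAST)
  expect_identical(mc$variant, "cox_framework")
  expect_identical(mc$scale, "hr")
  expect_lt(abs(coef(mc)[["pm_pct"]] - coef(ml)[["pm_pct"]]), 8)
  expect_lt(abs(log(coef(mc)[["indirect"]]) - log(coef(ml)[["indirect"]])), 0.01)
  # null contrast: all ratios exactly 1
  mnull <- o3_mediate(FULL_FORMULA, d, mediator = "gestational_hypertension",
                      variant = "cox", contrast = c(110, 110))
  expect_equal(unname(coef(mnull)[c("te", "direct", "indirect")]), c(1, 1, 1))
})

test_that("degenerate mediation inputs raise explicit errors", {
  d <- generate_cohort(sim_config(n_subjects = 2000, seed = 9))$records
  d$const_m <- 0L
  expect_error(o3_mediate(outcome ~ exposure_o3, d, mediator = "const_m"),
               "constant")
  expect_error(o3_mediate(outcome ~ exposure_o3, d,
                          mediator = "gestational_hypertension",
                          variant = "four_step", interaction = TRUE),
               "interaction")
  expect_error(o3_mediate(outcome ~ exposure_o3, d,
                          mediator = "gestational_hypertension", n_boot = 10),
               "n_boot")
})

test_that("planted mediator-path strength moves the estimated NIE monotonically", {
  b1_grid <- c(0.005, 0.02, 0.05)
  nie <- numeric(length(b1_grid))
  for (i in seq_along(b1_grid)) {
    cfg <- sim_config(n_subjects = 40000, seed = 321,
                      mediator = list(exposure = b1_grid[i]))
    d <- generate_cohort(cfg)$records
    m <- o3_mediate(outcome ~ exposure_o3 + maternal_age_y + temperature_c,
                    d, mediator = "gestational_hypertension",
                    variant = "counterfactual", contrast = STUDY_CONTRAST)
    nie[i] <- coef(m)[["indirect"]]
  }
  expect_true(all(diff(nie) > 0))
})

test_that("the BC bootstrap is deterministic, extendable, and guards failures", {
  d <- generate_cohort(sim_config(n_subjects = 8000, seed = 63))$records
  f <- outcome ~ exposure_o3 + maternal_age_y
  m1 <- o3_mediate(f, d, mediator = "gestational_hypertension",
                   variant = "counterfactual", n_boot = 60, seed = 17)
  m2 <- o3_mediate(f, d, mediator = "gestational_hypertension",
                   variant = "counterfactual", n_boot = 60, seed = 17)
  expect_identical(m1$ci, m2$ci)
  # replicate streams are child-seeded: the first replicates of a longer run
  # coincide with a shorter run
  stat <- function(idx) list(stats = c(mn = mean(d$exposure_o3[idx])))
  b60 <- ozmediate:::bc_boot(stat, nrow(d), c(mn = mean(d$exposure_o3)),
                             n_boot = 60, seed = 5)
  b90 <- ozmediate:::bc_boot(stat, nrow(d), c(mn = mean(d$exposure_o3)),
                             n_boot = 90, seed = 5)
  expect_equal(b60$replicates[, "mn"], b90$replicates[1:60, "mn"])
  # a constant estimator has a zero-width interval at the constant
  bconst <- ozmediate:::bc_boot(function(idx) list(stats = c(k = 4.2)),
                                nrow(d), c(k = 4.2), n_boot = 60, seed = 2)
  expect_equal(unname(bconst$ci["k", ]), c(4.2, 4.2))
  # replicate failures above 10% abort
  flaky <- local({
    i <- 0
    function(idx) {
      i <<- i + 1
      if (i %% 4 == 0) stop("boom")
      list(stats = c(k = mean(idx)))
    }
  })
  expect_error(ozmediate:::bc_boot(flaky, nrow(d), c(k = 1), n_boot = 60,
                                   seed = 3),
               "failure rate")
})
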
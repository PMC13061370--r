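#' Proportion mediated on the log-ratio scale
#'
#' `100 * log(NIE) / log(TE)`: the share of the log total effect transmitted
#' through the mediator.
#'
#' @param te total effect (ratio scale, > 0, not 1).
#' @param nie natural indirect effect (ratio scale, > 0).
#' @return percent mediated.
#' @export
proportion_mediated <- function(te, nie) {
  if (!is.numeric(te) || !is.numeric(nie) || any(te <= 0) || any(nie <= 0))
    stop("te and nie must be positive ratios", call. = FALSE)
  if (any(te == 1))
    stop("proportion mediated is undefined when the total effect is 1", call. = FALSE)
  100 * log(nie) / log(te)
}

#' Sobel test of the indirect path
#'
#' Normal-theory test of the product of the exposure-to-mediator coefficient
#' and the mediator-to-outcome coefficient:
#' `z = b1 * t2 / sqrt(t2^2 var(b1) + b1^2 var(t2))`.
#'
#' @param beta1 exposure coefficient of the mediator model.
#' @param se_beta1 its standard error.
#' @param theta2 mediator coefficient of the outcome model.
#' @param se_theta2 its standard error.
#' @return list with `z` and two-sided `p`.
#' @export
sobel_test <- function(beta1, se_beta1, theta2, se_theta2) {
  se <- sqrt(theta2^2 * se_beta1^2 + beta1^2 * se_theta2^2)
  z <- beta1 * theta2 / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Mediation of a per-IQR exposure effect by a binary mediator
#'
#' Decomposes the effect of an exposure contrast (by default the 25th to
#' 75th percentile of the observed exposure) on a rare binary outcome into
#' direct and mediator-transmitted components. Three variants:
#'
#' * `"counterfactual"` — natural direct and indirect effects on the
#'   odds-ratio scale under the rare-outcome approximation. Logistic models
#'   for mediator and outcome (optionally with exposure-mediator
#'   interaction); counterfactual risks are standardized over the empirical
#'   covariate distribution (averaged across subjects) before odds ratios
#'   are formed, so the point estimates satisfy `TE = NDE x NIE` exactly.
#' * `"four_step"` — traditional four-step analysis: the total effect from
#'   the outcome model without the mediator, the direct effect from the
#'   mediator-adjusted model, and the indirect effect from an
#'   average-predicted-odds decomposition in which the mediator is
#'   redistributed to its exposure-counterfactual distribution (Buis-style),
#'   with a Sobel test of the indirect path.
#' * `"cox"` — the counterfactual algebra with log-hazard coefficients from
#'   a proportional-hazards outcome model on the gestational-age time scale
#'   in place of log-odds (conditional effect expressions averaged on the
#'   log scale over the empirical covariate distribution).
#'
#' Inference is by nonparametric bootstrap of subjects with bias-corrected
#' percentile intervals.
#'
#' @param formula outcome model formula `outcome ~ exposure + covariates`;
#'   the first right-hand-side term is taken as the exposure. For
#'   `variant = "cox"` the left side is still the binary outcome flag; the
#'   time scale is supplied via `time`.
#' @param data data frame.
#' @param mediator name of the binary mediator column.
#' @param variant decomposition family (see above).
#' @param interaction include an exposure-mediator interaction in the
#'   outcome model (`"counterfactual"` and `"cox"` variants).
#' @param contrast numeric `c(a_star, a)`; default the exposure 25th/75th
#'   percentiles (type-7 quantiles).
#' @param weights optional case weights (e.g. `final_weight` of a
#'   [compose_weights()] set).
#' @param time name of the time column for `variant = "cox"` (default
#'   `"gestational_age_wk"`).
#' @param n_boot bootstrap replications (0 = point estimates only).
#' @param seed root seed for the bootstrap; replicate `r` draws from child
#'   stream `r`, so increasing `n_boot` never perturbs earlier replicates.
#' @param conf_level confidence level of the bootstrap intervals.
#' @return an object of class `o3_mediation`; see [print.o3_mediation()].
#' @export
o3_mediate <- function(formula, data, mediator,
                       variant = c("counterfactual", "four_step", "cox"),
                       interaction = FALSE, contrast = NULL, weights = NULL,
                       time = "gestational_age_wk",
                       n_boot = 0L, seed = 1L, conf_level = 0.95) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(data), mediator %in% names(data))
  if (variant == "four_step" && interaction)
    stop("the four-step decomposition excludes exposure-mediator interaction",
         call. = FALSE)
  if (n_boot > 0 && n_boot < 50)
    stop("n_boot must be 0 or at least 50", call. = FALSE)

  rhs <- attr(stats::terms(formula, data = data), "term.labels")
  exposure <- rhs[1L]
  covnames <- rhs[-1L]
  yvar <- all.vars(formula[[2L]])

  keep <- c(yvar, exposure, covnames, mediator,
            if (variant == "cox") time)
  cc <- stats::complete.cases(data[, keep, drop = FALSE])
  data <- data[cc, , drop = FALSE]
  if (!is.null(weights)) weights <- weights[cc]

  y <- data[[yvar]]
  a <- data[[exposure]]
  m <- data[[mediator]]
  if (!all(y %in% c(0, 1))) stop("outcome must be binary 0/1", call. = FALSE)
  if (!all(m %in% c(0, 1))) stop("mediator must be binary 0/1", call. = FALSE)
  if (length(unique(m)) < 2L)
    stop("mediator is constant; the indirect effect is undefined", call. = FALSE)

  Xc <- if (length(covnames)) {
    stats::model.matrix(stats::reformulate(covnames), data = data)
  } else {
    matrix(1, nrow(data), 1L, dimnames = list(NULL, "(Intercept)"))
  }
  w <- weights %||% rep(1, nrow(data))
  tt <- if (variant == "cox") data[[time]] else NULL

  if (is.null(contrast)) contrast <- quantile7(a, c(0.25, 0.75))
  a_star <- contrast[1L]; a1 <- contrast[2L]
  prev <- stats::weighted.mean(y, w)

  warm <- new.env(parent = emptyenv())
  est_fun <- switch(variant,
    counterfactual = function(idx) {
      est_counterfactual(Xc[idx, , drop = FALSE], a[idx], m[idx], y[idx],
                         w[idx], a_star, a1, interaction, warm)
    },
    four_step = function(idx) {
      est_four_step(Xc[idx, , drop = FALSE], a[idx], m[idx], y[idx],
                    w[idx], a_star, a1, warm)
    },
    cox = function(idx) {
      est_cox_cf(Xc[idx, , drop = FALSE], a[idx], m[idx], y[idx], tt[idx],
                 w[idx], a_star, a1, interaction, warm)
    }
  )

  point_full <- est_fun(seq_len(nrow(data)))
  point <- point_full$stats

  boot <- NULL
  if (n_boot > 0) {
    boot <- bc_boot(est_fun, n = nrow(data), point = point,
                    n_boot = n_boot, seed = seed, conf_level = conf_level)
  }

  note <- character()
  if (prev >= 0.10)
    note <- c(note, sprintf(
      "outcome prevalence %.1f%% >= 10%%: the rare-outcome OR-as-RR approximation is degraded",
      100 * prev))
  if (a_star == a1) note <- c(note, "null contrast (a = a_star): proportion mediated undefined")

  structure(list(
    variant = if (variant == "counterfactual") {
      if (interaction) "counterfactual_interaction" else "counterfactual_no_interaction"
    } else if (variant == "cox") "cox_framework" else "four_step",
    estimates = point,
    ci = boot$ci,
    se = boot$se,
    n_boot = n_boot,
    n_failed = boot$n_failed %||% 0L,
    detail = point_full$detail,
    sobel = point_full$sobel,
    contrast = c(a_star = unname(a_star), a = unname(a1)),
    iqr = unname(a1 - a_star),
    prevalence = prev,
    scale = if (variant == "cox") "hr" else if (prev < 0.10) "or_as_rr" else "or",
    notes = note,
    seed = seed,
    conf_level = conf_level,
    n = nrow(data),
    call = match.call()
  ), class = "o3_mediation")
}

# ---- estimator internals -----------------------------------------------------

# weighted logistic fit on an explicit design matrix; returns coef and vcov.
# Newton/IRLS with Cholesky normal-equation solves (cheap enough for the
# bootstrap loop, warm-startable at the full-sample estimates); falls back to
# stats::glm.fit if the Newton path stalls.
logit_fit_vcov <- function(X, y, w, start = NULL, tol = NULL, max_iter = 50L,
                           vcov = TRUE) {
  p <- ncol(X)
  # warm-started (bootstrap) refits tolerate a looser step criterion: the
  # residual coefficient error is orders of magnitude below resampling noise
  tol <- tol %||% if (is.null(start)) 1e-9 else 1e-5
  beta <- start %||% numeric(p)
  ok <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- expit(eta)
    wt <- w * mu * (1 - mu)
    if (any(!is.finite(wt))) break
    XtW <- crossprod(X, wt * X)
    score <- crossprod(X, w * (y - mu))
    ch <- tryCatch(chol(XtW), error = function(e) NULL)
    if (is.null(ch)) break
    step <- drop(chol2inv(ch) %*% score)
    if (!all(is.finite(step))) break
    beta <- beta + step
    if (max(abs(step)) / (1 + max(abs(beta))) < tol) {
      ok <- TRUE
      break
    }
  }
  if (!ok) {
    fit <- suppressWarnings(stats::glm.fit(
      X, y, weights = w, family = stats::binomial(),
      control = stats::glm.control(epsilon = 1e-10, maxit = 100)
    ))
    if (!fit$converged) stop("logistic sub-model did not converge", call. = FALSE)
    beta <- fit$coefficients
  }
  names(beta) <- colnames(X)
  V <- NULL
  if (vcov) {
    mu <- expit(drop(X %*% beta))
    V <- chol2inv(chol(crossprod(X, (w * mu * (1 - mu)) * X)))
    dimnames(V) <- list(colnames(X), colnames(X))
  }
  list(coef = beta, vcov = V)
}

# counterfactual risks standardized over the rows of Xc:
# Q(a_y, a_m) = mean_i sum_m P(Y=1 | a_y, m, C_i) P(M = m | a_m, C_i)
# returns the three marginal risks of the decomposition in one pass
cf_risks <- function(a_star, a1, Xc, b, th, w, interaction) {
  k <- ncol(Xc)
  cb <- drop(Xc %*% b[seq_len(k)])
  ct <- drop(Xc %*% th[seq_len(k)])
  pm_star <- expit(cb + b[k + 1L] * a_star)
  pm_a1 <- expit(cb + b[k + 1L] * a1)
  th3 <- if (interaction) th[k + 3L] else 0
  py <- function(a_y, pm1) {
    lpy0 <- ct + th[k + 1L] * a_y
    lpy1 <- lpy0 + th[k + 2L] + th3 * a_y
    stats::weighted.mean(expit(lpy0) * (1 - pm1) + expit(lpy1) * pm1, w)
  }
  c(base = py(a_star, pm_star), nde = py(a1, pm_star), te = py(a1, pm_a1))
}

est_counterfactual <- function(Xc, a, m, y, w, a_star, a1, interaction,
                               warm = new.env(parent = emptyenv())) {
  first <- is.null(warm$med)
  med <- logit_fit_vcov(cbind(Xc, exposure = a), m, w, start = warm$med,
                        vcov = first)
  Xy <- cbind(Xc, exposure = a, mediator = m)
  if (interaction) Xy <- cbind(Xy, `exposure:mediator` = a * m)
  out <- logit_fit_vcov(Xy, y, w, start = warm$out, vcov = first)
  if (first) { warm$med <- med$coef; warm$out <- out$coef }

  q <- cf_risks(a_star, a1, Xc, med$coef, out$coef, w, interaction)
  if (any(q <= 0) || any(q >= 1))
    stop("degenerate counterfactual risk", call. = FALSE)

  nde <- unname(odds(q[["nde"]]) / odds(q[["base"]]))
  nie <- unname(odds(q[["te"]]) / odds(q[["nde"]]))
  te <- nde * nie
  pm <- if (te != 1) 100 * log(nie) / log(te) else NA_real_

  list(stats = c(te = te, direct = nde, indirect = nie, pm_pct = pm),
       detail = list(mediator_coef = med$coef, outcome_coef = out$coef, q = q),
       sobel = NULL)
}

est_four_step <- function(Xc, a, m, y, w, a_star, a1,
                          warm = new.env(parent = emptyenv())) {
  k <- ncol(Xc)
  first <- is.null(warm$s1)
  step1 <- logit_fit_vcov(cbind(Xc, exposure = a), y, w, start = warm$s1,
                          vcov = first)
  step2 <- logit_fit_vcov(cbind(Xc, exposure = a), m, w, start = warm$s2)
  step3 <- logit_fit_vcov(cbind(Xc, exposure = a, mediator = m), y, w,
                          start = warm$s3)
  if (first) {
    warm$s1 <- step1$coef; warm$s2 <- step2$coef; warm$s3 <- step3$coef
  }

  delta <- a1 - a_star
  te_step1 <- exp(step1$coef[[k + 1L]] * delta)
  direct <- exp(step3$coef[[k + 1L]] * delta)

  # average-predicted-odds total effect: mediator redistributed to its
  # exposure-counterfactual distribution under the step-2 model
  q <- cf_risks(a_star, a1, Xc, step2$coef, step3$coef, w, FALSE)
  te <- unname(odds(q[["te"]]) / odds(q[["base"]]))
  indirect <- te / direct

  b1 <- step2$coef[[k + 1L]]
  th2 <- step3$coef[[k + 2L]]
  sob <- sobel_test(b1, sqrt(step2$vcov[k + 1L, k + 1L]),
                    th2, sqrt(step3$vcov[k + 2L, k + 2L]))

  pm_log <- if (te != 1) 100 * log(indirect) / log(te) else NA_real_
  pm_excess <- if (te != 1) 100 * (te - direct) / (te - 1) else NA_real_

  list(stats = c(te = te, direct = unname(direct), indirect = unname(indirect),
                 pm_pct = unname(pm_log), pm_excess_pct = unname(pm_excess),
                 te_step1 = unname(te_step1)),
       detail = list(beta1 = b1, theta2 = th2),
       sobel = sob)
}

# counterfactual algebra with log-hazard outcome coefficients; conditional
# NDE/NIE expressions averaged on the log scale over the covariate rows
est_cox_cf <- function(Xc, a, m, y, tt, w, a_star, a1, interaction,
                       warm = new.env(parent = emptyenv())) {
  med <- logit_fit_vcov(cbind(Xc, exposure = a), m, w, start = warm$med,
                        vcov = is.null(warm$med))
  if (is.null(warm$med)) warm$med <- med$coef
  k <- ncol(Xc)
  df <- data.frame(.t = tt, .y = y, .a = a, .m = m)
  Xc_nc <- Xc[, setdiff(colnames(Xc), "(Intercept)"), drop = FALSE]
  if (ncol(Xc_nc)) df <- cbind(df, Xc_nc)
  rhs <- c(".a", ".m", if (interaction) ".a:.m", colnames(Xc_nc))
  f <- stats::as.formula(paste("survival::Surv(.t, .y) ~", paste(rhs, collapse = "+")))
  cox <- if (all(w == 1)) survival::coxph(f, data = df, ties = "efron")
         else survival::coxph(f, data = df, weights = w, ties = "efron", robust = TRUE)
  cf <- stats::coef(cox)
  t_a <- cf[[".a"]]; t_m <- cf[[".m"]]
  t_am <- if (interaction) cf[[".a:.m"]] else 0

  lpm_star <- drop(Xc %*% med$coef[seq_len(k)]) + med$coef[k + 1L] * a_star
  lpm_a1 <- drop(Xc %*% med$coef[seq_len(k)]) + med$coef[k + 1L] * a1

  log_nde_i <- t_a * (a1 - a_star) +
    log1p(exp(t_m + t_am * a1 + lpm_star)) - log1p(exp(t_m + t_am * a_star + lpm_star))
  log_nie_i <- log1p(exp(lpm_star)) + log1p(exp(t_m + t_am * a1 + lpm_a1)) -
    log1p(exp(lpm_a1)) - log1p(exp(t_m + t_am * a1 + lpm_star))

  nde <- exp(stats::weighted.mean(log_nde_i, w))
  nie <- exp(stats::weighted.mean(log_nie_i, w))
  te <- nde * nie
  pm <- if (te != 1) 100 * log(nie) / log(te) else NA_real_

  list(stats = c(te = te, direct = nde, indirect = nie, pm_pct = pm),
       detail = list(mediator_coef = med$coef, cox_coef = cf),
       sobel = NULL)
}

# ---- bias-corrected bootstrap ------------------------------------------------

#' Bias-corrected bootstrap over subjects
#'
#' Nonparametric resampling of subjects with replacement; replicate `r`
#' draws its resample from child seed stream `r` of the root seed, so
#' increasing `n_boot` extends rather than reshuffles the replicate set.
#' Intervals are bias-corrected percentile (BC): the percentile bounds are
#' shifted by `2 * z0` where `z0` is the normal quantile of the fraction of
#' replicates strictly below the point estimate. Failed replicates are
#' dropped and counted; more than 10\% failures is a hard error.
#'
#' @param stat_fun function of an index vector returning `list(stats = ...)`
#'   with a named numeric vector.
#' @param n number of subjects.
#' @param point named point-estimate vector (from the full sample).
#' @param n_boot number of replicates.
#' @param seed root seed.
#' @param conf_level confidence level.
#' @return list with `ci` (matrix stats x (low, high)), `se`, `z0`,
#'   `n_failed`, `replicates`.
#' @keywords internal
bc_boot <- function(stat_fun, n, point, n_boot, seed, conf_level = 0.95) {
  seeds <- child_seeds(seed, n_boot)
  reps <- matrix(NA_real_, n_boot, length(point),
                 dimnames = list(NULL, names(point)))
  n_failed <- 0L
  for (r in seq_len(n_boot)) {
    set.seed(seeds[r])
    idx <- sample.int(n, n, replace = TRUE)
    st <- tryCatch(stat_fun(idx)$stats, error = function(e) NULL)
    if (is.null(st)) n_failed <- n_failed + 1L else reps[r, ] <- st
  }
  if (n_failed > 0.10 * n_boot)
    stop(sprintf("bootstrap failure rate too high: %d of %d replicates failed",
                 n_failed, n_boot), call. = FALSE)
  ok <- stats::complete.cases(reps)
  reps <- reps[ok, , drop = FALSE]

  alpha <- 1 - conf_level
  ci <- matrix(NA_real_, length(point), 2L,
               dimnames = list(names(point), c("low", "high")))
  z0 <- stats::setNames(numeric(length(point)), names(point))
  for (j in seq_along(point)) {
    x <- reps[, j]
    x <- x[is.finite(x)]
    if (!length(x) || !is.finite(point[j])) next
    frac <- mean(x < point[j])
    z0j <- if (frac <= 0) -Inf else if (frac >= 1) Inf else stats::qnorm(frac)
    plo <- stats::pnorm(2 * z0j + stats::qnorm(alpha / 2))
    phi <- stats::pnorm(2 * z0j + stats::qnorm(1 - alpha / 2))
    ci[j, ] <- boot_percentile(x, c(plo, phi))
    z0[j] <- z0j
  }
  list(ci = ci, se = apply(reps, 2L, stats::sd), z0 = z0,
       n_failed = n_failed, replicates = reps)
}

# Bootstrap percentile endpoints under the canonical convention: the
# (R+1)*p order statistic, interpolating between adjacent order statistics
# on the normal-quantile scale (Efron-style, as in standard BC software).
# Plain empirical quantiles give systematically narrower tails at moderate R.
boot_percentile <- function(x, probs) {
  x <- sort(x)
  R <- length(x)
  vapply(probs, function(p) {
    rk <- (R + 1) * p
    k <- trunc(rk)
    if (k <= 0) return(x[1L])
    if (k >= R) return(x[R])
    if (rk == k) return(x[k])
    g <- (stats::qnorm(p) - stats::qnorm(k / (R + 1))) /
      (stats::qnorm((k + 1) / (R + 1)) - stats::qnorm(k / (R + 1)))
    if (!is.finite(g)) g <- rk - k
    x[k] + g * (x[k + 1L] - x[k])
  }, numeric(1))
}

# ---- methods -----------------------------------------------------------------

#' @export
print.o3_mediation <- function(x, ...) {
  lab <- c(te = "Total effect", direct = "Direct effect (NDE)",
           indirect = "Indirect effect (NIE)")
  cat(sprintf("<o3_mediation> variant: %s | scale: %s | n = %d\n",
              x$variant, x$scale, x$n))
  cat(sprintf("  exposure contrast: %.2f -> %.2f (per %.2f ug/m3)\n",
              x$contrast[1L], x$contrast[2L], x$iqr))
  for (nm in names(lab)) {
    line <- sprintf("  %-22s %.4f", lab[[nm]], x$estimates[[nm]])
    if (!is.null(x$ci) && nm %in% rownames(x$ci))
      line <- sprintf("%s (%.4f-%.4f)", line, x$ci[nm, 1L], x$ci[nm, 2L])
    cat(line, "\n")
  }
  cat(sprintf("  %-22s %.2f%%\n", "Mediation effect", x$estimates[["pm_pct"]]))
  if (!is.null(x$sobel))
    cat(sprintf("  Sobel z = %.3f (p = %.3g)\n", x$sobel$z, x$sobel$p))
  if (x$n_boot > 0)
    cat(sprintf("  bootstrap: %d replicates (%d failed), BC %.0f%% CI, seed %s\n",
                x$n_boot, x$n_failed, 100 * x$conf_level, format(x$seed)))
  for (nt in x$notes) cat("  note:", nt, "\n")
  invisible(x)
}

#' @export
coef.o3_mediation <- function(object, ...) object$estimates

#' @export
confint.o3_mediation <- function(object, parm, level, ...) {
  if (is.null(object$ci))
    stop("no bootstrap intervals: refit with n_boot > 0", call. = FALSE)
  ci <- object$ci
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
summary.o3_mediation <- function(object, ...) {
  est <- object$estimates
  out <- data.frame(
    quantity = names(est),
    estimate = as.numeric(est),
    ci_low = if (!is.null(object$ci)) object$ci[names(est), 1L] else NA_real_,
    ci_high = if (!is.null(object$ci)) object$ci[names(est), 2L] else NA_real_,
    se = if (!is.null(object$se)) object$se[names(est)] else NA_real_,
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(list(table = out, variant = object$variant, scale = object$scale,
                 contrast = object$contrast, n = object$n,
                 n_boot = object$n_boot, notes = object$notes),
            class = "summary.o3_mediation")
}

#' @export
print.summary.o3_mediation <- function(x, ...) {
  cat(sprintf("Mediation decomposition (%s, %s scale), n = %d\n",
              x$variant, x$scale, x$n))
  print(transform(x$table, estimate = signif(estimate, 5),
                  ci_low = signif(ci_low, 5), ci_high = signif(ci_high, 5),
                  se = signif(se, 4)), row.names = FALSE)
  for (nt in x$notes) cat("note:", nt, "\n")
  invisible(x)
}
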
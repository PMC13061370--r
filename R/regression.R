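#' Fit the logistic outcome or mediator model
#'
#' Maximum-likelihood logistic regression via [stats::glm()]; with weights it
#' is a weighted pseudo-likelihood fit and a robust (sandwich) covariance is
#' attached in addition to the model-based one. Non-convergence is an
#' explicit failure and complete/quasi-complete separation is detected and
#' raised as a diagnostic error rather than silently tolerated.
#'
#' @param formula model formula; the binary outcome on the left.
#' @param data data frame.
#' @param weights optional non-negative case weights (e.g. the final column
#'   of a [compose_weights()] weight set).
#' @param tol convergence tolerance on the relative deviance change (tight
#'   enough that closed-form 2x2 odds ratios are reproduced to 1e-8).
#' @param max_iter IRLS iteration cap.
#' @return object of class `oz_fit`: list with `coefficients`, `vcov`,
#'   `robust_vcov` (NULL unless weighted), `n_used`, `converged`, `loglik`,
#'   `family = "logistic"`, and the underlying `fit`.
#' @export
fit_logistic <- function(formula, data, weights = NULL, tol = 1e-12,
                         max_iter = 100L) {
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("weights must be non-negative", call. = FALSE)
    data$.w <- weights
  }
  yvar <- all.vars(formula[[2L]])
  yvals <- stats::na.omit(data[[yvar]])
  if (!all(yvals %in% c(0, 1)))
    stop("outcome '", yvar, "' must be binary 0/1", call. = FALSE)

  fit <- withCallingHandlers(
    if (is.null(weights)) {
      stats::glm(formula, data = data, family = stats::binomial(),
                 control = stats::glm.control(epsilon = tol, maxit = max_iter))
    } else {
      stats::glm(formula, data = data, family = stats::binomial(),
                 weights = .w,
                 control = stats::glm.control(epsilon = tol, maxit = max_iter))
    },
    warning = function(w) {
      # perfect separation is re-raised as an error below; fractional case
      # weights are expected under pseudo-likelihood
      if (grepl("fitted probabilities numerically 0 or 1|non-integer #successes",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    }
  )

  if (!fit$converged)
    stop(sprintf("logistic fit did not converge in %d IRLS iterations (deviance %.6g)",
                 fit$iter, fit$deviance), call. = FALSE)
  mu <- stats::fitted(fit)
  if (any(abs(stats::coef(fit)) > 15) && (any(mu < 1e-10) || any(mu > 1 - 1e-10)))
    stop("complete or quasi-complete separation detected in logistic fit",
         call. = FALSE)

  robust <- if (!is.null(weights)) sandwich::sandwich(fit) else NULL
  structure(list(
    coefficients = stats::coef(fit),
    vcov = stats::vcov(fit),
    robust_vcov = robust,
    n_used = stats::nobs(fit),
    converged = fit$converged,
    iterations = fit$iter,
    loglik = as.numeric(stats::logLik(fit)),
    family = "logistic",
    formula = formula,
    fit = fit
  ), class = "oz_fit")
}

#' Fit the Cox sensitivity model on the gestational-age time scale
#'
#' Proportional-hazards fit via [survival::coxph()] with the Efron
#' approximation for ties (gestational age in weeks is heavily tied). Every
#' subject fails or is censored at delivery.
#'
#' @param formula a formula whose left side is `survival::Surv(time, event)`,
#'   with time the gestational age at delivery (weeks).
#' @param data data frame.
#' @param weights optional case weights (robust variance is then used).
#' @param ties tie-handling method, `"efron"` (default) or `"breslow"`.
#' @return object of class `oz_fit` with `family = "cox"`.
#' @export
fit_cox <- function(formula, data, weights = NULL, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  ev <- eval(formula[[2L]], envir = data, enclos = environment(formula))
  if (sum(ev[, "status"]) == 0) stop("no events in the data", call. = FALSE)
  if (!is.null(weights)) data$.w <- weights
  fit <- if (is.null(weights)) {
    survival::coxph(formula, data = data, ties = ties)
  } else {
    survival::coxph(formula, data = data, weights = .w, ties = ties,
                    robust = TRUE)
  }
  if (any(!is.finite(stats::coef(fit))))
    stop("Cox fit did not converge (non-finite coefficients)", call. = FALSE)
  structure(list(
    coefficients = stats::coef(fit),
    vcov = stats::vcov(fit),
    robust_vcov = if (!is.null(weights)) fit$var else NULL,
    n_used = fit$n,
    converged = TRUE,
    iterations = fit$iter,
    loglik = fit$loglik[2L],
    family = "cox",
    ties = ties,
    formula = formula,
    fit = fit
  ), class = "oz_fit")
}

#' @export
print.oz_fit <- function(x, ...) {
  cat(sprintf("<oz_fit> %s model, n = %d%s\n", x$family, x$n_used,
              if (!is.null(x$robust_vcov)) " (robust covariance attached)" else ""))
  print(round(x$coefficients, 6))
  invisible(x)
}

#' @export
coef.oz_fit <- function(object, ...) object$coefficients

#' @export
vcov.oz_fit <- function(object, robust = !is.null(object$robust_vcov), ...) {
  if (robust && !is.null(object$robust_vcov)) object$robust_vcov else object$vcov
}

#' Per-IQR effect estimate from a fitted model
#'
#' Rescales a log-odds (or log-hazard) coefficient to the exposure IQR:
#' `rr = exp(coef * iqr)` with Wald interval
#' `exp((coef +/- z * se) * iqr)`. The SE is taken from the robust
#' covariance when one is attached, else the model-based covariance.
#' Following the rare-outcome convention, logistic odds ratios are labelled
#' `or_as_rr` when the baseline outcome prevalence is below 10% (the
#' prevalence check is recorded in the output); Cox effects are labelled
#' `hr`.
#'
#' @param model an `oz_fit`.
#' @param iqr the exposure IQR (same units as the model's exposure term).
#' @param term coefficient name (default the first non-intercept term).
#' @param prevalence baseline outcome prevalence used for the OR-as-RR
#'   label (logistic only); `NA` skips the check and labels the estimate
#'   `or`.
#' @param conf_level confidence level.
#' @return one-row data frame: `term, rr, ci_low, ci_high, scale_note, per,
#'   se_log, prevalence`.
#' @export
rr_per_iqr <- function(model, iqr, term = NULL, prevalence = NA_real_,
                       conf_level = 0.95) {
  stopifnot(inherits(model, "oz_fit"))
  if (is.null(term)) {
    cand <- setdiff(names(model$coefficients), "(Intercept)")
    term <- cand[1L]
  }
  if (!term %in% names(model$coefficients))
    stop("term '", term, "' not in the fitted model", call. = FALSE)
  b <- model$coefficients[[term]]
  V <- vcov(model)
  se <- sqrt(V[term, term])
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  scale_note <- if (model$family == "cox") "hr"
    else if (!is.na(prevalence) && prevalence < 0.10) "or_as_rr"
    else "or"
  data.frame(
    term = term,
    rr = exp(b * iqr),
    ci_low = exp((b - z * se) * iqr),
    ci_high = exp((b + z * se) * iqr),
    scale_note = scale_note,
    per = iqr,
    se_log = se * iqr,
    prevalence = prevalence,
    stringsAsFactors = FALSE
  )
}

# ---- fast refit machinery for the bootstrap ---------------------------------
# glm.fit on a prebuilt model matrix, warm-started at the full-data estimates;
# this is the same IRLS engine as glm() without formula/model-frame overhead.
fast_logit_fit <- function(X, y, w = NULL, start = NULL) {
  fit <- suppressWarnings(stats::glm.fit(
    X, y, weights = w %||% rep(1, length(y)),
    start = start, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-8, maxit = 50)
  ))
  if (!fit$converged) stop("glm.fit did not converge", call. = FALSE)
  fit$coefficients
}
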
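#' Raking (iterative proportional fitting) calibration weights
#'
#' Reweights the sample so that, for each calibration variable, the weighted
#' category shares match known population margins. Classical raking: sweep
#' the margin variables in turn, multiplying each category's weights by
#' target share / current weighted share, until every margin matches within
#' `tol`.
#'
#' @param data data frame containing the margin variables (as categories).
#' @param targets named list: one element per margin variable, itself a named
#'   numeric vector of target proportions (or counts; normalized internally)
#'   over that variable's categories.
#' @param tol maximum absolute deviation of any weighted share from target.
#' @param max_iter maximum number of full sweeps.
#' @param base_weights optional starting weights (default 1).
#' @return list with `weights` (mean 1), `iterations`, and
#'   `max_margin_error`.
#' @export
calibrate_raking <- function(data, targets, tol = 1e-10, max_iter = 100L,
                             base_weights = NULL) {
  stopifnot(is.data.frame(data), is.list(targets), length(targets) >= 1L,
            !is.null(names(targets)))
  n <- nrow(data)
  w <- base_weights %||% rep(1, n)
  stopifnot(length(w) == n, all(w >= 0))

  fac <- list()
  for (v in names(targets)) {
    if (!v %in% names(data)) stop("margin variable '", v, "' not in data", call. = FALSE)
    tg <- targets[[v]]
    if (is.null(names(tg)) || any(tg < 0))
      stop("targets for '", v, "' must be a named non-negative vector", call. = FALSE)
    targets[[v]] <- tg / sum(tg)
    x <- as.character(data[[v]])
    extra <- setdiff(unique(x), names(tg))
    if (length(extra))
      stop("sample categories missing from targets for '", v, "': ",
           paste(extra, collapse = ", "), call. = FALSE)
    present <- names(tg)[names(tg) %in% unique(x)]
    if (any(targets[[v]][setdiff(names(tg), present)] > 0))
      stop("target category with no sample support for '", v, "'", call. = FALSE)
    fac[[v]] <- factor(x, levels = present)
    targets[[v]] <- targets[[v]][present] / sum(targets[[v]][present])
  }

  margin_error <- function(w) {
    max(vapply(names(targets), function(v) {
      share <- tapply(w, fac[[v]], sum, default = 0) / sum(w)
      max(abs(share - targets[[v]]))
    }, numeric(1)))
  }

  it <- 0L
  err <- margin_error(w)
  while (err > tol && it < max_iter) {
    it <- it + 1L
    for (v in names(targets)) {
      share <- tapply(w, fac[[v]], sum, default = 0) / sum(w)
      adj <- targets[[v]] / share
      w <- w * adj[as.integer(fac[[v]])]
    }
    err <- margin_error(w)
  }
  if (err > tol) {
    worst <- vapply(names(targets), function(v) {
      share <- tapply(w, fac[[v]], sum, default = 0) / sum(w)
      max(abs(share - targets[[v]]))
    }, numeric(1))
    stop(sprintf(
      "raking did not converge in %d sweeps; worst margin '%s' off by %.3g",
      max_iter, names(which.max(worst)), max(worst)), call. = FALSE)
  }
  list(weights = as.numeric(w / mean(w)), iterations = it, max_margin_error = err)
}

#' Selection probabilities and inverse-probability-of-selection weights
#'
#' Fits a logistic model for inclusion in the analytic sample on the
#' eligibility-level table and returns each subject's selection probability
#' together with the IPSW (`1 / probability`) for the included subjects
#' (`NA` for the excluded).
#'
#' @param data eligibility-level data frame including the inclusion flag.
#' @param inclusion name of the binary inclusion-flag column.
#' @param covariates character vector of predictor column names.
#' @return list with `selection_probability`, `ipsw`, and the fitted
#'   `oz_fit` as `model`.
#' @export
fit_selection_ipsw <- function(data, inclusion = "included",
                               covariates = c("maternal_age_y", "infant_sex",
                                              "gestational_diabetes",
                                              "husband_smoking", "occupation")) {
  stopifnot(inclusion %in% names(data))
  flag <- data[[inclusion]]
  if (!all(flag %in% c(0, 1))) stop("inclusion flag must be binary 0/1", call. = FALSE)
  if (sum(flag) == 0) stop("included subset is empty", call. = FALSE)
  if (all(flag == 1)) {
    # degenerate but legal: everyone sampled, all weights 1
    n <- length(flag)
    return(list(selection_probability = rep(1, n), ipsw = rep(1, n),
                model = NULL))
  }
  f <- stats::reformulate(covariates, response = inclusion)
  mod <- fit_logistic(f, data)
  p <- stats::predict(mod$fit, newdata = data, type = "response")
  if (any(p[flag == 1] < 1e-12)) {
    bad <- which(flag == 1 & p < 1e-12)
    stop("numerically zero selection probability for included subjects: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  ipsw <- ifelse(flag == 1, 1 / p, NA_real_)
  list(selection_probability = as.numeric(p), ipsw = ipsw, model = mod)
}

#' Compose the final analysis weights
#'
#' Final analytic weight = calibration weight x IPSW, truncated at the
#' empirical 99th percentile of the composite distribution, then rescaled to
#' mean 1 (i.e. the weights sum to the sample size). The truncation cap is
#' the upper order statistic at position `ceiling(p * n)` rather than an
#' interpolated quantile: with that convention capping is exactly
#' idempotent (re-composing already-truncated weights changes nothing),
#' which interpolated quantiles cannot guarantee.
#'
#' @param calibration numeric calibration weights.
#' @param ipsw numeric inverse-probability-of-selection weights.
#' @param truncation_pct percentile cap (default 99); `NA` disables capping.
#' @param normalize rescale to mean 1 (default TRUE).
#' @return object of class `weight_set`: data frame with columns
#'   `calibration_weight`, `ipsw`, `raw_composite`, `final_weight`, plus
#'   attributes `truncation_pct`, `cap`, `normalization_constant`.
#' @export
compose_weights <- function(calibration, ipsw, truncation_pct = 99,
                            normalize = TRUE) {
  stopifnot(length(calibration) == length(ipsw))
  raw <- calibration * ipsw
  if (all(!is.finite(raw)) || all(raw == 0, na.rm = TRUE))
    stop("composite weights are all zero or non-finite", call. = FALSE)
  cap <- NA_real_
  w <- raw
  if (!is.na(truncation_pct)) {
    x <- sort(raw[is.finite(raw)])
    cap <- x[ceiling(truncation_pct / 100 * length(x))]
    w <- pmin(raw, cap)
  }
  norm_const <- 1
  if (normalize) {
    norm_const <- mean(w, na.rm = TRUE)
    w <- w / norm_const
  }
  out <- data.frame(calibration_weight = calibration, ipsw = ipsw,
                    raw_composite = raw, final_weight = w)
  structure(out, truncation_pct = truncation_pct, cap = cap,
            normalization_constant = norm_const,
            class = c("weight_set", "data.frame"))
}

#' @export
print.weight_set <- function(x, ...) {
  w <- x$final_weight
  cat(sprintf(
    "<weight_set> n = %d | mean %.6f | range [%.4f, %.4f] | cap (p%.0f) = %.4f\n",
    nrow(x), mean(w, na.rm = TRUE), min(w, na.rm = TRUE), max(w, na.rm = TRUE),
    attr(x, "truncation_pct"), attr(x, "cap")))
  invisible(x)
}
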
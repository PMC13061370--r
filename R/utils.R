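#' @keywords internal
"_PACKAGE"

# expit/logit kept explicit so the mediation algebra reads like the formulas
# (expit inlined rather than plogis: it sits in the bootstrap hot loop)
expit <- function(x) 1 / (1 + exp(-x))
logit <- stats::qlogis

odds <- function(p) p / (1 - p)

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive reproducible child seeds from a root seed
#'
#' All stochastic stages draw their own seed from a fixed table generated once
#' from the root seed, so adding a stage (or more bootstrap replicates) never
#' perturbs the draws of earlier stages.
#'
#' @param seed integer root seed.
#' @param n number of child seeds.
#' @return integer vector of `n` seeds, each in `[1, 2^31 - 2]`.
#' @keywords internal
child_seeds <- function(seed, n = 64L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  sample.int(2147483646L, n)
}

# Quantile convention used throughout (IQR scale, weight truncation):
# linear interpolation between order statistics (R type 7).
QUANTILE_TYPE <- 7L

quantile7 <- function(x, probs) {
  stats::quantile(x, probs = probs, type = QUANTILE_TYPE, names = FALSE, na.rm = TRUE)
}

#' Truncated-normal sampler (rejection-free, via CDF inversion)
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- stats::runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration field '%s': %s", field, msg), call. = FALSE)
}
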
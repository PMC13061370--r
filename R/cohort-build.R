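#' Default eligibility rules
#'
#' The eligibility cascade in its documented order. Each rule is named; a
#' record is claimed by the first rule it fails (exclusive attribution), so
#' the report arithmetic reproduces a study flowchart.
#'
#' @param maternal_age_range,gestational_age_range,birth_weight_range numeric
#'   length-2 inclusive ranges; the birth-weight plausibility window defaults
#'   to 500-6000 g.
#' @return named list of predicate functions (`TRUE` = record passes).
#' @export
eligibility_rules <- function(maternal_age_range = c(20, 45),
                              gestational_age_range = c(37, 45),
                              birth_weight_range = c(500, 6000)) {
  in_range <- function(x, r) !is.na(x) & x >= r[1L] & x <= r[2L]
  list(
    singleton = function(d) !is.na(d$plurality) & d$plurality == 1L,
    firstborn = function(d) !is.na(d$birth_order) & d$birth_order == 1L,
    maternal_age = function(d) in_range(d$maternal_age_y, maternal_age_range),
    term_birth = function(d) in_range(d$gestational_age_wk, gestational_age_range),
    complete_linkage = function(d) {
      if (is.null(d$complete_linkage)) rep(TRUE, nrow(d))
      else !is.na(d$complete_linkage) & d$complete_linkage == 1L
    },
    married = function(d) !is.na(d$marital_status) & d$marital_status == "married",
    nonmissing_exposure = function(d) !is.na(d$exposure_o3),
    plausible_birth_weight = function(d) in_range(d$birth_weight_g, birth_weight_range)
  )
}

#' Apply the eligibility cascade
#'
#' Rules are applied in the order given; each record is attributed to the
#' first rule it fails. A record for which a rule cannot even be evaluated
#' (a needed field is absent from the table) is excluded under a dedicated
#' `unparseable` criterion rather than silently dropped.
#'
#' @param records data frame of birth records.
#' @param rules named list of predicate functions, as from
#'   [eligibility_rules()].
#' @return list with `records` (the survivors) and `report`
#'   (an [eligibility_report()]).
#' @export
apply_eligibility <- function(records, rules = eligibility_rules()) {
  stopifnot(is.data.frame(records), is.list(rules))
  if (is.null(names(rules)) || any(names(rules) == ""))
    stop("eligibility rules must be a fully named list", call. = FALSE)
  n0 <- nrow(records)
  if (n0 == 0L) {
    rep0 <- eligibility_report(0L, stats::setNames(rep(0L, length(rules) + 1L),
                                                   c(names(rules), "unparseable")))
    return(list(records = records, report = rep0))
  }

  claimed <- rep(NA_character_, n0)
  unparseable <- rep(FALSE, n0)
  for (nm in names(rules)) {
    open <- is.na(claimed) & !unparseable
    if (!any(open)) break
    pass <- tryCatch(rules[[nm]](records), error = function(e) NULL)
    if (is.null(pass) || length(pass) != n0 || !is.logical(pass)) {
      unparseable[open] <- TRUE
      next
    }
    pass[is.na(pass)] <- FALSE
    claimed[open & !pass] <- nm
  }
  claimed[unparseable & is.na(claimed)] <- "unparseable"

  counts <- vapply(c(names(rules), "unparseable"),
                   function(nm) sum(claimed == nm, na.rm = TRUE), integer(1))
  survivors <- records[is.na(claimed), , drop = FALSE]
  list(records = survivors, report = eligibility_report(n0, counts))
}

#' Construct an eligibility (flowchart) report
#'
#' @param n_input number of records entering the cascade.
#' @param exclusions named integer vector of exclusive exclusion counts, in
#'   cascade order.
#' @return object of class `eligibility_report`: data frame of
#'   (criterion, n_excluded, n_remaining) with attribute `n_input`.
#' @export
eligibility_report <- function(n_input, exclusions) {
  stopifnot(length(n_input) == 1L, n_input >= 0,
            is.numeric(exclusions), !is.null(names(exclusions)))
  if (any(exclusions < 0)) stop("exclusion counts must be non-negative", call. = FALSE)
  remaining <- n_input - cumsum(as.numeric(exclusions))
  if (any(remaining < 0))
    stop("exclusions exceed the input count; report is inconsistent", call. = FALSE)
  out <- data.frame(criterion = names(exclusions),
                    n_excluded = as.numeric(exclusions),
                    n_remaining = remaining,
                    stringsAsFactors = FALSE)
  structure(out, n_input = n_input, class = c("eligibility_report", "data.frame"))
}

#' @export
print.eligibility_report <- function(x, ...) {
  cat(sprintf("<eligibility_report> input n = %s\n",
              format(attr(x, "n_input"), big.mark = ",")))
  df <- as.data.frame(x)
  df$n_excluded <- format(df$n_excluded, big.mark = ",")
  df$n_remaining <- format(df$n_remaining, big.mark = ",")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Derive term LBW and term SGA outcome flags
#'
#' Term low birth weight is birth weight strictly below 2500 g. Term SGA is
#' birth weight strictly below the sex- and gestational-age-specific 10th
#' percentile of a growth reference; gestational age is looked up by
#' completed weeks (floor). When the reference lacks the (week, sex) row the
#' SGA flag is `NA` — missingness is a value, not an error.
#'
#' @param records data frame with `birth_weight_g`, `gestational_age_wk`,
#'   `infant_sex`.
#' @param reference growth reference data frame with columns
#'   `gestational_age_wk` (integer weeks), `infant_sex`, `p10_weight_g`.
#' @param lbw_cutoff_g LBW threshold in grams.
#' @return `records` with integer columns `term_lbw` and `term_sga` added.
#' @export
derive_outcomes <- function(records, reference, lbw_cutoff_g = 2500) {
  stopifnot(is.data.frame(records), is.data.frame(reference))
  req <- c("gestational_age_wk", "infant_sex", "p10_weight_g")
  if (!all(req %in% names(reference)))
    stop("growth reference must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  records$term_lbw <- as.integer(records$birth_weight_g < lbw_cutoff_g)
  wk <- floor(records$gestational_age_wk)
  key <- paste(wk, records$infant_sex)
  ref_key <- paste(reference$gestational_age_wk, reference$infant_sex)
  p10 <- reference$p10_weight_g[match(key, ref_key)]
  records$term_sga <- as.integer(records$birth_weight_g < p10)  # NA when no row
  records
}

#' Build a synthetic 10th-percentile growth reference
#'
#' A smooth, strictly increasing weight-for-gestational-age 10th-percentile
#' table by sex, spanning completed weeks 33-45. This is a synthetic
#' stand-in shaped like published fetal growth standards (not the published
#' values); use [read_growth_reference()] to supply a real table.
#'
#' @param weeks integer vector of completed gestational weeks.
#' @return data frame (gestational_age_wk, infant_sex, p10_weight_g).
#' @export
make_growth_reference <- function(weeks = 33:45) {
  # concave weight-for-age curve: ~2500 g at 37 wk rising to ~3000 g at 42 wk
  p10 <- function(w, sex) {
    base <- 2500 + 130 * (w - 37) - 6 * (w - 37)^2
    round(base + ifelse(sex == "male", 40, -40))
  }
  grid <- expand.grid(gestational_age_wk = as.integer(weeks),
                      infant_sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  grid$p10_weight_g <- p10(grid$gestational_age_wk, grid$infant_sex)
  grid[order(grid$infant_sex, grid$gestational_age_wk), , drop = FALSE]
}

#' Read a growth reference from 3-column delimited text
#'
#' @param path file with header columns `gestational_age_wk`, `infant_sex`,
#'   `p10_weight_g` (tab- or comma-delimited).
#' @return validated growth reference data frame.
#' @export
read_growth_reference <- function(path) {
  ref <- utils::read.delim(path, sep = "", stringsAsFactors = FALSE)
  if (ncol(ref) == 1L) ref <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("gestational_age_wk", "infant_sex", "p10_weight_g")
  if (!all(req %in% names(ref)))
    stop("growth reference must have columns: ", paste(req, collapse = ", "),
         call. = FALSE)
  for (s in unique(ref$infant_sex)) {
    sub <- ref[ref$infant_sex == s, ]
    sub <- sub[order(sub$gestational_age_wk), ]
    if (any(diff(sub$p10_weight_g) <= 0))
      stop("p10_weight_g must be strictly increasing in gestational age within sex",
           call. = FALSE)
  }
  ref
}

#' Whole-pregnancy mean exposure from a daily series
#'
#' Arithmetic mean of the available daily concentrations over the closed
#' interval \[lmp_date, delivery_date\]. When the series covers less than
#' `min_coverage` of the days in the window, the exposure is returned as
#' missing (this feeds the missing-exposure eligibility rule).
#'
#' @param series data frame with columns `date` and `o3_ugm3` (one subject).
#' @param lmp_date,delivery_date window bounds (`Date` or ISO-8601 strings).
#' @param min_coverage minimum fraction of window days with data.
#' @return list with `mean` (NA if under-covered), `coverage`, `n_days`.
#' @export
window_exposure <- function(series, lmp_date, delivery_date, min_coverage = 0.8) {
  lmp_date <- as.Date(lmp_date); delivery_date <- as.Date(delivery_date)
  if (delivery_date <= lmp_date)
    stop("delivery_date must be after lmp_date", call. = FALSE)
  days <- seq(lmp_date, delivery_date, by = "day")
  sub <- series[as.Date(series$date) %in% days & !is.na(series$o3_ugm3), , drop = FALSE]
  coverage <- nrow(sub) / length(days)
  list(
    mean = if (coverage >= min_coverage) mean(sub$o3_ugm3) else NA_real_,
    coverage = coverage,
    n_days = length(days)
  )
}

#' Exposure quartiles and IQR under the package quantile convention
#'
#' The interquartile range is the unit in which all exposure effects are
#' reported. Quantiles use linear interpolation between order statistics
#' (R type 7), fixed and documented so per-IQR effects are reproducible.
#'
#' @param x numeric exposure values (NA allowed).
#' @return list `(q25, q75, iqr)`; warns when the scale is degenerate
#'   (iqr = 0).
#' @export
compute_iqr_scale <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2L) stop("need at least 2 non-missing values", call. = FALSE)
  q <- quantile7(x, c(0.25, 0.75))
  iqr <- q[2L] - q[1L]
  if (iqr == 0) warning("degenerate exposure scale: IQR is 0", call. = FALSE)
  list(q25 = q[1L], q75 = q[2L], iqr = iqr)
}
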
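toy_records <- function() {
  # 20 records engineered so each eligibility rule claims at least one
  base <- data.frame(
    subject_id = sprintf("T%02d", 1:20),
    plurality = 1L, birth_order = 1L, maternal_age_y = 28,
    gestational_age_wk = 39, marital_status = "married",
    exposure_o3 = 110, birth_weight_g = 3300,
    stringsAsFactors = FALSE
  )
  base$plurality[1] <- 2L
  base$birth_order[2] <- 3L
  base$maternal_age_y[3] <- 19
  base$maternal_age_y[4] <- 46
  base$gestational_age_wk[5] <- 36
  base$gestational_age_wk[6] <- 46
  base$marital_status[7] <- "single"
  base$exposure_o3[8] <- NA
  base$birth_weight_g[9] <- 250
  base$birth_weight_g[10] <- 7000
  base$plurality[11] <- 2L; base$marital_status[11] <- "single"  # first rule claims
  base$maternal_age_y[12] <- NA
  base
}

test_that("eligibility cascade matches an exhaustive record-by-record oracle", {
  rec <- toy_records()
  res <- apply_eligibility(rec)
  # independent oracle: re-evaluate every rule per record, first failure wins
  oracle_claim <- function(r) {
    if (is.na(r$plurality) || r$plurality != 1) return("singleton")
    if (is.na(r$birth_order) || r$birth_order != 1) return("firstborn")
    if (is.na(r$maternal_age_y) || r$maternal_age_y < 20 || r$maternal_age_y > 45)
      return("maternal_age")
    if (is.na(r$gestational_age_wk) || r$gestational_age_wk < 37 ||
        r$gestational_age_wk > 45) return("term_birth")
    if (is.na(r$marital_status) || r$marital_status != "married") return("married")
    if (is.na(r$exposure_o3)) return("nonmissing_exposure")
    if (is.na(r$birth_weight_g) || r$birth_weight_g < 500 ||
        r$birth_weight_g > 6000) return("plausible_birth_weight")
    NA_character_
  }
  claims <- vapply(seq_len(nrow(rec)), function(i) oracle_claim(rec[i, ]),
                   character(1))
  expect_identical(sort(res$records$subject_id), sort(rec$subject_id[is.na(claims)]))
  for (nm in unique(stats::na.omit(claims))) {
    expect_equal(res$report$n_excluded[res$report$criterion == nm],
                 sum(claims == nm, na.rm = TRUE))
  }
  # conservation: input = survivors + sum of exclusive exclusions
  expect_equal(nrow(rec), nrow(res$records) + sum(res$report$n_excluded))
})

test_that("empty input yields an empty report with zero counts", {
  res <- apply_eligibility(toy_records()[0, ])
  expect_identical(nrow(res$records), 0L)
  expect_true(all(res$report$n_excluded == 0))
})

test_that("a record a rule cannot evaluate is excluded as unparseable", {
  rec <- toy_records()[13:20, ]
  rec$exposure_o3 <- NULL  # the exposure rule cannot be evaluated at all
  res <- apply_eligibility(rec)
  expect_equal(sum(res$report$n_excluded[res$report$criterion == "unparseable"]), 8)
  expect_identical(nrow(res$records), 0L)
})

test_that("eligibility report construction enforces conservation", {
  rep <- eligibility_report(100, c(a = 40, b = 10))
  expect_identical(rep$n_remaining, c(60, 50))
  expect_error(eligibility_report(40, c(a = 41)), "inconsistent")
})

test_that("term LBW and SGA flags honor their strict thresholds", {
  ref <- data.frame(gestational_age_wk = 39L, infant_sex = "female",
                    p10_weight_g = 2800)
  rec <- data.frame(
    birth_weight_g = c(2499, 2500, 2799, 2800, 3000),
    gestational_age_wk = c(38, 38, 39.6, 39.2, 40),
    infant_sex = c("male", "male", "female", "female", "female")
  )
  out <- derive_outcomes(rec, ref)
  expect_identical(out$term_lbw, c(1L, 0L, 0L, 0L, 0L))
  # SGA looked up at completed weeks (floor); missing reference row -> NA
  expect_identical(out$term_sga, c(NA, NA, 1L, 0L, NA))
})

test_that("decreasing birth weight never flips an outcome flag off", {
  ref <- make_growth_reference()
  set.seed(42)
  rec <- data.frame(
    birth_weight_g = round(stats::runif(200, 1500, 4500)),
    gestational_age_wk = sample(seq(37, 45, by = 0.5), 200, TRUE),
    infant_sex = sample(c("male", "female"), 200, TRUE)
  )
  o1 <- derive_outcomes(rec, ref)
  rec2 <- rec
  rec2$birth_weight_g <- rec2$birth_weight_g - 200
  o2 <- derive_outcomes(rec2, ref)
  expect_true(all(o2$term_lbw >= o1$term_lbw))
  both <- !is.na(o1$term_sga) & !is.na(o2$term_sga)
  expect_true(all(o2$term_sga[both] >= o1$term_sga[both]))
})

test_that("growth reference validation and round trip work", {
  ref <- make_growth_reference()
  for (s in c("male", "female")) {
    sub <- ref[ref$infant_sex == s, ]
    expect_true(all(diff(sub$p10_weight_g) > 0))
  }
  f <- tempfile(fileext = ".tsv")
  utils::write.table(ref, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(read_growth_reference(f)$p10_weight_g, ref$p10_weight_g)
  bad <- ref
  bad$p10_weight_g[3] <- bad$p10_weight_g[4] + 50
  utils::write.table(bad, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_growth_reference(f), "increasing")
})

test_that("pregnancy-window exposure averaging matches hand-computed values", {
  days <- seq(as.Date("2020-01-01"), as.Date("2020-01-07"), by = "day")
  s <- data.frame(date = days, o3_ugm3 = c(90, 95, 100, 105, 110, 115, 120))
  res <- window_exposure(s, "2020-01-01", "2020-01-07")
  expect_equal(res$mean, 105)
  expect_equal(res$coverage, 1)
  # constant series
  s2 <- data.frame(date = days, o3_ugm3 = rep(100, 7))
  expect_equal(window_exposure(s2, "2020-01-01", "2020-01-07")$mean, 100)
  # under-covered window signals missing exposure
  s3 <- s[1:3, ]
  res3 <- window_exposure(s3, "2020-01-01", "2020-01-07", min_coverage = 0.8)
  expect_true(is.na(res3$mean))
  expect_equal(res3$coverage, 3 / 7)
  # mean is bounded by the series range
  set.seed(1)
  s4 <- data.frame(date = days, o3_ugm3 = stats::runif(7, 50, 150))
  r4 <- window_exposure(s4, "2020-01-01", "2020-01-07")
  expect_gte(r4$mean, min(s4$o3_ugm3))
  expect_lte(r4$mean, max(s4$o3_ugm3))
})

test_that("IQR scale follows the linear-interpolation quantile convention", {
  sc <- compute_iqr_scale(1:100)
  expect_equal(sc$q25, 25.75)
  expect_equal(sc$q75, 75.25)
  expect_equal(sc$iqr, 49.5)
  expect_warning(sc0 <- compute_iqr_scale(rep(7, 10)), "degenerate")
  expect_equal(sc0$iqr, 0)
  expect_error(compute_iqr_scale(c(NA, NA, 1)), "at least 2")
})
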
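test_that("inclusion keeps only rows with both instruments and age/diagnosis", {
  d <- toy_participants()   # rows 2 and 4 lack VAS, row 3 lacks EQ-5D
  out <- apply_inclusion(d)
  expect_equal(nrow(out), 2)
  expect_setequal(out$participant_id, c("P01", "P05"))
  excl <- exclusion_counts(out)
  expect_equal(excl$n[excl$reason == "no complete HRQoL assessment"], 3)
  expect_equal(excl$n[excl$reason == "retained"], 2)
})

test_that("missing diagnosis information is counted as its own reason", {
  d <- toy_participants()
  d$years_since_diagnosis[1] <- NA
  out <- apply_inclusion(d)
  excl <- exclusion_counts(out)
  expect_equal(excl$n[excl$reason == "incomplete age/diagnosis"], 1)
  expect_false("P01" %in% out$participant_id)
})

test_that("apply_inclusion is idempotent", {
  out1 <- apply_inclusion(toy_participants())
  out2 <- apply_inclusion(out1)
  strip <- function(x) { attr(x, "exclusions") <- NULL; as.data.frame(x) }
  expect_equal(strip(out1), strip(out2))
  expect_equal(exclusion_counts(out2)$n[1:2], c(0, 0))
})

test_that("last complete measurement wins; completeness dominates recency", {
  d <- tibble::tibble(
    participant_id = c("A", "A", "B", "B", "C"),
    measurement_date = as.Date(c("2019-05-01", "2021-05-01",
                                 "2019-01-01", "2021-01-01", "2020-01-01")),
    age_years = 50, years_since_diagnosis = 10,
    eq5d_index = c(80, 85, 70, NA, 90),
    vas = c(75L, 78L, 65L, 70L, 88L)
  )
  out <- select_last_complete(d)
  expect_equal(nrow(out), 3)
  expect_equal(out$eq5d_index[out$participant_id == "A"], 85)  # later complete
  expect_equal(out$eq5d_index[out$participant_id == "B"], 70)  # later is incomplete
  expect_equal(out$eq5d_index[out$participant_id == "C"], 90)  # single row
})

test_that("equal dates break ties by file order (last row wins)", {
  d <- tibble::tibble(
    participant_id = c("A", "A"),
    measurement_date = as.Date(c("2021-05-01", "2021-05-01")),
    age_years = 50, years_since_diagnosis = 10,
    eq5d_index = c(80, 85), vas = c(70L, 72L)
  )
  expect_equal(select_last_complete(d)$eq5d_index, 85)
})

test_that("missing categoricals become explicit unknown levels, no rows lost", {
  d <- tibble::tibble(
    phenotype = c("RRMS", NA, "SPMS"),
    living_situation = c(NA, "alone", "with_partner"),
    marital_status = c("married", "married", NA),
    education = c(NA, NA, "university"),
    smoking = c("never", NA, "current")
  )
  out <- encode_missing_categories(d)
  expect_equal(nrow(out), 3)
  expect_false(anyNA(out))
  expect_equal(out$phenotype[2], "unclear")
  expect_equal(sum(out$education == "other_or_unknown"), 2)
  expect_equal(out$smoking[2], "unknown")
  # idempotent, and a no-op without missing values
  expect_equal(as.data.frame(encode_missing_categories(out)),
               as.data.frame(out))
})

make_bmi_table <- function(n = 30) {
  withr::with_seed(21, tibble::tibble(
    age_years = seq(25, 70, length.out = n),
    sex = rep(c("female", "male"), length.out = n),
    srdss_class = rep(c("0-3.5", "4-6.5", ">=7"), length.out = n),
    diabetes1 = rep(c(FALSE, FALSE, TRUE), length.out = n),
    diabetes2 = FALSE,
    cardiovascular = rep(c(TRUE, FALSE), length.out = n),
    bmi = 20 + 0.1 * seq(25, 70, length.out = n)
  ))
}

test_that("deterministic BMI imputation recovers an exact linear rule", {
  d <- make_bmi_table()
  d$bmi[5] <- NA
  age5 <- d$age_years[5]
  out <- impute_bmi(d)
  expect_equal(out$bmi[5], 20 + 0.1 * age5, tolerance = 1e-8)
  expect_true(out$bmi_imputed[5])
  expect_false(any(out$bmi_imputed[-5]))
  # observed values untouched
  expect_equal(out$bmi[-5], d$bmi[-5])
})

test_that("imputation is a no-op when nothing is missing, and on re-run", {
  d <- make_bmi_table()
  out <- impute_bmi(d)
  expect_equal(out$bmi, d$bmi)
  d$bmi[3] <- NA
  once <- impute_bmi(d)
  twice <- impute_bmi(once)
  expect_equal(as.data.frame(once), as.data.frame(twice))
})

test_that("too few complete cases for the imputation model errors", {
  d <- make_bmi_table(8)
  d$bmi[1:6] <- NA
  expect_error(impute_bmi(d), class = "qolseg_validation")
})
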
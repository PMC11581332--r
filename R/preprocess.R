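# Inclusion and data-preparation rules applied to a raw participant table.
# A "complete HRQoL measurement" requires both instruments at the same
# assessment: a VAS and either a computable EQ-5D index or (when domain
# columns are present) all five domain levels.

hrqol_complete <- function(data) {
  has_profile <- all(eq5d_domains %in% names(data))
  eq_ok <- if (has_profile) {
    stats::complete.cases(data[, eq5d_domains, drop = FALSE])
  } else if ("eq5d_index" %in% names(data)) {
    !is.na(data$eq5d_index)
  } else {
    rep(FALSE, nrow(data))
  }
  vas_ok <- if ("vas" %in% names(data)) !is.na(data$vas) else rep(FALSE, nrow(data))
  eq_ok & vas_ok
}

#' Apply the study inclusion rules
#'
#' Retains rows with at least one complete HRQoL assessment (both EQ-5D and
#' VAS present at the same measurement) and non-missing age and years since
#' diagnosis, and returns a flowchart-style accounting of exclusions as the
#' `"exclusions"` attribute (also available via [exclusion_counts()]).
#'
#' @param data Raw participant table.
#' @return The retained rows as a tibble, with attribute `"exclusions"`.
#' @export
apply_inclusion <- function(data) {
  assert_columns(data, c("age_years", "years_since_diagnosis"))
  data <- tibble::as_tibble(data)
  age_ok <- !is.na(data$age_years) & !is.na(data$years_since_diagnosis)
  hr_ok <- hrqol_complete(data)
  keep <- age_ok & hr_ok
  excl <- tibble::tibble(
    reason = c("incomplete age/diagnosis", "no complete HRQoL assessment",
               "retained"),
    n = c(sum(!age_ok), sum(age_ok & !hr_ok), sum(keep))
  )
  if (!any(keep)) abort_validation("no rows satisfy the inclusion rules")
  out <- data[keep, , drop = FALSE]
  attr(out, "exclusions") <- excl
  out
}

#' Exclusion accounting of an [apply_inclusion()] result
#'
#' @param data A table returned by [apply_inclusion()].
#' @return A tibble of reasons and counts.
#' @export
exclusion_counts <- function(data) {
  attr(data, "exclusions") %||%
    abort_validation("no exclusion accounting attached; run apply_inclusion() first")
}

#' Select each participant's last complete HRQoL measurement
#'
#' Among a participant's complete measurements, keeps the one with the
#' latest `measurement_date`; ties are broken by the last row in file
#' order. Incomplete measurements never win, even if later ("last
#' complete", not "last").
#'
#' @param data Measurement-level table with `participant_id` and
#'   `measurement_date`.
#' @return One row per participant.
#' @export
select_last_complete <- function(data) {
  assert_columns(data, c("participant_id", "measurement_date"))
  data <- tibble::as_tibble(data)
  data$.row <- seq_len(nrow(data))
  ok <- hrqol_complete(data)
  if (!all(unique(data$participant_id) %in% data$participant_id[ok])) {
    abort_validation("some participants have no complete HRQoL measurement")
  }
  out <- data[ok, , drop = FALSE] |>
    dplyr::arrange(.data$measurement_date, .data$.row) |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::slice_tail(n = 1) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row)
  out$.row <- NULL
  out
}

missing_category_vars <- c(phenotype = "unclear",
                           living_situation = "unknown",
                           marital_status = "unknown",
                           education = "other_or_unknown",
                           smoking = "unknown")

#' Replace missing categorical values by explicit "unknown" levels
#'
#' For clinical phenotype, living situation, marital status, education and
#' smoking, missing values become an explicit category (the descriptive
#' table's "unknown" rows) so that no row is lost from the regression models.
#'
#' @param data Participant table.
#' @return The table with `NA`s in those five columns replaced.
#' @export
encode_missing_categories <- function(data) {
  data <- tibble::as_tibble(data)
  for (v in names(missing_category_vars)) {
    if (!v %in% names(data)) next
    x <- as.character(data[[v]])
    x[is.na(x)] <- missing_category_vars[[v]]
    data[[v]] <- x
  }
  data
}

#' Deterministically impute missing BMI
#'
#' Fits an ordinary least-squares model of BMI on age, sex, gait-impairment
#' class (SRDSS), diabetes (either type) and cardiovascular comorbidity on
#' the complete cases, and replaces missing BMI by the fitted value.
#' Observed BMI is never touched; imputed rows are flagged in
#' `bmi_imputed`. The imputation is deterministic -- a functional fill-in,
#' not multiple imputation.
#'
#' @param data Participant table with columns `bmi`, `age_years`, `sex`,
#'   `srdss_class`, `diabetes1`, `diabetes2`, `cardiovascular`.
#' @return The table with `bmi` completed and a logical `bmi_imputed` column.
#' @export
impute_bmi <- function(data) {
  assert_columns(data, c("bmi", "age_years", "sex", "srdss_class",
                         "diabetes1", "diabetes2", "cardiovascular"))
  data <- tibble::as_tibble(data)
  if (!"bmi_imputed" %in% names(data)) data$bmi_imputed <- FALSE
  miss <- is.na(data$bmi)
  if (!any(miss)) return(data)
  work <- data
  work$.diabetes <- as.logical(work$diabetes1) | as.logical(work$diabetes2)
  vars <- c("age_years", "sex", "srdss_class", ".diabetes", "cardiovascular")
  cc <- !miss & stats::complete.cases(work[, vars, drop = FALSE])
  fit <- tryCatch(
    lm(bmi ~ age_years + sex + srdss_class + .diabetes + cardiovascular,
       data = work[cc, , drop = FALSE]),
    error = function(e) abort_validation(paste("BMI imputation model failed:",
                                               conditionMessage(e))))
  if (sum(cc) <= length(coef(fit))) {
    abort_validation("too few complete cases to fit the BMI imputation model")
  }
  pred <- predict(fit, newdata = work[miss, , drop = FALSE])
  data$bmi[miss] <- as.numeric(pred)
  data$bmi_imputed[miss] <- TRUE
  data
}
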
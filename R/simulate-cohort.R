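# Synthetic registry cohort generation.
#
# Generation contract, in order: (1) age from a truncated normal;
# (2) disease duration from a gamma truncated at age - 16 (diagnosis at 16
# or later); (3) sex and clinical phenotype categorically; (4) a latent
# severity score S = linear(duration, phenotype) + standard noise;
# (5) twelve symptom flags ~ Bernoulli(logistic(a_j + b_j S)) with
# intercepts a_j solved on the realized S so each symptom hits its target
# prevalence; gait-impairment class (SRDSS) by thresholding S at its
# realized quantiles; EDSS as a monotone half-point map of S; (6) latent
# HRQoL pair (E*, V*) = covariate linear predictors plus correlated
# standard bivariate residuals; (7) EQ-5D index as a monotone rank-quantile
# map of E* onto the target marginal with upper censoring at 100 (ceiling
# mass), VAS as the analogous integer-rounded map of V*; (8) benefits,
# employment and treatment class with severity gradients (intercepts again
# solved against realized marginals), remaining covariates from calibrated
# marginals.

trunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  qnorm(runif(n, plo, phi), mean, sd)
}

# intercept a such that mean(plogis(a + offset)) == target on realized data
solve_logit_intercept <- function(offset, target) {
  f <- function(a) mean(plogis(a + offset)) - target
  uniroot(f, c(-30, 30), tol = 1e-12)$root
}

marginal_quantile_map <- function(u, probs, values, ceiling_mass = 0,
                                  ceiling_value = 100) {
  out <- stats::approx(probs, values, xout = pmin(u, max(probs)),
                       rule = 2, ties = "ordered")$y
  if (ceiling_mass > 0) out[u >= 1 - ceiling_mass] <- ceiling_value
  out
}

#' Simulate a synthetic MS registry cohort
#'
#' Draws a complete (pre-missingness) participant table under the
#' configured generating process; see [generator_config()] for the
#' calibration and the package vignette for what the generator does and
#' does not emulate. The generation is reproducible: the same
#' (configuration, seed) pair yields a byte-identical table.
#'
#' The ground truth used in generation -- the covariate effects, the solved
#' intercepts and thresholds, and each participant's latent severity and
#' latent HRQoL values -- is recorded and available via [cohort_truth()]
#' for parameter-recovery testing.
#'
#' @param config A [generator_config()].
#' @param seed RNG seed; defaults to the seed stored in the configuration.
#' @return A tibble of class `qolseg_cohort` with one row per participant
#'   and attribute `"truth"`.
#' @export
simulate_cohort <- function(config = generator_config(), seed = config$seed) {
  stopifnot(inherits(config, "qolseg_generator_config"))
  n <- as.integer(config$n)
  withr::with_seed(as.integer(seed), {
    ap <- config$age_params
    age <- trunc_norm(n, ap$mean, ap$sd, ap$min, ap$max)

    dp <- config$duration_params
    dur_cap <- pgamma(age - dp$min_age_at_onset, dp$shape, scale = dp$scale)
    duration <- qgamma(runif(n, 0, dur_cap), dp$shape, scale = dp$scale)

    sex <- ifelse(runif(n) < config$sex_p, "female", "male")
    phenotype <- sample(names(config$phenotype_probs), n, replace = TRUE,
                        prob = config$phenotype_probs)

    sl <- config$severity_loadings
    severity <- sl$duration * (duration - sl$duration_center) +
      unname(sl$phenotype[phenotype]) +
      rnorm(n, sd = sl$noise_sd)

    # symptoms: prevalence-calibrated logistic regressions on severity
    sp <- config$symptom_params
    symptom_intercepts <- numeric(nrow(sp))
    symptoms <- matrix(FALSE, n, nrow(sp),
                       dimnames = list(NULL, sp$symptom))
    for (j in seq_len(nrow(sp))) {
      off <- sp$slope[j] * severity
      a <- solve_logit_intercept(off, sp$prevalence[j])
      symptom_intercepts[j] <- a
      symptoms[, j] <- runif(n) < plogis(a + off)
    }
    symptom_count <- rowSums(symptoms)
    symptom_count_class <- cut(symptom_count, c(-1, 2.5, 6.5, Inf),
                               labels = c("0-2", "3-6", ">=7"))

    # gait impairment class and EDSS: monotone in severity
    srdss_cuts <- quantile(severity, cumsum(config$srdss_probs)[1:2],
                           names = FALSE)
    srdss_class <- cut(severity, c(-Inf, srdss_cuts, Inf),
                       labels = names(config$srdss_probs))
    ep <- config$edss_params
    edss <- pmin(10, pmax(0, round(2 * (ep$intercept + ep$slope * severity)) / 2))

    # benefits / employment / treatment with severity gradients; the
    # intercept of each sequential draw is solved against its marginal
    so <- config$social_params
    bf <- so$benefit
    a_rec <- solve_logit_intercept(bf$slope_receives * severity, bf$p_receives)
    receives <- runif(n) < plogis(a_rec + bf$slope_receives * severity)
    rest <- which(!receives)
    target_applied <- min(0.999, bf$p_applied * n / max(length(rest), 1))
    a_app <- solve_logit_intercept(bf$slope_applied * severity[rest],
                                   target_applied)
    applied <- rep(FALSE, n)
    applied[rest] <- runif(length(rest)) <
      plogis(a_app + bf$slope_applied * severity[rest])
    disability_benefit <- ifelse(receives, "receives",
                                 ifelse(applied, "applied", "none"))

    a_emp <- solve_logit_intercept(so$employment$slope * severity,
                                   so$employment$p)
    employed <- runif(n) < plogis(a_emp + so$employment$slope * severity)

    dmt_class <- rep(NA_character_, n)
    remaining <- seq_len(n)
    dmt_names <- names(so$dmt$probs)
    dmt_intercepts <- numeric(0)
    for (k in dmt_names[-length(dmt_names)]) {
      tgt <- min(0.999, so$dmt$probs[[k]] * n / length(remaining))
      off <- so$dmt$slopes[[k]] * severity[remaining]
      a_k <- solve_logit_intercept(off, tgt)
      dmt_intercepts[k] <- a_k
      hit <- runif(length(remaining)) < plogis(a_k + off)
      dmt_class[remaining[hit]] <- k
      remaining <- remaining[!hit]
    }
    dmt_class[remaining] <- dmt_names[length(dmt_names)]

    swiss_citizen <- runif(n) < so$citizen_p
    education <- sample(names(so$education_probs), n, TRUE, so$education_probs)
    living_situation <- sample(names(so$living_probs), n, TRUE, so$living_probs)
    marital_status <- sample(names(so$marital_probs), n, TRUE, so$marital_probs)
    smoking <- sample(names(so$smoking_probs), n, TRUE, so$smoking_probs)
    family_ms <- runif(n) < so$family_ms_p

    fs <- so$first_symptom
    first_visual <- runif(n) < fs$visual_p
    first_paresthesia <- runif(n) < fs$paresthesia_p
    a_gait <- solve_logit_intercept(fs$gait_slope * severity, fs$gait_p)
    first_gait <- runif(n) < plogis(a_gait + fs$gait_slope * severity)
    first_spasms <- runif(n) < fs$spasms_p

    com <- so$comorbidity
    comorb <- matrix(FALSE, n, length(com$p),
                     dimnames = list(NULL, names(com$p)))
    for (k in names(com$p)) {
      if (com$slopes[[k]] == 0) {
        comorb[, k] <- runif(n) < com$p[[k]]
      } else {
        off <- com$slopes[[k]] * severity
        a_k <- solve_logit_intercept(off, com$p[[k]])
        comorb[, k] <- runif(n) < plogis(a_k + off)
      }
    }

    bp <- so$bmi
    bmi <- round(exp(rnorm(n, bp$meanlog + bp$severity_slope * severity,
                           bp$sdlog)), 1)

    # latent HRQoL pair: shared covariate predictor + correlated residuals
    eff <- config$covariate_effects$eq5d
    lp <- rep(0, n)
    for (nm in names(eff)) {
      lp <- lp + eff[[nm]] * switch(
        nm,
        severity = severity,
        age_per_decade = (age - ap$mean) / 10,
        benefit_receives = as.numeric(disability_benefit == "receives"),
        {
          if (!nm %in% colnames(symptoms)) {
            abort_config(sprintf("covariate effect `%s` has no generated column", nm))
          }
          as.numeric(symptoms[, nm])
        })
    }
    rho <- config$residual_rho
    e1 <- rnorm(n)
    e2 <- rho * e1 + sqrt(1 - rho^2) * rnorm(n)
    e_star <- lp + e1
    v_star <- config$covariate_effects$vas_scale * lp + e2

    em <- config$eq5d_marginal
    u_e <- (rank(e_star, ties.method = "first") - 0.5) / n
    eq5d_index <- round(marginal_quantile_map(u_e, em$probs, em$values,
                                              em$ceiling_mass), 1)
    vm <- config$vas_marginal
    u_v <- (rank(v_star, ties.method = "first") - 0.5) / n
    vas <- as.integer(round(marginal_quantile_map(u_v, vm$probs, vm$values)))

    measurement_date <- as.Date("2016-01-01") +
      sample.int(2800L, n, replace = TRUE)

    cohort <- tibble::tibble(
      participant_id = sprintf("P%05d", seq_len(n)),
      measurement_date = measurement_date,
      age_years = round(age, 1),
      years_since_diagnosis = round(duration, 1),
      sex, phenotype,
      eq5d_index, vas,
      srdss_class = as.character(srdss_class),
      tibble::as_tibble(symptoms),
      symptom_count_class = as.character(symptom_count_class),
      disability_benefit, employed, swiss_citizen,
      education, living_situation, marital_status, smoking,
      dmt_class,
      first_symptom_visual = first_visual,
      first_symptom_paresthesia = first_paresthesia,
      first_symptom_gait = first_gait,
      first_symptom_spasms = first_spasms,
      family_ms,
      tibble::as_tibble(comorb),
      bmi,
      edss,
      msss = if (n >= 5) compute_msss(edss, duration) else NA_real_
    )

    truth <- list(
      seed = as.integer(seed),
      covariate_effects = config$covariate_effects,
      residual_rho = rho,
      symptom_intercepts = setNames(symptom_intercepts, sp$symptom),
      srdss_cuts = srdss_cuts,
      benefit_intercepts = c(receives = a_rec, applied = a_app),
      employment_intercept = a_emp,
      dmt_intercepts = dmt_intercepts,
      severity = severity,
      linear_predictor = lp,
      e_star = e_star,
      v_star = v_star
    )
    attr(cohort, "truth") <- truth
    attr(cohort, "config") <- config
    class(cohort) <- c("qolseg_cohort", class(cohort))
    cohort
  })
}

#' Ground truth of a simulated cohort
#'
#' @param cohort A table produced by [simulate_cohort()].
#' @return The truth record: covariate effects, solved intercepts and
#'   thresholds, per-participant latent values, and the generation seed.
#' @export
cohort_truth <- function(cohort) {
  attr(cohort, "truth") %||%
    abort_validation("no truth record attached; not a simulated cohort?")
}

#' Inject the registry missingness pattern into a complete cohort
#'
#' Sets the five categorical variables (phenotype, living situation,
#' marital status, education, smoking) and BMI missing independently at the
#' configured per-variable rates (all below 3% by default), and masks
#' EDSS/MSSS jointly so they are observed with probability
#' `msss_fraction`. Age, disease duration and the HRQoL measurements are
#' never made missing (they are inclusion criteria).
#'
#' @param data A complete cohort table.
#' @param config The [generator_config()] holding `missingness` and
#'   `msss_fraction`.
#' @param seed RNG seed; defaults to the configuration seed plus one so the
#'   draw is independent of the generation stream yet reproducible.
#' @return The cohort with missing values injected.
#' @export
inject_missingness <- function(data, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "qolseg_generator_config"))
  rates <- config$missingness
  assert_prob(rates, "missingness")
  assert_prob(config$msss_fraction, "msss_fraction")
  cols <- c(phenotype = "phenotype", living_situation = "living_situation",
            marital_status = "marital_status", education = "education",
            smoking = "smoking", bmi = "bmi")
  withr::with_seed(as.integer(seed), {
    for (nm in names(rates)) {
      col <- cols[[nm]]
      if (is.null(col) || !col %in% names(data)) next
      hit <- runif(nrow(data)) < rates[[nm]]
      data[[col]][hit] <- NA
    }
    if (all(c("edss", "msss") %in% names(data))) {
      unobserved <- runif(nrow(data)) >= config$msss_fraction
      data$edss[unobserved] <- NA
      data$msss[unobserved] <- NA
    }
    data
  })
}

#' Write a cohort and its truth record to disk
#'
#' The cohort goes to CSV (UTF-8, header row, `.` decimal separator, empty
#' cell for missing); the truth record to JSON alongside it.
#'
#' @param cohort A simulated cohort.
#' @param dir Output directory (created if needed).
#' @param stem File stem; produces `<stem>.csv` and `<stem>_truth.json`.
#' @return Invisibly, the paths written.
#' @export
write_cohort <- function(cohort, dir, stem = "cohort") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, paste0(stem, ".csv"))
  utils::write.csv(cohort, csv, row.names = FALSE, na = "")
  truth <- attr(cohort, "truth")
  json <- file.path(dir, paste0(stem, "_truth.json"))
  if (!is.null(truth)) {
    jsonlite::write_json(truth, json, auto_unbox = TRUE, digits = NA)
  }
  invisible(c(cohort = csv, truth = json))
}
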
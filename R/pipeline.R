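#' Default ordered candidate list for model building
#'
#' The pre-specified variables of interest offered to forward retention, in
#' the documented default order: current symptoms first, then symptom
#' burden class, benefits/employment, body-mass index, sociodemographics,
#' treatment class, first-symptom history and familial risk, then
#' comorbidities. Forward selection is order-dependent, so the order is an
#' explicit, configurable input.
#'
#' @return Character vector of column names.
#' @export
default_candidate_order <- function() {
  c("balance", "bladder", "depression", "fatigue", "gait",
    "gastrointestinal", "memory", "pain", "paresthesia", "spasms",
    "tremors", "muscle_weakness", "symptom_count_class",
    "disability_benefit", "employed", "bmi", "education",
    "living_situation", "marital_status", "smoking", "dmt_class",
    "first_symptom_visual", "first_symptom_paresthesia",
    "first_symptom_gait", "first_symptom_spasms", "family_ms",
    "mononucleosis", "hypertension", "cancer", "diabetes1", "diabetes2",
    "cardiovascular")
}

#' Configuration of the end-to-end analysis pipeline
#'
#' @param input Path to a participant CSV, or `NULL` to simulate a cohort
#'   from `generator` instead.
#' @param generator A [generator_config()] used when `input` is `NULL`.
#' @param instruments Instruments to analyse.
#' @param taus Quantile levels for the segmentation (must contain the three
#'   quartiles), sorted, inside (0, 1).
#' @param base_terms Pre-specified confounders of the multinomial models.
#' @param candidates Ordered candidate covariates for forward retention.
#' @param aic_threshold Required AIC drop for retention (> 0).
#' @param bootstrap_B Bootstrap replicates of the sensitivity analysis.
#' @param alpha P-value threshold of the sensitivity-analysis selection.
#' @param seed Master seed of the run.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @return A validated `qolseg_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL,
                            generator = generator_config(),
                            instruments = c("eq5d_index", "vas"),
                            taus = c(0.25, 0.5, 0.75),
                            base_terms = c("sex", "phenotype", "srdss_class"),
                            candidates = default_candidate_order(),
                            aic_threshold = 2,
                            bootstrap_B = 100,
                            alpha = 0.05,
                            seed = 1L,
                            out_dir = NULL) {
  if (is.unsorted(taus) || any(taus <= 0 | taus >= 1)) {
    abort_config("`taus` must be sorted and lie strictly inside (0, 1)")
  }
  if (!is_scalar_number(aic_threshold) || aic_threshold <= 0) {
    abort_config("`aic_threshold` must be positive")
  }
  if (!is.null(input) && !file.exists(input)) {
    abort_config(sprintf("input file `%s` does not exist", input))
  }
  if (is.null(input)) stopifnot(inherits(generator, "qolseg_generator_config"))
  structure(list(input = input, generator = generator,
                 instruments = instruments, taus = taus,
                 base_terms = base_terms, candidates = candidates,
                 aic_threshold = aic_threshold, bootstrap_B = bootstrap_B,
                 alpha = alpha, seed = as.integer(seed), out_dir = out_dir),
            class = "qolseg_pipeline_config")
}

pipeline_log <- function(stage, msg, verbose = TRUE) {
  if (verbose) message(sprintf("[%s] %s", stage, msg))
}

#' Run the full segmentation-and-association analysis
#'
#' Executes the complete pipeline: load (or simulate) the cohort, apply
#' inclusion and preparation rules, segment both HRQoL instruments into
#' adjusted quartile groups, build the descriptive tables, run the
#' multinomial association models with AIC forward retention, collinearity
#' diagnostics and the severity-score subsample re-fit, run the
#' simultaneous-quantile-regression sensitivity analysis, and analyse
#' EQ-5D-VAS discordance. Analyses run separately per instrument. If
#' `config$out_dir` is set, every table and fit is written (CSV for tables,
#' JSON for models) together with a run manifest from which the entire
#' bundle can be re-derived.
#'
#' @param config A [pipeline_config()].
#' @param verbose Emit stage-tagged progress messages.
#' @return A `qolseg_pipeline` list bundle (cohort, segmentation,
#'   descriptives, association fits, sensitivity fits, discordance model,
#'   manifest).
#' @export
run_pipeline <- function(config = pipeline_config(), verbose = TRUE) {
  stopifnot(inherits(config, "qolseg_pipeline_config"))
  counts <- list()

  pipeline_log("load", "reading or simulating the cohort", verbose)
  if (!is.null(config$input)) {
    cohort <- tibble::as_tibble(utils::read.csv(config$input,
                                                stringsAsFactors = FALSE))
  } else {
    cohort <- simulate_cohort(config$generator, seed = config$seed)
    cohort <- inject_missingness(cohort, config$generator,
                                 seed = config$seed + 1L)
  }
  counts$input_rows <- nrow(cohort)

  pipeline_log("preprocess", "inclusion, missing categories, BMI imputation", verbose)
  cohort <- apply_inclusion(cohort)
  excl <- exclusion_counts(cohort)
  if ("participant_id" %in% names(cohort) &&
      anyDuplicated(cohort$participant_id) > 0 &&
      "measurement_date" %in% names(cohort)) {
    cohort <- select_last_complete(cohort)
  }
  cohort <- encode_missing_categories(cohort)
  if (all(c("bmi", "srdss_class") %in% names(cohort))) {
    cohort <- impute_bmi(cohort)
  }
  counts$analysed <- nrow(cohort)

  missing_cols <- setdiff(config$instruments, names(cohort))
  if (length(missing_cols) > 0) {
    abort_validation(paste("instrument column(s) missing from the cohort:",
                           paste(missing_cols, collapse = ", ")))
  }

  pipeline_log("segment", "fitting adjusted quartile surfaces", verbose)
  seg <- segment_cohort(cohort, instruments = config$instruments,
                        taus = config$taus)
  analysed <- dplyr::left_join(tidy(seg), cohort, by = "participant_id")

  descriptives <- list()
  associations <- list()
  sensitivity <- list()
  for (ins in config$instruments) {
    pre <- sub("_index$", "", ins)
    lab <- paste0(pre, "_label")
    pipeline_log("describe", pre, verbose)
    descriptives[[pre]] <- descriptive_table(
      analysed, lab,
      vars = intersect(c("sex", "age_years", "years_since_diagnosis",
                         "phenotype", "srdss_class", config$candidates,
                         "eq5d_index", "vas", "msss"),
                       names(analysed)))
    pipeline_log("associate", paste(pre, "multinomial + AIC retention"), verbose)
    sel <- forward_select_aic(analysed, lab, config$base_terms,
                              config$candidates,
                              threshold = config$aic_threshold)
    coll <- collinearity_check(
      analysed, as.formula(paste("~", paste(sel$final_terms, collapse = " + "))))
    msss_fit <- if ("msss" %in% names(analysed) && any(!is.na(analysed$msss))) {
      refit_with_msss(sel, analysed)
    }
    associations[[pre]] <- list(selection = sel, collinearity = coll,
                                msss_refit = msss_fit)
    pipeline_log("sensitivity", paste(pre, "simultaneous quantile regression"), verbose)
    sens_terms <- unique(c("age_years", "years_since_diagnosis",
                           config$base_terms,
                           setdiff(sel$final_terms, config$base_terms)))
    sensitivity[[pre]] <- fit_simultaneous_quantiles(
      analysed, ins, sens_terms, taus = config$taus,
      B = config$bootstrap_B, seed = config$seed + 2L)
  }

  discordance <- NULL
  if ("discordance" %in% names(analysed)) {
    pipeline_log("discord", "multinomial model of discordance groups", verbose)
    discordance <- forward_select_aic(analysed, "discordance",
                                      config$base_terms, config$candidates,
                                      threshold = config$aic_threshold,
                                      ref = "within_expectation")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("qolseg")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    input = config$input %||% "simulated",
    n_input = counts$input_rows,
    n_analysed = counts$analysed,
    exclusions = excl,
    instruments = config$instruments,
    taus = config$taus,
    aic_threshold = config$aic_threshold,
    bootstrap_B = config$bootstrap_B,
    alpha = config$alpha
  )
  bundle <- structure(list(cohort = cohort, segmentation = seg,
                           descriptives = descriptives,
                           associations = associations,
                           sensitivity = sensitivity,
                           discordance = discordance,
                           manifest = manifest),
                      class = "qolseg_pipeline")
  if (!is.null(config$out_dir)) write_pipeline(bundle, config$out_dir)
  bundle
}

write_pipeline <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(bundle$cohort, file.path(dir, "cohort_analysed.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(tidy(bundle$segmentation),
                   file.path(dir, "segmentation.csv"), row.names = FALSE,
                   na = "")
  for (pre in names(bundle$descriptives)) {
    utils::write.csv(bundle$descriptives[[pre]],
                     file.path(dir, sprintf("descriptive_%s.csv", pre)),
                     row.names = FALSE, na = "")
    assoc <- bundle$associations[[pre]]
    jsonlite::write_json(list(
      rrr_table = tidy(assoc$selection$fit),
      fit = glance(assoc$selection$fit),
      trace = assoc$selection$trace,
      collinearity = assoc$collinearity$terms,
      msss_rrr = if (!is.null(assoc$msss_refit)) tidy(assoc$msss_refit)
    ), file.path(dir, sprintf("association_%s.json", pre)),
    auto_unbox = TRUE, digits = NA, null = "null")
    sens <- bundle$sensitivity[[pre]]
    jsonlite::write_json(list(
      coefficients = tidy(sens), info = glance(sens),
      cross_tau = cross_tau_tests(sens)
    ), file.path(dir, sprintf("sensitivity_%s.json", pre)),
    auto_unbox = TRUE, digits = NA)
    utils::write.csv(tidy(sens),
                     file.path(dir, sprintf("sensitivity_%s.csv", pre)),
                     row.names = FALSE, na = "")
  }
  if (!is.null(bundle$discordance)) {
    jsonlite::write_json(list(
      rrr_table = tidy(bundle$discordance$fit),
      trace = bundle$discordance$trace
    ), file.path(dir, "discordance.json"), auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.qolseg_pipeline <- function(x, ...) {
  cat("HRQoL segmentation pipeline bundle\n")
  cat(sprintf("  %d participants analysed (of %d input rows), seed %d\n",
              x$manifest$n_analysed, x$manifest$n_input, x$manifest$seed))
  print(glance(x$segmentation))
  invisible(x)
}
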
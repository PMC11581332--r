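test_that("intercept-only fit reproduces category frequencies exactly", {
  counts <- c(low = 417, normal = 858, high = 422)
  d <- tibble::tibble(group = rep(names(counts), counts))
  fit <- fit_multinomial(d, group ~ 1)
  expect_equal(fit$reference, "normal")
  rrr <- exp(fit$coefficients["(Intercept)", ])
  expect_equal(unname(rrr["low"]), 417 / 858, tolerance = 1e-6)
  expect_equal(unname(rrr["high"]), 422 / 858, tolerance = 1e-6)
  # fitted probabilities equal observed frequencies
  expect_equal(unname(fit$fitted[1, ]), unname(counts[fit$levels] / 1697),
               tolerance = 1e-9)
  expect_lt(fit$max_grad, 1e-8)
  expect_equal(fit$aic, 2 * 2 - 2 * fit$loglik)
})

test_that("a saturated binary-covariate fit matches the count ratios", {
  # 2 x 3 table: z = 0 -> (30, 100, 40); z = 1 -> (60, 80, 20)
  d <- tibble::tibble(
    group = c(rep(c("low", "normal", "high"), c(30, 100, 40)),
              rep(c("low", "normal", "high"), c(60, 80, 20))),
    z = rep(c(0, 1), c(170, 160)))
  fit <- fit_multinomial(d, group ~ z)
  B <- fit$coefficients
  expect_equal(B["(Intercept)", "low"], log(30 / 100), tolerance = 1e-7)
  expect_equal(B["(Intercept)", "high"], log(40 / 100), tolerance = 1e-7)
  expect_equal(B["z", "low"], log(60 / 80) - log(30 / 100), tolerance = 1e-7)
  expect_equal(B["z", "high"], log(20 / 80) - log(40 / 100), tolerance = 1e-7)
  expect_lt(fit$max_grad, 1e-8)
})

test_that("the Newton fit agrees with an independent optimizer", {
  skip_if_not_installed("nnet")
  d <- simulate_multinomial(2000, beta_low = c(-0.6, 0.8, -0.4),
                            beta_high = c(-0.4, -0.5, 0.3), seed = 31)
  fit <- fit_multinomial(d, group ~ z + w, ref = "normal")
  nn <- nnet::multinom(factor(group, levels = c("normal", "high", "low")) ~ z + w,
                       data = d, trace = FALSE, reltol = 1e-14)
  expect_equal(unname(fit$coefficients[, "high"]), unname(coef(nn)["high", ]),
               tolerance = 1e-5)
  expect_equal(unname(fit$coefficients[, "low"]), unname(coef(nn)["low", ]),
               tolerance = 1e-5)
  expect_equal(glance(fit)$AIC, AIC(nn), tolerance = 1e-6)
})

test_that("Wald intervals cover the generating effects at a sane rate", {
  beta_low <- c(-0.6, 0.8, -0.4)
  beta_high <- c(-0.4, 0, 0.3)   # null z effect on the high category
  hits_z_low <- hits_z_high <- 0
  reps <- 30
  for (r in seq_len(reps)) {
    d <- simulate_multinomial(1500, beta_low, beta_high, seed = 100 + r)
    fit <- fit_multinomial(d, group ~ z + w, ref = "normal")
    td <- tidy(fit)
    row_l <- td[td$y_level == "low" & td$term == "z", ]
    row_h <- td[td$y_level == "high" & td$term == "z", ]
    hits_z_low <- hits_z_low +
      (row_l$conf.low <= exp(0.8) && exp(0.8) <= row_l$conf.high)
    hits_z_high <- hits_z_high +
      (row_h$conf.low <= 1 && 1 <= row_h$conf.high)
  }
  expect_gte(hits_z_low / reps, 0.8)
  expect_gte(hits_z_high / reps, 0.8)
})

test_that("forward retention respects the AIC threshold boundary exactly", {
  d <- simulate_multinomial(1200, c(-0.6, 0.9, 0), c(-0.4, -0.7, 0), seed = 51)
  sel <- forward_select_aic(d, "group", "w", "z")
  delta <- sel$trace$delta_aic[sel$trace$candidate == "z"]
  expect_true(sel$trace$retained[sel$trace$candidate == "z"])
  # a drop of exactly the threshold is retained ("two or more")
  sel_eq <- forward_select_aic(d, "group", "w", "z", threshold = -delta)
  expect_true(sel_eq$trace$retained[sel_eq$trace$candidate == "z"])
  # an infinitesimally stricter threshold rejects the same candidate
  sel_gt <- forward_select_aic(d, "group", "w", "z", threshold = -delta + 1e-6)
  expect_false(sel_gt$trace$retained[sel_gt$trace$candidate == "z"])
})

test_that("pure-noise candidates are almost always rejected", {
  rejected <- 0
  reps <- 50
  for (r in seq_len(reps)) {
    d <- simulate_multinomial(2000, c(-0.6, 0.8, -0.4), c(-0.4, -0.5, 0.3),
                              seed = 200 + r)
    d$noise <- withr::with_seed(500 + r, rnorm(nrow(d)))
    sel <- forward_select_aic(d, "group", c("z", "w"), "noise")
    rejected <- rejected + !sel$trace$retained[sel$trace$candidate == "noise"]
  }
  expect_gte(rejected / reps, 0.9)
})

test_that("severity score is excluded from candidacy but refit on the subsample", {
  cohort <- simulate_cohort(generator_config(n = 700, seed = 61))
  cohort <- inject_missingness(cohort, generator_config(n = 700, seed = 61))
  seg <- segment_cohort(cohort)
  d <- dplyr::left_join(tidy(seg), cohort, by = "participant_id")
  sel <- forward_select_aic(d, "eq5d_label", c("sex", "phenotype"),
                            c("msss", "depression"))
  expect_false("msss" %in% sel$final_terms)
  expect_match(sel$trace$reason[sel$trace$candidate == "msss"], "subsample")
  refit <- suppressWarnings(refit_with_msss(sel, d))
  expect_equal(refit$subsample_n, sum(!is.na(d$msss)))
  expect_true("msss" %in% rownames(refit$coefficients))
  # constant score on the subsample is inestimable
  d2 <- d
  d2$msss[!is.na(d2$msss)] <- 5
  expect_error(refit_with_msss(sel, d2), class = "qolseg_validation")
})

test_that("a generated severity effect on low HRQoL is recovered as RRR > 1", {
  hits <- 0
  reps <- 25
  for (r in seq_len(reps)) {
    d <- withr::with_seed(700 + r, {
      n <- 1200
      msss <- runif(n, 0, 10)
      eta_low <- -2 + 0.25 * msss
      eta_high <- -0.5 - 0.1 * msss
      denom <- 1 + exp(eta_low) + exp(eta_high)
      u <- runif(n)
      g <- ifelse(u < exp(eta_low) / denom, "low",
                  ifelse(u < (exp(eta_low) + exp(eta_high)) / denom,
                         "high", "normal"))
      tibble::tibble(group = g, msss = msss,
                     w = rnorm(n))
    })
    fit <- refit_with_msss("w", d, outcome = "group")
    hits <- hits + (exp(fit$coefficients["msss", "low"]) > 1)
  }
  expect_gte(hits / reps, 0.9)
})

test_that("collinearity diagnostics match the closed form for two predictors", {
  withr::with_seed(71, {
    n <- 400
    # centered orthonormal columns -> exact sample correlations
    raw <- qr.Q(qr(scale(cbind(rnorm(n), rnorm(n)), scale = FALSE)))
    x1 <- raw[, 1]
    x2 <- 0.9 * x1 + sqrt(1 - 0.81) * raw[, 2]  # exact correlation 0.9
  })
  d <- tibble::tibble(x1 = x1, x2 = x2)
  cc <- collinearity_check(d, ~ x1 + x2)
  expect_false(cc$rank_deficient)
  expect_equal(cc$terms$gvif, rep(1 / (1 - 0.81), 2), tolerance = 1e-9)
  expect_true(all(cc$terms$flagged))
  # orthogonal design: VIF exactly 1
  d0 <- tibble::tibble(x1 = raw[, 1], x2 = raw[, 2])
  cc0 <- collinearity_check(d0, ~ x1 + x2)
  expect_equal(cc0$terms$gvif, c(1, 1), tolerance = 1e-9)
  expect_false(any(cc0$terms$flagged))
  # duplicated column flags rank deficiency
  dd <- tibble::tibble(x1 = x1, x2 = x1)
  expect_true(collinearity_check(dd, ~ x1 + x2)$rank_deficient)
})

test_that("collinearity diagnostics agree with the car reference", {
  skip_if_not_installed("car")
  cohort <- simulate_cohort(generator_config(n = 500, seed = 73))
  fml <- ~ age_years + years_since_diagnosis + phenotype + srdss_class
  cc <- collinearity_check(cohort, fml)
  cohort$yy <- withr::with_seed(1, rnorm(nrow(cohort)))
  ref <- car::vif(lm(update(fml, yy ~ .), data = cohort))
  expect_equal(cc$terms$gvif, unname(ref[cc$terms$term, "GVIF"]),
               tolerance = 1e-6)
})

test_that("descriptive tables print medians, IQRs and percentages", {
  d <- tibble::tibble(
    g = rep("all", 20),
    score = c(1, 2, 3, rep(2, 17)),
    flag = c(rep(TRUE, 7), rep(FALSE, 13))
  )
  tab <- descriptive_table(d, "g", vars = c("score", "flag"))
  flag_row <- tab[tab$variable == "flag" & tab$group == "all", ]
  expect_equal(flag_row$count, 7)
  expect_equal(flag_row$pct, 35.0)
  expect_equal(flag_row$value, "7 (35.0)")
  d2 <- tibble::tibble(g = "x", v = c(1, 2, 3))
  row <- descriptive_table(d2, "g", vars = "v")
  expect_equal(row$median[1], 2)
  expect_equal(row$value[1], "2 [1; 3]")
  expect_error(descriptive_table(tibble::tibble(g = c("a", NA), v = 1:2), "g"),
               class = "qolseg_validation")
})
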
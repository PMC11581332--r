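test_that("restricted cubic spline basis has the expected dimension and rank", {
  withr::with_seed(1, x <- runif(200, 20, 80))
  B <- rcs_basis(x, n_knots = 3)
  expect_equal(ncol(B), 2)                # n_knots - 1 columns
  expect_equal(ncol(rcs_basis(x, n_knots = 5)), 4)
  expect_equal(qr(cbind(1, B))$rank, 3)   # full column rank with intercept
  expect_error(rcs_basis(c(1, 1, 1, 2), n_knots = 3),
               class = "qolseg_validation")
})

test_that("the spline is continuous and linear beyond the boundary knots", {
  knots <- c(30, 50, 70)
  eps <- 1e-8
  at_knot <- rcs_eval(c(70 - eps, 70, 70 + eps), knots)
  expect_lt(max(abs(at_knot[1, ] - at_knot[2, ])), 1e-6)
  expect_lt(max(abs(at_knot[3, ] - at_knot[2, ])), 1e-6)
  # second differences vanish outside the boundary knots (linearity)
  right <- rcs_eval(c(80, 90, 100), knots)
  expect_lt(max(abs(right[1, ] - 2 * right[2, ] + right[3, ])), 1e-8)
  left <- rcs_eval(c(0, 10, 20), knots)
  expect_lt(max(abs(left[1, ] - 2 * left[2, ] + left[3, ])), 1e-8)
})

test_that("simultaneous fits are deterministic and their covariance is PSD", {
  cohort <- simulate_cohort(generator_config(n = 500, seed = 81))
  seg <- segment_cohort(cohort)
  d <- dplyr::left_join(tidy(seg), cohort, by = "participant_id")
  terms <- c("age_years", "years_since_diagnosis", "sex", "depression")
  f1 <- fit_simultaneous_quantiles(d, "vas", terms, B = 25, seed = 5)
  f2 <- fit_simultaneous_quantiles(d, "vas", terms, B = 25, seed = 5)
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$vcov, f2$vcov)
  ev <- eigen(f1$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_gte(min(ev), -1e-8)
  expect_equal(glance(f1)$B, 25)
})

test_that("per-tau point estimates share the single-tau oracle", {
  cohort <- simulate_cohort(generator_config(n = 400, seed = 83))
  d <- tibble::tibble(age_years = cohort$age_years,
                      years_since_diagnosis = cohort$years_since_diagnosis,
                      y = cohort_truth(cohort)$v_star)
  # no splines: identical linear design in both code paths
  sq <- fit_simultaneous_quantiles(d, "y",
                                   c("age_years", "years_since_diagnosis"),
                                   spline_vars = character(0), B = 2, seed = 1)
  single <- fit_conditional_quantiles(d, "y")
  p <- length(sq$term_names)
  for (i in 1:3) {
    est_sq <- sq$estimates[(i - 1) * p + seq_len(p)]
    est_single <- single$fits[[i]]$coefficients
    expect_equal(unname(est_sq), unname(est_single), tolerance = 1e-6)
  }
})

test_that("bootstrap standard errors shrink roughly as one over root n", {
  make_data <- function(n, seed) {
    withr::with_seed(seed, tibble::tibble(
      x = rnorm(n),
      y = 70 + 3 * x + rnorm(n, sd = 8)))
  }
  small <- fit_simultaneous_quantiles(make_data(500, 1), "y", "x",
                                      spline_vars = character(0),
                                      taus = 0.5, B = 60, seed = 2)
  big <- fit_simultaneous_quantiles(make_data(2000, 1), "y", "x",
                                    spline_vars = character(0),
                                    taus = 0.5, B = 60, seed = 2)
  ratio <- small$se[["tau0.5:x"]] / big$se[["tau0.5:x"]]
  expect_lt(abs(ratio - 2), 0.6)   # within 30% of the root-n factor of 2
})

test_that("a lower-tail-only effect is flagged by the cross-tau contrast", {
  hits <- 0
  reps <- 12
  for (r in seq_len(reps)) {
    d <- withr::with_seed(900 + r, {
      n <- 1500
      x <- rbinom(n, 1, 0.5)
      u <- runif(n)
      # x widens the lower half only: q25 moves, q75 does not
      y <- 80 + qnorm(u) * 10 * (1 + 0.6 * x * (u < 0.5))
      tibble::tibble(x = x, y = y)
    })
    sq <- fit_simultaneous_quantiles(d, "y", "x", spline_vars = character(0),
                                     B = 60, seed = r)
    ct <- cross_tau_tests(sq)
    hits <- hits + (ct$p.value[ct$term == "x"] < 0.05)
  }
  expect_gte(hits / reps, 0.8)
})

test_that("p-value selection keeps any-tau hits and nothing at alpha zero", {
  cohort <- simulate_cohort(generator_config(n = 600, seed = 87))
  seg <- segment_cohort(cohort)
  d <- dplyr::left_join(tidy(seg), cohort, by = "participant_id")
  sq <- fit_simultaneous_quantiles(
    d, "eq5d_index", c("age_years", "years_since_diagnosis", "depression"),
    B = 40, seed = 9)
  expect_equal(select_by_pvalue(sq, c("depression"), alpha = 0), character(0))
  td <- tidy(sq)
  p_dep <- td$p.value[td$term == "depressionTRUE"]
  # alpha just above the smallest p retains; just below the smallest drops
  expect_equal(select_by_pvalue(sq, "depression", alpha = min(p_dep) * 1.01),
               "depression")
  expect_equal(select_by_pvalue(sq, "depression", alpha = min(p_dep) * 0.99),
               character(0))
})

test_that("degenerate designs are refused with a clear error", {
  d <- tibble::tibble(x = rep(1, 50), y = rnorm(50))
  expect_error(fit_simultaneous_quantiles(d, "y", "x",
                                          spline_vars = character(0),
                                          B = 5, seed = 1),
               class = "qolseg_validation")
  expect_error(fit_simultaneous_quantiles(tibble::tibble(x = rnorm(50),
                                                         y = rnorm(50)),
                                          "y", "x",
                                          spline_vars = character(0),
                                          B = 1, seed = 1),
               class = "qolseg_validation")
})
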
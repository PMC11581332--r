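#' Restricted cubic spline basis
#'
#' Builds the standard restricted (natural) cubic spline basis: linear
#' beyond the boundary knots, with `n_knots - 1` columns (the linear term
#' plus `n_knots - 2` nonlinear terms, each normalized by the squared knot
#' span). Default knots sit at equally spaced quantiles of the data --
#' the 10th/50th/90th percentiles for the default three knots.
#'
#' @param x Numeric values.
#' @param n_knots Number of knots (>= 3).
#' @param knots Optional explicit knot locations (overrides `n_knots`).
#' @return A matrix with `length(knots) - 1` columns and attributes
#'   `"knots"` and `"varname"`; use [rcs_eval()] to evaluate the same basis
#'   at new values.
#' @export
rcs_basis <- function(x, n_knots = 3, knots = NULL) {
  if (is.null(knots)) {
    if (n_knots < 3) abort_validation("`n_knots` must be at least 3")
    probs <- seq(0.1, 0.9, length.out = n_knots)
    knots <- quantile(x, probs, na.rm = TRUE, names = FALSE)
  }
  knots <- sort(unique(knots))
  if (length(knots) < 3) {
    abort_validation("need at least 3 distinct knot locations; too few distinct values")
  }
  if (length(unique(x[!is.na(x)])) < length(knots)) {
    abort_validation("fewer distinct data values than knots")
  }
  B <- rcs_eval(x, knots)
  attr(B, "varname") <- deparse(substitute(x))
  B
}

#' Evaluate a restricted cubic spline basis at given values
#'
#' @param x Numeric values.
#' @param knots Knot locations (sorted, length >= 3).
#' @return Basis matrix with `length(knots) - 1` columns.
#' @export
rcs_eval <- function(x, knots) {
  k <- length(knots)
  span2 <- (knots[k] - knots[1])^2
  cub <- function(u) pmax(u, 0)^3
  B <- matrix(0, length(x), k - 1)
  B[, 1] <- x
  for (j in seq_len(k - 2)) {
    B[, j + 1] <- (cub(x - knots[j]) -
                     cub(x - knots[k - 1]) * (knots[k] - knots[j]) / (knots[k] - knots[k - 1]) +
                     cub(x - knots[k]) * (knots[k - 1] - knots[j]) / (knots[k] - knots[k - 1])) / span2
  }
  colnames(B) <- c("lin", paste0("nl", seq_len(k - 2)))
  attr(B, "knots") <- knots
  B
}

sqr_design <- function(data, terms, spline_vars, n_knots, knots = NULL) {
  parts <- list(`(Intercept)` = matrix(1, nrow(data), 1))
  knot_list <- list()
  for (v in spline_vars) {
    kn <- knots[[v]] %||% {
      probs <- seq(0.1, 0.9, length.out = n_knots)
      quantile(data[[v]], probs, na.rm = TRUE, names = FALSE)
    }
    kn <- sort(unique(kn))
    knot_list[[v]] <- kn
    B <- rcs_eval(data[[v]], kn)
    colnames(B) <- paste0("rcs(", v, ")", colnames(B))
    parts[[v]] <- B
  }
  other <- setdiff(terms, spline_vars)
  if (length(other) > 0) {
    fml <- as.formula(paste("~", paste(other, collapse = " + ")))
    mm <- model.matrix(fml, model.frame(fml, data, na.action = NULL))
    parts[["other"]] <- mm[, -1, drop = FALSE]
  }
  X <- do.call(cbind, parts)
  colnames(X)[1] <- "(Intercept)"
  list(X = X, knots = knot_list)
}

#' Simultaneous quantile regression with bootstrap inference
#'
#' Fits the 25th/50th/75th (or any requested) conditional percentiles of a
#' continuous HRQoL outcome in one analysis: point estimates are the
#' per-tau pinball-loss minimizers on the original data; a participant-level
#' bootstrap (resampling rows with replacement, all taus re-fit on the same
#' resample) yields a joint covariance across every coefficient of every
#' tau. Age and disease duration enter through restricted cubic splines;
#' further confounders and candidate covariates enter linearly/categorically.
#' Per-coefficient p-values are two-sided normal-approximation Wald tests on
#' bootstrap standard errors; cross-tau contrasts (e.g. a covariate moving
#' the 25th percentile but not the 75th) are tested with the joint
#' covariance. Resamples on which the design degenerates (a category
#' vanishing, rank loss) are redrawn, at most 10 times each, and the count
#' is recorded.
#'
#' @param data Participant table.
#' @param outcome Outcome column name.
#' @param terms Covariate columns entering the design.
#' @param spline_vars Subset of `terms` expanded as restricted cubic
#'   splines (default age and disease duration).
#' @param taus Quantile levels.
#' @param n_knots Knots per spline variable.
#' @param B Bootstrap replicates (>= 2), default 100.
#' @param seed RNG seed for the bootstrap.
#' @return A `qolseg_sqr` object; `tidy()` gives per-(tau, term) estimates,
#'   bootstrap SEs and p-values, `glance()` fit-level information, and
#'   `cross_tau_tests()` the 25th-vs-75th contrasts.
#' @export
fit_simultaneous_quantiles <- function(data, outcome, terms,
                                       spline_vars = intersect(c("age_years", "years_since_diagnosis"), terms),
                                       taus = c(0.25, 0.5, 0.75),
                                       n_knots = 3, B = 100, seed = 1L) {
  assert_columns(data, c(outcome, terms))
  if (B < 2) abort_validation("`B` must be at least 2")
  keep <- complete.cases(data[, c(outcome, terms), drop = FALSE])
  data <- data[keep, , drop = FALSE]
  y <- as.numeric(data[[outcome]])
  des <- sqr_design(data, terms, spline_vars, n_knots)
  X <- des$X
  if (qr(X)$rank < ncol(X)) {
    abort_validation("simultaneous quantile design is rank deficient")
  }
  taus <- sort(taus)
  fits <- lapply(taus, function(tau) rq_fit_fn(X, y, tau))
  est <- unlist(lapply(fits, `[[`, "coefficients"))
  par_names <- as.vector(vapply(taus, function(tau) {
    paste0("tau", tau, ":", colnames(X))
  }, character(ncol(X))))
  names(est) <- par_names

  n <- nrow(X)
  p <- ncol(X)
  boot <- matrix(NA_real_, B, length(est))
  redraws <- 0L
  withr::with_seed(as.integer(seed), {
    for (b in seq_len(B)) {
      for (attempt in seq_len(11L)) {
        idx <- sample.int(n, n, replace = TRUE)
        Xb <- X[idx, , drop = FALSE]
        if (qr(Xb)$rank == p) break
        redraws <- redraws + 1L
        if (attempt == 11L) abort_validation("bootstrap design degenerate after 10 redraws")
      }
      yb <- y[idx]
      boot[b, ] <- unlist(lapply(taus, function(tau) {
        rq_fit_fn(Xb, yb, tau)$coefficients
      }))
    }
  })
  V <- stats::cov(boot)
  dimnames(V) <- list(par_names, par_names)
  se <- sqrt(pmax(diag(V), 0))
  structure(list(
    estimates = est, vcov = V, se = se, taus = taus, B = B,
    seed = as.integer(seed), n = n, term_names = colnames(X),
    knots = des$knots, redraws = redraws, outcome = outcome,
    terms = terms, spline_vars = spline_vars,
    loss = vapply(fits, `[[`, numeric(1), "loss")
  ), class = "qolseg_sqr")
}

#' @export
tidy.qolseg_sqr <- function(x, ...) {
  p <- length(x$term_names)
  purrr::map_dfr(seq_along(x$taus), function(i) {
    idx <- (i - 1) * p + seq_len(p)
    est <- unname(x$estimates[idx])
    se <- unname(x$se[idx])
    tibble::tibble(tau = x$taus[i], term = x$term_names, estimate = est,
                   std.error = se, statistic = est / se,
                   p.value = 2 * pnorm(-abs(est / se)))
  })
}

#' @export
glance.qolseg_sqr <- function(x, ...) {
  tibble::tibble(nobs = x$n, n_taus = length(x$taus), B = x$B,
                 seed = x$seed, bootstrap_redraws = x$redraws,
                 total_pinball_loss = sum(x$loss))
}

#' Cross-tau coefficient contrasts of a simultaneous quantile fit
#'
#' Tests, per term, whether the coefficient differs between two fitted
#' quantile levels (by default the 25th vs the 75th percentile), using the
#' joint bootstrap covariance. A significant contrast means a covariate
#' reshapes the outcome distribution rather than shifting it.
#'
#' @param x A `qolseg_sqr` fit.
#' @param tau_a,tau_b The two quantile levels to contrast.
#' @return Tibble with the difference, its bootstrap SE and p-value per term.
#' @export
cross_tau_tests <- function(x, tau_a = 0.25, tau_b = 0.75) {
  stopifnot(inherits(x, "qolseg_sqr"))
  ia <- match(tau_a, x$taus); ib <- match(tau_b, x$taus)
  if (is.na(ia) || is.na(ib)) abort_validation("requested taus were not fitted")
  p <- length(x$term_names)
  idx_a <- (ia - 1) * p + seq_len(p)
  idx_b <- (ib - 1) * p + seq_len(p)
  diff <- unname(x$estimates[idx_b] - x$estimates[idx_a])
  v <- diag(x$vcov)[idx_b] + diag(x$vcov)[idx_a] -
    2 * x$vcov[cbind(idx_b, idx_a)]
  se <- sqrt(pmax(unname(v), 0))
  tibble::tibble(term = x$term_names, tau_a = tau_a, tau_b = tau_b,
                 difference = diff, std.error = se,
                 statistic = diff / se,
                 p.value = 2 * pnorm(-abs(diff / se)))
}

#' Select candidate covariates by bootstrap p-value
#'
#' A candidate is retained when its coefficient reaches `p < alpha` at any
#' of the fitted quantile levels (every contrast column a categorical
#' candidate expands into counts). This "significant anywhere" reading is
#' the package's documented convention for p-value-based retention.
#'
#' @param fit A `qolseg_sqr` containing the candidates.
#' @param candidates Character vector of candidate column names.
#' @param alpha Significance level (default 0.05; `alpha = 0` retains
#'   nothing).
#' @return Character vector of retained candidates (possibly empty).
#' @export
select_by_pvalue <- function(fit, candidates, alpha = 0.05) {
  stopifnot(inherits(fit, "qolseg_sqr"))
  td <- tidy(fit)
  retained <- character(0)
  for (cand in candidates) {
    hit <- grepl(cand, td$term, fixed = TRUE) & td$term != "(Intercept)"
    if (!any(hit)) next
    if (any(td$p.value[hit] < alpha, na.rm = TRUE)) {
      retained <- c(retained, cand)
    }
  }
  retained
}

#' @export
print.qolseg_sqr <- function(x, ...) {
  cat(sprintf("Simultaneous quantile regression of %s (taus %s), B = %d bootstrap\n",
              x$outcome, paste(x$taus, collapse = "/"), x$B))
  print(tidy(x), n = 30)
  invisible(x)
}

#' Coefficients across quantile levels with bootstrap confidence bands
#'
#' @param object A `qolseg_sqr` fit.
#' @param ... Unused.
#' @return A ggplot: one panel per term, estimate vs tau with 95% bands.
#' @export
autoplot.qolseg_sqr <- function(object, ...) {
  d <- tidy(object)
  d$conf.low <- d$estimate - 1.96 * d$std.error
  d$conf.high <- d$estimate + 1.96 * d$std.error
  ggplot2::ggplot(d, ggplot2::aes(x = .data$tau, y = .data$estimate)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high), alpha = 0.25) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~ .data$term, scales = "free_y") +
    ggplot2::labs(x = "Quantile level", y = "Coefficient") +
    ggplot2::theme_minimal()
}
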
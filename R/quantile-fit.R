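#' Pinball (check) loss
#'
#' The asymmetric absolute loss whose minimizer over constants is the
#' `tau`-th sample quantile: for residual `u = y - yhat`, the loss is
#' `u * (tau - 1(u < 0))`, summed over observations.
#'
#' @param y Numeric vector of observed outcomes.
#' @param yhat Numeric vector of fitted values, same length as `y`.
#' @param tau Quantile level, strictly between 0 and 1.
#' @return A single non-negative number.
#' @examples
#' pinball_loss(c(1, 0), c(0, 1), tau = 0.25)
#' @export
pinball_loss <- function(y, yhat, tau) {
  if (!is_scalar_number(tau) || tau <= 0 || tau >= 1) {
    abort_validation("`tau` must be a single number strictly between 0 and 1")
  }
  if (length(y) != length(yhat)) {
    abort_validation("`y` and `yhat` must have the same length")
  }
  u <- y - yhat
  sum(u * (tau - (u < 0)))
}

# Frisch-Newton primal-dual interior point solver for the quantile
# regression linear program, plus a vertex "polish" step.
#
# The fit solves min_b sum_i rho_tau(y_i - x_i'b). Its LP dual is
#   max  y'a   s.t.  X'a = (1 - tau) X'1,  0 <= a <= 1,
# and the multiplier of the equality constraint is the coefficient vector.
# We run a Mehrotra predictor-corrector on the bounded-variable dual and
# recover b from the equality multipliers. Because interior-point iterates
# stop short of an exact vertex, we finish by solving the p x p system
# through the p observations with the smallest absolute residuals and keep
# that basic solution when it does not increase the loss; on generic data
# this reproduces the exact LP vertex.
rq_fit_fn <- function(X, y, tau, tol = 1e-10, max_iter = 200L) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) abort_validation("`y` must match the rows of `X`")
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[setdiff(seq_len(p), qrX$pivot[seq_len(qrX$rank)])]
    abort_validation(sprintf(
      "design matrix is rank deficient (collinear column%s: %s)",
      if (length(bad) > 1) "s" else "", paste(bad, collapse = ", ")))
  }

  # equilibrate: scale outcome and columns for numerical stability,
  # rescale coefficients at the end
  sc <- max(abs(y), 1)
  ys <- y / sc
  cs <- apply(abs(X), 2, max)
  cs[cs == 0] <- 1
  X_orig <- X
  X <- sweep(X, 2, cs, "/")

  a <- rep(tau, n)              # dual variable, interior of [0,1]
  s <- 1 - a
  lam <- qr.coef(qrX, ys) * cs  # equality multipliers ~ scaled coefficients
  r <- ys - drop(X %*% lam)
  z <- pmax(r, 0) + 1e-4
  w <- z - r                    # so z - w = r, both positive
  b_eq <- tau * colSums(X)

  for (iter in seq_len(max_iter)) {
    mu <- (sum(z * a) + sum(w * s)) / (2 * n)
    r_b <- b_eq - drop(crossprod(X, a))
    r_c <- ys - drop(X %*% lam) - z + w
    gap <- sum(z * a) + sum(w * s)
    if (gap < tol * n && max(abs(r_b)) < tol * n && max(abs(r_c)) < tol) break

    d <- 1 / (z / a + w / s)

    newton_dir <- function(sig_mu, cross_a, cross_s) {
      rhs_v <- r_c + z - w - (sig_mu - cross_a) / a + (sig_mu - cross_s) / s
      M <- crossprod(X, X * d)
      rhs <- r_b + drop(crossprod(X, d * rhs_v))
      dlam <- NULL
      jit <- 1e-12
      while (is.null(dlam) && jit < 1e-2) {
        dlam <- tryCatch(solve(M + diag(jit * max(diag(M)), p), rhs),
                         error = function(e) NULL)
        jit <- jit * 100
      }
      if (is.null(dlam)) dlam <- qr.solve(M, rhs, tol = 1e-300)
      da <- d * (drop(X %*% dlam) - rhs_v)
      dz <- (sig_mu - cross_a) / a - z - (z / a) * da
      dw <- (sig_mu - cross_s) / s - w + (w / s) * da
      list(dlam = dlam, da = da, ds = -da, dz = dz, dw = dw)
    }
    step_len <- function(v, dv) {
      neg <- dv < 0
      if (!any(neg)) return(1)
      min(1, 0.9995 * min(-v[neg] / dv[neg]))
    }

    # affine (predictor) step
    aff <- newton_dir(0, 0, 0)
    if (!all(is.finite(c(aff$da, aff$dz, aff$dw, aff$dlam)))) break
    ap <- min(step_len(a, aff$da), step_len(s, aff$ds))
    ad <- min(step_len(z, aff$dz), step_len(w, aff$dw))
    gap_aff <- sum((z + ad * aff$dz) * (a + ap * aff$da)) +
      sum((w + ad * aff$dw) * (s + ap * aff$ds))
    sigma <- min(1, (gap_aff / gap)^3)

    # corrector step with Mehrotra cross terms
    dir <- newton_dir(sigma * mu, aff$da * aff$dz, aff$ds * aff$dw)
    if (!all(is.finite(c(dir$da, dir$dz, dir$dw, dir$dlam)))) break
    ap <- min(step_len(a, dir$da), step_len(s, dir$ds))
    ad <- min(step_len(z, dir$dz), step_len(w, dir$dw))

    a <- pmax(a + ap * dir$da, 1e-14)
    s <- pmax(s + ap * dir$ds, 1e-14)
    z <- pmax(z + ad * dir$dz, 1e-14)
    w <- pmax(w + ad * dir$dw, 1e-14)
    lam <- lam + ad * dir$dlam
    if (!all(is.finite(lam))) break
  }

  beta <- lam * sc / cs
  X <- X_orig

  # vertex polish: an optimal basic solution interpolates p observations
  res <- y - drop(X %*% beta)
  ord <- order(abs(res))
  idx <- ord[seq_len(min(p, n))]
  if (length(idx) == p) {
    Xb <- X[idx, , drop = FALSE]
    if (abs(det(crossprod(Xb))) > 1e-12) {
      beta_v <- tryCatch(solve(Xb, y[idx]), error = function(e) NULL)
      if (!is.null(beta_v) &&
          pinball_loss(y, drop(X %*% beta_v), tau) <=
          pinball_loss(y, drop(X %*% beta), tau) + 1e-9 * (1 + abs(sc))) {
        beta <- beta_v
      }
    }
  }
  beta <- drop(beta)
  names(beta) <- colnames(X)
  loss <- pinball_loss(y, drop(X %*% beta), tau)
  list(coefficients = beta, tau = tau, loss = loss, n = n, iterations = iter)
}

#' Fit conditional quantile surfaces of an HRQoL outcome
#'
#' Fits linear quantile regressions of an outcome (EQ-5D index or VAS) on
#' adjustment covariates -- by default age and years since diagnosis -- at
#' each requested quantile level. Each level is fitted independently by
#' minimizing the pinball loss via an interior-point linear-programming
#' solver.
#'
#' @param data A data frame with one row per participant.
#' @param outcome Name of the outcome column (string).
#' @param covariates Character vector of adjustment covariate columns.
#' @param taus Quantile levels; default the three quartiles.
#' @return An object of class `qolseg_quantile_fits`: a list of per-tau fits
#'   with a `tidy()` method returning one row per (tau, term).
#' @examples
#' d <- tibble::tibble(age_years = 30:69,
#'                     years_since_diagnosis = rep(1:10, 4),
#'                     vas = 90 - 0.3 * (30:69) + rnorm(40))
#' fits <- fit_conditional_quantiles(d, "vas")
#' tidy(fits)
#' @export
fit_conditional_quantiles <- function(data, outcome,
                                      covariates = c("age_years", "years_since_diagnosis"),
                                      taus = c(0.25, 0.5, 0.75)) {
  assert_columns(data, c(outcome, covariates))
  if (any(taus <= 0 | taus >= 1)) abort_validation("all `taus` must lie in (0, 1)")
  keep <- complete.cases(data[, c(outcome, covariates), drop = FALSE])
  if (any(!keep)) {
    abort_validation(sprintf(
      "%d row(s) have missing outcome or covariates; apply the inclusion rules first",
      sum(!keep)))
  }
  y <- as.numeric(data[[outcome]])
  if (length(y) <= length(covariates) + 1L) {
    abort_validation("need more observations than coefficients")
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(data[, covariates, drop = FALSE]))
  storage.mode(X) <- "double"
  fits <- lapply(sort(taus), function(tau) rq_fit_fn(X, y, tau))
  structure(list(fits = fits, outcome = outcome, covariates = covariates,
                 taus = sort(taus)),
            class = "qolseg_quantile_fits")
}

#' Predict fitted quantile surfaces at participant covariates
#'
#' @param object A `qolseg_quantile_fits` object.
#' @param newdata Data frame containing the fit's covariate columns.
#' @return A tibble with one column `q<100*tau>` per fitted level.
#' @export
predict_quantiles <- function(object, newdata) {
  stopifnot(inherits(object, "qolseg_quantile_fits"))
  assert_columns(newdata, object$covariates, "newdata")
  X <- cbind(1, as.matrix(newdata[, object$covariates, drop = FALSE]))
  out <- lapply(object$fits, function(f) drop(X %*% f$coefficients))
  names(out) <- sprintf("q%g", 100 * object$taus)
  tibble::as_tibble(out)
}

#' @export
tidy.qolseg_quantile_fits <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble::tibble(tau = f$tau, term = names(f$coefficients),
                   estimate = unname(f$coefficients))
  })
}

#' @export
glance.qolseg_quantile_fits <- function(x, ...) {
  purrr::map_dfr(x$fits, function(f) {
    tibble::tibble(tau = f$tau, pinball_loss = f$loss, n = f$n,
                   iterations = f$iterations)
  })
}

#' @export
print.qolseg_quantile_fits <- function(x, ...) {
  cat(sprintf("Conditional quantile fits of %s on %s\n", x$outcome,
              paste(x$covariates, collapse = " + ")))
  print(tidy(x), n = Inf)
  invisible(x)
}
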
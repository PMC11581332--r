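#' Multinomial logistic regression by Newton-Raphson maximum likelihood
#'
#' Fits a baseline-category multinomial logit for a three-group (or
#' generally K-group) outcome. The reference category defaults to the
#' middle/"as expected" group when one is recognisable (`"normal"` or
#' `"within_expectation"`), so that coefficients are log relative risk
#' ratios (RRR) of being in the low or high tail versus the normal range.
#' Estimation is full Newton-Raphson on the multinomial log-likelihood with
#' step halving; convergence requires every score component below `1e-8`.
#' Wald 95% confidence intervals use the observed information.
#'
#' @param data Data frame holding the outcome and covariates.
#' @param formula Model formula, e.g. `group ~ sex + phenotype + srdss_class`.
#' @param ref Reference outcome category; sensible default chosen as above.
#' @param max_iter Maximum Newton iterations.
#' @param coef_cap Absolute log-RRR beyond which a separation warning is
#'   raised naming the covariate (sparse categories can separate).
#' @return An object of class `qolseg_multinom`; `tidy()` gives the RRR
#'   table (one row per non-reference category and term), `glance()` the
#'   log-likelihood, AIC, and convergence diagnostics.
#' @examples
#' cohort <- simulate_cohort(generator_config(n = 600, seed = 3))
#' seg <- segment_cohort(cohort)
#' d <- dplyr::left_join(tidy(seg), cohort, by = "participant_id")
#' fit <- fit_multinomial(d, eq5d_label ~ sex + srdss_class)
#' tidy(fit)
#' @export
fit_multinomial <- function(data, formula, ref = NULL, max_iter = 100L,
                            coef_cap = 15) {
  mf <- model.frame(formula, data = data, na.action = na.omit)
  y <- factor(stats::model.response(mf))
  if (nlevels(y) < 2) abort_validation("outcome must have at least 2 categories")
  if (any(table(y) == 0)) abort_validation("every outcome category needs observations")
  if (is.null(ref)) {
    ref <- intersect(c("normal", "within_expectation"), levels(y))[1]
    if (is.na(ref)) ref <- levels(y)[1]
  }
  if (!ref %in% levels(y)) abort_validation("`ref` is not an outcome category")
  y <- stats::relevel(y, ref = ref)
  X <- model.matrix(attr(mf, "terms"), mf)
  n <- nrow(X); p <- ncol(X); K <- nlevels(y)
  if (qr(X)$rank < p) {
    abort_validation("design matrix is rank deficient; drop aliased terms")
  }
  Y <- matrix(0, n, K - 1)
  for (k in 2:K) Y[, k - 1] <- as.numeric(y == levels(y)[k])

  B <- matrix(0, p, K - 1)
  loglik_fn <- function(B) {
    eta <- X %*% B
    m <- pmax(apply(cbind(0, eta), 1, max), 0)
    denom <- exp(-m) + rowSums(exp(eta - m))
    sum(rowSums(Y * eta)) - sum(m + log(denom))
  }
  probs_fn <- function(B) {
    eta <- X %*% B
    expeta <- exp(eta - apply(cbind(0, eta), 1, max))
    exp0 <- exp(-apply(cbind(0, eta), 1, max))
    sweep(expeta, 1, exp0 + rowSums(expeta), "/")
  }
  ll <- loglik_fn(B)
  converged <- FALSE
  max_grad <- Inf
  for (it in seq_len(max_iter)) {
    P <- probs_fn(B)
    G <- crossprod(X, Y - P)                       # p x (K-1) score
    max_grad <- max(abs(G))
    if (max_grad < 1e-8) { converged <- TRUE; break }
    H <- matrix(0, p * (K - 1), p * (K - 1))
    for (j in seq_len(K - 1)) {
      for (l in seq_len(j)) {
        wjl <- if (j == l) P[, j] * (1 - P[, j]) else -P[, j] * P[, l]
        blk <- crossprod(X, X * wjl)
        rj <- (j - 1) * p + seq_len(p); rl <- (l - 1) * p + seq_len(p)
        H[rj, rl] <- blk
        if (j != l) H[rl, rj] <- blk
      }
    }
    step <- tryCatch(solve(H, as.vector(G)), error = function(e) {
      solve(H + diag(1e-8, nrow(H)), as.vector(G))
    })
    # step halving keeps the likelihood ascending
    alpha <- 1
    repeat {
      B_new <- B + alpha * matrix(step, p, K - 1)
      ll_new <- loglik_fn(B_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      alpha <- alpha / 2
      if (alpha < 1e-10) { B_new <- B; ll_new <- ll; break }
    }
    B <- B_new; ll <- ll_new
  }
  if (any(abs(B) > coef_cap)) {
    bad <- unique(colnames(X)[which(abs(B) > coef_cap, arr.ind = TRUE)[, 1]])
    warn(paste("possible separation: coefficient magnitude exceeds cap for",
               paste(bad, collapse = ", ")), class = "qolseg_separation")
  }
  P <- probs_fn(B)
  H <- matrix(0, p * (K - 1), p * (K - 1))
  for (j in seq_len(K - 1)) {
    for (l in seq_len(j)) {
      wjl <- if (j == l) P[, j] * (1 - P[, j]) else -P[, j] * P[, l]
      blk <- crossprod(X, X * wjl)
      rj <- (j - 1) * p + seq_len(p); rl <- (l - 1) * p + seq_len(p)
      H[rj, rl] <- blk
      if (j != l) H[rl, rj] <- blk
    }
  }
  vc <- tryCatch(solve(H), error = function(e) solve(H + diag(1e-8, nrow(H))))
  dimnames(B) <- list(colnames(X), levels(y)[-1])
  par_names <- as.vector(outer(colnames(X), levels(y)[-1],
                               function(a, b) paste(b, a, sep = ":")))
  dimnames(vc) <- list(par_names, par_names)
  structure(list(
    coefficients = B, vcov = vc, loglik = ll,
    aic = 2 * length(B) - 2 * ll, n = n, k = length(B),
    levels = levels(y), reference = ref, converged = converged,
    max_grad = max_grad, iterations = it,
    fitted = {
      Pm <- cbind(1 - rowSums(P), P)
      colnames(Pm) <- levels(y)
      Pm
    },
    formula = formula,
    terms = attr(mf, "terms"), xlevels = stats::.getXlevels(attr(mf, "terms"), mf)
  ), class = "qolseg_multinom")
}

#' @export
tidy.qolseg_multinom <- function(x, conf_level = 0.95, ...) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- matrix(sqrt(diag(x$vcov)), nrow = nrow(x$coefficients),
               dimnames = dimnames(x$coefficients))
  purrr::map_dfr(colnames(x$coefficients), function(cat) {
    est <- x$coefficients[, cat]
    tibble::tibble(
      y_level = cat, term = rownames(x$coefficients),
      estimate = unname(est), std.error = unname(se[, cat]),
      statistic = unname(est / se[, cat]),
      p.value = 2 * pnorm(-abs(unname(est / se[, cat]))),
      rrr = exp(unname(est)),
      conf.low = exp(unname(est - z * se[, cat])),
      conf.high = exp(unname(est + z * se[, cat]))
    )
  })
}

#' @export
glance.qolseg_multinom <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, AIC = x$aic, df = x$k, nobs = x$n,
                 converged = x$converged, max_gradient = x$max_grad,
                 iterations = x$iterations)
}

#' @export
print.qolseg_multinom <- function(x, ...) {
  cat(sprintf("Multinomial logit (%d obs), reference category '%s'\n",
              x$n, x$reference))
  cat(sprintf("logLik %.2f, AIC %.2f, converged: %s\n", x$loglik, x$aic,
              x$converged))
  print(tidy(x), n = 20)
  invisible(x)
}

#' @export
vcov.qolseg_multinom <- function(object, ...) object$vcov

#' Forest plot of relative risk ratios
#'
#' @param object A `qolseg_multinom` fit.
#' @param ... Unused.
#' @return A ggplot object: RRR with 95% CI per term, faceted by outcome
#'   category, log-scaled x axis.
#' @export
autoplot.qolseg_multinom <- function(object, ...) {
  d <- tidy(object)
  d <- d[d$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rrr, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~ .data$y_level) +
    ggplot2::labs(x = "Relative risk ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
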
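#' Forward retention of candidate covariates by AIC
#'
#' Starting from the base confounder model (by default sex, clinical
#' phenotype and gait-impairment class on top of the age/duration
#' adjustment already absorbed by the segmentation), candidates are offered
#' one at a time in the given order; a candidate is retained if and only if
#' it lowers the AIC of the running model by at least `threshold` points
#' (default 2, so a drop of exactly 2.0 is retained). The MS Severity Score
#' is never a candidate -- it is reserved for the separate subsample
#' analysis ([refit_with_msss()]). A candidate whose addition makes the
#' design rank deficient is skipped with a logged reason.
#'
#' @param data Data frame with the outcome and all terms.
#' @param outcome Name of the grouped outcome column.
#' @param base_terms Character vector of always-included confounders.
#' @param candidates Ordered character vector of candidate terms.
#' @param threshold Required AIC reduction (> 0).
#' @param ref Reference outcome category, passed to [fit_multinomial()].
#' @return A `qolseg_selection`: the final `qolseg_multinom` fit plus a
#'   step-by-step trace; `tidy()` returns the trace.
#' @export
forward_select_aic <- function(data, outcome, base_terms, candidates,
                               threshold = 2, ref = NULL) {
  if (!is_scalar_number(threshold) || threshold <= 0) {
    abort_config("`threshold` must be a positive number")
  }
  assert_columns(data, c(outcome, base_terms))
  trace <- list()
  dropped_msss <- intersect(candidates, c("msss", "edss"))
  for (v in dropped_msss) {
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = NA_integer_, candidate = v, aic_before = NA_real_,
      aic_after = NA_real_, delta_aic = NA_real_, retained = FALSE,
      reason = "severity score reserved for the subsample analysis")
  }
  candidates <- setdiff(candidates, dropped_msss)

  current_terms <- base_terms
  fml <- as.formula(paste(outcome, "~", paste(current_terms, collapse = " + ")))
  fit <- fit_multinomial(data, fml, ref = ref)
  for (i in seq_along(candidates)) {
    cand <- candidates[i]
    if (!cand %in% names(data)) {
      trace[[length(trace) + 1]] <- tibble::tibble(
        step = i, candidate = cand, aic_before = fit$aic, aic_after = NA_real_,
        delta_aic = NA_real_, retained = FALSE, reason = "column not found")
      next
    }
    fml_new <- as.formula(paste(outcome, "~",
                                paste(c(current_terms, cand), collapse = " + ")))
    fit_new <- tryCatch(
      withCallingHandlers(
        fit_multinomial(data, fml_new, ref = ref),
        qolseg_separation = function(w) invokeRestart("muffleWarning")),
      error = function(e) e)
    if (inherits(fit_new, "error")) {
      trace[[length(trace) + 1]] <- tibble::tibble(
        step = i, candidate = cand, aic_before = fit$aic, aic_after = NA_real_,
        delta_aic = NA_real_, retained = FALSE,
        reason = paste("skipped:", conditionMessage(fit_new)))
      next
    }
    delta <- fit_new$aic - fit$aic
    keep <- delta <= -threshold
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = i, candidate = cand, aic_before = fit$aic, aic_after = fit_new$aic,
      delta_aic = delta, retained = keep,
      reason = if (keep) "AIC reduced by threshold" else "insufficient AIC reduction")
    if (keep) {
      current_terms <- c(current_terms, cand)
      fit <- fit_new
    }
  }
  structure(list(fit = fit, trace = dplyr::bind_rows(trace),
                 base_terms = base_terms, final_terms = current_terms,
                 outcome = outcome, threshold = threshold),
            class = "qolseg_selection")
}

#' @export
tidy.qolseg_selection <- function(x, ...) x$trace

#' @export
glance.qolseg_selection <- function(x, ...) {
  tibble::tibble(n_candidates = sum(!is.na(x$trace$step)),
                 n_retained = sum(x$trace$retained),
                 final_AIC = x$fit$aic,
                 final_terms = paste(x$final_terms, collapse = " + "))
}

#' @export
print.qolseg_selection <- function(x, ...) {
  cat(sprintf("AIC forward retention for `%s` (threshold %.1f)\n",
              x$outcome, x$threshold))
  print(x$trace, n = Inf)
  cat("Final terms:", paste(x$final_terms, collapse = " + "), "\n")
  invisible(x)
}

#' Collinearity diagnostics for a multinomial model design
#'
#' Computes generalized variance-inflation factors (GVIF) per model term --
#' categorical terms aggregated over their contrasts, following the
#' determinant-ratio definition -- together with the scaled design condition
#' number. Terms with `GVIF^(1/(2 df)) > 2.236` (the square root of the
#' conventional VIF threshold of 5) are flagged.
#'
#' @param data Data frame holding the model variables.
#' @param formula Right-hand-side or full formula describing the design.
#' @return A `qolseg_collinearity` list: `$terms` tibble (term, df, gvif,
#'   `gvif_adj` = GVIF^(1/(2 df)), flagged), `$condition_number`,
#'   `$rank_deficient`.
#' @export
collinearity_check <- function(data, formula) {
  mf <- model.frame(formula, data = data, na.action = na.omit)
  X <- model.matrix(attr(mf, "terms"), mf)
  asg <- attr(X, "assign")
  labs <- attr(attr(mf, "terms"), "term.labels")
  Xn <- X[, asg != 0, drop = FALSE]
  asg <- asg[asg != 0]
  rank_deficient <- qr(cbind(1, Xn))$rank < ncol(Xn) + 1
  sv <- svd(scale(Xn, center = TRUE, scale = TRUE), nu = 0, nv = 0)$d
  condition_number <- max(sv) / max(min(sv), .Machine$double.eps)
  terms_tbl <- NULL
  if (!rank_deficient) {
    R <- stats::cor(Xn)
    detR <- det(R)
    rows <- purrr::map_dfr(seq_along(labs), function(j) {
      idx <- which(asg == j)
      gvif <- det(R[idx, idx, drop = FALSE]) *
        det(R[-idx, -idx, drop = FALSE]) / detR
      if (length(idx) == ncol(R)) gvif <- 1
      df <- length(idx)
      tibble::tibble(term = labs[j], df = df, gvif = gvif,
                     gvif_adj = gvif^(1 / (2 * df)),
                     flagged = gvif^(1 / (2 * df)) > 2.236)
    })
    terms_tbl <- rows
  }
  structure(list(terms = terms_tbl, condition_number = condition_number,
                 rank_deficient = rank_deficient),
            class = "qolseg_collinearity")
}

#' @export
print.qolseg_collinearity <- function(x, ...) {
  if (x$rank_deficient) {
    cat("Design is RANK DEFICIENT (aliased terms present)\n")
  } else {
    print(x$terms, n = Inf)
  }
  cat(sprintf("Condition number of the scaled design: %.1f\n",
              x$condition_number))
  invisible(x)
}

#' Re-fit the final model on the severity-score subsample
#'
#' Restricts the data to rows where the MS Severity Score is observed,
#' re-fits the selected model there, and adds the score as a linear term,
#' reporting its per-unit RRR. The severity score is kept out of model
#' building and only enters through this separate analysis.
#'
#' @param selection A `qolseg_selection` (or a character vector of final
#'   terms).
#' @param data Data frame containing the terms, the outcome and `msss`.
#' @param outcome Outcome column; defaults to the selection's outcome.
#' @param ref Reference category passed to [fit_multinomial()].
#' @return A `qolseg_multinom` fitted on the subsample.
#' @export
refit_with_msss <- function(selection, data, outcome = NULL, ref = NULL) {
  if (inherits(selection, "qolseg_selection")) {
    terms_v <- selection$final_terms
    outcome <- outcome %||% selection$outcome
  } else {
    terms_v <- as.character(selection)
    if (is.null(outcome)) abort_validation("`outcome` required when passing raw terms")
  }
  assert_columns(data, c("msss", outcome))
  sub <- data[!is.na(data$msss), , drop = FALSE]
  if (nrow(sub) == 0) abort_validation("no rows with an observed severity score")
  if (length(unique(sub$msss)) < 2) {
    abort_validation("severity score is constant on the subsample; its effect is inestimable")
  }
  fml <- as.formula(paste(outcome, "~",
                          paste(c(terms_v, "msss"), collapse = " + ")))
  fit <- fit_multinomial(sub, fml, ref = ref)
  fit$subsample_n <- nrow(sub)
  fit
}
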
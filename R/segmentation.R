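#' Classify a measurement against its adjusted quartile band
#'
#' A participant is `"low"` when the measurement falls strictly below the
#' fitted 25th-percentile surface at their age and disease duration,
#' `"high"` when strictly above the fitted 75th percentile, and `"normal"`
#' otherwise. Boundary ties are normal: the comparison is strict, mirroring
#' "fell below" / "greater than".
#'
#' @param y Measurements.
#' @param q25,q75 Fitted lower/upper quartile at each participant's covariates.
#' @return Character vector in `c("low", "normal", "high")`.
#' @export
classify_hrqol <- function(y, q25, q75) {
  lo <- pmin(q25, q75)
  hi <- pmax(q25, q75)
  dplyr::case_when(y < lo ~ "low", y > hi ~ "high", TRUE ~ "normal")
}

#' Assign a four-level quartile bin relative to fitted quartile surfaces
#'
#' Bins partition the outcome axis: 1 below q25, 2 in `[q25, q50)`,
#' 3 in `[q50, q75]`, 4 above q75. The boundary conventions make bin 1
#' coincide with the `"low"` class and bin 4 with `"high"`.
#'
#' @param y Measurements.
#' @param q25,q50,q75 Fitted quartile surfaces (crossing fits are sorted
#'   pointwise before binning).
#' @return Integer vector of bins 1-4.
#' @export
assign_quartile_bin <- function(y, q25, q50, q75) {
  q <- t(apply(cbind(q25, q50, q75), 1, sort))
  dplyr::case_when(
    y < q[, 1] ~ 1L,
    y < q[, 2] ~ 2L,
    y <= q[, 3] ~ 3L,
    TRUE ~ 4L
  )
}

#' Label EQ-5D vs VAS discordance from quartile bins
#'
#' Discordance means the two instruments' quartile bins are separated by at
#' least two quantiles: `"lower_vas"` (high EQ-5D, low VAS) when EQ-5D is in
#' the highest quartile with VAS in the lowest two, or EQ-5D in the highest
#' two with VAS in the lowest; `"higher_vas"` is the mirror image; everything
#' else is `"within_expectation"`.
#'
#' @param eq_bin,vas_bin Integer quartile bins in 1-4 (see
#'   [assign_quartile_bin()]).
#' @return Character vector in
#'   `c("lower_vas", "within_expectation", "higher_vas")`.
#' @export
label_discordance <- function(eq_bin, vas_bin) {
  ok <- function(b) is.numeric(b) && !anyNA(b) && all(b %in% 1:4)
  if (!ok(eq_bin) || !ok(vas_bin)) {
    abort_validation("quartile bins must be integers in 1..4")
  }
  dplyr::case_when(
    (eq_bin == 4L & vas_bin <= 2L) | (eq_bin >= 3L & vas_bin == 1L) ~ "lower_vas",
    (eq_bin == 1L & vas_bin >= 3L) | (eq_bin <= 2L & vas_bin == 4L) ~ "higher_vas",
    TRUE ~ "within_expectation"
  )
}

#' Segment a cohort into age- and duration-adjusted HRQoL groups
#'
#' Runs the full segmentation: fits conditional 25th/50th/75th percentile
#' surfaces of each instrument on age and years since diagnosis, classifies
#' every participant as low/normal/high per instrument, assigns quartile
#' bins, and -- when both instruments are segmented -- labels EQ-5D-VAS
#' discordance.
#'
#' @param data Participant-level data frame with the outcome and covariate
#'   columns present and complete.
#' @param instruments Outcome columns to segment; default both `eq5d_index`
#'   and `vas`.
#' @param covariates Adjustment covariates for the quantile surfaces.
#' @param taus Quantile levels defining the band; must contain 0.25, 0.5, 0.75.
#' @return A `qolseg_segmentation` object wrapping a per-participant tibble
#'   (fitted quartiles, bin and label per instrument, discordance label) and
#'   the underlying quantile fits; `tidy()` returns the tibble, `glance()`
#'   per-instrument group counts.
#' @examples
#' cohort <- simulate_cohort(generator_config(n = 400, seed = 7))
#' seg <- segment_cohort(cohort)
#' glance(seg)
#' @export
segment_cohort <- function(data,
                           instruments = c("eq5d_index", "vas"),
                           covariates = c("age_years", "years_since_diagnosis"),
                           taus = c(0.25, 0.5, 0.75)) {
  assert_columns(data, c(instruments, covariates))
  if (!all(c(0.25, 0.5, 0.75) %in% taus)) {
    abort_validation("`taus` must include 0.25, 0.5 and 0.75")
  }
  res <- tibble::as_tibble(data)
  if (!"participant_id" %in% names(res)) {
    res$participant_id <- sprintf("P%05d", seq_len(nrow(res)))
  }
  fits <- list()
  crossings <- list()
  out <- res[, "participant_id"]
  for (ins in instruments) {
    qf <- fit_conditional_quantiles(data, ins, covariates, taus)
    fits[[ins]] <- qf
    qs <- predict_quantiles(qf, data)
    crossed <- !(qs$q25 <= qs$q50 & qs$q50 <= qs$q75)
    if (any(crossed)) {
      crossings[[ins]] <- tibble::tibble(
        participant_id = out$participant_id[crossed],
        instrument = ins,
        q25 = qs$q25[crossed], q50 = qs$q50[crossed], q75 = qs$q75[crossed])
    }
    # classification uses the pointwise-sorted band when fits cross
    qsort <- t(apply(as.matrix(qs), 1, sort))
    y <- as.numeric(data[[ins]])
    pre <- sub("_index$", "", ins)
    out[[paste0(pre, "_q25")]] <- qsort[, 1]
    out[[paste0(pre, "_q50")]] <- qsort[, 2]
    out[[paste0(pre, "_q75")]] <- qsort[, 3]
    out[[paste0(pre, "_bin")]] <- assign_quartile_bin(y, qsort[, 1], qsort[, 2], qsort[, 3])
    out[[paste0(pre, "_label")]] <- classify_hrqol(y, qsort[, 1], qsort[, 3])
  }
  if (all(c("eq5d_index", "vas") %in% instruments)) {
    out$discordance <- label_discordance(out$eq5d_bin, out$vas_bin)
  }
  empty_crossing <- tibble::tibble(participant_id = character(),
                                   instrument = character(), q25 = double(),
                                   q50 = double(), q75 = double())
  structure(list(result = out, fits = fits, data = res,
                 crossing_report = dplyr::bind_rows(empty_crossing, crossings),
                 instruments = instruments, taus = taus),
            class = "qolseg_segmentation")
}

#' @export
tidy.qolseg_segmentation <- function(x, ...) x$result

#' @export
glance.qolseg_segmentation <- function(x, ...) {
  purrr::map_dfr(x$instruments, function(ins) {
    pre <- sub("_index$", "", ins)
    lab <- factor(x$result[[paste0(pre, "_label")]],
                  levels = c("low", "normal", "high"))
    tibble::tibble(instrument = pre,
                   n = length(lab),
                   n_low = sum(lab == "low"),
                   n_normal = sum(lab == "normal"),
                   n_high = sum(lab == "high"),
                   n_crossing = sum(x$crossing_report$instrument == ins))
  })
}

#' @export
print.qolseg_segmentation <- function(x, ...) {
  cat("HRQoL quartile segmentation (adjusted for",
      paste(x$fits[[1]]$covariates, collapse = " + "), ")\n")
  print(glance(x))
  if ("discordance" %in% names(x$result)) {
    print(table(discordance = x$result$discordance))
  }
  invisible(x)
}

#' Scatter plot of the two instruments colored by discordance group
#'
#' @param object A `qolseg_segmentation` fitted on both instruments.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qolseg_segmentation <- function(object, ...) {
  res <- object$result
  if (!"discordance" %in% names(res)) {
    abort_validation("discordance plot needs both instruments segmented")
  }
  d <- dplyr::left_join(res, object$data, by = "participant_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$eq5d_index, y = .data$vas,
                                  colour = .data$discordance)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(
      lower_vas = "#c0392b", within_expectation = "grey60",
      higher_vas = "#27ae60")) +
    ggplot2::labs(x = "EQ-5D index (0-100)", y = "VAS (0-100)",
                  colour = "Discordance") +
    ggplot2::theme_minimal()
}
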
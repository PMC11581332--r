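#' Descriptive comparison of participant characteristics across groups
#'
#' Summarizes variables across HRQoL (or discordance) groups the way
#' registry cohort tables are printed: continuous variables as
#' `median [q25; q75]`, categorical and logical variables as `n (%)` of the
#' group. A "full_sample" column is always included.
#'
#' @param data Participant table.
#' @param group Name of the grouping column (its labels must cover all rows).
#' @param vars Variables to summarize; defaults to every column except the
#'   group and identifier columns.
#' @return A `qolseg_descriptive` tibble in long form: `variable`, `level`
#'   (`NA` for continuous rows), `group`, `n`, numeric summaries and a
#'   formatted `value`. The print method pivots it to the wide
#'   one-column-per-group layout.
#' @export
descriptive_table <- function(data, group, vars = NULL) {
  assert_columns(data, group)
  if (anyNA(data[[group]])) abort_validation("group labels must cover all rows")
  vars <- vars %||% setdiff(names(data),
                            c(group, "participant_id", "measurement_date"))
  data <- tibble::as_tibble(data)
  groups <- list(full_sample = rep(TRUE, nrow(data)))
  for (g in sort(unique(as.character(data[[group]])))) {
    groups[[g]] <- data[[group]] == g
  }
  out <- purrr::map_dfr(vars, function(v) {
    x <- data[[v]]
    purrr::map_dfr(names(groups), function(gname) {
      xi <- x[groups[[gname]]]
      n_g <- length(xi)
      if (is.numeric(xi)) {
        q <- quantile(xi, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE,
                      type = 2)
        tibble::tibble(variable = v, level = NA_character_, group = gname,
                       n = sum(!is.na(xi)), median = q[2], q25 = q[1],
                       q75 = q[3], count = NA_integer_, pct = NA_real_,
                       value = fmt_median_iqr(xi))
      } else {
        levs <- if (is.logical(x)) "yes" else sort(unique(na.omit(as.character(x))))
        xi <- if (is.logical(xi)) ifelse(xi, "yes", "no") else as.character(xi)
        purrr::map_dfr(levs, function(lv) {
          cnt <- sum(xi == lv, na.rm = TRUE)
          tibble::tibble(variable = v, level = lv, group = gname, n = n_g,
                         median = NA_real_, q25 = NA_real_, q75 = NA_real_,
                         count = cnt, pct = 100 * cnt / n_g,
                         value = sprintf("%d (%.1f)", cnt, 100 * cnt / n_g))
        })
      }
    })
  })
  class(out) <- c("qolseg_descriptive", class(out))
  attr(out, "group_var") <- group
  out
}

#' @export
print.qolseg_descriptive <- function(x, n = Inf, ...) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(x)[, c("variable", "level",
                                                      "group", "value")],
                             names_from = "group", values_from = "value")
  cat(sprintf("Descriptive table by `%s`\n", attr(x, "group_var")))
  print(wide, n = n)
  invisible(x)
}
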
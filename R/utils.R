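# internal helpers shared across modules

# stop with a classed condition so callers/tests can distinguish
# user-input problems ("qolseg_validation") from bad configuration
# ("qolseg_config_error")
abort_validation <- function(msg) {
  rlang::abort(msg, class = "qolseg_validation")
}

abort_config <- function(msg) {
  rlang::abort(msg, class = "qolseg_config_error")
}

assert_columns <- function(data, cols, what = "input table") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0) {
    abort_validation(sprintf(
      "%s is missing required column%s: %s",
      what, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort_config(sprintf("`%s` must be a probability in [0, 1]", name))
  }
  invisible(x)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# format p [q25; q75] the way registry tables print medians; type-2
# quantiles (inverse ECDF with averaging) match the usual published tables
# on small discrete sets
fmt_median_iqr <- function(x, digits = 1) {
  q <- quantile(x, c(0.25, 0.5, 0.75), na.rm = TRUE, names = FALSE, type = 2)
  sprintf("%s [%s; %s]",
          format(round(q[2], digits), trim = TRUE),
          format(round(q[1], digits), trim = TRUE),
          format(round(q[3], digits), trim = TRUE))
}
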
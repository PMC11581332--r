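#' Construct an EQ-5D value-set (tariff) table
#'
#' A value set converts a five-domain EQ-5D profile into a utility:
#' `U = constant - sum of per-domain decrements`, where level 1 of every
#' domain carries a zero decrement and the full-health profile has utility
#' exactly 1. `u_min` is the tariff's declared minimum achievable utility
#' (the utility of the worst profile); the package rescales `[u_min, 1]`
#' linearly onto the 0-100 index.
#'
#' The published country tariffs are licensed tables and are supplied by the
#' user; the package ships only a clearly labelled synthetic toy tariff for
#' tests and examples (see [toy_value_set()]).
#'
#' @param decrements Data frame with columns `domain`, `level` (integer,
#'   starting at 1) and `decrement` (non-negative utility decrement).
#' @param constant Utility of the full-health profile before decrements
#'   (almost always 1).
#' @param u_min Minimum achievable utility, strictly below 1.
#' @param version Free-text tag for the instrument/tariff version.
#' @return An object of class `qolseg_value_set`.
#' @export
value_set <- function(decrements, constant = 1, u_min, version = "unspecified") {
  decrements <- tibble::as_tibble(decrements)
  assert_columns(decrements, c("domain", "level", "decrement"), "value set")
  if (!is_scalar_number(u_min) || u_min >= 1) {
    abort_config("`u_min` must be a single number strictly below 1")
  }
  if (any(decrements$decrement < 0)) {
    abort_config("value-set decrements must be non-negative")
  }
  lvl1 <- decrements$decrement[decrements$level == 1]
  if (length(lvl1) > 0 && any(lvl1 != 0)) {
    abort_config("level-1 decrements must all be zero (full health)")
  }
  if (abs(constant - 1) > 1e-12) {
    abort_config("the full-health profile must score utility exactly 1")
  }
  worst <- constant - sum(tapply(decrements$decrement, decrements$domain, max))
  if (worst < u_min - 1e-9) {
    abort_config("worst achievable utility lies below the declared `u_min`")
  }
  structure(list(decrements = decrements, constant = constant,
                 u_min = u_min, version = version),
            class = "qolseg_value_set")
}

#' Read a value set from its CSV + JSON file pair
#'
#' The CSV holds the long decrement table (`domain`, `level`, `decrement`);
#' the JSON header holds `constant`, `u_min` and `version`.
#'
#' @param csv_path Path to the decrement CSV.
#' @param json_path Path to the JSON header; defaults to the CSV path with a
#'   `.json` extension.
#' @return A `qolseg_value_set`.
#' @export
read_value_set <- function(csv_path, json_path = sub("\\.csv$", ".json", csv_path)) {
  dec <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  hdr <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  value_set(dec, constant = hdr$constant %||% 1, u_min = hdr$u_min,
            version = hdr$version %||% "unspecified")
}

#' The packaged synthetic toy tariff
#'
#' A small, clearly synthetic EQ-5D-3L-shaped tariff (five domains, three
#' levels, `u_min = -0.53`) intended for tests, examples and the synthetic
#' pipeline. It is not a published country value set.
#'
#' @return A `qolseg_value_set`.
#' @export
toy_value_set <- function() {
  read_value_set(system.file("extdata", "toy_value_set.csv", package = "qolseg"),
                 system.file("extdata", "toy_value_set.json", package = "qolseg"))
}

eq5d_domains <- c("mobility", "self_care", "usual_activities",
                  "pain_discomfort", "anxiety_depression")

#' Score EQ-5D profiles to the 0-100 index
#'
#' Computes utility `U = constant - sum(decrements)` for each profile and
#' rescales it linearly from `[u_min, 1]` to `[0, 100]`, so full health maps
#' to 100 and the tariff's worst profile to 0.
#'
#' @param data Data frame containing one ordinal level column per domain.
#' @param value_set A [value_set()].
#' @param domains Names of the five domain columns, in tariff domain order.
#' @param into Name of the index column to add.
#' @return `data` with the index column appended.
#' @examples
#' d <- tibble::tibble(mobility = c(1, 2), self_care = 1,
#'                     usual_activities = 1, pain_discomfort = c(1, 3),
#'                     anxiety_depression = 1)
#' score_eq5d(d, toy_value_set())
#' @export
score_eq5d <- function(data, value_set, domains = eq5d_domains,
                       into = "eq5d_index") {
  stopifnot(inherits(value_set, "qolseg_value_set"))
  assert_columns(data, domains)
  dec <- value_set$decrements
  vs_domains <- unique(dec$domain)
  if (length(domains) != length(vs_domains)) {
    abort_validation(sprintf(
      "tariff declares %d domains but %d domain columns were given",
      length(vs_domains), length(domains)))
  }
  util <- rep(value_set$constant, nrow(data))
  for (i in seq_along(domains)) {
    dtab <- dec[dec$domain == vs_domains[i], ]
    lev <- data[[domains[i]]]
    rng <- range(dtab$level)
    bad <- !is.na(lev) & (lev < rng[1] | lev > rng[2] | lev != round(lev))
    if (any(bad)) {
      abort_validation(sprintf(
        "column `%s` has levels outside the tariff's declared range %d-%d",
        domains[i], rng[1], rng[2]))
    }
    util <- util - dtab$decrement[match(lev, dtab$level)]
  }
  data[[into]] <- 100 * (util - value_set$u_min) / (1 - value_set$u_min)
  tibble::as_tibble(data)
}

#' MS Severity Score by rank normalization of EDSS within duration strata
#'
#' Implements the rank-based severity score: participants are grouped into
#' integer-year disease-duration strata (sparse strata are pooled
#' symmetrically outward, `d + 1, d - 1, d + 2, ...`, until the minimum
#' stratum size is reached), EDSS values receive mid-ranks within the
#' stratum (ties share the mean rank), and the score is
#' `10 * midrank / (n_stratum + 1)`, so it lies strictly inside (0, 10).
#' High scores mean high disability relative to persons with the same
#' disease duration, i.e. fast progression.
#'
#' @param edss EDSS values on the 0-10 half-point grid.
#' @param duration Years since diagnosis (non-negative), same length.
#' @param min_stratum_size Minimum number of participants a duration
#'   stratum must reach after pooling (default 5; must be at least 2).
#' @return Numeric vector of severity scores in (0, 10).
#' @examples
#' compute_msss(edss = seq(1, 5, by = 0.5), duration = rep(5, 9))
#' @export
compute_msss <- function(edss, duration, min_stratum_size = 5) {
  if (length(edss) != length(duration)) {
    abort_validation("`edss` and `duration` must have the same length")
  }
  if (any(duration < 0, na.rm = TRUE)) abort_validation("durations must be >= 0")
  if (min_stratum_size < 2) abort_config("`min_stratum_size` must be >= 2")
  ok <- !is.na(edss) & !is.na(duration)
  if (sum(ok) < min_stratum_size) {
    abort_validation(sprintf(
      "only %d complete (EDSS, duration) pairs; cannot form a stratum of %d",
      sum(ok), min_stratum_size))
  }
  out <- rep(NA_real_, length(edss))
  dyr <- floor(duration[ok])
  ed <- edss[ok]
  res <- rep(NA_real_, length(ed))
  for (d in sort(unique(dyr))) {
    members <- which(dyr == d)
    pool <- members
    width <- 0L
    while (length(pool) < min_stratum_size) {
      width <- width + 1L
      pool <- which(dyr >= d - width & dyr <= d + width)
      if (width > max(dyr) + 1L) break
    }
    if (length(pool) < min_stratum_size) {
      abort_validation("could not pool duration strata to the minimum size")
    }
    r <- rank(ed[pool], ties.method = "average")
    res[members] <- 10 * r[match(members, pool)] / (length(pool) + 1)
  }
  out[ok] <- res
  out
}

#' Add MS Severity Scores to a participant table
#'
#' Wrapper around [compute_msss()]: computes the score from the `edss` and
#' `years_since_diagnosis` columns for rows where EDSS is observed and
#' stores it in `msss`.
#'
#' @param data Participant table with `edss` and `years_since_diagnosis`.
#' @param min_stratum_size Passed to [compute_msss()].
#' @return `data` with an `msss` column.
#' @export
add_msss <- function(data, min_stratum_size = 5) {
  assert_columns(data, c("edss", "years_since_diagnosis"))
  data$msss <- compute_msss(data$edss, data$years_since_diagnosis,
                            min_stratum_size = min_stratum_size)
  tibble::as_tibble(data)
}
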
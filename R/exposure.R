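#' Hours of equilibrium-equivalent exposure per working level month
#'
#' Conversion constant between cumulative progeny exposure expressed in
#' h Bq/m3 of EEC and working level months: 1 WLM = 6.37e5 h Bq/m3.
#' @export
WLM_H_BQM3 <- 6.37e5

# Display rounding: round half away from zero (the convention of the printed
# tables), unlike base round()'s round-half-to-even. Values are first snapped
# to 6 decimals so that binary representation error (e.g. 2080.4999999999995
# for the decimal 2080.5) cannot push a half-case below the boundary.
round_display <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(round(abs(x) * p, 6) + 0.5) / p
}

# Canonical microenvironment and age-group level orders, used throughout.
LOCATION_LEVELS <- c("home", "indoors_away", "outdoors", "vehicle")
AGE_GROUP_LEVELS <- c("infant", "young_child", "child", "adolescent", "adult", "senior")

# First and last whole year of life covered by each age group.
AGE_GROUP_BRACKETS <- data.frame(
  age_group = AGE_GROUP_LEVELS,
  from = c(0, 1, 5, 12, 20, 60),
  to   = c(0, 4, 11, 19, 59, 109),
  stringsAsFactors = FALSE
)

#' Equilibrium-equivalent concentration
#'
#' Radon progeny concentration expressed as the equilibrium-equivalent
#' concentration (EEC): the measured radon gas concentration times the
#' equilibrium factor \eqn{F_{eq}} describing the degree of disequilibrium
#' between radon and its short-lived progeny.
#'
#' @param radon radon gas concentration, Bq/m3 (>= 0).
#' @param f_eq equilibrium factor, in (0, 1].
#' @return EEC in Bq/m3, full precision.
#' @examples
#' eec(119, 0.6) # homes
#' eec(38, 0.4)  # public buildings
#' @export
eec <- function(radon, f_eq) {
  if (any(radon < 0)) stop("radon concentration must be >= 0")
  if (any(f_eq <= 0 | f_eq > 1)) stop("f_eq must be in (0, 1]")
  radon * f_eq
}

#' Annual exposure from daily occupancy and progeny concentration
#'
#' @param hours_per_day mean daily hours spent at the location, in [0, 24].
#' @param eec equilibrium-equivalent concentration at the location, Bq/m3.
#' @param days_per_year length of the exposure year (365 days).
#' @return Annual exposure in h Bq/m3 (EEC), full precision; round only for
#'   display.
#' @export
annual_exposure <- function(hours_per_day, eec, days_per_year = 365) {
  if (any(hours_per_day < 0 | hours_per_day > 24)) {
    stop("hours_per_day must be within [0, 24]")
  }
  if (any(eec < 0)) stop("eec must be >= 0")
  hours_per_day * eec * days_per_year
}

#' Read a time-activity pattern table
#'
#' CSV columns: \code{age_group} (one of infant, young_child, child,
#' adolescent, adult, senior), \code{location} (home, indoors_away,
#' outdoors, vehicle), \code{hours} (mean h/day) and \code{eec} (Bq/m3, the
#' progeny concentration assigned to that location for that age group; the
#' "indoors away from home" environment differs by age group).
#'
#' @param path path to CSV.
#' @return Validated data frame with one row per age group x location.
#' @export
read_time_activity_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("age_group", "location", "hours", "eec")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("time-activity CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  validate_time_activity(df)
  df
}

#' Packaged time-activity and microenvironment fixture
#'
#' Mean daily hours in four microenvironments (indoors at home, indoors away
#' from home, outdoors, in vehicle) for six age groups, with the
#' equilibrium-equivalent progeny concentration assigned to each
#' age-group-specific microenvironment. Home uses the national
#' population-weighted home EEC; "indoors away" is public buildings for
#' infants, adults and seniors, home-like daycares for young children, and
#' school buildings for children and adolescents; outdoors and vehicles use
#' the outdoor-air value.
#'
#' @return Data frame as in [read_time_activity_csv()].
#' @export
time_activity_fixture <- function() {
  read_time_activity_csv(system.file("extdata", "table2_time_activity.csv",
                                     package = "radonrisk", mustWork = TRUE))
}

validate_time_activity <- function(df) {
  if (!all(df$age_group %in% AGE_GROUP_LEVELS)) {
    stop("unknown age_group; expected one of: ",
         paste(AGE_GROUP_LEVELS, collapse = ", "))
  }
  if (!all(df$location %in% LOCATION_LEVELS)) {
    stop("unknown location; expected one of: ",
         paste(LOCATION_LEVELS, collapse = ", "))
  }
  if (any(df$hours < 0)) stop("hours must be >= 0")
  if (any(df$eec < 0)) stop("eec must be >= 0")
  daily <- tapply(df$hours, df$age_group, sum)
  off <- abs(daily - 24) > 0.01
  if (any(off)) {
    stop("daily hours for age group(s) ", paste(names(daily)[off], collapse = ", "),
         " do not sum to 24")
  }
  invisible(df)
}

#' Annual exposures and location contributions by age group
#'
#' For each age group, computes the per-location annual exposure
#' (hours x EEC x 365, h Bq/m3), the total annual exposure, and the percent
#' contribution of each reporting location. Totals and contributions are
#' computed on unrounded per-location values; outdoors and in-vehicle are
#' merged into a single "outdoors_vehicle" category for contribution
#' reporting (both are assigned outdoor-air progeny levels).
#'
#' @param patterns time-activity data frame (see [read_time_activity_csv()]).
#' @param days_per_year exposure year length in days.
#' @return List with two data frames: \code{exposure} (age_group, location,
#'   hours, eec, annual, annual_display) and \code{summary} (age_group,
#'   total, total_display, and contribution percentages \code{pct_home},
#'   \code{pct_indoors_away}, \code{pct_outdoors_vehicle}, rounded to one
#'   decimal).
#' @examples
#' age_group_exposure(time_activity_fixture())$summary
#' @export
age_group_exposure <- function(patterns, days_per_year = 365) {
  validate_time_activity(patterns)
  patterns$annual <- annual_exposure(patterns$hours, patterns$eec, days_per_year)
  patterns$annual_display <- round_display(patterns$annual)

  groups <- intersect(AGE_GROUP_LEVELS, unique(patterns$age_group))
  summ <- do.call(rbind, lapply(groups, function(g) {
    sub <- patterns[patterns$age_group == g, , drop = FALSE]
    total <- sum(sub$annual)
    by_loc <- tapply(sub$annual, factor(sub$location, LOCATION_LEVELS), sum,
                     default = 0)
    data.frame(
      age_group = g,
      total = total,
      total_display = round_display(total),
      pct_home = round_display(100 * by_loc[["home"]] / total, 1),
      pct_indoors_away = round_display(100 * by_loc[["indoors_away"]] / total, 1),
      pct_outdoors_vehicle = round_display(
        100 * (by_loc[["outdoors"]] + by_loc[["vehicle"]]) / total, 1),
      stringsAsFactors = FALSE
    )
  }))
  rownames(summ) <- NULL
  list(exposure = patterns, summary = summ)
}

#' Convert cumulative exposure to working level months
#'
#' @param exposure cumulative exposure in h Bq/m3 of EEC (>= 0).
#' @param wlm_per_unit h Bq/m3 per WLM; defaults to [WLM_H_BQM3].
#' @return Exposure in WLM.
#' @export
to_wlm <- function(exposure, wlm_per_unit = WLM_H_BQM3) {
  if (any(exposure < 0)) stop("exposure must be >= 0")
  exposure / wlm_per_unit
}

#' Age group containing a given whole year of life
#'
#' Years of life 0; 1-4; 5-11; 12-19; 20-59; 60-109 map to infant,
#' young_child, child, adolescent, adult and senior respectively.
#'
#' @param age integer vector of years of life in 0..109.
#' @return Character vector of age-group labels.
#' @export
age_group_for_age <- function(age) {
  if (any(age < 0 | age > 109)) stop("age must be in 0..109")
  idx <- findInterval(age, AGE_GROUP_BRACKETS$from)
  AGE_GROUP_BRACKETS$age_group[idx]
}

#' Build a lifetime exposure history
#'
#' Expands age-group annual exposures into a per-year-of-life exposure
#' history over a 110-year lifespan: each year of life 0..109 receives the
#' per-location annual exposure (in WLM) of the age group containing it.
#' Restricting \code{locations} zeroes all other locations, which is how
#' single-location histories for risk attribution are built.
#'
#' @param patterns time-activity data frame covering all six age groups.
#' @param locations character vector of locations to keep, or \code{"all"}.
#' @param days_per_year exposure year length in days.
#' @param wlm_per_unit h Bq/m3 per WLM.
#' @return An \code{exposure_history}: 110 x 4 numeric matrix (rows = years
#'   of life 0..109, columns = locations) of annual exposures in WLM.
#' @examples
#' h <- build_lifetime_history(time_activity_fixture())
#' rowSums(h)[31] # total annual WLM in the 31st year of life (age 30)
#' @export
build_lifetime_history <- function(patterns, locations = "all",
                                   days_per_year = 365,
                                   wlm_per_unit = WLM_H_BQM3) {
  validate_time_activity(patterns)
  have <- unique(patterns$age_group)
  if (!all(AGE_GROUP_LEVELS %in% have)) {
    stop("patterns must cover all age groups; missing: ",
         paste(setdiff(AGE_GROUP_LEVELS, have), collapse = ", "))
  }
  if (identical(locations, "all")) locations <- LOCATION_LEVELS
  if (!all(locations %in% LOCATION_LEVELS)) {
    stop("unknown location(s): ",
         paste(setdiff(locations, LOCATION_LEVELS), collapse = ", "))
  }

  # annual WLM per age group x location
  patterns$annual_wlm <- to_wlm(
    annual_exposure(patterns$hours, patterns$eec, days_per_year), wlm_per_unit)
  ann <- matrix(0, nrow = length(AGE_GROUP_LEVELS), ncol = length(LOCATION_LEVELS),
                dimnames = list(AGE_GROUP_LEVELS, LOCATION_LEVELS))
  for (i in seq_len(nrow(patterns))) {
    ann[patterns$age_group[i], patterns$location[i]] <-
      ann[patterns$age_group[i], patterns$location[i]] + patterns$annual_wlm[i]
  }
  ann[, setdiff(LOCATION_LEVELS, locations)] <- 0

  ages <- 0:109
  history <- ann[age_group_for_age(ages), , drop = FALSE]
  rownames(history) <- ages
  class(history) <- c("exposure_history", class(history))
  history
}

#' Time-since-exposure windows of cumulative exposure
#'
#' Partitions the exposure history at attained age \code{a} into the three
#' cumulative-exposure windows of the windowed excess-relative-risk model:
#' exposure received 5-14 years before \code{a}, 15-24 years before, and 25
#' or more years before. Exposure within the 5 most recent years carries no
#' weight (minimum latency); exposure at whole year of life \code{y} counts
#' as received \code{a - y} years before age \code{a}.
#'
#' @param history an \code{exposure_history} matrix, or a numeric vector of
#'   total annual exposure (WLM) indexed by year of life 0..109.
#' @param a attained age in whole years, 0..110.
#' @param lag minimum latency in years (5).
#' @return Named numeric vector \code{c(w5_14, w15_24, w25plus)} in WLM.
#' @examples
#' h <- build_lifetime_history(time_activity_fixture())
#' exposure_windows(h, 60)
#' @export
exposure_windows <- function(history, a, lag = 5) {
  if (a < 0 || a > 110) stop("attained age must be in 0..110")
  total <- if (is.matrix(history)) rowSums(history) else as.numeric(history)
  n <- length(total)
  window_sum <- function(from, to) {
    from <- max(from, 0)
    to <- min(to, n - 1)
    if (to < from) 0 else sum(total[(from:to) + 1L])
  }
  c(w5_14 = window_sum(a - 14, a - lag),
    w15_24 = window_sum(a - 24, a - 15),
    w25plus = window_sum(0, a - 25))
}
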
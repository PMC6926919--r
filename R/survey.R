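#' Read a regional radon survey table
#'
#' Reads a CSV of regional radon survey results, one row per survey of one
#' building function in one region. Columns: \code{region}, \code{population}
#' (census count for the region), \code{building_function} (one of
#' \code{home}, \code{school}, \code{public}, \code{senior_housing},
#' \code{other}), \code{n_tested} (number of places measured),
#' \code{mean_rn} (arithmetic mean radon concentration, Bq/m3), and optional
#' \code{sd}, \code{range_low}, \code{range_high} (Bq/m3; below-detection
#' values are coded as blank \code{range_low}).
#'
#' @param path path to a UTF-8 CSV file.
#' @return A validated data frame of survey records.
#' @seealso [radon_survey_fixture()] for the packaged national survey summary.
#' @export
read_survey_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(region = "character"))
  required <- c("region", "population", "building_function", "n_tested", "mean_rn")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("survey CSV is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (opt in c("sd", "range_low", "range_high")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  }
  validate_survey_records(df)
  df
}

#' Packaged regional radon survey fixture
#'
#' The regional survey summary shipped with the package: for each of 13
#' Canadian regions, the 2016 census population, the building function
#' surveyed, the number of places tested, and the arithmetic-mean radon
#' concentration (with standard deviation and range where reported).
#' Calgary homes appear twice (two independent surveys) and Prince Edward
#' Island includes a senior-housing survey.
#'
#' @return A data frame of survey records (see [read_survey_csv()]).
#' @export
radon_survey_fixture <- function() {
  read_survey_csv(system.file("extdata", "table1_surveys.csv",
                              package = "radonrisk", mustWork = TRUE))
}

# Validates invariants: n_tested >= 1, mean_rn >= 0, population > 0, sd >= 0.
validate_survey_records <- function(df) {
  if (nrow(df) == 0) stop("survey table is empty")
  bad <- function(cond, msg) {
    i <- which(cond)
    if (length(i) > 0) stop(sprintf("survey row %d: %s", i[1], msg))
  }
  bad(is.na(df$n_tested) | df$n_tested < 1, "n_tested must be >= 1")
  bad(is.na(df$mean_rn) | df$mean_rn < 0, "mean_rn must be >= 0")
  bad(is.na(df$population) | df$population <= 0, "population must be > 0")
  bad(!is.na(df$sd) & df$sd < 0, "sd must be >= 0 when present")
  known <- c("home", "school", "public", "senior_housing", "other")
  bad(!df$building_function %in% known,
      paste("building_function must be one of", paste(known, collapse = ", ")))
  invisible(df)
}

#' Default building-function to building-class mapping
#'
#' Maps each surveyed building function to the class used for national
#' aggregation. Civic, provincial and federal buildings are all counted as
#' public buildings upstream of this mapping (they arrive as
#' \code{"public"}). Senior housings are counted as residential (they are
#' dwellings): this reproduces both the national home measurement count and
#' the public-building count of the packaged fixture. Functions mapped to
#' \code{"excluded"} are dropped from aggregation.
#'
#' @return Named character vector: building function -> class or "excluded".
#' @export
default_building_map <- function() {
  c(home = "home",
    school = "school",
    public = "public",
    senior_housing = "home",
    other = "excluded")
}

#' Classify a survey record into a building class
#'
#' @param building_function character vector of building functions.
#' @param mapping named character vector mapping functions to classes
#'   (\code{"home"}, \code{"school"}, \code{"public"}) or \code{"excluded"}.
#' @return Character vector of classes (possibly \code{"excluded"}).
#' @export
classify_building <- function(building_function, mapping = default_building_map()) {
  unmapped <- setdiff(unique(building_function), names(mapping))
  if (length(unmapped) > 0) {
    stop("no mapping for building function(s): ", paste(unmapped, collapse = ", "))
  }
  unname(mapping[building_function])
}

#' Pool several surveys of the same class within one region
#'
#' Where one region reports several surveys of the same building class,
#' they are merged into a single regional mean weighted by the number of
#' places tested (the measurement count), i.e.
#' \deqn{\bar{c} = \sum_j n_j c_j / \sum_j n_j.}
#'
#' @param records data frame of survey records sharing one region and class.
#' @return One-row data frame with \code{region}, \code{population},
#'   \code{n_total} and \code{pooled_mean}.
#' @export
pool_within_region <- function(records) {
  if (nrow(records) == 0) stop("cannot pool an empty set of records")
  if (length(unique(records$region)) != 1) {
    stop("pool_within_region() requires records from a single region")
  }
  data.frame(
    region = records$region[1],
    population = records$population[1],
    n_total = sum(records$n_tested),
    pooled_mean = sum(records$n_tested * records$mean_rn) / sum(records$n_tested),
    stringsAsFactors = FALSE
  )
}

#' Population-weighted mean over regional pooled means
#'
#' @param pooled data frame with one row per region: \code{population} and
#'   \code{pooled_mean}.
#' @return The population-weighted arithmetic mean concentration (Bq/m3),
#'   full precision.
#' @export
population_weighted_mean <- function(pooled) {
  if (nrow(pooled) == 0) stop("no regional data to weight")
  if (anyDuplicated(pooled$region)) {
    stop("each region must appear at most once")
  }
  total_pop <- sum(pooled$population)
  if (total_pop <= 0) stop("total population is zero")
  sum(pooled$population * pooled$pooled_mean) / total_pop
}

#' National summary of radon surveys by building class
#'
#' Classifies every survey record, pools multiple surveys of the same class
#' within a region by measurement count, then weights the regional pooled
#' means by census population. Regions lacking data for a class are simply
#' omitted from that class's weighting. Classes with no data are absent from
#' the output (no data is not the same as zero concentration).
#'
#' @param records data frame of survey records (see [read_survey_csv()]).
#' @param mapping building-function mapping, see [default_building_map()].
#' @return Data frame with one row per building class present:
#'   \code{building_class}, \code{n_total} (summed measurement count),
#'   \code{weighted_mean} (full precision Bq/m3) and \code{weighted_mean_display}
#'   (rounded to the nearest integer Bq/m3).
#' @examples
#' national_summary(radon_survey_fixture())
#' @export
national_summary <- function(records, mapping = default_building_map()) {
  validate_survey_records(records)
  records$building_class <- classify_building(records$building_function, mapping)
  records <- records[records$building_class != "excluded", , drop = FALSE]
  if (nrow(records) == 0) stop("all records excluded; nothing to summarise")

  out <- lapply(sort(unique(records$building_class)), function(cls) {
    sub <- records[records$building_class == cls, , drop = FALSE]
    pooled <- do.call(rbind, lapply(split(sub, sub$region), pool_within_region))
    wm <- population_weighted_mean(pooled)
    data.frame(building_class = cls,
               n_total = sum(pooled$n_total),
               weighted_mean = wm,
               weighted_mean_display = round_display(wm),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
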
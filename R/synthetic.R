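#' Configuration for the synthetic-data generators
#'
#' Bundles the parameters of the synthetic survey generator, the parametric
#' mortality tables and the cohort simulator. Indoor radon concentrations
#' are drawn from lognormal distributions (the standard model for indoor
#' radon) with a geometric mean and geometric standard deviation per
#' building class. The synthetic mortality tables use a Gompertz-Makeham
#' all-cause hazard \eqn{h^*(x) = c + A e^{Bx}} and a logistic-shaped
#' lung-cancer hazard that is zero below a sex-specific onset age, rises
#' steeply after mid-life and saturates at a plateau, capped at the
#' all-cause hazard.
#'
#' @param n_regions number of synthetic survey regions.
#' @param population_range range of regional census populations.
#' @param n_tested_range range of measurement counts per survey.
#' @param radon_gm named geometric means (Bq/m3) per building class.
#' @param radon_gsd named geometric standard deviations (>= 1) per class.
#' @param mortality list with one element per sex; each a list of
#'   \code{makeham_c}, \code{makeham_a}, \code{makeham_b} (all-cause),
#'   \code{lung_onset} (first age with nonzero lung-cancer hazard),
#'   \code{lung_plateau} (asymptotic lung-cancer rate, 1/y),
#'   \code{lung_midpoint}, \code{lung_width} (logistic location/scale, y).
#' @param cohort_size default number of individuals for [cohort_simulator()].
#' @return A list of class \code{synthetic_config}.
#' @export
synthetic_config <- function(n_regions = 12,
                             population_range = c(3e4, 1.5e6),
                             n_tested_range = c(20, 500),
                             radon_gm = c(home = 85, school = 45, public = 28),
                             radon_gsd = c(home = 2.2, school = 2.0, public = 2.0),
                             mortality = list(
                               male = list(makeham_c = 8e-4, makeham_a = 4e-5,
                                           makeham_b = 0.088, lung_onset = 10,
                                           lung_plateau = 5.2e-3,
                                           lung_midpoint = 72, lung_width = 8),
                               female = list(makeham_c = 5e-4, makeham_a = 2.5e-5,
                                             makeham_b = 0.090, lung_onset = 20,
                                             lung_plateau = 4.0e-3,
                                             lung_midpoint = 74, lung_width = 8)),
                             cohort_size = 1e6) {
  if (any(radon_gm <= 0)) stop("radon_gm must be > 0")
  if (any(radon_gsd < 1)) stop("radon_gsd must be >= 1")
  if (!identical(sort(names(radon_gm)), sort(names(radon_gsd)))) {
    stop("radon_gm and radon_gsd must cover the same classes")
  }
  for (sx in names(mortality)) {
    m <- mortality[[sx]]
    needed <- c("makeham_c", "makeham_a", "makeham_b", "lung_onset",
                "lung_plateau", "lung_midpoint", "lung_width")
    if (!all(needed %in% names(m))) {
      stop("mortality parameters for ", sx, " must include: ",
           paste(needed, collapse = ", "))
    }
  }
  structure(list(n_regions = n_regions, population_range = population_range,
                 n_tested_range = n_tested_range, radon_gm = radon_gm,
                 radon_gsd = radon_gsd, mortality = mortality,
                 cohort_size = cohort_size),
            class = "synthetic_config")
}

#' Generate a synthetic regional radon survey table
#'
#' For each synthetic region and each building class, draws a measurement
#' count and reports the arithmetic mean of that many lognormal radon
#' concentrations, mimicking how a regional survey summary is produced.
#' Deterministic for a fixed (config, seed) pair.
#'
#' @param cfg a [synthetic_config()].
#' @param seed integer RNG seed.
#' @return A survey-record data frame in the schema of [read_survey_csv()].
#' @export
make_survey_table <- function(cfg = synthetic_config(), seed = 1) {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(seed)
  classes <- names(cfg$radon_gm)
  rows <- list()
  for (r in seq_len(cfg$n_regions)) {
    population <- round(stats::runif(1, cfg$population_range[1],
                                     cfg$population_range[2]))
    for (cls in classes) {
      n <- sample(seq(cfg$n_tested_range[1], cfg$n_tested_range[2]), 1)
      draws <- stats::rlnorm(n, meanlog = log(cfg$radon_gm[[cls]]),
                             sdlog = log(cfg$radon_gsd[[cls]]))
      rows[[length(rows) + 1]] <- data.frame(
        region = sprintf("region_%02d", r), population = population,
        building_function = cls, n_tested = n, mean_rn = mean(draws),
        sd = stats::sd(draws), range_low = min(draws), range_high = max(draws),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Generate synthetic sex-specific mortality tables
#'
#' Produces lung-cancer and all-cause mortality rates for ages 1..110 and
#' each configured sex from the parametric hazards in the configuration.
#' The tables are deterministic functions of the configuration (no
#' randomness). The lung-cancer hazard is exactly zero below the
#' sex-specific onset age and never exceeds the all-cause hazard; the
#' all-cause hazard is strictly increasing.
#'
#' @param cfg a [synthetic_config()].
#' @return Data frame with columns \code{sex}, \code{age} (1..110),
#'   \code{h_lung}, \code{h_all} (rates per person-year).
#' @export
make_mortality_table <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  ages <- 1:110
  out <- lapply(names(cfg$mortality), function(sx) {
    m <- cfg$mortality[[sx]]
    h_all <- m$makeham_c + m$makeham_a * exp(m$makeham_b * ages)
    h_lung <- m$lung_plateau *
      stats::plogis((ages - m$lung_midpoint) / m$lung_width)
    h_lung[ages < m$lung_onset] <- 0
    h_lung <- pmin(h_lung, h_all)
    data.frame(sex = sx, age = ages, h_lung = h_lung, h_all = h_all,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Packaged synthetic mortality table
#'
#' The default synthetic mortality table used by the examples, tests and
#' the pipeline when no external mortality table is supplied. It emulates
#' the qualitative structure of recent Canadian mortality (which is not
#' redistributable with the package): lung-cancer mortality is zero for
#' males below age 10 and for females below age 20, rises steeply after
#' mid-life, and the baseline lifetime risk it implies is of the same order
#' as national values. It is a synthetic stand-in, not national data.
#'
#' @return Data frame as in [make_mortality_table()].
#' @export
synthetic_mortality_fixture <- function() {
  make_mortality_table(synthetic_config())
}

#' Extract the single-sex mortality table
#'
#' @param mortality data frame with a \code{sex} column, as produced by
#'   [make_mortality_table()].
#' @param sex one of the sexes present in the table.
#' @return Data frame with columns \code{age}, \code{h_lung}, \code{h_all}.
#' @export
mortality_for_sex <- function(mortality, sex) {
  if (!sex %in% mortality$sex) {
    stop("sex '", sex, "' not present in mortality table")
  }
  out <- mortality[mortality$sex == sex, c("age", "h_lung", "h_all")]
  rownames(out) <- NULL
  out
}

#' Monte-Carlo cohort estimate of lifetime lung-cancer risk
#'
#' Simulates a closed cohort of \code{n} individuals year by year through
#' ages 1..110: in year \eqn{i} a surviving individual dies with
#' probability \eqn{1 - \exp(-(h_i^* + h_i e_i))}, and a death is lung
#' cancer with probability \eqn{h_i (1 + e_i) / (h_i^* + h_i e_i)}. Serves
#' as an independent stochastic check on the analytic life-table formula in
#' [lifetime_risk()].
#'
#' @param mortality single-sex mortality table (age, h_lung, h_all).
#' @param err_series excess relative risk per age (length 110 or recycled).
#' @param n cohort size.
#' @param seed integer RNG seed.
#' @return List with \code{estimate} (proportion dying of lung cancer),
#'   \code{se} (binomial standard error), \code{n_lung} and \code{n}.
#' @export
cohort_simulator <- function(mortality, err_series = 0, n = 1e6, seed = 1) {
  mortality <- validate_mortality(mortality)
  e <- rep_len(err_series, 110)
  if (any(e < 0)) stop("excess relative risk must be >= 0")
  set.seed(seed)
  total <- mortality$h_all + mortality$h_lung * e
  p_death <- 1 - exp(-total)
  p_lung <- ifelse(total > 0, mortality$h_lung * (1 + e) / total, 0)

  alive <- as.integer(n)
  n_lung <- 0L
  for (i in 1:110) {
    if (alive == 0L) break
    deaths <- stats::rbinom(1, alive, p_death[i])
    if (deaths > 0L) n_lung <- n_lung + stats::rbinom(1, deaths, p_lung[i])
    alive <- alive - deaths
  }
  estimate <- n_lung / n
  list(estimate = estimate, se = sqrt(estimate * (1 - estimate) / n),
       n_lung = n_lung, n = n)
}
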
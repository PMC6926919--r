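#' Parameters of the windowed excess-relative-risk model
#'
#' The excess relative risk (ERR) of lung-cancer mortality at attained age
#' \eqn{a} is modelled as
#' \deqn{e(a) = \beta \, (W_{5-14} + \theta_{15-24} W_{15-24} +
#'   \theta_{25+} W_{25+}) \, \Phi_{age}(a),}
#' where the \eqn{W} terms are cumulative exposures (WLM) in
#' time-since-exposure windows (see [exposure_windows()]), \eqn{\beta} is
#' the ERR per WLM, the \eqn{\theta} weights discount older exposure, and
#' \eqn{\Phi_{age}} is a piecewise-constant, non-increasing attained-age
#' modifier. Defaults are the EPA/BEIR-VI exposure-age-concentration values:
#' \eqn{\beta = 0.0634} per WLM, \eqn{\theta_{15-24} = 0.78},
#' \eqn{\theta_{25+} = 0.51}, and \eqn{\Phi_{age}} equal to 1 below age 55,
#' 0.57 for 55-64, 0.29 for 65-74 and 0.09 at 75 and above
#' (BEIR VI, National Research Council 1999; US EPA 2003).
#'
#' @param beta ERR per WLM (> 0).
#' @param theta_15_24,theta_25plus weights of the 15-24 y and 25+ y windows,
#'   in (0, 1].
#' @param phi_breaks increasing vector of attained-age breakpoints.
#' @param phi_values values of the modifier on the intervals delimited by
#'   \code{phi_breaks} (length \code{length(phi_breaks) + 1}); must be
#'   non-increasing and within [0, 1].
#' @param lag minimum latency in years; exposure in the most recent
#'   \code{lag} years carries no risk.
#' @param wlm_per_unit h Bq/m3 of EEC per WLM.
#' @return A validated list of class \code{risk_params}.
#' @export
risk_params <- function(beta = 0.0634,
                        theta_15_24 = 0.78,
                        theta_25plus = 0.51,
                        phi_breaks = c(55, 65, 75),
                        phi_values = c(1, 0.57, 0.29, 0.09),
                        lag = 5,
                        wlm_per_unit = WLM_H_BQM3) {
  if (beta <= 0) stop("beta must be > 0")
  if (theta_15_24 <= 0 || theta_15_24 > 1 || theta_25plus <= 0 || theta_25plus > 1) {
    stop("theta weights must lie in (0, 1]")
  }
  if (length(phi_values) != length(phi_breaks) + 1) {
    stop("phi_values must have one more element than phi_breaks")
  }
  if (is.unsorted(phi_breaks, strictly = TRUE)) {
    stop("phi_breaks must be strictly increasing")
  }
  if (any(diff(phi_values) > 0)) stop("phi_values must be non-increasing")
  if (any(phi_values < 0 | phi_values > 1)) stop("phi_values must be in [0, 1]")
  structure(
    list(beta = beta, theta_15_24 = theta_15_24, theta_25plus = theta_25plus,
         phi_breaks = phi_breaks, phi_values = phi_values, lag = lag,
         wlm_per_unit = wlm_per_unit),
    class = "risk_params")
}

#' Attained-age effect modifier
#'
#' @param a attained age(s) in years.
#' @param params a [risk_params()] object.
#' @return The piecewise-constant modifier value(s).
#' @export
phi_age <- function(a, params = risk_params()) {
  params$phi_values[findInterval(a, params$phi_breaks) + 1L]
}

#' Excess relative risk at an attained age
#'
#' @param a attained age in whole years.
#' @param history an exposure history (see [build_lifetime_history()]).
#' @param params a [risk_params()] object.
#' @return Dimensionless excess relative risk e(a) >= 0.
#' @export
err <- function(a, history, params = risk_params()) {
  w <- exposure_windows(history, a, lag = params$lag)
  params$beta *
    (w[["w5_14"]] + params$theta_15_24 * w[["w15_24"]] +
       params$theta_25plus * w[["w25plus"]]) *
    phi_age(a, params)
}

#' Excess-relative-risk series over the life table ages
#'
#' Evaluates e(a) at every life-table age a = 1..110 using the exposure
#' history accumulated up to that age.
#'
#' @inheritParams err
#' @return Numeric vector of length 110 (ages 1..110).
#' @export
err_series <- function(history, params = risk_params()) {
  vapply(1:110, err, numeric(1), history = history, params = params)
}

# Validates a single-sex mortality table: ages 1..110 with lung-cancer and
# all-cause hazards.
validate_mortality <- function(mortality) {
  required <- c("age", "h_lung", "h_all")
  if (!all(required %in% names(mortality))) {
    stop("mortality table needs columns: ", paste(required, collapse = ", "))
  }
  mortality <- mortality[order(mortality$age), , drop = FALSE]
  if (!identical(as.integer(mortality$age), 1:110)) {
    stop("mortality table must cover ages 1..110 exactly once")
  }
  if (any(mortality$h_all <= 0)) stop("all-cause hazard must be > 0 at every age")
  if (any(mortality$h_lung < 0 | mortality$h_lung > mortality$h_all)) {
    stop("lung-cancer hazard must satisfy 0 <= h_lung <= h_all")
  }
  mortality
}

#' Lifetime lung-cancer risk from a life table with excess relative risk
#'
#' BEIR-IV-style double-decrement life table. With lung-cancer hazard
#' \eqn{h_i}, all-cause hazard \eqn{h_i^*} (which already includes baseline
#' lung cancer) and excess relative risk \eqn{e_i} at age \eqn{i}, the
#' cumulative absolute risk of lung-cancer death by age \eqn{a} is
#' \deqn{R_e(a) = \sum_{i=1}^{a} \frac{h_i (1 + e_i)}{h_i^* + h_i e_i}
#'  \prod_{k=1}^{i-1} e^{-(h_k^* + h_k e_k)}
#'  \left[1 - e^{-(h_i^* + h_i e_i)}\right],}
#' i.e. the probability of surviving to age \eqn{i}, dying during year
#' \eqn{i} under the total hazard \eqn{h_i^* + h_i e_i}, and the death being
#' lung cancer with the hazard-fraction probability. The lifetime risk is
#' \eqn{R_e = R_e(110)}; a lifespan of 110 years is assumed. A year in which
#' the total hazard in the cause fraction is zero contributes nothing.
#'
#' @param mortality single-sex mortality table: data frame with columns
#'   \code{age} (1..110), \code{h_lung} and \code{h_all} (rates per
#'   person-year).
#' @param err_series excess relative risk per age, length 110 (ages 1..110)
#'   or a single number recycled; defaults to 0 (baseline).
#' @param printed_sign_variant if \code{TRUE}, uses a minus sign in the
#'   yearly death-probability bracket,
#'   \eqn{1 - \exp(-(h_i^* - h_i e_i))}, instead of the total hazard.
#'   This variant makes exposure reduce total deaths and exists only for
#'   comparison; the default is the total-hazard form required by the
#'   double-decrement construction.
#' @return A list of class \code{lifetime_risk}: \code{table} (data frame
#'   with age, err, yearly lung-cancer death probability \code{term},
#'   cumulative risk \code{cum_risk}, survival to the start of each year
#'   \code{surv}), and \code{lifetime} = \eqn{R_e(110)}.
#' @examples
#' m <- synthetic_mortality_fixture()
#' baseline_risk(mortality_for_sex(m, "male"))$lifetime
#' @export
lifetime_risk <- function(mortality, err_series = 0,
                          printed_sign_variant = FALSE) {
  mortality <- validate_mortality(mortality)
  e <- rep_len(err_series, 110)
  if (any(e < 0)) stop("excess relative risk must be >= 0")
  h <- mortality$h_lung
  hs <- mortality$h_all

  total_hazard <- hs + h * e
  bracket_hazard <- if (printed_sign_variant) hs - h * e else total_hazard
  frac <- ifelse(total_hazard > 0, h * (1 + e) / total_hazard, 0)
  surv <- c(1, exp(-cumsum(total_hazard)))[1:110] # survival to start of year i
  term <- frac * surv * (1 - exp(-bracket_hazard))
  cum <- cumsum(term)

  structure(
    list(table = data.frame(age = 1:110, err = e, term = term,
                            cum_risk = cum, surv = surv),
         lifetime = cum[110],
         printed_sign_variant = printed_sign_variant),
    class = "lifetime_risk")
}

#' Baseline lifetime lung-cancer risk
#'
#' The life-table risk with zero excess relative risk at every age.
#'
#' @inheritParams lifetime_risk
#' @return A \code{lifetime_risk} object (see [lifetime_risk()]).
#' @export
baseline_risk <- function(mortality) {
  lifetime_risk(mortality, err_series = 0)
}

#' Relative risk by attained age
#'
#' RR(a) = R_e(a) / R_0(a): the proportional increment in cumulative
#' lung-cancer risk over baseline. Undefined (NA) at ages where the baseline
#' cumulative risk is still zero.
#'
#' @param exposed,baseline \code{lifetime_risk} results computed on the same
#'   mortality table.
#' @return Data frame with columns \code{age}, \code{r_e}, \code{r_0},
#'   \code{rr}.
#' @export
relative_risk <- function(exposed, baseline) {
  stopifnot(inherits(exposed, "lifetime_risk"), inherits(baseline, "lifetime_risk"))
  r_e <- exposed$table$cum_risk
  r_0 <- baseline$table$cum_risk
  data.frame(age = 1:110, r_e = r_e, r_0 = r_0,
             rr = ifelse(r_0 > 0, r_e / r_0, NA_real_))
}

#' Attribute excess lifetime risk to exposure locations
#'
#' Builds the all-location lifetime exposure history and one single-location
#' history per microenvironment from the same time-activity patterns, runs
#' each through the life table, and reports each location's share of the
#' excess lifetime risk,
#' \deqn{share(loc) = \frac{R_{loc} - R_0}{R_{all} - R_0} \times 100,}
#' evaluated at age 110. Because the ERR enters the life table nonlinearly,
#' shares need not sum exactly to 100; at realistic exposures the deviation
#' is well under one percentage point.
#'
#' @param patterns time-activity data frame covering all age groups.
#' @param mortality single-sex mortality table.
#' @param params a [risk_params()] object.
#' @param locations locations to attribute; defaults to all four.
#' @return Data frame with \code{location}, lifetime risk \code{r_loc}, and
#'   \code{share_pct}; attributes \code{r_all} and \code{r_0} carry the
#'   all-location and baseline lifetime risks.
#' @export
attribute_by_location <- function(patterns, mortality, params = risk_params(),
                                  locations = LOCATION_LEVELS) {
  r_0 <- baseline_risk(mortality)$lifetime
  all_hist <- build_lifetime_history(patterns, wlm_per_unit = params$wlm_per_unit)
  r_all <- lifetime_risk(mortality, err_series(all_hist, params))$lifetime
  if (r_all <= r_0) stop("no excess risk to attribute (all-location risk equals baseline)")

  shares <- do.call(rbind, lapply(locations, function(loc) {
    hist_loc <- build_lifetime_history(patterns, locations = loc,
                                       wlm_per_unit = params$wlm_per_unit)
    r_loc <- lifetime_risk(mortality, err_series(hist_loc, params))$lifetime
    data.frame(location = loc, r_loc = r_loc,
               share_pct = 100 * (r_loc - r_0) / (r_all - r_0),
               stringsAsFactors = FALSE)
  }))
  rownames(shares) <- NULL
  attr(shares, "r_all") <- r_all
  attr(shares, "r_0") <- r_0
  shares
}
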
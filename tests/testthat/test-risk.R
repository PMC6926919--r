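test_that("risk parameter validation enforces the model's constraints", {
  p <- risk_params()
  expect_equal(p$beta, 0.0634)
  expect_equal(p$theta_15_24, 0.78)
  expect_equal(p$theta_25plus, 0.51)
  expect_equal(p$lag, 5)
  expect_error(risk_params(beta = 0), "beta")
  expect_error(risk_params(theta_15_24 = 1.2), "theta")
  expect_error(risk_params(phi_values = c(0.5, 1, 0.2, 0.1)), "non-increasing")
  expect_error(risk_params(phi_breaks = c(65, 55, 75)), "increasing")
})

test_that("the attained-age modifier is piecewise constant and non-increasing", {
  p <- risk_params()
  expect_equal(phi_age(c(30, 54), p), c(1, 1))
  expect_equal(phi_age(c(55, 64), p), c(0.57, 0.57))
  expect_equal(phi_age(c(65, 74), p), c(0.29, 0.29))
  expect_equal(phi_age(c(75, 110), p), c(0.09, 0.09))
  a <- 1:110
  expect_true(all(diff(phi_age(a, p)) <= 0))
})

test_that("excess relative risk combines the windows with their weights", {
  # uniform 1 WLM/y at age 30: windows (10, 10, 6), flat phi
  e <- err(30, uniform_history(1), flat_phi_params())
  expect_equal(e, 0.0634 * (10 + 0.78 * 10 + 0.51 * 6), tolerance = 1e-12)
  expect_equal(e, 1.322524, tolerance = 1e-9)
  # zero history gives zero ERR at every age
  expect_true(all(err_series(uniform_history(0)) == 0))
})

test_that("the life table reproduces the hand-evaluated one-year closed form", {
  toy <- toy_one_year_mortality(h_all1 = 0.1, h_lung1 = 0.02)
  r <- lifetime_risk(toy, err_series = 0)
  expect_equal(r$lifetime, 0.2 * (1 - exp(-0.1)), tolerance = 1e-12)
  expect_equal(r$lifetime, 0.019032516393, tolerance = 1e-10)
  expect_equal(baseline_risk(toy)$lifetime, r$lifetime)
})

test_that("lifetime risk is zero without lung-cancer hazard and non-decreasing in age", {
  none <- data.frame(age = 1:110, h_lung = 0, h_all = 0.01)
  expect_identical(lifetime_risk(none, err_series = 2)$lifetime, 0)
  m <- mortality_for_sex(synthetic_mortality_fixture(), "male")
  r <- lifetime_risk(m, err_series(build_lifetime_history(time_activity_fixture())))
  expect_true(all(diff(r$table$cum_risk) >= 0))
  expect_gte(r$lifetime, 0)
  expect_lte(r$lifetime, 1)
})

test_that("yearly cause-specific deaths conserve total deaths", {
  set.seed(7)
  m <- random_mortality()
  e <- runif(110, 0, 1)
  r <- lifetime_risk(m, e)
  total_hazard <- m$h_all + m$h_lung * e
  p_death_year <- r$table$surv * (1 - exp(-total_hazard))
  # lung + other deaths equal total deaths in every year
  frac <- m$h_lung * (1 + e) / total_hazard
  other <- (1 - frac) * p_death_year
  expect_equal(r$table$term + other, p_death_year, tolerance = 1e-12)
  # total deaths equal the complement of survival past the last age
  expect_equal(sum(p_death_year), 1 - exp(-sum(total_hazard)), tolerance = 1e-12)
})

test_that("lifetime risk increases with beta and with any single year's exposure", {
  m <- mortality_for_sex(synthetic_mortality_fixture(), "male")
  h <- build_lifetime_history(time_activity_fixture())
  risks <- vapply(c(0.01, 0.0634, 0.2), function(b) {
    lifetime_risk(m, err_series(h, flat_phi_params(beta = b)))$lifetime
  }, numeric(1))
  expect_true(all(diff(risks) > 0))

  bumped <- h
  bumped[41, "home"] <- bumped[41, "home"] + 1 # extra WLM at age 40
  expect_gt(lifetime_risk(m, err_series(bumped))$lifetime,
            lifetime_risk(m, err_series(h))$lifetime)
})

test_that("exposure received within five years of the end of life never matters", {
  m <- mortality_for_sex(synthetic_mortality_fixture(), "female")
  h <- build_lifetime_history(time_activity_fixture())
  late <- h
  late[107:110, ] <- late[107:110, ] + 1000 # ages 106-109
  expect_identical(lifetime_risk(m, err_series(late))$lifetime,
                   lifetime_risk(m, err_series(h))$lifetime)
})

test_that("the printed-sign bracket variant lowers yearly deaths under exposure", {
  m <- mortality_for_sex(synthetic_mortality_fixture(), "male")
  e <- rep(0.5, 110)
  std <- lifetime_risk(m, e)
  alt <- lifetime_risk(m, e, printed_sign_variant = TRUE)
  expect_lt(alt$lifetime, std$lifetime)
  expect_equal(lifetime_risk(m, 0, printed_sign_variant = TRUE)$lifetime,
               baseline_risk(m)$lifetime)
})

test_that("relative risk is one without exposure and at least one with it", {
  m <- mortality_for_sex(synthetic_mortality_fixture(), "female")
  base <- baseline_risk(m)
  rr0 <- relative_risk(lifetime_risk(m, 0), base)
  expect_true(all(rr0$rr[!is.na(rr0$rr)] == 1))
  # baseline risk is undefined below the female onset age
  expect_true(all(is.na(rr0$rr[rr0$age < 20])))

  es <- err_series(build_lifetime_history(time_activity_fixture()))
  rr1 <- relative_risk(lifetime_risk(m, es), base)
  expect_true(all(rr1$rr[!is.na(rr1$rr)] >= 1))
  # exposure accumulated through childhood makes RR jump at onset
  expect_gt(rr1$rr[rr1$age == 20], 1.3)
})

test_that("attribution gives 100% to the only exposed location", {
  pat <- time_activity_fixture()
  solo <- pat
  solo$eec[solo$location != "home"] <- 0
  m <- mortality_for_sex(synthetic_mortality_fixture(), "male")
  sh <- attribute_by_location(solo, m)
  expect_equal(sh$share_pct[sh$location == "home"], 100)
  expect_equal(sum(sh$share_pct[sh$location != "home"]), 0)
})

test_that("attribution shares converge to windowed exposure shares as beta vanishes", {
  pat <- time_activity_fixture()
  m <- mortality_for_sex(synthetic_mortality_fixture(), "male")
  sh_small <- attribute_by_location(pat, m, flat_phi_params(beta = 1e-4))
  sh_tiny <- attribute_by_location(pat, m, flat_phi_params(beta = 1e-6))
  expect_equal(sh_small$share_pct, sh_tiny$share_pct, tolerance = 1e-3)
  # in the linear limit shares sum to exactly 100
  expect_equal(sum(sh_tiny$share_pct), 100, tolerance = 1e-3)
})

test_that("attribution errors when there is no excess risk", {
  pat <- time_activity_fixture()
  zero <- pat
  zero$eec <- 0
  m <- mortality_for_sex(synthetic_mortality_fixture(), "male")
  expect_error(attribute_by_location(zero, m), "no excess risk")
})

test_that("mortality table validation catches structural defects", {
  m <- mortality_for_sex(synthetic_mortality_fixture(), "male")
  expect_silent(validate_mortality(m))
  short <- m[-1, ]
  expect_error(validate_mortality(short), "1..110")
  bad <- m
  bad$h_lung[50] <- bad$h_all[50] * 2
  expect_error(validate_mortality(bad), "h_lung <= h_all")
  zero <- m
  zero$h_all[10] <- 0
  expect_error(validate_mortality(zero), "> 0")
})
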
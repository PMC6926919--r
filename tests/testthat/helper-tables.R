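# Shared test helpers: toy mortality tables and flat-phi risk parameters.

# Single-sex mortality table in which only year 1 has appreciable hazard;
# later ages have zero lung-cancer hazard so they contribute exactly nothing
# to the lung-cancer risk sum (the all-cause floor keeps the table valid).
toy_one_year_mortality <- function(h_all1 = 0.1, h_lung1 = 0.02,
                                   floor = 1e-12) {
  data.frame(age = 1:110,
             h_lung = c(h_lung1, rep(0, 109)),
             h_all = c(h_all1, rep(floor, 109)))
}

# Risk parameters with a flat attained-age modifier (phi == 1 at all ages).
flat_phi_params <- function(...) {
  risk_params(phi_breaks = 110, phi_values = c(1, 1), ...)
}

# A uniform exposure history: `rate` WLM/year at home for every year of life.
uniform_history <- function(rate = 1) {
  h <- matrix(0, nrow = 110, ncol = 4,
              dimnames = list(0:109, c("home", "indoors_away", "outdoors", "vehicle")))
  h[, "home"] <- rate
  h
}

# Random but valid single-sex mortality table (for property-style tests).
random_mortality <- function() {
  h_all <- runif(110, 1e-4, 0.05) * exp(seq(0, 2, length.out = 110))
  h_lung <- runif(110, 0, 1) * h_all * 0.3
  data.frame(age = 1:110, h_lung = h_lung, h_all = h_all)
}
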
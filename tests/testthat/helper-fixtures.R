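# Small in-code fixtures shared across tests.

# Two-band toy population: 1000 harmful men, 500 dependent women,
# the rest abstinent/moderate/heavy/hazardous at zero.
toy_population <- function(n_men = 1000, n_women = 500) {
  bands <- audit_bands()$band
  fr <- rbind(
    data.frame(gender = "men", band = bands,
               fraction = c(0, 0, 0, 0, 1, 0)),
    data.frame(gender = "women", band = bands,
               fraction = c(0, 0, 0, 0, 0, 1))
  )
  ints <- rbind(
    data.frame(gender = "men", band = bands,
               mean_intake = c(0, 10, 40, 80, 120, 200)),
    data.frame(gender = "women", band = bands,
               mean_intake = c(0, 10, 40, 80, 120, 200))
  )
  population_profile(n_men, n_women, fr, band_intakes = ints)
}

# One-intervention catalog; degenerate = all uncertainty collapsed.
toy_catalog <- function(degenerate = FALSE) {
  df <- data.frame(
    disorder = c("harmful", "dependence"),
    intervention = c("cbt", "cbt"),
    cost = c(1000, 2000), cost_low = c(800, 1500), cost_high = c(1300, 2600),
    d = c(0.4, 0.3), d_low = c(0.2, 0.1), d_high = c(0.6, 0.5),
    intake_reduction = 0.2
  )
  if (degenerate) {
    df$cost_low <- df$cost_high <- df$cost
    df$d_low <- df$d_high <- df$d
  }
  intervention_catalog(df)
}

toy_scenario <- function(name = "s", coverage = c(0.1, 0.1)) {
  scenario(name, data.frame(
    disorder = c("harmful", "dependence"),
    intervention = c("cbt", "cbt"),
    coverage = coverage
  ))
}

# Constant-rate mortality table with analytic life expectancy.
flat_mortality <- function(rate = 0.004, ages = 18:69, max_age = 100) {
  do.call(rbind, lapply(c("men", "women"), function(g) {
    k <- max_age - ages
    le <- (1 - rate) * (1 - (1 - rate)^k) / rate
    data.frame(gender = g, age = ages, rate = rate, life_expectancy = le)
  })) |> as_mortality_table()
}
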
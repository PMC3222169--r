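# Resolve scenario entries against the catalog; returns the entries with
# catalog columns joined plus a `key` column ("disorder:intervention").
resolve_entries <- function(scen, catalog) {
  e <- scen$entries
  key <- paste(e$disorder, e$intervention, sep = ":")
  ckey <- paste(catalog$disorder, catalog$intervention, sep = ":")
  idx <- match(key, ckey)
  if (any(is.na(idx))) {
    stop("scenario '", scen$name, "' references entries not in the catalog: ",
         paste(key[is.na(idx)], collapse = ", "))
  }
  cbind(e, catalog[idx, c("cost", "cost_low", "cost_high", "d", "d_low",
                          "d_high", "intake_reduction")],
        key = key, stringsAsFactors = FALSE)
}

# Evaluate one scenario: total cost, YLD, deaths (age-resolved) and YLL.
# `cost_draws` / `effect_draws` are named vectors keyed "disorder:intervention"
# (NULL = use catalog point estimates); `cf` is the conversion factor.
evaluate_scenario <- function(scen, population, catalog, mortality,
                              burden = burden_settings(),
                              cost_draws = NULL, effect_draws = NULL,
                              cf = burden$conversion_factor,
                              second_term = "linear") {
  res <- resolve_entries(scen, catalog)
  strata <- stratify(population)
  age_dist <- age_weights(population)
  by_dis <- tapply(strata$count, strata$disorder_class, sum)

  unit_cost <- if (is.null(cost_draws)) res$cost else unname(cost_draws[res$key])
  d <- if (is.null(effect_draws)) res$d else unname(effect_draws[res$key])
  n_dis <- unname(by_dis[res$disorder])

  cost <- sum(n_dis * res$coverage * unit_cost)
  yld <- sum(yld_averted(n_dis * res$coverage, d, burden,
                         adherence = res$adherence, conversion_factor = cf))

  # Mortality side: per entry and per gender stratum of the targeted class.
  ages <- age_dist$age
  dth <- list()
  for (i in seq_len(nrow(res))) {
    sub <- strata[strata$disorder_class == res$disorder[i], ]
    for (j in seq_len(nrow(sub))) {
      dv <- deaths_by_age(sub$gender[j], sub$count[j], sub$mean_intake[j],
                          res$intake_reduction[i], mortality, ages,
                          age_dist$weight, burden,
                          coverage = res$coverage[i],
                          adherence = res$adherence[i],
                          second_term = second_term)
      dth[[length(dth) + 1]] <- data.frame(gender = sub$gender[j],
                                           age = ages, deaths = dv)
    }
  }
  deaths_df <- if (length(dth)) do.call(rbind, dth) else
    data.frame(gender = character(0), age = integer(0), deaths = numeric(0))
  deaths_total <- sum(deaths_df$deaths)
  yll <- yll_averted(deaths_df, mortality)

  list(cost = cost, yld = yld, yll = yll, daly = daly(yld, yll),
       deaths = deaths_total, deaths_by_age = deaths_df)
}

#' Compare two intervention-mix scenarios (deterministic mode)
#'
#' Runs the full model once with every parameter at its mean value: scenario
#' costs, YLD averted via the disability-weight conversion factor, deaths and
#' YLL averted via the dose-response mortality model, incremental cost and
#' effect, ICER, and benefit-cost ratios at the willingness-to-pay value.
#'
#' @param base,alt [scenario()] objects (base case and alternative).
#' @param population a [population_profile()] object.
#' @param catalog an `intervention_catalog`.
#' @param mortality a `mortality_table`; defaults to the packaged synthetic
#'   Netherlands-like fixture.
#' @param burden a [burden_settings()] object.
#' @param econ an [econ_settings()] object.
#' @param second_term dose-response variant, see [relative_risk()].
#' @return An object of class `alc_ce` with per-scenario results
#'   (`$base`, `$alt`: cost, yld, yll, daly, deaths), incrementals
#'   (`$delta_c`, `$delta_e`), `$icer` (see [icer()]) and benefit-cost
#'   ratios `$bcr_base`, `$bcr_alt`. Use [simulate()] on it to run the
#'   probabilistic sensitivity analysis.
#' @seealso [run_psa()], [nl_population()], [default_catalog()],
#'   [default_scenarios()]
#' @export
#' @examples
#' scen <- default_scenarios()
#' fit <- compare_scenarios(scen$base_case, scen$alternative_1,
#'                          nl_population(), default_catalog())
#' fit
compare_scenarios <- function(base, alt, population, catalog,
                              mortality = nl_mortality(),
                              burden = burden_settings(),
                              econ = econ_settings(),
                              second_term = "linear") {
  b <- evaluate_scenario(base, population, catalog, mortality, burden,
                         second_term = second_term)
  a <- evaluate_scenario(alt, population, catalog, mortality, burden,
                         second_term = second_term)
  delta_c <- a$cost - b$cost
  delta_e <- a$daly - b$daly
  structure(list(
    base = b, alt = a,
    scenario_names = c(base = base$name, alt = alt$name),
    delta_c = delta_c, delta_e = delta_e,
    icer = icer(delta_c, delta_e),
    bcr_base = benefit_cost_ratio(b$daly, b$cost, econ$wtp),
    bcr_alt = benefit_cost_ratio(a$daly, a$cost, econ$wtp),
    inputs = list(base = base, alt = alt, population = population,
                  catalog = catalog, mortality = mortality,
                  burden = burden, econ = econ,
                  second_term = second_term),
    call = match.call()
  ), class = "alc_ce")
}

#' Probabilistic sensitivity analysis settings
#'
#' @param n_iterations number of Monte-Carlo iterations (1 to 10,000;
#'   500 is sufficient in practice).
#' @param seed integer RNG seed; recorded in every output.
#' @param sample_conversion_factor sample the disability-weight conversion
#'   factor from normal(0.18, (0.20 - 0.16)/3.92)? Default `TRUE`.
#' @return An object of class `psa_settings`.
#' @export
psa_settings <- function(n_iterations = 500, seed = 1,
                         sample_conversion_factor = TRUE) {
  if (n_iterations < 1 || n_iterations > 10000) {
    stop("n_iterations must lie in [1, 10000]")
  }
  structure(list(n_iterations = as.integer(n_iterations),
                 seed = as.integer(seed),
                 sample_conversion_factor = isTRUE(sample_conversion_factor)),
            class = "psa_settings")
}

#' Seeded Monte-Carlo probabilistic sensitivity analysis
#'
#' Per iteration, one cost draw (gamma) and one effect draw (normal) is taken
#' for every (disorder, intervention) catalog row, plus optionally one
#' conversion-factor draw; the draws are shared between the base and
#' alternative scenario within the iteration (common random numbers), so an
#' intervention offered identically in both arms cancels exactly from every
#' incremental draw. Vectors of per-iteration costs, effects, incrementals
#' and ICERs are stored together with mean/median summaries.
#'
#' @inheritParams compare_scenarios
#' @param psa a [psa_settings()] object.
#' @return An object of class `alc_ce_psa`: `$iterations` (data frame with
#'   columns `c0, c1, e0, e1, delta_c, delta_e, icer`), `$summary`
#'   (mean/median per column), `$ceac` (via [ceac()] on the default grid),
#'   `$settings`, `$deterministic` (the matching [compare_scenarios()] fit).
#' @export
run_psa <- function(base, alt, population, catalog,
                    mortality = nl_mortality(),
                    burden = burden_settings(), econ = econ_settings(),
                    psa = psa_settings(), second_term = "linear") {
  stopifnot(inherits(psa, "psa_settings"))
  det <- compare_scenarios(base, alt, population, catalog, mortality,
                           burden, econ, second_term)
  keys <- paste(catalog$disorder, catalog$intervention, sep = ":")
  n <- psa$n_iterations

  set.seed(psa$seed)
  cost_mat <- sapply(seq_len(nrow(catalog)), function(k) {
    sample_distribution(cost_distribution(catalog$cost[k],
                                          catalog$cost_low[k],
                                          catalog$cost_high[k]), n)
  })
  eff_mat <- sapply(seq_len(nrow(catalog)), function(k) {
    sample_distribution(effect_distribution(catalog$d[k], catalog$d_low[k],
                                            catalog$d_high[k]), n)
  })
  cost_mat <- matrix(cost_mat, nrow = n); colnames(cost_mat) <- keys
  eff_mat <- matrix(eff_mat, nrow = n); colnames(eff_mat) <- keys
  cf_draws <- if (psa$sample_conversion_factor) {
    stats::rnorm(n, burden$conversion_factor,
                 (burden$cf_ci[2] - burden$cf_ci[1]) / 3.92)
  } else rep(burden$conversion_factor, n)

  it <- data.frame(c0 = numeric(n), c1 = numeric(n), e0 = numeric(n),
                   e1 = numeric(n))
  for (i in seq_len(n)) {
    cd <- cost_mat[i, ]; ed <- eff_mat[i, ]
    b <- evaluate_scenario(base, population, catalog, mortality, burden,
                           cost_draws = cd, effect_draws = ed,
                           cf = cf_draws[i], second_term = second_term)
    a <- evaluate_scenario(alt, population, catalog, mortality, burden,
                           cost_draws = cd, effect_draws = ed,
                           cf = cf_draws[i], second_term = second_term)
    it$c0[i] <- b$cost; it$c1[i] <- a$cost
    it$e0[i] <- b$daly; it$e1[i] <- a$daly
  }
  it$delta_c <- it$c1 - it$c0
  it$delta_e <- it$e1 - it$e0
  it$icer <- ifelse(it$delta_e != 0, it$delta_c / it$delta_e, NA_real_)

  summ <- data.frame(
    statistic = c("mean", "median"),
    rbind(vapply(it, mean, numeric(1), na.rm = TRUE),
          vapply(it, stats::median, numeric(1), na.rm = TRUE))
  )
  structure(list(
    iterations = it, summary = summ,
    ceac = ceac(it$delta_c, it$delta_e, econ),
    settings = psa, deterministic = det,
    scenario_names = det$scenario_names, econ = econ
  ), class = "alc_ce_psa")
}

#' Simulate method: probabilistic sensitivity analysis of a comparison
#'
#' Re-runs the comparison held in an `alc_ce` object in stochastic mode.
#'
#' @param object an `alc_ce` object from [compare_scenarios()].
#' @param nsim number of Monte-Carlo iterations.
#' @param seed integer RNG seed.
#' @param ... passed to [psa_settings()].
#' @return An `alc_ce_psa` object, see [run_psa()].
#' @export
simulate.alc_ce <- function(object, nsim = 500, seed = 1, ...) {
  inp <- object$inputs
  run_psa(inp$base, inp$alt, inp$population, inp$catalog, inp$mortality,
          inp$burden, inp$econ,
          psa = psa_settings(n_iterations = nsim, seed = seed, ...),
          second_term = inp$second_term)
}
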
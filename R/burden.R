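#' Disease-burden settings
#'
#' @param conversion_factor disability-weight shift per unit of effect size d
#'   (expert-panel estimate 0.18, 95% CI 0.16--0.20).
#' @param cf_ci 95% confidence interval of the conversion factor, used when
#'   the probabilistic mode samples it.
#' @param attenuation downward adjustment of all health gains (both YLD and
#'   YLL), reflecting residual risk in former heavy drinkers; default 0.20.
#' @return An object of class `burden_settings`.
#' @export
burden_settings <- function(conversion_factor = 0.18, cf_ci = c(0.16, 0.20),
                            attenuation = 0.20) {
  stopifnot(conversion_factor > 0, length(cf_ci) == 2,
            cf_ci[1] <= conversion_factor, conversion_factor <= cf_ci[2])
  if (attenuation < 0 || attenuation >= 1) {
    stop("attenuation must lie in [0, 1)")
  }
  structure(list(conversion_factor = conversion_factor, cf_ci = cf_ci,
                 attenuation = attenuation, horizon_months = 12),
            class = "burden_settings")
}

#' Years lived with disability averted by a treated group
#'
#' The treatment effect d shifts the disability weight down by
#' `d x conversion_factor`; multiplied by the number of adherent treated
#' persons and attenuated, this gives the YLD averted over the 12-month
#' horizon: `n_treated x adherence x d x conversion_factor x
#' (1 - attenuation)`.
#'
#' @param n_treated persons offered the intervention (count x coverage).
#' @param d standardised mean difference (may be negative in probabilistic
#'   draws; negative values propagate to negative YLD averted).
#' @param settings a [burden_settings()] object.
#' @param adherence compliance moderator in `[0, 1]`.
#' @param conversion_factor override of the settings value (used by the
#'   probabilistic engine when the conversion factor is sampled).
#' @return Years lived with disability averted.
#' @export
#' @examples
#' yld_averted(1000, 0.5, burden_settings(), adherence = 1)  # 72
yld_averted <- function(n_treated, d, settings = burden_settings(),
                        adherence = 0.5,
                        conversion_factor = settings$conversion_factor) {
  stopifnot(all(n_treated >= 0))
  n_treated * adherence * d * conversion_factor * (1 - settings$attenuation)
}

# Age-resolved deaths averted for one (gender, band) stratum under one
# intervention entry: treated persons, spread over the age distribution,
# times the age-specific mortality rate and the drop in relative risk from
# reducing intake by `reduction`, attenuated.
deaths_by_age <- function(gender, count, mean_intake, reduction, mortality,
                          ages, age_weight, settings = burden_settings(),
                          coverage = 1, adherence = 0.5,
                          second_term = "linear") {
  if (reduction < 0 || reduction >= 1) stop("reduction must lie in [0, 1)")
  co <- mortality_coefficients(gender)
  d_rr <- relative_risk(mean_intake, co, second_term) -
    relative_risk(mean_intake * (1 - reduction), co, second_term)
  rate <- lookup_mortality_rate(mortality, gender, ages)
  count * coverage * adherence * age_weight * rate * d_rr *
    (1 - settings$attenuation)
}

#' Deaths averted in the present year for a population stratum
#'
#' Avoided deaths from a fractional reduction in alcohol intake:
#' `treated x adherence x mbar x [RR(x) - RR(x(1 - reduction))] x
#' (1 - attenuation)`, where `mbar` is the age-distribution-weighted annual
#' mortality rate for the stratum's gender. Can be negative when reduced
#' intake raises the relative risk (the J-curve); negative values are kept.
#'
#' @param gender `"men"` or `"women"`.
#' @param count stratum size (persons).
#' @param mean_intake grams pure ethanol/day before intervention.
#' @param reduction fractional intake reduction in `[0, 1)`.
#' @param mortality a `mortality_table`.
#' @param age_dist data frame `age`, `weight` (see [age_weights()]).
#' @param settings a [burden_settings()] object.
#' @param coverage,adherence fractions in `[0, 1]`.
#' @param second_term dose-response variant, see [relative_risk()].
#' @return Deaths averted (persons/year).
#' @export
deaths_averted <- function(gender, count, mean_intake, reduction, mortality,
                           age_dist, settings = burden_settings(),
                           coverage = 1, adherence = 0.5,
                           second_term = "linear") {
  sum(deaths_by_age(gender, count, mean_intake, reduction, mortality,
                    age_dist$age, age_dist$weight, settings, coverage,
                    adherence, second_term))
}

#' Years of life lost averted from avoided deaths
#'
#' Each avoided death contributes the remaining life expectancy at the age
#' of death; ages are weighted by the population age distribution upstream
#' (the `deaths` input is already age-resolved).
#'
#' @param deaths data frame with columns `gender`, `age`, `deaths`.
#' @param mortality a `mortality_table` providing `life_expectancy`.
#' @return Years of life lost averted.
#' @export
#' @examples
#' mt <- generate_synthetic_mortality()
#' yll_averted(data.frame(gender = "men", age = 45, deaths = 1), mt)
yll_averted <- function(deaths, mortality) {
  if (nrow(deaths) == 0) return(0)
  le <- lookup_life_expectancy(mortality, deaths$gender, deaths$age)
  sum(deaths$deaths * le)
}

#' Disability-adjusted life years
#'
#' @param yld years lived with disability.
#' @param yll years of life lost.
#' @return `yld + yll`, exactly.
#' @export
daly <- function(yld, yll) yld + yll
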
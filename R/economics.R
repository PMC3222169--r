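#' Health-economic settings
#'
#' @param wtp willingness to pay per averted DALY, euros (default 50,000, the
#'   conservative Dutch lower bound for fatal disorders).
#' @param wtp_grid ascending grid of willingness-to-pay ceilings for the
#'   cost-effectiveness acceptability curve.
#' @return An object of class `econ_settings`.
#' @export
econ_settings <- function(wtp = 50000, wtp_grid = seq(0, 50000, by = 1000)) {
  stopifnot(wtp >= 0, all(diff(wtp_grid) > 0), all(wtp_grid >= 0))
  structure(list(wtp = wtp, wtp_grid = wtp_grid), class = "econ_settings")
}

#' Total annual cost of a scenario
#'
#' Sums, over all scenario entries, the disorder-class population count times
#' the coverage rate times the per-participant full economic cost. Costs
#' accrue to all covered persons regardless of adherence.
#'
#' @param scen a [scenario()] object.
#' @param population a [population_profile()] object.
#' @param catalog an `intervention_catalog`.
#' @param cost_draws optional named numeric vector of per-participant costs,
#'   named `disorder:intervention`, overriding the catalog point estimates
#'   (used by the probabilistic engine).
#' @return Total cost in euros.
#' @export
scenario_cost <- function(scen, population, catalog, cost_draws = NULL) {
  stopifnot(inherits(scen, "ce_scenario"))
  strata <- stratify(population)
  by_dis <- tapply(strata$count, strata$disorder_class, sum)
  e <- scen$entries
  key <- paste(e$disorder, e$intervention, sep = ":")
  ckey <- paste(catalog$disorder, catalog$intervention, sep = ":")
  idx <- match(key, ckey)
  if (any(is.na(idx))) {
    stop("scenario '", scen$name, "' references entries not in the catalog: ",
         paste(key[is.na(idx)], collapse = ", "))
  }
  unit <- if (is.null(cost_draws)) catalog$cost[idx] else {
    stopifnot(all(key %in% names(cost_draws)))
    unname(cost_draws[key])
  }
  n_dis <- by_dis[e$disorder]
  if (any(is.na(n_dis))) {
    stop("scenario targets disorder classes absent from the population: ",
         paste(unique(e$disorder[is.na(n_dis)]), collapse = ", "))
  }
  sum(n_dis * e$coverage * unit)
}

#' Incremental cost-effectiveness ratio with CE-plane quadrant handling
#'
#' @param delta_c incremental cost (euros).
#' @param delta_e incremental effect (DALYs averted).
#' @return A list with `estimate` (euros/DALY; `NA` when flagged undefined or
#'   dominant/dominated) and `status`: `"ratio"` (north-east quadrant),
#'   `"dominant"` (cheaper and at least as effective), `"dominated"` (costlier
#'   and at most as effective), `"sw_ratio"` (south-west quadrant: the raw
#'   ratio is reported with an explicit tag), or `"undefined"` (both deltas
#'   zero).
#' @export
#' @examples
#' icer(86e6, 5296)     # ratio ~16,238
#' icer(-68e6, 16)      # dominant
icer <- function(delta_c, delta_e) {
  stopifnot(length(delta_c) == 1, length(delta_e) == 1)
  if (delta_c == 0 && delta_e == 0) {
    return(list(estimate = NA_real_, status = "undefined"))
  }
  if (delta_c > 0 && delta_e > 0) {
    return(list(estimate = delta_c / delta_e, status = "ratio"))
  }
  if (delta_c <= 0 && delta_e >= 0) {
    return(list(estimate = NA_real_, status = "dominant"))
  }
  if (delta_c >= 0 && delta_e <= 0) {
    return(list(estimate = NA_real_, status = "dominated"))
  }
  # delta_c < 0 and delta_e < 0: south-west quadrant, raw ratio with tag
  list(estimate = delta_c / delta_e, status = "sw_ratio")
}

#' Net monetary benefit
#'
#' @param delta_c,delta_e incremental cost (euros) and effect (DALYs).
#' @param wtp willingness to pay, euros/DALY.
#' @return `wtp * delta_e - delta_c` (vectorised).
#' @export
net_monetary_benefit <- function(delta_c, delta_e, wtp) {
  wtp * delta_e - delta_c
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay ceiling, the fraction of probabilistic draws
#' with strictly positive net monetary benefit (ties count as not
#' cost-effective, so the curve is anchored at 0 for lambda = 0 whenever no
#' draw is cost-saving).
#'
#' @param delta_c,delta_e equal-length vectors of incremental cost and effect
#'   draws.
#' @param wtp_grid ascending vector of willingness-to-pay ceilings, or an
#'   [econ_settings()] object.
#' @return Data frame with columns `wtp`, `probability`.
#' @export
#' @examples
#' ceac(c(10, 30), c(1, 1), c(0, 20, 40))
ceac <- function(delta_c, delta_e, wtp_grid = econ_settings()) {
  if (inherits(wtp_grid, "econ_settings")) wtp_grid <- wtp_grid$wtp_grid
  if (length(delta_c) != length(delta_e)) {
    stop("delta_c and delta_e must have the same length")
  }
  if (length(delta_c) < 1) stop("need at least one draw")
  prob <- vapply(wtp_grid, function(l) {
    mean(net_monetary_benefit(delta_c, delta_e, l) > 0)
  }, numeric(1))
  data.frame(wtp = wtp_grid, probability = prob)
}

#' Benefit-cost ratio
#'
#' Health gains monetised at the willingness-to-pay value, divided by the
#' health-care cost: `(effect x wtp) / cost`.
#'
#' @param effect DALYs averted.
#' @param cost euros (must be > 0).
#' @param wtp euros per averted DALY.
#' @return Unitless ratio.
#' @export
#' @examples
#' benefit_cost_ratio(10319, 319e6, 50000)  # ~1.62
benefit_cost_ratio <- function(effect, cost, wtp = 50000) {
  if (any(cost <= 0)) stop("cost must be positive")
  (effect * wtp) / cost
}
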
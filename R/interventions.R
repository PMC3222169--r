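#' Construct / validate an intervention catalog
#'
#' The catalog lists, per (disorder class, intervention), the per-participant
#' full economic cost in euros (point estimate plus an uncertainty range) and
#' the treatment effect as a standardised mean difference d with its 95%
#' confidence interval, together with the assumed fractional reduction in
#' alcohol intake. Costs are keyed on (intervention, disorder) because the
#' same intervention can cost more in a more severe disorder class.
#'
#' @param df data frame with columns `disorder`, `intervention`, `cost`,
#'   `cost_low`, `cost_high`, `d`, `d_low`, `d_high` and optionally
#'   `intake_reduction` (defaults to 0.20).
#' @param currency_year reference year of the euro amounts.
#' @return The validated data frame, classed `intervention_catalog`.
#' @export
intervention_catalog <- function(df, currency_year = 2009) {
  need <- c("disorder", "intervention", "cost", "cost_low", "cost_high",
            "d", "d_low", "d_high")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("catalog validation failed; missing fields: ",
         paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0) stop("catalog validation failed: catalog is empty")
  if (is.null(df$intake_reduction)) df$intake_reduction <- 0.20
  bad <- character(0)
  if (any(!df$disorder %in% disorder_classes()))
    bad <- c(bad, "disorder (unknown class)")
  if (any(df$cost_low > df$cost | df$cost > df$cost_high))
    bad <- c(bad, "cost (need cost_low <= cost <= cost_high)")
  if (any(df$cost <= 0 | df$cost_low <= 0))
    bad <- c(bad, "cost (must be > 0)")
  if (any(df$d_low > df$d | df$d > df$d_high))
    bad <- c(bad, "d (need d_low <= d <= d_high)")
  if (any(df$intake_reduction < 0 | df$intake_reduction >= 1))
    bad <- c(bad, "intake_reduction (need 0 <= r < 1)")
  if (anyDuplicated(paste(df$disorder, df$intervention)))
    bad <- c(bad, "disorder/intervention (duplicated pair)")
  if (length(bad)) {
    stop("catalog validation failed; offending fields: ",
         paste(bad, collapse = "; "))
  }
  attr(df, "currency_year") <- currency_year
  class(df) <- c("intervention_catalog", "data.frame")
  df
}

#' Read / write an intervention catalog as CSV
#'
#' @param path file path; `#` lines are comments.
#' @return For `load_catalog()`, a validated `intervention_catalog`.
#' @export
load_catalog <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  intervention_catalog(df)
}

#' @rdname load_catalog
#' @param catalog an `intervention_catalog`.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.csv(as.data.frame(catalog), path, row.names = FALSE)
  invisible(path)
}

#' Gamma sampling distribution for a cost parameter
#'
#' Costs are sampled from a gamma distribution whose mean equals the point
#' estimate and whose standard deviation is `(high - low) / 3.92`, treating
#' the uncertainty range as a central 95% interval (moment matching). A
#' degenerate range collapses to a point mass.
#'
#' @param point,low,high euros per participant.
#' @return A list with `type` (`"gamma"` or `"point"`), `mean`, `sd` and for
#'   the gamma case `shape` and `scale` (mean = shape x scale).
#' @export
#' @examples
#' cost_distribution(2024, 1702, 2550)
cost_distribution <- function(point, low, high) {
  stopifnot(low <= point, point <= high, point > 0)
  s <- (high - low) / 3.92
  if (s == 0) return(list(type = "point", mean = point, sd = 0))
  list(type = "gamma", mean = point, sd = s,
       shape = point^2 / s^2, scale = s^2 / point)
}

#' Normal sampling distribution for an effect size
#'
#' Effect sizes d are sampled from a normal distribution with mean d and
#' standard deviation `(ci_high - ci_low) / 3.92`. No truncation: negative
#' draws are allowed, reflecting confidence intervals that cross zero.
#'
#' @param d,ci_low,ci_high standardised mean difference and its 95% CI.
#' @return A list with `type`, `mean`, `sd`.
#' @export
#' @examples
#' effect_distribution(0.58, 0.29, 0.88)
effect_distribution <- function(d, ci_low, ci_high) {
  stopifnot(ci_low <= d, d <= ci_high)
  s <- (ci_high - ci_low) / 3.92
  list(type = if (s == 0) "point" else "normal", mean = d, sd = s)
}

# One random draw vector from a cost/effect distribution list.
sample_distribution <- function(dist, n) {
  switch(dist$type,
    point = rep(dist$mean, n),
    gamma = stats::rgamma(n, shape = dist$shape, scale = dist$scale),
    normal = stats::rnorm(n, mean = dist$mean, sd = dist$sd),
    stop("unknown distribution type: ", dist$type)
  )
}

#' Per-participant cost of a population-reach intervention
#'
#' Spreads fixed annual delivery costs (website upgrading, hosting, research,
#' moderation) over the expected number of participants, determined by the
#' fraction of the target population reached with information and the uptake
#' rate among those reached, and adds any per-participant variable cost.
#'
#' @param fixed_annual_costs euros/year.
#' @param target_n target population size.
#' @param reach fraction of the target population reached.
#' @param uptake fraction of those reached who participate.
#' @param variable_cost euros per participant.
#' @return Euros per participant.
#' @export
#' @examples
#' per_participant_cost(125000, 1255000, 0.40, 0.08) # ~3.11
per_participant_cost <- function(fixed_annual_costs, target_n, reach, uptake,
                                 variable_cost = 0) {
  participants <- target_n * reach * uptake
  if (participants < 1) {
    stop("reach x uptake x target_n gives fewer than one participant; ",
         "cannot allocate fixed costs")
  }
  variable_cost + fixed_annual_costs / participants
}

#' Define an intervention-mix scenario
#'
#' A scenario is a set of (disorder class, intervention) entries with the
#' coverage rate (fraction of the disorder-class population offered the
#' intervention) and adherence rate (compliance moderator of the treatment
#' response). The default adherence is 0.50 for every entry.
#'
#' @param name scenario name.
#' @param entries data frame with columns `disorder`, `intervention`,
#'   `coverage`, and optionally `adherence`.
#' @param default_adherence adherence used where `entries$adherence` is
#'   absent or `NA`.
#' @return An object of class `ce_scenario`.
#' @export
scenario <- function(name, entries, default_adherence = 0.5) {
  need <- c("disorder", "intervention", "coverage")
  if (!all(need %in% names(entries))) {
    stop("scenario entries need columns: ", paste(need, collapse = ", "))
  }
  if (is.null(entries$adherence)) entries$adherence <- NA_real_
  entries$adherence[is.na(entries$adherence)] <- default_adherence
  if (any(entries$coverage < 0 | entries$coverage > 1)) {
    stop("coverage must lie in [0, 1] (stored as fractions, not percent)")
  }
  if (any(entries$adherence < 0 | entries$adherence > 1)) {
    stop("adherence must lie in [0, 1]")
  }
  if (anyDuplicated(paste(entries$disorder, entries$intervention))) {
    stop("duplicate (disorder, intervention) pair in scenario '", name, "'")
  }
  structure(list(name = name, entries = entries), class = "ce_scenario")
}

#' @export
print.ce_scenario <- function(x, ...) {
  cat("Scenario:", x$name, "\n")
  print(x$entries, row.names = FALSE)
  invisible(x)
}

#' Read scenarios from a CSV file
#'
#' CSV columns: `scenario, disorder, intervention, coverage` and optionally
#' `adherence`. Coverage and adherence are fractions in `[0, 1]`; values
#' above 1 are rejected to avoid percent/fraction confusion.
#'
#' @param path file path.
#' @param default_adherence adherence applied where the file leaves it blank.
#' @return Named list of [scenario()] objects.
#' @export
load_scenarios <- function(path, default_adherence = 0.5) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("scenario", "disorder", "intervention", "coverage") %in%
           names(df))) {
    stop("scenario file needs columns: scenario, disorder, intervention, ",
         "coverage")
  }
  if (any(df$coverage > 1)) {
    stop("coverage > 1 found; scenario files store fractions, not percent")
  }
  out <- lapply(split(df, df$scenario), function(sub) {
    scenario(sub$scenario[1],
             sub[, setdiff(names(sub), "scenario"), drop = FALSE],
             default_adherence = default_adherence)
  })
  out[unique(df$scenario)]
}
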
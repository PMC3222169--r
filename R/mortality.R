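#' Validate a gender x age mortality / life-expectancy table
#'
#' @param df data frame with columns `gender`, `age`, `rate` (annual
#'   all-cause mortality probability) and `life_expectancy` (remaining years).
#' @param age_range ages that must be covered per gender.
#' @return The validated data frame, classed `mortality_table`.
#' @export
as_mortality_table <- function(df, age_range = c(18L, 69L)) {
  need <- c("gender", "age", "rate", "life_expectancy")
  if (!all(need %in% names(df))) {
    stop("mortality table needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$rate < 0 | df$rate > 1)) {
    stop("mortality rates must lie in [0, 1]")
  }
  ages <- seq(age_range[1], age_range[2])
  for (g in unique(df$gender)) {
    sub <- df[df$gender == g, ]
    sub <- sub[order(sub$age), ]
    if (!all(ages %in% sub$age)) {
      stop("mortality table for ", g, " must cover ages ",
           age_range[1], "-", age_range[2])
    }
    if (any(diff(sub$life_expectancy) >= 0)) {
      stop("remaining life expectancy must be strictly decreasing in age (",
           g, ")")
    }
  }
  df <- df[order(df$gender, df$age), ]
  class(df) <- c("mortality_table", "data.frame")
  df
}

#' Generate a synthetic Gompertz mortality table
#'
#' Builds a gender x age table of annual mortality rates and remaining life
#' expectancies from a Gompertz hazard, `rate(age) = exp(level + slope x age)`.
#' Remaining life expectancy is computed by the standard period-life-table
#' recursion `e(a) = (1 - q(a)) * (1 + e(a + 1))` (expected whole years of
#' life remaining), with the hazard extended beyond the output age range up
#' to `max_age` (rates capped at 1; everyone dies during year `max_age`).
#'
#' This is a stand-in for national life-table data: parameters are chosen to
#' mimic the gross shape of a western-European period life table, and the
#' packaged default fixture is generated by this function (see
#' `nl_mortality()`), clearly labelled synthetic.
#'
#' @param level,slope named numeric vectors with elements `men` and `women`;
#'   Gompertz log-level and log-slope per year of age.
#' @param ages integer ages to include in the output table.
#' @param max_age age at which the extended life table closes.
#' @return A [as_mortality_table()] object.
#' @export
#' @examples
#' mt <- generate_synthetic_mortality()
#' head(mt)
generate_synthetic_mortality <- function(level = c(men = -9.8, women = -10.4),
                                         slope = c(men = 0.085,
                                                   women = 0.088),
                                         ages = 18:69, max_age = 100) {
  stopifnot(all(c("men", "women") %in% names(level)),
            all(c("men", "women") %in% names(slope)),
            max(ages) < max_age)
  out <- lapply(c("men", "women"), function(g) {
    full_ages <- min(ages):max_age
    q <- exp(level[[g]] + slope[[g]] * full_ages)
    if (any(q[full_ages %in% ages] > 1)) {
      stop("Gompertz parameters for ", g,
           " yield mortality rates > 1 inside the output age range")
    }
    q <- pmin(q, 1)
    q[length(q)] <- 1
    e <- numeric(length(q))
    for (i in (length(q) - 1):1) e[i] <- (1 - q[i]) * (1 + e[i + 1])
    keep <- full_ages %in% ages
    data.frame(gender = g, age = full_ages[keep], rate = q[keep],
               life_expectancy = e[keep], stringsAsFactors = FALSE)
  })
  as_mortality_table(do.call(rbind, out), range(ages))
}

#' Read / write a mortality table as CSV
#'
#' CSV columns: `gender, age, rate, life_expectancy`. Lines starting with `#`
#' are treated as comments (provenance headers).
#'
#' @param path file path.
#' @return For `read_mortality()`, a validated `mortality_table`.
#' @export
read_mortality <- function(path) {
  as_mortality_table(utils::read.csv(path, comment.char = "#",
                                     stringsAsFactors = FALSE))
}

#' @rdname read_mortality
#' @param table a `mortality_table`.
#' @export
write_mortality <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

# Look up life expectancy for (gender, age) pairs; error if any are missing.
lookup_life_expectancy <- function(mortality, gender, age) {
  key <- paste(gender, age)
  tkey <- paste(mortality$gender, mortality$age)
  le <- mortality$life_expectancy[match(key, tkey)]
  if (any(is.na(le))) {
    stop("mortality table lacks rows for: ",
         paste(unique(key[is.na(le)]), collapse = "; "))
  }
  le
}

# Look up annual mortality rate for (gender, age) pairs.
lookup_mortality_rate <- function(mortality, gender, age) {
  key <- paste(gender, age)
  tkey <- paste(mortality$gender, mortality$age)
  r <- mortality$rate[match(key, tkey)]
  if (any(is.na(r))) {
    stop("mortality table lacks rows for: ",
         paste(unique(key[is.na(r)]), collapse = "; "))
  }
  r
}
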
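#' AUDIT band definitions
#'
#' The six AUDIT score bands used to stratify the target population, their
#' score ranges (partitioning 0--40 without overlap) and the disorder class
#' each maps to. Abstinent and moderate drinkers belong to disorder class
#' `"none"` and are not targeted by any intervention.
#'
#' @return A data frame with columns `band`, `audit_min`, `audit_max`,
#'   `disorder_class`.
#' @export
audit_bands <- function() {
  data.frame(
    band = c("abstinent", "moderate", "heavy", "hazardous", "harmful",
             "dependence"),
    audit_min = c(0L, 2L, 8L, 16L, 20L, 30L),
    audit_max = c(1L, 7L, 15L, 19L, 29L, 40L),
    disorder_class = c("none", "none", "heavy", "hazardous", "harmful",
                       "dependence"),
    stringsAsFactors = FALSE
  )
}

disorder_classes <- function() c("heavy", "hazardous", "harmful", "dependence")

#' Construct a target population profile
#'
#' A population of problem drinkers stratified by gender and AUDIT band, with
#' a normal age structure truncated to the working-age range. Band mean
#' intakes (grams pure ethanol/day) drive the mortality side of the model;
#' they are typically calibrated from published band-level relative risks
#' via [calibrate_band_intakes()].
#'
#' @param n_men,n_women person counts (>= 0).
#' @param band_fractions data frame with columns `gender` (`"men"`/`"women"`),
#'   `band`, `fraction`; per-gender fractions must sum to 1 (tolerance 1e-9)
#'   and bands must match [audit_bands()].
#' @param band_intakes data frame with columns `gender`, `band`,
#'   `mean_intake` (g/day, >= 0). Defaults to the packaged calibrated values.
#' @param mean_age,age_sd age distribution parameters (years); ages are
#'   discretised to integers on `age_range` from a truncated normal.
#' @param age_range integer vector `c(min, max)` of modelled ages.
#' @return An object of class `ce_population`.
#' @export
#' @examples
#' pop <- nl_population()
#' stratify(pop)
population_profile <- function(n_men, n_women, band_fractions,
                               band_intakes = default_band_intakes(),
                               mean_age = 44.7, age_sd = 10.7,
                               age_range = c(18L, 69L)) {
  stopifnot(is.numeric(n_men), is.numeric(n_women),
            length(n_men) == 1, length(n_women) == 1)
  if (n_men < 0 || n_women < 0) stop("population counts must be non-negative")
  need <- c("gender", "band", "fraction")
  if (!all(need %in% names(band_fractions))) {
    stop("band_fractions needs columns: ", paste(need, collapse = ", "))
  }
  bands <- audit_bands()$band
  for (g in c("men", "women")) {
    fr <- band_fractions[band_fractions$gender == g, ]
    if (!setequal(fr$band, bands)) {
      stop("band_fractions for ", g, " must cover exactly the bands: ",
           paste(bands, collapse = ", "))
    }
    if (any(fr$fraction < 0 | fr$fraction > 1)) {
      stop("band fractions must lie in [0, 1]")
    }
    if (abs(sum(fr$fraction) - 1) > 1e-9) {
      stop(sprintf("band fractions for %s sum to %.12f, not 1", g,
                   sum(fr$fraction)))
    }
  }
  if (!all(c("gender", "band", "mean_intake") %in% names(band_intakes))) {
    stop("band_intakes needs columns: gender, band, mean_intake")
  }
  if (any(band_intakes$mean_intake < 0)) stop("mean_intake must be >= 0")
  structure(
    list(n_men = n_men, n_women = n_women,
         band_fractions = band_fractions[order(band_fractions$gender,
                                               match(band_fractions$band,
                                                     bands)), ,
                                         drop = FALSE],
         band_intakes = band_intakes,
         mean_age = mean_age, age_sd = age_sd,
         age_range = as.integer(age_range)),
    class = "ce_population"
  )
}

#' @export
print.ce_population <- function(x, ...) {
  cat("Target population profile\n")
  cat(sprintf("  men: %s   women: %s   (total %s)\n",
              format(x$n_men, big.mark = ","),
              format(x$n_women, big.mark = ","),
              format(x$n_men + x$n_women, big.mark = ",")))
  cat(sprintf("  age ~ N(%.1f, %.1f) truncated to [%d, %d]\n",
              x$mean_age, x$age_sd, x$age_range[1], x$age_range[2]))
  wide <- stats::reshape(x$band_fractions, idvar = "band",
                         timevar = "gender", direction = "wide")
  print(wide, row.names = FALSE)
  invisible(x)
}

#' Stratify a population into gender x band counts
#'
#' @param profile a [population_profile()] object.
#' @return Data frame with columns `gender`, `band`, `disorder_class`,
#'   `count`, `mean_intake`. Counts are fractional (count =
#'   n_gender x fraction); their sum equals `n_men + n_women` exactly.
#' @export
stratify <- function(profile) {
  stopifnot(inherits(profile, "ce_population"))
  fr <- profile$band_fractions
  n <- ifelse(fr$gender == "men", profile$n_men, profile$n_women)
  out <- data.frame(gender = fr$gender, band = fr$band,
                    count = n * fr$fraction, stringsAsFactors = FALSE)
  ab <- audit_bands()
  out$disorder_class <- ab$disorder_class[match(out$band, ab$band)]
  key <- paste(out$gender, out$band)
  ikey <- paste(profile$band_intakes$gender, profile$band_intakes$band)
  out$mean_intake <- profile$band_intakes$mean_intake[match(key, ikey)]
  if (any(is.na(out$mean_intake))) {
    stop("band_intakes is missing entries for: ",
         paste(key[is.na(out$mean_intake)], collapse = "; "))
  }
  out[, c("gender", "band", "disorder_class", "count", "mean_intake")]
}

#' Discretised age distribution of the population
#'
#' Weights for integer ages, from the truncated normal age structure of the
#' profile: `w(a)` proportional to the normal mass on `[a - 0.5, a + 0.5]`,
#' renormalised over the modelled age range.
#'
#' @param profile a [population_profile()] object.
#' @return Data frame with columns `age`, `weight` (weights sum to 1).
#' @export
age_weights <- function(profile) {
  stopifnot(inherits(profile, "ce_population"))
  a <- seq(profile$age_range[1], profile$age_range[2])
  w <- stats::pnorm(a + 0.5, profile$mean_age, profile$age_sd) -
       stats::pnorm(a - 0.5, profile$mean_age, profile$age_sd)
  data.frame(age = a, weight = w / sum(w))
}
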
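#' Gender-specific coefficients of the alcohol dose-response mortality model
#'
#' Returns the regression coefficients of the all-cause mortality
#' dose-response model \eqn{\ln RR = b_1 \ln(x + 1) + b_2 x}, where
#' \eqn{x} is pure ethanol intake in grams/day. The coefficients are
#' meta-analytic estimates for men (\eqn{b_1 = -0.1030}, \eqn{b_2 = 0.0035})
#' and women (\eqn{b_1 = -0.0645}, \eqn{b_2 = 0.0029}).
#'
#' @param gender `"men"` or `"women"`.
#' @return A list with elements `b1`, `b2` and `gender`.
#' @export
#' @examples
#' mortality_coefficients("men")
mortality_coefficients <- function(gender = c("men", "women")) {
  gender <- match.arg(gender)
  co <- switch(gender,
    men   = list(b1 = -0.1030, b2 = 0.0035),
    women = list(b1 = -0.0645, b2 = 0.0029)
  )
  co$gender <- gender
  class(co) <- "mortality_coefficients"
  co
}

#' Relative risk of all-cause mortality at a given alcohol intake
#'
#' Evaluates the dose-response curve
#' \eqn{RR(x) = \exp(b_1 \ln(x + 1) + b_2 x)} with the residual term fixed
#' at zero, so that \eqn{RR(0) = 1} exactly. The curve is J-shaped: it dips
#' below 1 at moderate intakes and rises above 1 for heavy intakes.
#'
#' The second term is linear in intake by default. A literal
#' \eqn{b_2 \ln(x)} variant is available via `second_term = "log"` for
#' auditability; it is undefined at \eqn{x = 0} (returns `RR = 0` there as
#' the limit of \eqn{\exp(-\infty)}) and is not used by the model.
#'
#' @param intake pure ethanol intake, grams/day (vectorised, must be >= 0).
#' @param coeffs a [mortality_coefficients()] object (or a gender string).
#' @param second_term `"linear"` (default) or `"log"`.
#' @return Relative risk, same length as `intake`.
#' @export
#' @examples
#' relative_risk(0, "men")    # exactly 1
#' relative_risk(100, "men")  # ~0.882
relative_risk <- function(intake, coeffs = mortality_coefficients("men"),
                          second_term = c("linear", "log")) {
  second_term <- match.arg(second_term)
  if (is.character(coeffs)) coeffs <- mortality_coefficients(coeffs)
  if (any(!is.finite(intake)) || any(intake < 0)) {
    stop("intake must be finite and non-negative (grams pure ethanol/day)")
  }
  term2 <- if (second_term == "linear") coeffs$b2 * intake else
    coeffs$b2 * log(intake)
  exp(coeffs$b1 * log(intake + 1) + term2)
}

# Intake at which the J-shaped RR curve attains its minimum (linear form).
rr_turning_point <- function(coeffs) -coeffs$b1 / coeffs$b2 - 1

#' Calibrate band mean intakes from target relative risks
#'
#' Inverts the dose-response curve: finds, for each AUDIT band, the intake
#' (grams/day) whose relative risk matches a target RR. The curve is
#' J-shaped, so targets below 1 have up to two roots; the larger root (on the
#' increasing branch) is returned so that calibrated intake is monotone in
#' band severity. A target of exactly 1 returns intake 0 (abstainers).
#'
#' @param target_rr named numeric vector of target relative risks per band.
#' @param coeffs a [mortality_coefficients()] object (or gender string).
#' @param upper upper bound of the search interval, grams/day.
#' @return Named numeric vector of intakes; `relative_risk()` of each matches
#'   its target to within 1e-6.
#' @export
#' @examples
#' calibrate_band_intakes(c(harmful = 1.10, dependence = 1.36), "men")
calibrate_band_intakes <- function(target_rr,
                                   coeffs = mortality_coefficients("men"),
                                   upper = 500) {
  if (is.character(coeffs)) coeffs <- mortality_coefficients(coeffs)
  x_min <- rr_turning_point(coeffs)
  rr_min <- relative_risk(x_min, coeffs)
  rr_max <- relative_risk(upper, coeffs)
  out <- vapply(seq_along(target_rr), function(i) {
    tgt <- target_rr[[i]]
    band <- if (!is.null(names(target_rr))) names(target_rr)[i] else
      paste0("band ", i)
    if (!is.finite(tgt) || tgt < rr_min - 1e-12 || tgt > rr_max + 1e-12) {
      stop(sprintf(
        "target RR %.4f for band '%s' is unattainable on intake [0, %g]",
        tgt, band, upper))
    }
    if (abs(tgt - 1) < 1e-12) return(0)
    stats::uniroot(
      function(x) log(relative_risk(x, coeffs)) - log(tgt),
      lower = x_min, upper = upper, tol = 1e-12
    )$root
  }, numeric(1))
  names(out) <- names(target_rr)
  out
}
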
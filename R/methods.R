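fmt_eur_m <- function(x) sprintf("%.1f", x / 1e6)

#' @export
print.alc_ce <- function(x, ...) {
  cat("Scenario comparison (deterministic, 12-month horizon)\n\n")
  tab <- data.frame(
    scenario = unname(x$scenario_names),
    `cost (M EUR)` = c(fmt_eur_m(x$base$cost), fmt_eur_m(x$alt$cost)),
    `DALYs averted` = sprintf("%.0f", c(x$base$daly, x$alt$daly)),
    `deaths averted` = sprintf("%.1f", c(x$base$deaths, x$alt$deaths)),
    `benefit/cost` = sprintf("%.2f", c(x$bcr_base, x$bcr_alt)),
    check.names = FALSE
  )
  print(tab, row.names = FALSE)
  cat(sprintf("\nIncremental cost:   EUR %s million\n", fmt_eur_m(x$delta_c)))
  cat(sprintf("Incremental effect: %.0f DALYs averted\n", x$delta_e))
  if (x$icer$status == "ratio") {
    cat(sprintf("ICER: EUR %.0f per DALY averted\n", x$icer$estimate))
  } else if (x$icer$status == "sw_ratio") {
    cat(sprintf("ICER (south-west quadrant): EUR %.0f per DALY forgone\n",
                x$icer$estimate))
  } else {
    cat("ICER:", x$icer$status, "\n")
  }
  invisible(x)
}

#' @export
summary.alc_ce <- function(object, ...) {
  out <- data.frame(
    scenario = rep(unname(object$scenario_names), each = 1),
    cost = c(object$base$cost, object$alt$cost),
    yld = c(object$base$yld, object$alt$yld),
    yll = c(object$base$yll, object$alt$yll),
    daly = c(object$base$daly, object$alt$daly),
    deaths = c(object$base$deaths, object$alt$deaths)
  )
  structure(list(table = out, delta_c = object$delta_c,
                 delta_e = object$delta_e, icer = object$icer,
                 bcr = c(base = object$bcr_base, alt = object$bcr_alt)),
            class = "summary.alc_ce")
}

#' @export
print.summary.alc_ce <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("delta_c = %.0f EUR, delta_e = %.1f DALYs, status = %s\n",
              x$delta_c, x$delta_e, x$icer$status))
  invisible(x)
}

#' @export
print.alc_ce_psa <- function(x, ...) {
  n <- nrow(x$iterations)
  cat(sprintf("Probabilistic sensitivity analysis: %d iterations (seed %d)\n",
              n, x$settings$seed))
  cat(sprintf("Comparison: %s vs %s\n\n", x$scenario_names["base"],
              x$scenario_names["alt"]))
  s <- x$summary
  cat(sprintf("mean   delta_c = EUR %s M, delta_e = %.0f DALYs\n",
              fmt_eur_m(s$delta_c[1]), s$delta_e[1]))
  cat(sprintf("median delta_c = EUR %s M, delta_e = %.0f DALYs\n",
              fmt_eur_m(s$delta_c[2]), s$delta_e[2]))
  p <- ceac_at(x, x$econ$wtp)
  cat(sprintf("P(cost-effective at EUR %s/DALY) = %.1f%%\n",
              format(x$econ$wtp, big.mark = ","), 100 * p))
  invisible(x)
}

#' @export
summary.alc_ce_psa <- function(object, ...) object$summary

#' CEAC probability at a given willingness-to-pay value
#'
#' @param psa an `alc_ce_psa` object.
#' @param wtp willingness to pay, euros/DALY (vectorised).
#' @return Probability that the alternative scenario is cost-effective
#'   (strictly positive net monetary benefit) at each `wtp`.
#' @export
ceac_at <- function(psa, wtp) {
  vapply(wtp, function(l) {
    mean(net_monetary_benefit(psa$iterations$delta_c,
                              psa$iterations$delta_e, l) > 0)
  }, numeric(1))
}

#' Plot method for probabilistic sensitivity analyses
#'
#' `type = "ce_plane"` draws the cloud of incremental (effect, cost) draws on
#' the cost-effectiveness plane with the willingness-to-pay line;
#' `type = "ceac"` draws the cost-effectiveness acceptability curve.
#'
#' @param x an `alc_ce_psa` object.
#' @param type `"ce_plane"` or `"ceac"`.
#' @param ... passed to the underlying plot call.
#' @export
plot.alc_ce_psa <- function(x, type = c("ce_plane", "ceac"), ...) {
  type <- match.arg(type)
  it <- x$iterations
  if (type == "ce_plane") {
    graphics::plot(it$delta_e, it$delta_c / 1e6,
                   xlab = "Incremental DALYs averted",
                   ylab = "Incremental cost (million EUR)",
                   main = "Cost-effectiveness plane", ...)
    graphics::abline(h = 0, v = 0, col = "grey60")
    graphics::abline(0, x$econ$wtp / 1e6, lty = 2, col = "steelblue")
  } else {
    graphics::plot(x$ceac$wtp, x$ceac$probability, type = "s", ylim = c(0, 1),
                   xlab = "Willingness to pay (EUR/DALY)",
                   ylab = "P(alternative is cost-effective)",
                   main = "Cost-effectiveness acceptability curve", ...)
    graphics::abline(h = c(0, 0.5, 1), col = "grey80", lty = 3)
  }
  invisible(x)
}
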
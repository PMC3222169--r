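# Version string stamped into output provenance headers.
FIXTURE_VERSION <- "nl-2009.1"

extdata <- function(file) {
  path <- system.file("extdata", file, package = "alccea")
  if (path == "") stop("packaged fixture not found: ", file)
  path
}

#' Packaged Dutch target-population profile
#'
#' Problem drinkers aged 18--69 stratified by gender and AUDIT band. Three
#' published totals are selectable:
#' \describe{
#'   \item{`"audit"`}{987,000 men / 267,000 women -- the counts that accompany
#'     the AUDIT band distribution (default, used throughout the model).}
#'   \item{`"national"`}{993,200 men / 222,800 women -- the national
#'     problem-drinker estimate.}
#'   \item{`"combined"`}{1,255,000 total, gender split kept proportional to
#'     the `"audit"` pair.}
#' }
#' Band mean intakes are the packaged calibrated values
#' (see [default_band_intakes()]).
#'
#' @param which population total to use.
#' @return A [population_profile()] object.
#' @export
nl_population <- function(which = c("audit", "national", "combined")) {
  which <- match.arg(which)
  fr <- utils::read.csv(extdata("nl_population.csv"), comment.char = "#",
                        stringsAsFactors = FALSE)
  n <- switch(which,
    audit = c(men = 987000, women = 267000),
    national = c(men = 993200, women = 222800),
    combined = {
      tot <- 1255000
      c(men = tot * 987000 / 1254000, women = tot * 267000 / 1254000)
    })
  population_profile(n[["men"]], n[["women"]], fr)
}

#' Packaged calibrated band mean intakes
#'
#' Mean pure-ethanol intake (grams/day) per gender and AUDIT band. The
#' original band-level intakes are not published; these values were obtained
#' by inverting the dose-response mortality curve against the published
#' band-level relative risks of death (see [calibrate_band_intakes()]) and
#' are stored so that runs are reproducible without re-calibration. The file
#' also carries the target RRs, so the calibration can be re-checked.
#'
#' @return Data frame with columns `gender`, `band`, `target_rr`,
#'   `mean_intake`.
#' @export
default_band_intakes <- function() {
  utils::read.csv(extdata("nl_band_intakes.csv"), comment.char = "#",
                  stringsAsFactors = FALSE)
}

#' Packaged intervention catalog (Netherlands, 2009 euros)
#'
#' Per-participant full economic cost (point estimate and uncertainty range)
#' and effect size d (with 95% CI) for every (disorder class, intervention)
#' pair of the modelled Dutch care system, plus the assumed 20% intake
#' reduction.
#'
#' @return An `intervention_catalog`.
#' @export
default_catalog <- function() load_catalog(extdata("intervention_catalog.csv"))

#' Packaged scenario definitions
#'
#' Coverage rates (fractions) for the three modelled Dutch health-care
#' scenarios: `base_case` (current care, no eHealth), `alternative_1`
#' (eHealth added on top of current care) and `alternative_2` (face-to-face
#' care 50% substituted by eHealth). Adherence defaults to 0.50 everywhere.
#'
#' @return Named list of [scenario()] objects.
#' @export
default_scenarios <- function() load_scenarios(extdata("scenarios.csv"))

#' Packaged synthetic mortality / life-expectancy table
#'
#' Gender x age (18--69) annual all-cause mortality rates and remaining life
#' expectancies. SYNTHETIC data: generated by
#' [generate_synthetic_mortality()] with Gompertz parameters chosen to mimic
#' a Dutch 2009 period life table; not observed national statistics.
#'
#' @return A `mortality_table`.
#' @export
nl_mortality <- function() read_mortality(extdata("nl_mortality_synthetic.csv"))
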
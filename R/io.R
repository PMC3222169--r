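#' Read / write a run configuration
#'
#' A YAML file describing a full model run: fixture paths (empty = packaged
#' defaults), the scenario pair, mode, and the burden / economic / PSA
#' settings. See `inst/extdata/default_config.yaml` for the documented
#' schema.
#'
#' @param path YAML file path.
#' @return A list of class `run_config`.
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg, dir = dirname(normalizePath(path)))
}

#' @rdname read_config
#' @param config a `run_config` list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname read_config
#' @param cfg a raw config list (e.g. from `yaml::read_yaml()`); defaults are
#'   filled in and referenced paths checked.
#' @param dir directory against which relative fixture paths are resolved.
#' @export
validate_config <- function(cfg, dir = ".") {
  defaults <- list(
    mode = "deterministic",
    population = list(which = "audit"),
    scenarios = list(base = "base_case", alternative = "alternative_1"),
    paths = list(),
    burden = list(conversion_factor = 0.18, cf_ci = c(0.16, 0.20),
                  attenuation = 0.20),
    econ = list(wtp = 50000, wtp_grid = list(from = 0, to = 50000,
                                             by = 1000)),
    psa = list(n_iterations = 500, seed = 1,
               sample_conversion_factor = TRUE)
  )
  cfg <- utils::modifyList(defaults, cfg)
  if (!cfg$mode %in% c("deterministic", "stochastic")) {
    stop("config: mode must be 'deterministic' or 'stochastic'")
  }
  for (nm in names(cfg$paths)) {
    p <- cfg$paths[[nm]]
    if (!file.exists(p)) {
      p2 <- file.path(dir, p)
      if (!file.exists(p2)) stop("config: referenced file missing: ", p)
      cfg$paths[[nm]] <- p2
    }
  }
  class(cfg) <- "run_config"
  cfg
}

#' Materialise the model inputs described by a run configuration
#'
#' Loads the population, catalog, scenarios and mortality table a
#' `run_config` refers to (packaged defaults where no path is given) and
#' builds the settings objects.
#'
#' @param cfg a `run_config` from [read_config()] / [validate_config()].
#' @return A list with elements `base`, `alt`, `population`, `catalog`,
#'   `mortality`, `burden`, `econ`, `psa`.
#' @export
config_inputs <- function(cfg) {
  pop_fr <- if (!is.null(cfg$paths$population)) {
    utils::read.csv(cfg$paths$population, comment.char = "#",
                    stringsAsFactors = FALSE)
  } else NULL
  population <- if (is.null(pop_fr)) {
    nl_population(cfg$population$which)
  } else {
    base <- nl_population(cfg$population$which)
    population_profile(base$n_men, base$n_women, pop_fr)
  }
  catalog <- if (!is.null(cfg$paths$catalog)) load_catalog(cfg$paths$catalog)
    else default_catalog()
  scens <- if (!is.null(cfg$paths$scenarios))
    load_scenarios(cfg$paths$scenarios) else default_scenarios()
  mortality <- if (!is.null(cfg$paths$mortality))
    read_mortality(cfg$paths$mortality) else nl_mortality()
  for (nm in c(cfg$scenarios$base, cfg$scenarios$alternative)) {
    if (!nm %in% names(scens)) stop("config: unknown scenario '", nm, "'")
  }
  g <- cfg$econ$wtp_grid
  grid <- if (is.list(g)) seq(g$from, g$to, by = g$by) else unlist(g)
  list(
    base = scens[[cfg$scenarios$base]],
    alt = scens[[cfg$scenarios$alternative]],
    population = population, catalog = catalog, mortality = mortality,
    burden = burden_settings(cfg$burden$conversion_factor,
                             unlist(cfg$burden$cf_ci),
                             cfg$burden$attenuation),
    econ = econ_settings(cfg$econ$wtp, grid),
    psa = psa_settings(cfg$psa$n_iterations, cfg$psa$seed,
                       cfg$psa$sample_conversion_factor)
  )
}

# Short hex digest of the settings for provenance headers.
settings_hash <- function(...) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(paste(utils::capture.output(utils::str(list(...))),
                   collapse = "\n"), tf)
  unname(substr(tools::md5sum(tf), 1, 12))
}

provenance_header <- function(seed = NA, ...) {
  c(sprintf("# fixtures: %s", FIXTURE_VERSION),
    sprintf("# seed: %s", seed),
    sprintf("# settings_hash: %s", settings_hash(...)),
    sprintf("# written_by: alccea %s",
            as.character(utils::packageVersion("alccea"))))
}

#' Write a result table as CSV with a provenance header
#'
#' Prepends `#`-comment lines recording the fixture version, seed and a hash
#' of the settings, then the CSV body. Readable back with any CSV reader
#' that honours `comment.char = "#"`.
#'
#' @param df data frame to write.
#' @param path output path.
#' @param seed RNG seed used (NA for deterministic outputs).
#' @param ... settings objects folded into the provenance hash.
#' @return The path, invisibly.
#' @export
write_result_csv <- function(df, path, seed = NA, ...) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed = seed, ...), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Write a comparison or PSA summary as JSON
#'
#' @param x an `alc_ce` or `alc_ce_psa` object.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_summary_json <- function(x, path) {
  out <- if (inherits(x, "alc_ce_psa")) {
    list(kind = "psa",
         scenarios = as.list(x$scenario_names),
         n_iterations = nrow(x$iterations),
         seed = x$settings$seed,
         summary = x$summary,
         ceac_at_wtp = ceac_at(x, x$econ$wtp),
         wtp = x$econ$wtp,
         provenance = list(fixtures = FIXTURE_VERSION,
                           settings_hash = settings_hash(x$settings)))
  } else {
    list(kind = "deterministic",
         scenarios = as.list(x$scenario_names),
         base = x$base[c("cost", "yld", "yll", "daly", "deaths")],
         alt = x$alt[c("cost", "yld", "yll", "daly", "deaths")],
         delta_c = x$delta_c, delta_e = x$delta_e,
         icer = x$icer, bcr = c(x$bcr_base, x$bcr_alt),
         provenance = list(fixtures = FIXTURE_VERSION,
                           settings_hash = settings_hash(x$inputs$burden,
                                                         x$inputs$econ)))
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Generate a synthetic per-person AUDIT sample
#'
#' Emulates a screening data set: assigns each person to an AUDIT band by
#' multinomial sampling of the band fractions, then draws a uniform integer
#' score within the band's score range.
#'
#' @param n number of persons.
#' @param fractions named numeric vector of band fractions (must sum to 1).
#' @param bands band definition table, see [audit_bands()].
#' @param seed optional RNG seed.
#' @return Data frame with columns `band`, `audit_score` (`n` rows).
#' @export
generate_synthetic_audit_sample <- function(n, fractions,
                                            bands = audit_bands(),
                                            seed = NULL) {
  stopifnot(abs(sum(fractions) - 1) < 1e-9, all(fractions >= 0))
  if (!is.null(seed)) set.seed(seed)
  if (n == 0) {
    return(data.frame(band = character(0), audit_score = integer(0)))
  }
  band <- sample(names(fractions), n, replace = TRUE, prob = fractions)
  i <- match(band, bands$band)
  lo <- bands$audit_min[i]
  hi <- bands$audit_max[i]
  score <- lo + floor(stats::runif(n) * (hi - lo + 1))
  data.frame(band = band, audit_score = as.integer(score),
             stringsAsFactors = FALSE)
}
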
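Package: alccea
Title: Population-Level Cost-Effectiveness Modelling of Health Care Systems
    for Alcohol Use Disorders
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Deterministic and probabilistic (Monte-Carlo) estimation of the
    12-month incremental cost-effectiveness of competing intervention mixes
    for alcohol use disorders at the national level. Populations are
    stratified by gender and AUDIT score band; disease burden averted is
    computed as DALYs (years lived with disability from treatment effect
    sizes via a disability-weight conversion factor, plus years of life lost
    from intake reduction through a dose-response all-cause mortality model).
    Outputs include incremental costs, DALYs averted, ICERs with
    cost-effectiveness-plane quadrant handling, cost-effectiveness
    acceptability curves, and benefit-cost ratios, with seeded probabilistic
    sensitivity analysis over gamma-distributed costs and normally
    distributed effect sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
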
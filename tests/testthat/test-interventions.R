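test_that("packaged catalog reproduces the published cost and effect tables", {
  cat_ <- default_catalog()
  beh <- cat_[cat_$disorder == "harmful" &
              cat_$intervention == "behavioral", ]
  expect_equal(beh$cost, 2024)
  expect_equal(c(beh$cost_low, beh$cost_high), c(1702, 2550))
  otl <- cat_[cat_$disorder == "harmful" &
              cat_$intervention == "online_therapist_led", ]
  expect_equal(otl$d, 0.58)
  expect_equal(c(otl$d_low, otl$d_high), c(0.29, 0.88))
  # cost keyed on (intervention, disorder): same intervention, other class
  otl2 <- cat_[cat_$disorder == "dependence" &
               cat_$intervention == "online_therapist_led", ]
  expect_equal(otl2$cost, 1276)
  expect_true(all(cat_$intake_reduction == 0.20))
})

test_that("catalog validation lists offending fields; empty catalog errors", {
  tf <- tempfile(fileext = ".csv")
  writeLines("disorder,intervention,cost,cost_low,cost_high,d,d_low,d_high",
             tf)
  expect_error(load_catalog(tf), "empty")
  df <- as.data.frame(default_catalog())
  df$cost_low[1] <- df$cost[1] + 1
  expect_error(intervention_catalog(df), "cost_low <= cost <= cost_high")
  df <- as.data.frame(default_catalog())
  df$d_high[2] <- df$d[2] - 1
  expect_error(intervention_catalog(df), "d_low <= d <= d_high")
})

test_that("catalog round-trips through write -> read identically", {
  cat_ <- default_catalog()
  tf <- tempfile(fileext = ".csv")
  write_catalog(cat_, tf)
  expect_equal(as.data.frame(load_catalog(tf)), as.data.frame(cat_),
               ignore_attr = TRUE)
})

test_that("gamma cost distribution moment-matches the uncertainty range", {
  g <- cost_distribution(2024, 1702, 2550)
  expect_equal(g$mean, 2024)
  expect_equal(g$sd, (2550 - 1702) / 3.92, tolerance = 1e-12)
  expect_equal(g$sd, 216.3265, tolerance = 1e-4)
  expect_equal(g$shape * g$scale, 2024, tolerance = 1e-9)
  expect_equal(sqrt(g$shape) * g$scale, g$sd, tolerance = 1e-9)
  g2 <- cost_distribution(58, 52, 75)
  expect_equal(g2$shape * g2$scale, 58, tolerance = 1e-9)
  # degenerate range: point mass
  p <- cost_distribution(58, 58, 58)
  expect_identical(p$type, "point")
  expect_true(all(alccea:::sample_distribution(p, 5) == 58))
})

test_that("normal effect distribution spans CIs crossing zero, untruncated", {
  e <- effect_distribution(0.58, 0.29, 0.88)
  expect_equal(e$sd, 0.1505102, tolerance = 1e-6)
  e2 <- effect_distribution(0.31, -0.69, 1.30)
  expect_equal(e2$sd, 0.5076531, tolerance = 1e-6)
  set.seed(7)
  draws <- alccea:::sample_distribution(e2, 2000)
  expect_true(any(draws < 0))  # no truncation
  p <- effect_distribution(0.2, 0.2, 0.2)
  expect_identical(p$type, "point")
})

test_that("sampled means converge to the point estimates", {
  set.seed(11)
  n <- 20000
  g <- cost_distribution(2024, 1702, 2550)
  cd <- alccea:::sample_distribution(g, n)
  expect_lt(abs(mean(cd) - 2024), 3 * g$sd / sqrt(n))
  e <- effect_distribution(0.31, -0.69, 1.30)
  ed <- alccea:::sample_distribution(e, n)
  expect_lt(abs(mean(ed) - 0.31), 3 * e$sd / sqrt(n))
})

test_that("per-participant cost spreads fixed costs over participants", {
  expect_equal(per_participant_cost(125000, 1255000, 0.40, 0.08),
               125000 / 40160, tolerance = 1e-12)
  expect_equal(per_participant_cost(225000, 1255000, 0.15, 0.05),
               225000 / 9412.5, tolerance = 1e-12)
  expect_equal(per_participant_cost(0, 1e6, 0.5, 0.5, variable_cost = 12.5),
               12.5)
  expect_error(per_participant_cost(1000, 100, 0, 0.5), "fewer than one")
})

test_that("scenarios validate coverage/adherence and default adherence 0.5", {
  scens <- default_scenarios()
  expect_named(scens, c("base_case", "alternative_1", "alternative_2"))
  expect_true(all(scens$base_case$entries$adherence == 0.5))
  expect_error(
    scenario("x", data.frame(disorder = "harmful", intervention = "cbt",
                             coverage = 1.2)),
    "coverage")
  expect_error(
    scenario("x", data.frame(disorder = c("harmful", "harmful"),
                             intervention = c("cbt", "cbt"),
                             coverage = 0.1)),
    "duplicate")
})
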
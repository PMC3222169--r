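test_that("YLD averted follows the conversion-factor chain", {
  bs <- burden_settings()
  expect_identical(yld_averted(1000, 0, bs, adherence = 1), 0)
  expect_equal(yld_averted(1000, 0.5, bs, adherence = 1), 72)
  # harmful drinkers under a behavioural intervention at 9% coverage
  n_treated <- 610365 * 0.09
  expect_equal(yld_averted(n_treated, 0.34, bs, adherence = 0.5),
               n_treated * 0.5 * 0.34 * 0.18 * 0.8, tolerance = 1e-12)
  expect_equal(yld_averted(n_treated, 0.34, bs, adherence = 0.5),
               1344.8, tolerance = 1e-4)
})

test_that("YLD is monotone in its factors and scales with attenuation off", {
  bs <- burden_settings()
  base <- yld_averted(1000, 0.3, bs, adherence = 0.5)
  expect_gt(yld_averted(2000, 0.3, bs, adherence = 0.5), base)
  expect_gt(yld_averted(1000, 0.4, bs, adherence = 0.5), base)
  expect_gt(yld_averted(1000, 0.3, bs, adherence = 0.6), base)
  bs0 <- burden_settings(attenuation = 0)
  expect_equal(yld_averted(1000, 0.3, bs0, adherence = 0.5),
               base / (1 - 0.2), tolerance = 1e-12)
})

test_that("deaths averted match the product oracle on a flat hazard", {
  mt <- flat_mortality(rate = 0.004)
  pop <- toy_population()
  aw <- age_weights(pop)
  co <- mortality_coefficients("men")
  x <- 200
  d_rr <- relative_risk(x, co) - relative_risk(0.8 * x, co)
  got <- deaths_averted("men", 4538, x, 0.2, mt, aw,
                        coverage = 1, adherence = 0.5)
  # treated x adherence x mbar x [RR(x) - RR(0.8x)] x (1 - attenuation)
  expect_equal(got, 4538 * 0.5 * 0.004 * d_rr * 0.8, tolerance = 1e-12)
})

test_that("deaths averted vanish for zero reduction and for abstainers", {
  mt <- flat_mortality()
  aw <- age_weights(toy_population())
  expect_equal(deaths_averted("men", 1000, 150, 0, mt, aw), 0)
  expect_equal(deaths_averted("women", 1000, 0, 0.2, mt, aw), 0)
  # continuity: reduction -> 0 drives deaths -> 0
  small <- sapply(c(1e-2, 1e-4, 1e-6), function(r)
    deaths_averted("men", 1000, 150, r, mt, aw))
  expect_true(all(diff(abs(small)) < 0))
  expect_lt(abs(small[3]), 1e-5)
})

test_that("deaths can be negative on the protective branch and are kept", {
  mt <- flat_mortality()
  aw <- age_weights(toy_population())
  # intake 20 g/day is on the descending branch: cutting it raises RR
  expect_lt(deaths_averted("men", 1000, 20, 0.5, mt, aw), 0)
})

test_that("YLL pairs avoided deaths with remaining life expectancy", {
  mt <- nl_mortality()
  expect_equal(yll_averted(data.frame(gender = character(0),
                                      age = integer(0),
                                      deaths = numeric(0)), mt), 0)
  le45 <- mt$life_expectancy[mt$gender == "men" & mt$age == 45]
  expect_equal(yll_averted(data.frame(gender = "men", age = 45, deaths = 1),
                           mt), le45)
  expect_equal(
    yll_averted(data.frame(gender = "men", age = 45, deaths = 32), mt),
    32 * le45)
  expect_error(
    yll_averted(data.frame(gender = "men", age = 15, deaths = 1), mt),
    "lacks rows")
})

test_that("DALY is the exact sum of YLD and YLL, and is linear", {
  expect_identical(daly(0, 0), 0)
  expect_identical(daly(72, 0), 72)
  expect_identical(daly(4450.3, 845.9), 4450.3 + 845.9)
  a <- c(1.2, 3); b <- c(0.5, 2); c_ <- c(9, 0.1); d_ <- c(4, 7)
  expect_equal(daly(a + c_, b + d_), daly(a, b) + daly(c_, d_))
})

test_that("burden settings validate their domains", {
  expect_error(burden_settings(attenuation = 1), "attenuation")
  expect_error(burden_settings(conversion_factor = -0.1))
})
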
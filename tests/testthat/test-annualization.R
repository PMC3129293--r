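test_that("straight-line charges follow the class lifetimes", {
  out <- straight_line_depreciation(data.frame(
    asset_class = c("medical_equipment", "general_equipment", "vehicle"),
    initial_value_ksh = c(80000, 50000, 160000)))
  expect_equal(out$annual_depreciation_ksh, c(80000 / 8, 50000 / 10, 160000 / 8))
})

test_that("buildings are valued from floor area and depreciate over 30 years", {
  expect_equal(building_initial_cost(100, 1500), 150000)
  expect_equal(building_initial_cost(1, 1), 1)
  expect_equal(building_initial_cost(250.5, 2000), 501000)
  expect_error(building_initial_cost(-1, 2000), "> 0")

  out <- straight_line_depreciation(data.frame(
    asset_class = "building", initial_value_ksh = NA,
    floor_area_sqm = 300, unit_build_cost_ksh = 2000))
  expect_equal(out$initial_value_ksh, 600000)
  expect_equal(out$annual_depreciation_ksh, 20000)
})

test_that("depreciation telescopes back to the initial value", {
  set.seed(101)
  assets <- data.frame(
    asset_class = sample(c("general_equipment", "medical_equipment",
                           "vehicle", "building"), 50, replace = TRUE),
    initial_value_ksh = runif(50, 1e3, 1e7),
    lifetime_years = sample(c(NA, 5, 12, 25), 50, replace = TRUE),
    condition_adjustment = runif(50, 0.5, 1.5))
  out <- straight_line_depreciation(assets)
  recovered <- out$annual_depreciation_ksh * out$effective_lifetime_years
  expect_equal(recovered, out$initial_value_ksh, tolerance = 1e-6)
})

test_that("zero or negative effective lifetime is a parameter error", {
  expect_error(straight_line_depreciation(data.frame(
    asset_class = "vehicle", initial_value_ksh = 1000,
    condition_adjustment = 0)), "lifetime")
})

test_that("two-year averaging uplifts the earlier year by inflation", {
  expect_equal(inflation_average(100, 110), 107.5)
  expect_equal(inflation_average(0, 0), 0)
  expect_equal(inflation_average(42, 42, inflation = 0), 42)
  expect_error(inflation_average(10, 10, inflation = -2), "rate")
  # linear in each argument
  a <- runif(20); b <- runif(20)
  expect_equal(inflation_average(3 * a, b), 3 * inflation_average(a, 0) + inflation_average(0, b))
})

test_that("currency conversion is exact and round-trips", {
  expect_equal(convert_currency(90.66), 1)
  expect_equal(convert_currency(0), 0)
  eur <- convert_currency(63e9)
  expect_equal(eur, 63e9 / 90.66)
  # report-level rounding to the nearest 10 million gives the headline figure
  expect_equal(round_half_away(eur / 1e7) * 1e7, 690e6)
  x <- runif(50, 1, 1e9)
  expect_equal(convert_currency(x) * 90.66, x, tolerance = 1e-9)
})

test_that("staff minute cost divides full remuneration by direct minutes", {
  base <- staff_minute_cost(data.frame(cadre = "nurse", annual_base_ksh = 792000,
                                       annual_allowances_ksh = 0))
  expect_equal(base$minutes_per_year, 79200)
  expect_equal(base$cost_per_minute_ksh, 10)

  with_allow <- staff_minute_cost(data.frame(
    cadre = "nurse", annual_base_ksh = 792000, annual_allowances_ksh = 792000))
  expect_equal(with_allow$cost_per_minute_ksh, 2 * base$cost_per_minute_ksh)

  half_days <- staff_minute_cost(data.frame(
    cadre = "nurse", annual_base_ksh = 792000, annual_allowances_ksh = 0,
    working_days = 110, direct_hours = 6))
  expect_equal(half_days$cost_per_minute_ksh, 2 * base$cost_per_minute_ksh)

  expect_error(staff_minute_cost(data.frame(
    cadre = "x", annual_base_ksh = 1, annual_allowances_ksh = 0,
    working_days = 0, direct_hours = 6)), "working_days")
})

test_that("in-kind supplies are imputed from the price list as drug costs", {
  prices <- c(amoxicillin = 5, ORS = 20)
  out <- impute_inkind(data.frame(item_code = "amoxicillin", quantity = 100,
                                  centre_id = "OPD"), prices)
  expect_equal(out$amount_ksh, 500)
  expect_equal(out$category, "drugs_supplies")

  expect_equal(nrow(impute_inkind(data.frame(), prices)), 0)

  set.seed(7)
  recs <- data.frame(item_code = sample(names(prices), 20, replace = TRUE),
                     quantity = sample(1:50, 20, replace = TRUE),
                     centre_id = "OPD")
  out <- impute_inkind(recs, prices)
  expect_equal(sum(out$amount_ksh),
               sum(recs$quantity * prices[recs$item_code]))

  expect_error(impute_inkind(data.frame(item_code = "unobtainium", quantity = 1,
                                        centre_id = "OPD"), prices),
               "unobtainium")
})

test_that("missing pay falls back to the public scale and is flagged", {
  scale <- data.frame(cadre = c("nurse", "doctor"),
                      annual_base_ksh = c(600000, 1800000),
                      annual_allowances_ksh = c(200000, 600000))
  pay <- data.frame(cadre = c("nurse", "doctor"),
                    annual_base_ksh = c(NA, 2000000),
                    annual_allowances_ksh = c(NA, 500000))
  out <- fallback_salary(pay, scale)
  expect_equal(out$annual_base_ksh, c(600000, 2000000))
  expect_equal(out$annual_allowances_ksh, c(200000, 500000))
  expect_equal(out$pay_imputed, c(TRUE, FALSE))

  expect_error(fallback_salary(
    data.frame(cadre = "astronaut", annual_base_ksh = NA,
               annual_allowances_ksh = NA), scale), "astronaut")
})

test_that("annualize_ledger collapses two ledger years item by item", {
  rec <- make_toy_record()
  y1 <- rec$items |> dplyr::mutate(year = "2005/2006", amount_ksh = amount_ksh * 0.9)
  rec$items <- dplyr::bind_rows(y1, rec$items)
  ann <- annualize_ledger(rec, inflation = 0.05)
  expect_equal(unique(ann$items$year), "annualized")
  expect_equal(sum(ann$items$amount_ksh),
               inflation_average(sum(y1$amount_ksh),
                                 sum(make_toy_record()$items$amount_ksh)))
  # one-year ledgers pass through unchanged
  expect_identical(annualize_ledger(make_toy_record())$items,
                   make_toy_record()$items)
})
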
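test_that("fixed bed-day cost rescales with the utilization gap", {
  u <- tibble::tibble(
    measure = c("admission", "bed_day"),
    total_ksh = c(0, 0), output = c(100, 600),
    unit_cost_ksh = c(9000, 1500), direct_ksh = 0,
    indirect_ksh = c(9000, 1500),
    fixed_ksh = c(6000, 1000), variable_ksh = c(3000, 500))
  beds <- 10
  # actual occupancy 42.5% = half the 85% standard: fixed per bed-day halves
  actual_days <- beds * 365 * 0.425
  std <- standard_occupancy_unit_costs(u, beds, actual_days)
  expect_equal(std$fixed_ksh[std$measure == "bed_day"], 500)
  expect_equal(std$unit_cost_ksh[std$measure == "bed_day"], 1000)
  # admission cost keeps the actual length-of-stay proxy (9000/1500 = 6)
  expect_equal(std$unit_cost_ksh[std$measure == "admission"], 6000)

  # already at standard occupancy: identity
  at_std <- standard_occupancy_unit_costs(u, beds, beds * 365 * 0.85)
  expect_equal(at_std$unit_cost_ksh, u$unit_cost_ksh)
  expect_equal(at_std$fixed_ksh, u$fixed_ksh)

  expect_error(standard_occupancy_unit_costs(u[0, ], beds, 100), "bed-day|split")
})

test_that("standard occupancy cuts under-utilized private district costs", {
  s <- small_sample(seed = 1)
  rec <- annualize_ledger(s$facilities[["district_hospital_private_001"]])
  res <- stepdown_allocate(rec)
  u <- unit_costs(res, rec)
  occ <- rec$statistics$bed_days / (rec$beds * 365)
  expect_lt(occ, 0.85)
  std <- standard_occupancy_unit_costs(u, rec$beds, rec$statistics$bed_days)
  expect_lt(std$unit_cost_ksh[std$measure == "admission"],
            u$unit_cost_ksh[u$measure == "admission"])
  expect_lt(std$unit_cost_ksh[std$measure == "bed_day"],
            u$unit_cost_ksh[u$measure == "bed_day"])
})

test_that("the fixed/variable split conserves the grand total under both policies", {
  m <- kenya_cost_matrix()
  fo <- fixed_variable_split(m, "fixed_only")
  expect_equal(fo$F, 191709086)
  expect_equal(fo$V, 503238016)
  expect_equal(fo$F + fo$V, 694947102)
  fs <- fixed_variable_split(m, "fixed_plus_staffing")
  expect_equal(fs$F, 191709086 + 259734287)
  expect_equal(fs$F + fs$V, 694947102)

  all_fixed <- cost_matrix(tibble::tibble(
    stratum = "x", trustee_group = "all", drugs_supplies = 0, staffing = 0,
    other_recurrent = 0, fixed = 1000))
  expect_equal(fixed_variable_split(all_fixed)$V, 0)
})

test_that("demand multiplier factor follows (F + mV)/(F + V)", {
  expect_equal(demand_multiplier_factor(100, 100, 3), 2)
  expect_equal(demand_multiplier_factor(0, 50, 7), 7)
  expect_equal(demand_multiplier_factor(50, 0, 7), 1)
  set.seed(21)
  for (i in 1:50) {
    F <- runif(1, 0, 1e6); V <- runif(1, 1, 1e6); m <- runif(1, 1, 10)
    f <- demand_multiplier_factor(F, V, m)
    expect_lte(f, m)          # subproportional whenever m >= 1
    expect_gte(f, 1)
  }
})

test_that("tripling demand on the national matrix raises cost less than threefold", {
  fv <- fixed_variable_split(kenya_cost_matrix(), "fixed_only")
  f3 <- demand_multiplier_factor(fv$F, fv$V, 3)
  expect_lt(f3, 3)
  expect_gt(f3, 1)
})

test_that("the coverage curve is anchored at 1, monotone and subproportional", {
  m <- kenya_cost_matrix()
  cv <- coverage_response(m, scenario_spec())
  expect_equal(cv$cost_factor[1], 1)
  expect_true(all(diff(cv$total_cost) >= 0))
  expect_true(all(cv$cost_factor <= cv$utilization + 1e-12))
  # threefold coverage with positive fixed cost: strictly below 3
  cv3 <- coverage_response(m, scenario_spec(), coverages = c(0.25, 0.75))
  expect_lt(cv3$cost_factor[2], 3)
  expect_error(coverage_response(m, scenario_spec(), coverages = c(0.1)),
               "below baseline")
})

test_that("capacity blocks add one step at the configured threshold", {
  m <- cost_matrix(tibble::tibble(
    stratum = "x", trustee_group = "all", drugs_supplies = 600,
    staffing = 0, other_recurrent = 0, fixed = 400))
  spec <- scenario_spec(capacity_threshold = 1.4, expansion_step_cost = 100,
                        capacity_block = 0.5)
  cov <- seq(0.25, 0.55, by = 0.025)  # utilization 1.0 .. 2.2
  cv <- coverage_response(m, spec, coverages = cov)
  # hand-computed piecewise oracle: F + uV + 100 * ceil((u - 1.4)/0.5)
  u <- cov / 0.25
  expected <- 400 + u * 600 + 100 * ceiling(pmax(u - 1.4, 0) / 0.5 - 1e-12)
  expect_equal(cv$total_cost, expected)
  expect_equal(unique(cv$capacity_blocks), c(0L, 1L, 2L))
  # exactly one jump per block boundary in the evaluated range
  jumps <- diff(cv$total_cost) - diff(u) * 600
  expect_equal(sum(jumps > 1e-9), 2)
})

test_that("scenario specification rejects out-of-range rates", {
  expect_error(scenario_spec(standard_occupancy = 0), "rate")
  expect_error(scenario_spec(standard_occupancy = 1.6), "rate")
  expect_error(scenario_spec(demand_multipliers = c(1, -2)), "> 0")
})
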
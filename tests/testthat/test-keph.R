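prices <- c(pill = 50, rdt = 70)
rates <- c(nurse = 10)

test_that("direct episode cost prices drugs, staff minutes and lab tests", {
  comp <- tibble::tibble(component = c("drug", "staff"),
                         code = c("pill", "nurse"), quantity = c(2, 30))
  expect_equal(episode_direct_cost(comp, prices, rates), 400)
  expect_equal(episode_direct_cost(comp[0, ], prices, rates), 0)
  comp2 <- comp; comp2$quantity <- comp2$quantity * 2
  expect_equal(episode_direct_cost(comp2, prices, rates),
               2 * episode_direct_cost(comp, prices, rates))
  expect_error(episode_direct_cost(
    tibble::tibble(component = "drug", code = "unpriced", quantity = 1),
    prices, rates), "unpriced")
  expect_error(episode_direct_cost(
    tibble::tibble(component = "staff", code = "surgeon", quantity = 1),
    prices, rates), "surgeon")
})

test_that("direct cost is linear in quantities and prices", {
  set.seed(11)
  for (i in 1:20) {
    comp <- tibble::tibble(
      component = sample(c("drug", "lab", "staff"), 5, replace = TRUE),
      code = NA_character_, quantity = runif(5, 0, 10))
    comp$code <- ifelse(comp$component == "staff", "nurse",
                        sample(names(prices), 5, replace = TRUE))
    k <- runif(1, 0.1, 5)
    base <- episode_direct_cost(comp, prices, rates)
    scaled_q <- comp; scaled_q$quantity <- scaled_q$quantity * k
    expect_equal(episode_direct_cost(scaled_q, prices, rates), k * base)
    expect_equal(episode_direct_cost(comp, prices * k, rates * k), k * base)
  }
})

mk_units <- function(visit_ind = 150, bedday_ind = 2000) {
  tibble::tibble(
    measure = c("outpatient_visit", "admission", "bed_day"),
    total_ksh = 0, output = 1,
    unit_cost_ksh = c(visit_ind + 50, 6 * (bedday_ind + 100), bedday_ind + 100),
    direct_ksh = c(50, 600, 100),
    indirect_ksh = c(visit_ind, 6 * bedday_ind, bedday_ind),
    fixed_ksh = 0, variable_ksh = 0)
}

test_that("an inpatient episode adds bed-day overhead times length of stay", {
  ec <- episode_total_cost(500, mk_units(bedday_ind = 2000), "inpatient",
                           length_of_stay = 3)
  expect_equal(ec$indirect_ksh, 6000)
  expect_equal(ec$total_ksh, 6500)

  ec0 <- episode_total_cost(0, mk_units(), "inpatient", length_of_stay = 2)
  expect_equal(ec0$total_ksh, ec0$indirect_ksh)

  expect_error(episode_total_cost(10, mk_units(), "inpatient"),
               "length_of_stay")
  u_op_only <- mk_units()[1, ]
  expect_error(episode_total_cost(10, u_op_only, "inpatient",
                                  length_of_stay = 2), "bed_day")
})

test_that("only the indirect unit-cost component is used as overhead", {
  ec <- episode_total_cost(100, mk_units(visit_ind = 150), "outpatient")
  expect_equal(ec$indirect_ksh, 150)  # not 200: the direct share is excluded
  expect_equal(ec$total_ksh, 250)
})

test_that("episode totals decompose exactly and order by overhead", {
  set.seed(3)
  for (i in 1:25) {
    d <- runif(1, 0, 5000)
    u <- mk_units(visit_ind = runif(1, 50, 5000))
    ec <- episode_total_cost(d, u, "outpatient")
    expect_identical(ec$total_ksh, ec$direct_ksh + ec$indirect_ksh)
  }
  lo <- episode_total_cost(300, mk_units(visit_ind = 100), "outpatient")
  hi <- episode_total_cost(300, mk_units(visit_ind = 900), "outpatient")
  expect_lt(lo$total_ksh, hi$total_ksh)
})

test_that("normative costing equals actual for identical schemes and dominates supersets", {
  comp <- tibble::tibble(component = "drug", code = "pill", quantity = 4)
  u <- mk_units()
  actual <- episode_total_cost(episode_direct_cost(comp, prices, rates),
                               u, "outpatient")
  norm <- normative_episode_cost(comp, prices, rates, u, "outpatient")
  expect_equal(norm$total_ksh, actual$total_ksh)
  expect_equal(norm$variant, "normative")

  richer <- dplyr::bind_rows(comp, tibble::tibble(component = "lab",
                                                  code = "rdt", quantity = 1))
  norm2 <- normative_episode_cost(richer, prices, rates, u, "outpatient")
  expect_gte(norm2$direct_ksh, actual$direct_ksh)

  u0 <- u; u0$indirect_ksh <- 0
  expect_equal(normative_episode_cost(comp, prices, rates, u0,
                                      "outpatient")$total_ksh,
               episode_direct_cost(comp, prices, rates))
})

test_that("the synthetic scheme collection costs out for both variants", {
  sch <- synthetic_keph_schemes()
  pl <- synthetic_price_list()
  st_rates <- c(nurse = 8, clinical_officer = 12, doctor = 25)
  eps <- cost_keph_episodes(sch$schemes, sch$components, pl, st_rates,
                            mk_units(), age_group = "under5")
  expect_equal(nrow(eps), nrow(sch$schemes))
  expect_equal(eps$total_ksh, eps$direct_ksh + eps$indirect_ksh)
  # normative direct never below actual (stock-outs depress actual use)
  cmp <- eps |>
    dplyr::select(condition_id, variant, direct_ksh) |>
    tidyr::pivot_wider(names_from = variant, values_from = direct_ksh)
  expect_true(all(cmp$normative >= cmp$actual))
})

test_that("demand-side adjustment adds the mean outside drug purchase only", {
  u <- mk_units()
  ints <- tibble::tibble(
    patient_type = c("outpatient", "outpatient", "inpatient"),
    outside_drug_cost = c(40, 60, 90),
    user_fees = c(500, 500, 500), transport_cost = c(200, 200, 200))
  adj <- demand_side_adjust(u, ints)
  expect_equal(adj$unit_cost_ksh[adj$measure == "outpatient_visit"],
               u$unit_cost_ksh[u$measure == "outpatient_visit"] + 50)
  expect_equal(adj$unit_cost_ksh[adj$measure == "admission"],
               u$unit_cost_ksh[u$measure == "admission"] + 90)
  # user fees and transport are never folded in
  only_transport <- ints; only_transport$outside_drug_cost <- 0
  adj2 <- demand_side_adjust(u, only_transport)
  expect_equal(adj2$unit_cost_ksh, u$unit_cost_ksh)
  # adjusted costs never fall below unadjusted
  expect_true(all(adj$unit_cost_ksh >= u$unit_cost_ksh))
})

test_that("an empty interview cell leaves costs unchanged with a warning", {
  u <- mk_units()
  expect_warning(adj <- demand_side_adjust(u, tibble::tibble(
    patient_type = character(), outside_drug_cost = numeric(),
    user_fees = numeric(), transport_cost = numeric())),
    "unadjusted")
  expect_equal(adj$unit_cost_ksh, u$unit_cost_ksh)
})
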
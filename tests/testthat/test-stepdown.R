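test_that("classification conserves the ledger total and splits by traceability", {
  rec <- make_toy_record()
  b <- classify_costs(rec)
  expect_equal(nrow(b$direct), 2)
  expect_equal(sum(b$direct$amount_ksh) + sum(b$indirect$amount_ksh), 1820000)

  all_direct <- rec$items |>
    dplyr::mutate(traceability = "direct", cost_unit_id = "outpatient_visit",
                  centre_id = NA_character_)
  b2 <- classify_costs(all_direct)
  expect_equal(nrow(b2$indirect), 0)
  expect_equal(sum(b2$direct$amount_ksh), sum(rec$items$amount_ksh))

  bad <- rec$items
  bad$cost_unit_id[bad$traceability == "direct"] <- NA
  expect_error(classify_costs(bad), "cost-unit id")
})

test_that("support centres close largest-first with id tie-break, or as listed", {
  centres <- tibble::tibble(centre_id = c("A", "B", "F1"),
                            kind = c("support", "support", "final"))
  tot <- tibble::tibble(centre_id = c("A", "B"), amount_ksh = c(500, 700))
  expect_equal(order_support_centres(centres, allocation_config(), tot),
               c("B", "A"))
  tot_tie <- tibble::tibble(centre_id = c("A", "B"), amount_ksh = c(500, 500))
  expect_equal(order_support_centres(centres, allocation_config(), tot_tie),
               c("A", "B"))
  cfg <- allocation_config("explicit_list", explicit_order = c("A", "B"))
  expect_equal(order_support_centres(centres, cfg, tot), c("A", "B"))
  cfg_bad <- allocation_config("explicit_list", explicit_order = c("A"))
  expect_error(order_support_centres(centres, cfg_bad, tot), "exactly once")
})

test_that("one support centre splits 600 over 2:1 weights as 400/200", {
  centres <- tibble::tibble(
    centre_id = c("S", "F1", "F2"), name = centre_id,
    kind = c("support", "final", "final"),
    output_measure = c("none", "outpatient_visits", "outpatient_visits"),
    output_count = c(0, 10, 10))
  items <- tibble::tibble(centre_id = "S", cost_unit_id = NA_character_,
                          category = "other_recurrent", year = "y",
                          amount_ksh = 600, traceability = "indirect")
  cfg <- allocation_config(basis_map = list(
    S = list(kind = "explicit_weights", weights = c(F1 = 2, F2 = 1))))
  res <- stepdown_allocate(classify_costs(items), cfg, centres = centres)
  tot <- tidy(res) |> dplyr::group_by(centre_id) |>
    dplyr::summarise(amount = sum(amount_ksh))
  expect_equal(tot$amount[tot$centre_id == "F1"], 400)
  expect_equal(tot$amount[tot$centre_id == "F2"], 200)
})

test_that("the cascade accumulates before closing: 4-centre worked example", {
  # S1 (300) closes first over equal weights {S2, F}; S2 then holds
  # 100 + 150 = 250 and passes it all to F: F = 150 + 250 + own 300 = 700
  centres <- tibble::tibble(
    centre_id = c("S1", "S2", "F"), name = centre_id,
    kind = c("support", "support", "final"),
    output_measure = c("none", "none", "outpatient_visits"),
    output_count = c(0, 0, 10))
  items <- tibble::tibble(
    centre_id = c("S1", "S2", "F"), cost_unit_id = NA_character_,
    category = "other_recurrent", year = "y",
    amount_ksh = c(300, 100, 300), traceability = "indirect")
  eq <- function(ids) stats::setNames(rep(1, length(ids)), ids)
  cfg <- allocation_config(
    ordering = "explicit_list", explicit_order = c("S1", "S2"),
    basis_map = list(
      S1 = list(kind = "explicit_weights", weights = c(S2 = 1, F = 1)),
      S2 = list(kind = "explicit_weights", weights = c(F = 1))))
  res <- stepdown_allocate(classify_costs(items), cfg, centres = centres)
  expect_equal(sum(tidy(res)$amount_ksh), 700)
  expect_equal(sum(res$trace$amount_ksh[res$trace$source == "S2"]), 250)
  expect_equal(glance(res)$conservation_error, 0)
})

test_that("zero support centres leave final centres with their own costs", {
  centres <- tibble::tibble(centre_id = c("F1", "F2"), name = centre_id,
                            kind = "final",
                            output_measure = "outpatient_visits",
                            output_count = c(10, 10))
  items <- tibble::tibble(centre_id = c("F1", "F2"),
                          cost_unit_id = NA_character_,
                          category = "staffing", year = "y",
                          amount_ksh = c(111, 222), traceability = "indirect")
  res <- stepdown_allocate(classify_costs(items), allocation_config(),
                           centres = centres)
  tot <- tidy(res) |> dplyr::group_by(centre_id) |>
    dplyr::summarise(amount = sum(amount_ksh))
  expect_equal(tot$amount, c(111, 222))
})

test_that("an all-zero basis over the remaining receivers is an error naming the centre", {
  centres <- tibble::tibble(centre_id = c("S", "F"), name = centre_id,
                            kind = c("support", "final"),
                            output_measure = c("none", "outpatient_visits"),
                            output_count = c(0, 10))
  items <- tibble::tibble(centre_id = "S", cost_unit_id = NA_character_,
                          category = "fixed", year = "y", amount_ksh = 100,
                          traceability = "indirect")
  # the final centre has zero own indirect cost, so direct_cost_share fails
  expect_error(
    stepdown_allocate(classify_costs(items), allocation_config(),
                      centres = centres),
    "'S'.*zero weight")
})

test_that("engine matches the brute-force oracle exactly on small instances", {
  set.seed(2024)
  for (case in 1:300) {
    inst <- random_stepdown_instance(sample(1:4, 1), sample(1:3, 1))
    both <- run_both_allocators(inst)
    expect_equal(both$engine[names(both$oracle)], both$oracle,
                 tolerance = 1e-12)
  }
})

test_that("conservation and category preservation hold on random instances", {
  set.seed(515)
  for (case in 1:60) {
    inst <- random_stepdown_instance(sample(0:7, 1), sample(1:4, 1))
    res <- stepdown_allocate(classify_costs(inst$items),
                             allocation_config(), centres = inst$centres)
    total_in <- sum(inst$items$amount_ksh)
    expect_lt(abs(sum(res$final_totals$amount_ksh) - total_in) / total_in, 1e-6)
    by_cat_in <- tapply(inst$items$amount_ksh, inst$items$category, sum)
    by_cat_out <- tapply(res$final_totals$amount_ksh,
                         res$final_totals$category, sum)
    expect_equal(by_cat_out[names(by_cat_in)], by_cat_in, tolerance = 1e-9)
  }
})

test_that("closure order changes final totals but never their sum", {
  set.seed(99)
  inst <- random_stepdown_instance(4, 3)
  perms <- list(inst$sup_ids, rev(inst$sup_ids),
                inst$sup_ids[c(2, 4, 1, 3)], inst$sup_ids[c(3, 1, 4, 2)])
  sums <- vapply(perms, function(p) {
    sum(run_both_allocators(inst, order = p)$engine)
  }, numeric(1))
  expect_equal(max(sums) - min(sums), 0, tolerance = 1e-8)
})

test_that("unit costs divide service-group totals by outputs and scale inversely", {
  rec <- make_toy_record()
  res <- stepdown_allocate(rec)
  u <- unit_costs(res, rec)
  expect_setequal(u$measure, c("outpatient_visit", "admission", "bed_day"))
  # conservation: unit cost x output re-sums to the ledger total
  op <- u[u$measure == "outpatient_visit", ]
  bd <- u[u$measure == "bed_day", ]
  expect_equal(op$unit_cost_ksh * op$output + bd$unit_cost_ksh * bd$output,
               sum(rec$items$amount_ksh))
  # homogeneity: doubling every output halves every unit cost
  rec2 <- rec
  rec2$statistics <- lapply(rec$statistics, function(x) x * 2)
  u2 <- unit_costs(res, rec2)
  expect_equal(u2$unit_cost_ksh, u$unit_cost_ksh / 2)
  # direct + indirect decompose the unit cost
  expect_equal(u$direct_ksh + u$indirect_ksh, u$unit_cost_ksh)
  expect_equal(u$fixed_ksh + u$variable_ksh, u$unit_cost_ksh)
})

test_that("a final centre with cost but no output is flagged, not divided", {
  rec <- make_toy_record()
  rec$statistics$outpatient_visits <- 0
  res <- stepdown_allocate(rec)
  expect_error(unit_costs(res, rec), class = "khscm_unit_cost_error")
})

test_that("simple quotient unit costs: 10,000 over 50 visits is 200 per visit", {
  centres <- tibble::tibble(centre_id = "OPD", name = "OPD", kind = "final",
                            output_measure = "outpatient_visits",
                            output_count = 50)
  items <- tibble::tibble(centre_id = "OPD", cost_unit_id = NA_character_,
                          category = "staffing", year = "y",
                          amount_ksh = 10000, traceability = "indirect")
  res <- stepdown_allocate(classify_costs(items), allocation_config(),
                           centres = centres)
  u <- unit_costs(res, list(outpatient_visits = 50, admissions = 0, bed_days = 0))
  expect_equal(u$unit_cost_ksh, 200)
})

test_that("published unit-cost pairs reproduce their printed 1-dp ratios", {
  ratios <- function(adm, bd, visit = NA) {
    unit_cost_ratios(tibble::tibble(
      measure = c("admission", "bed_day", "outpatient_visit"),
      unit_cost_ksh = c(adm, bd, visit)))
  }
  expect_equal(ratios(12970, 2186)$admission_per_bedday, 5.9)
  expect_equal(ratios(48474, 4921)$admission_per_bedday, 9.9)
  expect_equal(ratios(3500, 3500, 223)$bedday_per_visit, 15.7)
  expect_equal(ratios(100, 100, 100)$admission_per_bedday, 1.0)
  # missing inpatient costs give NA, not zero
  expect_true(is.na(ratios(NA, NA, 174)$admission_per_bedday))
})
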
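# Test helpers: an independent brute-force step-down oracle, random instance
# builders, and small fixture constructors. The oracle deliberately shares no
# code with stepdown_allocate(): plain lists and nested loops.

# Brute-force sequential allocator. `own` is a named list: centre id ->
# named numeric vector of category amounts; `kind` a named character vector
# ("support"/"final"); `order` the closure order; `weights_fun(open_ids)`
# returns the receiver weights for a closing centre.
oracle_stepdown <- function(own, kind, order, weights_fun) {
  acc <- own
  open <- names(kind)
  for (src in order) {
    open <- setdiff(open, src)
    amt <- acc[[src]]
    if (sum(amt) == 0) next
    w <- weights_fun(src, open)
    stopifnot(sum(w) > 0)
    for (i in seq_along(open)) {
      rec <- open[i]
      acc[[rec]] <- acc[[rec]] + amt * w[i] / sum(w)
    }
    acc[[src]] <- amt * 0
  }
  acc[names(kind)[kind == "final"]]
}

# random step-down instance: n_support support centres, n_final final
# centres, category amounts drawn uniformly; explicit weights per closure so
# the oracle and engine share only the instance definition
random_stepdown_instance <- function(n_support, n_final) {
  cats <- c("drugs_supplies", "staffing", "other_recurrent", "fixed")
  sup_ids <- sprintf("S%02d", seq_len(n_support))
  fin_ids <- sprintf("F%02d", seq_len(n_final))
  ids <- c(sup_ids, fin_ids)
  own <- lapply(ids, function(i) {
    stats::setNames(round(stats::runif(4, 0, 1000), 2), cats)
  })
  names(own) <- ids
  # ensure final centres carry some weight for direct_cost_share
  for (f in fin_ids) own[[f]]["staffing"] <- own[[f]]["staffing"] + 10
  centres <- tibble::tibble(
    centre_id = ids,
    name = ids,
    kind = c(rep("support", n_support), rep("final", n_final)),
    output_measure = c(rep("none", n_support),
                       rep("outpatient_visits", n_final)),
    output_count = c(rep(0, n_support), rep(100, n_final))
  )
  items <- dplyr::bind_rows(lapply(ids, function(i) {
    tibble::tibble(centre_id = i, cost_unit_id = NA_character_,
                   category = cats, year = "y",
                   amount_ksh = as.numeric(own[[i]]),
                   traceability = "indirect")
  }))
  list(own = own, centres = centres, items = items,
       sup_ids = sup_ids, fin_ids = fin_ids)
}

# run both paths with the package's default basis (receiver's own indirect
# cost before allocation) and return the final totals from each
run_both_allocators <- function(inst, order = NULL) {
  cfg <- if (is.null(order)) {
    allocation_config()
  } else {
    allocation_config("explicit_list", explicit_order = order)
  }
  buckets <- classify_costs(inst$items)
  res <- stepdown_allocate(buckets, cfg, centres = inst$centres)

  own_tot <- vapply(inst$own, sum, numeric(1))
  kind <- stats::setNames(inst$centres$kind, inst$centres$centre_id)
  oracle_order <- if (is.null(order)) {
    sup <- inst$sup_ids
    sup[order(-own_tot[sup], sup)]
  } else order
  orc <- oracle_stepdown(inst$own, kind, oracle_order,
                         weights_fun = function(src, open) own_tot[open])
  eng <- res$final_totals |>
    dplyr::group_by(centre_id) |>
    dplyr::summarise(amount_ksh = sum(amount_ksh), .groups = "drop")
  list(engine = stats::setNames(eng$amount_ksh, eng$centre_id),
       oracle = vapply(orc, sum, numeric(1)),
       result = res)
}

# a small single-facility record built in code (1 support, 2 final)
make_toy_record <- function() {
  centres <- tibble::tibble(
    centre_id = c("ADMIN", "OPD", "WARD"),
    name = c("Administration", "OPD", "Ward"),
    kind = c("support", "final", "final"),
    output_measure = c("none", "outpatient_visits", "bed_days"),
    output_count = c(0, 5000, 3600)
  )
  items <- tibble::tibble(
    centre_id = c("ADMIN", "OPD", "WARD", NA, NA),
    cost_unit_id = c(NA, NA, NA, "outpatient_visit", "bed_day"),
    category = c("other_recurrent", "staffing", "staffing",
                 "drugs_supplies", "drugs_supplies"),
    year = "2006/2007",
    amount_ksh = c(400000, 500000, 700000, 100000, 120000),
    traceability = c("indirect", "indirect", "indirect", "direct", "direct")
  )
  facility_record(
    id = "toy", level = "3", trustee = "public", beds = 12,
    centres = centres, items = items,
    statistics = list(outpatient_visits = 5000, admissions = 600,
                      bed_days = 3600, catchment_population = 25000)
  )
}

# small generator plan (a public district hospital stratum and a private
# district stratum, two facilities each) for fast end-to-end tests
small_plan <- function() {
  plan <- strata_plan()
  plan <- plan[plan$stratum %in% c("district_hospital_public",
                                   "district_hospital_private",
                                   "health_centre_public",
                                   "district_administration"), ]
  plan$n <- c(2L, 2L, 2L, 1L)
  plan
}

small_sample <- function(seed = 1) {
  generate_sample(generator_config(small_plan()), seed = seed)
}
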
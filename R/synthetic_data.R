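# Seeded synthetic facility sample generator. Emulates a stratified national
# facility sample (levels of care x trustee), with log-normal per-category
# cost scales per stratum (private strata more dispersed than public ones),
# two ledger years so the inflation-averaging path is exercised, occupancy
# distributions per stratum, exit interviews and treatment schemes. Scale
# defaults are set so the sample aggregates near the bundled national cost
# matrix; calibrate_to_matrix() closes the remaining stochastic gap.

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Stratified facility sampling plan
#'
#' The default plan mirrors the analysed national study sample: 154 units
#' across levels 2-6, nursing homes and district administration, split 85
#' public / 35 FBO-NGO / 34 private by trustee. The extended plan adds the
#' singleton strata needed to cover every row of the national cost matrix
#' (community services, a public nursing home, the ministry) and splits
#' administration into district and provincial offices.
#'
#' @param extended add the matrix-only strata (default `FALSE`).
#' @return tibble `stratum`, `level`, `trustee`, `trustee_group`, `n`.
#' @export
strata_plan <- function(extended = FALSE) {
  plan <- tibble::tribble(
    ~stratum,                            ~level,           ~trustee,  ~trustee_group, ~n,
    "dispensary_public",                 "2",              "public",  "public",   20L,
    "health_centre_public",              "3",              "public",  "public",   27L,
    "district_hospital_public",          "4",              "public",  "public",   20L,
    "provincial_hospital_public",        "5",              "public",  "public",    7L,
    "tertiary_hospital_public",          "6",              "public",  "public",    2L,
    "dispensary_health_centre_fbo_ngo",  "2",              "fbo_ngo", "fbo_ngo",  24L,
    "district_hospital_fbo_ngo",         "4",              "fbo_ngo", "fbo_ngo",  10L,
    "nursing_home_fbo_ngo",              "nursing_home",   "fbo_ngo", "fbo_ngo",   1L,
    "dispensary_health_centre_private",  "2",              "private", "private",  10L,
    "district_hospital_private",         "4",              "private", "private",  11L,
    "tertiary_hospital_private",         "6",              "private", "private",   1L,
    "nursing_home_other",                "nursing_home",   "private", "other",    12L,
    "district_administration",           "admin_district", "public",  "administration", 9L
  )
  if (extended) {
    plan$n[plan$stratum == "district_administration"] <- 7L
    plan <- bind_rows(plan, tibble::tribble(
      ~stratum,                    ~level,           ~trustee, ~trustee_group, ~n,
      "provincial_administration", "admin_province", "public", "administration", 2L,
      "community_public",          "community",      "public", "public", 1L,
      "nursing_home_public",       "nursing_home",   "public", "public", 1L,
      "ministry",                  "ministry",       "public", "administration", 1L
    ))
  }
  plan
}

# per-stratum occupancy distribution, average length of stay and (for
# strata absent from the published unit-cost table) synthetic unit costs
# used to derive service volumes; public district hospitals run over-full
# (107%), provincial at 90%, private hospitals well below capacity
STRATUM_OCCUPANCY <- tibble::tribble(
  ~stratum,                           ~occ_mean, ~occ_sd, ~alos_default, ~cpv_default, ~cpbd_default,
  "dispensary_public",                       0,      0,      0,   NA,   NA,
  "health_centre_public",                 0.35,   0.08,    1.0,   NA,   NA,
  "district_hospital_public",             1.07,   0.10,    5.9,   NA,   NA,
  "provincial_hospital_public",           0.90,   0.08,    6.9,   NA,   NA,
  "tertiary_hospital_public",             0.95,   0.05,    9.9,   NA,   NA,
  "dispensary_health_centre_fbo_ngo",     0.30,   0.08,    0.5,   NA,   NA,
  "district_hospital_fbo_ngo",            0.60,   0.10,    4.0,   NA,   NA,
  "nursing_home_fbo_ngo",                 0.50,   0.10,    3.0,  800, 4000,
  "dispensary_health_centre_private",     0.30,   0.08,    0.5,   NA,   NA,
  "district_hospital_private",            0.45,   0.10,    5.7,   NA,   NA,
  "tertiary_hospital_private",            0.50,   0.08,    5.2,   NA,   NA,
  "nursing_home_other",                   0.45,   0.10,    3.0,  800, 4000,
  "nursing_home_public",                  0.50,   0.10,    3.0,  800, 4000,
  "district_administration",                 0,      0,      0,   NA,   NA,
  "provincial_administration",               0,      0,      0,   NA,   NA,
  "community_public",                        0,      0,      0,   NA,   NA,
  "ministry",                                0,      0,      0,   NA,   NA
)

#' Per-stratum service profiles for the generator
#'
#' Derives each stratum's typical service volumes from the bundled national
#' cost matrix and published average unit costs, so that synthetic unit
#' costs come out at realistic magnitudes: the mean facility cost of the
#' stratum (cell total / facility count) is split half outpatient, half
#' inpatient (all outpatient where there is no inpatient care) and divided
#' by the published cost per visit and per bed-day to give annual visits and
#' bed-days; beds follow from the stratum's mean occupancy, admissions from
#' the published admission/bed-day cost ratio (an average-length-of-stay
#' proxy). Occupancy distributions are model defaults.
#'
#' @param plan a [strata_plan()].
#' @param matrix national cost matrix, default [kenya_cost_matrix()].
#' @param unit_cost_table published unit costs, default [kenya_unit_costs()].
#' @param ksh_per_eur exchange rate.
#' @return tibble `stratum`, `beds`, `occ_mean`, `occ_sd`, `visits`, `alos`.
#' @export
stratum_service_profiles <- function(plan, matrix = kenya_cost_matrix(),
                                     unit_cost_table = kenya_unit_costs(),
                                     ksh_per_eur = 90.66) {
  mt <- as_tibble(matrix)
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    p <- plan[i, ]
    occ <- STRATUM_OCCUPANCY[STRATUM_OCCUPANCY$stratum == p$stratum, ]
    if (nrow(occ) == 0) {
      occ <- tibble(occ_mean = 0.5, occ_sd = 0.1, alos_default = 3,
                    cpv_default = 800, cpbd_default = 4000)
    }
    uc <- unit_cost_table[unit_cost_table$stratum == p$stratum, ]
    cpv <- if (nrow(uc) == 1) uc$cost_per_outpatient_visit else occ$cpv_default
    cpbd <- if (nrow(uc) == 1) uc$cost_per_bedday else occ$cpbd_default
    alos <- if (nrow(uc) == 1 && !is.na(uc$cost_per_admission) && !is.na(cpbd)) {
      uc$cost_per_admission / cpbd
    } else occ$alos_default
    cell <- mt[mt$stratum == p$stratum, , drop = FALSE]
    mean_cost <- if (nrow(cell) == 1) cell$total * ksh_per_eur / max(p$n, 1) else 0
    inpatient <- !is.na(cpbd) && occ$occ_mean > 0 && mean_cost > 0
    out_share <- if (inpatient) 0.5 else 1
    visits <- if (!is.na(cpv) && cpv > 0 && mean_cost > 0) {
      round(mean_cost * out_share / cpv)
    } else 0
    if (inpatient) {
      bed_days <- mean_cost * (1 - out_share) / cpbd
      beds <- max(1, ceiling(bed_days / (365 * occ$occ_mean)))
    } else {
      beds <- 0
    }
    tibble(stratum = p$stratum, beds = beds, occ_mean = occ$occ_mean,
           occ_sd = occ$occ_sd, visits = visits,
           alos = if (is.na(alos)) 0 else alos)
  })
  bind_rows(rows)
}

# log-normal dispersion by trustee: the private and not-for-profit sectors
# show a much wider spread of cost per service unit than the public sector
SDLOG_BY_TRUSTEE <- c(public = 0.30, fbo_ngo = 0.60, private = 0.90)

default_cost_scales <- function(plan, matrix = kenya_cost_matrix(),
                                ksh_per_eur = 90.66) {
  mt <- as_tibble(matrix)
  rows <- lapply(seq_len(nrow(plan)), function(i) {
    p <- plan[i, ]
    cell <- mt[mt$stratum == p$stratum, , drop = FALSE]
    out <- tibble(stratum = p$stratum, category = COST_CATEGORIES,
                  meanlog = NA_real_,
                  sdlog = unname(SDLOG_BY_TRUSTEE[p$trustee]))
    if (nrow(cell) == 1) {
      for (k in seq_along(COST_CATEGORIES)) {
        eur <- cell[[COST_CATEGORIES[k]]]
        if (!is.na(eur) && eur > 0) {
          mean_ksh <- eur * ksh_per_eur / p$n
          out$meanlog[k] <- log(mean_ksh) - out$sdlog[k]^2 / 2
        }
      }
    }
    out
  })
  bind_rows(rows)
}

#' Generator configuration
#'
#' @param plan a [strata_plan()] (counts per stratum).
#' @param scales per-stratum log-normal cost scales: tibble `stratum`,
#'   `category`, `meanlog`, `sdlog` (Ksh, later ledger year). `NA` meanlog
#'   means the stratum incurs no cost in that category. Defaults are set so
#'   each stratum's expected aggregate matches the bundled national matrix,
#'   with trustee-specific dispersion (private > FBO/NGO > public).
#' @param exit_params exit-interview parameters: `n`, per-trustee mean
#'   outside drug cost (public highest — stock-outs), `sdlog`,
#'   `outpatient_share`, mean `user_fees` and `transport`.
#' @param profiles per-stratum service-volume profiles, default
#'   [stratum_service_profiles()].
#' @param inflation annual inflation between the two ledger years.
#' @param ksh_per_eur exchange rate.
#' @return a `generator_config` object.
#' @export
generator_config <- function(plan = strata_plan(),
                             scales = default_cost_scales(plan),
                             profiles = stratum_service_profiles(plan),
                             exit_params = list(
                               n = 1369,
                               outside_drug_mean = c(public = 450, fbo_ngo = 300,
                                                     private = 150),
                               sdlog = 0.8, outpatient_share = 0.7,
                               user_fee_mean = 120, transport_mean = 80),
                             inflation = 0.05, ksh_per_eur = 90.66) {
  if (any(plan$n < 0)) abort("stratum counts must be >= 0")
  if (any(scales$sdlog <= 0)) abort("sdlog must be > 0")
  structure(list(plan = plan, scales = scales, profiles = profiles,
                 exit_params = exit_params,
                 inflation = inflation, ksh_per_eur = ksh_per_eur),
            class = "generator_config")
}

# fraction of drugs cost attached directly to cost units; the rest is
# indirect on the centres where it occurs
DIRECT_DRUG_SHARE <- 0.2

generate_one_facility <- function(stratum, level, trustee, idx, scales,
                                  profiles, inflation) {
  prof <- profiles[profiles$stratum == stratum, ]
  sc <- scales[scales$stratum == stratum, ]
  sc <- sc[match(COST_CATEGORIES, sc$category), ]

  # cost draws: always consume 4 normals so the RNG stream is invariant to
  # which cells are active (calibration rescales without disturbing draws)
  z <- stats::rnorm(4)
  y2 <- ifelse(is.na(sc$meanlog), 0, exp(sc$meanlog + sc$sdlog * z))
  names(y2) <- COST_CATEGORIES
  # earlier ledger year sits 2-12% below the later one (nominal growth)
  y1 <- y2 * stats::runif(1, 0.88, 0.98)
  occ <- min(max(stats::rnorm(1, prof$occ_mean, prof$occ_sd), 0.05), 1.40)
  visit_noise <- exp(stats::rnorm(1, 0, 0.25))

  beds <- prof$beds
  service <- prof$visits > 0 || beds > 0
  visits <- if (prof$visits > 0) round(prof$visits * visit_noise) else 0
  bed_days <- if (beds > 0) max(1, round(beds * 365 * occ)) else 0
  admissions <- if (beds > 0) max(1, round(bed_days / prof$alos)) else 0

  id <- sprintf("%s_%03d", stratum, idx)
  if (!service) {
    centres <- tibble(centre_id = "ADMIN", name = "Administration",
                      kind = "support", output_measure = "none",
                      output_count = 0, staff_count = 5, floor_area = 120)
    items <- make_items(list(ADMIN = 1), y1, y2, direct = NULL)
  } else {
    inpatient <- beds > 0
    centres <- bind_rows(
      tibble(centre_id = "ADMIN", name = "Administration", kind = "support",
             output_measure = "none", output_count = 0,
             staff_count = 3 + beds %/% 40, floor_area = 60 + beds),
      if (inpatient) tibble(centre_id = "KITCHEN", name = "Kitchen and laundry",
                            kind = "support", output_measure = "none",
                            output_count = 0, staff_count = 2 + beds %/% 60,
                            floor_area = 40 + beds / 2),
      tibble(centre_id = "OPD", name = "Outpatient department", kind = "final",
             output_measure = "outpatient_visits", output_count = visits,
             staff_count = 4 + visits %/% 20000, floor_area = 100),
      if (inpatient) tibble(centre_id = "WARD", name = "General ward",
                            kind = "final", output_measure = "bed_days",
                            output_count = bed_days,
                            staff_count = 4 + beds %/% 10, floor_area = 20 * beds)
    )
    # indirect split: administration 12%, hotel services 8% (if inpatient),
    # remainder to OPD/WARD at the national 53/47 outpatient/inpatient split
    if (inpatient) {
      rest <- 0.80
      split <- list(ADMIN = 0.12, KITCHEN = 0.08,
                    OPD = rest * 0.53, WARD = rest * 0.47)
      direct <- list(outpatient_visit = 0.53, bed_day = 0.47)
    } else {
      split <- list(ADMIN = 0.12, OPD = 0.88)
      direct <- list(outpatient_visit = 1)
    }
    items <- make_items(split, y1, y2, direct)
  }

  assets <- make_assets(y2[["fixed"]], beds)
  payroll <- make_payroll(y2[["staffing"]])

  facility_record(
    id = id, level = level, trustee = trustee,
    location = if (idx %% 3 == 0) "urban" else "rural",
    province = c("Central", "Coast", "Nyanza", "Rift Valley",
                 "Eastern", "Western", "Nairobi")[(idx %% 7) + 1],
    beds = beds, centres = centres, items = items,
    statistics = list(outpatient_visits = visits, admissions = admissions,
                      bed_days = bed_days,
                      catchment_population = max(1000, visits * 3)),
    assets = assets, payroll = payroll, stratum = stratum
  )
}

make_items <- function(split, y1, y2, direct) {
  rows <- list()
  years <- list(`2005/2006` = y1, `2006/2007` = y2)
  for (yr in names(years)) {
    y <- years[[yr]]
    for (cat in COST_CATEGORIES) {
      amt <- y[[cat]]
      if (amt <= 0) next
      dshare <- if (cat == "drugs_supplies" && !is.null(direct)) DIRECT_DRUG_SHARE else 0
      for (cid in names(split)) {
        rows[[length(rows) + 1L]] <- tibble(
          centre_id = cid, cost_unit_id = NA_character_, category = cat,
          year = yr, amount_ksh = amt * (1 - dshare) * split[[cid]],
          traceability = "indirect")
      }
      if (dshare > 0) {
        for (cu in names(direct)) {
          rows[[length(rows) + 1L]] <- tibble(
            centre_id = NA_character_, cost_unit_id = cu,
            category = cat, year = yr, amount_ksh = amt * dshare * direct[[cu]],
            traceability = "direct")
        }
      }
    }
  }
  bind_rows(rows)
}

make_assets <- function(fixed_annual, beds) {
  if (fixed_annual <= 0) return(NULL)
  # an asset register whose straight-line charges reproduce the fixed draw:
  # 60% buildings (30y), 25% medical equipment (8y), 15% general (10y)
  bld_charge <- 0.6 * fixed_annual
  tibble(
    asset_class = c("building", "medical_equipment", "general_equipment"),
    initial_value_ksh = c(NA, 0.25 * fixed_annual * 8, 0.15 * fixed_annual * 10),
    floor_area_sqm = c(bld_charge * 30 / 2000, NA, NA),
    unit_build_cost_ksh = c(2000, NA, NA),
    lifetime_years = c(NA, NA, NA),
    condition_adjustment = c(1, 1, 1)
  )
}

make_payroll <- function(staffing_annual) {
  if (staffing_annual <= 0) return(NULL)
  # per-person positions: the cadre wage bill divided over a headcount set
  # by a typical full remuneration of ~800k Ksh/year
  shares <- c(nurse = 0.45, clinical_officer = 0.25, doctor = 0.15,
              support_staff = 0.15)
  typical <- c(nurse = 700000, clinical_officer = 900000, doctor = 2000000,
               support_staff = 350000)
  headcount <- pmax(1, round(staffing_annual * shares / typical))
  tibble(
    cadre = names(shares),
    headcount = headcount,
    annual_base_ksh = staffing_annual * shares * 0.75 / headcount,
    annual_allowances_ksh = staffing_annual * shares * 0.25 / headcount,
    working_days = 220, direct_hours = 6
  )
}

#' Generate a synthetic facility sample
#'
#' Draws one facility per planned slot: per-category annual costs for two
#' consecutive ledger years from the stratum's log-normal scales, a
#' stratum-typical bed stock, occupancy and outpatient volume, a cost-centre
#' chart (administration and hotel-services support centres, OPD and ward
#' final centres), an asset register and payroll consistent with the drawn
#' fixed and staffing costs, plus exit interviews and a synthetic treatment
#' scheme collection. Identical seed and config give identical output.
#'
#' @param config a [generator_config()].
#' @param seed integer seed.
#' @return a `khscm_sample`: list with `facilities` (list of
#'   [facility_record()]), `exit_interviews`, `schemes`, `scheme_components`,
#'   `price_list`, `config`, `seed`.
#' @export
generate_sample <- function(config = generator_config(), seed = 42) {
  plan <- config$plan
  with_seed(seed, {
    facilities <- list()
    for (i in seq_len(nrow(plan))) {
      p <- plan[i, ]
      if (p$n == 0) next
      for (j in seq_len(p$n)) {
        rec <- generate_one_facility(p$stratum, p$level, p$trustee, j,
                                     config$scales, config$profiles,
                                     config$inflation)
        facilities[[rec$id]] <- rec
      }
    }
    interviews <- generate_exit_interviews(config$exit_params$n,
                                           config$exit_params)
    sch <- synthetic_keph_schemes()
    structure(list(facilities = facilities, exit_interviews = interviews,
                   schemes = sch$schemes, scheme_components = sch$components,
                   price_list = synthetic_price_list(),
                   config = config, seed = seed),
              class = "khscm_sample")
  })
}

#' @export
print.khscm_sample <- function(x, ...) {
  plan <- x$config$plan
  cat(sprintf("<khscm_sample> %d facilities in %d strata (seed %d)\n",
              length(x$facilities), nrow(plan), x$seed))
  tg <- table(plan$trustee[rep(seq_len(nrow(plan)), plan$n)])
  cat("  by trustee:", paste(sprintf("%s %d", names(tg), tg), collapse = ", "), "\n")
  cat(sprintf("  exit interviews: %d\n", nrow(x$exit_interviews)))
  invisible(x)
}

#' Generate synthetic patient exit interviews
#'
#' Outside drug purchases are drawn log-normally with trustee-specific means
#' — highest for public facilities, where stock-outs push patients to
#' private pharmacies. User fees and transport are recorded but not used in
#' provider costing.
#'
#' @param n number of interviews.
#' @param params parameter list, see [generator_config()].
#' @param seed optional seed; when `NULL` the current RNG stream is used
#'   (as inside [generate_sample()]).
#' @return tibble `patient_type`, `outside_drug_cost`, `user_fees`,
#'   `transport_cost`, `level`, `trustee`.
#' @export
generate_exit_interviews <- function(n, params = generator_config()$exit_params,
                                     seed = NULL) {
  gen <- function() {
    if (n == 0) {
      return(tibble(patient_type = character(), outside_drug_cost = numeric(),
                    user_fees = numeric(), transport_cost = numeric(),
                    level = character(), trustee = character()))
    }
    trustee <- sample(TRUSTEES, n, replace = TRUE, prob = c(0.55, 0.20, 0.25))
    mu <- params$outside_drug_mean[trustee]
    sdl <- params$sdlog
    tibble(
      patient_type = ifelse(stats::runif(n) < params$outpatient_share,
                            "outpatient", "inpatient"),
      outside_drug_cost = stats::rlnorm(n, log(mu) - sdl^2 / 2, sdl),
      user_fees = stats::rlnorm(n, log(params$user_fee_mean) - 0.32, 0.8),
      transport_cost = stats::rlnorm(n, log(params$transport_mean) - 0.32, 0.8),
      level = sample(c("2", "3", "4", "5", "6"), n, replace = TRUE,
                     prob = c(0.35, 0.2, 0.3, 0.1, 0.05)),
      trustee = trustee
    )
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Synthetic price list
#'
#' Unit prices (Ksh) for the drug and laboratory codes used by the synthetic
#' treatment schemes, plus per-level standard equipment bundles. Synthetic:
#' invented plausible values, not a published ministry price list.
#'
#' @return list with `items` (named numeric) and `bundles`.
#' @export
synthetic_price_list <- function() {
  list(
    items = c(
      AL_tab = 30, ORS = 20, zinc = 15, amoxicillin = 8, iv_antibiotic = 350,
      delivery_kit = 800, gloves = 25, paracetamol = 3, iv_fluid = 180,
      malaria_rdt = 70, hb_test = 120, stool_test = 150, xray = 500,
      oxytocin = 90
    ),
    bundles = list(
      `2` = list(list(item_code = "gloves", quantity = 200)),
      `3` = list(list(item_code = "gloves", quantity = 600))
    )
  )
}

#' Synthetic treatment schemes for selected essential-package conditions
#'
#' A small, invented scheme collection (malaria by age group, diarrhoea with
#' dehydration, normal delivery, inpatient pneumonia) in actual and
#' normative variants; normative recipes are supersets of the actual ones
#' (actual resource use is depressed by stock-outs). Synthetic: plausible
#' recipes, not the expert-committee schemes.
#'
#' @return list with `schemes` (tibble `condition_id`, `condition`,
#'   `setting`, `variant`, `length_of_stay`) and `components` (tibble
#'   `condition_id`, `variant`, `age_group`, `component`, `code`,
#'   `quantity`).
#' @export
synthetic_keph_schemes <- function() {
  schemes <- tibble::tribble(
    ~condition_id, ~condition,        ~setting,     ~variant,    ~length_of_stay,
    1L, "malaria_uncomplicated",      "outpatient", "actual",    NA_real_,
    1L, "malaria_uncomplicated",      "outpatient", "normative", NA_real_,
    2L, "diarrhoea_dehydration",      "outpatient", "actual",    NA_real_,
    2L, "diarrhoea_dehydration",      "outpatient", "normative", NA_real_,
    3L, "normal_delivery",            "inpatient",  "actual",    2,
    3L, "normal_delivery",            "inpatient",  "normative", 2,
    4L, "pneumonia_severe",           "inpatient",  "actual",    5,
    4L, "pneumonia_severe",           "inpatient",  "normative", 5
  )
  comp <- tibble::tribble(
    ~condition_id, ~variant, ~age_group, ~component, ~code, ~quantity,
    1L, "actual",    "under5", "drug",  "AL_tab",        6,
    1L, "actual",    "under5", "lab",   "malaria_rdt",   1,
    1L, "actual",    "under5", "staff", "nurse",        15,
    1L, "actual",    "over5",  "drug",  "AL_tab",       24,
    1L, "actual",    "over5",  "lab",   "malaria_rdt",   1,
    1L, "actual",    "over5",  "staff", "nurse",        10,
    1L, "normative", "under5", "drug",  "AL_tab",        6,
    1L, "normative", "under5", "drug",  "paracetamol",   6,
    1L, "normative", "under5", "lab",   "malaria_rdt",   1,
    1L, "normative", "under5", "staff", "nurse",        20,
    1L, "normative", "under5", "staff", "clinical_officer", 10,
    1L, "normative", "over5",  "drug",  "AL_tab",       24,
    1L, "normative", "over5",  "drug",  "paracetamol",   9,
    1L, "normative", "over5",  "lab",   "malaria_rdt",   1,
    1L, "normative", "over5",  "staff", "nurse",        15,
    2L, "actual",    "under5", "drug",  "ORS",           2,
    2L, "actual",    "under5", "staff", "nurse",        15,
    2L, "normative", "under5", "drug",  "ORS",           2,
    2L, "normative", "under5", "drug",  "zinc",         10,
    2L, "normative", "under5", "lab",   "stool_test",    1,
    2L, "normative", "under5", "staff", "nurse",        20,
    3L, "actual",    NA,       "drug",  "delivery_kit",  1,
    3L, "actual",    NA,       "drug",  "oxytocin",      1,
    3L, "actual",    NA,       "staff", "nurse",       120,
    3L, "normative", NA,       "drug",  "delivery_kit",  1,
    3L, "normative", NA,       "drug",  "oxytocin",      1,
    3L, "normative", NA,       "drug",  "gloves",        4,
    3L, "normative", NA,       "staff", "nurse",       180,
    3L, "normative", NA,       "staff", "doctor",       20,
    4L, "actual",    "under5", "drug",  "iv_antibiotic", 5,
    4L, "actual",    "under5", "drug",  "iv_fluid",      2,
    4L, "actual",    "under5", "lab",   "xray",          1,
    4L, "actual",    "under5", "staff", "nurse",        90,
    4L, "normative", "under5", "drug",  "iv_antibiotic", 7,
    4L, "normative", "under5", "drug",  "iv_fluid",      3,
    4L, "normative", "under5", "lab",   "xray",          1,
    4L, "normative", "under5", "lab",   "hb_test",       1,
    4L, "normative", "under5", "staff", "nurse",       120,
    4L, "normative", "under5", "staff", "doctor",       30
  )
  list(schemes = schemes, components = comp)
}

#' Aggregate a synthetic sample to a national cost matrix
#'
#' Annualizes each facility's two-year ledger (inflation-averaged), sums by
#' stratum and input category and expands by sampling weights.
#'
#' @param sample a `khscm_sample`.
#' @param weights optional sampling weights (see [national_totals()]).
#' @param currency `"KSH"` (default) or `"EUR"`.
#' @return a [cost_matrix()].
#' @export
aggregate_sample <- function(sample, weights = NULL, currency = "KSH") {
  plan <- sample$config$plan
  rows <- purrr::map(sample$facilities, function(rec) {
    ann <- annualize_ledger(rec, inflation = sample$config$inflation)
    ann$items |>
      group_by(.data$category) |>
      summarise(amount = sum(.data$amount_ksh), .groups = "drop") |>
      mutate(facility_id = rec$id, stratum = rec$stratum)
  })
  fr <- bind_rows(rows) |>
    left_join(plan[, c("stratum", "trustee_group")], by = "stratum")
  mat <- national_totals(fr, weights = weights, currency = "KSH")
  if (currency == "EUR") convert_matrix(mat, sample$config$ksh_per_eur) else mat
}

#' Calibrate the generator to a target cost matrix
#'
#' Rescales each stratum's log-normal location parameters so that the sample
#' generated under a given seed aggregates to the target matrix. Because a
#' location shift scales every draw of that cell multiplicatively without
#' disturbing the random stream, one deterministic rescaling pass
#' (`meanlog += log(target / actual)`) reproduces the target cell exactly
#' under the same seed; the function verifies all row and column margins
#' against the tolerance and errors with the achieved residuals otherwise.
#'
#' @param config a [generator_config()] whose plan covers every target row.
#' @param target a [cost_matrix()] (EUR or Ksh).
#' @param tolerance maximum relative margin residual, default 0.01. A
#'   stochastic generator cannot promise exactly zero; `tolerance <= 0` is an
#'   error.
#' @param seed seed the calibration is valid for.
#' @return the recalibrated `generator_config`, with a `residuals` attribute
#'   (named relative margin errors).
#' @export
calibrate_to_matrix <- function(config, target, tolerance = 0.01, seed = 42) {
  if (tolerance <= 0) {
    abort("tolerance must be > 0: the generator is stochastic and cannot hit a margin exactly to zero tolerance")
  }
  rate <- config$ksh_per_eur
  target_ksh <- if (attr(target, "currency") == "EUR") {
    convert_matrix(target, rate)
  } else target
  missing <- setdiff(target_ksh$stratum, config$plan$stratum)
  if (length(missing) > 0) {
    abort(sprintf("generator plan lacks target stratum(s): %s (use strata_plan(extended = TRUE))",
                  paste(missing, collapse = ", ")))
  }

  actual <- aggregate_sample(generate_sample(config, seed), currency = "KSH")
  scales <- config$scales
  tm <- as_tibble(target_ksh)
  am <- as_tibble(actual)
  for (i in seq_len(nrow(tm))) {
    st <- tm$stratum[i]
    arow <- am[am$stratum == st, , drop = FALSE]
    for (cat in COST_CATEGORIES) {
      tcell <- tm[[cat]][i]
      acell <- if (nrow(arow) == 1) arow[[cat]] else 0
      k <- which(scales$stratum == st & scales$category == cat)
      if (tcell > 0) {
        if (acell <= 0) {
          abort(sprintf("cannot calibrate %s/%s: target is positive but the generator draws no cost there",
                        st, cat))
        }
        scales$meanlog[k] <- scales$meanlog[k] + log(tcell / acell)
      } else if (acell > 0) {
        scales$meanlog[k] <- NA_real_
      }
    }
  }
  out <- config
  out$scales <- scales

  achieved <- aggregate_sample(generate_sample(out, seed), currency = "KSH")
  tmarg <- cost_matrix_margins(target_ksh)
  amarg <- cost_matrix_margins(achieved)
  rel <- function(a, t) abs(a - t) / ifelse(t == 0, 1, abs(t))
  res <- c(
    stats::setNames(rel(unname(amarg$rows[names(tmarg$rows)]), unname(tmarg$rows)),
                    paste0("row.", names(tmarg$rows))),
    stats::setNames(rel(unname(amarg$columns), unname(tmarg$columns)),
                    paste0("col.", names(tmarg$columns))),
    grand_total = rel(amarg$grand_total, tmarg$grand_total)
  )
  if (any(res > tolerance, na.rm = TRUE)) {
    worst <- sort(res, decreasing = TRUE)[1:5]
    abort(paste0("calibration failed to reach tolerance; worst residuals:\n",
                 paste(sprintf("  %s: %.4f", names(worst), worst), collapse = "\n")))
  }
  attr(out, "residuals") <- res
  out
}

#' Write / read a sample fixture directory
#'
#' Serializes a sample to the plain-text layout the pipeline consumes:
#' `facilities/<id>/` directories (see [write_facility()]),
#' `exit_interviews.csv`, `schemes.csv`, `scheme_components.csv`,
#' `price_list.json` and `plan.csv`.
#'
#' @param sample a `khscm_sample`.
#' @param dir target directory.
#' @return `dir` (write) or a `khscm_sample`-shaped list (read), where
#'   `config` holds only the plan.
#' @export
write_sample <- function(sample, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in sample$facilities) {
    write_facility(rec, file.path(dir, "facilities", rec$id))
  }
  readr::write_csv(sample$exit_interviews, file.path(dir, "exit_interviews.csv"))
  readr::write_csv(sample$schemes, file.path(dir, "schemes.csv"))
  readr::write_csv(sample$scheme_components, file.path(dir, "scheme_components.csv"))
  jsonlite::write_json(list(items = as.list(sample$price_list$items),
                            bundles = sample$price_list$bundles),
                       file.path(dir, "price_list.json"),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(sample$config$plan, file.path(dir, "plan.csv"))
  invisible(dir)
}

#' @rdname write_sample
#' @export
read_sample <- function(dir) {
  fac_dirs <- list.dirs(file.path(dir, "facilities"), recursive = FALSE)
  facilities <- lapply(fac_dirs, load_facility_ledger)
  names(facilities) <- vapply(facilities, function(r) r$id, character(1))
  plan <- read_csv_quiet(file.path(dir, "plan.csv"), readr::cols(
    stratum = readr::col_character(), level = readr::col_character(),
    trustee = readr::col_character(), trustee_group = readr::col_character(),
    n = readr::col_integer()))
  pl <- jsonlite::read_json(file.path(dir, "price_list.json"), simplifyVector = TRUE)
  structure(list(
    facilities = facilities,
    exit_interviews = read_csv_quiet(file.path(dir, "exit_interviews.csv"),
                                     readr::cols(patient_type = readr::col_character(),
                                                 level = readr::col_character(),
                                                 trustee = readr::col_character(),
                                                 .default = readr::col_double())),
    schemes = read_csv_quiet(file.path(dir, "schemes.csv"),
                             readr::cols(condition_id = readr::col_integer(),
                                         condition = readr::col_character(),
                                         setting = readr::col_character(),
                                         variant = readr::col_character(),
                                         length_of_stay = readr::col_double())),
    scheme_components = read_csv_quiet(file.path(dir, "scheme_components.csv"),
                                       readr::cols(condition_id = readr::col_integer(),
                                                   variant = readr::col_character(),
                                                   age_group = readr::col_character(),
                                                   component = readr::col_character(),
                                                   code = readr::col_character(),
                                                   quantity = readr::col_double())),
    price_list = list(items = unlist(pl$items), bundles = pl$bundles),
    config = list(plan = plan, inflation = 0.05, ksh_per_eur = 90.66),
    seed = NA_integer_
  ), class = "khscm_sample")
}
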
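# Annualization: turn raw expenditures, asset registers and payrolls into
# annual, inflation-consistent, currency-consistent costs.

# Default straight-line lifetimes (years) by asset class.
ASSET_LIFETIMES <- c(general_equipment = 10, medical_equipment = 8,
                     vehicle = 8, building = 30)

#' Model constants
#'
#' Default parameters of the costing model: straight-line asset lifetimes in
#' years (10 for general equipment, 8 for medical equipment, 8 for vehicles,
#' 30 for buildings), the standard annual inflation uplift (5%) applied when
#' averaging two fiscal years, the fixed Ksh/EUR exchange rate (90.66), and
#' the staff availability assumptions (220 working days/year, 6 direct-service
#' hours/day).
#'
#' @return named list of model constants.
#' @export
khscm_defaults <- function() {
  list(
    asset_lifetimes = ASSET_LIFETIMES,
    inflation = 0.05,
    ksh_per_eur = 90.66,
    working_days = 220,
    direct_hours_per_day = 6,
    standard_occupancy = 0.85
  )
}

#' Annual straight-line depreciation charge of an asset
#'
#' Assets depreciate linearly over their effective lifetime from full initial
#' value (no salvage value, no mid-year convention). The effective lifetime is
#' the class default (10/8/8/30 years for general equipment, medical
#' equipment, vehicles, buildings) or a per-asset override, multiplied by a
#' condition adjustment factor (e.g. 0.5 halves the remaining life of a
#' run-down building). Buildings may be valued as `floor_area` x
#' `unit_build_cost` instead of an explicit initial value.
#'
#' @param assets a data frame with columns `asset_class` (one of
#'   `general_equipment`, `medical_equipment`, `vehicle`, `building`),
#'   `initial_value_ksh` (may be `NA` for buildings given by area),
#'   and optionally `floor_area_sqm`, `unit_build_cost_ksh`,
#'   `lifetime_years` (override, `NA` for class default) and
#'   `condition_adjustment` (default 1).
#' @return the input as a tibble with columns `initial_value_ksh` (resolved),
#'   `effective_lifetime_years` and `annual_depreciation_ksh` added.
#' @examples
#' straight_line_depreciation(data.frame(
#'   asset_class = "medical_equipment", initial_value_ksh = 80000))
#' # 80000 / 8 = 10000 per year
#' @export
straight_line_depreciation <- function(assets) {
  assets <- as_tibble(assets)
  assert_has_columns(assets, "asset_class", "asset register")
  bad <- setdiff(unique(assets$asset_class), names(ASSET_LIFETIMES))
  if (length(bad) > 0) {
    abort(sprintf("unknown asset class(es): %s", paste(bad, collapse = ", ")))
  }
  if (!"initial_value_ksh" %in% names(assets)) assets$initial_value_ksh <- NA_real_
  if (!"floor_area_sqm" %in% names(assets)) assets$floor_area_sqm <- NA_real_
  if (!"unit_build_cost_ksh" %in% names(assets)) assets$unit_build_cost_ksh <- NA_real_
  if (!"lifetime_years" %in% names(assets)) assets$lifetime_years <- NA_real_
  if (!"condition_adjustment" %in% names(assets)) assets$condition_adjustment <- 1

  assets <- assets |>
    mutate(
      condition_adjustment = dplyr::coalesce(.data$condition_adjustment, 1),
      initial_value_ksh = dplyr::if_else(
        is.na(.data$initial_value_ksh) & .data$asset_class == "building",
        building_initial_cost(.data$floor_area_sqm, .data$unit_build_cost_ksh),
        .data$initial_value_ksh
      ),
      effective_lifetime_years =
        dplyr::coalesce(.data$lifetime_years,
                        unname(ASSET_LIFETIMES[.data$asset_class])) *
        .data$condition_adjustment
    )
  if (any(is.na(assets$initial_value_ksh) | assets$initial_value_ksh <= 0)) {
    abort("every asset needs initial_value_ksh > 0 (or building area and unit cost)")
  }
  if (any(assets$effective_lifetime_years <= 0)) {
    abort("effective asset lifetime must be > 0 after condition adjustment")
  }
  mutate(assets, annual_depreciation_ksh =
           .data$initial_value_ksh / .data$effective_lifetime_years)
}

#' Initial cost of a building from floor area
#'
#' @param floor_area_sqm floor area in square metres, > 0.
#' @param unit_build_cost_ksh regional building cost per square metre, > 0.
#' @return initial value in Ksh (`floor_area_sqm * unit_build_cost_ksh`).
#' @export
building_initial_cost <- function(floor_area_sqm, unit_build_cost_ksh) {
  if (any(!is.na(floor_area_sqm) & floor_area_sqm <= 0) ||
      any(!is.na(unit_build_cost_ksh) & unit_build_cost_ksh <= 0)) {
    abort("floor area and unit build cost must both be > 0")
  }
  floor_area_sqm * unit_build_cost_ksh
}

#' Inflation-adjusted two-year cost average
#'
#' Averages two consecutive fiscal years with the earlier year uplifted by a
#' standard inflation rate: `(cost_year1 * (1 + inflation) + cost_year2) / 2`.
#'
#' @param cost_year1 earlier-year cost (vectorised), >= 0.
#' @param cost_year2 later-year cost, >= 0.
#' @param inflation annual rate, default 0.05.
#' @return averaged cost on the later year's price level.
#' @export
inflation_average <- function(cost_year1, cost_year2, inflation = 0.05) {
  if (length(inflation) != 1L || is.na(inflation) || inflation < -1) {
    abort("`inflation` must be a single rate >= -1")
  }
  if (any(cost_year1 < 0, na.rm = TRUE) || any(cost_year2 < 0, na.rm = TRUE)) {
    abort("costs must be >= 0")
  }
  (cost_year1 * (1 + inflation) + cost_year2) / 2
}

#' Annualize a two-year facility ledger
#'
#' Collapses a ledger that reports two consecutive fiscal years into one
#' annual ledger by inflation-averaging each line item:
#' the earlier year is uplifted by the inflation rate and averaged with the
#' later year (see [inflation_average()]). Single-year ledgers pass through
#' unchanged. Fiscal-year labels are opaque; their order is alphabetical by
#' default and can be overridden.
#'
#' @param record a [facility_record()].
#' @param inflation annual rate, default 0.05.
#' @param year_order optional character vector giving the fiscal years in
#'   chronological order; defaults to `sort(unique(years))`.
#' @return the record with `items` collapsed to one `year = "annualized"`
#'   ledger.
#' @export
annualize_ledger <- function(record, inflation = 0.05, year_order = NULL) {
  items <- record$items
  years <- year_order %||% sort(unique(items$year))
  if (length(years) <= 1) return(record)
  if (length(years) > 2) {
    abort("only two-year ledgers are modelled; pass a pre-averaged ledger for longer series")
  }
  wide <- items |>
    group_by(.data$centre_id, .data$cost_unit_id, .data$category,
             .data$traceability, .data$year) |>
    summarise(amount_ksh = sum(.data$amount_ksh), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "year", values_from = "amount_ksh",
                       values_fill = 0)
  record$items <- wide |>
    mutate(amount_ksh = inflation_average(.data[[years[1]]], .data[[years[2]]],
                                          inflation),
           year = "annualized") |>
    select(all_of(c("centre_id", "cost_unit_id", "category", "year",
                    "amount_ksh", "traceability")))
  record
}

#' Convert Kenyan shillings to euro
#'
#' @param amount_ksh amount(s) in Ksh.
#' @param rate exchange rate in Ksh per EUR, default 90.66.
#' @return amount in EUR, unrounded (rounding is a reporting concern).
#' @export
convert_currency <- function(amount_ksh, rate = 90.66) {
  assert_scalar_number(rate, "rate", min = 0, strict_min = TRUE)
  amount_ksh / rate
}

#' Cost per minute of direct staff time
#'
#' Divides full remuneration (base salary plus allowances) by expected direct
#' service minutes per year. Defaults assume 220 working days/year and 6
#' direct-service hours/day, i.e. 79,200 minutes.
#'
#' @param payroll a data frame with columns `cadre`, `annual_base_ksh`,
#'   `annual_allowances_ksh`, and optionally `working_days` and
#'   `direct_hours` (defaults 220 and 6).
#' @return the payroll as a tibble with `minutes_per_year` and
#'   `cost_per_minute_ksh` columns added.
#' @examples
#' staff_minute_cost(data.frame(cadre = "nurse", annual_base_ksh = 792000,
#'                              annual_allowances_ksh = 0))
#' # 792000 / 79200 = 10 Ksh per minute
#' @export
staff_minute_cost <- function(payroll) {
  payroll <- as_tibble(payroll)
  assert_has_columns(payroll, c("cadre", "annual_base_ksh", "annual_allowances_ksh"),
                     "payroll")
  if (!"working_days" %in% names(payroll)) payroll$working_days <- 220
  if (!"direct_hours" %in% names(payroll)) payroll$direct_hours <- 6
  payroll <- payroll |>
    mutate(
      working_days = dplyr::coalesce(.data$working_days, 220),
      direct_hours = dplyr::coalesce(.data$direct_hours, 6),
      annual_allowances_ksh = dplyr::coalesce(.data$annual_allowances_ksh, 0)
    )
  with(payroll, {
    if (any(annual_base_ksh < 0) || any(annual_allowances_ksh < 0)) {
      abort("salaries and allowances must be >= 0")
    }
    if (any(working_days <= 0 | working_days > 365)) {
      abort("working_days must be in (0, 365]")
    }
    if (any(direct_hours <= 0 | direct_hours > 24)) {
      abort("direct_hours must be in (0, 24]")
    }
  })
  payroll |>
    mutate(
      minutes_per_year = .data$working_days * .data$direct_hours * 60,
      cost_per_minute_ksh =
        (.data$annual_base_ksh + .data$annual_allowances_ksh) / .data$minutes_per_year
    )
}

#' Impute the value of in-kind supplies
#'
#' Supplies received in kind (mainly pharmaceuticals) carry no ledger amount;
#' their value is imputed as quantity times the unit price from a price list
#' and returned as `drugs_supplies` cost items.
#'
#' @param inkind data frame with columns `item_code`, `quantity`, `centre_id`
#'   and optionally `year`.
#' @param prices a price list as returned by [read_price_list()] or a named
#'   numeric vector of unit prices by item code.
#' @return a tibble of cost items (`centre_id`, `cost_unit_id`, `category`,
#'   `year`, `amount_ksh`, `traceability`), one per in-kind record.
#' @export
impute_inkind <- function(inkind, prices) {
  inkind <- as_tibble(inkind)
  if (nrow(inkind) == 0) {
    return(tibble(centre_id = character(), cost_unit_id = character(),
                  category = character(), year = character(),
                  amount_ksh = numeric(), traceability = character()))
  }
  assert_has_columns(inkind, c("item_code", "quantity", "centre_id"), "in-kind records")
  price_map <- if (is.list(prices) && !is.null(prices$items)) prices$items else prices
  unpriced <- setdiff(unique(inkind$item_code), names(price_map))
  if (length(unpriced) > 0) {
    abort(sprintf("no price for in-kind item code(s): %s",
                  paste(unpriced, collapse = ", ")))
  }
  tibble(
    centre_id = inkind$centre_id,
    cost_unit_id = NA_character_,
    category = "drugs_supplies",
    year = if ("year" %in% names(inkind)) inkind$year else NA_character_,
    amount_ksh = inkind$quantity * unname(unlist(price_map)[inkind$item_code]),
    traceability = "indirect"
  )
}

#' Fill missing pay from the public salary scale
#'
#' Private and FBO/NGO payrolls sometimes lack salary data; the equivalent
#' public-sector salary for the cadre is assumed and the row is flagged as
#' imputed.
#'
#' @param payroll data frame with `cadre`, `annual_base_ksh`,
#'   `annual_allowances_ksh` (either may be `NA`).
#' @param public_scale data frame with `cadre`, `annual_base_ksh`,
#'   `annual_allowances_ksh` giving the public scale.
#' @return the payroll tibble with missing pay filled and a logical
#'   `pay_imputed` column.
#' @export
fallback_salary <- function(payroll, public_scale) {
  payroll <- as_tibble(payroll)
  public_scale <- as_tibble(public_scale)
  assert_has_columns(payroll, c("cadre", "annual_base_ksh"), "payroll")
  assert_has_columns(public_scale, c("cadre", "annual_base_ksh"), "public salary scale")
  if (!"annual_allowances_ksh" %in% names(payroll)) {
    payroll$annual_allowances_ksh <- NA_real_
  }
  if (!"annual_allowances_ksh" %in% names(public_scale)) {
    public_scale$annual_allowances_ksh <- 0
  }
  needs <- is.na(payroll$annual_base_ksh)
  missing_cadre <- setdiff(unique(payroll$cadre[needs]), public_scale$cadre)
  if (length(missing_cadre) > 0) {
    abort(sprintf("cadre(s) absent from the public salary scale: %s",
                  paste(missing_cadre, collapse = ", ")))
  }
  scale_base <- stats::setNames(public_scale$annual_base_ksh, public_scale$cadre)
  scale_allow <- stats::setNames(public_scale$annual_allowances_ksh, public_scale$cadre)
  payroll |>
    mutate(
      pay_imputed = needs,
      annual_allowances_ksh = dplyr::if_else(
        needs, unname(scale_allow[.data$cadre]),
        dplyr::coalesce(.data$annual_allowances_ksh, 0)),
      annual_base_ksh = dplyr::if_else(
        needs, unname(scale_base[.data$cadre]), .data$annual_base_ksh)
    )
}
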
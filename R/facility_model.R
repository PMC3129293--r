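# Facility domain model: a facility record bundles the cost ledger, cost
# centres, service statistics, asset register and payroll of one health
# facility, plus its sampling-stratum labels.

OUTPUT_MEASURES <- c("outpatient_visits", "admissions", "bed_days", "none")

#' Construct a facility record
#'
#' A facility record is the unit the costing engine operates on: one
#' facility's cost ledger (line items), cost-centre chart, annual service
#' statistics, and optionally its asset register and payroll, tagged with the
#' sampling-stratum labels (level of care, trustee, urban/rural location).
#'
#' @param id facility identifier.
#' @param level level of care: `"2"` (dispensary), `"3"` (health centre),
#'   `"4"` (district hospital), `"5"` (provincial hospital), `"6"` (tertiary
#'   hospital), `"nursing_home"`, or an administrative unit
#'   (`"admin_district"`, `"admin_province"`, `"ministry"`).
#' @param trustee `"public"`, `"fbo_ngo"` or `"private"`.
#' @param location `"urban"` or `"rural"`.
#' @param province province label (free text).
#' @param beds bed count (0 for outpatient-only facilities).
#' @param centres cost-centre chart: tibble with `centre_id`, `name`, `kind`
#'   (`"support"`/`"final"`), `output_measure`, `output_count`; extra columns
#'   (e.g. `staff_count`, `floor_area`) may carry allocation-basis data.
#' @param items cost ledger: tibble with `centre_id`, `cost_unit_id`,
#'   `category`, `year`, `amount_ksh`, `traceability`.
#' @param statistics named list or one-row data frame with
#'   `outpatient_visits`, `admissions`, `bed_days`, `catchment_population`.
#' @param assets optional asset register (see [straight_line_depreciation()]).
#' @param payroll optional payroll (see [staff_minute_cost()]).
#' @param stratum optional stratum label; defaults to `level x trustee`.
#' @return an object of class `facility_record`.
#' @export
facility_record <- function(id, level, trustee, location = "rural",
                            province = NA_character_, beds = 0,
                            centres, items, statistics,
                            assets = NULL, payroll = NULL, stratum = NULL) {
  level <- as.character(level)
  if (!level %in% FACILITY_LEVELS) {
    abort(sprintf("unknown level '%s'", level))
  }
  if (!trustee %in% TRUSTEES) abort(sprintf("unknown trustee '%s'", trustee))
  statistics <- as.list(statistics)
  for (f in c("outpatient_visits", "admissions", "bed_days")) {
    statistics[[f]] <- statistics[[f]] %||% 0
  }
  statistics$catchment_population <- statistics$catchment_population %||% NA_real_
  rec <- structure(
    list(
      id = as.character(id), level = level, trustee = trustee,
      location = location, province = province, beds = beds,
      centres = as_tibble(centres), items = as_tibble(items),
      statistics = statistics,
      assets = if (!is.null(assets)) as_tibble(assets) else NULL,
      payroll = if (!is.null(payroll)) as_tibble(payroll) else NULL,
      stratum = stratum %||% paste(level, trustee, sep = "_")
    ),
    class = "facility_record"
  )
  rec
}

#' @export
print.facility_record <- function(x, ...) {
  cat(sprintf("<facility_record> %s  level %s  %s  %s\n",
              x$id, x$level, x$trustee, x$location))
  cat(sprintf("  beds %d | centres %d (%d support, %d final) | ledger items %d\n",
              as.integer(x$beds), nrow(x$centres),
              sum(x$centres$kind == "support"), sum(x$centres$kind == "final"),
              nrow(x$items)))
  cat(sprintf("  visits %s, admissions %s, bed-days %s | total ledger %s Ksh\n",
              format(x$statistics$outpatient_visits, big.mark = ","),
              format(x$statistics$admissions, big.mark = ","),
              format(x$statistics$bed_days, big.mark = ","),
              format(round(sum(x$items$amount_ksh)), big.mark = ",")))
  invisible(x)
}

#' Validate a facility record
#'
#' Checks the structural invariants of a facility record and returns the
#' violations as data, not errors: each row names the field, the rule broken
#' and a severity. `"error"` rows make the record unusable for costing;
#' `"warning"` rows flag suspicious but legal states. In particular, bed
#' occupancy above 100% is legal (over-full wards are observed in practice);
#' only occupancy beyond 150% draws a warning, as a sanity bound.
#'
#' @param record a [facility_record()].
#' @return tibble with columns `field`, `rule`, `severity`, `detail`; zero
#'   rows when the record is fully consistent.
#' @export
validate_facility <- function(record) {
  v <- list()
  note <- function(field, rule, severity, detail = "") {
    v[[length(v) + 1L]] <<- tibble(field = field, rule = rule,
                                   severity = severity, detail = detail)
  }
  st <- record$statistics
  items <- record$items
  centres <- record$centres

  for (f in c("outpatient_visits", "admissions", "bed_days")) {
    if (is.null(st[[f]]) || is.na(st[[f]]) || st[[f]] < 0) {
      note(paste0("statistics.", f), "count must be >= 0", "error")
    }
  }
  if (st$admissions > 0 && record$beds <= 0) {
    note("beds", "facility reports admissions but has no beds", "error")
  }
  if (record$beds > 0 && st$admissions == 0 && st$bed_days == 0) {
    note("beds", "beds declared but no inpatient activity", "warning")
  }
  if (record$beds > 0 && st$bed_days > record$beds * 365 * 1.5) {
    note("statistics.bed_days",
         "occupancy above 150% of capacity", "warning",
         sprintf("occupancy %.0f%%", 100 * st$bed_days / (record$beds * 365)))
  }
  if (any(items$amount_ksh < 0, na.rm = TRUE)) {
    note("items.amount_ksh", "amounts must be >= 0", "error")
  }
  if (!all(items$category %in% COST_CATEGORIES)) {
    note("items.category", "category must be one of the four input categories",
         "error", paste(setdiff(unique(items$category), COST_CATEGORIES),
                        collapse = ", "))
  }
  ind <- items$traceability == "indirect"
  bad_centre <- setdiff(items$centre_id[ind], centres$centre_id)
  bad_centre <- bad_centre[!is.na(bad_centre)]
  if (length(bad_centre) > 0) {
    note("items.centre_id", "indirect item references undeclared centre",
         "error", paste(bad_centre, collapse = ", "))
  }
  if (any(ind & (is.na(items$centre_id) | items$centre_id == ""))) {
    note("items.centre_id", "indirect item lacks a cost-centre id", "error")
  }
  dir <- items$traceability == "direct"
  if (any(dir & (is.na(items$cost_unit_id) | items$cost_unit_id == ""))) {
    note("items.cost_unit_id", "direct item lacks a cost-unit id", "error")
  }
  if (any(!items$traceability %in% c("direct", "indirect"))) {
    note("items.traceability", "traceability must be direct or indirect", "error")
  }
  sup <- centres$kind == "support"
  if (any(sup & centres$output_measure != "none")) {
    note("centres.output_measure", "support centres carry no output measure",
         "error", paste(centres$centre_id[sup & centres$output_measure != "none"],
                        collapse = ", "))
  }
  fin <- centres$kind == "final"
  if (any(fin & centres$output_measure == "none")) {
    note("centres.output_measure", "final centres need an output measure",
         "error")
  }
  if (any(!centres$output_measure %in% OUTPUT_MEASURES)) {
    note("centres.output_measure", "unknown output measure", "error")
  }
  if (anyDuplicated(centres$centre_id)) {
    note("centres.centre_id", "duplicate centre id", "error")
  }
  if (length(v) == 0) {
    return(tibble(field = character(), rule = character(),
                  severity = character(), detail = character()))
  }
  bind_rows(v)
}

# ---- fixture-format readers / writers --------------------------------------

read_csv_quiet <- function(path, col_types) {
  readr::read_csv(path, col_types = col_types, progress = FALSE,
                  na = c("", "NA"))
}

#' Load a facility from its fixture directory
#'
#' Reads the plain-text fixture layout for one facility: `facility.csv` (the
#' cost ledger, one row per item), `centres.csv` (the cost-centre chart),
#' `statistics.json` (service statistics plus `beds`, `level`, `trustee`,
#' `location`), and optionally `assets.csv` and `payroll.csv`.
#'
#' @param dir directory holding the facility files, or the path to
#'   `facility.csv` with the companions alongside (then `statistics_path`
#'   may override the JSON location).
#' @param statistics_path optional explicit path to `statistics.json`.
#' @return a validated [facility_record()]. Rows of `facility.csv` that
#'   reference an undeclared cost centre raise an error naming the row.
#' @export
load_facility_ledger <- function(dir, statistics_path = NULL) {
  if (grepl("\\.csv$", dir)) {
    ledger_path <- dir
    dir <- dirname(dir)
  } else {
    ledger_path <- file.path(dir, "facility.csv")
  }
  centres_path <- file.path(dir, "centres.csv")
  statistics_path <- statistics_path %||% file.path(dir, "statistics.json")
  for (p in c(ledger_path, centres_path, statistics_path)) {
    if (!file.exists(p)) abort(sprintf("missing facility file: %s", p))
  }
  items <- read_csv_quiet(ledger_path, readr::cols(
    centre_id = readr::col_character(), cost_unit_id = readr::col_character(),
    category = readr::col_character(), year = readr::col_character(),
    amount_ksh = readr::col_double(), traceability = readr::col_character()))
  centres <- read_csv_quiet(centres_path, readr::cols(
    centre_id = readr::col_character(), name = readr::col_character(),
    kind = readr::col_character(), output_measure = readr::col_character(),
    output_count = readr::col_double(), .default = readr::col_double()))
  meta <- jsonlite::read_json(statistics_path, simplifyVector = TRUE)

  ind <- items$traceability == "indirect"
  bad <- which(ind & !items$centre_id %in% centres$centre_id)
  if (length(bad) > 0) {
    abort(sprintf(
      "facility.csv row(s) %s reference undeclared centre(s): %s",
      paste(bad, collapse = ", "),
      paste(unique(items$centre_id[bad]), collapse = ", ")))
  }
  if (any(items$amount_ksh < 0, na.rm = TRUE)) {
    abort(sprintf("facility.csv row(s) %s have negative amounts",
                  paste(which(items$amount_ksh < 0), collapse = ", ")))
  }

  assets_path <- file.path(dir, "assets.csv")
  payroll_path <- file.path(dir, "payroll.csv")
  assets <- if (file.exists(assets_path)) {
    read_csv_quiet(assets_path, readr::cols(
      asset_class = readr::col_character(), .default = readr::col_double()))
  }
  payroll <- if (file.exists(payroll_path)) {
    read_csv_quiet(payroll_path, readr::cols(
      cadre = readr::col_character(), .default = readr::col_double()))
  }

  rec <- facility_record(
    id = meta$id %||% basename(dir),
    level = meta$level, trustee = meta$trustee,
    location = meta$location %||% "rural",
    province = meta$province %||% NA_character_,
    beds = meta$beds %||% 0,
    centres = centres, items = items,
    statistics = meta[intersect(names(meta),
                                c("outpatient_visits", "admissions",
                                  "bed_days", "catchment_population"))],
    assets = assets, payroll = payroll,
    stratum = meta$stratum %||% NULL
  )
  bad <- validate_facility(rec)
  if (any(bad$severity == "error")) {
    abort(paste0("facility record fails validation:\n",
                 paste(sprintf("- %s: %s", bad$field, bad$rule)[bad$severity == "error"],
                       collapse = "\n")))
  }
  rec
}

#' Write a facility record to a fixture directory
#'
#' Inverse of [load_facility_ledger()]: writes `facility.csv`, `centres.csv`,
#' `statistics.json`, and `assets.csv` / `payroll.csv` when present.
#'
#' @param record a [facility_record()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_facility <- function(record, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(record$items, file.path(dir, "facility.csv"))
  readr::write_csv(record$centres, file.path(dir, "centres.csv"))
  meta <- c(list(id = record$id, level = record$level, trustee = record$trustee,
                 location = record$location, province = record$province,
                 beds = record$beds, stratum = record$stratum),
            record$statistics)
  jsonlite::write_json(meta, file.path(dir, "statistics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  if (!is.null(record$assets)) {
    readr::write_csv(record$assets, file.path(dir, "assets.csv"))
  }
  if (!is.null(record$payroll)) {
    readr::write_csv(record$payroll, file.path(dir, "payroll.csv"))
  }
  invisible(dir)
}

#' Read a price list
#'
#' A price list JSON has an `items` map of item-code to unit price (Ksh) and
#' optionally `bundles`, a per-level map of standard-equipment bundles (lists
#' of `{item_code, quantity}`) used to price standard equipment at levels
#' where actual asset values are not collected.
#'
#' @param path path to `price_list.json`.
#' @return list with elements `items` (named numeric) and `bundles`.
#' @export
read_price_list <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(pl$items)) abort("price list needs an `items` map")
  items <- unlist(pl$items)
  if (any(items <= 0)) abort("prices must be > 0")
  list(items = items, bundles = pl$bundles)
}
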
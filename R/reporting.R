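# National aggregation and report surfaces: the stratum x input-category
# cost matrix, trustee and category shares, per-capita figures, and the
# rendered CSV report tables.

#' Build a stratum-by-category cost matrix
#'
#' The national summary shape: one row per facility stratum (level of care x
#' trustee, plus administration rows), one column per input category (drugs
#' and supplies, staffing, other recurrent, fixed). Published matrices carry
#' independently rounded cells and margins; supplied margins are therefore
#' validated against cell sums with a small absolute slack (1 currency unit
#' per row) and then kept as authoritative.
#'
#' @param rows tibble with columns `stratum`, `trustee_group` and the four
#'   category columns (`drugs_supplies`, `staffing`, `other_recurrent`,
#'   `fixed`); an optional `total` column gives printed row margins.
#' @param currency `"EUR"` or `"KSH"` (uniform across the matrix).
#' @param col_margins optional named vector of printed column margins
#'   (categories plus `total`); recomputed from cells when absent.
#' @return a `cost_matrix`: the row tibble (with `total`) carrying
#'   `currency` and `col_margins` attributes.
#' @export
cost_matrix <- function(rows, currency = c("EUR", "KSH"), col_margins = NULL) {
  currency <- match.arg(currency)
  rows <- as_tibble(rows)
  assert_has_columns(rows, c("stratum", COST_CATEGORIES), "cost matrix")
  if (!"trustee_group" %in% names(rows)) rows$trustee_group <- "all"
  for (cat in COST_CATEGORIES) rows[[cat]][is.na(rows[[cat]])] <- 0
  if (any(as.matrix(rows[COST_CATEGORIES]) < 0)) {
    abort("cost matrix cells must be >= 0")
  }
  cell_row_sums <- rowSums(rows[COST_CATEGORIES])
  if ("total" %in% names(rows) && !all(is.na(rows$total))) {
    off <- abs(rows$total - cell_row_sums)
    # printed margins are independently rounded; allow a couple of currency
    # units per row (relative slack so currency conversion keeps working)
    if (any(off > pmax(2, 1e-5 * abs(rows$total)))) {
      abort(sprintf("row margin inconsistent with cells for stratum %s",
                    paste(rows$stratum[off > 2], collapse = ", ")))
    }
  } else {
    rows$total <- cell_row_sums
  }
  computed <- c(colSums(rows[COST_CATEGORIES]), total = sum(rows$total))
  if (is.null(col_margins)) {
    col_margins <- computed
  } else {
    need <- c(COST_CATEGORIES, "total")
    missing <- setdiff(need, names(col_margins))
    if (length(missing) > 0) col_margins[missing] <- computed[missing]
    col_margins <- col_margins[need]
    if (any(abs(col_margins - computed) > pmax(2 * nrow(rows), 1e-5 * abs(computed)))) {
      abort("column margins inconsistent with cells")
    }
  }
  structure(rows[, c("stratum", "trustee_group", COST_CATEGORIES, "total")],
            class = c("cost_matrix", class(rows)),
            currency = currency, col_margins = col_margins)
}

#' Margins of a cost matrix
#'
#' @param matrix a [cost_matrix()].
#' @return list with `rows` (named row totals), `columns` (named category
#'   margins) and `grand_total`.
#' @export
cost_matrix_margins <- function(matrix) {
  cm <- attr(matrix, "col_margins")
  if (is.null(cm)) {
    cm <- c(colSums(matrix[COST_CATEGORIES]), total = sum(matrix$total))
  }
  list(rows = stats::setNames(matrix$total, matrix$stratum),
       columns = cm[COST_CATEGORIES], grand_total = unname(cm["total"]))
}

#' @export
print.cost_matrix <- function(x, ...) {
  m <- cost_matrix_margins(x)
  cat(sprintf("<cost_matrix> %d strata x 4 categories [%s]\n",
              nrow(x), attr(x, "currency")))
  cat(sprintf("  grand total: %s\n", format(m$grand_total, big.mark = ",")))
  NextMethod()
}

#' Read / write a cost matrix CSV
#'
#' The CSV has the row columns of [cost_matrix()]; a final row with
#' `stratum == "TOTAL"` holds the column margins.
#'
#' @param path CSV path.
#' @param currency currency tag, default `"EUR"`.
#' @return `read_cost_matrix()`: a `cost_matrix`; `write_cost_matrix()`: the
#'   path, invisibly.
#' @export
read_cost_matrix <- function(path, currency = "EUR") {
  df <- read_csv_quiet(path, readr::cols(
    stratum = readr::col_character(), trustee_group = readr::col_character(),
    .default = readr::col_double()))
  margin_row <- df$stratum == "TOTAL"
  col_margins <- NULL
  if (any(margin_row)) {
    mr <- df[margin_row, , drop = FALSE][1, ]
    col_margins <- c(unlist(mr[COST_CATEGORIES]), total = mr$total)
    df <- df[!margin_row, , drop = FALSE]
  }
  cost_matrix(df, currency = currency, col_margins = col_margins)
}

#' @rdname read_cost_matrix
#' @param matrix a [cost_matrix()].
#' @export
write_cost_matrix <- function(matrix, path) {
  m <- cost_matrix_margins(matrix)
  margin_row <- tibble(stratum = "TOTAL", trustee_group = "",
                       !!!as.list(m$columns), total = m$grand_total)
  readr::write_csv(bind_rows(as_tibble(matrix), margin_row), path)
  invisible(path)
}

#' Bundled national cost matrix, Kenya FY 2006/07
#'
#' The published summary of total health-service costs in Kenya for fiscal
#' year 2006/07, in euro: 17 strata (facility levels by trustee plus
#' district/provincial administration and the ministry) by the four input
#' categories, with the printed margins (grand total 694,947,102 EUR).
#'
#' @return a `cost_matrix` in EUR.
#' @export
kenya_cost_matrix <- function() {
  path <- system.file("extdata", "kenya_cost_matrix_2006_07.csv",
                      package = "khscm", mustWork = TRUE)
  read_cost_matrix(path, currency = "EUR")
}

#' Bundled national average unit costs, Kenya FY 2006/07
#'
#' Published average cost per outpatient visit, per admission and per bed-day
#' (Ksh) by stratum, used for ratio analyses.
#'
#' @return tibble with `stratum`, `cost_per_outpatient_visit`,
#'   `cost_per_admission`, `cost_per_bedday`.
#' @export
kenya_unit_costs <- function() {
  path <- system.file("extdata", "kenya_unit_costs_2006_07.csv",
                      package = "khscm", mustWork = TRUE)
  read_csv_quiet(path, readr::cols(stratum = readr::col_character(),
                                   .default = readr::col_double()))
}

#' Aggregate facility results to a national cost matrix
#'
#' @param facility_results tibble with one row per facility and category:
#'   `facility_id`, `stratum`, `trustee_group`, `category`, `amount` (in the
#'   matrix currency).
#' @param weights optional sampling weights: tibble `stratum`, `weight`
#'   (expansion factor, >= 1) or a named vector. Default 1 for every stratum
#'   (report the sample itself).
#' @param currency currency tag of the amounts.
#' @return a `cost_matrix` whose cell `(stratum, category)` is the
#'   weight-expanded sum over facilities.
#' @export
national_totals <- function(facility_results, weights = NULL, currency = "KSH") {
  fr <- as_tibble(facility_results)
  assert_has_columns(fr, c("stratum", "category", "amount"), "facility results")
  if (!"trustee_group" %in% names(fr)) fr$trustee_group <- "all"
  if (is.null(weights)) {
    fr$weight <- 1
  } else {
    if (is.data.frame(weights)) {
      weights <- stats::setNames(weights$weight, weights$stratum)
    }
    if (any(weights < 1)) abort("expansion weights must be >= 1")
    missing <- setdiff(unique(fr$stratum), names(weights))
    if (length(missing) > 0) {
      abort(sprintf("no sampling weight for stratum(s): %s",
                    paste(missing, collapse = ", ")))
    }
    fr$weight <- unname(weights[fr$stratum])
  }
  cells <- fr |>
    group_by(.data$stratum, .data$trustee_group, .data$category) |>
    summarise(amount = sum(.data$amount * .data$weight), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "category", values_from = "amount",
                       values_fill = 0)
  for (cat in setdiff(COST_CATEGORIES, names(cells))) cells[[cat]] <- 0
  cost_matrix(cells, currency = if (currency == "EUR") "EUR" else "KSH")
}

#' Convert a cost matrix between Ksh and EUR
#'
#' @param matrix a [cost_matrix()].
#' @param rate Ksh per EUR, default 90.66.
#' @return the matrix in the other currency.
#' @export
convert_matrix <- function(matrix, rate = 90.66) {
  cur <- attr(matrix, "currency")
  f <- if (cur == "KSH") 1 / rate else rate
  out <- as_tibble(matrix)
  for (cat in c(COST_CATEGORIES, "total")) out[[cat]] <- out[[cat]] * f
  cost_matrix(out, currency = if (cur == "KSH") "EUR" else "KSH",
              col_margins = attr(matrix, "col_margins") * f)
}

#' Cost shares by trustee group
#'
#' Row sums per trustee group as integer percentages of the grand total,
#' rounded half away from zero. The default grouping is the matrix's
#' `trustee_group` column; strata whose ownership the source table leaves
#' unlabelled should be grouped as `"other"` so that the labelled-sector
#' shares match what a reader computes from the labelled rows alone.
#'
#' @param matrix a [cost_matrix()].
#' @param grouping optional named vector mapping stratum to group, overriding
#'   the `trustee_group` column; must cover every row.
#' @return tibble `group`, `amount`, `share_pct` (integer percent).
#' @export
share_by_trustee <- function(matrix, grouping = NULL) {
  m <- cost_matrix_margins(matrix)
  df <- as_tibble(matrix)
  if (!is.null(grouping)) {
    missing <- setdiff(df$stratum, names(grouping))
    if (length(missing) > 0) {
      abort(sprintf("grouping does not cover stratum(s): %s",
                    paste(missing, collapse = ", ")))
    }
    df$trustee_group <- unname(grouping[df$stratum])
  }
  df |>
    group_by(group = .data$trustee_group) |>
    summarise(amount = sum(.data$total), .groups = "drop") |>
    mutate(share_pct = round_half_away(100 * .data$amount / m$grand_total))
}

#' Cost shares by input category
#'
#' Column margins as percentages of the grand total and — for the three
#' recurrent categories — of the recurrent base (grand total minus fixed
#' cost). Integer percent, rounded half away from zero.
#'
#' @param matrix a [cost_matrix()].
#' @return tibble `category`, `amount`, `share_of_total_pct`,
#'   `share_of_recurrent_pct` (`NA` for the fixed row).
#' @export
share_by_category <- function(matrix) {
  m <- cost_matrix_margins(matrix)
  recurrent <- m$grand_total - m$columns[["fixed"]]
  tibble(category = COST_CATEGORIES,
         amount = unname(m$columns[COST_CATEGORIES])) |>
    mutate(
      share_of_total_pct = round_half_away(100 * .data$amount / m$grand_total),
      share_of_recurrent_pct = dplyr::if_else(
        .data$category == "fixed", NA_real_,
        round_half_away(100 * .data$amount / recurrent))
    )
}

#' Cost per capita
#'
#' @param total total cost.
#' @param population catchment or national population, > 0.
#' @return `total / population` rounded to 2 decimals (half away from zero).
#' @export
per_capita <- function(total, population) {
  assert_scalar_number(population, "population", min = 0, strict_min = TRUE)
  round_half_away(total / population, 2)
}

#' Analysed facility count
#'
#' @param sampled facilities in the original sample.
#' @param excluded facilities omitted for incomplete or unreliable data.
#' @return `sampled - excluded`; negative results are a data error.
#' @export
analysed_facility_count <- function(sampled, excluded) {
  assert_scalar_number(sampled, "sampled", min = 0)
  assert_scalar_number(excluded, "excluded", min = 0)
  if (excluded > sampled) abort("more facilities excluded than sampled")
  sampled - excluded
}

#' Render the report tables
#'
#' Writes the standard report surfaces as CSV plus a text summary:
#' `matrix.csv` (stratum x category totals with margins), `unit_costs.csv`
#' (per-stratum unit costs with the admission/bed-day and bed-day/visit ratio
#' columns at one decimal), `episodes.csv` (episode costs) and `summary.txt`.
#' Output is deterministic: identical inputs give byte-identical files.
#'
#' @param matrix a [cost_matrix()].
#' @param unit_cost_table tibble of per-stratum unit costs (may be empty):
#'   columns `stratum`, `measure`, `unit_cost_ksh`.
#' @param episodes tibble of episode costs (may be empty).
#' @param dir output directory, created if needed.
#' @return invisibly, the paths written.
#' @export
render_tables <- function(matrix, unit_cost_table = NULL, episodes = NULL, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  p <- file.path(dir, "matrix.csv")
  write_cost_matrix(matrix, p)
  paths <- c(paths, p)

  p <- file.path(dir, "unit_costs.csv")
  if (is.null(unit_cost_table) || nrow(unit_cost_table) == 0) {
    readr::write_csv(tibble(stratum = character(), measure = character(),
                            unit_cost_ksh = numeric()), p)
  } else {
    wide <- unit_cost_table |>
      select(all_of(c("stratum", "measure", "unit_cost_ksh"))) |>
      tidyr::pivot_wider(names_from = "measure", values_from = "unit_cost_ksh") |>
      arrange(.data$stratum)
    for (cc in c("outpatient_visit", "admission", "bed_day")) {
      if (!cc %in% names(wide)) wide[[cc]] <- NA_real_
    }
    wide <- wide |>
      mutate(
        admission_per_bedday = dplyr::if_else(
          !is.na(.data$admission) & !is.na(.data$bed_day) & .data$bed_day > 0,
          round_half_away(.data$admission / .data$bed_day, 1), NA_real_),
        bedday_per_visit = dplyr::if_else(
          !is.na(.data$bed_day) & !is.na(.data$outpatient_visit) & .data$outpatient_visit > 0,
          round_half_away(.data$bed_day / .data$outpatient_visit, 1), NA_real_))
    readr::write_csv(wide, p)
  }
  paths <- c(paths, p)

  p <- file.path(dir, "episodes.csv")
  if (is.null(episodes) || nrow(episodes) == 0) {
    readr::write_csv(tibble(condition_id = integer(), stratum = character(),
                            setting = character(), variant = character(),
                            direct_ksh = numeric(), indirect_ksh = numeric(),
                            total_ksh = numeric()), p)
  } else {
    readr::write_csv(arrange(as_tibble(episodes), .data$condition_id,
                             .data$stratum, .data$variant), p)
  }
  paths <- c(paths, p)

  m <- cost_matrix_margins(matrix)
  cats <- share_by_category(matrix)
  trust <- share_by_trustee(matrix)
  lines <- c(
    sprintf("Grand total: %s %s", format(m$grand_total, big.mark = ",", scientific = FALSE),
            attr(matrix, "currency")),
    "Shares by input category (% of total):",
    sprintf("  %-16s %3.0f", cats$category, cats$share_of_total_pct),
    "Shares by trustee group (% of total):",
    sprintf("  %-16s %3.0f", trust$group, trust$share_pct),
    "Note: episode overhead uses the indirect unit-cost component only,",
    "so direct drugs and staff time are not double counted."
  )
  p <- file.path(dir, "summary.txt")
  writeLines(lines, p)
  paths <- c(paths, p)
  invisible(paths)
}

#' @describeIn cost_matrix autoplot method: stacked category composition by
#'   stratum.
#' @param object a `cost_matrix`.
#' @param ... unused.
#' @method autoplot cost_matrix
#' @export
autoplot.cost_matrix <- function(object, ...) {
  long <- as_tibble(object) |>
    tidyr::pivot_longer(all_of(COST_CATEGORIES), names_to = "category",
                        values_to = "amount")
  ggplot2::ggplot(long, ggplot2::aes(x = stats::reorder(.data$stratum, .data$amount),
                                     y = .data$amount, fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = paste0("cost [", attr(object, "currency"), "]"),
                  title = "Cost composition by stratum") +
    ggplot2::theme_minimal()
}
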
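# Step-down cost allocation: support-centre costs cascade sequentially onto
# the remaining centres until only final (patient-serving) centres hold cost.
# One pass, no back-allocation to closed centres (no reciprocal allocation).

ALLOCATION_BASES <- c("direct_cost_share", "bed_days", "patient_days",
                      "outpatient_visits", "staff_count", "floor_area",
                      "explicit_weights")

#' Allocation configuration for the step-down cascade
#'
#' @param ordering `"descending_cost"` (default): support centres close in
#'   order of accumulated indirect cost, largest first, ties broken by centre
#'   id; `"explicit_list"`: close in the order of `explicit_order`.
#' @param explicit_order character vector of support-centre ids, required
#'   when `ordering = "explicit_list"`; must contain every support centre
#'   exactly once.
#' @param basis_map named list mapping support-centre id to an allocation
#'   basis: either a basis kind string or `list(kind =, weights =)` for
#'   `"explicit_weights"`. Centres not in the map use `default_basis`.
#' @param default_basis basis kind used when a centre has no entry in
#'   `basis_map`. The default, `"direct_cost_share"`, weights each receiving
#'   centre by its own indirect cost before allocation — always computable
#'   and scale-free. Other kinds (`"bed_days"`, `"patient_days"`,
#'   `"outpatient_visits"`, `"staff_count"`, `"floor_area"`) read the
#'   matching column of the centre chart.
#' @return an `allocation_config` object.
#' @export
allocation_config <- function(ordering = c("descending_cost", "explicit_list"),
                              explicit_order = NULL, basis_map = list(),
                              default_basis = "direct_cost_share") {
  ordering <- match.arg(ordering)
  if (ordering == "explicit_list" && is.null(explicit_order)) {
    abort("`explicit_list` ordering requires `explicit_order`")
  }
  if (!default_basis %in% setdiff(ALLOCATION_BASES, "explicit_weights")) {
    abort(sprintf("invalid default basis '%s'", default_basis))
  }
  basis_map <- lapply(basis_map, function(b) {
    if (is.character(b)) b <- list(kind = b)
    if (!b$kind %in% ALLOCATION_BASES) {
      abort(sprintf("unknown allocation basis kind '%s'", b$kind))
    }
    if (b$kind == "explicit_weights" &&
        (is.null(b$weights) || any(b$weights < 0))) {
      abort("explicit_weights basis needs a named nonnegative `weights` vector")
    }
    b
  })
  structure(list(ordering = ordering, explicit_order = explicit_order,
                 basis_map = basis_map, default_basis = default_basis),
            class = "allocation_config")
}

#' Read an allocation configuration from YAML
#'
#' YAML keys: `ordering`, `explicit_order`, `default_basis`, and `bases`, a
#' map of support-centre id to basis kind or `{kind, weights}`.
#'
#' @param path path to the YAML file.
#' @return an [allocation_config()].
#' @export
read_allocation_config <- function(path) {
  y <- yaml::read_yaml(path)
  basis_map <- lapply(y$bases %||% list(), function(b) {
    if (is.list(b) && !is.null(b$weights)) {
      list(kind = b$kind, weights = unlist(b$weights))
    } else b
  })
  allocation_config(
    ordering = y$ordering %||% "descending_cost",
    explicit_order = unlist(y$explicit_order),
    basis_map = basis_map,
    default_basis = y$default_basis %||% "direct_cost_share"
  )
}

#' Split a ledger into direct and indirect cost
#'
#' Cost induced by a single cost unit (an outpatient visit, an operation) is
#' direct and attaches to that cost unit; everything else is indirect and
#' attaches to the cost centre where it occurs.
#'
#' @param record a [facility_record()] whose `items` hold annualized amounts,
#'   or a ledger tibble with the cost-item columns.
#' @return list with `direct` (tibble `cost_unit_id`, `category`,
#'   `amount_ksh`) and `indirect` (tibble `centre_id`, `category`,
#'   `amount_ksh`), whose amounts sum to the ledger total.
#' @export
classify_costs <- function(record) {
  items <- if (inherits(record, "facility_record")) record$items else as_tibble(record)
  assert_has_columns(items, c("category", "amount_ksh", "traceability"), "ledger")
  if (any(!items$traceability %in% c("direct", "indirect"))) {
    abort("traceability must be 'direct' or 'indirect'")
  }
  dir <- items[items$traceability == "direct", , drop = FALSE]
  if (any(is.na(dir$cost_unit_id) | dir$cost_unit_id == "")) {
    abort("direct cost item without a cost-unit id")
  }
  ind <- items[items$traceability == "indirect", , drop = FALSE]
  if (any(is.na(ind$centre_id) | ind$centre_id == "")) {
    abort("indirect cost item without a cost-centre id")
  }
  list(
    direct = dir |>
      group_by(.data$cost_unit_id, .data$category) |>
      summarise(amount_ksh = sum(.data$amount_ksh), .groups = "drop"),
    indirect = ind |>
      group_by(.data$centre_id, .data$category) |>
      summarise(amount_ksh = sum(.data$amount_ksh), .groups = "drop")
  )
}

#' Order the support centres for closure
#'
#' @param centres the centre chart (tibble with `centre_id`, `kind`).
#' @param config an [allocation_config()].
#' @param indirect_totals tibble `centre_id`, `amount_ksh` of accumulated
#'   indirect cost per centre (only used for `"descending_cost"`).
#' @return character vector of support-centre ids in closure order.
#' @export
order_support_centres <- function(centres, config = allocation_config(),
                                  indirect_totals = NULL) {
  support <- centres$centre_id[centres$kind == "support"]
  if (config$ordering == "explicit_list") {
    eo <- config$explicit_order
    if (!setequal(eo, support) || length(eo) != length(support)) {
      abort("explicit_order must contain every support centre exactly once")
    }
    return(eo)
  }
  totals <- stats::setNames(rep(0, length(support)), support)
  if (!is.null(indirect_totals)) {
    it <- indirect_totals |>
      group_by(.data$centre_id) |>
      summarise(amount_ksh = sum(.data$amount_ksh), .groups = "drop")
    found <- intersect(support, it$centre_id)
    totals[found] <- it$amount_ksh[match(found, it$centre_id)]
  }
  # largest first; ties broken by centre id ascending
  support[order(-totals[support], support)]
}

basis_weights <- function(centre_ids, basis, centres, own_indirect) {
  kind <- basis$kind
  if (kind == "explicit_weights") {
    w <- basis$weights[centre_ids]
    w[is.na(w)] <- 0
    return(unname(w))
  }
  col <- switch(kind,
    direct_cost_share = NULL,
    bed_days = "bed_days", patient_days = "bed_days",
    outpatient_visits = "outpatient_visits",
    staff_count = "staff_count", floor_area = "floor_area")
  if (kind == "direct_cost_share") {
    w <- own_indirect[centre_ids]
    w[is.na(w)] <- 0
    return(unname(w))
  }
  if (!col %in% names(centres)) {
    abort(sprintf("allocation basis '%s' needs a '%s' column in the centre chart",
                  kind, col))
  }
  w <- centres[[col]][match(centre_ids, centres$centre_id)]
  w[is.na(w)] <- 0
  unname(w)
}

#' Step-down allocation of indirect costs to final cost centres
#'
#' Support centres close one at a time in the configured order. A closing
#' centre's accumulated cost (its own indirect cost plus anything received
#' from earlier closures) is distributed over all not-yet-closed centres —
#' remaining support centres and final centres alike — in proportion to the
#' basis weights. Closed centres never receive, so the cascade terminates
#' with all indirect cost on final centres. The input-category breakdown
#' (drugs, staffing, other recurrent, fixed) is preserved: each category of a
#' closing centre is distributed with the same weight shares.
#'
#' @param record a [facility_record()] (annualized ledger) or a list as
#'   returned by [classify_costs()] together with a `centres` chart via the
#'   `centres` argument.
#' @param config an [allocation_config()].
#' @param centres centre chart, only needed when `record` is a
#'   `classify_costs()` result.
#' @return an `allocation_result`: list with `final_totals` (tibble
#'   `centre_id`, `category`, `amount_ksh` over final centres),
#'   `direct_costs` (tibble from [classify_costs()]), `trace` (tibble
#'   `step`, `source`, `receiver`, `category`, `amount_ksh`), `order`
#'   (closure order) and `total_ksh` (ledger grand total).
#' @export
stepdown_allocate <- function(record, config = allocation_config(),
                              centres = NULL) {
  if (inherits(record, "facility_record")) {
    centres <- record$centres
    buckets <- classify_costs(record)
  } else {
    if (is.null(centres)) abort("`centres` is required when not passing a facility record")
    buckets <- record
  }
  centres <- as_tibble(centres)
  final_ids <- centres$centre_id[centres$kind == "final"]
  if (length(final_ids) == 0) abort("step-down needs at least one final cost centre")
  support_ids <- centres$centre_id[centres$kind == "support"]

  # accumulated cost per centre x category, dense
  all_ids <- centres$centre_id
  acc <- matrix(0, nrow = length(all_ids), ncol = length(COST_CATEGORIES),
                dimnames = list(all_ids, COST_CATEGORIES))
  ind <- buckets$indirect
  if (nrow(ind) > 0) {
    stray <- setdiff(unique(ind$centre_id), all_ids)
    if (length(stray) > 0) {
      abort(sprintf("indirect cost on undeclared centre(s): %s",
                    paste(stray, collapse = ", ")))
    }
    acc[cbind(ind$centre_id, ind$category)] <-
      acc[cbind(ind$centre_id, ind$category)] + ind$amount_ksh
  }
  own_indirect <- stats::setNames(rowSums(acc), all_ids)

  order <- order_support_centres(
    centres, config,
    indirect_totals = tibble(centre_id = all_ids, amount_ksh = rowSums(acc)))

  open <- all_ids
  trace <- vector("list", length(order))
  for (k in seq_along(order)) {
    src <- order[k]
    open <- setdiff(open, src)
    basis <- config$basis_map[[src]] %||% list(kind = config$default_basis)
    w <- basis_weights(open, basis, centres, own_indirect)
    amount <- acc[src, ]
    if (sum(amount) == 0) next
    if (sum(w) <= 0) {
      abort(sprintf(
        "support centre '%s' cannot allocate: basis '%s' gives zero weight to every remaining centre",
        src, basis$kind))
    }
    share <- w / sum(w)
    alloc <- outer(share, amount)  # receivers x categories
    acc[open, ] <- acc[open, , drop = FALSE] + alloc
    acc[src, ] <- 0
    trace[[k]] <- tibble(step = k, source = src, receiver = rep(open, times = length(COST_CATEGORIES)),
                         category = rep(COST_CATEGORIES, each = length(open)),
                         amount_ksh = as.vector(alloc))
  }
  trace <- bind_rows(trace)
  if (nrow(trace) > 0) trace <- trace[trace$amount_ksh > 0, , drop = FALSE]

  final_totals <- as_tibble(as.data.frame.table(
    acc[final_ids, , drop = FALSE], responseName = "amount_ksh",
    stringsAsFactors = FALSE))
  names(final_totals)[1:2] <- c("centre_id", "category")
  final_totals <- arrange(final_totals, .data$centre_id, .data$category)

  total <- sum(buckets$direct$amount_ksh) + sum(own_indirect)
  structure(
    list(final_totals = final_totals, direct_costs = buckets$direct,
         trace = trace, order = order, centres = centres,
         total_ksh = total),
    class = "allocation_result"
  )
}

#' @export
print.allocation_result <- function(x, ...) {
  cat(sprintf("<allocation_result> %d support centre(s) closed onto %d final centre(s)\n",
              length(x$order), length(unique(x$final_totals$centre_id))))
  cat(sprintf("  order: %s\n", paste(x$order, collapse = " > ")))
  cat(sprintf("  total cost %s Ksh (direct %s, indirect %s)\n",
              format(round(x$total_ksh), big.mark = ","),
              format(round(sum(x$direct_costs$amount_ksh)), big.mark = ","),
              format(round(sum(x$final_totals$amount_ksh)), big.mark = ",")))
  invisible(x)
}

#' @describeIn stepdown_allocate tidy method: final-centre totals in long form,
#'   one row per final centre and input category.
#' @param x an `allocation_result`.
#' @param ... unused.
#' @method tidy allocation_result
#' @export
tidy.allocation_result <- function(x, ...) x$final_totals

#' @describeIn stepdown_allocate glance method: one-row summary with total,
#'   direct and allocated indirect cost and the conservation error.
#' @method glance allocation_result
#' @export
glance.allocation_result <- function(x, ...) {
  ind <- sum(x$final_totals$amount_ksh)
  dir <- sum(x$direct_costs$amount_ksh)
  tibble(total_ksh = x$total_ksh, direct_ksh = dir, indirect_ksh = ind,
         n_support = length(x$order),
         n_final = length(unique(x$final_totals$centre_id)),
         conservation_error = abs(dir + ind - x$total_ksh) / max(x$total_ksh, 1))
}

# which cost units and output measures feed each service group
SERVICE_GROUPS <- list(
  outpatient = list(measures = "outpatient_visits", units = "outpatient_visit"),
  inpatient  = list(measures = c("admissions", "bed_days"),
                    units = c("admission", "bed_day", "inpatient_day"))
)

#' Unit costs per outpatient visit, admission and bed-day
#'
#' Divides each service group's total cost (allocated indirect cost of its
#' final centres plus direct cost attached to its cost units) by the
#' facility's annual output: outpatient-visit cost over outpatient visits,
#' admission and bed-day cost over the inpatient total. Each unit cost is
#' split direct/indirect and fixed/variable; the fixed share follows the
#' input categories (`fixed_only`: annualized capital only;
#' `fixed_plus_staffing`: capital plus staffing, treating hiring as sticky).
#'
#' @param result an `allocation_result` from [stepdown_allocate()].
#' @param statistics service statistics (named list with `outpatient_visits`,
#'   `admissions`, `bed_days`) or a [facility_record()].
#' @param fixed_policy `"fixed_only"` (default) or `"fixed_plus_staffing"`.
#' @return a `unit_costs` tibble with one row per measure
#'   (`outpatient_visit`, `admission`, `bed_day`): `total_ksh`, `output`,
#'   `unit_cost_ksh`, `direct_ksh`, `indirect_ksh`, `fixed_ksh`,
#'   `variable_ksh` (all per unit). Inpatient rows are absent for facilities
#'   without inpatient care. A service group with cost but zero output raises
#'   an error of class `khscm_unit_cost_error` (such facilities are excluded
#'   from aggregation and counted, not silently dropped).
#' @export
unit_costs <- function(result, statistics, fixed_policy = c("fixed_only", "fixed_plus_staffing")) {
  fixed_policy <- match.arg(fixed_policy)
  if (inherits(statistics, "facility_record")) statistics <- statistics$statistics
  statistics <- as.list(statistics)
  centres <- result$centres
  fixed_cats <- if (fixed_policy == "fixed_plus_staffing") {
    c("fixed", "staffing")
  } else "fixed"

  group_totals <- function(group) {
    ids <- centres$centre_id[centres$kind == "final" &
                               centres$output_measure %in% group$measures]
    ft <- result$final_totals
    ind <- ft[ft$centre_id %in% ids, , drop = FALSE] |>
      group_by(.data$category) |>
      summarise(amount_ksh = sum(.data$amount_ksh), .groups = "drop")
    dc <- result$direct_costs
    dir <- dc[dc$cost_unit_id %in% group$units, , drop = FALSE] |>
      group_by(.data$category) |>
      summarise(amount_ksh = sum(.data$amount_ksh), .groups = "drop")
    list(indirect = sum(ind$amount_ksh), direct = sum(dir$amount_ksh),
         fixed = sum(ind$amount_ksh[ind$category %in% fixed_cats]) +
           sum(dir$amount_ksh[dir$category %in% fixed_cats]))
  }

  rows <- list()
  add_row <- function(measure, totals, output) {
    total <- totals$indirect + totals$direct
    if (total > 0 && (is.null(output) || is.na(output) || output <= 0)) {
      abort(sprintf("nonzero %s cost but zero output", measure),
            class = "khscm_unit_cost_error")
    }
    if (total == 0 && (is.null(output) || is.na(output) || output == 0)) {
      return()
    }
    rows[[measure]] <<- tibble(
      measure = measure, total_ksh = total, output = output,
      unit_cost_ksh = total / output,
      direct_ksh = totals$direct / output,
      indirect_ksh = totals$indirect / output,
      fixed_ksh = totals$fixed / output,
      variable_ksh = (total - totals$fixed) / output
    )
  }

  out <- group_totals(SERVICE_GROUPS$outpatient)
  add_row("outpatient_visit", out, statistics$outpatient_visits)
  has_inpatient <- any(centres$kind == "final" &
                         centres$output_measure %in% SERVICE_GROUPS$inpatient$measures)
  if (has_inpatient) {
    inp <- group_totals(SERVICE_GROUPS$inpatient)
    add_row("admission", inp, statistics$admissions)
    add_row("bed_day", inp, statistics$bed_days)
  }
  res <- bind_rows(rows)
  structure(res, class = c("unit_costs", class(res)), fixed_policy = fixed_policy)
}

#' Unit-cost ratios
#'
#' The admission/bed-day cost ratio approximates the average length of stay;
#' the bed-day/visit ratio compares inpatient and outpatient workload
#' intensity. Both are reported at one decimal, rounded half away from zero.
#'
#' @param u a `unit_costs` tibble from [unit_costs()], or any data frame with
#'   `measure` and `unit_cost_ksh` columns.
#' @return tibble with `admission_per_bedday` and `bedday_per_visit`; a ratio
#'   whose components are missing is `NA`, not zero.
#' @export
unit_cost_ratios <- function(u) {
  get <- function(m) {
    v <- u$unit_cost_ksh[u$measure == m]
    if (length(v) == 0 || is.na(v[1])) NA_real_ else v[1]
  }
  adm <- get("admission"); bd <- get("bed_day"); op <- get("outpatient_visit")
  tibble(
    admission_per_bedday =
      if (!is.na(adm) && !is.na(bd) && bd > 0) round_half_away(adm / bd, 1) else NA_real_,
    bedday_per_visit =
      if (!is.na(bd) && !is.na(op) && op > 0) round_half_away(bd / op, 1) else NA_real_
  )
}
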
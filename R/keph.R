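# Costing of essential-package (KEPH) condition episodes: direct resource
# recipes (drugs, staff minutes, lab tests) plus apportioned facility
# overhead, in actual and normative variants, and the demand-side adjustment
# of provider unit costs from patient exit interviews.

#' Direct cost of a treatment episode
#'
#' Values a treatment scheme's resource recipe at unit prices: drug and lab
#' quantities times price-list prices, plus staff minutes times per-minute
#' staff rates (full remuneration, see [staff_minute_cost()]).
#'
#' @param components a scheme's component tibble with columns `component`
#'   (`"drug"`, `"staff"`, `"lab"`), `code` (item code or cadre) and
#'   `quantity` (units, minutes or test counts). An `age_group` column, if
#'   present, is filtered with the `age_group` argument.
#' @param prices price list ([read_price_list()] result or named numeric
#'   vector) covering every drug and lab code.
#' @param staff_rates named numeric vector of Ksh per minute by cadre.
#' @param age_group age band of the patient, default `"under5"`; ignored when
#'   the scheme has no `age_group` column.
#' @return direct episode cost in Ksh.
#' @export
episode_direct_cost <- function(components, prices, staff_rates,
                                age_group = "under5") {
  components <- as_tibble(components)
  if (nrow(components) == 0) return(0)
  assert_has_columns(components, c("component", "code", "quantity"), "scheme components")
  if ("age_group" %in% names(components)) {
    components <- components[is.na(components$age_group) |
                               components$age_group == age_group, , drop = FALSE]
  }
  if (any(components$quantity < 0)) abort("scheme quantities must be >= 0")
  price_map <- if (is.list(prices) && !is.null(prices$items)) prices$items else prices
  priced <- components$component %in% c("drug", "lab")
  unpriced <- setdiff(unique(components$code[priced]), names(price_map))
  if (length(unpriced) > 0) {
    abort(sprintf("no price for code(s): %s", paste(unpriced, collapse = ", ")))
  }
  staffed <- components$component == "staff"
  unrated <- setdiff(unique(components$code[staffed]), names(staff_rates))
  if (length(unrated) > 0) {
    abort(sprintf("no staff rate for cadre(s): %s", paste(unrated, collapse = ", ")))
  }
  rate <- numeric(nrow(components))
  rate[priced] <- unlist(price_map)[components$code[priced]]
  rate[staffed] <- staff_rates[components$code[staffed]]
  sum(components$quantity * rate)
}

#' Total cost of a treatment episode (direct + overhead)
#'
#' Adds the appropriate facility overhead to an episode's direct cost. Only
#' the indirect (allocated) component of the unit cost is used as overhead,
#' since the direct drugs and staff time are already counted in the episode's
#' direct cost. Outpatient episodes take the indirect cost per outpatient
#' visit; inpatient episodes take the indirect cost per bed-day times the
#' length of stay.
#'
#' @param direct direct episode cost in Ksh (see [episode_direct_cost()]).
#' @param unit_costs a `unit_costs` tibble for the facility or stratum.
#' @param setting `"outpatient"` or `"inpatient"`.
#' @param length_of_stay days, required for inpatient episodes.
#' @param condition_id,stratum,variant optional labels carried into the
#'   result.
#' @return an `episode_cost` tibble row: `condition_id`, `stratum`,
#'   `setting`, `variant`, `direct_ksh`, `indirect_ksh`, `total_ksh`, with
#'   `total_ksh = direct_ksh + indirect_ksh` exactly.
#' @export
episode_total_cost <- function(direct, unit_costs, setting = c("outpatient", "inpatient"),
                               length_of_stay = NULL, condition_id = NA_integer_,
                               stratum = NA_character_, variant = "actual") {
  setting <- match.arg(setting)
  assert_scalar_number(direct, "direct", min = 0)
  overhead_rate <- function(measure) {
    v <- unit_costs$indirect_ksh[unit_costs$measure == measure]
    if (length(v) == 0 || is.na(v[1])) {
      abort(sprintf("facility has no %s unit cost; cannot cost a %s episode",
                    measure, setting))
    }
    v[1]
  }
  indirect <- if (setting == "outpatient") {
    overhead_rate("outpatient_visit")
  } else {
    if (is.null(length_of_stay) || is.na(length_of_stay) || length_of_stay <= 0) {
      abort("inpatient episodes need length_of_stay > 0")
    }
    overhead_rate("bed_day") * length_of_stay
  }
  structure(
    tibble(condition_id = condition_id, stratum = stratum, setting = setting,
           variant = variant, direct_ksh = direct, indirect_ksh = indirect,
           total_ksh = direct + indirect),
    class = c("episode_cost", class(tibble())))
}

#' Normative cost of a treatment episode
#'
#' Costs the expert-committee standard (normative) treatment scheme instead
#' of observed resource use, then adds overhead exactly as
#' [episode_total_cost()] does. Identical schemes give identical costs; a
#' normative scheme richer than the actual one (e.g. drugs the facility had
#' stocked out) gives a direct cost at least as high.
#'
#' @inheritParams episode_direct_cost
#' @inheritParams episode_total_cost
#' @return an `episode_cost` row with `variant = "normative"`.
#' @export
normative_episode_cost <- function(components, prices, staff_rates, unit_costs,
                                   setting = c("outpatient", "inpatient"),
                                   length_of_stay = NULL, age_group = "under5",
                                   condition_id = NA_integer_,
                                   stratum = NA_character_) {
  direct <- episode_direct_cost(components, prices, staff_rates, age_group)
  episode_total_cost(direct, unit_costs, setting, length_of_stay,
                     condition_id = condition_id, stratum = stratum,
                     variant = "normative")
}

#' Cost a whole scheme collection against one facility's unit costs
#'
#' @param schemes scheme header tibble: `condition_id`, `condition`,
#'   `setting`, `variant`, `length_of_stay`.
#' @param components component tibble as for [episode_direct_cost()], keyed
#'   by `condition_id` and `variant`.
#' @param prices,staff_rates as in [episode_direct_cost()].
#' @param unit_costs a `unit_costs` tibble.
#' @param age_group age band, default `"under5"`.
#' @param stratum stratum label carried into the result.
#' @return tibble of episode costs, one row per scheme. Inpatient schemes at
#'   facilities without inpatient unit costs are skipped with a warning.
#' @export
cost_keph_episodes <- function(schemes, components, prices, staff_rates,
                               unit_costs, age_group = "under5",
                               stratum = NA_character_) {
  schemes <- as_tibble(schemes)
  has_inpatient <- "bed_day" %in% unit_costs$measure
  out <- vector("list", nrow(schemes))
  skipped <- character()
  for (i in seq_len(nrow(schemes))) {
    s <- schemes[i, ]
    if (s$setting == "inpatient" && !has_inpatient) {
      skipped <- c(skipped, as.character(s$condition_id))
      next
    }
    comp <- components[components$condition_id == s$condition_id &
                         components$variant == s$variant, , drop = FALSE]
    direct <- episode_direct_cost(comp, prices, staff_rates, age_group)
    ec <- episode_total_cost(direct, unit_costs, s$setting,
                             length_of_stay = s$length_of_stay,
                             condition_id = s$condition_id, stratum = stratum,
                             variant = s$variant)
    ec$condition <- s$condition
    ec$age_group <- age_group
    out[[i]] <- ec
  }
  if (length(skipped) > 0) {
    warn(sprintf("skipped inpatient scheme(s) %s: facility has no inpatient unit costs",
                 paste(unique(skipped), collapse = ", ")))
  }
  bind_rows(out)
}

#' Fold demand-side household costs into provider unit costs
#'
#' Patients often buy drugs outside the facility (stock-outs); the mean
#' outside drug purchase per patient, from exit interviews, is added to the
#' provider unit cost so that the adjusted figure reflects resource use, not
#' just facility expenditure. Outpatient interview means adjust the cost per
#' visit; inpatient means adjust the cost per admission. User fees and
#' transport costs are recorded in the interviews but deliberately not added
#' (they are transfers or non-provider costs, kept for cost-of-illness use
#' only).
#'
#' @param unit_costs a `unit_costs` tibble.
#' @param interviews exit-interview tibble: `patient_type` (`"outpatient"`/
#'   `"inpatient"`), `outside_drug_cost`, `user_fees`, `transport_cost`, and
#'   optionally `level`/`trustee` stratum labels.
#' @param level,trustee optional stratum filter applied to the interviews.
#' @return the unit-cost tibble with `demand_side_ksh` added per row and
#'   `unit_cost_ksh` increased accordingly. Cells with no interviews are left
#'   unadjusted with a warning.
#' @export
demand_side_adjust <- function(unit_costs, interviews, level = NULL, trustee = NULL) {
  interviews <- as_tibble(interviews)
  if (nrow(interviews) > 0) {
    assert_has_columns(interviews, c("patient_type", "outside_drug_cost"),
                       "exit interviews")
    if (any(interviews$outside_drug_cost < 0, na.rm = TRUE)) {
      abort("outside_drug_cost must be >= 0")
    }
    if (!is.null(level) && "level" %in% names(interviews)) {
      interviews <- interviews[interviews$level == as.character(level), , drop = FALSE]
    }
    if (!is.null(trustee) && "trustee" %in% names(interviews)) {
      interviews <- interviews[interviews$trustee == trustee, , drop = FALSE]
    }
  }
  cell_mean <- function(type) {
    x <- interviews$outside_drug_cost[interviews$patient_type == type]
    if (length(x) == 0) NA_real_ else mean(x)
  }
  adj <- c(outpatient_visit = cell_mean("outpatient"),
           admission = cell_mean("inpatient"),
           bed_day = 0)
  u <- unit_costs
  u$demand_side_ksh <- unname(adj[u$measure])
  missing_cells <- u$measure[is.na(u$demand_side_ksh)]
  if (length(missing_cells) > 0) {
    warn(sprintf("no exit interviews for %s; unit cost left unadjusted",
                 paste(missing_cells, collapse = ", ")))
    u$demand_side_ksh[is.na(u$demand_side_ksh)] <- 0
  }
  u$unit_cost_ksh <- u$unit_cost_ksh + u$demand_side_ksh
  u$variable_ksh <- u$variable_ksh + u$demand_side_ksh
  u
}
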
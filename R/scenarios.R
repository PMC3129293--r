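# What-if engine: unit costs at a standard bed occupancy, and national cost
# as a function of coverage through a fixed/variable cost decomposition.

#' Scenario specification
#'
#' @param standard_occupancy benchmark bed occupancy rate, default 0.85.
#' @param demand_multipliers demand factors to evaluate, default `c(1, 1.4, 2, 3)`.
#' @param baseline_coverage share of theoretical health-care need met at
#'   baseline, default 0.25.
#' @param capacity_threshold utilization level (relative to baseline = 1)
#'   above which existing capacity is exhausted and must expand, default 1.4.
#' @param expansion_step_cost cost of one capacity block, default 0 (no
#'   capacity constraint).
#' @param capacity_block size of one capacity block in utilization units,
#'   default 0.2.
#' @return a `scenario_spec` object.
#' @export
scenario_spec <- function(standard_occupancy = 0.85,
                          demand_multipliers = c(1, 1.4, 2, 3),
                          baseline_coverage = 0.25,
                          capacity_threshold = 1.4,
                          expansion_step_cost = 0,
                          capacity_block = 0.2) {
  for (nm in c("standard_occupancy", "baseline_coverage")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v <= 0 || v > 1.5) {
      abort(sprintf("`%s` must be a rate in (0, 1.5]", nm))
    }
  }
  if (any(demand_multipliers <= 0)) abort("demand multipliers must be > 0")
  assert_scalar_number(capacity_threshold, "capacity_threshold", min = 0, strict_min = TRUE)
  assert_scalar_number(expansion_step_cost, "expansion_step_cost", min = 0)
  assert_scalar_number(capacity_block, "capacity_block", min = 0, strict_min = TRUE)
  structure(list(standard_occupancy = standard_occupancy,
                 demand_multipliers = demand_multipliers,
                 baseline_coverage = baseline_coverage,
                 capacity_threshold = capacity_threshold,
                 expansion_step_cost = expansion_step_cost,
                 capacity_block = capacity_block),
            class = "scenario_spec")
}

#' Read a scenario specification from YAML
#'
#' @param path YAML file with any subset of the [scenario_spec()] fields.
#' @return a `scenario_spec`.
#' @export
read_scenario_spec <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(scenario_spec, y[intersect(names(y), names(formals(scenario_spec)))])
}

#' Unit costs at standard bed occupancy
#'
#' Recomputes inpatient unit costs as if the facility ran at the standard
#' occupancy instead of its actual one. Fixed cost per bed-day is spread over
#' standard bed-days (`beds x 365 x standard_occupancy`) instead of actual
#' bed-days, so the fixed component rescales by `actual / standard` bed-days;
#' the variable component per bed-day is unchanged. The standard cost per
#' admission keeps the actual average length of stay (the actual
#' admission/bed-day cost ratio) applied to the standard bed-day cost.
#' Facilities already at standard occupancy are returned unchanged.
#'
#' @param u a `unit_costs` tibble with fixed/variable split.
#' @param beds bed count, > 0.
#' @param actual_bed_days actual annual bed-days, > 0.
#' @param spec a [scenario_spec()].
#' @return the unit-cost tibble with inpatient rows restated at standard
#'   occupancy; an `occupancy` attribute records actual and standard rates.
#' @export
standard_occupancy_unit_costs <- function(u, beds, actual_bed_days,
                                          spec = scenario_spec()) {
  assert_scalar_number(beds, "beds", min = 0, strict_min = TRUE)
  assert_scalar_number(actual_bed_days, "actual_bed_days", min = 0, strict_min = TRUE)
  if (!all(c("fixed_ksh", "variable_ksh") %in% names(u))) {
    abort("unit costs lack a fixed/variable split; cannot restate occupancy")
  }
  if (!"bed_day" %in% u$measure) {
    abort("no bed-day unit cost; standard-occupancy restatement needs inpatient care")
  }
  standard_days <- beds * 365 * spec$standard_occupancy
  scale <- actual_bed_days / standard_days

  bd <- u[u$measure == "bed_day", ]
  fixed_std <- bd$fixed_ksh * scale
  bd_std <- fixed_std + bd$variable_ksh

  out <- u
  i <- out$measure == "bed_day"
  out$fixed_ksh[i] <- fixed_std
  out$unit_cost_ksh[i] <- bd_std
  out$total_ksh[i] <- bd_std * out$output[i]
  if ("admission" %in% u$measure) {
    adm <- u[u$measure == "admission", ]
    alos <- adm$unit_cost_ksh / bd$unit_cost_ksh
    j <- out$measure == "admission"
    adm_std <- alos * bd_std
    # keep the direct/variable share of the admission cost, rescale the fixed part
    out$fixed_ksh[j] <- adm$fixed_ksh * scale
    out$unit_cost_ksh[j] <- adm_std
    out$variable_ksh[j] <- adm_std - out$fixed_ksh[j]
    out$total_ksh[j] <- adm_std * out$output[j]
  }
  attr(out, "occupancy") <- c(actual = actual_bed_days / (beds * 365),
                              standard = spec$standard_occupancy)
  out
}

#' Fixed/variable decomposition of a cost matrix
#'
#' @param matrix a [cost_matrix()].
#' @param policy `"fixed_only"`: fixed (annualized capital) cost is fixed,
#'   everything else variable; `"fixed_plus_staffing"`: staffing is also
#'   treated as fixed (hiring is sticky in the short run).
#' @return list with `F` (fixed), `V` (variable); `F + V` equals the matrix
#'   grand total exactly.
#' @export
fixed_variable_split <- function(matrix, policy = c("fixed_only", "fixed_plus_staffing")) {
  policy <- match.arg(policy)
  m <- cost_matrix_margins(matrix)
  fixed_cats <- if (policy == "fixed_plus_staffing") c("fixed", "staffing") else "fixed"
  F <- sum(m$columns[fixed_cats])
  list(F = F, V = m$grand_total - F, policy = policy)
}

#' Cost factor of a demand multiplier
#'
#' Within existing capacity, multiplying demand by `m` scales only the
#' variable cost: total becomes `F + m V`, a factor `(F + mV) / (F + V)` of
#' baseline — subproportional whenever any cost is fixed.
#'
#' @param F fixed cost, >= 0.
#' @param V variable cost, >= 0 (with `F + V > 0`).
#' @param m demand multiplier, > 0.
#' @return the cost factor (vectorised over `m`).
#' @export
demand_multiplier_factor <- function(F, V, m) {
  assert_scalar_number(F, "F", min = 0)
  assert_scalar_number(V, "V", min = 0)
  if (F + V <= 0) abort("F + V must be > 0")
  if (any(m <= 0)) abort("demand multiplier must be > 0")
  (F + m * V) / (F + V)
}

#' National cost as a function of coverage
#'
#' Evaluates total cost over a grid of coverage levels. Utilization is
#' coverage relative to baseline (`u = c / baseline_coverage`). Below the
#' capacity threshold only variable cost scales (`F + u V`); above it,
#' capacity blocks are added at `expansion_step_cost` each (one block per
#' `capacity_block` utilization units of excess demand, rounded up), making
#' the curve piecewise with jumps at block boundaries but monotone
#' nondecreasing and subproportional overall.
#'
#' @param matrix a [cost_matrix()] giving the baseline cost structure.
#' @param spec a [scenario_spec()].
#' @param coverages coverage grid; default from `baseline_coverage` to 0.8 in
#'   steps of 0.05. Values below baseline raise an error (demand shrinkage is
#'   not modelled).
#' @param policy fixed/variable policy, see [fixed_variable_split()].
#' @return a `coverage_curve` tibble: `coverage`, `utilization`,
#'   `capacity_blocks`, `total_cost`, `cost_factor`.
#' @export
coverage_response <- function(matrix, spec = scenario_spec(), coverages = NULL,
                              policy = c("fixed_only", "fixed_plus_staffing")) {
  policy <- match.arg(policy)
  coverages <- coverages %||% seq(spec$baseline_coverage, 0.8, by = 0.05)
  if (any(coverages < spec$baseline_coverage - 1e-12)) {
    abort("coverage below baseline: demand shrinkage is not modelled")
  }
  coverages <- sort(unique(coverages))
  fv <- fixed_variable_split(matrix, policy)
  u <- coverages / spec$baseline_coverage
  excess <- pmax(u - spec$capacity_threshold, 0)
  blocks <- ceiling(excess / spec$capacity_block - 1e-12)
  total <- fv$F + u * fv$V + blocks * spec$expansion_step_cost
  baseline <- fv$F + fv$V
  res <- tibble(coverage = coverages, utilization = u,
                capacity_blocks = as.integer(blocks),
                total_cost = total, cost_factor = total / baseline)
  structure(res, class = c("coverage_curve", class(res)),
            F = fv$F, V = fv$V, policy = policy, spec = spec)
}

#' @describeIn coverage_response glance method: baseline cost, fixed share
#'   and the cost factor at the top of the grid.
#' @param x a `coverage_curve`.
#' @param ... unused.
#' @method glance coverage_curve
#' @export
glance.coverage_curve <- function(x, ...) {
  F <- attr(x, "F"); V <- attr(x, "V")
  tibble(baseline_cost = F + V, fixed_share = F / (F + V),
         policy = attr(x, "policy"),
         max_coverage = max(x$coverage), max_cost_factor = max(x$cost_factor))
}

#' @describeIn coverage_response autoplot method: cost factor against
#'   coverage, with the proportional (all-variable) reference line.
#' @param object a `coverage_curve`.
#' @method autoplot coverage_curve
#' @export
autoplot.coverage_curve <- function(object, ...) {
  spec <- attr(object, "spec")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$coverage)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$utilization, linetype = "proportional"),
                       colour = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$cost_factor, linetype = "model"),
                       linewidth = 0.9) +
    ggplot2::geom_vline(xintercept = spec$baseline_coverage * spec$capacity_threshold,
                        linetype = "dotted") +
    ggplot2::labs(x = "coverage of theoretical need",
                  y = "cost factor vs baseline", linetype = NULL,
                  title = "Cost response to rising coverage",
                  subtitle = "dotted line: capacity threshold") +
    ggplot2::theme_minimal()
}
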
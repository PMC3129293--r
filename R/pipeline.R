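# End-to-end pipeline: ingest a sample directory, annualize, run the
# step-down allocation per facility, compute and demand-adjust unit costs,
# cost episode schemes per stratum, aggregate to the national matrix, run
# the coverage scenario and render the report directory with a run manifest.

#' Run the full costing pipeline on a sample directory
#'
#' Stages: ingest -> annualize -> step-down -> unit costs -> demand-side
#' adjust -> episode costing -> national aggregation -> coverage scenario ->
#' report rendering. Every intermediate is written as plain CSV so each stage
#' can be inspected or re-run. Facilities whose final centres carry cost but
#' no output fail the unit-cost stage preconditions; they are excluded from
#' unit costs and counted in the manifest, not silently dropped. Non-service
#' units (administration, community programmes) contribute to the national
#' matrix only.
#'
#' @param sample_dir directory in the [write_sample()] layout.
#' @param out_dir report output directory.
#' @param allocation an [allocation_config()] or path to an allocation YAML.
#' @param spec a [scenario_spec()] or path to a scenario YAML.
#' @param fixed_policy fixed/variable policy for unit costs and scenarios.
#' @param population optional national population for the per-capita figure.
#' @param rate Ksh per EUR for the EUR report matrix.
#' @return invisibly, a list with the national `matrix` (EUR), the
#'   `unit_cost_table`, `episodes`, the coverage `curve` and the `manifest`.
#' @export
run_pipeline <- function(sample_dir, out_dir,
                         allocation = allocation_config(),
                         spec = scenario_spec(),
                         fixed_policy = "fixed_only",
                         population = NULL, rate = 90.66) {
  if (is.character(allocation)) allocation <- read_allocation_config(allocation)
  if (is.character(spec)) spec <- read_scenario_spec(spec)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(sprintf("FAILED at stage: %s\n%s", name, conditionMessage(e)),
                 file.path(out_dir, "FAILED"))
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
            class = paste0("khscm_stage_", name))
    })
  }

  sample <- stage("ingest", read_sample(sample_dir))
  plan <- sample$config$plan
  inflation <- sample$config$inflation %||% 0.05

  annualized <- stage("annualize",
                      lapply(sample$facilities, annualize_ledger, inflation = inflation))

  excluded <- character()
  per_fac <- list()
  stage("stepdown", {
    for (rec in annualized) {
      service <- any(rec$centres$kind == "final")
      if (!service) {
        per_fac[[rec$id]] <- list(record = rec, result = NULL, units = NULL)
        next
      }
      res <- stepdown_allocate(rec, allocation)
      units <- tryCatch(unit_costs(res, rec, fixed_policy = fixed_policy),
                        khscm_unit_cost_error = function(e) NULL)
      if (is.null(units)) excluded <- c(excluded, rec$id)
      per_fac[[rec$id]] <- list(record = rec, result = res, units = units)
    }
    invisible(NULL)
  })

  unit_cost_table <- stage("unit_costs", {
    rows <- purrr::map(per_fac, function(f) {
      if (is.null(f$units)) return(NULL)
      u <- suppressWarnings(
        demand_side_adjust(f$units, sample$exit_interviews,
                           level = f$record$level, trustee = f$record$trustee))
      mutate(as_tibble(u), facility_id = f$record$id, stratum = f$record$stratum)
    })
    bind_rows(rows)
  })
  stratum_units <- unit_cost_table |>
    group_by(.data$stratum, .data$measure) |>
    summarise(across(all_of(c("unit_cost_ksh", "direct_ksh", "indirect_ksh",
                              "fixed_ksh", "variable_ksh")), mean),
              .groups = "drop")
  readr::write_csv(stratum_units, file.path(out_dir, "unit_costs.csv"))

  episodes <- stage("keph", {
    if (is.null(sample$schemes) || nrow(sample$schemes) == 0) {
      abort("no treatment schemes in the sample directory")
    }
    staff_rates <- default_staff_rates(annualized)
    rows <- list()
    for (st in unique(stratum_units$stratum)) {
      u <- stratum_units[stratum_units$stratum == st, ]
      class(u) <- c("unit_costs", class(tibble()))
      for (ag in c("under5", "over5")) {
        rows[[paste(st, ag)]] <- suppressWarnings(
          cost_keph_episodes(sample$schemes, sample$scheme_components,
                             sample$price_list, staff_rates, u,
                             age_group = ag, stratum = st))
      }
    }
    bind_rows(rows)
  })

  matrix_eur <- stage("aggregate", {
    mat <- aggregate_sample(sample)
    convert_matrix(mat, rate)
  })

  curve <- stage("scenario", {
    cv <- coverage_response(matrix_eur, spec, policy = fixed_policy)
    readr::write_csv(as_tibble(cv), file.path(out_dir, "curve.csv"))
    cv
  })

  stage("render", render_tables(matrix_eur, stratum_units, episodes, out_dir))

  manifest <- stage("manifest", {
    inputs <- list.files(sample_dir, recursive = TRUE, full.names = TRUE)
    man <- list(
      tool = "khscm", version = as.character(utils::packageVersion("khscm")),
      timestamp = format(Sys.time(), tz = "UTC"),
      sample_dir = normalizePath(sample_dir),
      n_facilities = length(sample$facilities),
      n_excluded_unit_costs = length(excluded),
      excluded = excluded,
      input_hashes = as.list(tools::md5sum(inputs)),
      fixed_policy = fixed_policy,
      scenario = unclass(spec)
    )
    if (!is.null(population)) {
      m <- cost_matrix_margins(matrix_eur)
      man$per_capita_eur <- per_capita(m$grand_total, population)
    }
    jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    man
  })

  invisible(list(matrix = matrix_eur, unit_cost_table = stratum_units,
                 episodes = episodes, curve = curve, manifest = manifest,
                 excluded = excluded))
}

# mean per-minute staff cost by cadre across the sample's payrolls
default_staff_rates <- function(facilities) {
  pay <- bind_rows(purrr::compact(purrr::map(facilities, "payroll")))
  if (nrow(pay) == 0) {
    return(c(nurse = 8, clinical_officer = 12, doctor = 25, support_staff = 4))
  }
  rates <- staff_minute_cost(pay) |>
    group_by(.data$cadre) |>
    summarise(rate = mean(.data$cost_per_minute_ksh), .groups = "drop")
  stats::setNames(rates$rate, rates$cadre)
}
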
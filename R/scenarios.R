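# Scenario orchestration on a seascape: climate-naive vs climate-smart
# prioritisations at global or country scale, threshold sweeps and the
# global-vs-country efficiency comparison.

# Assemble the (features, amounts) tables of a scenario: optionally
# country-split, then optionally CPA-expanded at `threshold`.
scenario_tables <- function(dataset, threshold, resilience_field,
                            scale = c("global", "country"),
                            features = NULL, amounts = NULL) {
  scale <- match.arg(scale)
  feats <- features %||% dataset$features
  amts <- amounts %||% dataset$amounts
  if (scale == "country") {
    sp <- split_features_by_country(feats, amts, dataset$planning_units)
    feats <- sp$features
    amts <- sp$amounts
  }
  if (threshold > 0) {
    cs <- build_climate_smart_features(feats, amts,
                                       dataset$planning_units,
                                       threshold, resilience_field)
    feats <- cs$features
    amts <- cs$amounts
  }
  list(features = feats, amounts = amts)
}

# Build the list of problems for a scenario: one global problem, or one per
# country. Returns list(problems = <list>, country_ids = <chr or NULL>).
scenario_problems <- function(dataset, threshold, resilience_field,
                              scale = c("global", "country"),
                              features = NULL, amounts = NULL) {
  scale <- match.arg(scale)
  tabs <- scenario_tables(dataset, threshold, resilience_field, scale,
                          features, amounts)
  units <- dataset$planning_units
  if (scale == "global") {
    return(list(problems = list(build_problem(units, tabs$features,
                                              tabs$amounts)),
                country_ids = NULL))
  }
  countries <- sort(unique(units$country_id))
  problems <- lapply(countries, function(cc) {
    u <- units[units$country_id == cc, , drop = FALSE]
    f <- tabs$features[tabs$features$country_id %in% cc, , drop = FALSE]
    a <- tabs$amounts[tabs$amounts$feature_id %in% f$feature_id, ,
                      drop = FALSE]
    build_problem(u, f, a)
  })
  list(problems = problems, country_ids = countries)
}

#' Prioritise a seascape
#'
#' Runs one minimum-set prioritisation of a synthetic (or imported)
#' seascape. `threshold = 0` is the climate-naive design; positive
#' thresholds make it climate-smart by adding climate-priority-area
#' features for the chosen resilience field. At country scale each
#' country's problem is solved independently and the selections merged.
#'
#' @param dataset A `seascape` object.
#' @param threshold Climate-smart threshold in [0, 1].
#' @param resilience_field `"mean"`, `"landward"` or `"seaward"`.
#' @param scale `"global"` (transboundary) or `"country"`.
#' @param gap Relative optimality gap passed to the solver.
#' @param features,amounts Optional replacement feature/amount tables (e.g.
#'   rebuilt under a uniform target rule); default uses the dataset's own.
#' @return A `minset_solution`; for country scale, the merged solution with
#'   `status` `"infeasible"` if any country fails (the failing countries
#'   are listed in attribute `infeasible_countries`).
#' @export
prioritize_seascape <- function(dataset, threshold = 0,
                                resilience_field = "mean",
                                scale = c("global", "country"),
                                gap = 1e-4,
                                features = NULL, amounts = NULL) {
  scale <- match.arg(scale)
  built <- scenario_problems(dataset, threshold, resilience_field, scale,
                             features, amounts)
  sols <- solve_minset_batch(built$problems, gap = gap)
  if (scale == "global") return(sols[[1L]])
  merge_country_solutions(sols, built$country_ids, dataset$planning_units)
}

# Union of per-country solutions as one network-level solution.
merge_country_solutions <- function(solutions, country_ids, units) {
  bad <- vapply(solutions, function(s) s$status == "infeasible",
                logical(1))
  if (any(bad)) {
    sol <- new_solution(integer(0), NA_real_, "infeasible",
                        relative_gap_achieved = NA_real_,
                        solver_name = "merged country-scale")
    attr(sol, "infeasible_countries") <- country_ids[bad]
    return(sol)
  }
  sel <- sort(unique(unlist(lapply(solutions, `[[`,
                                   "selected_unit_ids"))))
  gaps <- vapply(solutions, `[[`, numeric(1), "relative_gap_achieved")
  new_solution(
    sel,
    sum(units$mangrove_area_km2[units$pu_id %in% sel]),
    if (any(vapply(solutions, `[[`, character(1),
                   "status") == "gap_reached")) "gap_reached"
    else "optimal",
    relative_gap_achieved = max(gaps),
    solver_name = "merged country-scale",
    wall_time_s = sum(vapply(solutions, `[[`, numeric(1), "wall_time_s"))
  )
}

#' Sweep the climate-smart threshold
#'
#' Solves one prioritisation per threshold and reports, for each, the
#' percent mangrove area selected, the area-weighted resilience of the
#' selection, and their relative changes versus the climate-naive
#' (threshold 0) baseline of the same scale. The default grid runs from
#' 0.05 to 1.00 in steps of 0.05 (20 runs).
#'
#' @param dataset A `seascape`.
#' @param thresholds Numeric vector of thresholds in [0, 1].
#' @param resilience_field Field driving the CPA split and the reported
#'   resilience.
#' @param scale `"global"` or `"country"`.
#' @param gap Relative optimality gap.
#' @param features,amounts Optional replacement tables (see
#'   [prioritize_seascape()]).
#' @return Tibble with columns `threshold`, `objective_km2`, `area_pct`,
#'   `resilience`, `d_area_pct`, `d_resilience_pct`, `scale`; attribute
#'   `"baseline"` holds the climate-naive solution.
#' @export
threshold_sweep <- function(dataset, thresholds = seq(0.05, 1, by = 0.05),
                            resilience_field = "mean",
                            scale = c("global", "country"),
                            gap = 1e-4,
                            features = NULL, amounts = NULL) {
  scale <- match.arg(scale)
  if (any(thresholds < 0 | thresholds > 1)) {
    stop_validation("thresholds must lie in [0, 1]")
  }
  units <- dataset$planning_units

  # one backend invocation for the whole sweep (baseline + thresholds)
  all_th <- unique(c(0, thresholds))
  built <- lapply(all_th, function(th) {
    scenario_problems(dataset, th, resilience_field, scale,
                      features, amounts)
  })
  problems <- unlist(lapply(built, `[[`, "problems"), recursive = FALSE)
  sols_flat <- solve_minset_batch(problems, gap = gap)
  solutions <- vector("list", length(all_th))
  pos <- 0L
  for (k in seq_along(all_th)) {
    n_k <- length(built[[k]]$problems)
    chunk <- sols_flat[pos + seq_len(n_k)]
    pos <- pos + n_k
    solutions[[k]] <- if (scale == "global") chunk[[1L]]
                      else merge_country_solutions(chunk,
                                                   built[[k]]$country_ids,
                                                   units)
  }
  baseline <- solutions[[match(0, all_th)]]
  if (baseline$status == "infeasible") {
    stop_infeasible("climate-naive baseline is infeasible")
  }
  base_area <- percent_area_selected(baseline, units)
  base_res <- area_weighted_resilience(baseline, units, resilience_field)

  rows <- vector("list", length(thresholds))
  for (k in seq_along(thresholds)) {
    th <- thresholds[k]
    sol <- solutions[[match(th, all_th)]]
    if (sol$status == "infeasible") {
      partial <- dplyr::bind_rows(rows[seq_len(k - 1L)])
      cond <- rlang::error_cnd(
        class = c("mangroveplan_infeasible_error", "mangroveplan_error"),
        message = sprintf("sweep aborted: threshold %.2f infeasible", th),
        partial = partial
      )
      rlang::cnd_signal(cond)
    }
    area <- percent_area_selected(sol, units)
    res <- area_weighted_resilience(sol, units, resilience_field)
    rows[[k]] <- tibble::tibble(
      threshold = th,
      objective_km2 = sol$objective_km2,
      area_pct = area,
      resilience = res,
      d_area_pct = relative_change(area, base_area),
      d_resilience_pct = relative_change(res, base_res),
      scale = scale
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "baseline") <- baseline
  out
}

#' Compare global-scale and country-scale prioritisations
#'
#' Solves the same scenario at both planning scales and reports the
#' efficiency comparison: total percent area and resilience of each, the
#' relative area change of the country-scale network versus the global one,
#' a per-country selection table, the standard deviation of per-country
#' selected proportions (a representativeness measure: lower at country
#' scale), and an audit of the merged country-scale solution against the
#' shared parent biodiversity targets, for which it is always feasible
#' because inherited child target fractions sum to the parent targets.
#'
#' @param dataset A `seascape` with at least two countries.
#' @param threshold Climate-smart threshold in [0, 1].
#' @param resilience_field Resilience field for the CPA split and reports.
#' @param gap Relative optimality gap.
#' @return A `scale_comparison` list.
#' @export
compare_scales <- function(dataset, threshold = 0.3,
                           resilience_field = "mean", gap = 1e-4) {
  units <- dataset$planning_units
  if (length(unique(units$country_id)) < 2L) {
    stop_validation("scale comparison needs at least 2 countries")
  }
  sol_global <- prioritize_seascape(dataset, threshold, resilience_field,
                                    "global", gap)
  sol_country <- prioritize_seascape(dataset, threshold, resilience_field,
                                     "country", gap)
  if (sol_country$status == "infeasible") {
    stop_infeasible(
      "country-scale problem infeasible for: %s",
      paste(attr(sol_country, "infeasible_countries"), collapse = ", ")
    )
  }

  per_country <- units |>
    dplyr::group_by(country_id = .data$country_id) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(
        pct_selected_global = 100 *
          sum(df$mangrove_area_km2[df$pu_id %in%
                                     sol_global$selected_unit_ids]) /
          sum(df$mangrove_area_km2),
        pct_selected_country = 100 *
          sum(df$mangrove_area_km2[df$pu_id %in%
                                     sol_country$selected_unit_ids]) /
          sum(df$mangrove_area_km2)
      )
    }) |>
    dplyr::ungroup()

  # Merged country-scale solution audited against the parent biodiversity
  # targets (the climate-naive global problem). Both scales must meet these
  # identical objectives; the audit is exact by construction because child
  # targets sum to parent targets under inherited fractions. At positive
  # thresholds the two scales carry *different* CPA constraints (resilience
  # is ranked within-country at country scale), so the climate-smart
  # constraint sets are not comparable across scales.
  global_problem <- scenario_problems(dataset, 0, resilience_field,
                                      "global")$problems[[1L]]
  merged_audit <- audit_solution(global_problem, sol_country)

  area_global <- percent_area_selected(sol_global, units)
  area_country <- percent_area_selected(sol_country, units)
  structure(
    list(
      threshold = threshold,
      resilience_field = resilience_field,
      solution_global = sol_global,
      solution_country = sol_country,
      area_pct_global = area_global,
      area_pct_country = area_country,
      d_area_pct = relative_change(area_country, area_global),
      resilience_global = area_weighted_resilience(sol_global, units,
                                                   resilience_field),
      resilience_country = area_weighted_resilience(sol_country, units,
                                                    resilience_field),
      per_country = per_country,
      sd_prop_selected_global =
        stats::sd(per_country$pct_selected_global / 100),
      sd_prop_selected_country =
        stats::sd(per_country$pct_selected_country / 100),
      merged_feasible_for_global = all(merged_audit$met),
      merged_audit = merged_audit
    ),
    class = "scale_comparison"
  )
}

#' @export
print.scale_comparison <- function(x, ...) {
  cat(sprintf("<scale_comparison> threshold %.2f, field %s\n",
              x$threshold, x$resilience_field))
  cat(sprintf("  global:  %.1f%% area, resilience %.1f\n",
              x$area_pct_global, x$resilience_global))
  cat(sprintf("  country: %.1f%% area, resilience %.1f (= %+.1f%% area)\n",
              x$area_pct_country, x$resilience_country, x$d_area_pct))
  cat(sprintf("  sd of per-country selected proportion: %.2f (global) vs %.2f (country)\n",
              x$sd_prop_selected_global, x$sd_prop_selected_country))
  cat(sprintf("  merged country solution feasible for global problem: %s\n",
              x$merged_feasible_for_global))
  invisible(x)
}
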
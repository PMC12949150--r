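# Network evaluation statistics: percent area selected, area-weighted
# resilience, relative changes, Cohen's kappa agreement, protected-area
# audits, threshold sweeps and global-vs-country scale comparisons.

#' Percent of mangrove area selected
#'
#' @param solution A `minset_solution` or vector of selected `pu_id`s.
#' @param units Planning-unit table.
#' @param country Optional country id restricting the scope; default is the
#'   whole planning region.
#' @return Percentage in [0, 100] of the scope's mangrove area that lies in
#'   selected units.
#' @export
percent_area_selected <- function(solution, units, country = NULL) {
  sel <- as_selected_ids(solution)
  scope <- if (is.null(country)) units
           else units[units$country_id %in% country, , drop = FALSE]
  if (nrow(scope) == 0L) {
    stop_validation("empty scope: no planning units in country %s",
                    paste(country, collapse = ", "))
  }
  100 * sum(scope$mangrove_area_km2[scope$pu_id %in% sel]) /
    sum(scope$mangrove_area_km2)
}

#' Area-weighted climate resilience of a selection
#'
#' Mean resilience of the selected network, weighting each selected unit by
#' its mangrove area. For `field = "mean"` the per-unit value is the
#' arithmetic mean of the landward and seaward edge resilience.
#'
#' @inheritParams percent_area_selected
#' @param field `"mean"`, `"landward"` or `"seaward"`.
#' @return Area-weighted resilience in [0, 100]; `NA` for an empty
#'   selection (undefined).
#' @export
area_weighted_resilience <- function(solution, units,
                                     field = c("mean", "landward",
                                               "seaward")) {
  field <- match.arg(field)
  sel <- as_selected_ids(solution)
  picked <- units[units$pu_id %in% sel, , drop = FALSE]
  if (nrow(picked) == 0L) return(NA_real_)
  r <- resolve_resilience(picked, field)
  weighted_mean_safe(unname(r), picked$mangrove_area_km2)
}

#' Relative change between two scenario values
#'
#' `100 * (new - base) / base`, the form used to compare prioritisation
#' scenarios (e.g. climate-smart vs climate-naive area, or country-scale vs
#' global-scale area).
#'
#' @param new_value,base_value Scenario values; `base_value` must be
#'   non-zero.
#' @return Percent change.
#' @examples
#' relative_change(42.6, 39.7)  # 7.3 (to 1 d.p.)
#' @export
relative_change <- function(new_value, base_value) {
  if (any(base_value == 0)) {
    stop_validation("relative change is undefined for a zero baseline")
  }
  100 * (new_value - base_value) / base_value
}

#' Cohen's kappa agreement between two selections
#'
#' Chance-corrected agreement of two binary unit selections over a common
#' set of planning units: `kappa = (p_o - p_e) / (1 - p_e)` with the
#' expected agreement `p_e` taken from the marginal selection rates. When
#' both selections are degenerate and identical (`p_o = p_e = 1`) kappa is
#' defined as 1. Units are unweighted by default; optional weights (e.g.
#' mangrove area) may be supplied.
#'
#' @param selection_a,selection_b `minset_solution`s or vectors of selected
#'   `pu_id`s.
#' @param units_subset Vector of `pu_id`s defining the comparison scope, or
#'   a planning-unit table (its `pu_id` column is used).
#' @param weights Optional per-unit weights aligned with `units_subset`.
#' @return A `kappa_result`: list with `kappa`, `n_units`, `category` and
#'   the 2x2 `counts`.
#' @export
cohen_kappa <- function(selection_a, selection_b, units_subset,
                        weights = NULL) {
  ids <- if (is.data.frame(units_subset)) units_subset$pu_id
         else units_subset
  if (length(ids) == 0L) stop_validation("empty unit subset for kappa")
  w <- weights %||% rep(1, length(ids))
  a <- ids %in% as_selected_ids(selection_a)
  b <- ids %in% as_selected_ids(selection_b)
  tot <- sum(w)
  both <- sum(w[a & b]) / tot
  a_only <- sum(w[a & !b]) / tot
  b_only <- sum(w[!a & b]) / tot
  neither <- sum(w[!a & !b]) / tot
  p_o <- both + neither
  p_a <- both + a_only
  p_b <- both + b_only
  p_e <- p_a * p_b + (1 - p_a) * (1 - p_b)
  kappa <- if (p_e >= 1) {
    if (p_o >= 1) 1 else 0
  } else {
    (p_o - p_e) / (1 - p_e)
  }
  structure(
    list(
      kappa = kappa,
      n_units = length(ids),
      category = kappa_category(kappa),
      counts = c(both = both, a_only = a_only, b_only = b_only,
                 neither = neither) * tot
    ),
    class = "kappa_result"
  )
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f over %d units: %s\n",
              x$kappa, x$n_units, x$category))
  invisible(x)
}

#' Verbal agreement category for a kappa value
#'
#' The two lowest bands follow the convention used for mapping agreement of
#' reserve-selection maps: kappa at or below 0 is "great disagreement" and
#' (0, 0.1] "none to slight". The remaining bands follow a standard
#' Landis-Koch-style scale under which 0.38 is "fair" agreement: (0.1, 0.2]
#' "slight", (0.2, 0.4] "fair", (0.4, 0.6] "moderate", (0.6, 0.8]
#' "substantial", (0.8, 1] "almost perfect".
#'
#' @param kappa Kappa value(s) in [-1, 1].
#' @return Character vector of category labels.
#' @export
kappa_category <- function(kappa) {
  if (any(kappa < -1 - 1e-12 | kappa > 1 + 1e-12)) {
    stop_validation("kappa must lie in [-1, 1]")
  }
  breaks <- c(-Inf, 0, 0.1, 0.2, 0.4, 0.6, 0.8, Inf)
  labels <- c("great disagreement", "none to slight", "slight", "fair",
              "moderate", "substantial", "almost perfect")
  as.character(cut(kappa, breaks = breaks, labels = labels, right = TRUE))
}

#' Evaluate a solution as a network report
#'
#' @param solution A `minset_solution` or vector of selected `pu_id`s.
#' @param units Planning-unit table.
#' @param scenario_label Free-text label carried into the report.
#' @return An `evaluation_report`: percent area selected; area-weighted
#'   resilience for the mean, landward and seaward fields; and a per-country
#'   table of percent selected and area-weighted mean resilience.
#' @export
evaluate_solution <- function(solution, units, scenario_label = "") {
  sel <- as_selected_ids(solution)
  per_country <- units |>
    dplyr::group_by(country_id = .data$country_id) |>
    dplyr::group_modify(function(df, key) {
      tibble::tibble(
        pct_area_selected = 100 *
          sum(df$mangrove_area_km2[df$pu_id %in% sel]) /
          sum(df$mangrove_area_km2),
        resilience = area_weighted_resilience(sel, df, "mean")
      )
    }) |>
    dplyr::ungroup()
  structure(
    list(
      scenario_label = scenario_label,
      pct_area_selected = percent_area_selected(sel, units),
      resilience_mean = area_weighted_resilience(sel, units, "mean"),
      resilience_landward = area_weighted_resilience(sel, units,
                                                     "landward"),
      resilience_seaward = area_weighted_resilience(sel, units, "seaward"),
      per_country = per_country
    ),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s\n", x$scenario_label))
  cat(sprintf("  %% mangrove area selected: %.1f\n", x$pct_area_selected))
  cat(sprintf("  area-weighted resilience (mean/landward/seaward): %.1f / %.1f / %.1f\n",
              x$resilience_mean, x$resilience_landward,
              x$resilience_seaward))
  cat(sprintf("  countries with selection: %d of %d\n",
              sum(x$per_country$pct_area_selected > 0),
              nrow(x$per_country)))
  invisible(x)
}

#' Audit the existing protected-area network against feature targets
#'
#' Evaluates a protected-area overlay (per-unit protected fractions) the
#' way a candidate reserve network is evaluated: per-feature protected
#' amounts, how many targets it meets, the mean shortfall (as percent of
#' range area) over unmet features, overall percent of mangrove area
#' protected, area-weighted resilience of the protected estate, and - when
#' a prioritisation solution is supplied - the percent of the solution's
#' mangrove area already protected (overlap).
#'
#' @param features,amounts Feature and amount tables.
#' @param units Planning-unit table.
#' @param protected_fractions Per-unit protected fractions in [0, 1];
#'   defaults to `units$protected_fraction`.
#' @param solution Optional `minset_solution` (or selected id vector) for
#'   the overlap statistic.
#' @return A `pa_audit` list: `per_feature` tibble, `n_targets_met`,
#'   `n_features`, `mean_shortfall_pct_range`, `pct_area_protected`,
#'   `resilience` (named vector over the three fields) and `overlap_pct`
#'   (`NA` without a solution).
#' @export
audit_protected_network <- function(features, amounts, units,
                                    protected_fractions = NULL,
                                    solution = NULL) {
  frac <- protected_fractions %||% units$protected_fraction
  if (is.null(frac)) {
    stop_validation("no protected fractions supplied or found in `units`")
  }
  if (any(frac < 0 | frac > 1)) {
    stop_validation("protected fractions must lie in [0, 1]")
  }
  frac_by_unit <- stats::setNames(frac, units$pu_id)

  amt <- amounts
  amt$protected_km2 <- amt$area_km2 *
    unname(frac_by_unit[as.character(amt$pu_id)])
  per_feature <- amt |>
    dplyr::group_by(feature_id = .data$feature_id) |>
    dplyr::summarise(protected_km2 = sum(.data$protected_km2),
                     .groups = "drop") |>
    dplyr::right_join(
      features[, c("feature_id", "range_area_km2", "target_amount_km2")],
      by = "feature_id"
    ) |>
    dplyr::mutate(
      protected_km2 = dplyr::coalesce(.data$protected_km2, 0),
      met = .data$protected_km2 >= .data$target_amount_km2 * (1 - 1e-6),
      shortfall_pct_range =
        100 * pmax(0, .data$target_amount_km2 - .data$protected_km2) /
          .data$range_area_km2
    ) |>
    dplyr::arrange(.data$feature_id)

  unmet <- per_feature[!per_feature$met, , drop = FALSE]
  prot_weight <- units$mangrove_area_km2 * frac
  resilience <- vapply(c("mean", "landward", "seaward"), function(f) {
    weighted_mean_safe(unname(resolve_resilience(units, f)), prot_weight)
  }, numeric(1))

  overlap_pct <- NA_real_
  if (!is.null(solution)) {
    sel <- as_selected_ids(solution)
    in_sel <- units$pu_id %in% sel
    sol_area <- sum(units$mangrove_area_km2[in_sel])
    overlap_pct <- if (sol_area > 0) {
      100 * sum(prot_weight[in_sel]) / sol_area
    } else {
      NA_real_
    }
  }

  structure(
    list(
      per_feature = per_feature,
      n_targets_met = sum(per_feature$met),
      n_features = nrow(per_feature),
      mean_shortfall_pct_range =
        if (nrow(unmet) > 0L) mean(unmet$shortfall_pct_range) else 0,
      pct_area_protected =
        100 * sum(prot_weight) / sum(units$mangrove_area_km2),
      resilience = resilience,
      overlap_pct = overlap_pct
    ),
    class = "pa_audit"
  )
}

#' @export
print.pa_audit <- function(x, ...) {
  cat("<pa_audit>\n")
  cat(sprintf("  %.1f%% of mangrove area protected\n",
              x$pct_area_protected))
  cat(sprintf("  targets met: %d of %d; mean shortfall of unmet: %.1f%% of range\n",
              x$n_targets_met, x$n_features, x$mean_shortfall_pct_range))
  cat(sprintf("  protected-estate resilience (mean/landward/seaward): %.1f / %.1f / %.1f\n",
              x$resilience[["mean"]], x$resilience[["landward"]],
              x$resilience[["seaward"]]))
  if (!is.na(x$overlap_pct)) {
    cat(sprintf("  overlap with supplied solution: %.1f%%\n",
                x$overlap_pct))
  }
  invisible(x)
}
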
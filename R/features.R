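#' Area-based target rule
#'
#' Representation targets for conservation features are set from species
#' range size: species with ranges at or below `lower_cap_km2` receive the
#' maximum target fraction, species at or above `upper_cap_km2` the minimum,
#' and intermediate ranges are interpolated linearly in log10 of range area.
#' A uniform mode assigns the same fraction to every species regardless of
#' range size (the 30 percent sensitivity setting).
#'
#' @param lower_cap_km2 Range area at or below which the maximum target
#'   applies (default 10,000 km2).
#' @param upper_cap_km2 Range area at or above which the minimum target
#'   applies (default 250,000 km2).
#' @param max_fraction,min_fraction Target fractions at the two caps
#'   (defaults 1.0 and 0.1).
#' @param mode `"area_based"` (default) or `"uniform"`.
#' @param uniform_fraction Fraction used when `mode = "uniform"`
#'   (default 0.30).
#' @return A `target_rule` object.
#' @export
target_rule <- function(lower_cap_km2 = 10000, upper_cap_km2 = 250000,
                        max_fraction = 1.0, min_fraction = 0.1,
                        mode = c("area_based", "uniform"),
                        uniform_fraction = 0.30) {
  mode <- match.arg(mode)
  assert_scalar_number(lower_cap_km2, "lower_cap_km2", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(upper_cap_km2, "upper_cap_km2", lower = 0,
                       strict_lower = TRUE)
  if (lower_cap_km2 >= upper_cap_km2) {
    stop_validation("invariant violated: lower_cap_km2 < upper_cap_km2")
  }
  assert_scalar_number(max_fraction, "max_fraction", lower = 0, upper = 1)
  assert_scalar_number(min_fraction, "min_fraction", lower = 0, upper = 1)
  if (min_fraction >= max_fraction) {
    stop_validation("invariant violated: min_fraction < max_fraction")
  }
  assert_scalar_number(uniform_fraction, "uniform_fraction", lower = 0,
                       upper = 1)
  structure(
    list(lower_cap_km2 = lower_cap_km2, upper_cap_km2 = upper_cap_km2,
         max_fraction = max_fraction, min_fraction = min_fraction,
         mode = mode, uniform_fraction = uniform_fraction),
    class = "target_rule"
  )
}

#' Target fraction for a given range area
#'
#' Log10-interpolated, area-based representation target: 100 percent for the
#' smallest-ranged species down to 10 percent for the widest-ranged, under
#' the default rule. Vectorised over `range_area_km2`.
#'
#' @param range_area_km2 Positive species range area(s) in km2.
#' @param rule A [target_rule()].
#' @return Target fraction(s) in `[min_fraction, max_fraction]`.
#' @examples
#' target_fraction(c(5e3, 5e4, 3e5))  # 1.00, 0.55, 0.10
#' @export
target_fraction <- function(range_area_km2, rule = target_rule()) {
  if (any(!is.finite(range_area_km2)) || any(range_area_km2 <= 0)) {
    stop_validation("`range_area_km2` must be positive and finite")
  }
  if (rule$mode == "uniform") {
    return(rep(rule$uniform_fraction, length(range_area_km2)))
  }
  span <- log10(rule$upper_cap_km2) - log10(rule$lower_cap_km2)
  p <- (log10(range_area_km2) - log10(rule$lower_cap_km2)) / span
  p <- pmin(pmax(p, 0), 1)
  rule$max_fraction - (rule$max_fraction - rule$min_fraction) * p
}

#' Assign species to unoccupied planning units from the nearest occupied unit
#'
#' Planning units intersected by no species range inherit the full species
#' set of the nearest occupied unit (Euclidean distance between centroids in
#' projected coordinates); distance ties are broken by the smallest donor
#' unit id.
#'
#' @param species_ranges Named list: species id -> integer vector of
#'   occupied `pu_id`s.
#' @param units Planning-unit table with `pu_id`, `x`, `y`.
#' @return The augmented `species_ranges` list (unit ids sorted).
#' @export
nearest_unit_assignment <- function(species_ranges, units) {
  occupied <- sort(unique(unlist(species_ranges, use.names = FALSE)))
  orphans <- setdiff(units$pu_id, occupied)
  if (length(orphans) == 0L) return(lapply(species_ranges, sort))
  if (length(occupied) == 0L) {
    stop_validation("no occupied planning unit exists to donate species")
  }
  donors <- units[match(occupied, units$pu_id), , drop = FALSE]
  # donors sorted by pu_id, so which.min's first-match rule implements the
  # smallest-id tie-break
  donor_of <- vapply(orphans, function(o) {
    u <- units[match(o, units$pu_id), ]
    d2 <- (donors$x - u$x)^2 + (donors$y - u$y)^2
    donors$pu_id[which.min(d2)]
  }, numeric(1))
  aug <- lapply(species_ranges, function(ids) {
    sort(unique(c(ids, orphans[donor_of %in% ids])))
  })
  aug
}

#' Build geomorphic-species features and the amount matrix
#'
#' Each species range is subdivided by biophysical typology class, producing
#' one conservation feature per (species, typology) pair with non-zero area.
#' The amount of a feature in a planning unit is the area of that typology
#' in the unit, provided the species occurs there. The representation target
#' fraction is computed from the species' total range area (the sum of all
#' its occupied typology areas) and applied identically to each of the
#' species' geomorphic subgroups; each feature's target amount is that
#' fraction of the feature's own range area.
#'
#' @param species_ranges Named list: species id -> integer vector of
#'   occupied `pu_id`s.
#' @param typology_map Long table with `pu_id`, `typology`, `area_km2`.
#' @param rule A [target_rule()].
#' @return List with `features` (feature_id, species_id, typology,
#'   country_id, range_area_km2, target_fraction, target_amount_km2) and
#'   `amounts` (pu_id, feature_id, area_km2) tibbles.
#' @export
build_features <- function(species_ranges, typology_map,
                           rule = target_rule()) {
  assert_columns(typology_map, c("pu_id", "typology", "area_km2"),
                 "typology map")
  range_tbl <- tibble::tibble(
    species_id = rep(names(species_ranges),
                     lengths(species_ranges)),
    pu_id = unlist(species_ranges, use.names = FALSE)
  )
  missing_units <- setdiff(range_tbl$pu_id, typology_map$pu_id)
  if (length(missing_units) > 0L) {
    stop_validation(
      "species range unit(s) absent from the typology map: %s",
      paste(utils::head(missing_units, 10L), collapse = ", ")
    )
  }
  cells <- dplyr::inner_join(range_tbl, typology_map, by = "pu_id",
                             relationship = "many-to-many")
  cells <- cells[cells$area_km2 > 0, , drop = FALSE]

  empty <- setdiff(names(species_ranges), unique(cells$species_id))
  if (length(empty) > 0L) {
    stop_validation(
      "species with empty range after typology intersection: %s",
      paste(empty, collapse = ", ")
    )
  }

  species_area <- cells |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(species_range_km2 = sum(.data$area_km2),
                     .groups = "drop")
  species_area$species_fraction <-
    target_fraction(species_area$species_range_km2, rule)

  features <- cells |>
    dplyr::group_by(.data$species_id, .data$typology) |>
    dplyr::summarise(range_area_km2 = sum(.data$area_km2),
                     .groups = "drop") |>
    dplyr::inner_join(species_area, by = "species_id") |>
    dplyr::mutate(
      feature_id = paste(.data$species_id, .data$typology, sep = "_"),
      country_id = NA_character_,
      target_fraction = .data$species_fraction,
      target_amount_km2 = .data$target_fraction * .data$range_area_km2
    ) |>
    dplyr::select("feature_id", "species_id", "typology", "country_id",
                  "range_area_km2", "target_fraction",
                  "target_amount_km2") |>
    dplyr::arrange(.data$feature_id)

  amounts <- cells |>
    dplyr::mutate(
      feature_id = paste(.data$species_id, .data$typology, sep = "_")
    ) |>
    dplyr::select("pu_id", "feature_id", "area_km2") |>
    dplyr::arrange(.data$feature_id, .data$pu_id)

  list(features = features, amounts = tibble::as_tibble(amounts))
}

#' Split features by country
#'
#' Partitions every feature into per-country child features according to the
#' country of each planning unit carrying it. By default the child inherits
#' the parent's target fraction, so child target amounts sum exactly to the
#' parent target amount (which makes the union of per-country optima
#' feasible for the corresponding global problem). Alternatively the
#' fractions can be recomputed from country-level species range areas.
#'
#' @param features,amounts Tables from [build_features()].
#' @param units Planning-unit table with `pu_id` and `country_id`.
#' @param recompute_targets If `TRUE`, recompute each child's target
#'   fraction from the species' country-level range area under `rule`
#'   instead of inheriting the parent fraction.
#' @param rule A [target_rule()]; used only when `recompute_targets = TRUE`.
#' @return List with country-split `features` and `amounts` tables; child
#'   feature ids are `<parent>@<country>`.
#' @export
split_features_by_country <- function(features, amounts, units,
                                      recompute_targets = FALSE,
                                      rule = target_rule()) {
  assert_columns(units, c("pu_id", "country_id"), "planning-unit table")
  if (anyNA(units$country_id)) {
    stop_validation("every planning unit must have a country id")
  }
  amt <- dplyr::inner_join(
    amounts,
    units[, c("pu_id", "country_id")],
    by = "pu_id"
  )
  amt$child_id <- paste(amt$feature_id, amt$country_id, sep = "@")

  child <- amt |>
    dplyr::group_by(.data$feature_id, .data$country_id, .data$child_id) |>
    dplyr::summarise(range_area_km2 = sum(.data$area_km2),
                     .groups = "drop") |>
    dplyr::inner_join(
      features[, c("feature_id", "species_id", "typology",
                   "target_fraction")],
      by = "feature_id"
    )

  if (recompute_targets) {
    species_country <- child |>
      dplyr::group_by(.data$species_id, .data$country_id) |>
      dplyr::summarise(species_range_km2 = sum(.data$range_area_km2),
                       .groups = "drop")
    species_country$target_fraction <-
      target_fraction(species_country$species_range_km2, rule)
    child$target_fraction <- NULL
    child <- dplyr::inner_join(
      child,
      species_country[, c("species_id", "country_id", "target_fraction")],
      by = c("species_id", "country_id")
    )
  }

  child <- child |>
    dplyr::mutate(
      feature_id = .data$child_id,
      parent_feature_id = sub("@[^@]*$", "", .data$child_id),
      target_amount_km2 = .data$target_fraction * .data$range_area_km2
    ) |>
    dplyr::select("feature_id", "parent_feature_id", "species_id",
                  "typology", "country_id", "range_area_km2",
                  "target_fraction", "target_amount_km2") |>
    dplyr::arrange(.data$feature_id)

  amounts_out <- amt |>
    dplyr::transmute(pu_id = .data$pu_id, feature_id = .data$child_id,
                     area_km2 = .data$area_km2) |>
    dplyr::arrange(.data$feature_id, .data$pu_id)

  list(features = child, amounts = tibble::as_tibble(amounts_out))
}
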
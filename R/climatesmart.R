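# Climate-priority-area (CPA) splitting: each feature is divided into its
# most climate-resilient portion, which receives a 100% target, and the rest
# of its distribution, which must make up the remainder of the overall
# target.

#' Resolve a per-unit resilience field
#'
#' @param units Planning-unit table with `resilience_landward` and
#'   `resilience_seaward` columns.
#' @param field One of `"mean"`, `"landward"`, `"seaward"`; `"mean"` is the
#'   per-unit arithmetic mean of the landward and seaward values.
#' @return Named numeric vector of resilience values (names = `pu_id`).
#' @export
resolve_resilience <- function(units, field = c("mean", "landward",
                                                "seaward")) {
  field <- match.arg(field)
  assert_columns(units, c("pu_id", "resilience_landward",
                          "resilience_seaward"), "planning-unit table")
  r <- switch(field,
    mean = (units$resilience_landward + units$resilience_seaward) / 2,
    landward = units$resilience_landward,
    seaward = units$resilience_seaward
  )
  stats::setNames(r, units$pu_id)
}

#' Required climate-priority area for a feature
#'
#' The climate-smart threshold is expressed as a fraction of the feature's
#' conservation-target amount: a threshold of 0.05 requires 5 percent of the
#' area that would need to be selected to reach the feature's target to come
#' from its most climate-resilient portion.
#'
#' @param feature One row of a feature table (needs `target_amount_km2`), or
#'   a list with that element.
#' @param threshold Climate-smart threshold in [0, 1].
#' @return Required CPA area in km2 (`threshold * target_amount_km2`).
#' @export
required_cpa_area <- function(feature, threshold) {
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  threshold * feature$target_amount_km2
}

#' Split one feature into climate-priority area and remainder
#'
#' Amount records are ranked by unit resilience (descending, ties broken by
#' ascending unit id) and accumulated whole until their summed area first
#' reaches the required CPA area. Those records form the CPA (target = its
#' own area, i.e. 100 percent); the remainder keeps the rest of the records
#' with target `max(0, parent target - CPA area)`.
#'
#' @param feature One feature row (needs `feature_id`, `target_amount_km2`).
#' @param records Amount records of this feature (`pu_id`, `area_km2`).
#' @param unit_resilience Named vector: `pu_id` -> resilience in [0, 100].
#' @param threshold Climate-smart threshold in [0, 1].
#' @return A `cpa_split` list: `parent_feature_id`, `threshold`,
#'   `cpa_records`, `remainder_records`, `cpa_area_km2`, `cpa_target_km2`,
#'   `remainder_target_km2`, `cutoff_resilience`.
#' @export
split_cpa <- function(feature, records, unit_resilience, threshold) {
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 1)
  if (threshold > 0 && nrow(records) == 0L) {
    stop_validation("feature %s has no amount records to split",
                    feature$feature_id)
  }
  res <- unit_resilience[as.character(records$pu_id)]
  if (anyNA(res)) {
    stop_validation(
      "missing resilience for unit(s) %s of feature %s",
      paste(records$pu_id[is.na(res)], collapse = ", "),
      feature$feature_id
    )
  }
  ord <- order(-res, records$pu_id)
  required <- required_cpa_area(feature, threshold)
  if (required <= 0) {
    n_cpa <- 0L
  } else {
    cum <- cumsum(records$area_km2[ord])
    n_cpa <- which(cum >= required - 1e-12)[1L]
    if (is.na(n_cpa)) n_cpa <- length(ord)  # all records still short: take all
  }
  cpa_idx <- ord[seq_len(n_cpa)]
  rem_idx <- if (n_cpa < length(ord)) ord[seq.int(n_cpa + 1L, length(ord))]
             else integer(0)
  cpa_area <- sum(records$area_km2[cpa_idx])
  structure(
    list(
      parent_feature_id = feature$feature_id,
      threshold = threshold,
      cpa_records = records[cpa_idx, , drop = FALSE],
      remainder_records = records[rem_idx, , drop = FALSE],
      cpa_area_km2 = cpa_area,
      cpa_target_km2 = cpa_area,
      remainder_target_km2 = max(0, feature$target_amount_km2 - cpa_area),
      cutoff_resilience = if (n_cpa > 0L) unname(res[ord[n_cpa]])
                          else NA_real_
    ),
    class = "cpa_split"
  )
}

#' Expand features into climate-smart (CPA + remainder) features
#'
#' Replaces every feature by two features: its climate-priority area, whose
#' target equals its own area (a 100 percent target), and the remainder of
#' its distribution, whose target is the residual of the parent target.
#' Remainder features whose target is driven to zero by whole-record
#' overshoot are kept inert (target 0). At threshold 0 the CPA is empty and
#' the problem is identical to the climate-naive one up to feature ids.
#'
#' @param features,amounts Feature and amount tables.
#' @param units Planning-unit table with resilience columns.
#' @param threshold Climate-smart threshold in [0, 1].
#' @param resilience_field `"mean"`, `"landward"` or `"seaward"`.
#' @return List with expanded `features` (adds `parent_feature_id` and
#'   `component` in `{"cpa", "remainder"}`, plus `cutoff_resilience`) and
#'   `amounts` tables.
#' @export
build_climate_smart_features <- function(features, amounts, units,
                                         threshold,
                                         resilience_field = c("mean",
                                                              "landward",
                                                              "seaward")) {
  resilience_field <- match.arg(resilience_field)
  unit_res <- resolve_resilience(units, resilience_field)
  amt_split <- split(amounts, amounts$feature_id)

  rows <- vector("list", nrow(features))
  amount_rows <- vector("list", nrow(features))
  for (k in seq_len(nrow(features))) {
    f <- features[k, , drop = FALSE]
    recs <- amt_split[[f$feature_id]]
    if (is.null(recs)) {
      recs <- amounts[0, , drop = FALSE]
    }
    sp <- split_cpa(f, recs, unit_res, threshold)
    cpa_id <- paste0(f$feature_id, "#cpa")
    rem_id <- paste0(f$feature_id, "#rem")
    rows[[k]] <- tibble::tibble(
      feature_id = c(cpa_id, rem_id),
      parent_feature_id = f$feature_id,
      species_id = f$species_id,
      typology = f$typology,
      country_id = f$country_id,
      component = c("cpa", "remainder"),
      range_area_km2 = c(sp$cpa_area_km2,
                         sum(sp$remainder_records$area_km2)),
      target_fraction = f$target_fraction,
      target_amount_km2 = c(sp$cpa_target_km2, sp$remainder_target_km2),
      cutoff_resilience = sp$cutoff_resilience
    )
    cpa_amt <- sp$cpa_records
    rem_amt <- sp$remainder_records
    if (nrow(cpa_amt) > 0L) cpa_amt$feature_id <- cpa_id
    if (nrow(rem_amt) > 0L) rem_amt$feature_id <- rem_id
    amount_rows[[k]] <- rbind(cpa_amt, rem_amt)
  }
  features_out <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$feature_id)
  amounts_out <- dplyr::bind_rows(amount_rows) |>
    dplyr::select("pu_id", "feature_id", "area_km2") |>
    dplyr::arrange(.data$feature_id, .data$pu_id)
  list(features = features_out, amounts = tibble::as_tibble(amounts_out))
}
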
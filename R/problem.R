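# Minimum-set problem construction and serialisation.

#' Build a minimum-set reserve-selection problem
#'
#' Formulates the binary program: minimise the total mangrove area of the
#' selected planning units subject to every feature reaching its target,
#' `sum_i a_ij x_i >= T_j`. The cost of a unit is its mangrove area, so each
#' km2 of mangrove has the same selection priority. Units and features are
#' ordered deterministically (sorted ids) to stabilise solver tie-breaking;
#' features with non-positive targets are dropped from the constraint set.
#'
#' @param units Planning-unit table with `pu_id` and `mangrove_area_km2`.
#' @param features Feature table with `feature_id`, `target_amount_km2` and
#'   `range_area_km2`.
#' @param amounts Amount table (`pu_id`, `feature_id`, `area_km2`).
#' @param locked_in,locked_out Optional vectors of `pu_id`s forced in or out
#'   of every solution.
#' @return A `minset_problem` object.
#' @export
build_problem <- function(units, features, amounts,
                          locked_in = integer(0),
                          locked_out = integer(0)) {
  assert_columns(units, c("pu_id", "mangrove_area_km2"),
                 "planning-unit table")
  assert_columns(features, c("feature_id", "target_amount_km2",
                             "range_area_km2"), "feature table")
  assert_columns(amounts, c("pu_id", "feature_id", "area_km2"),
                 "amount table")
  if (anyDuplicated(units$pu_id)) {
    stop_validation("duplicate pu_id in planning-unit table")
  }
  if (anyDuplicated(features$feature_id)) {
    stop_validation("duplicate feature_id in feature table")
  }
  if (any(units$mangrove_area_km2 <= 0)) {
    stop_validation(
      "non-positive cost (mangrove area) for unit(s): %s",
      paste(utils::head(units$pu_id[units$mangrove_area_km2 <= 0], 10L),
            collapse = ", ")
    )
  }
  bad_u <- setdiff(amounts$pu_id, units$pu_id)
  if (length(bad_u) > 0L) {
    stop_validation("amount record references unknown unit(s): %s",
                    paste(utils::head(bad_u, 10L), collapse = ", "))
  }
  bad_f <- setdiff(amounts$feature_id, features$feature_id)
  if (length(bad_f) > 0L) {
    stop_validation("amount record references unknown feature(s): %s",
                    paste(utils::head(bad_f, 10L), collapse = ", "))
  }
  bad_lock <- setdiff(c(locked_in, locked_out), units$pu_id)
  if (length(bad_lock) > 0L) {
    stop_validation("locked unit(s) not in planning-unit table: %s",
                    paste(bad_lock, collapse = ", "))
  }
  both <- intersect(locked_in, locked_out)
  if (length(both) > 0L) {
    stop_validation("unit(s) locked both in and out: %s",
                    paste(both, collapse = ", "))
  }

  ord <- order(units$pu_id)
  unit_ids <- units$pu_id[ord]
  costs <- units$mangrove_area_km2[ord]

  constrained <- features[features$target_amount_km2 > 0, , drop = FALSE]
  constrained <- constrained[order(constrained$feature_id), , drop = FALSE]
  targets <- tibble::tibble(
    feature_id = constrained$feature_id,
    target_km2 = constrained$target_amount_km2,
    range_area_km2 = constrained$range_area_km2
  )
  amt <- amounts[amounts$feature_id %in% targets$feature_id, , drop = FALSE]
  amt <- amt[order(amt$feature_id, amt$pu_id), , drop = FALSE]

  structure(
    list(
      unit_ids = unit_ids,
      costs = costs,
      amounts = tibble::as_tibble(amt),
      targets = targets,
      locked_in = sort(unique(locked_in)),
      locked_out = sort(unique(locked_out))
    ),
    class = "minset_problem"
  )
}

#' @export
print.minset_problem <- function(x, ...) {
  cat("<minset_problem>\n")
  cat(sprintf("  %d units, %d constrained features, %d amount records\n",
              length(x$unit_ids), nrow(x$targets), nrow(x$amounts)))
  cat(sprintf("  total cost available: %.1f km2; locked in/out: %d/%d\n",
              sum(x$costs), length(x$locked_in), length(x$locked_out)))
  invisible(x)
}

#' Serialise / deserialise a minimum-set problem
#'
#' Canonical JSON form used by the command-line pipeline; a round trip
#' through `write_problem()` and `read_problem()` is the identity.
#'
#' @param problem A `minset_problem`.
#' @param path File path for the JSON document.
#' @return `read_problem()` returns the `minset_problem`;
#'   `write_problem()` returns `path` invisibly.
#' @export
write_problem <- function(problem, path) {
  payload <- list(
    schema = "minset_problem/1",
    unit_ids = problem$unit_ids,
    costs = problem$costs,
    amounts = list(
      pu_id = problem$amounts$pu_id,
      feature_id = problem$amounts$feature_id,
      area_km2 = problem$amounts$area_km2
    ),
    targets = list(
      feature_id = problem$targets$feature_id,
      target_km2 = problem$targets$target_km2,
      range_area_km2 = problem$targets$range_area_km2
    ),
    locked_in = problem$locked_in,
    locked_out = problem$locked_out
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_problem
#' @export
read_problem <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$schema, "minset_problem/1")) {
    stop_validation("unrecognised problem schema in %s", path)
  }
  # empty JSON arrays deserialise as bare lists; coerce to typed vectors
  int_vec <- function(x) {
    if (length(x) == 0L) integer(0) else as.integer(unlist(x))
  }
  num_vec <- function(x) {
    if (length(x) == 0L) numeric(0) else as.numeric(unlist(x))
  }
  chr_vec <- function(x) {
    if (length(x) == 0L) character(0) else as.character(unlist(x))
  }
  structure(
    list(
      unit_ids = int_vec(p$unit_ids),
      costs = num_vec(p$costs),
      amounts = tibble::tibble(
        pu_id = int_vec(p$amounts$pu_id),
        feature_id = chr_vec(p$amounts$feature_id),
        area_km2 = num_vec(p$amounts$area_km2)
      ),
      targets = tibble::tibble(
        feature_id = chr_vec(p$targets$feature_id),
        target_km2 = num_vec(p$targets$target_km2),
        range_area_km2 = num_vec(p$targets$range_area_km2)
      ),
      locked_in = int_vec(p$locked_in),
      locked_out = int_vec(p$locked_out)
    ),
    class = "minset_problem"
  )
}
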
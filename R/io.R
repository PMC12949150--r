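# Validated CSV/JSON input and output. CSV dialect: UTF-8, comma separator,
# '.' decimal mark, header row required. Validation enumerates every
# violation (with row numbers) instead of stopping at the first.

check_range <- function(df, col, what, lower = -Inf, upper = Inf,
                        strict_lower = FALSE) {
  x <- df[[col]]
  errs <- character(0)
  if (!is.numeric(x)) {
    return(sprintf("%s: column `%s` must be numeric", what, col))
  }
  bad_na <- which(!is.finite(x))
  if (length(bad_na) > 0L) {
    errs <- c(errs, sprintf("%s row %d: `%s` is missing or non-finite",
                            what, bad_na, col))
  }
  low_bad <- if (strict_lower) which(x <= lower) else which(x < lower)
  low_bad <- setdiff(low_bad, bad_na)
  if (length(low_bad) > 0L) {
    errs <- c(errs, sprintf(
      "%s row %d: `%s` = %g violates bound %s %g",
      what, low_bad, col, x[low_bad], if (strict_lower) ">" else ">=",
      lower
    ))
  }
  hi_bad <- setdiff(which(x > upper), bad_na)
  if (length(hi_bad) > 0L) {
    errs <- c(errs, sprintf("%s row %d: `%s` = %g violates bound <= %g",
                            what, hi_bad, col, x[hi_bad], upper))
  }
  errs
}

raise_if_errors <- function(errs) {
  if (length(errs) > 0L) {
    stop_validation("%s", paste(errs, collapse = "\n"))
  }
  invisible(NULL)
}

#' Validate pipeline tables
#'
#' Strict schema validation for the three core tables (column presence,
#' types, value ranges), reporting every violation with its row number.
#'
#' @param df The table to validate.
#' @return The validated table (as a tibble), invisibly usable in a pipe.
#' @name validate_tables
NULL

#' @rdname validate_tables
#' @export
validate_planning_units <- function(df) {
  cols <- c("pu_id", "x", "y", "country_id", "mangrove_area_km2",
            "resilience_landward", "resilience_seaward",
            "protected_fraction")
  assert_columns(df, cols, "planning_units")
  errs <- character(0)
  if (anyDuplicated(df$pu_id)) {
    errs <- c(errs, "planning_units: duplicated pu_id values")
  }
  errs <- c(
    errs,
    check_range(df, "mangrove_area_km2", "planning_units", lower = 0,
                strict_lower = TRUE),
    check_range(df, "resilience_landward", "planning_units", 0, 100),
    check_range(df, "resilience_seaward", "planning_units", 0, 100),
    check_range(df, "protected_fraction", "planning_units", 0, 1)
  )
  raise_if_errors(errs)
  tibble::as_tibble(df)
}

#' @rdname validate_tables
#' @export
validate_amounts <- function(df) {
  assert_columns(df, c("pu_id", "feature_id", "area_km2"), "amounts")
  raise_if_errors(check_range(df, "area_km2", "amounts", lower = 0,
                              strict_lower = TRUE))
  tibble::as_tibble(df)
}

#' @rdname validate_tables
#' @export
validate_features <- function(df) {
  cols <- c("feature_id", "species_id", "typology", "range_area_km2",
            "target_fraction", "target_amount_km2")
  assert_columns(df, cols, "features")
  errs <- character(0)
  if (anyDuplicated(df$feature_id)) {
    errs <- c(errs, "features: duplicated feature_id values")
  }
  errs <- c(
    errs,
    check_range(df, "range_area_km2", "features", lower = 0,
                strict_lower = TRUE),
    check_range(df, "target_fraction", "features", 0, 1),
    check_range(df, "target_amount_km2", "features", lower = 0)
  )
  raise_if_errors(errs)
  tibble::as_tibble(df)
}

#' Write / read a seascape directory
#'
#' Serialises a seascape as plain-text CSV tables plus a JSON manifest:
#' `planning_units.csv`, `features.csv`, `amounts.csv`, `typology.csv` and
#' `manifest.json` (config, seed, schema version). The write -> read round
#' trip reproduces the dataset.
#'
#' @param dataset A `seascape` object.
#' @param dir Output directory (created if missing).
#' @return `write_seascape()` returns `dir` invisibly; `read_seascape()`
#'   returns the `seascape`.
#' @export
write_seascape <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(dataset$planning_units,
                   file.path(dir, "planning_units.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$features, file.path(dir, "features.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$amounts, file.path(dir, "amounts.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(dataset$typology_map, file.path(dir, "typology.csv"),
                   row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(
      schema = "seascape/1",
      config = dataset$provenance$config,
      seed = dataset$provenance$seed
    ),
    file.path(dir, "manifest.json"), digits = NA, auto_unbox = TRUE
  )
  invisible(dir)
}

#' @rdname write_seascape
#' @export
read_seascape <- function(dir) {
  need <- c("planning_units.csv", "features.csv", "amounts.csv",
            "typology.csv", "manifest.json")
  missing <- need[!file.exists(file.path(dir, need))]
  if (length(missing) > 0L) {
    stop_validation("seascape directory %s is missing: %s", dir,
                    paste(missing, collapse = ", "))
  }
  units <- validate_planning_units(
    utils::read.csv(file.path(dir, "planning_units.csv"))
  )
  features <- validate_features(
    utils::read.csv(file.path(dir, "features.csv"))
  )
  features$country_id <- features$country_id %||% NA_character_
  amounts <- validate_amounts(
    utils::read.csv(file.path(dir, "amounts.csv"))
  )
  typology <- utils::read.csv(file.path(dir, "typology.csv"))
  assert_columns(typology, c("pu_id", "typology", "area_km2"), "typology")
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)

  # species ranges are implicit in the amount matrix
  amt_species <- dplyr::inner_join(
    amounts, features[, c("feature_id", "species_id")], by = "feature_id"
  )
  species_ranges <- lapply(
    split(amt_species$pu_id, amt_species$species_id),
    function(ids) sort(unique(ids))
  )

  structure(
    list(
      planning_units = units,
      features = features,
      amounts = amounts,
      species_ranges = species_ranges,
      typology_map = tibble::as_tibble(typology),
      provenance = list(config = manifest$config, seed = manifest$seed,
                        schema_version = "1")
    ),
    class = "seascape"
  )
}
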
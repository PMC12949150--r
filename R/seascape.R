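#' Configure a synthetic seascape
#'
#' Defines the study conditions for a seeded synthetic seascape that mimics
#' the statistical structure of the global mangrove planning problem at desk
#' scale: planning units strung along a one-dimensional coastline, a
#' right-skewed species range-size distribution wide enough to span both
#' target-interpolation caps, an alongshore richness gradient, a mosaic of
#' four biophysical typology classes, spatially autocorrelated landward and
#' seaward climate-resilience fields with weak cross-correlation, a partition
#' of the coastline into countries, and a clustered protected-area overlay.
#'
#' @param n_units Number of hexagonal planning units along the coastline.
#' @param n_species Number of mangrove plant species.
#' @param n_countries Number of countries partitioning the coastline into
#'   contiguous blocks.
#' @param unit_area_km2 Planning-unit footprint in km2 (default 631, the
#'   alongshore hexagon resolution used in global mangrove planning).
#' @param range_size_log_mean,range_size_log_sd Mean and standard deviation,
#'   on the natural-log scale, of the lognormal distribution of species range
#'   extents (km2 of coastline footprint). Defaults give a right-skewed
#'   distribution whose realised range areas span the 10,000 and 250,000 km2
#'   interpolation caps on most seeds.
#' @param richness_gradient_strength Non-negative exponent controlling how
#'   strongly species ranges concentrate toward the high-richness end of the
#'   coastline (0 = uniform placement).
#' @param resilience_corr_length Spatial smoothing half-width, in planning
#'   units, of the resilience fields.
#' @param edge_cross_correlation Target Pearson correlation in [-1, 1]
#'   between the landward and seaward resilience fields.
#' @param protected_coverage Area-weighted fraction of mangrove area inside
#'   existing protected areas, in [0, 1].
#' @param protected_clustering Spatial smoothing half-width, in planning
#'   units, of the protected-fraction overlay.
#' @param mangrove_fill_mean Mean fraction of each unit's footprint occupied
#'   by mangrove. Deliberately denser than real mangrove cover so that
#'   desk-scale seascapes produce range areas spanning the interpolation
#'   caps; see the methods vignette.
#' @param seed Integer seed; together with the other fields it fully
#'   determines the generated dataset.
#' @return A `seascape_config` object (a validated list).
#' @seealso [generate_seascape()]
#' @export
seascape_config <- function(n_units = 1400,
                            n_species = 40,
                            n_countries = 12,
                            unit_area_km2 = 631,
                            range_size_log_mean = 11.5,
                            range_size_log_sd = 2.0,
                            richness_gradient_strength = 2.5,
                            resilience_corr_length = 10,
                            edge_cross_correlation = 0.3,
                            protected_coverage = 0.43,
                            protected_clustering = 8,
                            mangrove_fill_mean = 0.35,
                            seed = 1L) {
  n_units <- assert_count(n_units, "n_units")
  n_species <- assert_count(n_species, "n_species")
  n_countries <- assert_count(n_countries, "n_countries")
  if (n_units < n_countries) {
    stop_validation(
      "invariant violated: n_units >= n_countries (got %d < %d)",
      n_units, n_countries
    )
  }
  assert_scalar_number(unit_area_km2, "unit_area_km2", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(range_size_log_mean, "range_size_log_mean")
  assert_scalar_number(range_size_log_sd, "range_size_log_sd", lower = 0)
  assert_scalar_number(richness_gradient_strength,
                       "richness_gradient_strength", lower = 0)
  assert_scalar_number(resilience_corr_length, "resilience_corr_length",
                       lower = 0, strict_lower = TRUE)
  assert_scalar_number(edge_cross_correlation, "edge_cross_correlation",
                       lower = -1, upper = 1)
  assert_scalar_number(protected_coverage, "protected_coverage",
                       lower = 0, upper = 1)
  assert_scalar_number(protected_clustering, "protected_clustering", lower = 0)
  assert_scalar_number(mangrove_fill_mean, "mangrove_fill_mean",
                       lower = 0, upper = 1, strict_lower = TRUE)
  seed <- assert_count(seed, "seed", lower = 0L)
  structure(
    list(
      n_units = n_units, n_species = n_species, n_countries = n_countries,
      unit_area_km2 = unit_area_km2,
      range_size_log_mean = range_size_log_mean,
      range_size_log_sd = range_size_log_sd,
      richness_gradient_strength = richness_gradient_strength,
      resilience_corr_length = resilience_corr_length,
      edge_cross_correlation = edge_cross_correlation,
      protected_coverage = protected_coverage,
      protected_clustering = protected_clustering,
      mangrove_fill_mean = mangrove_fill_mean,
      seed = seed
    ),
    class = "seascape_config"
  )
}

#' @export
print.seascape_config <- function(x, ...) {
  cat("<seascape_config>\n")
  cat(sprintf("  units: %d  species: %d  countries: %d  seed: %d\n",
              x$n_units, x$n_species, x$n_countries, x$seed))
  cat(sprintf("  unit area: %g km2, mangrove fill mean: %g\n",
              x$unit_area_km2, x$mangrove_fill_mean))
  cat(sprintf("  range extent: lognormal(meanlog=%.3f, sdlog=%.3f)\n",
              x$range_size_log_mean, x$range_size_log_sd))
  cat(sprintf(
    "  resilience corr length: %g units, edge cross-correlation: %g\n",
    x$resilience_corr_length, x$edge_cross_correlation))
  cat(sprintf("  protected coverage: %g (clustering %g)\n",
              x$protected_coverage, x$protected_clustering))
  invisible(x)
}

# Shape parameters of the Beta fill distribution given its mean; fixed
# concentration keeps the spread realistic while the mean is configurable.
fill_beta_shapes <- function(mean) {
  conc <- 5
  c(shape1 = mean * conc, shape2 = (1 - mean) * conc)
}

#' Generate a synthetic seascape
#'
#' Draws a complete synthetic dataset for the prioritisation pipeline:
#' planning units with coordinates, country, mangrove area, resilience and
#' protection; species ranges as contiguous alongshore intervals; a typology
#' mosaic partitioning each unit's mangrove area among the four biophysical
#' classes (deltaic, estuarine, lagoonal, open-coast); and the derived
#' geomorphic-species feature and amount tables with default area-based
#' targets. All randomness flows from `config$seed`; identical configs
#' reproduce the dataset exactly.
#'
#' Units without any intersecting species range inherit the species set of
#' the nearest occupied unit, mirroring how sparse range maps are reconciled
#' with a planning-unit grid.
#'
#' @param config A [seascape_config()].
#' @return A `seascape` object: a list with elements `planning_units`,
#'   `features`, `amounts`, `species_ranges`, `typology_map` and
#'   `provenance`.
#' @examples
#' sea <- generate_seascape(seascape_config(n_units = 60, n_species = 8,
#'                                          n_countries = 3, seed = 42))
#' sea$planning_units
#' @export
generate_seascape <- function(config) {
  if (!inherits(config, "seascape_config")) {
    config <- do.call(seascape_config, as.list(config))
  }
  n <- config$n_units
  withr::with_seed(config$seed, {
    sub_seeds <- sample.int(2147483646L, 3L)

    # 1-D coastline ordering with 2-D jittered centroids.
    spacing <- sqrt(config$unit_area_km2)
    x <- seq_len(n) * spacing + stats::rnorm(n, 0, spacing / 20)
    meander <- smooth_along(stats::rnorm(n), max(3, n / 40))
    y <- rescale_range(meander, -3 * spacing, 3 * spacing) +
      stats::rnorm(n, 0, spacing / 20)

    # Contiguous country blocks with uneven sizes.
    share <- stats::rgamma(config$n_countries, shape = 4)
    sizes <- diff(round(c(0, cumsum(share) / sum(share)) * n))
    # guarantee each country at least one unit
    while (any(sizes == 0L)) {
      i <- which.min(sizes)
      j <- which.max(sizes)
      sizes[i] <- sizes[i] + 1L
      sizes[j] <- sizes[j] - 1L
    }
    country_id <- rep(sprintf("C%02d", seq_len(config$n_countries)), sizes)

    # Mangrove area inside each unit footprint.
    sh <- fill_beta_shapes(config$mangrove_fill_mean)
    fill <- stats::rbeta(n, sh[1L], sh[2L])
    fill <- pmax(fill, 1e-3)  # areas must be strictly positive
    mangrove_area <- config$unit_area_km2 * fill

    # Typology mosaic: one smooth field per class, softmax-sharpened so one
    # class tends to dominate locally, then scaled to partition the area.
    typ_fields <- vapply(
      TYPOLOGY_CLASSES,
      function(cl) smooth_along(stats::rnorm(n), max(2, n / 50)),
      numeric(n)
    )
    typ_fields <- apply(typ_fields, 2L, function(z) {
      s <- stats::sd(z)
      if (s == 0) z else z / s
    })
    w <- exp(3 * typ_fields)
    props <- w / rowSums(w)
    typology_map <- tibble::tibble(
      pu_id = rep(seq_len(n), times = length(TYPOLOGY_CLASSES)),
      typology = rep(TYPOLOGY_CLASSES, each = n),
      area_km2 = as.vector(props) * rep(mangrove_area,
                                        times = length(TYPOLOGY_CLASSES))
    )
    typology_map <- typology_map[typology_map$area_km2 > 0, , drop = FALSE]
    typology_map <- typology_map[order(typology_map$pu_id,
                                       typology_map$typology), ]

    # Species ranges: contiguous alongshore intervals; lognormal extents,
    # centers biased toward the high-index (species-rich) end.
    extent <- stats::rlnorm(config$n_species,
                            config$range_size_log_mean,
                            config$range_size_log_sd)
    len <- pmin(pmax(round(extent / config$unit_area_km2), 1L), n)
    g <- config$richness_gradient_strength
    center_w <- (seq_len(n) / n)^g
    centers <- sample.int(n, config$n_species, replace = TRUE,
                          prob = center_w)
    starts <- pmin(pmax(centers - (len - 1L) %/% 2L, 1L), n - len + 1L)
    species_id <- sprintf("S%03d", seq_len(config$n_species))
    species_ranges <- stats::setNames(
      lapply(seq_len(config$n_species), function(s) {
        seq.int(starts[s], starts[s] + len[s] - 1L)
      }),
      species_id
    )

    units <- tibble::tibble(
      pu_id = seq_len(n),
      x = x, y = y,
      country_id = country_id,
      mangrove_area_km2 = mangrove_area
    )

    res <- generate_resilience_fields(
      units,
      corr_length = config$resilience_corr_length,
      cross_corr = config$edge_cross_correlation,
      seed = sub_seeds[1L]
    )
    units$resilience_landward <- res$landward
    units$resilience_seaward <- res$seaward
    units$protected_fraction <- generate_protected_fractions(
      units,
      coverage = config$protected_coverage,
      clustering = config$protected_clustering,
      seed = sub_seeds[2L]
    )

    species_ranges <- nearest_unit_assignment(species_ranges, units)
    built <- build_features(species_ranges, typology_map, target_rule())

    structure(
      list(
        planning_units = units,
        features = built$features,
        amounts = built$amounts,
        species_ranges = species_ranges,
        typology_map = typology_map,
        provenance = list(
          config = unclass(config),
          seed = config$seed,
          schema_version = "1"
        )
      ),
      class = "seascape"
    )
  })
}

#' @export
print.seascape <- function(x, ...) {
  cat("<seascape>\n")
  cat(sprintf("  %d planning units, %d species, %d countries\n",
              nrow(x$planning_units), length(x$species_ranges),
              length(unique(x$planning_units$country_id))))
  cat(sprintf("  %d geomorphic-species features, %d amount records\n",
              nrow(x$features), nrow(x$amounts)))
  cat(sprintf("  total mangrove area: %.0f km2\n",
              sum(x$planning_units$mangrove_area_km2)))
  invisible(x)
}

#' Generate spatially autocorrelated resilience fields
#'
#' Produces landward and seaward climate-resilience fields on the 0-100
#' scale (probability of mangrove net gain/stability under climate change)
#' by smoothing Gaussian noise along the coastline ordering and mixing the
#' two noise sources to approximate a requested cross-correlation. Smoothing
#' and the min-max rescale to [0, 100] are linear, so `cross_corr = 1` with
#' shared noise yields identical fields.
#'
#' @param units Planning-unit table with a `pu_id` column; rows are taken in
#'   alongshore order.
#' @param corr_length Smoothing half-width in planning units (> 0).
#' @param cross_corr Target Pearson correlation in [-1, 1].
#' @param seed Integer seed.
#' @return A list with numeric vectors `landward` and `seaward`, both in
#'   [0, 100], aligned with `units`.
#' @export
generate_resilience_fields <- function(units, corr_length, cross_corr,
                                       seed) {
  assert_scalar_number(corr_length, "corr_length", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(cross_corr, "cross_corr", lower = -1, upper = 1)
  n <- nrow(units)
  withr::with_seed(seed, {
    e1 <- stats::rnorm(n)
    e2 <- stats::rnorm(n)
    mixed <- cross_corr * e1 + sqrt(max(0, 1 - cross_corr^2)) * e2
    landward <- rescale_range(smooth_along(e1, corr_length), 0, 100)
    seaward <- rescale_range(smooth_along(mixed, corr_length), 0, 100)
    list(
      landward = pmin(pmax(landward, 0), 100),
      seaward = pmin(pmax(seaward, 0), 100)
    )
  })
}

#' Generate a clustered protected-fraction overlay
#'
#' Emulates the per-unit fraction of mangrove area lying inside existing
#' protected areas: a smooth spatial field is raised to the power that makes
#' the area-weighted mean fraction equal the requested coverage, so
#' protection is spatially clustered and the network covers approximately
#' `coverage` of the total mangrove area.
#'
#' @param units Planning-unit table with `mangrove_area_km2`.
#' @param coverage Target area-weighted protected fraction in [0, 1].
#' @param clustering Smoothing half-width in planning units.
#' @param seed Integer seed.
#' @return Numeric vector of per-unit protected fractions in [0, 1].
#' @export
generate_protected_fractions <- function(units, coverage, clustering, seed) {
  assert_scalar_number(coverage, "coverage", lower = 0, upper = 1)
  assert_scalar_number(clustering, "clustering", lower = 0)
  n <- nrow(units)
  if (coverage == 0) return(rep(0, n))
  if (coverage == 1) return(rep(1, n))
  withr::with_seed(seed, {
    z <- rescale_range(smooth_along(stats::runif(n), clustering), 0, 1)
    # keep the field strictly inside (0, 1) so the power transform can move
    # the weighted mean to any interior coverage
    z <- 0.001 + 0.998 * z
    w <- units$mangrove_area_km2
    target_fun <- function(log_gamma) {
      sum(w * z^exp(log_gamma)) / sum(w) - coverage
    }
    root <- stats::uniroot(target_fun, lower = -25, upper = 25,
                           tol = 1e-12)
    pmin(pmax(z^exp(root$root), 0), 1)
  })
}
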
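# Small programmatic fixtures shared across tests.

make_units <- function(n,
                       mangrove_area = rep(10, n),
                       country = rep("C01", n),
                       res_land = rep(50, n),
                       res_sea = rep(50, n),
                       protected = rep(0, n),
                       x = seq_len(n) * 10,
                       y = rep(0, n)) {
  tibble::tibble(
    pu_id = seq_len(n), x = x, y = y,
    country_id = country,
    mangrove_area_km2 = mangrove_area,
    resilience_landward = res_land,
    resilience_seaward = res_sea,
    protected_fraction = protected
  )
}

# Two units, each deltaic 10 km2 + estuarine 5 km2, one species on both.
make_tiny_world <- function() {
  units <- make_units(2, mangrove_area = c(15, 15))
  typology <- tibble::tibble(
    pu_id = c(1L, 1L, 2L, 2L),
    typology = c("deltaic", "estuarine", "deltaic", "estuarine"),
    area_km2 = c(10, 5, 10, 5)
  )
  ranges <- list(S001 = c(1L, 2L))
  list(units = units, typology = typology, ranges = ranges)
}

# Random feasible minimum-set instance for oracle comparisons.
random_instance <- function(n_units, n_features, seed) {
  withr::with_seed(seed, {
    units <- make_units(n_units,
                        mangrove_area = round(stats::runif(n_units, 1, 20),
                                              3))
    rows <- list()
    for (j in seq_len(n_features)) {
      support <- which(stats::runif(n_units) < 0.6)
      if (length(support) == 0L) support <- sample.int(n_units, 1L)
      rows[[j]] <- tibble::tibble(
        pu_id = support,
        feature_id = sprintf("F%02d", j),
        area_km2 = round(stats::runif(length(support), 0.5,
                                      units$mangrove_area_km2[support]),
                         3)
      )
    }
    amounts <- dplyr::bind_rows(rows)
    totals <- vapply(split(amounts$area_km2, amounts$feature_id), sum,
                     numeric(1))
    features <- tibble::tibble(
      feature_id = names(totals),
      range_area_km2 = unname(totals),
      target_amount_km2 = unname(totals) * stats::runif(length(totals),
                                                        0.2, 0.9)
    )
    build_problem(units, features, amounts)
  })
}

# Quick small seascape for integration-style tests.
small_seascape <- function(seed = 7, n_units = 80, n_species = 10,
                           n_countries = 4) {
  generate_seascape(seascape_config(
    n_units = n_units, n_species = n_species, n_countries = n_countries,
    seed = seed
  ))
}
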
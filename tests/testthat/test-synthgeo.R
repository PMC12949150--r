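# Synthetic seascape generator: determinism, structural invariants,
# resilience and protection overlays.

test_that("identical config and seed reproduce the dataset bit-for-bit", {
  cfg <- seascape_config(n_units = 100, n_species = 10, n_countries = 4,
                         seed = 1)
  a <- generate_seascape(cfg)
  b <- generate_seascape(cfg)
  expect_identical(a, b)
  expect_equal(nrow(a$planning_units), 100L)
  expect_length(a$species_ranges, 10L)

  dir_a <- withr::local_tempdir()
  dir_b <- withr::local_tempdir()
  write_seascape(a, dir_a)
  write_seascape(b, dir_b)
  for (f in list.files(dir_a)) {
    expect_identical(unname(tools::md5sum(file.path(dir_a, f))),
                     unname(tools::md5sum(file.path(dir_b, f))),
                     label = paste("md5 of", f))
  }

  c_ <- generate_seascape(seascape_config(n_units = 100, n_species = 10,
                                          n_countries = 4, seed = 2))
  expect_false(identical(a$planning_units, c_$planning_units))
})

test_that("generated seascapes satisfy the structural invariants", {
  sea <- small_seascape(seed = 3, n_units = 150, n_species = 12)
  u <- sea$planning_units

  expect_true(all(u$mangrove_area_km2 > 0))
  expect_true(all(u$resilience_landward >= 0 &
                    u$resilience_landward <= 100))
  expect_true(all(u$resilience_seaward >= 0 &
                    u$resilience_seaward <= 100))
  expect_true(all(u$protected_fraction >= 0 & u$protected_fraction <= 1))

  # typology areas partition each unit's mangrove area
  typ_sum <- vapply(split(sea$typology_map$area_km2,
                          sea$typology_map$pu_id), sum, numeric(1))
  expect_equal(unname(typ_sum[as.character(u$pu_id)]),
               u$mangrove_area_km2, tolerance = 1e-9)
  expect_true(all(sea$typology_map$typology %in%
                    c("deltaic", "estuarine", "lagoonal", "open_coast")))

  # every amount record references an existing unit and feature, and no
  # unit carries more feature area (per feature) than its mangrove area
  expect_true(all(sea$amounts$pu_id %in% u$pu_id))
  expect_true(all(sea$amounts$feature_id %in% sea$features$feature_id))
  amax <- vapply(split(sea$amounts$area_km2, sea$amounts$pu_id), max,
                 numeric(1))
  expect_true(all(amax <= u$mangrove_area_km2[
    match(as.integer(names(amax)), u$pu_id)] + 1e-9))

  # species ranges are contiguous alongshore after generation, and every
  # unit hosts at least one species (nearest-unit assignment)
  occupied <- sort(unique(unlist(sea$species_ranges)))
  expect_setequal(occupied, u$pu_id)

  # countries are contiguous blocks covering all units
  expect_equal(length(unique(u$country_id)), 4L)
  expect_true(all(diff(match(u$country_id, unique(u$country_id))) >= 0))
})

test_that("degenerate configurations behave as specified", {
  sea <- generate_seascape(seascape_config(n_units = 40, n_species = 4,
                                           n_countries = 1, seed = 5))
  expect_equal(unique(sea$planning_units$country_id), "C01")

  expect_error(seascape_config(n_units = 3, n_countries = 5),
               "n_units >= n_countries")
  expect_error(seascape_config(unit_area_km2 = 0), "unit_area_km2")
  expect_error(seascape_config(n_species = 0), "n_species")
  expect_error(seascape_config(edge_cross_correlation = 2),
               "edge_cross_correlation")
})

test_that("default seascapes concentrate richness enough to leave countries unselected", {
  # global minimum-set plans meet targets in species-rich areas and skip
  # species-poor countries on most seeds; a 2% optimality gap is ample for
  # this zero/non-zero selection question
  skipped <- vapply(1:20, function(s) {
    sea <- generate_seascape(seascape_config(seed = s))
    sol <- prioritize_seascape(sea, 0, gap = 0.02)
    ev <- evaluate_solution(sol, sea$planning_units)
    any(ev$per_country$pct_area_selected == 0)
  }, logical(1))
  expect_gte(sum(skipped), 18L)
})

test_that("default seascapes span both target-interpolation caps", {
  for (s in 1:10) {
    sea <- generate_seascape(seascape_config(seed = s))
    species_area <- vapply(
      split(sea$amounts$area_km2,
            sub("_[a-z_]+$", "", sea$amounts$feature_id)),
      sum, numeric(1)
    )
    expect_lt(min(species_area), 10000)
    expect_gt(max(species_area), 250000)
  }
})

test_that("resilience fields honour the cross-correlation contract", {
  units <- make_units(500)

  perfect <- generate_resilience_fields(units, corr_length = 10,
                                        cross_corr = 1, seed = 4)
  expect_equal(perfect$landward, perfect$seaward, tolerance = 1e-12)

  # independent fields: sample correlation near 0 (sampling band from a
  # pilot across seeds)
  for (s in c(11, 12, 13)) {
    f <- generate_resilience_fields(units, corr_length = 10,
                                    cross_corr = 0, seed = s)
    expect_lt(abs(stats::cor(f$landward, f$seaward)), 0.25)
  }

  # vanishing smoothing scale: neighbour correlation is indistinguishable
  # from white noise
  f0 <- generate_resilience_fields(units, corr_length = 1e-9,
                                   cross_corr = 0, seed = 6)
  lag1 <- stats::cor(f0$landward[-1], f0$landward[-500])
  expect_lt(abs(lag1), 2.58 / sqrt(500) + 0.05)

  # positive smoothing scale: strong neighbour correlation
  fs <- generate_resilience_fields(units, corr_length = 15,
                                   cross_corr = 0, seed = 6)
  expect_gt(stats::cor(fs$landward[-1], fs$landward[-500]), 0.5)
})

test_that("protected fractions hit the requested coverage and bounds", {
  units <- make_units(500, mangrove_area = stats::runif(500, 1, 30))

  expect_equal(generate_protected_fractions(units, 0, 8, 1), rep(0, 500))
  expect_equal(generate_protected_fractions(units, 1, 8, 1), rep(1, 500))

  for (s in c(21, 22, 23)) {
    f <- generate_protected_fractions(units, coverage = 0.43,
                                      clustering = 8, seed = s)
    expect_true(all(f >= 0 & f <= 1))
    wmean <- sum(units$mangrove_area_km2 * f) /
      sum(units$mangrove_area_km2)
    expect_gt(wmean, 0.38)
    expect_lt(wmean, 0.48)
  }
})
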
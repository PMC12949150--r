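# Geomorphic-species feature construction and area-based targets.

test_that("target fractions follow the log10 interpolation rule", {
  expect_equal(target_fraction(5000), 1.0)
  expect_equal(target_fraction(10000), 1.0)
  expect_equal(target_fraction(250000), 0.1)
  expect_equal(target_fraction(300000), 0.1)
  # geometric midpoint of the caps: exactly halfway in log10 space
  expect_equal(target_fraction(50000), 0.55)

  # non-increasing in range area, continuous at the caps
  areas <- sort(withr::with_seed(1, stats::runif(200, 1e3, 1e6)))
  fr <- target_fraction(areas)
  expect_true(all(diff(fr) <= 1e-12))
  expect_equal(target_fraction(10000 * (1 + 1e-9)), 1.0,
               tolerance = 1e-6)
  expect_equal(target_fraction(250000 * (1 - 1e-9)), 0.1,
               tolerance = 1e-6)

  # uniform sensitivity mode ignores range area
  u <- target_rule(mode = "uniform")
  expect_equal(target_fraction(c(5e3, 5e4, 5e5), u), rep(0.30, 3))

  expect_error(target_fraction(-1), "positive")
  expect_error(target_rule(lower_cap_km2 = 3e5, upper_cap_km2 = 1e4),
               "lower_cap")
})

test_that("build_features subdivides ranges by typology with shared species targets", {
  w <- make_tiny_world()
  built <- build_features(w$ranges, w$typology)

  expect_equal(nrow(built$features), 2L)
  f <- built$features[order(built$features$typology), ]
  expect_equal(f$range_area_km2, c(20, 10))
  # species range area = 30 km2 < lower cap, so both subgroups get 100%
  expect_equal(f$target_fraction, c(1, 1))
  expect_equal(f$target_amount_km2, c(20, 10))
  expect_equal(nrow(built$amounts), 4L)

  # a typology absent from the species' units yields no feature
  typ2 <- w$typology[w$typology$typology != "estuarine", ]
  built2 <- build_features(w$ranges, typ2)
  expect_equal(built2$features$typology, "deltaic")

  # species whose range misses the typology map entirely is reported
  expect_error(build_features(list(S001 = 1L, S002 = 99L), w$typology),
               "absent from the typology map")
})

test_that("feature count equals the number of nonzero species-typology pairs", {
  sea <- small_seascape(seed = 9, n_units = 120, n_species = 20)
  # exhaustive pair enumeration oracle
  pairs <- 0L
  for (sp in names(sea$species_ranges)) {
    tm <- sea$typology_map[sea$typology_map$pu_id %in%
                             sea$species_ranges[[sp]], ]
    pairs <- pairs + length(unique(tm$typology[tm$area_km2 > 0]))
  }
  expect_equal(nrow(sea$features), pairs)
  expect_lte(nrow(sea$features), 20L * 4L)

  # amount-matrix consistency with the declared feature range areas
  sums <- vapply(split(sea$amounts$area_km2, sea$amounts$feature_id),
                 sum, numeric(1))
  expect_equal(unname(sums[sea$features$feature_id]),
               sea$features$range_area_km2, tolerance = 1e-9)
})

test_that("nearest-unit assignment uses distance with smallest-id ties", {
  units <- make_units(4, x = c(0, 3, 5, 14), y = rep(0, 4))
  # unit 3 is the orphan; donors 1, 2, 4 at distances 5, 2, 9
  ranges <- list(A = 1L, B = 2L, C = c(2L, 4L))
  aug <- nearest_unit_assignment(ranges, units)
  expect_equal(aug$B, c(2L, 3L))
  expect_equal(aug$C, c(2L, 3L, 4L))
  expect_equal(aug$A, 1L)

  # exact midway tie between donors 1 and 2 goes to the smaller unit id
  units_tie <- make_units(3, x = c(0, 10, 5), y = rep(0, 3))
  aug_tie <- nearest_unit_assignment(list(A = 1L, B = 2L), units_tie)
  expect_equal(aug_tie$A, c(1L, 3L))
  expect_equal(aug_tie$B, 2L)

  # no orphans: identity
  expect_equal(nearest_unit_assignment(list(A = c(1L, 2L, 3L)),
                                       make_units(3)),
               list(A = c(1L, 2L, 3L)))

  expect_error(nearest_unit_assignment(list(), make_units(2)),
               "no occupied planning unit")
})

test_that("country split conserves ranges and targets", {
  units <- make_units(5, mangrove_area = c(30, 30, 20, 20, 20),
                      country = c("A", "A", "B", "B", "B"))
  features <- tibble::tibble(
    feature_id = "S1_deltaic", species_id = "S1", typology = "deltaic",
    country_id = NA_character_, range_area_km2 = 100,
    target_fraction = 0.3, target_amount_km2 = 30
  )
  amounts <- tibble::tibble(
    pu_id = 1:5, feature_id = "S1_deltaic",
    area_km2 = c(30, 30, 20, 10, 10)
  )
  sp <- split_features_by_country(features, amounts, units)
  expect_equal(nrow(sp$features), 2L)
  expect_equal(sum(sp$features$range_area_km2), 100)
  expect_equal(sort(sp$features$target_amount_km2), c(12, 18))
  expect_equal(sp$features$target_fraction, c(0.3, 0.3))

  # achieved protection of any selection sums across children to the parent
  for (s in 1:10) {
    sel <- withr::with_seed(s, sample(1:5, sample(0:5, 1)))
    parent_achieved <- sum(amounts$area_km2[amounts$pu_id %in% sel])
    child_achieved <- sum(sp$amounts$area_km2[sp$amounts$pu_id %in% sel])
    expect_equal(child_achieved, parent_achieved)
  }

  # single-country split is the identity up to ids
  one <- split_features_by_country(features, amounts,
                                   make_units(5, country = rep("A", 5)))
  expect_equal(nrow(one$features), 1L)
  expect_equal(one$features$range_area_km2, 100)
  expect_equal(one$features$target_amount_km2, 30)

  # recomputed country-level fractions use country range areas
  rec <- split_features_by_country(features, amounts, units,
                                   recompute_targets = TRUE)
  expect_equal(sort(rec$features$target_fraction),
               sort(unname(target_fraction(c(60, 40)))))
})
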
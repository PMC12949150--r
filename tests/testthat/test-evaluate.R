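# Network evaluation statistics.

test_that("percent area selected is the area share of the scope", {
  units <- make_units(3, mangrove_area = c(10, 30, 60),
                      country = c("A", "A", "B"))
  expect_equal(percent_area_selected(c(1L, 3L), units), 70)
  expect_equal(percent_area_selected(units$pu_id, units), 100)
  expect_equal(percent_area_selected(integer(0), units), 0)
  expect_equal(percent_area_selected(c(1L, 3L), units, country = "A"), 25)
  expect_error(percent_area_selected(1L, units, country = "Z"),
               "empty scope")

  # selection-monotone: adding a unit never decreases it
  sel <- c(1L)
  expect_gte(percent_area_selected(c(sel, 2L), units),
             percent_area_selected(sel, units))
})

test_that("area-weighted resilience averages the selected estate", {
  units <- make_units(2, mangrove_area = c(1, 3),
                      res_land = c(0, 100), res_sea = c(0, 100))
  expect_equal(area_weighted_resilience(c(1L, 2L), units), 75)
  expect_equal(area_weighted_resilience(c(1L, 2L), units, "landward"), 75)
  expect_true(is.na(area_weighted_resilience(integer(0), units)))

  # uniform resilience: any selection scores the same
  flat <- make_units(5, mangrove_area = 1:5)
  expect_equal(area_weighted_resilience(c(2L, 4L), flat), 50)

  # symmetric fields: mean equals either single field
  sym <- make_units(4, res_land = c(10, 40, 60, 90),
                    res_sea = c(10, 40, 60, 90))
  expect_equal(area_weighted_resilience(1:4, sym, "mean"),
               area_weighted_resilience(1:4, sym, "seaward"))
})

test_that("relative change reproduces the printed scenario comparisons", {
  expect_equal(round(relative_change(42.6, 39.7), 1), 7.3)
  expect_equal(round(relative_change(48.6, 39.7), 1), 22.4)
  expect_equal(round(relative_change(50.5, 42.6), 1), 18.5)
  expect_equal(relative_change(5, 5), 0)
  expect_error(relative_change(1, 0), "zero baseline")
})

test_that("Cohen's kappa matches the confusion-matrix formula", {
  ids <- 1:100

  # identical non-degenerate selections
  k1 <- cohen_kappa(1:40, 1:40, ids)
  expect_equal(k1$kappa, 1)

  # both=40, a-only=10, b-only=10, neither=40 -> kappa = 0.6
  a <- 1:50
  b <- 11:60
  k <- cohen_kappa(a, b, ids)
  expect_equal(k$kappa, 0.6)
  expect_equal(unname(k$counts), c(40, 10, 10, 40))

  # complementary equal-size selections
  expect_equal(cohen_kappa(1:50, 51:100, ids)$kappa, -1)

  # degenerate identical selections
  expect_equal(cohen_kappa(ids, ids, ids)$kappa, 1)

  # symmetry and agreement with the direct formula on random selections
  for (s in 1:10) {
    sel <- withr::with_seed(s, list(sample(ids, sample(10:90, 1)),
                                    sample(ids, sample(10:90, 1))))
    ka <- cohen_kappa(sel[[1]], sel[[2]], ids)$kappa
    kb <- cohen_kappa(sel[[2]], sel[[1]], ids)$kappa
    expect_equal(ka, kb)
    av <- ids %in% sel[[1]]
    bv <- ids %in% sel[[2]]
    po <- mean(av == bv)
    pe <- mean(av) * mean(bv) + mean(!av) * mean(!bv)
    expect_equal(ka, (po - pe) / (1 - pe))
  }
})

test_that("kappa categories follow the agreement bands", {
  expect_equal(kappa_category(-0.2), "great disagreement")
  expect_equal(kappa_category(0), "great disagreement")
  expect_equal(kappa_category(0.05), "none to slight")
  expect_equal(kappa_category(0.38), "fair")
  expect_equal(kappa_category(c(0.15, 0.5, 0.7, 0.9)),
               c("slight", "moderate", "substantial", "almost perfect"))
  expect_error(kappa_category(1.5), "kappa")
})

test_that("protected-area audit matches hand arithmetic and the solution audit", {
  units <- make_units(2, mangrove_area = c(10, 10),
                      protected = c(1, 0.5))
  features <- tibble::tibble(
    feature_id = c("F1", "F2"), species_id = "S", typology = "deltaic",
    range_area_km2 = c(12, 8), target_fraction = c(0.5, 1),
    target_amount_km2 = c(6, 8)
  )
  amounts <- tibble::tibble(
    pu_id = c(1L, 2L, 2L), feature_id = c("F1", "F1", "F2"),
    area_km2 = c(8, 4, 8)
  )
  aud <- audit_protected_network(features, amounts, units)
  # protected: F1 = 8*1 + 4*0.5 = 10 >= 6 met; F2 = 8*0.5 = 4 < 8 unmet
  expect_equal(aud$per_feature$protected_km2, c(10, 4))
  expect_equal(aud$n_targets_met, 1L)
  expect_equal(aud$mean_shortfall_pct_range, 100 * (8 - 4) / 8)
  expect_equal(aud$pct_area_protected, 75)

  # full protection: every target met, overlap 100%
  full <- audit_protected_network(features, amounts,
                                  make_units(2,
                                             mangrove_area = c(10, 10),
                                             protected = c(1, 1)),
                                  solution = c(1L, 2L))
  expect_equal(full$n_targets_met, 2L)
  expect_equal(full$overlap_pct, 100)

  # zero protection: nothing met; mean shortfall = mean target fraction
  none <- audit_protected_network(features, amounts, units,
                                  protected_fractions = c(0, 0))
  expect_equal(none$n_targets_met, 0L)
  expect_equal(none$mean_shortfall_pct_range,
               mean(features$target_fraction) * 100)

  # indicator fractions reproduce the solution audit exactly
  sea <- small_seascape(seed = 23, n_units = 40, n_species = 6)
  pr <- build_problem(sea$planning_units, sea$features, sea$amounts)
  sel <- withr::with_seed(5, sample(sea$planning_units$pu_id, 25))
  indicator <- as.numeric(sea$planning_units$pu_id %in% sel)
  pa <- audit_protected_network(sea$features, sea$amounts,
                                sea$planning_units,
                                protected_fractions = indicator)
  sol_aud <- audit_solution(pr, sel)
  expect_equal(
    pa$per_feature$met[match(sol_aud$feature_id,
                             pa$per_feature$feature_id)],
    sol_aud$met
  )
})

test_that("evaluation reports summarise by country", {
  units <- make_units(4, mangrove_area = c(10, 10, 20, 20),
                      country = c("A", "A", "B", "B"),
                      res_land = c(20, 40, 60, 80),
                      res_sea = c(20, 40, 60, 80))
  ev <- evaluate_solution(c(1L, 3L), units, "demo")
  expect_equal(ev$pct_area_selected, 50)
  expect_equal(ev$per_country$pct_area_selected, c(50, 50))
  expect_equal(ev$per_country$resilience, c(20, 60))
  expect_equal(ev$resilience_mean,
               (10 * 20 + 20 * 60) / 30)
})
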
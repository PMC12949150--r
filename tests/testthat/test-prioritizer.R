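# Minimum-set problem construction, exact solving and auditing.

test_that("build_problem validates references and drops zero targets", {
  units <- make_units(3, mangrove_area = c(5, 6, 7))
  features <- tibble::tibble(feature_id = "F1", range_area_km2 = 10,
                             target_amount_km2 = 0)
  amounts <- tibble::tibble(pu_id = 1:2, feature_id = "F1",
                            area_km2 = c(5, 5))
  pr <- build_problem(units, features, amounts)
  expect_equal(nrow(pr$targets), 0L)
  sol <- solve_minset(pr)
  expect_equal(sol$selected_unit_ids, integer(0))
  expect_equal(sol$objective_km2, 0)
  expect_equal(sol$status, "optimal")

  expect_error(
    build_problem(units, features,
                  tibble::tibble(pu_id = 9L, feature_id = "F1",
                                 area_km2 = 1)),
    "unknown unit.*9"
  )
  expect_error(
    build_problem(make_units(2, mangrove_area = c(0, 1)), features,
                  amounts[0, ]),
    "non-positive cost"
  )

  # serialisation round trip is the identity
  pr2 <- random_instance(8, 4, seed = 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_problem(pr2, path)
  expect_equal(read_problem(path), pr2)
})

test_that("solve_minset picks dominant units and honours locks", {
  units <- make_units(2, mangrove_area = c(10, 4))
  features <- tibble::tibble(feature_id = "F1", range_area_km2 = 14,
                             target_amount_km2 = 4)
  amounts <- tibble::tibble(pu_id = c(1L, 2L), feature_id = "F1",
                            area_km2 = c(10, 4))
  sol <- solve_minset(build_problem(units, features, amounts))
  expect_equal(sol$selected_unit_ids, 2L)
  expect_equal(sol$objective_km2, 4)

  # 100% targets force every carrier unit into the solution
  sea <- small_seascape(seed = 17, n_units = 30, n_species = 5)
  full <- sea$features
  full$target_amount_km2 <- full$range_area_km2
  sol_full <- solve_minset(build_problem(sea$planning_units, full,
                                         sea$amounts))
  expect_setequal(sol_full$selected_unit_ids, unique(sea$amounts$pu_id))

  # locked-in units always appear
  locked <- solve_minset(
    build_problem(units, features, amounts, locked_in = 1L)
  )
  expect_true(1L %in% locked$selected_unit_ids)

  # uncoverable target is reported infeasible before solving
  bad <- build_problem(units,
                       tibble::tibble(feature_id = "F1",
                                      range_area_km2 = 14,
                                      target_amount_km2 = 99),
                       amounts)
  sol_bad <- solve_minset(bad)
  expect_equal(sol_bad$status, "infeasible")
  expect_equal(sol_bad$infeasible_feature, "F1")
})

test_that("brute force enumeration handles degenerate cases", {
  # no constraints: empty selection
  units <- make_units(3)
  empty <- build_problem(
    units,
    tibble::tibble(feature_id = character(0),
                   range_area_km2 = numeric(0),
                   target_amount_km2 = numeric(0)),
    tibble::tibble(pu_id = integer(0), feature_id = character(0),
                   area_km2 = numeric(0))
  )
  expect_equal(brute_force_minset(empty)$selected_unit_ids, integer(0))

  # one feature needing both of two units
  both <- build_problem(
    make_units(2, mangrove_area = c(5, 5)),
    tibble::tibble(feature_id = "F", range_area_km2 = 10,
                   target_amount_km2 = 10),
    tibble::tibble(pu_id = 1:2, feature_id = "F", area_km2 = c(5, 5))
  )
  expect_equal(brute_force_minset(both)$selected_unit_ids, c(1L, 2L))

  expect_error(brute_force_minset(random_instance(21, 2, 1)),
               "at most 20 units")
})

test_that("exact solver agrees with the enumeration oracle", {
  sizes <- withr::with_seed(55, {
    list(units = sample(6:10, 30, replace = TRUE),
         feats = sample(2:5, 30, replace = TRUE))
  })
  problems <- lapply(1:30, function(s) {
    random_instance(sizes$units[s], sizes$feats[s], seed = 100 + s)
  })
  sols <- solve_minset_batch(problems, gap = 1e-4)
  for (k in seq_along(problems)) {
    bf <- brute_force_minset(problems[[k]])
    expect_equal(sols[[k]]$objective_km2, bf$objective_km2,
                 tolerance = 2e-4)
    expect_true(all(audit_solution(problems[[k]], sols[[k]])$met))
  }
})

test_that("audit_solution reports achievements and shortfalls", {
  units <- make_units(2, mangrove_area = c(10, 10))
  features <- tibble::tibble(
    feature_id = c("F1", "F2"), range_area_km2 = c(12, 8),
    target_amount_km2 = c(6, 8)
  )
  amounts <- tibble::tibble(
    pu_id = c(1L, 2L, 2L), feature_id = c("F1", "F1", "F2"),
    area_km2 = c(8, 4, 8)
  )
  pr <- build_problem(units, features, amounts)

  aud_empty <- audit_solution(pr, integer(0))
  expect_false(any(aud_empty$met))
  expect_equal(aud_empty$shortfall_pct_range, c(50, 100))

  aud1 <- audit_solution(pr, 1L)
  expect_equal(aud1$achieved_km2, c(8, 0))
  expect_equal(aud1$met, c(TRUE, FALSE))

  aud_all <- audit_solution(pr, c(1L, 2L))
  expect_true(all(aud_all$met))
  expect_equal(aud_all$shortfall_pct_range, c(0, 0))
})
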
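# Exact solution of the minimum-set problem.
#
# The binary program is handed to the open-source HiGHS branch-and-bound
# solver through SciPy's `milp` interface, run in a `python` subprocess (the
# published analysis used a commercial solver; any exact MILP solver meeting
# the optimality-gap contract is interchangeable here). The backend
# interface is minimal - costs, constraint triplets and a gap go in; a
# selection and the achieved bound come out - and `brute_force_minset()`
# provides an independent pure-R enumeration oracle for small instances.

solver_python <- function() {
  cand <- Sys.getenv("MANGROVEPLAN_PYTHON", "")
  if (!nzchar(cand)) cand <- Sys.which("python")
  if (!nzchar(cand)) cand <- Sys.which("python3")
  if (!nzchar(cand)) {
    stop_solver(
      "no `python` interpreter with scipy found on PATH; set MANGROVEPLAN_PYTHON"
    )
  }
  cand
}

solver_script <- function() {
  path <- system.file("python", "minset_solver.py",
                      package = "mangroveplan", mustWork = FALSE)
  if (!nzchar(path)) {
    # during development (pkgload) the file lives under inst/
    path <- file.path("inst", "python", "minset_solver.py")
  }
  if (!file.exists(path)) stop_solver("solver backend script not found")
  path
}

new_solution <- function(selected_unit_ids, objective_km2, status,
                         relative_gap_achieved = 0,
                         solver_name = "none", wall_time_s = 0,
                         infeasible_feature = NA_character_) {
  structure(
    list(
      selected_unit_ids = selected_unit_ids,
      objective_km2 = objective_km2,
      status = status,
      relative_gap_achieved = relative_gap_achieved,
      solver_name = solver_name,
      wall_time_s = wall_time_s,
      infeasible_feature = infeasible_feature
    ),
    class = "minset_solution"
  )
}

#' @export
print.minset_solution <- function(x, ...) {
  cat("<minset_solution>\n")
  cat(sprintf("  status: %s (%s, %.2fs)\n", x$status, x$solver_name,
              x$wall_time_s))
  cat(sprintf("  selected %d units, objective %.3f km2, gap %.3g\n",
              length(x$selected_unit_ids), x$objective_km2,
              x$relative_gap_achieved))
  invisible(x)
}

# Uncoverable-target pre-check; returns the first uncoverable feature id or
# NA. Coverage excludes locked-out units.
first_uncoverable_feature <- function(problem) {
  if (nrow(problem$targets) == 0L) return(NA_character_)
  amt <- problem$amounts
  if (length(problem$locked_out) > 0L) {
    amt <- amt[!(amt$pu_id %in% problem$locked_out), , drop = FALSE]
  }
  coverable <- vapply(
    split(amt$area_km2, factor(amt$feature_id,
                               levels = problem$targets$feature_id)),
    sum, numeric(1)
  )
  short <- which(coverable < problem$targets$target_km2 * (1 - 1e-9))
  if (length(short) == 0L) NA_character_
  else problem$targets$feature_id[short[1L]]
}

#' Solve a minimum-set problem exactly
#'
#' Solves the binary minimum-set program to within a relative optimality
#' gap (default 0.0001, i.e. 0.01 percent) with the HiGHS solver. Locked-in
#' units are always selected; infeasible problems are detected up front
#' (first uncoverable feature named in the returned solution) rather than
#' passed to the solver.
#'
#' @param problem A `minset_problem` from [build_problem()].
#' @param gap Relative optimality gap in [0, 1); default `1e-4`.
#' @return A `minset_solution` with `selected_unit_ids`, `objective_km2`,
#'   `status` (`"optimal"`, `"gap_reached"` or `"infeasible"`),
#'   `relative_gap_achieved`, `solver_name` and `wall_time_s`.
#' @seealso [brute_force_minset()] for the enumeration oracle,
#'   [audit_solution()] for target verification.
#' @export
solve_minset <- function(problem, gap = 1e-4) {
  solve_minset_batch(list(problem), gap = gap)[[1L]]
}

#' Solve several minimum-set problems in one solver invocation
#'
#' Identical contract to [solve_minset()], amortising the backend startup
#' across many instances (used by threshold sweeps and scale comparisons).
#'
#' @param problems List of `minset_problem` objects.
#' @param gap Relative optimality gap.
#' @return List of `minset_solution` objects, in input order.
#' @export
solve_minset_batch <- function(problems, gap = 1e-4) {
  assert_scalar_number(gap, "gap", lower = 0, upper = 0.999)
  solutions <- vector("list", length(problems))
  needs_solver <- logical(length(problems))
  payloads <- vector("list", length(problems))

  for (k in seq_along(problems)) {
    pb <- problems[[k]]
    if (!inherits(pb, "minset_problem")) {
      stop_validation("element %d is not a minset_problem", k)
    }
    uncov <- first_uncoverable_feature(pb)
    if (!is.na(uncov)) {
      solutions[[k]] <- new_solution(
        integer(0), NA_real_, "infeasible",
        relative_gap_achieved = NA_real_,
        solver_name = "precheck", infeasible_feature = uncov
      )
      next
    }
    if (nrow(pb$targets) == 0L) {
      sel <- sort(pb$locked_in)
      solutions[[k]] <- new_solution(
        sel, sum(pb$costs[match(sel, pb$unit_ids)]), "optimal",
        solver_name = "trivial"
      )
      next
    }
    uidx <- stats::setNames(seq_along(pb$unit_ids) - 1L, pb$unit_ids)
    fidx <- stats::setNames(seq_len(nrow(pb$targets)) - 1L,
                            pb$targets$feature_id)
    payloads[[k]] <- list(
      n = length(pb$unit_ids),
      costs = I(pb$costs),
      con_i = I(unname(uidx[as.character(pb$amounts$pu_id)])),
      con_j = I(unname(fidx[pb$amounts$feature_id])),
      con_a = I(pb$amounts$area_km2),
      targets = I(pb$targets$target_km2),
      lock_in = I(unname(uidx[as.character(pb$locked_in)])),
      lock_out = I(unname(uidx[as.character(pb$locked_out)])),
      gap = gap
    )
    needs_solver[k] <- TRUE
  }

  if (any(needs_solver)) {
    idx <- which(needs_solver)
    in_path <- tempfile(fileext = ".json")
    out_path <- tempfile(fileext = ".json")
    on.exit(unlink(c(in_path, out_path)), add = TRUE)
    jsonlite::write_json(list(problems = payloads[idx]), in_path,
                         digits = NA, auto_unbox = TRUE)
    t0 <- proc.time()[["elapsed"]]
    status <- suppressWarnings(system2(
      solver_python(), c(shQuote(solver_script()), shQuote(in_path),
                         shQuote(out_path)),
      stdout = TRUE, stderr = TRUE
    ))
    elapsed <- proc.time()[["elapsed"]] - t0
    code <- attr(status, "status") %||% 0L
    if (code != 0L || !file.exists(out_path)) {
      stop_solver("MILP backend failed (exit %s): %s", code,
                  paste(status, collapse = "\n"))
    }
    res <- jsonlite::read_json(out_path, simplifyVector = FALSE)$solutions
    per_solve <- elapsed / length(idx)
    for (m in seq_along(idx)) {
      k <- idx[m]
      r <- res[[m]]
      pb <- problems[[k]]
      if (identical(r$status, "error")) {
        stop_solver("MILP backend error on problem %d: %s", k,
                    r$message %||% "unknown")
      }
      if (identical(r$status, "infeasible")) {
        solutions[[k]] <- new_solution(
          integer(0), NA_real_, "infeasible",
          relative_gap_achieved = NA_real_,
          solver_name = r$solver %||% "highs",
          wall_time_s = per_solve
        )
        next
      }
      sel_idx <- unlist(r$selected) %||% integer(0)
      sel <- sort(pb$unit_ids[sel_idx + 1L])
      solutions[[k]] <- new_solution(
        sel,
        sum(pb$costs[match(sel, pb$unit_ids)]),
        if ((r$gap %||% 0) > 0) "gap_reached" else "optimal",
        relative_gap_achieved = r$gap %||% 0,
        solver_name = r$solver %||% "highs (scipy milp)",
        wall_time_s = per_solve
      )
    }
  }
  solutions
}

#' Exhaustive-enumeration oracle for small minimum-set problems
#'
#' Enumerates every subset of planning units (at most 20 units) and returns
#' the minimum-cost feasible selection; cost ties are broken by the
#' lexicographically smallest sorted set of selected unit ids. Serves as the
#' independent correctness oracle for [solve_minset()].
#'
#' @param problem A `minset_problem` with at most 20 units.
#' @return A `minset_solution` with `status` `"optimal"` or `"infeasible"`.
#' @export
brute_force_minset <- function(problem) {
  n <- length(problem$unit_ids)
  if (n > 20L) {
    stop_validation("brute_force_minset handles at most 20 units (got %d)",
                    n)
  }
  m <- nrow(problem$targets)
  A <- matrix(0, n, m,
              dimnames = list(problem$unit_ids, problem$targets$feature_id))
  if (nrow(problem$amounts) > 0L && m > 0L) {
    A[cbind(match(problem$amounts$pu_id, problem$unit_ids),
            match(problem$amounts$feature_id,
                  problem$targets$feature_id))] <- problem$amounts$area_km2
  }
  tol_target <- problem$targets$target_km2 * (1 - 1e-9)
  in_mask <- problem$unit_ids %in% problem$locked_in
  out_mask <- problem$unit_ids %in% problem$locked_out

  best_cost <- Inf
  best_sets <- list()
  n_subsets <- 2^n
  chunk <- 65536L
  for (start in seq(0, n_subsets - 1, by = chunk)) {
    ids <- start + seq_len(min(chunk, n_subsets - start)) - 1
    S <- matrix(0L, length(ids), n)
    for (b in seq_len(n)) S[, b] <- bitwAnd(ids %/% 2^(b - 1), 1)
    ok <- rep(TRUE, length(ids))
    if (any(in_mask)) ok <- ok & rowSums(S[, in_mask, drop = FALSE]) ==
        sum(in_mask)
    if (any(out_mask)) ok <- ok & rowSums(S[, out_mask, drop = FALSE]) == 0
    if (m > 0L) {
      achieved <- S %*% A
      ok <- ok & apply(achieved >= rep(tol_target, each = nrow(achieved)),
                       1L, all)
    }
    if (!any(ok)) next
    costs <- as.vector(S[ok, , drop = FALSE] %*% problem$costs)
    sel_rows <- which(ok)
    cmin <- min(costs)
    if (!is.finite(best_cost) ||
        cmin < best_cost - 1e-12 * max(1, abs(best_cost))) {
      best_cost <- cmin
      best_sets <- list()
    }
    near <- which(costs <= best_cost * (1 + 1e-12) + 1e-12)
    for (r in near) {
      best_sets[[length(best_sets) + 1L]] <-
        problem$unit_ids[S[sel_rows[r], ] == 1L]
    }
  }
  if (!is.finite(best_cost)) {
    return(new_solution(integer(0), NA_real_, "infeasible",
                        relative_gap_achieved = NA_real_,
                        solver_name = "brute_force"))
  }
  keys <- vapply(best_sets, function(ids) {
    paste(sprintf("%012d", sort(ids)), collapse = ",")
  }, character(1))
  sel <- sort(best_sets[[which.min(rank(keys, ties.method = "first"))]])
  new_solution(sel, sum(problem$costs[match(sel, problem$unit_ids)]),
               "optimal", solver_name = "brute_force")
}

#' Audit a solution against the problem's targets
#'
#' @param problem A `minset_problem`.
#' @param solution A `minset_solution` (or a vector of selected `pu_id`s).
#' @return Tibble with one row per constrained feature: `feature_id`,
#'   `achieved_km2`, `target_km2`, `met` (achieved >= target minus a
#'   relative 1e-6 tolerance) and `shortfall_pct_range` (unmet area as a
#'   percentage of the feature's range area).
#' @export
audit_solution <- function(problem, solution) {
  sel <- as_selected_ids(solution)
  amt <- problem$amounts[problem$amounts$pu_id %in% sel, , drop = FALSE]
  achieved <- vapply(
    split(amt$area_km2, factor(amt$feature_id,
                               levels = problem$targets$feature_id)),
    sum, numeric(1)
  )
  tibble::tibble(
    feature_id = problem$targets$feature_id,
    achieved_km2 = unname(achieved),
    target_km2 = problem$targets$target_km2,
    met = unname(achieved) >= problem$targets$target_km2 * (1 - 1e-6),
    shortfall_pct_range =
      100 * pmax(0, problem$targets$target_km2 - unname(achieved)) /
        problem$targets$range_area_km2
  )
}

# Accept either a minset_solution or a plain vector of selected unit ids.
as_selected_ids <- function(solution) {
  if (inherits(solution, "minset_solution")) solution$selected_unit_ids
  else solution
}

#' Serialise / deserialise a solution
#'
#' The wall-clock time is informational and not serialised, so identical
#' runs produce byte-identical solution files.
#'
#' @param solution A `minset_solution`.
#' @param path File path for the JSON document.
#' @return `read_solution()` returns the `minset_solution`;
#'   `write_solution()` returns `path` invisibly.
#' @export
write_solution <- function(solution, path) {
  jsonlite::write_json(
    list(
      schema = "minset_solution/1",
      selected_unit_ids = solution$selected_unit_ids,
      objective_km2 = solution$objective_km2,
      status = solution$status,
      relative_gap_achieved = solution$relative_gap_achieved,
      solver_name = solution$solver_name
    ),
    path, digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_solution
#' @export
read_solution <- function(path) {
  s <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_solution(
    s$selected_unit_ids %||% integer(0),
    s$objective_km2, s$status,
    relative_gap_achieved = s$relative_gap_achieved %||% 0,
    solver_name = s$solver_name %||% "unknown",
    wall_time_s = s$wall_time_s %||% 0
  )
}
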
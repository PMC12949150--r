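# Internal helpers shared across modules.

TYPOLOGY_CLASSES <- c("deltaic", "estuarine", "lagoonal", "open_coast")

stopf <- function(fmt, ..., class = "mangroveplan_error") {
  rlang::abort(sprintf(fmt, ...), class = c(class, "mangroveplan_error"))
}

# Validation failures (bad configs, malformed tables) -> exit code 2 in the CLI
stop_validation <- function(fmt, ...) {
  stopf(fmt, ..., class = "mangroveplan_validation_error")
}

# Infeasible optimisation problems -> exit code 3 in the CLI
stop_infeasible <- function(fmt, ...) {
  stopf(fmt, ..., class = "mangroveplan_infeasible_error")
}

# Solver backend failures -> exit code 4 in the CLI
stop_solver <- function(fmt, ...) {
  stopf(fmt, ..., class = "mangroveplan_solver_error")
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation("`%s` must be a single finite number", name)
  }
  if (strict_lower && x <= lower) {
    stop_validation("`%s` must be > %s (got %s)", name, lower, x)
  }
  if (!strict_lower && x < lower) {
    stop_validation("`%s` must be >= %s (got %s)", name, lower, x)
  }
  if (x > upper) {
    stop_validation("`%s` must be <= %s (got %s)", name, upper, x)
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  assert_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) {
    stop_validation("`%s` must be a whole number (got %s)", name, x)
  }
  invisible(as.integer(x))
}

assert_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0L) {
    stop_validation(
      "%s is missing required column(s): %s",
      what, paste(missing, collapse = ", ")
    )
  }
  invisible(df)
}

# Area-weighted mean, NA-safe for empty input (returns NA_real_).
weighted_mean_safe <- function(x, w) {
  if (length(x) == 0L || sum(w) <= 0) return(NA_real_)
  sum(x * w) / sum(w)
}

# Moving-average smoothing along an ordering, with edge truncation.
# `half_width` in units of positions; widths below one position smooth
# nothing (the window would contain only the point itself).
smooth_along <- function(x, half_width) {
  n <- length(x)
  if (half_width < 1 || n == 1L) return(x)
  hw <- min(as.integer(floor(half_width)), n - 1L)
  cs <- cumsum(c(0, x))
  i <- seq_len(n)
  lo <- pmax(i - hw, 1L)
  hi <- pmin(i + hw, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# Min-max rescale to [lo, hi]; constant input maps to the midpoint.
rescale_range <- function(x, lo = 0, hi = 100) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep((lo + hi) / 2, length(x)))
  lo + (hi - lo) * (x - rng[1L]) / diff(rng)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
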
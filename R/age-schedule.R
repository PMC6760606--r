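# Age-indexed piecewise-linear schedules (intake rates, body weights,
# volume-of-distribution adjustment factors).

#' Days per month and per year used for all age conversions
#'
#' All age-group boundaries are converted to days with a fixed-length month
#' of 30.4375 days (365.25 / 12) and a year of 365.25 days, so that anchor
#' placement is deterministic.
#'
#' @format Numeric scalars, in days.
#' @name age-units
#' @aliases DAYS_PER_MONTH DAYS_PER_YEAR
#' @export
DAYS_PER_MONTH <- 365.25 / 12

#' @rdname age-units
#' @export
DAYS_PER_YEAR <- 365.25

#' Construct an age-indexed schedule
#'
#' An `age_schedule` is an ordered set of (age in days, value) anchor points.
#' Values between anchors are obtained by linear interpolation; queries
#' before the first anchor or after the last return the end value unchanged
#' (constant extrapolation). Anchors are conventionally placed at the
#' midpoint in time of each published age group so that interpolation avoids
#' abrupt steps between groups.
#'
#' @param ages Numeric vector of anchor ages in days, strictly increasing,
#'   all `>= 0`.
#' @param values Numeric vector of schedule values at those ages (same
#'   length as `ages`).
#' @param name Label for the schedule.
#' @param units Units of the values (e.g. `"mL/kg/day"`, `"kg"`).
#' @return An object of class `age_schedule`.
#' @examples
#' sched <- age_schedule(c(0, 10), c(2, 1), "toy", "unitless")
#' interpolate(sched, 5) # 1.5
#' @export
age_schedule <- function(ages, values, name = "schedule", units = "") {
  ages <- as.numeric(ages)
  values <- as.numeric(values)
  if (length(ages) < 1L || length(ages) != length(values)) {
    stop("`ages` and `values` must be non-empty and of equal length")
  }
  if (anyNA(ages) || anyNA(values)) stop("schedule anchors must be finite")
  if (any(ages < 0)) stop("anchor ages must be non-negative")
  if (is.unsorted(ages, strictly = TRUE)) {
    stop("anchor ages must be strictly increasing")
  }
  structure(
    list(ages = ages, values = values, name = name, units = units),
    class = "age_schedule"
  )
}

#' @export
print.age_schedule <- function(x, ...) {
  cat(sprintf("<age_schedule> %s [%s], %d anchors\n",
              x$name, x$units, length(x$ages)))
  print(data.frame(age_days = x$ages, value = x$values), row.names = FALSE)
  invisible(x)
}

#' Interpolate a schedule at given ages
#'
#' Exact at anchors, linear between adjacent anchors, constant beyond the
#' first and last anchor.
#'
#' @param schedule An [age_schedule()].
#' @param age Numeric vector of ages in days, all `>= 0`.
#' @return Numeric vector of interpolated values.
#' @export
interpolate <- function(schedule, age) {
  stopifnot(inherits(schedule, "age_schedule"))
  if (any(age < 0)) stop("age must be non-negative")
  if (length(schedule$ages) == 1L) {
    return(rep(schedule$values, length(age)))
  }
  stats::approx(schedule$ages, schedule$values, xout = age,
                method = "linear", rule = 2)$y
}

#' Time-weighted average of a schedule over an age window
#'
#' Computes the exact integral of the piecewise-linear (constant-tailed)
#' schedule over `[start, end]` divided by the window length. Used, for
#' example, to reduce the age-varying water-intake schedule to the single
#' lifetime-average intake rate that sets the maternal steady state.
#'
#' @param schedule An [age_schedule()].
#' @param start,end Window in days, `0 <= start < end`.
#' @return The average schedule value over the window.
#' @export
time_weighted_average <- function(schedule, start, end) {
  stopifnot(inherits(schedule, "age_schedule"))
  if (start < 0) stop("start must be non-negative")
  if (start >= end) stop("start must be strictly less than end")
  inner <- schedule$ages[schedule$ages > start & schedule$ages < end]
  pts <- c(start, inner, end)
  vals <- interpolate(schedule, pts)
  n <- length(pts)
  area <- sum(diff(pts) * (vals[-n] + vals[-1]) / 2)
  area / (end - start)
}

# Midpoint (in days) of an age group [lo, hi), given in days.
age_group_midpoint <- function(lo, hi) (lo + hi) / 2
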
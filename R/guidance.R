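# Guidance-derivation layer: reference serum concentration, reference dose,
# relative source contribution, health-based guidance value (HBGV) solver,
# exceedance durations, traditional steady-state HBGV, health risk index.

#' Round to significant figures, always toward zero
#'
#' Guidance values are reported at two significant figures; rounding *down*
#' guarantees the reported water concentration still satisfies the serum
#' target it was solved for.
#'
#' @param x Positive numeric.
#' @param digits Significant figures.
#' @return `x` truncated to `digits` significant figures.
#' @export
signif_floor <- function(x, digits = 2) {
  if (any(x < 0)) stop("x must be non-negative")
  ifelse(x == 0, 0, {
    e <- floor(log10(x)) - (digits - 1)
    # guard against floating-point representation pushing an exact value
    # like 0.035 below its own floor
    floor(x / 10^e + 1e-9) * 10^e
  })
}

#' Reference serum concentration from a point of departure
#'
#' @param pod Point-of-departure serum concentration, mg/L.
#' @param uf Total uncertainty factor.
#' @param digits Significant figures for the reported value (2 by default);
#'   `NULL` for the unrounded quotient.
#' @return Reference serum concentration, mg/L.
#' @examples
#' reference_serum(38, 300) # 0.13
#' @export
reference_serum <- function(pod, uf, digits = 2) {
  if (pod <= 0 || uf <= 0) stop("pod and uf must be positive")
  x <- pod / uf
  if (is.null(digits)) x else signif(x, digits)
}

#' Reference dose from a reference serum concentration
#'
#' Converts the internal-dose reference level back to an administered daily
#' dose through the clearance rate.
#'
#' @param ref_serum Reference serum concentration, mg/L.
#' @param clearance Clearance rate, L/kg/day.
#' @param digits Significant figures (2); `NULL` for unrounded.
#' @return Reference dose, mg/kg/day.
#' @examples
#' rfd(0.13, 0.00014) # 1.8e-05
#' @export
rfd <- function(ref_serum, clearance, digits = 2) {
  if (ref_serum <= 0 || clearance <= 0) stop("inputs must be positive")
  x <- ref_serum * clearance
  if (is.null(digits)) x else signif(x, digits)
}

#' Relative source contribution via the exposure decision tree
#'
#' Subtracts the serum level attributable to non-water sources from the
#' decision-tree ceiling allocation of the reference serum concentration.
#' The residual fraction places the appropriate RSC band; the conservative
#' selection is the band floor.
#'
#' @param ref_serum Reference serum concentration, mg/L.
#' @param background_serum Serum level from non-water exposure sources
#'   (e.g. a national biomonitoring 95th percentile), mg/L.
#' @param ceiling,floor Decision-tree ceiling and floor fractions (0.8, 0.2).
#' @return A list: `residual` (mg/L available to water exposure),
#'   `residual_fraction` (of the reference serum), `band` (RSC interval the
#'   residual supports), `rsc` (selected value, the band floor),
#'   `allocated_serum` (`ref_serum * rsc`, mg/L).
#' @examples
#' rsc_decision(0.13, 0.00557)$residual  # 0.0984
#' @export
rsc_decision <- function(ref_serum, background_serum,
                         ceiling = 0.8, floor = 0.2) {
  if (ref_serum <= 0) stop("ref_serum must be positive")
  if (background_serum < 0) stop("background_serum must be non-negative")
  if (!(floor > 0 && floor < ceiling && ceiling <= 1)) {
    stop("require 0 < floor < ceiling <= 1")
  }
  cap <- ref_serum * ceiling
  if (background_serum >= cap) {
    stop(sprintf(
      "background serum (%g mg/L) consumes the entire %g%% ceiling allocation; no RSC can be assigned",
      background_serum, 100 * ceiling))
  }
  residual <- cap - background_serum
  frac <- residual / ref_serum
  band <- if (frac > 0.5) c(0.5, ceiling) else c(floor, 0.5)
  rsc <- band[1]
  list(residual = residual,
       residual_fraction = frac,
       band = band,
       rsc = rsc,
       allocated_serum = ref_serum * rsc)
}

#' Solve for the health-based guidance value of a scenario
#'
#' Finds the drinking-water concentration whose lifetime peak serum
#' concentration equals the target (the water-allocated fraction of the
#' reference serum concentration). Because the kinetics are linear in the
#' water concentration, the exact solution is `target / peak(1 µg/L)`;
#' a bisection on the full simulator verifies it independently. The
#' reported value is rounded down to two significant figures so that the
#' rounded concentration still meets the target.
#'
#' @param scenario An [exposure_scenario()].
#' @param target_serum Target lifetime maximum serum concentration, mg/L.
#' @param library Parameter library.
#' @param n_days Simulation horizon (days).
#' @param verify Run the bisection cross-check (default `TRUE`).
#' @param tol Bisection tolerance on the water concentration, µg/L.
#' @return A list: `hbgv` (µg/L, rounded down to 2 significant figures),
#'   `unrounded` (µg/L), `peak_serum` and `peak_day` of the simulation at
#'   the rounded value, and `bisection` (the verified root, µg/L, when
#'   `verify = TRUE`).
#' @examples
#' \donttest{
#' solve_hbgv(rme_formula(), target_serum = 0.065)$hbgv   # 0.15
#' }
#' @export
solve_hbgv <- function(scenario, target_serum,
                       library = default_parameter_library(),
                       n_days = 20000, verify = TRUE, tol = 1e-6) {
  if (target_serum <= 0) stop("target_serum must be positive")
  peak1 <- max(simulate_lifetime(scenario, 1, library, n_days)$infant_serum)
  if (peak1 <= 0) stop("scenario produces zero serum at unit concentration")
  exact <- target_serum / peak1
  hbgv <- signif_floor(exact, 2)

  bisect_root <- NA_real_
  if (verify) {
    f <- function(w) {
      max(simulate_lifetime(scenario, w, library, n_days)$infant_serum) -
        target_serum
    }
    lo <- 0
    hi <- 2 * exact
    it <- 0
    while (f(hi) < 0) {
      hi <- 2 * hi
      it <- it + 1
      if (it > 60) stop("bisection failed to bracket the target")
    }
    it <- 0
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) hi <- mid else lo <- mid
      it <- it + 1
      if (it > 100) stop("bisection failed to converge in 100 iterations")
    }
    bisect_root <- (lo + hi) / 2
    if (abs(bisect_root - exact) > max(10 * tol, 1e-6 * exact)) {
      stop("bisection cross-check disagrees with the linear solution")
    }
  }

  at_hbgv <- simulate_lifetime(scenario, hbgv, library, n_days)
  i <- which.max(at_hbgv$infant_serum)
  list(hbgv = hbgv,
       unrounded = exact,
       peak_serum = at_hbgv$infant_serum[i],
       peak_day = at_hbgv$day[i],
       bisection = bisect_root)
}

#' Time spent above serum thresholds
#'
#' @param result A `tk_simulation`.
#' @param thresholds Serum thresholds, mg/L.
#' @return Named numeric vector: years (days / 365.25) during which the
#'   infant serum series exceeds each threshold.
#' @export
exceedance_durations <- function(result, thresholds) {
  stopifnot(inherits(result, "tk_simulation"))
  out <- vapply(thresholds,
                function(th) sum(result$infant_serum > th) / DAYS_PER_YEAR,
                numeric(1))
  names(out) <- paste0(">", thresholds, " mg/L")
  out
}

#' Traditional steady-state health-based guidance value
#'
#' The conventional derivation that ignores placental and lactational
#' transfer: reference dose times RSC divided by a time-weighted-average
#' intake rate, converted to µg/L.
#'
#' @param rfd Reference dose, mg/kg/day.
#' @param rsc Relative source contribution (fraction).
#' @param intake Time-weighted-average water intake rate, L/kg/day.
#' @param digits Significant figures (2); `NULL` for unrounded.
#' @return Guidance value, µg/L.
#' @examples
#' traditional_hbgv(0.000018, 0.5, 0.064) # 0.14
#' @export
traditional_hbgv <- function(rfd, rsc, intake, digits = 2) {
  if (rfd <= 0 || rsc <= 0 || intake <= 0) stop("inputs must be positive")
  x <- rfd * rsc / intake * 1000   # mg/L -> ug/L
  if (is.null(digits)) x else signif(x, digits)
}

#' Additive health risk index for co-occurring chemicals
#'
#' @param concs Water concentrations, µg/L.
#' @param hbgvs Corresponding guidance values, µg/L (> 0).
#' @return The sum of `concs / hbgvs`, with attribute `flagged = TRUE` when
#'   it exceeds 1.
#' @examples
#' health_risk_index(c(0.07, 0.07), c(0.035, 0.035)) # 4
#' @export
health_risk_index <- function(concs, hbgvs) {
  if (length(concs) != length(hbgvs)) {
    stop("concs and hbgvs must have equal length")
  }
  if (any(hbgvs <= 0)) stop("hbgvs must be positive")
  if (any(concs < 0)) stop("concs must be non-negative")
  idx <- sum(concs / hbgvs)
  attr(idx, "flagged") <- idx > 1
  idx
}
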
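# Exposure scenarios: feeding mode, tier selections, breastfeeding timing.
#
# A scenario names, for each sensitive parameter, which tier (central or
# upper) of the parameter library to bind: intake rates, breastfeeding
# duration, half-life, transfer factors, Vd, Vd adjustment factor. The
# reasonable-maximum-exposure (RME) combination is upper intake and upper
# duration with everything else central; three alternative combinations are
# kept for protectiveness checks.

.tier_names <- c("intake", "duration", "half_life", "transfer", "vd", "vd_af")

#' Construct an exposure scenario
#'
#' @param feeding_mode `"breastfed"` or `"formula"`. Formula-fed infants
#'   ingest water (formula reconstituted with tap water) from day 1; their
#'   milk intake is identically zero.
#' @param tiers Named character vector/list selecting `"central"` or
#'   `"upper"` for each of `intake`, `duration`, `half_life`, `transfer`,
#'   `vd`, `vd_af`. Missing entries default to `"central"`.
#' @param placental_transfer If `FALSE`, the infant starts life with zero
#'   body burden (used to isolate the placental pathway's contribution).
#' @param breastfeeding_months Optional override of the duration tier:
#'   exclusive breastfeeding for this many months with no phase-out. `0`
#'   makes a breastfed scenario behave exactly like a formula-fed one.
#' @param name Scenario label.
#' @return An object of class `exposure_scenario`.
#' @export
exposure_scenario <- function(feeding_mode = c("breastfed", "formula"),
                              tiers = list(),
                              placental_transfer = TRUE,
                              breastfeeding_months = NULL,
                              name = NULL) {
  feeding_mode <- match.arg(feeding_mode)
  t <- stats::setNames(rep("central", length(.tier_names)), .tier_names)
  if (length(tiers)) {
    tiers <- unlist(tiers)
    bad <- setdiff(names(tiers), .tier_names)
    if (length(bad)) stop("unknown tier name(s): ", paste(bad, collapse = ", "))
    if (!all(tiers %in% c("central", "upper"))) {
      stop("tiers must be 'central' or 'upper'")
    }
    t[names(tiers)] <- tiers
  }
  # breastfeeding window, in days from birth
  if (!is.null(breastfeeding_months)) {
    if (breastfeeding_months < 0) stop("breastfeeding_months must be >= 0")
    excl <- breastfeeding_months * DAYS_PER_MONTH
    wean <- excl
  } else if (t[["duration"]] == "upper") {
    excl <- 12 * DAYS_PER_MONTH   # exclusive through 12 months, then water
    wean <- excl
  } else {
    excl <- 6 * DAYS_PER_MONTH    # exclusive 6 months, phased out by 12
    wean <- 12 * DAYS_PER_MONTH
  }
  if (feeding_mode == "formula") excl <- wean <- 0
  structure(
    list(name = name %||% paste0(feeding_mode, " scenario"),
         feeding_mode = feeding_mode,
         tiers = as.list(t),
         placental_transfer = isTRUE(placental_transfer),
         bf_exclusive_end = excl,
         bf_wean_end = wean),
    class = "exposure_scenario"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.exposure_scenario <- function(x, ...) {
  cat(sprintf("<exposure_scenario> %s\n", x$name))
  cat(sprintf("  feeding: %s; placental transfer: %s\n",
              x$feeding_mode, x$placental_transfer))
  if (x$feeding_mode == "breastfed") {
    cat(sprintf("  exclusive breastfeeding to day %.0f, weaned by day %.0f\n",
                x$bf_exclusive_end, x$bf_wean_end))
  }
  cat("  tiers:", paste(sprintf("%s=%s", names(x$tiers), unlist(x$tiers)),
                        collapse = ", "), "\n")
  invisible(x)
}

#' Named scenarios used in guidance derivation
#'
#' `rme_formula()` and `rme_breastfed()` are the reasonable-maximum-exposure
#' scenarios: upper-percentile intake rates and breastfeeding duration
#' (12 months exclusive), with central half-life (840 d), transfer factors
#' (placental 0.87, milk 0.052), Vd (0.17 L/kg) and Vd adjustment.
#' `alternative_scenarios()` returns the three alternative tier
#' combinations used to check that the RME choice is protective.
#'
#' @return An `exposure_scenario`, or for `alternative_scenarios()` a named
#'   list of three.
#' @examples
#' rme_breastfed()
#' @export
rme_breastfed <- function() {
  exposure_scenario("breastfed",
                    tiers = c(intake = "upper", duration = "upper"),
                    name = "MDH RME breastfed")
}

#' @rdname rme_breastfed
#' @export
rme_formula <- function() {
  exposure_scenario("formula",
                    tiers = c(intake = "upper", duration = "upper"),
                    name = "MDH RME formula-fed")
}

#' @rdname rme_breastfed
#' @export
alternative_scenarios <- function() {
  list(
    alternative_1 = exposure_scenario(
      "breastfed",
      tiers = c(intake = "central", duration = "central",
                half_life = "upper", transfer = "upper"),
      name = "Alternative 1"),
    alternative_2 = exposure_scenario(
      "breastfed",
      tiers = c(intake = "upper", duration = "central",
                half_life = "upper", transfer = "central"),
      name = "Alternative 2"),
    alternative_3 = exposure_scenario(
      "breastfed",
      tiers = c(intake = "central", duration = "upper",
                half_life = "upper", transfer = "central"),
      name = "Alternative 3")
  )
}

#' Look up a scenario by name
#'
#' @param name One of `"rme_breastfed"`, `"rme_formula"`,
#'   `"alternative_1"`, `"alternative_2"`, `"alternative_3"`.
#' @return An `exposure_scenario`.
#' @export
scenario_by_name <- function(name) {
  all <- c(list(rme_breastfed = rme_breastfed(), rme_formula = rme_formula()),
           alternative_scenarios())
  if (!name %in% names(all)) {
    stop("unknown scenario '", name, "'; valid names: ",
         paste(names(all), collapse = ", "))
  }
  all[[name]]
}

# Bind a scenario's tier selections to concrete parameter values.
resolve_scenario <- function(scenario, lib = default_parameter_library()) {
  stopifnot(inherits(scenario, "exposure_scenario"),
            inherits(lib, "parameter_library"))
  t <- scenario$tiers
  chem <- chemical_params(
    half_life = lib$half_life[[t$half_life]],
    vd = lib$vd,
    placental_tf = if (scenario$placental_transfer)
      lib$placental_tf[[t$transfer]] else 0,
    milk_tf = lib$milk_tf[[t$transfer]]
  )
  water_intake <- lib$water_intake[[t$intake]]
  list(
    chem = chem,
    vd_af = lib$vd_af,                       # single (central) AF schedule
    milk_intake = lib$milk_intake[[t$intake]],
    milk_bw = lib$milk_bw[[t$intake]],
    water_intake = water_intake,
    water_bw = lib$water_bw[[t$intake]],
    # lifetime-average intake of a mother at delivery (~age 30), mL/kg/day;
    # the unrounded schedule integral (the printed rounded values sit in
    # lib$maternal_twa_intake)
    maternal_twa_intake = time_weighted_average(water_intake, 0,
                                                30 * DAYS_PER_YEAR),
    maternal_bw = lib$maternal_bw[[t$intake]]                   # kg
  )
}

#' Adult steady-state serum concentration for a scenario
#'
#' Closed-form steady state (dose / clearance) for an adult drinking water
#' at the scenario tier's `>21 years` intake rate.
#'
#' @param scenario An [exposure_scenario()].
#' @param water_ug_L Water concentration in µg/L.
#' @param library Parameter library.
#' @return Steady-state serum concentration in mg/L.
#' @export
adult_steady_state <- function(scenario, water_ug_L,
                               library = default_parameter_library()) {
  p <- resolve_scenario(scenario, library)
  adult_intake <- interpolate(p$water_intake, 100 * DAYS_PER_YEAR) # >21 y value
  steady_state_serum(adult_intake * 1e-3 * water_ug_L * 1e-3, p$chem$clearance)
}

#' Express a simulated serum series as percent of adult steady state
#'
#' @param result A `tk_simulation` from [simulate_lifetime()].
#' @param adult_ss Adult steady-state serum (mg/L); by default computed from
#'   the simulation's own scenario and water concentration via
#'   [adult_steady_state()].
#' @return Numeric vector, percent of steady state per day.
#' @export
percent_of_steady_state <- function(result, adult_ss = NULL) {
  stopifnot(inherits(result, "tk_simulation"))
  if (is.null(adult_ss)) {
    adult_ss <- adult_steady_state(attr(result, "scenario"),
                                   attr(result, "water_ug_L"),
                                   attr(result, "library"))
  }
  if (adult_ss <= 0) stop("adult steady state must be positive")
  100 * result$infant_serum / adult_ss
}

#' Ratio of peak infant serum concentrations between two simulations
#'
#' By linearity of the kinetics in the water concentration, the ratio is
#' independent of the (common) water concentration used.
#'
#' @param a,b `tk_simulation` objects.
#' @return `max(a) / max(b)` of the infant serum series.
#' @export
peak_ratio <- function(a, b) {
  stopifnot(inherits(a, "tk_simulation"), inherits(b, "tk_simulation"))
  pb <- max(b$infant_serum)
  if (pb <= 0) stop("denominator simulation has zero peak serum")
  max(a$infant_serum) / pb
}
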
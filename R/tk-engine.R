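# One-compartment daily-timestep toxicokinetics.
#
# Serum is tracked as a concentration (mg/L) over a distribution volume of
# Vd (L/kg) x body weight (kg). Each simulated day the intake mass is added
# to the compartment and first-order elimination (e^-k) is then applied:
#
#   C[d] = (C[d-1] + intake_mg / (Vd_eff x BW)) * e^-k,   k = ln(2) / t1/2.
#
# During lactation the mother and infant are coupled: the infant's milk dose
# is the milk volume times the milk concentration (maternal serum x milk
# transfer factor, start-of-day value), and exactly that mass is debited
# from the maternal compartment, so mass is conserved across the pair.

#' First-order elimination constant
#'
#' @param half_life Elimination half-life in days (> 0).
#' @return `ln(2) / half_life`, in 1/day.
#' @export
elimination_constant <- function(half_life) {
  if (any(half_life <= 0)) stop("half_life must be positive")
  log(2) / half_life
}

#' Clearance rate
#'
#' @param vd Volume of distribution, L/kg (> 0).
#' @param half_life Elimination half-life in days (> 0).
#' @return `vd * ln(2) / half_life`, in L/kg/day.
#' @examples
#' clearance_rate(0.17, 840) # ~0.00014 L/kg/day
#' @export
clearance_rate <- function(vd, half_life) {
  if (any(vd <= 0)) stop("vd must be positive")
  vd * elimination_constant(half_life)
}

#' Steady-state serum concentration from a constant dose
#'
#' @param dose Daily dose in mg/kg/day (for water ingestion: water intake
#'   rate in L/kg/day times water concentration in mg/L).
#' @param clearance Clearance rate in L/kg/day (> 0).
#' @return Serum concentration in mg/L.
#' @export
steady_state_serum <- function(dose, clearance) {
  if (any(clearance <= 0)) stop("clearance must be positive")
  if (any(dose < 0)) stop("dose must be non-negative")
  dose / clearance
}

#' Infant serum concentration at birth
#'
#' @param maternal_serum Maternal serum concentration (mg/L) at delivery.
#' @param placental_tf Placental transfer factor (infant:maternal ratio).
#' @return `maternal_serum * placental_tf`, mg/L.
#' @export
birth_serum <- function(maternal_serum, placental_tf) {
  if (any(maternal_serum < 0) || any(placental_tf < 0)) {
    stop("inputs must be non-negative")
  }
  maternal_serum * placental_tf
}

#' Single daily serum update
#'
#' Adds the day's intake mass to the compartment, then applies one day of
#' first-order elimination.
#'
#' @param prev_serum Previous day's serum concentration, mg/L.
#' @param intake_mass Today's intake, mg.
#' @param vd_eff Effective volume of distribution (Vd x age adjustment), L/kg.
#' @param bw Body weight, kg.
#' @param k Elimination constant, 1/day.
#' @return Post-elimination serum concentration, mg/L.
#' @export
daily_update <- function(prev_serum, intake_mass, vd_eff, bw, k) {
  if (any(vd_eff <= 0) || any(bw <= 0)) stop("vd_eff and bw must be positive")
  if (any(k <= 0)) stop("k must be positive")
  if (any(prev_serum < 0) || any(intake_mass < 0)) {
    stop("serum and intake must be non-negative")
  }
  (prev_serum + intake_mass / (vd_eff * bw)) * exp(-k)
}

#' Breastmilk concentration from maternal serum
#'
#' @param maternal_serum Maternal serum concentration, mg/L.
#' @param milk_tf Breastmilk transfer factor (milk:maternal ratio).
#' @return Milk concentration, mg/L.
#' @export
breastmilk_concentration <- function(maternal_serum, milk_tf) {
  if (any(maternal_serum < 0) || any(milk_tf < 0)) {
    stop("inputs must be non-negative")
  }
  maternal_serum * milk_tf
}

# Fraction of full breastmilk feeding on each day of age. 1 during exclusive
# breastfeeding, a linear ramp to 0 across the phase-out window, 0 after.
milk_fraction <- function(age_days, scenario) {
  excl <- scenario$bf_exclusive_end
  wean <- scenario$bf_wean_end
  if (scenario$feeding_mode != "breastfed" || wean <= 0) {
    return(rep(0, length(age_days)))
  }
  f <- ifelse(age_days <= excl, 1,
              ifelse(age_days >= wean, 0,
                     (wean - age_days) / (wean - excl)))
  f
}

#' Simulate lifetime serum concentrations for a mother-infant pair
#'
#' Runs the daily one-compartment model over `n_days` days of life. The
#' mother is assumed at steady state at delivery (time-weighted-average
#' water intake times water concentration, divided by clearance); the
#' infant starts at the placentally transferred fraction of that serum
#' level. During lactation the infant's dose is breastmilk volume times
#' milk concentration and the same mass is debited from the maternal
#' compartment (mass balance), so milk concentration declines over
#' lactation. After weaning (or from day 1 for formula-fed infants) the
#' dose is the age-interpolated water intake times the water concentration.
#' Maternal exposure during lactation is assumed unchanged from before
#' delivery: each day her intake is her serum concentration times the
#' clearance rate (times body weight) — the dose that would hold her at
#' steady state — so her serum declines only through the mass exported in
#' milk. The maternal steady state at delivery uses the time-weighted
#' average of the tier's water-intake schedule from birth to age 30.
#'
#' @param scenario An [exposure_scenario()].
#' @param water_ug_L Drinking-water concentration, µg/L (>= 0).
#' @param library Parameter library; defaults to
#'   [default_parameter_library()].
#' @param n_days Simulation horizon in days (default 20000, ~55 years, long
#'   enough to attain steady state). A horizon shorter than the
#'   breastfeeding window simply truncates the lactation period, which the
#'   evaluation workflows use to read serum mid-lactation.
#' @param maternal_serum_ug_L Optional override: maternal steady-state serum
#'   at delivery in µg/L, replacing the water-derived value (used in the
#'   model-evaluation workflows where measured maternal serum is the input).
#' @param infant_birth_serum_ug_L Optional override of the infant's day-0
#'   serum (µg/L), replacing placental transfer applied to maternal serum.
#' @return A `tk_simulation`: a data frame with one row per day and columns
#'   `day` (age in days), `infant_serum`, `maternal_serum`, `milk_conc`
#'   (mg/L; `NA` outside lactation), `dose_mg_kg` (infant daily dose),
#'   `milk_dose_mg` and `water_dose_mg` (infant intake masses, the former
#'   equal to the mass debited from the mother), `bw_kg`, `vd_eff` (L/kg).
#'   Scenario, library and inputs are kept as attributes.
#' @examples
#' sim <- simulate_lifetime(rme_breastfed(), water_ug_L = 0.035)
#' max(sim$infant_serum)  # lifetime peak, mg/L
#' @export
simulate_lifetime <- function(scenario, water_ug_L,
                              library = default_parameter_library(),
                              n_days = 20000,
                              maternal_serum_ug_L = NULL,
                              infant_birth_serum_ug_L = NULL) {
  stopifnot(inherits(scenario, "exposure_scenario"))
  if (water_ug_L < 0) stop("water_ug_L must be non-negative")
  if (n_days < 2) stop("n_days must be at least 2")
  p <- resolve_scenario(scenario, library)
  chem <- p$chem
  k <- chem$k
  ek <- exp(-k)
  water_mg_L <- water_ug_L * 1e-3

  # maternal steady state at delivery (mg/L)
  maternal_ss <- if (!is.null(maternal_serum_ug_L)) {
    maternal_serum_ug_L * 1e-3
  } else {
    steady_state_serum(p$maternal_twa_intake * 1e-3 * water_mg_L,
                       chem$clearance)
  }
  maternal_vol <- chem$vd * p$maternal_bw                           # L

  days <- 0:(n_days - 1)
  mfrac <- milk_fraction(days, scenario)
  wfrac <- if (scenario$feeding_mode == "formula") rep(1, n_days) else 1 - mfrac
  lactating <- mfrac > 0

  milk_rate <- interpolate(p$milk_intake, days) * 1e-3 * mfrac   # L/kg/day
  water_rate <- interpolate(p$water_intake, days) * 1e-3 * wfrac # L/kg/day
  # body weight: milk-based series while any breastfeeding, blending into
  # the water-based series as milk is phased out
  bw <- mfrac * interpolate(p$milk_bw, days) +
    (1 - mfrac) * interpolate(p$water_bw, days)
  vd_eff <- chem$vd * interpolate(p$vd_af, days)

  infant0 <- if (!is.null(infant_birth_serum_ug_L)) {
    infant_birth_serum_ug_L * 1e-3
  } else {
    birth_serum(maternal_ss, chem$placental_tf)
  }

  # Maternal series is autonomous: her daily intake is her own serum times
  # clearance (the ongoing pre-delivery exposure), which exactly offsets
  # elimination, so each day multiplies her serum by
  #   g = (1 + k - milk_volume * milk_tf / maternal_volume) * e^-k,
  # the milk term being the mass-balance debit for the infant's milk dose.
  milk_vol <- milk_rate * bw                                 # L/day
  g <- (1 + k - milk_vol * chem$milk_tf / maternal_vol) * ek
  maternal <- maternal_ss * cumprod(c(1, g[-1]))

  milk_conc <- rep(NA_real_, n_days)
  is_milk <- lactating
  if (scenario$feeding_mode == "breastfed") is_milk[1] <- TRUE
  # start-of-day maternal serum sets the day's milk concentration
  prev_maternal <- c(maternal_ss, maternal[-n_days])
  milk_conc[is_milk] <- breastmilk_concentration(prev_maternal[is_milk],
                                                 chem$milk_tf)
  milk_dose_mg <- ifelse(lactating, milk_vol * milk_conc, 0)  # mg
  water_dose_mg <- water_rate * bw * water_mg_L               # mg
  milk_dose_mg[1] <- water_dose_mg[1] <- 0                    # birth day
  dose <- (milk_dose_mg + water_dose_mg) / bw                 # mg/kg/day

  # infant recurrence C[i] = (C[i-1] + a[i]) e^-k as a linear filter
  a <- (milk_dose_mg + water_dose_mg) / (vd_eff * bw)
  infant <- c(infant0,
              as.numeric(stats::filter(a[-1] * ek, ek, "recursive",
                                       init = infant0)))

  out <- data.frame(
    day = days,
    infant_serum = infant,
    maternal_serum = maternal,
    milk_conc = milk_conc,
    dose_mg_kg = dose,
    milk_dose_mg = milk_dose_mg,
    water_dose_mg = water_dose_mg,
    bw_kg = bw,
    vd_eff = vd_eff
  )
  structure(out,
            class = c("tk_simulation", "data.frame"),
            scenario = scenario,
            library = library,
            water_ug_L = water_ug_L,
            maternal_ss = maternal_ss,
            chem = chem)
}

#' @export
print.tk_simulation <- function(x, ...) {
  sc <- attr(x, "scenario")
  cat(sprintf("<tk_simulation> %s, water = %g ug/L, %d days\n",
              sc$name, attr(x, "water_ug_L"), nrow(x)))
  i <- which.max(x$infant_serum)
  cat(sprintf("  peak infant serum %.6g mg/L on day %d (%.2f years)\n",
              x$infant_serum[i], x$day[i], x$day[i] / DAYS_PER_YEAR))
  cat(sprintf("  terminal infant serum %.6g mg/L\n",
              x$infant_serum[nrow(x)]))
  invisible(x)
}

#' @export
summary.tk_simulation <- function(object, ...) {
  i <- which.max(object$infant_serum)
  out <- list(
    scenario = attr(object, "scenario")$name,
    water_ug_L = attr(object, "water_ug_L"),
    n_days = nrow(object),
    peak_serum_mg_L = object$infant_serum[i],
    peak_day = object$day[i],
    terminal_serum_mg_L = object$infant_serum[nrow(object)],
    maternal_ss_mg_L = attr(object, "maternal_ss")
  )
  class(out) <- "summary.tk_simulation"
  out
}

#' @export
print.summary.tk_simulation <- function(x, ...) {
  cat(sprintf("Scenario: %s at %g ug/L (%d days)\n",
              x$scenario, x$water_ug_L, x$n_days))
  cat(sprintf("Peak infant serum:     %.6g mg/L (day %d)\n",
              x$peak_serum_mg_L, x$peak_day))
  cat(sprintf("Terminal infant serum: %.6g mg/L\n", x$terminal_serum_mg_L))
  cat(sprintf("Maternal steady state: %.6g mg/L\n", x$maternal_ss_mg_L))
  invisible(x)
}

#' @export
plot.tk_simulation <- function(x, y, ...) {
  yrs <- x$day / DAYS_PER_YEAR
  plot(yrs, x$infant_serum, type = "l", xlab = "Age (years)",
       ylab = "Serum concentration (mg/L)",
       main = attr(x, "scenario")$name, ...)
  graphics::lines(yrs, x$maternal_serum, lty = 2)
  graphics::legend("topright", c("offspring", "mother"), lty = c(1, 2),
                   bty = "n")
  invisible(x)
}
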
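# Independent spreadsheet-style re-implementation of the coupled
# mother-infant lactation kinetics, written row by row straight from the
# published equations and parameter table. Used only as a cross-check
# oracle for the package's simulator; shares no code with it.

oracle_lerp <- function(ages, values) {
  function(a) {
    n <- length(ages)
    if (a <= ages[1]) return(values[1])
    if (a >= ages[n]) return(values[n])
    j <- findInterval(a, ages)
    values[j] + (values[j + 1] - values[j]) * (a - ages[j]) /
      (ages[j + 1] - ages[j])
  }
}

# midpoints of the published age groups, in days (30.4375-day month)
.o_milk_mid <- c(15.21875, 60.875, 136.96875, 273.9375)
oracle_tables <- list(
  milk_rate = list(
    central = oracle_lerp(.o_milk_mid, c(150, 140, 110, 83)),
    upper   = oracle_lerp(.o_milk_mid, c(220, 190, 150, 130))
  ),
  milk_bw = list(
    central = oracle_lerp(c(0, .o_milk_mid), c(3.38, 3.4, 4.9, 7.0, 7.5)),
    upper   = oracle_lerp(c(0, .o_milk_mid), c(3.38, 4.3, 5.2, 6.7, 7.7))
  ),
  vd_af = oracle_lerp(
    c(0.5, 15.5, 60.875, 136.96875, 273.9375, 730.5, 1461, 2739.375, 3652.5),
    c(2.4, 2.1, 1.7, 1.6, 1.5, 1.4, 1.1, 1.2, 1.0)
  )
)

# exclusive breastfeeding, no direct water exposure; day 0 is birth
oracle_lactation <- function(maternal_ug_L, tier = "upper", n_days,
                             birth_ug_L = NULL, half_life = 840, vd = 0.17,
                             placental_tf = 0.87, milk_tf = 0.052,
                             maternal_bw = if (tier == "upper") 73.6
                                           else 76.7) {
  k <- log(2) / half_life
  rate_f <- oracle_tables$milk_rate[[tier]]
  bw_f <- oracle_tables$milk_bw[[tier]]
  m_serum <- maternal_ug_L * 1e-3
  i_serum <- if (is.null(birth_ug_L)) m_serum * placental_tf
             else birth_ug_L * 1e-3
  out <- data.frame(day = 0:(n_days - 1), infant = NA_real_,
                    maternal = NA_real_, milk = NA_real_)
  out$infant[1] <- i_serum
  out$maternal[1] <- m_serum
  out$milk[1] <- m_serum * milk_tf
  for (r in 2:n_days) {
    d <- r - 1
    milk_c <- m_serum * milk_tf                       # start-of-day serum
    mass <- rate_f(d) * 1e-3 * bw_f(d) * milk_c       # mg into the infant
    i_serum <- (i_serum + mass / (vd * oracle_tables$vd_af(d) * bw_f(d))) *
      exp(-k)
    intake_m <- m_serum * (vd * k) * maternal_bw      # ongoing maternal dose
    m_serum <- (m_serum + (intake_m - mass) / (vd * maternal_bw)) * exp(-k)
    out$infant[r] <- i_serum
    out$maternal[r] <- m_serum
    out$milk[r] <- milk_c
  }
  out
}

# parameter library with flat schedules: isolates the pure one-compartment
# kinetics from the age structure
constant_library <- function(water_mL_kg = 42, bw_kg = 70) {
  lib <- default_parameter_library()
  for (t in c("central", "upper")) {
    lib$water_intake[[t]] <- age_schedule(0, water_mL_kg, "const water")
    lib$water_bw[[t]] <- age_schedule(0, bw_kg, "const bw")
    lib$milk_intake[[t]] <- age_schedule(0, 0, "no milk")
    lib$milk_bw[[t]] <- age_schedule(0, bw_kg, "const bw")
  }
  lib$vd_af <- age_schedule(0, 1, "unit AF")
  lib
}
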
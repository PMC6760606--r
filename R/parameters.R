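# Default chemical and exposure parameter library for PFOA.
#
# All values are the Minnesota Department of Health 2017 PFOA parameter set:
# central-tendency (mean) and upper-percentile (~95th) variants for the
# chemical constants and the age-group intake/body-weight schedules. Anchor
# ages are placed at the arithmetic midpoint of each published age group,
# converted to days with a 30.4375-day month; the open-ended last group is
# anchored at its lower bound with constant extrapolation beyond it.

#' Chemical-specific toxicokinetic parameters
#'
#' @param half_life Elimination half-life in days.
#' @param vd Volume of distribution in L/kg (extracellular-fluid scale).
#' @param placental_tf Placental transfer factor: infant:maternal serum
#'   concentration ratio at birth (dimensionless).
#' @param milk_tf Breastmilk transfer factor: milk:maternal serum
#'   concentration ratio (dimensionless).
#' @return An object of class `chemical_params` with the four fields plus
#'   the derived elimination constant `k` (1/day) and `clearance` (L/kg/day).
#' @examples
#' chemical_params(840, 0.17, 0.87, 0.052)$clearance # ~0.00014
#' @export
chemical_params <- function(half_life, vd, placental_tf, milk_tf) {
  if (half_life <= 0 || vd <= 0) stop("half_life and vd must be positive")
  if (placental_tf < 0 || milk_tf < 0 || !is.finite(placental_tf) ||
      !is.finite(milk_tf)) {
    stop("transfer factors must be finite and non-negative")
  }
  structure(
    list(half_life = half_life, vd = vd,
         placental_tf = placental_tf, milk_tf = milk_tf,
         k = elimination_constant(half_life),
         clearance = clearance_rate(vd, half_life)),
    class = "chemical_params"
  )
}

#' @export
print.chemical_params <- function(x, ...) {
  cat(sprintf(
    paste0("<chemical_params> t1/2 = %g d, Vd = %g L/kg, ",
           "placental TF = %g, milk TF = %g\n  k = %.5g /day, ",
           "clearance = %.5g L/kg/day\n"),
    x$half_life, x$vd, x$placental_tf, x$milk_tf, x$k, x$clearance))
  invisible(x)
}

# -- Table of age-group schedules ---------------------------------------

mo <- function(x) x * DAYS_PER_MONTH
yr <- function(x) x * DAYS_PER_YEAR

# Breastmilk intake age groups (months): [0,1), [1,3), [3,6), [6,12)
.milk_group_mid <- c(
  age_group_midpoint(0, mo(1)),
  age_group_midpoint(mo(1), mo(3)),
  age_group_midpoint(mo(3), mo(6)),
  age_group_midpoint(mo(6), mo(12))
)

# Water intake age groups: four infant month groups, then year groups
# [1,2), [2,3), [3,6), [6,11), [11,16), [16,18), [18,21), >21 (anchored at 21).
.water_group_mid <- c(
  .milk_group_mid,
  age_group_midpoint(yr(1), yr(2)),
  age_group_midpoint(yr(2), yr(3)),
  age_group_midpoint(yr(3), yr(6)),
  age_group_midpoint(yr(6), yr(11)),
  age_group_midpoint(yr(11), yr(16)),
  age_group_midpoint(yr(16), yr(18)),
  age_group_midpoint(yr(18), yr(21)),
  yr(21)
)

# Vd adjustment-factor groups: 0-1 day, 1-30 days, then month/year groups,
# >10 years anchored at 10 years.
.vdaf_group_mid <- c(
  0.5, (1 + 30) / 2,
  age_group_midpoint(mo(1), mo(3)),
  age_group_midpoint(mo(3), mo(6)),
  age_group_midpoint(mo(6), mo(12)),
  age_group_midpoint(yr(1), yr(3)),
  age_group_midpoint(yr(3), yr(5)),
  age_group_midpoint(yr(5), yr(10)),
  yr(10)
)

#' Default PFOA parameter library
#'
#' Assembles the full central/upper parameter set: chemical constants,
#' breastmilk- and water-intake schedules with their body-weight series, the
#' volume-of-distribution age-adjustment schedule, breastfeeding-duration
#' variants, and the maternal time-weighted-average water intake rates used
#' to set the maternal steady state (18 and 47 mL/kg/day for the central and
#' upper tiers). The milk-based body-weight series starts at the 3.38 kg
#' mean singleton birth weight for both tiers.
#'
#' @return An object of class `parameter_library`: a named list with
#'   components `half_life`, `placental_tf`, `milk_tf` (named central/upper
#'   numeric pairs), `vd` (single value, 0.17 L/kg), `vd_af`
#'   ([age_schedule()]), `milk_intake`, `milk_bw`, `water_intake`,
#'   `water_bw` (lists of central/upper [age_schedule()]s),
#'   `maternal_twa_intake` and `maternal_bw` (central/upper pairs, the
#'   latter the adult >21 y body weights of the water table).
#' @examples
#' lib <- default_parameter_library()
#' lib$milk_tf[["central"]]                      # 0.052
#' interpolate(lib$milk_intake$upper, 0)         # 220 mL/kg/day at birth
#' @export
default_parameter_library <- function() {
  sched <- function(ages, values, name, units) {
    age_schedule(ages, values, name, units)
  }
  structure(list(
    half_life    = c(central = 840, upper = 1679),
    placental_tf = c(central = 0.87, upper = 1.69),
    milk_tf      = c(central = 0.052, upper = 0.12),
    vd           = 0.17,
    vd_af = sched(.vdaf_group_mid,
                  c(2.4, 2.1, 1.7, 1.6, 1.5, 1.4, 1.1, 1.2, 1.0),
                  "Vd age adjustment factor", "unitless"),
    milk_intake = list(
      central = sched(.milk_group_mid, c(150, 140, 110, 83),
                      "breastmilk intake (mean)", "mL/kg/day"),
      upper = sched(.milk_group_mid, c(220, 190, 150, 130),
                    "breastmilk intake (upper)", "mL/kg/day")
    ),
    milk_bw = list(
      central = sched(c(0, .milk_group_mid), c(3.38, 3.4, 4.9, 7.0, 7.5),
                      "body weight, milk-based (mean)", "kg"),
      upper = sched(c(0, .milk_group_mid), c(3.38, 4.3, 5.2, 6.7, 7.7),
                    "body weight, milk-based (upper)", "kg")
    ),
    water_intake = list(
      central = sched(.water_group_mid,
                      c(137, 119, 80, 53, 27, 26, 21, 17, 12, 10, 11, 16),
                      "water intake (mean)", "mL/kg/day"),
      upper = sched(.water_group_mid,
                    c(238, 285, 173, 129, 75, 62, 52, 47, 35, 30, 36, 42),
                    "water intake (upper)", "mL/kg/day")
    ),
    water_bw = list(
      central = sched(.water_group_mid,
                      c(3.4, 4.6, 7.0, 8.8, 11.4, 13.7, 18.2, 30.1,
                        53.1, 70.2, 74.2, 76.7),
                      "body weight, water-based (mean)", "kg"),
      upper = sched(.water_group_mid,
                    c(3.6, 3.7, 6.8, 8.9, 11.9, 14.7, 19.2, 29.9,
                      56.5, 62.8, 78.3, 73.6),
                    "body weight, water-based (upper)", "kg")
    ),
    maternal_twa_intake = c(central = 18, upper = 47),
    maternal_bw = c(central = 76.7, upper = 73.6)
  ), class = "parameter_library")
}

#' @export
print.parameter_library <- function(x, ...) {
  cat("<parameter_library> PFOA defaults\n")
  cat(sprintf("  half-life: %g / %g days (central/upper)\n",
              x$half_life[["central"]], x$half_life[["upper"]]))
  cat(sprintf("  placental TF: %g / %g; milk TF: %g / %g\n",
              x$placental_tf[["central"]], x$placental_tf[["upper"]],
              x$milk_tf[["central"]], x$milk_tf[["upper"]]))
  cat(sprintf("  Vd: %g L/kg; maternal TWA intake: %g / %g mL/kg/day\n",
              x$vd, x$maternal_twa_intake[["central"]],
              x$maternal_twa_intake[["upper"]]))
  cat("  schedules: vd_af, milk_intake, milk_bw, water_intake, water_bw\n")
  invisible(x)
}

# -- Serialization -------------------------------------------------------

sched_to_list <- function(s) {
  list(name = s$name, units = s$units, ages = s$ages, values = s$values)
}
sched_from_list <- function(l) {
  age_schedule(l$ages, l$values, l$name, l$units)
}

#' Write or read a parameter library as YAML
#'
#' The on-disk form is a nested key-value document carrying every numeric in
#' the library, so users can dump the defaults, edit values, and load the
#' result back. Round-trips are exact (numbers written at full precision).
#'
#' @param lib A [default_parameter_library()]-shaped `parameter_library`.
#' @param path File path.
#' @return `write_parameter_library` returns `path` invisibly;
#'   `read_parameter_library` returns a `parameter_library`.
#' @export
write_parameter_library <- function(lib, path) {
  stopifnot(inherits(lib, "parameter_library"))
  out <- list(
    half_life = as.list(lib$half_life),
    placental_tf = as.list(lib$placental_tf),
    milk_tf = as.list(lib$milk_tf),
    vd = lib$vd,
    vd_af = sched_to_list(lib$vd_af),
    milk_intake = lapply(lib$milk_intake, sched_to_list),
    milk_bw = lapply(lib$milk_bw, sched_to_list),
    water_intake = lapply(lib$water_intake, sched_to_list),
    water_bw = lapply(lib$water_bw, sched_to_list),
    maternal_twa_intake = as.list(lib$maternal_twa_intake),
    maternal_bw = as.list(lib$maternal_bw)
  )
  yaml::write_yaml(out, path, precision = 15L)
  invisible(path)
}

#' @rdname write_parameter_library
#' @export
read_parameter_library <- function(path) {
  raw <- yaml::read_yaml(path)
  pair <- function(l) c(central = l$central, upper = l$upper)
  structure(list(
    half_life = pair(raw$half_life),
    placental_tf = pair(raw$placental_tf),
    milk_tf = pair(raw$milk_tf),
    vd = raw$vd,
    vd_af = sched_from_list(raw$vd_af),
    milk_intake = lapply(raw$milk_intake, sched_from_list),
    milk_bw = lapply(raw$milk_bw, sched_from_list),
    water_intake = lapply(raw$water_intake, sched_from_list),
    water_bw = lapply(raw$water_bw, sched_from_list),
    maternal_twa_intake = pair(raw$maternal_twa_intake),
    maternal_bw = pair(raw$maternal_bw)
  ), class = "parameter_library")
}
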
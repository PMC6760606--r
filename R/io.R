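# Output serialization for simulation results.

#' Write a simulation to a daily table and a JSON summary
#'
#' The table is comma-separated with one row per day (age_days,
#' infant_serum_mg_L, maternal_serum_mg_L, milk_conc_mg_L, dose_mg_kg_d,
#' bw_kg); the summary JSON carries the scenario name, water concentration,
#' peak serum and its day, and the terminal serum.
#'
#' @param result A `tk_simulation`.
#' @param table_path Path for the daily CSV (`NULL` to skip).
#' @param summary_path Path for the JSON summary (`NULL` to skip).
#' @return The summary list, invisibly.
#' @export
write_simulation <- function(result, table_path = NULL, summary_path = NULL) {
  stopifnot(inherits(result, "tk_simulation"))
  if (!is.null(table_path)) {
    tab <- data.frame(
      age_days = result$day,
      infant_serum_mg_L = result$infant_serum,
      maternal_serum_mg_L = result$maternal_serum,
      milk_conc_mg_L = result$milk_conc,
      dose_mg_kg_d = result$dose_mg_kg,
      bw_kg = result$bw_kg
    )
    utils::write.csv(tab, table_path, row.names = FALSE, quote = FALSE)
  }
  s <- summary(result)
  out <- list(scenario = s$scenario,
              water_ug_L = s$water_ug_L,
              n_days = s$n_days,
              peak_serum_mg_L = s$peak_serum_mg_L,
              peak_day = s$peak_day,
              terminal_serum_mg_L = s$terminal_serum_mg_L,
              maternal_ss_mg_L = s$maternal_ss_mg_L)
  if (!is.null(summary_path)) {
    jsonlite::write_json(out, summary_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(out)
}
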
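# Plain-text I/O for the solution-thermodynamics data: melting curves as
# two-column CSV, ITC series as a CSV with a JSON sidecar holding the
# concentrations and cell volume.

#' Read / write melting-curve CSV files
#'
#' Columns `temperature_C`, `absorbance`.  The strand concentration is not
#' part of the file and must be supplied on reading.
#'
#' @param curve a [melting_curve].
#' @param path file path.
#' @param c0 single-strand concentration (M).
#' @return `read_melting_csv()` returns a [melting_curve]; the writer
#'   returns `path` invisibly.
#' @export
write_melting_csv <- function(curve, path) {
  write.csv(as.data.frame(curve), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_melting_csv
#' @export
read_melting_csv <- function(path, c0) {
  df <- read.csv(path)
  if (!all(c("temperature_C", "absorbance") %in% names(df)))
    stop("melting CSV must have columns temperature_C, absorbance: ", path)
  melting_curve(df$temperature_C, df$absorbance, c0)
}

itc_sidecar_path <- function(path) {
  paste0(tools::file_path_sans_ext(path), ".json")
}

#' Read / write ITC series files
#'
#' The CSV holds `injection_index`, `volume_uL`, `heat_ucal`; a JSON sidecar
#' (same basename, `.json`) holds `cell_conc_M`, `syringe_conc_M`,
#' `cell_volume_L` and `T_C`.
#'
#' @param series an [itc_series].
#' @param path CSV file path.
#' @return `read_itc_csv()` returns an [itc_series]; the writer returns
#'   `path` invisibly.
#' @export
write_itc_csv <- function(series, path) {
  df <- data.frame(injection_index = series$table$injection,
                   volume_uL = series$table$volume_uL,
                   heat_ucal = series$table$heat_ucal)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(cell_conc_M = series$cell_conc,
         syringe_conc_M = series$syringe_conc,
         cell_volume_L = series$cell_volume, T_C = series$T_C),
    itc_sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_itc_csv
#' @export
read_itc_csv <- function(path) {
  df <- read.csv(path)
  need <- c("injection_index", "volume_uL", "heat_ucal")
  if (!all(need %in% names(df)))
    stop("ITC CSV must have columns ", paste(need, collapse = ", "),
         ": ", path)
  side <- itc_sidecar_path(path)
  if (!file.exists(side)) stop("missing ITC sidecar: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  itc_series(df$heat_ucal, df$volume_uL * 1e-6, meta$cell_conc_M,
             meta$syringe_conc_M, meta$cell_volume_L, meta$T_C)
}
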
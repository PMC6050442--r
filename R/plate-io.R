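#' Read and write plate CSV files
#'
#' The package's single on-disk plate format: a UTF-8, comma-separated file
#' with header columns `well_id`, `sample_type`, `nominal_conc`,
#' `dilution_factor`, `od` (an `effective_conc` column is accepted and
#' otherwise recomputed). Concentrations are in ug/L, ODs dimensionless.
#' `sample_type` is one of `standard`, `blank`, `qc`, `unknown`; standards, QC
#' and blanks must carry a nominal concentration (0 for blanks), unknowns must
#' not. Validation failures name the offending row.
#'
#' @param path File path.
#' @param plate A plate tibble (as from [simulate_plate()] or
#'   [read_plate_csv()]).
#' @return `read_plate_csv()` returns a validated plate tibble with an
#'   `effective_conc` column; `write_plate_csv()` returns `plate` invisibly.
#' @export
read_plate_csv <- function(path) {
  if (!file.exists(path)) {
    stop_elisacal(sprintf("plate file not found: %s", path), "elisacal_io_error")
  }
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (nrow(df) == 0) stop_elisacal("no wells: plate file is empty", "elisacal_validation_error")
  required <- c("well_id", "sample_type", "nominal_conc", "dilution_factor", "od")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_elisacal(paste0("missing column(s): ", paste(missing, collapse = ", ")),
                  "elisacal_validation_error")
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(!is.na(df[[col]]) & df[[col]] != "NA" & is.na(v))
    if (length(bad) > 0) {
      stop_elisacal(sprintf("non-numeric %s at row %d: '%s'", col, bad[1], df[[col]][bad[1]]),
                    "elisacal_validation_error")
    }
    v
  }
  plate <- tibble::tibble(
    well_id = df$well_id,
    sample_type = df$sample_type,
    nominal_conc = num("nominal_conc"),
    dilution_factor = num("dilution_factor"),
    od = num("od")
  )
  validate_plate(plate) |>
    dplyr::mutate(effective_conc = .data$nominal_conc / .data$dilution_factor)
}

#' @rdname read_plate_csv
#' @export
write_plate_csv <- function(plate, path) {
  cols <- intersect(c("well_id", "sample_type", "nominal_conc",
                      "dilution_factor", "effective_conc", "od"), names(plate))
  readr::write_csv(plate[cols], path)
  invisible(plate)
}

validate_plate <- function(plate) {
  row_fail <- function(cond, what) {
    cond[is.na(cond)] <- FALSE
    if (any(cond)) {
      stop_elisacal(sprintf("%s at row %d", what, which(cond)[1]),
                    "elisacal_validation_error")
    }
  }
  types <- c("standard", "blank", "qc", "unknown")
  row_fail(!plate$sample_type %in% types,
           paste0("unknown sample_type (expected ", paste(types, collapse = "/"), ")"))
  row_fail(duplicated(plate$well_id), "duplicate well_id")
  row_fail(is.na(plate$od), "missing od")
  row_fail(plate$od <= -0.1, "implausible od (<= -0.1)")
  row_fail(is.na(plate$dilution_factor) | plate$dilution_factor < 1,
           "dilution_factor missing or < 1")
  known <- plate$sample_type != "unknown"
  row_fail(known & is.na(plate$nominal_conc),
           "standard/qc/blank well without nominal_conc")
  row_fail(known & !is.na(plate$nominal_conc) & plate$nominal_conc < 0,
           "negative nominal_conc")
  row_fail(plate$sample_type == "blank" & plate$nominal_conc != 0,
           "blank well with nonzero nominal_conc")
  row_fail(!known & !is.na(plate$nominal_conc),
           "unknown well must not carry a nominal_conc")
  plate
}
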
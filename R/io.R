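#' @name csv-dialects
#' @title CSV dialects
#' @description All tables are long-format CSV with a header row; days are
#'   float days since inoculation, concentrations mM, moles mol. Column
#'   schemas: scans `(bottle, day, elapsed_s, mz, signal)`; events
#'   `(bottle, day, liquid_mL, gas_mL)`; calibration
#'   `(analyte, mz, slope, intercept)`; iron samples
#'   `(bottle, day, fe2_raw_mM, fetot_raw_mM, aqueous_mM, dilution)`;
#'   acetate `(bottle, day, acetate_mM)`.
#' @keywords internal
NULL

.schemas <- list(
  scans = c("bottle", "day", "elapsed_s", "mz", "signal"),
  events = c("bottle", "day", "liquid_mL", "gas_mL"),
  calibration = c("analyte", "mz", "slope", "intercept"),
  fe = c("bottle", "day", "fe2_raw_mM", "fetot_raw_mM", "aqueous_mM",
         "dilution"),
  acetate = c("bottle", "day", "acetate_mM")
)

#' Read one of the package's CSV dialects with schema validation
#'
#' @param path CSV file.
#' @param schema one of `"scans"`, `"events"`, `"calibration"`, `"fe"`,
#'   `"acetate"`.
#' @return data.frame with exactly the schema's columns.
#' @export
read_table_csv <- function(path, schema = names(.schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  want <- .schemas[[schema]]
  missing <- setdiff(want, names(df))
  if (length(missing)) {
    stop(sprintf("%s: schema '%s' requires column(s) %s", path, schema,
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(df), want)
  if (length(extra)) {
    stop(sprintf("%s: unknown column(s) %s for schema '%s'", path,
                 paste(extra, collapse = ", "), schema), call. = FALSE)
  }
  num_cols <- setdiff(want, c("bottle", "analyte"))
  for (cn in num_cols) {
    if (!is.numeric(df[[cn]])) {
      stop(sprintf("%s: column '%s' must be numeric", path, cn),
           call. = FALSE)
    }
  }
  df
}

#' Read a calibration CSV into calibration curves
#'
#' @param path calibration CSV (`analyte, mz, slope, intercept`), one row
#'   per analyte (CH4, CO2).
#' @return list with `CH4` and `CO2` [calibration_curve()]s.
#' @export
read_calibration_csv <- function(path) {
  df <- read_table_csv(path, "calibration")
  get <- function(an) {
    row <- df[df$analyte == an, ]
    if (nrow(row) != 1L) {
      stop("calibration must have exactly one row for ", an, call. = FALSE)
    }
    calibration_curve(an, slope = row$slope, intercept = row$intercept,
                      mz = row$mz)
  }
  list(CH4 = get("CH4"), CO2 = get("CO2"))
}

#' Write a table as CSV with fixed numeric formatting
#'
#' Numeric columns are rendered with `%.10g` so that re-running a pipeline
#' on identical inputs yields byte-identical output files.
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) out[[cn]] <- sprintf("%.10g", out[[cn]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a table as TSV with fixed numeric formatting
#' @inheritParams write_table_csv
#' @export
write_table_tsv <- function(df, path) {
  out <- df
  for (cn in names(out)) {
    if (is.numeric(out[[cn]])) out[[cn]] <- sprintf("%.10g", out[[cn]])
  }
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

.config_keys <- list(
  top = c("seed", "paths", "conditions", "pipeline", "thermo"),
  paths = c("scans", "events", "calibration", "fe", "out_dir"),
  pipeline = c("n_last", "pressure_atm", "temperature_K", "initial_mL",
               "nominal_gas_mL", "include_current_removal", "tol_frac"),
  thermo = c("pH", "acetate", "activities", "temperature_K")
)

#' Read and validate a run configuration (JSON)
#'
#' Structured key-value config with nested maps. Unknown keys are rejected
#' so typos fail loudly rather than silently falling back to defaults.
#'
#' @param path JSON file.
#' @return Validated nested list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  check <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stop(sprintf("config %s: unknown key(s) %s", where,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  check(cfg, .config_keys$top, "top level")
  if (!is.null(cfg$paths)) check(cfg$paths, .config_keys$paths, "paths")
  if (!is.null(cfg$pipeline)) check(cfg$pipeline, .config_keys$pipeline,
                                    "pipeline")
  if (!is.null(cfg$thermo)) check(cfg$thermo, .config_keys$thermo, "thermo")
  cfg
}
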
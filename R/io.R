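# Delimited-text input of vessel-day measurement records and output of
# result tables. One row per (vessel, day); analytes in wide columns;
# empty cells are genuinely missing values, distinct from measured zeros.

# accepted column-name aliases (case-insensitive) -> canonical names
.column_aliases <- c(
  vessel = "vessel", vessel_id = "vessel", fermenter = "vessel",
  treatment = "treatment", trt = "treatment", diet = "treatment",
  day = "day", study_day = "day",
  vfa_total = "vfa_total", total_vfa = "vfa_total", tvfa = "vfa_total",
  formate = "formate", acetate = "acetate", propionate = "propionate",
  butyrate = "butyrate", isobutyrate = "isobutyrate",
  valerate = "valerate", isovalerate = "isovalerate",
  caproate = "caproate", heptanoate = "heptanoate",
  ethanol = "ethanol", n_propanol = "n_propanol", propanol = "n_propanol",
  ammonium = "ammonium", nh4 = "ammonium",
  nitrate = "nitrate", no3 = "nitrate",
  nitrite = "nitrite", no2 = "nitrite",
  gas_total = "gas_total", total_gas = "gas_total",
  ch4_pct = "ch4_pct", methane_pct = "ch4_pct",
  h2_pct = "h2_pct", hydrogen_pct = "h2_pct",
  co2_pct = "co2_pct", n2o_pct = "n2o_pct",
  dh2 = "dh2", dissolved_h2 = "dh2", dh2_um = "dh2",
  substrate_in = "substrate_in", residue = "residue",
  microbial_n = "microbial_n", om_fermented = "om_fermented"
)

.profile_cols <- c(
  "formate", "acetate", "propionate", "butyrate", "isobutyrate",
  "valerate", "isovalerate", "caproate", "heptanoate"
)

# the mol/100 mol composition is closed over the eight acids from acetate
# to heptanoate; formate is expressed on the same mol/100 mol scale but
# rides on top of the 100-sum
.profile_sum_cols <- setdiff(.profile_cols, "formate")

.nonneg_cols <- c(
  "vfa_total", .profile_cols, "ethanol", "n_propanol", "ammonium",
  "nitrate", "nitrite", "gas_total", "dh2", "substrate_in", "residue",
  "microbial_n", "om_fermented"
)

.pct_cols <- c("ch4_pct", "h2_pct", "co2_pct", "n2o_pct")

#' Read vessel-day measurement records from a delimited text file
#'
#' Reads a CSV of per-vessel, per-day measurements into the record layout
#' the pipeline consumes. Column names are matched case-insensitively
#' against a documented alias table (e.g. `total_VFA` -> `vfa_total`,
#' `propanol` -> `n_propanol`); unknown columns are kept and reported.
#' Empty cells become `NA` (explicitly missing), never zero.
#'
#' Validation: `vessel`, `treatment` and `day` are mandatory;
#' concentrations, volumes and masses must be non-negative; gas
#' percentages must lie in \[0, 100\]; when the full eight-acid VFA
#' composition (acetate through heptanoate) is present its shares must sum
#' to 100 +/- 0.5 (formate is on the same mol/100 mol scale but outside
#' the closed sum).
#'
#' @param path File path.
#' @param delim Field delimiter (default `","`).
#' @return A tibble of validated records, one row per vessel-day.
#' @export
read_records <- function(path, delim = ",") {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_delim(path,
    delim = delim, show_col_types = FALSE,
    na = c("", "NA"), trim_ws = TRUE
  )
  validate_records(.rename_record_columns(raw))
}

.rename_record_columns <- function(raw) {
  lc <- tolower(names(raw))
  known <- lc %in% names(.column_aliases)
  if (any(!known)) {
    inform(paste0(
      "Unknown columns kept as-is: ",
      paste(names(raw)[!known], collapse = ", ")
    ))
  }
  names(raw)[known] <- unname(.column_aliases[lc[known]])
  raw
}

#' Validate a tibble of vessel-day records
#'
#' Applies the record invariants (see [read_records()]) to an in-memory
#' tibble; errors name the offending row and field.
#'
#' @param records A tibble of records.
#' @return The validated tibble, invisibly unchanged.
#' @export
validate_records <- function(records) {
  missing_cols <- setdiff(c("vessel", "treatment", "day"), names(records))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "Missing mandatory column(s): ", paste(missing_cols, collapse = ", ")
    ))
  }
  for (col in intersect(.nonneg_cols, names(records))) {
    bad <- which(records[[col]] < 0)
    if (length(bad) > 0) {
      abort(paste0(
        "Negative value in column '", col, "' at row ", bad[1],
        " (", records[[col]][bad[1]], ")"
      ))
    }
  }
  for (col in intersect(.pct_cols, names(records))) {
    bad <- which(records[[col]] < 0 | records[[col]] > 100)
    if (length(bad) > 0) {
      abort(paste0(
        "Gas fraction out of [0, 100] in column '", col, "' at row ",
        bad[1], " (", records[[col]][bad[1]], ")"
      ))
    }
  }
  if (all(.profile_sum_cols %in% names(records))) {
    sums <- rowSums(records[.profile_sum_cols])
    bad <- which(!is.na(sums) & abs(sums - 100) > 0.5)
    if (length(bad) > 0) {
      abort(paste0(
        "VFA profile at row ", bad[1], " sums to ",
        round(sums[bad[1]], 2), " (must be 100 +/- 0.5)"
      ))
    }
  }
  invisible(records)
}

#' Write result tables to delimited text plus a structured sidecar
#'
#' Writes each table to `<name>.csv` under `dir` and mirrors all content
#' into `results.yaml` so downstream tools can consume either form. Values
#' round-trip through [readr::read_csv()] without loss at double precision.
#'
#' @param tables A named list of data frames.
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, dir) {
  stopifnot(is.list(tables), length(names(tables)) == length(tables))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    readr::write_csv(tibble::as_tibble(tables[[nm]]), p)
    paths <- c(paths, p)
  }
  yml <- file.path(dir, "results.yaml")
  yaml::write_yaml(
    purrr::map(tables, ~ as.list(tibble::as_tibble(.x))), yml
  )
  invisible(c(paths, yml))
}
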
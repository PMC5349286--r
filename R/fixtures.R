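# Printed treatment means of the source study's report tables. These are
# read-only reference values: they seed worked examples, the synthetic
# generator's default treatment profiles, and cross-checks of the ledger.

.fixture_env <- new.env(parent = emptyenv())

# One row per (item, treatment); `sem` is the printed pooled SEM (n = 4
# vessels), repeated across treatments of the same row.
.build_fixtures <- function() {
  row <- function(table, item, con, nit, nop, aq, sem = NA_real_) {
    tibble::tibble(
      table = table, item = item,
      treatment = c("CON", "NIT", "NOP", "AQ"),
      value = c(con, nit, nop, aq), sem = sem
    )
  }
  dplyr::bind_rows(
    # substrate ingredient and chemical composition (% DM)
    row("T1", "corn_silage", 60.0, 60.0, 60.0, 60.0),
    row("T1", "barley_grain", 28.0, 28.0, 28.0, 28.0),
    row("T1", "urea", 4.26, 0, 4.26, 4.26),
    row("T1", "calcium_carbonate", 4.50, 0, 4.50, 4.50),
    row("T1", "calcium_ammonium_nitrate", 0, 10.7, 0, 0),
    row("T1", "nop_active", 0, 0, 0.05, 0),
    row("T1", "nop_carrier", 0.38, 0.38, 0.38, 0.38),
    row("T1", "dicalcium_phosphate", 2.86, 0.92, 2.81, 2.86),
    row("T1", "om", 89.2, 92.3, 89.7, 93.1),
    row("T1", "cp", 17.9, 18.8, 23.6, 23.6),
    row("T1", "npn", 2.00, 2.00, 2.00, 2.00),
    row("T1", "ndf", 39.7, 35.1, 36.5, 39.7),
    row("T1", "adf", 20.3, 17.1, 17.6, 19.8),
    # gas production and substrate disappearance
    row("T3", "gas_total", 0.74, 0.54, 0.63, 0.76, 0.066),
    row("T3", "ghg_co2eq", 1.00, 0.16, 0.34, 0.83, 0.122),
    row("T3", "ch4_pct", 17.1, 3.6, 5.0, 12.6, 0.84),
    row("T3", "h2_pct", 2.0, 1.0, 10.3, 6.6, 0.99),
    row("T3", "co2_pct", 80.9, 95.4, 84.7, 80.9, 1.19),
    row("T3", "n2o_pct", 0.00, 0.04, 0.00, 0.00, 0.006),
    row("T3", "dh2", 40.8, 28.7, 53.7, 9.7, 3.79),
    row("T3", "dm_disappearance", 47.9, 43.3, 46.6, 45.7, 2.07),
    row("T3", "om_disappearance", 47.9, 45.2, 48.1, 46.6, 1.97),
    row("T3", "cp_disappearance", 77.4, 69.5, 78.6, 75.4, 1.97),
    # fermentation variables; VFA profile in mol/100 mol
    row("T4", "ph", 6.92, 6.95, 6.97, 6.96, 0.016),
    row("T4", "vfa_total", 65.5, 50.9, 59.7, 63.8, 4.02),
    row("T4", "formate", 5.76, 5.52, 7.21, 5.68, 0.664),
    row("T4", "acetate", 52.1, 68.1, 44.7, 46.5, 0.82),
    row("T4", "propionate", 12.6, 11.3, 13.8, 11.3, 0.69),
    row("T4", "butyrate", 15.3, 13.5, 17.4, 16.3, 0.47),
    row("T4", "isobutyrate", 0.56, 0.30, 0.53, 0.47, 0.022),
    row("T4", "valerate", 5.56, 4.05, 8.26, 5.92, 0.187),
    row("T4", "isovalerate", 7.61, 0.84, 6.03, 6.83, 0.268),
    row("T4", "caproate", 4.72, 1.43, 6.96, 9.50, 0.671),
    row("T4", "heptanoate", 1.57, 0.48, 2.31, 3.15, 0.222),
    row("T4", "a_to_p", 4.16, 6.36, 3.28, 4.18, 0.391),
    row("T4", "ab_to_p", 5.38, 7.57, 4.54, 5.64, 0.431),
    row("T4", "ethanol", 5.89, 9.92, 7.68, 4.25, 0.600),
    row("T4", "n_propanol", 0.19, 0.16, 0.41, 0.16, 0.044),
    row("T4", "ammonium", 14.1, 11.3, 19.2, 19.6, 0.54),
    row("T4", "nitrate", 0.00, 0.27, 0.00, 0.00, 0.053),
    row("T4", "nitrite", 0.00, 0.03, 0.00, 0.00, 0.008),
    # microbial protein synthesis
    row("T5", "microbial_n", 59.8, 69.7, 54.2, 51.7, 2.68),
    row("T5", "microbial_n_sa", 33.6, 36.6, 33.8, 30.4, 1.64),
    row("T5", "microbial_n_wa", 5.6, 4.8, 4.9, 4.4, 0.58),
    row("T5", "microbial_n_lq", 22.4, 28.8, 15.6, 16.9, 2.42),
    row("T5", "emps", 15.9, 18.5, 14.1, 13.3, 0.91),
    # [2H] balance (production/consumption in mmol/d, balance in mmol/d and %)
    row("T7", "prod_acetate", 42.7, 43.1, 33.4, 37.2, 2.53),
    row("T7", "prod_butyrate", 12.5, 8.7, 13.1, 13.1, 1.08),
    row("T7", "prod_caproate_sc1", 0, 0, 0, 0, 0),
    row("T7", "prod_caproate_sc2", 3.88, 0.92, 5.01, 7.51, 0.302),
    row("T7", "prod_total_sc1", 55.2, 51.8, 46.5, 50.3, 3.54),
    row("T7", "prod_total_sc2", 59.1, 52.7, 51.5, 57.9, 3.41),
    row("T7", "cons_formate", 2.33, 1.65, 2.58, 2.25, 0.157),
    row("T7", "cons_propionate", 5.17, 3.71, 5.25, 4.53, 0.549),
    row("T7", "cons_valerate", 2.28, 1.33, 3.09, 2.35, 0.193),
    row("T7", "cons_caproate_sc1", 7.75, 1.83, 10.02, 15.02, 0.605),
    row("T7", "cons_caproate_sc2", 0, 0, 0, 0, 0),
    row("T7", "cons_heptanoate", 1.29, 0.30, 1.66, 2.49, 0.100),
    row("T7", "cons_methane", 4.54, 0.24, 1.00, 3.79, 0.562),
    row("T7", "cons_hydrogen", 0.16, 0.03, 0.46, 0.65, 0.096),
    row("T7", "cons_total_sc1", 23.5, NA, 24.0, 30.8, 1.08),
    row("T7", "cons_total_sc2", 15.8, NA, 13.7, 16.0, 0.89),
    row("T7", "balance_sc1", 31.7, NA, 21.4, 19.9, 2.50),
    row("T7", "balance_sc2", 43.3, NA, 36.2, 42.1, 1.71),
    row("T7", "recovery_sc1", 42.4, NA, 54.3, 61.2, 2.99),
    row("T7", "recovery_sc2", 26.6, NA, 27.7, 27.5, 1.14)
  )
}

.fixtures <- function() {
  if (is.null(.fixture_env$tables)) .fixture_env$tables <- .build_fixtures()
  .fixture_env$tables
}

#' Printed treatment means of the study report tables
#'
#' Returns the treatment-mean values as printed in the study's report
#' tables: substrate composition (`"T1"`), gas production and substrate
#' disappearance (`"T3"`), fermentation variables including the VFA molar
#' profile (`"T4"`), microbial protein synthesis (`"T5"`), and the
#' metabolic-hydrogen balance (`"T7"`). Values are stored exactly as
#' printed; a `NA` marks a cell the study left uncomputed (the nitrate
#' treatment's consumption totals, whose nitrate electron sink was not part
#' of the ledger).
#'
#' @param table Table identifier, one of `"T1"`, `"T3"`, `"T4"`, `"T5"`,
#'   `"T7"`. Omit to get all tables.
#' @param layout `"long"` (one row per item × treatment) or `"wide"` (one
#'   row per item, one column per treatment plus `sem`).
#'
#' @return A tibble. Long layout has columns `table`, `item`, `treatment`,
#'   `value`, `sem`; wide layout has `table`, `item`, `CON`, `NIT`, `NOP`,
#'   `AQ`, `sem`.
#'
#' @examples
#' rusitec_fixture("T4", layout = "wide")
#' @export
rusitec_fixture <- function(table = NULL, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  fx <- .fixtures()
  if (!is.null(table)) {
    table <- toupper(table)
    known <- unique(fx$table)
    if (!all(table %in% known)) {
      abort(paste0(
        "Unknown fixture table id: ",
        paste(setdiff(table, known), collapse = ", "),
        ". Known ids: ", paste(known, collapse = ", ")
      ))
    }
    fx <- dplyr::filter(fx, .data$table %in% !!table)
  }
  if (layout == "wide") {
    fx <- tidyr::pivot_wider(fx,
      names_from = "treatment", values_from = "value"
    ) |>
      dplyr::relocate("sem", .after = dplyr::last_col())
  }
  fx
}

#' Look up one printed fixture value
#'
#' @param table Table id (see [rusitec_fixture()]).
#' @param item Row label within the table.
#' @param treatment Treatment column, one of `"CON"`, `"NIT"`, `"NOP"`, `"AQ"`.
#' @return A single numeric value (possibly `NA` for cells the study left
#'   uncomputed).
#' @examples
#' fixture_value("T4", "vfa_total", "CON") # 65.5
#' @export
fixture_value <- function(table, item, treatment) {
  fx <- rusitec_fixture(table)
  hit <- dplyr::filter(fx, .data$item == !!item, .data$treatment == !!treatment)
  if (nrow(hit) == 0) {
    abort(paste0("No fixture cell (", table, ", ", item, ", ", treatment, ")"))
  }
  hit$value
}

#' Assemble pipeline-ready records from the printed treatment means
#'
#' Builds one pseudo-vessel measurement record per treatment from the
#' printed means of the gas, fermentation and microbial tables, in the same
#' layout [read_records()] produces, so the whole pipeline can be exercised
#' on the study's own numbers. Substrate input is the study's 10 g DM bag
#' per day; the residue mass is backed out of the printed DM disappearance.
#'
#' @param treatments Character vector of treatments to include.
#' @return A tibble of vessel-day records (one per treatment, `vessel`
#'   labelled after the treatment, `day` = `NA`).
#' @examples
#' fixture_records()
#' @export
fixture_records <- function(treatments = c("CON", "NIT", "NOP", "AQ")) {
  wide <- rusitec_fixture(layout = "wide") |>
    dplyr::select(-"sem") |>
    tidyr::pivot_longer(c("CON", "NIT", "NOP", "AQ"),
      names_to = "treatment", values_to = "value"
    ) |>
    dplyr::filter(.data$treatment %in% treatments) |>
    dplyr::mutate(key = paste0(.data$table, ".", .data$item)) |>
    dplyr::select("treatment", "key", "value") |>
    tidyr::pivot_wider(names_from = "key", values_from = "value")

  tibble::tibble(
    vessel = paste0("mean_", wide$treatment),
    treatment = factor(wide$treatment, levels = treatments),
    day = NA_integer_,
    vfa_total = wide$T4.vfa_total,
    formate = wide$T4.formate,
    acetate = wide$T4.acetate,
    propionate = wide$T4.propionate,
    butyrate = wide$T4.butyrate,
    isobutyrate = wide$T4.isobutyrate,
    valerate = wide$T4.valerate,
    isovalerate = wide$T4.isovalerate,
    caproate = wide$T4.caproate,
    heptanoate = wide$T4.heptanoate,
    ethanol = wide$T4.ethanol,
    n_propanol = wide$T4.n_propanol,
    ammonium = wide$T4.ammonium,
    nitrate = wide$T4.nitrate,
    nitrite = wide$T4.nitrite,
    gas_total = wide$T3.gas_total,
    ch4_pct = wide$T3.ch4_pct,
    h2_pct = wide$T3.h2_pct,
    co2_pct = wide$T3.co2_pct,
    n2o_pct = wide$T3.n2o_pct,
    dh2 = wide$T3.dh2,
    substrate_in = 10,
    residue = 10 * (1 - wide$T3.dm_disappearance / 100),
    microbial_n = wide$T5.microbial_n
  ) |>
    dplyr::arrange(.data$treatment) |>
    dplyr::mutate(treatment = as.character(.data$treatment))
}

#' Per-gas daily molar fluxes implied by the printed hydrogen ledger
#'
#' The printed gas percentages are expressed on the four-gas sum and do not
#' reconcile with total bag volume, so per-gas molar fluxes cannot be
#' recovered from the gas table alone (see the methods vignette). This
#' helper backs the methane and gaseous dihydrogen fluxes out of the
#' printed ledger's gas entries (methane [2H] entry / 4, hydrogen entry /
#' 1), giving per-gas inputs consistent with the printed balance.
#'
#' @param treatments Character vector of treatments to include.
#' @return A tibble with columns `treatment`, `gas` (`"CH4"`, `"H2"`) and
#'   `mmol_d`.
#' @export
fixture_gas_mmol <- function(treatments = c("CON", "NIT", "NOP", "AQ")) {
  t7 <- rusitec_fixture("T7")
  ch4 <- dplyr::filter(t7, .data$item == "cons_methane")
  h2 <- dplyr::filter(t7, .data$item == "cons_hydrogen")
  dplyr::bind_rows(
    tibble::tibble(treatment = ch4$treatment, gas = "CH4", mmol_d = ch4$value / 4),
    tibble::tibble(treatment = h2$treatment, gas = "H2", mmol_d = h2$value / 1)
  ) |>
    dplyr::filter(.data$treatment %in% treatments)
}
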
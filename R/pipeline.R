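# End-to-end orchestration: records in, flux tables, hydrogen ledgers,
# greenhouse-gas totals and descriptive summaries out.

#' Run the full hydrogen-accounting pipeline on a set of records
#'
#' Validates the records, converts them to daily molar fluxes, scores the
#' ledger under the requested caproate scenarios, aggregates greenhouse
#' gases into CO2 equivalents, and produces descriptive summaries
#' (VFA ratios, substrate disappearance, treatment-level ledger means when
#' several vessels are present).
#'
#' Units whose records show a nonzero nitrate outflow (i.e. an active
#' nitrate electron sink, as in a nitrate-supplemented treatment) have
#' their consumption totals, balance and recovery masked to `NA` unless a
#' `nitrate_sink` value is supplied for their treatment: without the
#' nitrate term the consumed side of their ledger would be materially
#' incomplete. A supplied sink (mmol [2H]/d, e.g. from
#' [nitrate_h2_sink()]) is added to the consumed total before balance and
#' recovery are formed.
#'
#' @inheritParams build_flux_table
#' @param scenario `"SC1"`, `"SC2"` or both (default).
#' @param nitrate_sink Optional named numeric: [2H] sink (mmol/d) per
#'   treatment with an active nitrate pathway.
#' @param gwp GWP weights for the CO2-equivalent total.
#' @param deduct_heptanoate_propionate Passed to [h2_ledger()].
#' @return A list with class `"h2_pipeline"`: `fluxes`, `ledger`,
#'   `totals`, `ghg`, `summaries`, `config`.
#' @examples
#' res <- run_pipeline(fixture_records(), gas_mmol = fixture_gas_mmol())
#' res$totals
#' @export
run_pipeline <- function(records,
                         scenario = c("SC1", "SC2"),
                         constants = physical_constants(),
                         gas_mmol = NULL,
                         nitrate_sink = NULL,
                         gwp = gwp_coefficients(),
                         deduct_heptanoate_propionate = FALSE) {
  scenario <- match.arg(toupper(scenario), c("SC1", "SC2"), several.ok = TRUE)
  if (all(c("vessel", "treatment", "day") %in% names(records))) {
    validate_records(records)
  }

  fluxes <- build_flux_table(records, constants = constants, gas_mmol = gas_mmol)
  ledger <- h2_ledger(fluxes,
    scenario = scenario,
    deduct_heptanoate_propionate = deduct_heptanoate_propionate
  )
  totals <- ledger$totals

  # nitrate-active units: mask incomplete consumption totals or add the
  # supplied sink
  if ("nitrate" %in% names(records) && "treatment" %in% names(records)) {
    nit_trt <- unique(records$treatment[
      !is.na(records$nitrate) & records$nitrate > 0
    ])
    if (length(nit_trt) > 0) {
      supplied <- intersect(nit_trt, names(nitrate_sink %||% character(0)))
      unsupplied <- setdiff(nit_trt, supplied)
      if (length(supplied) > 0) {
        totals <- totals |>
          dplyr::mutate(
            consumed = .data$consumed +
              dplyr::coalesce(unname(nitrate_sink[.data$treatment]), 0),
            balance = .data$produced - .data$consumed,
            recovery = dplyr::if_else(.data$produced > 0,
              100 * .data$consumed / .data$produced, NA_real_
            )
          )
      }
      if (length(unsupplied) > 0) {
        inform(paste0(
          "Nitrate outflow detected for treatment(s) ",
          paste(unsupplied, collapse = ", "),
          " but no `nitrate_sink` supplied; their consumption totals, ",
          "balance and recovery are reported as NA"
        ))
        mask <- totals$treatment %in% unsupplied
        totals$consumed[mask] <- NA_real_
        totals$balance[mask] <- NA_real_
        totals$recovery[mask] <- NA_real_
      }
    }
  }

  key_cols <- intersect(c("vessel", "treatment", "day"), names(records))
  ghg <- NULL
  if (all(c("gas_total", .pct_cols) %in% names(records))) {
    vols <- as.matrix(records[.pct_cols]) / 100 * records$gas_total * 1000
    colnames(vols) <- c("CH4", "H2", "CO2", "N2O")
    ghg <- dplyr::bind_cols(
      records[key_cols],
      tibble::tibble(
        ghg_co2eq_l = apply(vols, 1, function(v) {
          co2_equivalents(v, gwp = gwp)
        }) / 1000
      )
    )
  }

  summaries <- list()
  prof_cols <- intersect(.profile_sum_cols, names(records))
  if (all(c("acetate", "propionate") %in% prof_cols)) {
    summaries$vfa_ratios <- records |>
      dplyr::select(dplyr::all_of(c(key_cols, "acetate", "propionate"))) |>
      dplyr::mutate(
        butyrate = if ("butyrate" %in% names(records)) records$butyrate else 0,
        a_to_p = .data$acetate / .data$propionate,
        ab_to_p = (.data$acetate + .data$butyrate) / .data$propionate
      ) |>
      dplyr::select(dplyr::all_of(key_cols), "a_to_p", "ab_to_p")
  }
  if (all(c("substrate_in", "residue") %in% names(records))) {
    summaries$disappearance <- dplyr::bind_cols(
      records[key_cols],
      tibble::tibble(dm_disappearance = substrate_disappearance(
        records$substrate_in, records$residue
      ))
    )
  }
  if (all(c("microbial_n", "om_fermented") %in% names(records))) {
    summaries$emps <- dplyr::bind_cols(
      records[key_cols],
      tibble::tibble(emps = emps(records$microbial_n, records$om_fermented))
    )
  }
  if (all(c("vessel", "treatment") %in% names(records)) &&
    dplyr::n_distinct(records$vessel) > dplyr::n_distinct(records$treatment)) {
    long_tot <- totals |>
      tidyr::pivot_longer(c("produced", "consumed", "balance", "recovery"),
        names_to = "quantity", values_to = "value"
      )
    summaries$treatment_ledger <- aggregate_by_treatment(
      long_tot, .data$value, .data$scenario, .data$quantity
    )
  }

  structure(
    list(
      fluxes = fluxes, ledger = ledger, totals = totals, ghg = ghg,
      summaries = summaries,
      config = list(
        scenario = scenario, constants = constants,
        gwp = gwp, nitrate_sink = nitrate_sink,
        deduct_heptanoate_propionate = deduct_heptanoate_propionate,
        gas_basis = if (is.null(gas_mmol)) "volume_x_percentage" else "supplied_moles"
      )
    ),
    class = "h2_pipeline"
  )
}

#' @export
print.h2_pipeline <- function(x, ...) {
  cat(
    "<h2_pipeline> scenarios:", paste(x$config$scenario, collapse = ", "),
    "| gas basis:", x$config$gas_basis, "\n\n"
  )
  print(x$totals, ...)
  invisible(x)
}
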
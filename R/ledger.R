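# The hydrogen ledger: daily molar fluxes of fermentation end products are
# scored with the stoichiometric registry to give [2H] produced, consumed,
# balance (produced - consumed) and recovery (100 * consumed / produced)
# per experimental unit and caproate scenario.

.flux_unit_cols <- function(fluxes) {
  setdiff(names(fluxes), c("product", "flux", "in_ledger"))
}

#' Build a single-unit flux table from named daily fluxes
#'
#' Convenience constructor for a long flux table (the layout
#' [build_flux_table()] produces) from named per-product fluxes in mmol/d.
#'
#' @param ... Named fluxes, e.g. `acetate = 21.4, CH4 = 1.13`.
#' @param unit_id Identifier stored in the `unit` column.
#' @return A tibble with columns `unit`, `product`, `flux`, `in_ledger`.
#' @examples
#' flux_table(acetate = 21.4, butyrate = 6.2, CH4 = 1.13)
#' @export
flux_table <- function(..., unit_id = "unit1") {
  vals <- c(...)
  if (is.null(names(vals)) || any(names(vals) == "")) {
    abort("all fluxes must be named by end product")
  }
  product <- .canonical_product(names(vals))
  tibble::tibble(
    unit = unit_id,
    product = product,
    flux = unname(vals),
    in_ledger = !product %in% .excluded_products
  )
}

#' Daily molar fluxes of all measured end products for each record
#'
#' Converts one vessel-day record (layout of [read_records()] /
#' [fixture_records()]) into daily molar fluxes (mmol/d): each VFA's flux
#' is total VFA concentration x molar share / 100 x daily outflow, and gas
#' fluxes come either from explicitly supplied per-gas moles (`gas_mmol`)
#' or, failing that, from total gas volume x percentage via the ideal-gas
#' molar volume. Branched-chain VFA (isobutyrate, isovalerate) and nitrous
#' oxide are carried with `in_ledger = FALSE`: they are reported but never
#' scored by the ledger.
#'
#' Prefer supplying `gas_mmol` when per-gas daily volumes or moles were
#' measured: percentages expressed on a four-gas sum need not reconcile
#' with total bag volume (see the methods vignette).
#'
#' @param records Tibble of vessel-day records.
#' @param constants [physical_constants()] used for outflow and molar volume.
#' @param gas_mmol Optional tibble of per-gas molar fluxes with columns
#'   `gas` (`"CH4"`, `"H2"`, optionally `"N2O"`), `mmol_d`, and any key
#'   columns shared with `records` (e.g. `treatment` or `vessel`). When
#'   supplied it overrides volume-derived gas fluxes.
#' @return A long tibble: the record key columns (`vessel`, `treatment`,
#'   `day` as present), `product`, `flux` (mmol/d), `in_ledger`.
#' @examples
#' build_flux_table(fixture_records("CON"), gas_mmol = fixture_gas_mmol("CON"))
#' @export
build_flux_table <- function(records,
                             constants = physical_constants(),
                             gas_mmol = NULL) {
  stopifnot(is.data.frame(records))
  profile_cols <- intersect(
    c(
      "formate", "acetate", "propionate", "butyrate", "isobutyrate",
      "valerate", "isovalerate", "caproate", "heptanoate"
    ),
    names(records)
  )
  if (length(profile_cols) > 0 && !"vfa_total" %in% names(records)) {
    abort("records carry a VFA profile but no `vfa_total` column")
  }
  key_cols <- intersect(c("vessel", "treatment", "day"), names(records))
  if (length(key_cols) == 0) {
    abort("records need at least one of `vessel`, `treatment`, `day`")
  }

  vfa <- records |>
    dplyr::select(dplyr::all_of(c(key_cols, "vfa_total", profile_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(profile_cols),
      names_to = "product", values_to = "share"
    ) |>
    dplyr::mutate(
      flux = concentration_to_daily_flux(
        .data$vfa_total * .data$share / 100, constants$outflow
      )
    ) |>
    dplyr::select(-"vfa_total", -"share")

  gas <- NULL
  if (!is.null(gas_mmol)) {
    stopifnot(all(c("gas", "mmol_d") %in% names(gas_mmol)))
    join_cols <- intersect(key_cols, names(gas_mmol))
    gas_keys <- records |> dplyr::distinct(dplyr::across(dplyr::all_of(key_cols)))
    gas <- if (length(join_cols) > 0) {
      dplyr::inner_join(gas_keys, gas_mmol, by = join_cols)
    } else {
      tidyr::crossing(gas_keys, gas_mmol)
    }
    gas <- gas |>
      dplyr::mutate(product = .canonical_product(.data$gas), flux = .data$mmol_d) |>
      dplyr::select(dplyr::all_of(c(key_cols, "product", "flux")))
  } else if (all(c("gas_total", "ch4_pct", "h2_pct") %in% names(records))) {
    mv <- molar_volume(constants)
    pct_cols <- intersect(c("ch4_pct", "h2_pct", "n2o_pct"), names(records))
    gas <- records |>
      dplyr::select(dplyr::all_of(c(key_cols, "gas_total", pct_cols))) |>
      tidyr::pivot_longer(dplyr::all_of(pct_cols),
        names_to = "gas", values_to = "pct"
      ) |>
      dplyr::mutate(
        product = .canonical_product(sub("_pct$", "", .data$gas)),
        flux = gas_volume_to_mmol(
          .data$gas_total * 1000 * .data$pct / 100, mv
        )
      ) |>
      dplyr::select(dplyr::all_of(c(key_cols, "product", "flux")))
  }

  dplyr::bind_rows(vfa, gas) |>
    dplyr::mutate(in_ledger = !.data$product %in% .excluded_products) |>
    dplyr::arrange(dplyr::across(dplyr::all_of(key_cols)))
}

.score_scenario <- function(fluxes, scenario, deduct_heptanoate_propionate) {
  reg <- h2_stoichiometry(scenario)
  scored <- fluxes |>
    dplyr::filter(.data$in_ledger) |>
    dplyr::inner_join(reg, by = "product")
  if (deduct_heptanoate_propionate) {
    # the heptanoate reaction co-produces one propionate per heptanoate;
    # optionally remove that share from the measured propionate flux so the
    # coupled propionate is not scored twice
    key_cols <- .flux_unit_cols(fluxes)
    hept <- scored |>
      dplyr::filter(.data$product == "heptanoate") |>
      dplyr::select(dplyr::all_of(key_cols), hept_flux = "flux")
    scored <- scored |>
      dplyr::left_join(hept, by = key_cols) |>
      dplyr::mutate(
        flux = dplyr::if_else(
          .data$product == "propionate",
          pmax(.data$flux - dplyr::coalesce(.data$hept_flux, 0), 0),
          .data$flux
        )
      ) |>
      dplyr::select(-"hept_flux")
  }
  scored |>
    dplyr::mutate(
      scenario = scenario,
      role = dplyr::if_else(.data$coefficient > 0, "produced", "consumed"),
      h2_mmol_d = .data$flux * abs(.data$coefficient)
    )
}

#' Score a flux table into a metabolic-hydrogen ledger
#'
#' The central accounting step: each ledger-eligible end-product flux is
#' multiplied by the magnitude of its stoichiometric [2H] coefficient and
#' assigned to the produced side (acetate, butyrate, caproate under SC2) or
#' the consumed side (formate, propionate, valerate, caproate under SC1,
#' heptanoate, methane, gaseous dihydrogen). Totals, balance
#' (produced - consumed) and recovery (100 x consumed / produced) are
#' computed per experimental unit and scenario.
#'
#' @param fluxes Long flux table from [build_flux_table()] or
#'   [flux_table()]: any unit key columns plus `product`, `flux`,
#'   and optionally `in_ledger`.
#' @param scenario Character vector of caproate scenarios to evaluate;
#'   default both `"SC1"` and `"SC2"`.
#' @param deduct_heptanoate_propionate If `TRUE`, the propionate co-produced
#'   stoichiometrically with heptanoate is removed from the propionate flux
#'   before scoring (default `FALSE`, which follows the study's accounting
#'   of scoring every product from its own measured concentration).
#' @return An object of class `"h2_ledger"`: a list with `contributions`
#'   (per unit x scenario x product) and `totals` (per unit x scenario:
#'   `produced`, `consumed`, `balance`, `recovery`). Use [tidy()] /
#'   [glance()] to extract them.
#' @examples
#' fx <- build_flux_table(fixture_records("CON"), gas_mmol = fixture_gas_mmol("CON"))
#' h2_ledger(fx)
#' @export
h2_ledger <- function(fluxes, scenario = c("SC1", "SC2"),
                      deduct_heptanoate_propionate = FALSE) {
  stopifnot(is.data.frame(fluxes), all(c("product", "flux") %in% names(fluxes)))
  scenario <- match.arg(toupper(scenario), c("SC1", "SC2"), several.ok = TRUE)
  if (!"in_ledger" %in% names(fluxes)) {
    fluxes <- dplyr::mutate(fluxes,
      product = .canonical_product(.data$product),
      in_ledger = !.data$product %in% .excluded_products
    )
  }
  if (any(fluxes$flux < 0, na.rm = TRUE)) {
    abort("fluxes must be >= 0 mmol/d")
  }
  key_cols <- .flux_unit_cols(fluxes)

  contributions <- purrr::map(
    scenario, .score_scenario,
    fluxes = fluxes,
    deduct_heptanoate_propionate = deduct_heptanoate_propionate
  ) |>
    purrr::list_rbind() |>
    dplyr::select(dplyr::all_of(key_cols), "scenario", "product", "role",
      coefficient = "coefficient", flux = "flux", h2_mmol_d = "h2_mmol_d"
    )

  totals <- contributions |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(key_cols, "scenario")))) |>
    dplyr::summarise(
      produced = sum(.data$h2_mmol_d[.data$role == "produced"], na.rm = TRUE),
      consumed = sum(.data$h2_mmol_d[.data$role == "consumed"], na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      balance = .data$produced - .data$consumed,
      recovery = dplyr::if_else(
        .data$produced > 0, 100 * .data$consumed / .data$produced, NA_real_
      )
    )
  if (any(totals$produced == 0 & totals$consumed > 0)) {
    warn("recovery undefined for units with zero [2H] produced but nonzero consumed")
  }

  structure(
    list(
      contributions = contributions, totals = totals,
      scenarios = scenario, unit_cols = key_cols,
      deduct_heptanoate_propionate = deduct_heptanoate_propionate
    ),
    class = "h2_ledger"
  )
}

#' Per-product [2H] released, with total
#'
#' @inheritParams h2_ledger
#' @param scenario A single caproate scenario.
#' @return Tibble of per-unit produced contributions; rows with
#'   `product = "total"` carry the sum.
#' @export
h2_production <- function(fluxes, scenario = "SC1") {
  .ledger_side(fluxes, scenario, "produced")
}

#' Per-product [2H] taken up, with total
#'
#' @inheritParams h2_production
#' @return Tibble of per-unit consumed contributions plus `total` rows.
#' @export
h2_consumption <- function(fluxes, scenario = "SC1") {
  .ledger_side(fluxes, scenario, "consumed")
}

.ledger_side <- function(fluxes, scenario, side) {
  led <- h2_ledger(fluxes, scenario = scenario)
  per <- led$contributions |>
    dplyr::filter(.data$role == side) |>
    dplyr::select(dplyr::all_of(led$unit_cols), "scenario", "product", "h2_mmol_d")
  tot <- per |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(led$unit_cols, "scenario")))) |>
    dplyr::summarise(h2_mmol_d = sum(.data$h2_mmol_d), .groups = "drop") |>
    dplyr::mutate(product = "total")
  dplyr::bind_rows(per, tot)
}

#' Balance and recovery from ledger totals
#'
#' @param produced Total [2H] produced, mmol/d.
#' @param consumed Total [2H] consumed, mmol/d.
#' @return Tibble with `balance` (produced - consumed, mmol/d) and
#'   `recovery` (100 x consumed / produced, %; `NA` with a warning when
#'   produced is zero but consumed is not).
#' @examples
#' h2_balance(55.2, 23.5)
#' @export
h2_balance <- function(produced, consumed) {
  if (any(produced < 0 | consumed < 0, na.rm = TRUE)) {
    abort("totals must be >= 0")
  }
  recovery <- dplyr::if_else(produced > 0, 100 * consumed / produced, NA_real_)
  if (any(produced == 0 & consumed > 0, na.rm = TRUE)) {
    warn("recovery undefined when nothing is produced; returning NA")
  }
  tibble::tibble(
    produced = produced, consumed = consumed,
    balance = produced - consumed, recovery = recovery
  )
}

#' @export
print.h2_ledger <- function(x, ...) {
  cat("<h2_ledger> scenarios:", paste(x$scenarios, collapse = ", "), "\n")
  cat("units keyed by:", paste(x$unit_cols, collapse = ", "), "\n\n")
  print(x$totals, ...)
  invisible(x)
}

#' @rdname h2_ledger
#' @param x An `h2_ledger` object.
#' @param ... Unused.
#' @method tidy h2_ledger
#' @export
tidy.h2_ledger <- function(x, ...) {
  x$contributions
}

#' @rdname h2_ledger
#' @method glance h2_ledger
#' @export
glance.h2_ledger <- function(x, ...) {
  x$totals
}

#' Display-rounded ledger table
#'
#' Mirrors the study's report layout: per-product entries rounded to 2
#' decimals, totals/balances/recoveries to 1 decimal. Internal arithmetic
#' stays at full precision; use this only for presentation.
#'
#' @param ledger An [h2_ledger()] object.
#' @return A long tibble with columns the ledger unit keys, `scenario`,
#'   `item`, `value`.
#' @export
ledger_report <- function(ledger) {
  stopifnot(inherits(ledger, "h2_ledger"))
  per <- ledger$contributions |>
    dplyr::mutate(
      item = paste0(substr(.data$role, 1, 4), "_", .data$product),
      value = round(.data$h2_mmol_d, 2)
    ) |>
    dplyr::select(dplyr::all_of(ledger$unit_cols), "scenario", "item", "value")
  tot <- ledger$totals |>
    tidyr::pivot_longer(c("produced", "consumed", "balance", "recovery"),
      names_to = "item", values_to = "value"
    ) |>
    dplyr::mutate(value = round(.data$value, 1))
  dplyr::bind_rows(per, tot)
}
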
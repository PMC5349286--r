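# ggplot2 displays of the main result types.

#' Plot a hydrogen ledger
#'
#' Stacked per-product [2H] contributions, produced vs consumed, faceted
#' by caproate scenario. Units are put on the x axis using the first unit
#' key column of the ledger (typically `treatment`).
#'
#' @param object An [h2_ledger()] object.
#' @param ... Unused.
#' @return A ggplot.
#' @examples
#' fx <- build_flux_table(fixture_records(), gas_mmol = fixture_gas_mmol())
#' autoplot(h2_ledger(fx))
#' @method autoplot h2_ledger
#' @export
autoplot.h2_ledger <- function(object, ...) {
  x_col <- if ("treatment" %in% object$unit_cols) {
    "treatment"
  } else {
    object$unit_cols[1]
  }
  dat <- object$contributions |>
    dplyr::mutate(
      signed = dplyr::if_else(
        .data$role == "produced", .data$h2_mmol_d, -.data$h2_mmol_d
      )
    )
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data[[x_col]], y = .data$signed, fill = .data$product
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scenario)) +
    ggplot2::labs(
      y = "[2H] flux (mmol/d; released above, taken up below)",
      x = NULL, fill = "end product"
    ) +
    ggplot2::theme_minimal()
}

#' Plot VFA molar profiles by treatment
#'
#' @param records A tibble of vessel-day records carrying the VFA profile
#'   columns (e.g. from [fixture_records()] or [simulate_experiment()]).
#' @return A ggplot of stacked mol/100 mol shares per treatment.
#' @export
plot_vfa_profile <- function(records) {
  cols <- intersect(.profile_sum_cols, names(records))
  if (length(cols) == 0) abort("no VFA profile columns in `records`")
  records |>
    dplyr::select("treatment", dplyr::all_of(cols)) |>
    tidyr::pivot_longer(dplyr::all_of(cols),
      names_to = "acid", values_to = "share"
    ) |>
    dplyr::group_by(.data$treatment, .data$acid) |>
    dplyr::summarise(share = mean(.data$share), .groups = "drop") |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$treatment, y = .data$share, fill = .data$acid
    )) +
    ggplot2::geom_col() +
    ggplot2::labs(y = "VFA profile (mol/100 mol)", x = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot greenhouse-gas CO2-equivalent totals
#'
#' @param ghg The `ghg` tibble of a [run_pipeline()] result.
#' @return A ggplot of CO2-equivalent daily volumes.
#' @export
plot_ghg <- function(ghg) {
  stopifnot("ghg_co2eq_l" %in% names(ghg))
  x_col <- if ("treatment" %in% names(ghg)) "treatment" else names(ghg)[1]
  ggplot2::ggplot(ghg, ggplot2::aes(
    x = .data[[x_col]], y = .data$ghg_co2eq_l
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(y = "GHG (L CO2-eq/d)", x = NULL) +
    ggplot2::theme_minimal()
}
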
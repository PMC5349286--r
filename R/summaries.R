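# Descriptive fermentation summaries: VFA molar profile and ratios,
# substrate disappearance, efficiency of microbial protein synthesis, and
# treatment-level aggregation (mean, SEM over vessels).

#' VFA molar profile and ratios from concentrations
#'
#' Expresses each acid's concentration as mol/100 mol of the VFA sum and
#' derives the acetate:propionate and (acetate+butyrate):propionate
#' ratios. Scale-invariant: only the relative concentrations matter.
#'
#' @param concentrations Named numeric vector of VFA concentrations (mM);
#'   names are acid identifiers (isovalerate is the co-eluted
#'   isovalerate + 2-methylbutyrate pool).
#' @return A list with `shares` (named, sums to 100), `a_to_p` and
#'   `ab_to_p` (`NA` with a warning when propionate is absent or zero).
#' @examples
#' vfa_profile(c(acetate = 34.1, propionate = 8.3, butyrate = 10.0))
#' @export
vfa_profile <- function(concentrations) {
  if (is.null(names(concentrations)) || any(names(concentrations) == "")) {
    abort("`concentrations` must be named by acid")
  }
  if (any(concentrations < 0, na.rm = TRUE)) {
    abort("concentrations must be >= 0")
  }
  total <- sum(concentrations, na.rm = TRUE)
  if (total <= 0) abort("all-zero VFA concentrations: profile undefined")
  shares <- 100 * concentrations / total
  share_of <- function(nm, default) {
    if (nm %in% names(shares)) shares[[nm]] else default
  }
  p <- share_of("propionate", NA_real_)
  a <- share_of("acetate", NA_real_)
  b <- share_of("butyrate", 0)
  if (is.na(p) || p == 0) {
    warn("propionate absent or zero: ratios undefined")
    a_to_p <- ab_to_p <- NA_real_
  } else {
    a_to_p <- a / p
    ab_to_p <- (a + b) / p
  }
  list(shares = shares, a_to_p = a_to_p, ab_to_p = ab_to_p)
}

#' Apparent substrate disappearance over the incubation
#'
#' @param mass_in Substrate mass incubated, g.
#' @param mass_residue Residue recovered after incubation, g.
#' @return Percentage of mass lost; a residue exceeding the input yields a
#'   negative value with a warning, never silent clipping.
#' @examples
#' substrate_disappearance(10, 5.21)
#' @export
substrate_disappearance <- function(mass_in, mass_residue) {
  if (any(mass_in <= 0)) abort("`mass_in` must be > 0")
  if (any(mass_residue < 0)) abort("`mass_residue` must be >= 0")
  if (any(mass_residue > mass_in)) {
    warn("residue exceeds input mass; reporting negative disappearance")
  }
  100 * (mass_in - mass_residue) / mass_in
}

#' Efficiency of microbial protein synthesis
#'
#' Grams of microbial nitrogen produced per kilogram of organic matter
#' fermented (mg/g equals g/kg, so no unit factor is needed).
#'
#' @param microbial_n Microbial N production, mg/d.
#' @param om_fermented Organic matter fermented, g/d.
#' @return g microbial N / kg OM fermented; `NA` with a warning when no OM
#'   was fermented.
#' @examples
#' emps(59.8, 4.27)
#' @export
emps <- function(microbial_n, om_fermented) {
  if (any(microbial_n < 0)) abort("microbial N must be >= 0")
  if (any(om_fermented < 0)) abort("OM fermented must be >= 0")
  out <- dplyr::if_else(
    om_fermented > 0, microbial_n / om_fermented, NA_real_
  )
  if (any(om_fermented == 0)) warn("EMPS undefined at zero OM fermented")
  out
}

#' Treatment means and standard errors over vessels
#'
#' Aggregates per-unit values to treatment level. The vessel is the
#' experimental unit: repeated days within a vessel are averaged first,
#' then the mean and SEM (sd / sqrt(n vessels)) are computed over vessel
#' means. Groups with a single vessel get a mean and an `NA` SEM; empty
#' groups are dropped with a warning rather than yielding silent `NaN`s.
#'
#' @param data A tibble with at least `treatment`, `vessel` and the value
#'   column.
#' @param value Column to aggregate (tidy-eval).
#' @param ... Extra grouping columns beyond `treatment` (e.g. `scenario`,
#'   `product`).
#' @return A tibble with `treatment`, the extra groups, `mean`, `sem`,
#'   `n_vessels`.
#' @examples
#' df <- tibble::tibble(
#'   treatment = "CON", vessel = rep(1:4, each = 2),
#'   day = rep(1:2, 4), y = c(1, 1, 2, 2, 3, 3, 4, 4)
#' )
#' aggregate_by_treatment(df, y)
#' @export
aggregate_by_treatment <- function(data, value, ...) {
  stopifnot(all(c("treatment", "vessel") %in% names(data)))
  val <- rlang::enquo(value)
  groups <- rlang::enquos(...)
  per_vessel <- data |>
    dplyr::filter(!is.na(!!val)) |>
    dplyr::group_by(.data$treatment, !!!groups, .data$vessel) |>
    dplyr::summarise(v = mean(!!val), .groups = "drop_last")
  out <- per_vessel |>
    dplyr::summarise(
      mean = mean(.data$v),
      sem = dplyr::if_else(
        dplyr::n() >= 2, sd(.data$v) / sqrt(dplyr::n()), NA_real_
      ),
      n_vessels = dplyr::n(),
      .groups = "drop"
    )
  if (nrow(out) == 0) warn("no non-missing values to aggregate")
  out
}
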
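# Stoichiometric registry: moles of metabolic hydrogen ([2H], one
# reducing-equivalent pair = one H2 equivalent) released (+) or consumed (-)
# per mole of fermentation end product formed from glucose.

.stoichiometry_registry <- function() {
  tibble::tribble(
    ~product,      ~coefficient, ~pathway,
    "formate",     -1,           "default",
    "acetate",     +2,           "default",
    "propionate",  -1,           "default",
    "butyrate",    +2,           "default",
    "valerate",    -1,           "default",
    # caproate has two candidate origins: chain elongation of
    # propionyl-CoA (net uptake of 4 [2H]/mol, scenario SC1) or
    # condensation of acetyl-CoA units (net release of 2 [2H]/mol, SC2)
    "caproate",    -4,           "SC1",
    "caproate",    +2,           "SC2",
    # heptanoate: condensation of one propionyl-CoA and two acetyl-CoA,
    # net uptake of 2 [2H]/mol (co-produces one propionate, which is
    # scored separately from its own measured concentration)
    "heptanoate",  -2,           "default",
    "CH4",         -4,           "default",
    # gaseous H2 is itself one [2H] pair per mole
    "H2",          -1,           "default"
  )
}

# products measured and carried in flux tables but excluded from the ledger
# (branched-chain VFA derive from amino acids, not glucose; N2O belongs to
# the nitrate sink)
.excluded_products <- c("isobutyrate", "isovalerate", "N2O")

.product_aliases <- c(
  methane = "CH4", ch4 = "CH4", hydrogen = "H2", h2 = "H2",
  gh2 = "H2", n2o = "N2O"
)

.canonical_product <- function(product) {
  key <- tolower(product)
  out <- product
  hit <- key %in% names(.product_aliases)
  out[hit] <- .product_aliases[key[hit]]
  out
}

#' Stoichiometric [2H] coefficients of the fermentation end products
#'
#' Returns the registry of signed metabolic-hydrogen coefficients: moles of
#' [2H] released (positive) or taken up (negative) per mole of end product
#' formed from glucose. Caproate carries two entries, one per origin
#' scenario: `"SC1"` (propionyl-CoA chain elongation, -4) and `"SC2"`
#' (acetyl-CoA condensation, +2). Supplying `scenario` resolves caproate to
#' a single row.
#'
#' @param scenario `NULL` (full registry) or `"SC1"`/`"SC2"`.
#' @return A tibble with columns `product`, `coefficient`, `pathway`.
#' @examples
#' h2_stoichiometry()
#' h2_stoichiometry("SC1")
#' @export
h2_stoichiometry <- function(scenario = NULL) {
  reg <- .stoichiometry_registry()
  if (is.null(scenario)) {
    return(reg)
  }
  scenario <- match.arg(toupper(scenario), c("SC1", "SC2"))
  dplyr::filter(reg, .data$pathway %in% c("default", scenario))
}

#' Signed [2H] coefficient of one end product
#'
#' @param product End-product name (canonical names plus aliases
#'   `"methane"`/`"hydrogen"`).
#' @param scenario Caproate origin scenario, `"SC1"` or `"SC2"`; required
#'   when `product = "caproate"`, ignored otherwise.
#' @return Integer moles [2H] per mole of product (positive = released).
#' @examples
#' h2_coefficient("acetate") # +2
#' h2_coefficient("caproate", "SC2") # +2
#' @export
h2_coefficient <- function(product, scenario = NULL) {
  product <- .canonical_product(product)
  reg <- .stoichiometry_registry()
  out <- vapply(product, function(p) {
    rows <- reg[reg$product == p, ]
    if (nrow(rows) == 0) {
      abort(paste0(
        "Unknown end product: '", p, "'. Registry products: ",
        paste(unique(reg$product), collapse = ", ")
      ))
    }
    if (nrow(rows) > 1) {
      if (is.null(scenario)) {
        abort(paste0(
          "'", p, "' has scenario-dependent stoichiometry; ",
          "supply scenario = \"SC1\" or \"SC2\""
        ))
      }
      sc <- match.arg(toupper(scenario), c("SC1", "SC2"))
      rows <- rows[rows$pathway == sc, ]
    }
    rows$coefficient
  }, numeric(1))
  unname(out)
}
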
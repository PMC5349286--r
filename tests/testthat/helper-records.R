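# shared fixtures built in code

# a minimal well-formed record: CON-like means, profile closing to 100
make_record <- function(vessel = "V1", treatment = "CON", day = 8L,
                        vfa_total = 60) {
  tibble::tibble(
    vessel = vessel, treatment = treatment, day = day,
    vfa_total = vfa_total,
    formate = 5.0, acetate = 52.0, propionate = 13.0, butyrate = 15.0,
    isobutyrate = 0.5, valerate = 5.5, isovalerate = 7.5,
    caproate = 4.8, heptanoate = 1.7,
    ethanol = 6, n_propanol = 0.2, ammonium = 14,
    nitrate = 0, nitrite = 0,
    gas_total = 0.7, ch4_pct = 17, h2_pct = 2, co2_pct = 81, n2o_pct = 0,
    dh2 = 40, substrate_in = 10, residue = 5.2, microbial_n = 60
  )
}

write_records_csv <- function(records, path = withr::local_tempfile(
                                fileext = ".csv",
                                .local_envir = parent.frame()
                              )) {
  readr::write_csv(records, path, na = "")
  path
}

# independent brute-force oracle: signed [2H] sum straight from the
# reaction table, with no produced/consumed grouping
oracle_coefficients <- function(scenario) {
  c(
    formate = -1, acetate = 2, propionate = -1, butyrate = 2,
    valerate = -1,
    caproate = if (scenario == "SC1") -4 else 2,
    heptanoate = -2, CH4 = -4, H2 = -1
  )
}

oracle_net_h2 <- function(flux_named, scenario) {
  coefs <- oracle_coefficients(scenario)
  keep <- intersect(names(flux_named), names(coefs))
  sum(flux_named[keep] * coefs[keep])
}

# random single-unit flux tables for property tests
random_flux_table <- function(unit_id) {
  products <- c(
    "formate", "acetate", "propionate", "butyrate", "valerate",
    "caproate", "heptanoate", "CH4", "H2"
  )
  vals <- stats::runif(length(products), 0, 30)
  names(vals) <- products
  vals
}
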
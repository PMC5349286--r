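# Synthetic RUSITEC-like data: vessel x day measurement records drawn
# around known treatment means with additive vessel, day and residual
# effects, truncated at zero. The generator's defaults are the study's own
# treatment means and printed SEMs, so simulated experiments look like the
# design they emulate (4 treatments x 4 vessels, pooled SEM on n = 4).

.sim_analytes <- function() c(
  "vfa_total", .profile_cols, "ethanol", "n_propanol", "ammonium",
  "nitrate", "nitrite", "gas_total", .pct_cols, "dh2",
  "substrate_in", "residue", "microbial_n"
)

#' Default treatment profiles (analyte means per treatment)
#'
#' One row per treatment with the mean of every simulated analyte, loaded
#' from the study's printed tables via [fixture_records()].
#'
#' @param treatments Treatments to include.
#' @return A tibble, `treatment` plus one column per analyte.
#' @export
treatment_profiles <- function(treatments = c("CON", "NIT", "NOP", "AQ")) {
  fixture_records(treatments) |>
    dplyr::select("treatment", dplyr::all_of(.sim_analytes()))
}

#' Override analyte means in a treatment profile
#'
#' @param profiles A [treatment_profiles()] tibble.
#' @param treatment Which treatment row to modify.
#' @param ... Named analyte overrides, e.g. `vfa_total = 0`.
#' @return A new profiles tibble; the input is untouched.
#' @examples
#' perturb_profile(treatment_profiles(), "CON", acetate = 68.1)
#' @export
perturb_profile <- function(profiles, treatment, ...) {
  overrides <- list(...)
  if (length(overrides) == 0) {
    return(profiles)
  }
  unknown <- setdiff(names(overrides), names(profiles))
  if (length(unknown) > 0) {
    abort(paste0("Unknown analyte(s): ", paste(unknown, collapse = ", ")))
  }
  i <- which(profiles$treatment == treatment)
  if (length(i) != 1) abort(paste0("No profile row for treatment ", treatment))
  for (nm in names(overrides)) profiles[[nm]][i] <- overrides[[nm]]
  profiles
}

#' Between-vessel / between-day / residual variance model
#'
#' Per-analyte standard deviations of the additive noise components. The
#' default is anchored to the printed pooled SEMs: with n = 4 vessels the
#' implied between-vessel-mean standard deviation is `2 x SEM`, and its
#' variance is split between vessel, day and residual components in
#' configurable fractions (default 50 / 25 / 25 — the study reports SEMs
#' but not a variance partition, so the split is a declared convention).
#'
#' @param vessel_frac,day_frac Fractions of the implied variance assigned
#'   to the vessel and day components (residual takes the rest).
#' @param n_vessels Vessel count behind the printed SEMs (4).
#' @return A tibble: `analyte`, `vessel_sd`, `day_sd`, `residual_sd`.
#' @export
default_variance_model <- function(vessel_frac = 0.5, day_frac = 0.25,
                                   n_vessels = 4) {
  if (vessel_frac < 0 || day_frac < 0 || vessel_frac + day_frac > 1) {
    abort("variance fractions must be >= 0 and sum to <= 1")
  }
  sem_map <- c(
    vfa_total = 4.02, formate = 0.664, acetate = 0.82, propionate = 0.69,
    butyrate = 0.47, isobutyrate = 0.022, valerate = 0.187,
    isovalerate = 0.268, caproate = 0.671, heptanoate = 0.222,
    ethanol = 0.600, n_propanol = 0.044, ammonium = 0.54,
    nitrate = 0.053, nitrite = 0.008,
    gas_total = 0.066, ch4_pct = 0.84, h2_pct = 0.99, co2_pct = 1.19,
    n2o_pct = 0.006, dh2 = 3.79,
    substrate_in = 0, residue = 0.207, # 10 g x DM-disappearance SEM / 100
    microbial_n = 2.68
  )
  total_sd <- sem_map * sqrt(n_vessels)
  residual_frac <- 1 - vessel_frac - day_frac
  tibble::tibble(
    analyte = names(sem_map),
    vessel_sd = total_sd * sqrt(vessel_frac),
    day_sd = total_sd * sqrt(day_frac),
    residual_sd = total_sd * sqrt(residual_frac)
  )
}

#' Simulation configuration
#'
#' @param profiles Treatment mean profiles ([treatment_profiles()]).
#' @param n_vessels Vessels per treatment (default 4, the study design).
#' @param days Integer study days (default 8:13, the six-day measurement
#'   window).
#' @param variance A [default_variance_model()]-shaped tibble.
#' @param seed Integer seed; identical seeds give identical experiments.
#' @return A list with class `"sim_config"`.
#' @export
sim_config <- function(profiles = treatment_profiles(),
                       n_vessels = 4, days = 8:13,
                       variance = default_variance_model(),
                       seed = NULL) {
  if (n_vessels < 1) abort("`n_vessels` must be >= 1")
  if (length(days) == 0) abort("`days` must be nonempty")
  stopifnot(all(c("analyte", "vessel_sd", "day_sd", "residual_sd")
  %in% names(variance)))
  if (any(variance$vessel_sd < 0 | variance$day_sd < 0 |
    variance$residual_sd < 0)) {
    abort("variance-model standard deviations must be >= 0")
  }
  structure(
    list(
      profiles = profiles, n_vessels = n_vessels, days = as.integer(days),
      variance = variance, seed = seed
    ),
    class = "sim_config"
  )
}

#' Simulate a vessel-by-day fermentation experiment
#'
#' Every analyte value is treatment mean + vessel effect + day effect +
#' residual, each component Gaussian with the configured SD, truncated at
#' zero; analytes with a zero treatment mean are structural zeros and get
#' no noise. Day effects are shared by all vessels of a treatment on the
#' same day. The eight-acid VFA composition and the four gas percentages
#' are renormalised to their treatment-mean closure sums, so simulated
#' records always pass [validate_records()] and, with all SDs zero, every
#' record equals its treatment mean exactly.
#'
#' @param config A [sim_config()].
#' @return A list: `records` (tibble of vessel-day records) and `truth`
#'   (the treatment-mean profiles the records were drawn around).
#' @examples
#' sim <- simulate_experiment(sim_config(seed = 1, days = 8:9))
#' head(sim$records)
#' @export
simulate_experiment <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  run <- function() .simulate_impl(config)
  if (!is.null(config$seed)) {
    withr::with_seed(config$seed, run())
  } else {
    run()
  }
}

.simulate_impl <- function(config) {
  profiles <- config$profiles
  grid <- tidyr::crossing(
    treatment = profiles$treatment,
    vessel_no = seq_len(config$n_vessels),
    day = config$days
  ) |>
    dplyr::mutate(vessel = paste0(.data$treatment, "_V", .data$vessel_no))

  n_trt <- nrow(profiles)
  vessel_key <- paste(grid$treatment, grid$vessel_no)
  day_key <- paste(grid$treatment, grid$day)
  vessel_idx <- match(vessel_key, unique(vessel_key))
  day_idx <- match(day_key, unique(day_key))
  n_vk <- max(vessel_idx)
  n_dk <- max(day_idx)
  trt_idx <- match(grid$treatment, profiles$treatment)

  analytes <- intersect(.sim_analytes(), names(profiles))
  vm <- config$variance
  out <- grid |> dplyr::select("vessel", "treatment", "day")
  mus <- list()
  for (a in analytes) {
    mu <- profiles[[a]][trt_idx]
    mus[[a]] <- mu
    row <- vm[vm$analyte == a, ]
    vs <- if (nrow(row) == 1) row$vessel_sd else 0
    ds <- if (nrow(row) == 1) row$day_sd else 0
    rs <- if (nrow(row) == 1) row$residual_sd else 0
    val <- mu +
      rnorm(n_vk, 0, vs)[vessel_idx] +
      rnorm(n_dk, 0, ds)[day_idx] +
      rnorm(nrow(grid), 0, rs)
    # structural zeros stay zero: an analyte absent from a treatment
    # (e.g. nitrate without a nitrate dose) produces no signal
    val[mu == 0] <- 0
    out[[a]] <- pmax(val, 0)
  }

  # keep compositions valid: renormalise the eight-acid VFA shares and the
  # four gas percentages to their treatment-mean closure sums, so noise
  # perturbs the composition without breaking it (and zero noise
  # reproduces the means exactly)
  renorm <- function(cols) {
    target <- Reduce(`+`, mus[cols])
    s <- rowSums(out[cols])
    f <- target / s
    f[abs(target - s) < 1e-9] <- 1 # already closed: leave values bitwise
    out[cols] <<- out[cols] * f
  }
  if (all(.profile_sum_cols %in% names(out))) renorm(.profile_sum_cols)
  if (all(.pct_cols %in% names(out))) renorm(.pct_cols)

  truth <- profiles |>
    dplyr::mutate(vessel = paste0("truth_", .data$treatment), day = NA_integer_) |>
    dplyr::relocate("vessel", "treatment", "day")
  list(records = out, truth = truth)
}

#' Theoretical standard error of a simulated treatment mean
#'
#' For the additive variance model, the treatment mean over `n_vessels`
#' vessels and `length(days)` days has standard error
#' `sqrt(vessel_sd^2 / n_v + day_sd^2 / n_d + residual_sd^2 / (n_v n_d))`.
#' Renormalisation of compositions perturbs this slightly; see the methods
#' vignette.
#'
#' @param config A [sim_config()].
#' @return A tibble `analyte`, `sem`.
#' @export
theoretical_sem <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n_v <- config$n_vessels
  n_d <- length(config$days)
  config$variance |>
    dplyr::mutate(
      sem = sqrt(.data$vessel_sd^2 / n_v + .data$day_sd^2 / n_d +
        .data$residual_sd^2 / (n_v * n_d))
    ) |>
    dplyr::select("analyte", "sem")
}
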
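#' Parametric sensitivity-surface truth for simulation
#'
#' Defines the data-generating process of the synthetic observations: a
#' bilinear temperature-sensitivity surface
#' \deqn{b(\mathrm{MAT}, \mathrm{IVT}) = \gamma_0 + \gamma_M \mathrm{MAT} +
#'   \gamma_V \mathrm{IVT} + \gamma_{MV} \mathrm{MAT}\cdot\mathrm{IVT}}
#' (days/degC, in raw MAT and IVT units), optional per-species deviations of
#' that slope, a precipitation slope (days/mm), species and phenophase
#' baseline day-of-year offsets, and Gaussian residual noise.
#'
#' The default surface coefficients are the unique bilinear surface through a
#' 3x3 grid of published marginal-slope estimates for these species
#' (e.g. -2.31 days/degC at MAT = 5, IVT = 0.8, steepening to -4.27 at
#' MAT = 15, IVT = 1.2), so the default generator emulates the empirically
#' observed sensitivity regime. Default species slope offsets are sum-to-zero
#' and sized to the reported interspecific extremes; baselines place spring
#' bloomers in early spring and summer bloomers in mid-summer.
#'
#' @param gamma0 Baseline slope at MAT = 0, IVT = 0 (days/degC).
#' @param gammaM Change in slope per degC MAT (days/degC per degC).
#' @param gammaV Change in slope per s.d. IVT.
#' @param gammaMV MAT-by-IVT interaction on the slope.
#' @param betaP Precipitation slope (days/mm).
#' @param species_baseline Named numeric vector of species baseline DOY.
#' @param species_slope_offset Named numeric vector of per-species additive
#'   deviations from the shared slope surface (days/degC); should sum to 0 so
#'   the species-averaged surface equals the shared surface.
#' @param phenophase_offset Named numeric vector of DOY offsets for budding,
#'   flowering, fruiting.
#' @param noise_sd Residual DOY noise s.d. (days).
#' @return An object of class `sensitivity_truth` (a named list).
#' @export
#' @examples
#' truth_slope(sensitivity_truth(), MAT = 5, IVT = 0.8)
sensitivity_truth <- function(gamma0 = -1.58875,
                              gammaM = 0.01225,
                              gammaV = -0.278125,
                              gammaMV = -0.140625,
                              betaP = 0.03,
                              species_baseline = c(
                                "Tussilago farfara" = 80,
                                "Ficaria verna" = 95,
                                "Alliaria petiolata" = 115,
                                "Cirsium arvense" = 175,
                                "Daucus carota" = 185,
                                "Lythrum salicaria" = 195
                              ),
                              species_slope_offset = c(
                                "Tussilago farfara" = -1.05,
                                "Ficaria verna" = -0.25,
                                "Alliaria petiolata" = 1.20,
                                "Cirsium arvense" = 0.35,
                                "Daucus carota" = 0.15,
                                "Lythrum salicaria" = -0.40
                              ),
                              phenophase_offset = c(
                                budding = 0, flowering = 10, fruiting = 25
                              ),
                              noise_sd = 20) {
  species <- study_species()$species
  if (!all(species %in% names(species_baseline))) {
    abort("species_baseline must name all six study species.")
  }
  if (!all(species %in% names(species_slope_offset))) {
    abort("species_slope_offset must name all six study species.")
  }
  if (noise_sd < 0) abort("noise_sd must be non-negative.")
  grid <- tidyr::expand_grid(MAT = c(-5, 15), IVT = c(0.4, 1.2))
  b <- gamma0 + gammaM * grid$MAT + gammaV * grid$IVT + gammaMV * grid$MAT * grid$IVT
  if (!all(is.finite(b))) abort("Truth slope is not finite over the study MAT/IVT box.")
  structure(
    list(
      gamma0 = gamma0, gammaM = gammaM, gammaV = gammaV, gammaMV = gammaMV,
      betaP = betaP,
      species_baseline = species_baseline[species],
      species_slope_offset = species_slope_offset[species],
      phenophase_offset = phenophase_offset,
      noise_sd = noise_sd
    ),
    class = "sensitivity_truth"
  )
}

#' @export
print.sensitivity_truth <- function(x, ...) {
  cat("<sensitivity_truth> b(MAT,IVT) = ", x$gamma0, " + ", x$gammaM, "*MAT + ",
    x$gammaV, "*IVT + ", x$gammaMV, "*MAT*IVT  (days/degC)\n",
    sep = ""
  )
  cat("  betaP =", x$betaP, "days/mm; noise_sd =", x$noise_sd, "days\n")
  invisible(x)
}

#' True temperature-sensitivity slope at given climate conditions
#'
#' @param truth A [sensitivity_truth()].
#' @param MAT,IVT Numeric vectors (recycled) of mean annual minimum
#'   temperature (degC) and interannual temperature variability (s.d.).
#' @param species Optional species name(s); if supplied, the per-species
#'   slope offset is added.
#' @return Numeric vector of slopes, days/degC.
#' @export
truth_slope <- function(truth, MAT, IVT, species = NULL) {
  b <- truth$gamma0 + truth$gammaM * MAT + truth$gammaV * IVT +
    truth$gammaMV * MAT * IVT
  if (!is.null(species)) {
    off <- truth$species_slope_offset[species]
    if (anyNA(off)) abort("Unknown species in truth_slope().")
    b <- b + unname(off)
  }
  b
}

#' Generate synthetic phenology observations
#'
#' Draws observation records over a synthetic climate grid and generates
#' their day of year from the configured truth: a random cell (uniform
#' within the continent's cells, optionally biased), uniform coordinates
#' within the cell, a random year and phenophase; then
#' \deqn{DOY = baseline_{sp} + offset_{ph} + b(\mathrm{MAT}, \mathrm{IVT},
#'   sp)\, T_{std} + \beta_P P_{std} + \varepsilon,}
#' rounded and clamped to `[1, 365]`. `Tstd` and `Pstd` are computed through
#' [add_climate_covariates()] -- the same seasonal windows and centering the
#' analysis pipeline uses -- so the generated data are exactly consistent
#' with the estimation machinery.
#'
#' @param grid A [climate_grid()] with both continents.
#' @param truth A [sensitivity_truth()].
#' @param n_per_species_continent Records per species per continent.
#' @param seed Integer seed.
#' @param years Candidate observation years.
#' @param phenophase_prob Sampling probabilities for budding, flowering,
#'   fruiting.
#' @param continent_weight Optional named weights biasing the continent
#'   sampling of cells (sampling-bias knob; default balanced by design).
#' @param species Species subset (default all six).
#' @param grouping Standardization grouping passed to
#'   [add_climate_covariates()].
#' @return A tibble in the observation schema, plus covariate and truth
#'   columns (`Tstd`, `Pstd`, `MAT`, `IVT`, `true_slope`).
#' @export
generate_observations <- function(grid, truth = sensitivity_truth(),
                                  n_per_species_continent = 100L,
                                  seed = 1L,
                                  years = 2017:2019,
                                  phenophase_prob = c(
                                    budding = 0.2, flowering = 0.5, fruiting = 0.3
                                  ),
                                  continent_weight = NULL,
                                  species = study_species()$species,
                                  grouping = "species") {
  if (n_per_species_continent < 1) abort("n_per_species_continent must be >= 1.")
  if (nrow(grid$cells) == 0) abort("Empty climate grid.")
  bad <- setdiff(species, study_species()$species)
  if (length(bad) > 0) {
    abort(paste0("Species not configured: ", paste(bad, collapse = ", ")))
  }
  continents <- unique(grid$cells$continent)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )

  frame <- tidyr::expand_grid(species = species, continent = continents) |>
    dplyr::slice(rep(dplyr::row_number(), each = n_per_species_continent))
  n <- nrow(frame)

  cell_of <- integer(n)
  for (cont in continents) {
    pool <- grid$cells$cell[grid$cells$continent == cont]
    w <- if (is.null(continent_weight)) NULL else {
      rep(continent_weight[[cont]] %||% 1, length(pool))
    }
    i <- frame$continent == cont
    cell_of[i] <- sample(pool, sum(i), replace = TRUE, prob = w)
  }
  cl <- grid$cells[match(cell_of, grid$cells$cell), ]

  obs <- tibble::tibble(
    id = sprintf("syn%06d", seq_len(n)),
    species = frame$species,
    latitude = cl$lat + runif(n, -0.25, 0.25),
    longitude = cl$lon + runif(n, -0.25, 0.25),
    continent = frame$continent,
    year = sample(years, n, replace = TRUE),
    phenophase = sample(names(phenophase_prob), n,
      replace = TRUE, prob = phenophase_prob
    )
  )
  obs <- add_climate_covariates(obs, grid, grouping = grouping)

  b <- truth_slope(truth, obs$MAT, obs$IVT, species = obs$species)
  mu <- unname(truth$species_baseline[obs$species]) +
    unname(truth$phenophase_offset[obs$phenophase]) +
    b * obs$Tstd + truth$betaP * obs$Pstd
  doy <- round(mu + rnorm(n, sd = truth$noise_sd))
  obs$doy <- as.integer(pmin(pmax(doy, 1), 365))
  obs$date <- as.Date(obs$doy - 1, origin = paste0(obs$year, "-01-01"))
  obs$true_slope <- b

  dplyr::relocate(obs, "id", "species", "date", "latitude", "longitude",
    "continent", "phenophase", "doy", "year"
  )
}

#' Serialize truth parameters to a config file
#'
#' @param truth A [sensitivity_truth()].
#' @param path YAML file path.
#' @export
write_truth <- function(truth, path) {
  yaml::write_yaml(unclass(truth), path)
  invisible(path)
}
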
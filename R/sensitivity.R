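axis_seq <- function(range, step, what) {
  n <- (range[2] - range[1]) / step
  if (abs(n - round(n)) > 1e-8) {
    abort(paste0("Step ", step, " does not divide the ", what, " range evenly."))
  }
  seq(range[1], range[2], by = step)
}

#' Temperature-sensitivity surface over an MAT x IVT grid
#'
#' Evaluates the marginal slope of standardized temperature at every node of
#' a regular MAT x IVT grid, averaged with equal weights across species and
#' phenophase (or per species with `by_species = TRUE`) and with
#' standardized precipitation controlled at its sample mean. The default
#' grid iterates MAT at 0.2 degC steps over [-5, 15] and IVT at 0.05 s.d.
#' steps over [0.4, 1.2] (1717 nodes); the coarser grid used for
#' intraspecific-range summaries iterates at 1 degC / 0.1 s.d. (189 nodes).
#'
#' @param model A fitted global model (`pheno_fit`).
#' @param mat_range,mat_step MAT axis (degC).
#' @param ivt_range,ivt_step IVT axis (s.d.).
#' @param by_species If `TRUE`, one surface per species (species is a
#'   moderator instead of being averaged over).
#' @param focal Focal covariate (default `"Tstd"`).
#' @return A tibble of class `sensitivity_surface`: columns `MAT`, `IVT`,
#'   (`species`,) `estimate` (days/degC), `std.error`, `statistic`,
#'   `p.value`, `df`.
#' @export
sensitivity_surface <- function(model,
                                mat_range = c(-5, 15), mat_step = 0.2,
                                ivt_range = c(0.4, 1.2), ivt_step = 0.05,
                                by_species = FALSE, focal = "Tstd") {
  at <- list(
    MAT = axis_seq(mat_range, mat_step, "MAT"),
    IVT = axis_seq(ivt_range, ivt_step, "IVT")
  )
  if (by_species) at$species <- model$xlevels$species
  grid <- suppressWarnings(make_reference_grid(model, at = at))
  out <- marginal_slope(model, focal, grid)
  attr(out, "mat_axis") <- at$MAT
  attr(out, "ivt_axis") <- at$IVT
  attr(out, "by_species") <- by_species
  attr(out, "units") <- if (focal == "Pstd") "days/mm" else "days/degC"
  class(out) <- unique(c("sensitivity_surface", class(out)))
  out
}

#' Project temperature sensitivity onto observations
#'
#' Assigns each observation the marginal slope of standardized temperature
#' evaluated at the record's exact MAT and IVT (not the nearest surface
#' node), giving a per-record sensitivity table keyed by id with
#' coordinates, ready for range mapping.
#'
#' @param observations Observation tibble with `MAT` and `IVT` columns.
#' @param model The fitted global model.
#' @param focal Focal covariate (default `"Tstd"`).
#' @return A tibble: `id`, `latitude`, `longitude`, `species`, `MAT`, `IVT`,
#'   `estimate`, `std.error`.
#' @export
map_sensitivity <- function(observations, model, focal = "Tstd") {
  obs <- tibble::as_tibble(observations)
  if (!all(c("MAT", "IVT") %in% names(obs)) || anyNA(obs$MAT) || anyNA(obs$IVT)) {
    abort("Observations lack MAT/IVT covariates; run add_climate_covariates() first.")
  }
  # evaluate at each record's exact (MAT, IVT) pair -- not crossed axes, and
  # not the nearest surface node -- via one paired reference grid
  combos <- dplyr::distinct(obs, .data$MAT, .data$IVT)
  grids <- marginal_slope(model, focal, reference_grid_from(model, combos))
  keyed <- dplyr::left_join(
    obs[, intersect(c("id", "latitude", "longitude", "species", "MAT", "IVT"), names(obs))],
    grids[, c("MAT", "IVT", "estimate", "std.error")],
    by = c("MAT", "IVT")
  )
  keyed
}

#' Intraspecific range of temperature sensitivity
#'
#' Maximum, minimum and total range of the marginal temperature slope across
#' the climatic study area, evaluated on the coarse MAT x IVT summary grid
#' (1 degC / 0.1 s.d. steps by default).
#'
#' @param model Fitted global model.
#' @param mat_range,mat_step,ivt_range,ivt_step Grid of climate conditions.
#' @return A one-row tibble: `max_slope`, `min_slope`, `range`, with the
#'   grid coordinates where the extremes occur.
#' @export
intraspecific_range <- function(model,
                                mat_range = c(-5, 15), mat_step = 1,
                                ivt_range = c(0.4, 1.2), ivt_step = 0.1) {
  surf <- sensitivity_surface(model,
    mat_range = mat_range, mat_step = mat_step,
    ivt_range = ivt_range, ivt_step = ivt_step
  )
  i_max <- which.max(surf$estimate)
  i_min <- which.min(surf$estimate)
  tibble::tibble(
    max_slope = surf$estimate[i_max],
    max_at_MAT = surf$MAT[i_max], max_at_IVT = surf$IVT[i_max],
    min_slope = surf$estimate[i_min],
    min_at_MAT = surf$MAT[i_min], min_at_IVT = surf$IVT[i_min],
    range = surf$estimate[i_max] - surf$estimate[i_min]
  )
}

#' Interspecific range of temperature sensitivity
#'
#' Mean marginal temperature slope per species (averaged over phenophases,
#' with MAT, IVT and standardized precipitation controlled at their sample
#' means), its Tukey-adjusted pairwise contrasts, and the max-min range.
#'
#' @param model Fitted global model.
#' @return A list: `by_species` tibble of per-species slopes, `contrasts`
#'   (Tukey HSD pairwise), and `range` (one-row tibble).
#' @export
interspecific_range <- function(model) {
  sl <- marginal_slope(model, "Tstd", list(species = model$xlevels$species))
  C <- contrast_rows(
    model,
    make_reference_grid(model, at = list(species = model$xlevels$species)),
    derivative = "Tstd"
  )
  Sigma <- C %*% model$vcov %*% t(C)
  contrasts <- pairwise_contrasts(
    setNames(sl$estimate, sl$species), Sigma, model$df.residual,
    adjust = "tukey"
  )
  i_max <- which.max(sl$estimate)
  i_min <- which.min(sl$estimate)
  list(
    by_species = sl,
    contrasts = contrasts,
    range = tibble::tibble(
      max_slope = sl$estimate[i_max], max_species = sl$species[i_max],
      min_slope = sl$estimate[i_min], min_species = sl$species[i_min],
      range = sl$estimate[i_max] - sl$estimate[i_min]
    )
  )
}

#' Precipitation sensitivity
#'
#' Marginal slope of standardized precipitation (days/mm), averaged over
#' species and phenophases with temperature, MAT and IVT controlled;
#' optionally a full surface over the MAT x IVT grid.
#'
#' @param model Fitted global model.
#' @param surface If `TRUE`, also return the precipitation-sensitivity
#'   surface on the coarse grid.
#' @inheritParams intraspecific_range
#' @return A tibble (overall slope; `units` attribute `"days/mm"`), or a
#'   list with `overall` and `surface` when `surface = TRUE`.
#' @export
precipitation_sensitivity <- function(model, surface = FALSE,
                                      mat_range = c(-5, 15), mat_step = 1,
                                      ivt_range = c(0.4, 1.2), ivt_step = 0.1) {
  overall <- marginal_slope(model, "Pstd")
  attr(overall, "units") <- "days/mm"
  if (!surface) {
    return(overall)
  }
  list(
    overall = overall,
    surface = sensitivity_surface(model,
      mat_range = mat_range, mat_step = mat_step,
      ivt_range = ivt_range, ivt_step = ivt_step, focal = "Pstd"
    )
  )
}

#' Conditional effect of MAT on temperature sensitivity
#'
#' The second-order trend (change in the marginal temperature slope per degC
#' of MAT) evaluated overall (at the sample-mean IVT) and at fixed IVT
#' levels, mirroring the headline conditional-effect table: in high-IVT
#' regions MAT is a strong predictor of sensitivity, in low-IVT regions it
#' is not.
#'
#' @param model Fitted global model.
#' @param ivt_levels IVT values (s.d.) at which to condition the trend.
#' @return A tibble: `IVT` (`NA` for the overall row), `estimate`
#'   (delta sensitivity per degC MAT), `std.error`, `statistic`, `p.value`,
#'   `df`.
#' @export
mat_trend_profile <- function(model, ivt_levels = c(0.4, 0.8, 1.2)) {
  overall <- slope_trend(model, "Tstd", "MAT")
  overall <- dplyr::mutate(overall, IVT = NA_real_, .before = 1)
  by_ivt <- slope_trend(model, "Tstd", "MAT", list(IVT = ivt_levels))
  dplyr::bind_rows(overall, by_ivt)
}

#' Write a sensitivity surface as long-format CSV
#'
#' @param surface A [sensitivity_surface()].
#' @param path File path.
#' @export
write_surface <- function(surface, path) {
  readr::write_csv(tibble::as_tibble(surface), path)
  invisible(path)
}

#' Heat-map of a sensitivity surface
#'
#' @param object A [sensitivity_surface()].
#' @param ... Unused.
#' @return A ggplot: MAT on x, IVT on y, fill = marginal slope, facetted by
#'   species when the surface is species-specific.
#' @export
autoplot.sensitivity_surface <- function(object, ...) {
  p <- ggplot2::ggplot(
    tibble::as_tibble(object),
    ggplot2::aes(x = .data$MAT, y = .data$IVT, fill = .data$estimate)
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "units") %||% "days/degC") +
    ggplot2::labs(
      x = "MAT (degC)", y = "IVT (s.d.)",
      title = "Marginal temperature sensitivity"
    )
  if (isTRUE(attr(object, "by_species"))) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$species))
  }
  p
}

#' Geographic map of projected sensitivity
#'
#' @param mapped Output of [map_sensitivity()].
#' @return A ggplot of observation points coloured by estimated sensitivity.
#' @export
plot_sensitivity_map <- function(mapped) {
  ggplot2::ggplot(
    mapped,
    ggplot2::aes(x = .data$longitude, y = .data$latitude, colour = .data$estimate)
  ) +
    ggplot2::geom_point(size = 0.4) +
    ggplot2::scale_colour_viridis_c(name = "days/degC") +
    ggplot2::labs(x = "Longitude", y = "Latitude")
}
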
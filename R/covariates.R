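#' Mean-center values within groups
#'
#' Subtracts the group mean from each value; groups are centered
#' independently, so the grand mean of the output is generally nonzero when
#' group means differ.
#'
#' @param values Numeric vector.
#' @param groups Grouping vector (same length); each group must be non-empty
#'   and free of missing values.
#' @return Numeric vector of centered values.
#' @export
#' @examples
#' standardize(c(1, 3, 10, 14), c("a", "a", "b", "b"))
standardize <- function(values, groups) {
  if (length(values) == 0) abort("Cannot standardize an empty vector.")
  if (length(groups) != length(values)) abort("values and groups differ in length.")
  if (anyNA(values)) abort("Missing values in standardization input.")
  values - stats::ave(values, groups)
}

#' Derive per-record climate covariates
#'
#' For each observation: locates its 0.5-degree climate cell, computes the
#' seasonal mean temperature (`tmp`) and precipitation (`pre`) of the
#' observation year over the species' seasonal window (Jan--Mar for spring
#' bloomers, Mar--May for summer bloomers), mean-centers those within the
#' standardization group to give `Tstd` (degC) and `Pstd` (mm), and attaches
#' the cell's long-term `MAT` (degC) and `IVT` (s.d. degC) computed from
#' monthly minimum temperature over the grid's full span.
#'
#' @param observations Validated observation tibble with `id`, `species`,
#'   `latitude`, `longitude`, `year` columns (e.g. the `observations` element
#'   of [filter_observations()]).
#' @param grid A [climate_grid()].
#' @param grouping Standardization grouping: center within `"species"`
#'   (default), within `"species_continent"`, or globally.
#' @return The observation tibble with columns `cell`, `Tstd`, `Pstd`,
#'   `MAT`, `IVT` appended.
#' @export
add_climate_covariates <- function(observations, grid,
                                   grouping = c("species", "species_continent", "global")) {
  grouping <- match.arg(grouping)
  obs <- tibble::as_tibble(observations)
  if (nrow(obs) == 0) abort("No observations to derive covariates for.")
  obs$cell <- locate_cell(grid, obs$latitude, obs$longitude, id = obs$id)

  win <- season_window(obs$species)
  t_raw <- p_raw <- numeric(nrow(obs))
  for (w in unique(win)) {
    i <- win == w
    t_raw[i] <- seasonal_mean(grid, obs$cell[i], obs$year[i], w, var = "tmp")
    p_raw[i] <- seasonal_mean(grid, obs$cell[i], obs$year[i], w, var = "pre")
  }
  grp <- switch(grouping,
    species = obs$species,
    species_continent = paste(obs$species, obs$continent),
    global = rep("all", nrow(obs))
  )
  obs$Tstd <- standardize(t_raw, grp)
  obs$Pstd <- standardize(p_raw, grp)

  cell_ids <- sort(unique(obs$cell))
  mat <- compute_mat(grid, cell_ids)
  ivt <- compute_ivt(grid, cell_ids)
  obs$MAT <- mat[match(obs$cell, cell_ids)]
  obs$IVT <- ivt[match(obs$cell, cell_ids)]
  attr(obs, "standardization_grouping") <- grouping
  obs
}

#' Write a per-record covariate table
#'
#' @param covariates Output of [add_climate_covariates()].
#' @param path File path (`.csv`).
#' @export
write_covariates <- function(covariates, path) {
  cols <- c("id", "cell", "Tstd", "Pstd", "MAT", "IVT")
  readr::write_csv(covariates[, cols], path)
  invisible(path)
}
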
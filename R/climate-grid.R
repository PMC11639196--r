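#' Gridded monthly climate container
#'
#' An in-memory 0.5-degree gridded monthly climate series in the layout of
#' CRU TS: per cell and per month over a span of years, monthly mean
#' temperature (`tmp`, degC), monthly minimum temperature (`tmn`, degC) and
#' precipitation (`pre`, mm). Cells carry a continent label.
#'
#' @param cells Tibble with columns `cell` (integer id), `lat`, `lon` (cell
#'   centers, 0.5-degree spacing), `continent`.
#' @param years Integer vector of consecutive years.
#' @param tmp,tmn,pre Numeric arrays of dimension `c(ncell, nyear, 12)`.
#' @return An object of class `climate_grid`.
#' @export
climate_grid <- function(cells, years, tmp, tmn, pre) {
  cells <- tibble::as_tibble(cells)
  dims <- c(nrow(cells), length(years), 12L)
  for (nm in c("tmp", "tmn", "pre")) {
    a <- get(nm)
    if (!identical(dim(a), as.integer(dims))) {
      abort(paste0("Array '", nm, "' must have dimension [ncell, nyear, 12]."))
    }
  }
  lats <- sort(unique(cells$lat))
  lons <- sort(unique(cells$lon))
  spacing_ok <- function(v) length(v) < 2 || all(abs(diff(v) %% 0.5) < 1e-9)
  if (!spacing_ok(lats) || !spacing_ok(lons)) {
    abort("Cell centers must lie on a regular 0.5-degree lattice.")
  }
  if (any(tmn > tmp, na.rm = TRUE)) {
    abort("Minimum temperature exceeds mean temperature in some cell-months.")
  }
  structure(
    list(cells = cells, years = as.integer(years), tmp = tmp, tmn = tmn, pre = pre),
    class = "climate_grid"
  )
}

#' @export
print.climate_grid <- function(x, ...) {
  cat(
    "<climate_grid> ", nrow(x$cells), " cells x ", length(x$years),
    " years (", min(x$years), "-", max(x$years), ") x 12 months\n",
    sep = ""
  )
  cat(
    "  lat [", min(x$cells$lat), ", ", max(x$cells$lat), "], continents: ",
    paste(unique(x$cells$continent), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Default spatial layout for synthetic grids
#'
#' Two disjoint longitude bands, one per continent, spanning the shared
#' mid-latitude range of the study species.
#'
#' @return A list with `lat_range` and a `bands` tibble
#'   (`continent`, `lon_min`, `lon_max`).
#' @export
default_region_spec <- function() {
  list(
    lat_range = c(35, 65),
    bands = tibble::tibble(
      continent = c("North America", "Eurasia"),
      lon_min = c(-100, 5),
      lon_max = c(-91, 14)
    )
  )
}

#' Default climate gradient parameters
#'
#' Latitudinal and continental structure of long-term climate in the study
#' region: MAT cools with latitude while interannual variability (IVT) rises;
#' Eurasia is warmer and less variable than North America at equal latitude.
#' `seasonal_amplitude` is the half-range of the within-year temperature
#' cycle; `monthly_sd` is independent month-to-month weather noise;
#' `tmp_offset` is the mean offset of monthly mean over minimum temperature.
#'
#' @return Named list of generator parameters.
#' @export
default_gradient_params <- function() {
  list(
    mat_intercept = 24, # degC at latitude 0 (North America reference)
    mat_lapse = -0.45, # degC per degree latitude
    ivt_intercept = -0.05, # s.d. degC at latitude 0
    ivt_per_lat = 0.02, # s.d. per degree latitude
    eurasia_mat_offset = 4.91, # degC
    eurasia_ivt_offset = -0.22, # s.d. degC
    seasonal_amplitude = 10, # degC
    monthly_sd = 1.0, # degC
    tmp_offset = 5.0, # degC
    pre_mean = 60, # mm/month
    pre_amplitude = 20, # mm seasonal half-range
    pre_sd = 15 # mm month-to-month noise
  )
}

#' Generate a synthetic gridded climate
#'
#' Builds a 0.5-degree monthly climate series (1901--2021 by default) whose
#' long-term cell statistics follow configured latitudinal gradients and
#' continental offsets in MAT and IVT. Monthly minimum temperature is a
#' sinusoidal seasonal cycle around the cell's target MAT, plus an annual
#' anomaly shared by all months of a year (variance set so the realized
#' interannual s.d. of annual means matches the target IVT after accounting
#' for averaged monthly noise), plus independent monthly noise. Monthly mean
#' temperature shares the cycle and anomaly with a positive offset above the
#' minimum; precipitation is an independent seasonal cycle plus noise,
#' truncated at zero.
#'
#' @param region_spec See [default_region_spec()].
#' @param gradient_params See [default_gradient_params()].
#' @param seed Integer seed; the grid is reproducible bit-for-bit.
#' @param years Year span of the series.
#' @return A [climate_grid()].
#' @export
generate_climate_grid <- function(region_spec = default_region_spec(),
                                  gradient_params = default_gradient_params(),
                                  seed = 1L,
                                  years = 1901:2021) {
  p <- utils::modifyList(default_gradient_params(), gradient_params)
  rs <- region_spec
  if (diff(rs$lat_range) <= 0) abort("Non-positive latitude extent in region_spec.")
  if (any(rs$bands$lon_max <= rs$bands$lon_min)) {
    abort("Non-positive longitude extent in region_spec band.")
  }

  lat_centers <- seq(
    floor(rs$lat_range[1] * 2) / 2 + 0.25,
    ceiling(rs$lat_range[2] * 2) / 2 - 0.25, by = 0.5
  )
  cells <- purrr::pmap_dfr(rs$bands, function(continent, lon_min, lon_max) {
    lon_centers <- seq(
      floor(lon_min * 2) / 2 + 0.25,
      ceiling(lon_max * 2) / 2 - 0.25, by = 0.5
    )
    tidyr::expand_grid(lat = lat_centers, lon = lon_centers) |>
      dplyr::mutate(continent = continent)
  })
  cells <- dplyr::mutate(cells, cell = dplyr::row_number(), .before = 1)

  eurasia <- cells$continent == "Eurasia"
  mat_target <- p$mat_intercept + p$mat_lapse * cells$lat +
    ifelse(eurasia, p$eurasia_mat_offset, 0)
  ivt_target <- p$ivt_intercept + p$ivt_per_lat * cells$lat +
    ifelse(eurasia, p$eurasia_ivt_offset, 0)
  if (any(ivt_target <= 0)) {
    abort("IVT parameterization yields non-positive interannual variability in some cells.")
  }
  # Monthly noise averaged over 12 months adds monthly_sd^2/12 to the variance
  # of annual means; shrink the shared anomaly so realized IVT hits the target.
  anom_var <- ivt_target^2 - p$monthly_sd^2 / 12
  if (any(anom_var <= 0)) {
    abort("IVT target too small relative to monthly noise (monthly_sd^2/12).")
  }

  ncell <- nrow(cells)
  nyear <- length(years)
  cycle <- -p$seasonal_amplitude * cos(2 * pi * (1:12 - 1) / 12) # min in January
  pre_cycle <- p$pre_amplitude * sin(2 * pi * (1:12 - 1) / 12)

  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit(
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()),
    add = TRUE
  )

  anomaly <- matrix(rnorm(ncell * nyear, sd = rep(sqrt(anom_var), nyear)), ncell, nyear)
  base <- array(0, dim = c(ncell, nyear, 12L))
  base[] <- mat_target + anomaly[] # recycles [cell, year] over months
  base <- sweep(base, 3L, cycle, `+`)

  tmn <- base + array(rnorm(ncell * nyear * 12, sd = p$monthly_sd), dim = dim(base))
  tmp <- tmn + pmax(0.2, p$tmp_offset +
    array(rnorm(ncell * nyear * 12, sd = p$monthly_sd), dim = dim(base)))
  pre <- array(p$pre_mean, dim = dim(base))
  pre <- sweep(pre, 3L, pre_cycle, `+`) +
    array(rnorm(ncell * nyear * 12, sd = p$pre_sd), dim = dim(base))
  pre <- pmax(pre, 0)

  climate_grid(cells, years, tmp = tmp, tmn = tmn, pre = pre)
}

#' Locate the grid cell containing a point
#'
#' Cells are half-open 0.5-degree boxes `[lower, upper)` in both axes, so a
#' point exactly on a shared boundary belongs to the higher cell.
#'
#' @param grid A [climate_grid()].
#' @param latitude,longitude Numeric vectors of point coordinates.
#' @param id Optional record ids used in error messages.
#' @return Integer vector of cell ids.
#' @export
locate_cell <- function(grid, latitude, longitude, id = NULL) {
  center_of <- function(x) floor(x * 2) / 2 + 0.25
  key <- paste(center_of(latitude), center_of(longitude))
  cell_key <- paste(grid$cells$lat, grid$cells$lon)
  idx <- match(key, cell_key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))
    lab <- if (!is.null(id)) paste0(" (record ", id[bad[1]], ")") else ""
    abort(paste0(
      "Coordinate outside the climate grid: (",
      latitude[bad[1]], ", ", longitude[bad[1]], ")", lab, "."
    ))
  }
  cell <- grid$cells$cell[idx]
  all_missing <- apply(is.na(grid$tmn[cell, , , drop = FALSE]), 1L, all)
  if (any(all_missing)) {
    bad <- which(all_missing)
    lab <- if (!is.null(id)) paste0(" for record ", id[bad[1]]) else ""
    abort(paste0("Climate cell ", cell[bad[1]], " has an all-missing series", lab, "."))
  }
  cell
}

#' Seasonal mean of a monthly climate variable
#'
#' Arithmetic mean of the three monthly values in the seasonal window
#' (`"winter"` = Jan--Mar, `"spring"` = Mar--May) of a given year.
#'
#' @param grid A [climate_grid()].
#' @param cell Integer cell ids.
#' @param year Integer years (recycled against `cell`).
#' @param window `"winter"` or `"spring"`.
#' @param var `"tmp"`, `"tmn"`, or `"pre"`.
#' @return Numeric vector of seasonal means.
#' @export
seasonal_mean <- function(grid, cell, year, window, var = "tmp") {
  months <- window_months(window)
  yi <- match(year, grid$years)
  if (anyNA(yi)) abort("Year outside the climate grid series.")
  a <- grid[[var]]
  vals <- vapply(
    months,
    function(m) a[cbind(cell, yi, m)],
    numeric(length(cell))
  )
  out <- if (is.matrix(vals)) rowMeans(vals) else mean(vals)
  if (anyNA(out)) abort("Missing monthly values inside the seasonal window.")
  out
}

annual_min_means <- function(grid, cells = grid$cells$cell) {
  # [cell, year] matrix of annual means of monthly minimum temperature
  a <- grid$tmn[cells, , , drop = FALSE]
  m <- matrix(a, nrow = length(cells) * length(grid$years), ncol = 12L)
  matrix(rowMeans(m), nrow = length(cells))
}

#' Long-term MAT and IVT of grid cells
#'
#' `compute_mat()` is the long-term mean, and `compute_ivt()` the sample
#' standard deviation (denominator n-1), of annual means of monthly minimum
#' temperature over the grid's full year span.
#'
#' @param grid A [climate_grid()].
#' @param cell Integer cell ids (default: all cells).
#' @return Numeric vector, degC for MAT and s.d. degC for IVT.
#' @export
compute_mat <- function(grid, cell = grid$cells$cell) {
  ann <- annual_min_means(grid, cell)
  if (anyNA(ann)) abort("Missing months in the minimum-temperature series.")
  rowMeans(ann)
}

#' @rdname compute_mat
#' @export
compute_ivt <- function(grid, cell = grid$cells$cell) {
  ann <- annual_min_means(grid, cell)
  if (anyNA(ann)) abort("Missing months in the minimum-temperature series.")
  mu <- rowMeans(ann)
  sqrt(rowSums((ann - mu)^2) / (ncol(ann) - 1))
}

#' Per-cell climate summary
#'
#' @param grid A [climate_grid()].
#' @return The grid's `cells` tibble with `mat` and `ivt` columns appended.
#' @export
cell_climate_summary <- function(grid) {
  dplyr::mutate(grid$cells, mat = compute_mat(grid), ivt = compute_ivt(grid))
}

#' Read / write a climate grid as long-format CSV
#'
#' The on-disk format is a plain-text long table with one row per
#' cell-year-month and CRU TS variable names: columns `lat`, `lon`,
#' `continent`, `year`, `month`, `tmp`, `tmn`, `pre`. Round-tripping is
#' lossless up to numeric printing precision (full double precision is
#' written).
#'
#' @param grid A [climate_grid()].
#' @param path File path (`.csv`).
#' @return `read_climate_grid()` returns a [climate_grid()].
#' @export
write_climate_grid <- function(grid, path) {
  long <- tidyr::expand_grid(
    month = 1:12, year = grid$years, cell = grid$cells$cell
  )
  # expand_grid varies the last column fastest -> cell fastest matches array layout
  long$tmp <- as.vector(grid$tmp)
  long$tmn <- as.vector(grid$tmn)
  long$pre <- as.vector(grid$pre)
  long <- dplyr::left_join(long, grid$cells, by = "cell") |>
    dplyr::select("lat", "lon", "continent", "year", "month", "tmp", "tmn", "pre") |>
    dplyr::arrange(.data$lat, .data$lon, .data$year, .data$month)
  readr::write_csv(long, path)
  invisible(path)
}

#' @rdname write_climate_grid
#' @export
read_climate_grid <- function(path) {
  long <- readr::read_csv(
    path,
    col_types = readr::cols(
      lat = readr::col_double(), lon = readr::col_double(),
      continent = readr::col_character(),
      year = readr::col_integer(), month = readr::col_integer(),
      tmp = readr::col_double(), tmn = readr::col_double(),
      pre = readr::col_double()
    )
  )
  cells <- dplyr::distinct(long, .data$lat, .data$lon, .data$continent) |>
    dplyr::arrange(.data$lat, .data$lon) |>
    dplyr::mutate(cell = dplyr::row_number(), .before = 1)
  years <- sort(unique(long$year))
  long <- dplyr::left_join(long, cells, by = c("lat", "lon", "continent"))
  dims <- c(nrow(cells), length(years), 12L)
  mk <- function(v) {
    a <- array(NA_real_, dim = dims)
    a[cbind(long$cell, match(long$year, years), long$month)] <- long[[v]]
    a
  }
  climate_grid(cells, years, tmp = mk("tmp"), tmn = mk("tmn"), pre = mk("pre"))
}
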
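#' Classify a phenophase from organ presence flags
#'
#' Applies the four-stage "latest phenophase wins" labelling rule used to
#' annotate community-science images: a plant showing fruit is `fruiting`
#' regardless of other organs, else an open flower makes it `flowering`, else
#' an unopened bud makes it `budding`, and a plant with no reproductive parts
#' is `vegetative`.
#'
#' @param has_bud,has_flower,has_fruit Logical vectors (recycled to a common
#'   length) flagging the presence of unopened buds, open flowers, and fully
#'   formed fruits.
#' @return Character vector of phenophase labels.
#' @export
#' @examples
#' classify_phenophase(TRUE, TRUE, TRUE)   # fruiting
#' classify_phenophase(TRUE, FALSE, FALSE) # budding
classify_phenophase <- function(has_bud, has_flower, has_fruit) {
  n <- max(length(has_bud), length(has_flower), length(has_fruit))
  has_bud <- rep_len(as.logical(has_bud), n)
  has_flower <- rep_len(as.logical(has_flower), n)
  has_fruit <- rep_len(as.logical(has_fruit), n)
  dplyr::case_when(
    has_fruit ~ "fruiting",
    has_flower ~ "flowering",
    has_bud ~ "budding",
    .default = "vegetative"
  )
}

#' Day of year on the 1--365 scale
#'
#' Ordinal day of the calendar date, with 31 December of leap years clamped
#' to 365 so every record falls on the fixed 1--365 scale used as the model
#' response.
#'
#' @param date A `Date` vector (or something coercible via [as.Date()]).
#' @return Integer vector in `[1, 365]`; `NA` dates propagate.
#' @export
#' @examples
#' day_of_year(as.Date(c("2018-01-01", "2018-12-31", "2020-12-31")))
day_of_year <- function(date) {
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  pmin(doy, 365L)
}

phenophase_levels <- function() c("vegetative", "budding", "flowering", "fruiting")

#' Default excluded regions
#'
#' Bounding boxes (degrees) for regions dropped from analysis because they
#' fall outside the primary shared range of the study species: Iceland, the
#' Azores, eastern Asia, and Australia. The named regions have no canonical
#' boundaries, so the boxes are configuration, not data.
#'
#' @return A tibble with columns `region`, `lat_min`, `lat_max`, `lon_min`,
#'   `lon_max`.
#' @export
default_excluded_regions <- function() {
  tibble::tribble(
    ~region,        ~lat_min, ~lat_max, ~lon_min, ~lon_max,
    "Iceland",          63.0,     67.0,    -25.0,    -13.0,
    "Azores",           36.5,     40.0,    -31.5,    -24.5,
    "eastern Asia",    -10.0,     80.0,     90.0,    180.0,
    "Australia",       -45.0,    -10.0,    110.0,    155.0
  )
}

in_regions <- function(lat, lon, regions) {
  hit <- rep(FALSE, length(lat))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    hit <- hit | (!is.na(lat) & !is.na(lon) &
      lat >= r$lat_min & lat <= r$lat_max &
      lon >= r$lon_min & lon <= r$lon_max)
  }
  hit
}

#' Validate an observation table against the schema
#'
#' Checks column presence and types, species membership, coordinate and DOY
#' ranges, and phenophase labels. Missing values are allowed (they are what
#' [filter_observations()] removes); out-of-range non-missing values are not.
#'
#' @param observations A data frame with columns `id`, `species`, `date`,
#'   `latitude`, `longitude`, `continent`, `phenophase`.
#' @return The table as a tibble, with `date` parsed to `Date`, `doy` and
#'   `year` columns added, invisibly checkable.
#' @export
validate_observations <- function(observations) {
  req <- c("id", "species", "date", "latitude", "longitude", "continent", "phenophase")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols) > 0) {
    abort(paste0("Observation table lacks columns: ", paste(missing_cols, collapse = ", ")))
  }
  obs <- tibble::as_tibble(observations)
  obs$date <- as.Date(obs$date)
  known <- study_species()$species
  bad_sp <- setdiff(unique(obs$species[!is.na(obs$species)]), known)
  if (length(bad_sp) > 0) {
    abort(paste0("Unknown species label(s): ", paste(bad_sp, collapse = ", ")))
  }
  bad_ph <- setdiff(unique(obs$phenophase[!is.na(obs$phenophase)]), phenophase_levels())
  if (length(bad_ph) > 0) {
    abort(paste0("Unknown phenophase label(s): ", paste(bad_ph, collapse = ", ")))
  }
  ok_lat <- is.na(obs$latitude) | (obs$latitude >= -90 & obs$latitude <= 90)
  ok_lon <- is.na(obs$longitude) | (obs$longitude >= -180 & obs$longitude <= 180)
  if (!all(ok_lat) || !all(ok_lon)) {
    abort("Coordinates outside [-90, 90] latitude / [-180, 180] longitude.")
  }
  obs$doy <- day_of_year(obs$date)
  obs$year <- as.integer(strftime(obs$date, "%Y"))
  if (any(is.na(obs$continent) & !is.na(obs$longitude))) {
    obs$continent <- dplyr::if_else(
      is.na(obs$continent) & !is.na(obs$longitude),
      dplyr::if_else(obs$longitude > -30, "Eurasia", "North America"),
      obs$continent
    )
  }
  obs
}

#' Filter observations by the curation rules
#'
#' Applies the exclusion rules sequentially, in order: (1) records missing
#' coordinates or observation date (`missing_meta`); (2) records whose
#' phenophase could not be annotated, encoded as missing phenophase
#' (`unannotatable`); (3) vegetative records, which are unconstrained in time
#' and uninformative about reproductive sensitivity (`vegetative`);
#' (4) records inside excluded regions (`excluded_region`). A record is
#' counted once, in the first category it matches, so the per-category counts
#' sum with the retained count to the input count.
#'
#' @param observations Observation table (validated by
#'   [validate_observations()], which this calls).
#' @param excluded_regions Bounding-box tibble; defaults to
#'   [default_excluded_regions()].
#' @return An object of class `pheno_filter`: a list with `observations`
#'   (retained tibble) and `report` (tibble of `category`, `n`, including a
#'   `retained` row).
#' @export
#' @examples
#' obs <- tibble::tibble(
#'   id = 1:3, species = "Daucus carota",
#'   date = as.Date(c("2018-07-01", NA, "2018-07-03")),
#'   latitude = c(45, 45, 46), longitude = c(-75, -75, -74),
#'   continent = "North America",
#'   phenophase = c("flowering", "flowering", "vegetative")
#' )
#' filter_observations(obs)$report
filter_observations <- function(observations, excluded_regions = default_excluded_regions()) {
  obs <- validate_observations(observations)
  n_in <- nrow(obs)

  missing_meta <- is.na(obs$latitude) | is.na(obs$longitude) | is.na(obs$date)
  remaining <- !missing_meta
  unannotatable <- remaining & is.na(obs$phenophase)
  remaining <- remaining & !unannotatable
  vegetative <- remaining & obs$phenophase == "vegetative"
  remaining <- remaining & !vegetative
  excluded_region <- remaining &
    in_regions(obs$latitude, obs$longitude, excluded_regions)
  remaining <- remaining & !excluded_region

  report <- tibble::tibble(
    category = c("missing_meta", "unannotatable", "vegetative", "excluded_region", "retained"),
    n = c(
      sum(missing_meta), sum(unannotatable), sum(vegetative),
      sum(excluded_region), sum(remaining)
    )
  )
  stopifnot(sum(report$n) == n_in)
  structure(
    list(observations = obs[remaining, , drop = FALSE], report = report),
    class = "pheno_filter"
  )
}

#' @export
print.pheno_filter <- function(x, ...) {
  cat("<pheno_filter> ", nrow(x$observations), " records retained\n", sep = "")
  print(x$report)
  invisible(x)
}

#' Read / write the observation CSV schema
#'
#' The fixed schema is `id,species,date,latitude,longitude,continent,phenophase`
#' with ISO dates; round-tripping through these functions is lossless.
#'
#' @param path File path.
#' @return `read_observations()` returns a validated tibble.
#' @export
read_observations <- function(path) {
  obs <- readr::read_csv(
    path,
    col_types = readr::cols(
      id = readr::col_character(),
      species = readr::col_character(),
      date = readr::col_date(),
      latitude = readr::col_double(),
      longitude = readr::col_double(),
      continent = readr::col_character(),
      phenophase = readr::col_character()
    )
  )
  validate_observations(obs)
}

#' @param observations Observation tibble.
#' @rdname read_observations
#' @export
write_observations <- function(observations, path) {
  cols <- c("id", "species", "date", "latitude", "longitude", "continent", "phenophase")
  readr::write_csv(observations[, cols], path)
  invisible(path)
}
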
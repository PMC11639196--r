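#' Study species and their seasonal standardization windows
#'
#' The six widespread herbaceous species tracked by the pipeline, each present
#' across Eurasia (native) and North America (introduced). Species that bloom
#' in spring are standardized against winter climate (January--March of the
#' observation year); summer bloomers against spring climate (March--May),
#' because reproductive phenology responds most strongly to conditions
#' directly preceding the event.
#'
#' @return A tibble with columns `species` (scientific name), `season`
#'   (`"spring"` or `"summer"`), and `window` (`"winter"` = Jan--Mar,
#'   `"spring"` = Mar--May), one row per species.
#' @export
#' @examples
#' study_species()
study_species <- function() {
  tibble::tibble(
    species = c(
      "Tussilago farfara", "Ficaria verna", "Alliaria petiolata",
      "Cirsium arvense", "Daucus carota", "Lythrum salicaria"
    ),
    season = rep(c("spring", "summer"), each = 3L),
    window = rep(c("winter", "spring"), each = 3L)
  )
}

#' Seasonal group of a study species
#'
#' Maps each study species to its blooming season, which determines the
#' three-month climate window used to standardize temperature and
#' precipitation for its records.
#'
#' @param species Character vector of scientific names; must be among the six
#'   study species (see [study_species()]).
#' @return Character vector, `"spring"` or `"summer"`, same length as input.
#' @export
#' @examples
#' assign_season_group(c("Tussilago farfara", "Lythrum salicaria"))
assign_season_group <- function(species) {
  tbl <- study_species()
  idx <- match(species, tbl$species)
  if (anyNA(idx)) {
    bad <- unique(species[is.na(idx)])
    abort(paste0(
      "Unknown species: ", paste(bad, collapse = ", "),
      ". Expected one of: ", paste(tbl$species, collapse = ", ")
    ))
  }
  tbl$season[idx]
}

#' Seasonal climate window (months) for a species
#'
#' @param species Character vector of study species names.
#' @return Integer list-column free representation: a character vector of
#'   window names, `"winter"` (months 1--3) or `"spring"` (months 3--5).
#' @keywords internal
season_window <- function(species) {
  ifelse(assign_season_group(species) == "spring", "winter", "spring")
}

window_months <- function(window) {
  switch(window,
    winter = 1:3,
    spring = 3:5,
    abort(paste0("Unknown seasonal window '", window, "'; use 'winter' or 'spring'."))
  )
}
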
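#' Default run configuration
#'
#' @return Named list of defaults for [run_all()]: a synthetic-generation
#'   block, standardization grouping, grid specifications for the fine
#'   (surface) and coarse (range) analyses, and a seed.
#' @export
default_config <- function() {
  list(
    observations_csv = NULL,
    climate_csv = NULL,
    synthetic = list(
      n_per_species_continent = 200L,
      truth = list() # overrides to sensitivity_truth() defaults
    ),
    grouping = "species",
    surface_grid = list(
      mat_range = c(-5, 15), mat_step = 0.2,
      ivt_range = c(0.4, 1.2), ivt_step = 0.05
    ),
    range_grid = list(
      mat_range = c(-5, 15), mat_step = 1,
      ivt_range = c(0.4, 1.2), ivt_step = 0.1
    ),
    ivt_levels = c(0.4, 0.8, 1.2),
    seed = 1L
  )
}

#' Validate and normalize a run configuration
#'
#' Fills defaults, rejects unknown keys, requires exactly one input source
#' (real observation + climate files, or the synthetic block), and checks
#' grid specifications (positive steps no larger than their range).
#'
#' @param config Named list (e.g. parsed from a YAML file via
#'   [yaml::read_yaml()]), or a path to such a file.
#' @return The normalized config list, with defaults echoed.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  known <- names(default_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(default_config(), config, keep.null = TRUE)

  real <- !is.null(cfg$observations_csv) || !is.null(cfg$climate_csv)
  synth <- !is.null(config$synthetic)
  if (real && synth) {
    abort("Config must activate exactly one of real inputs or the synthetic block.")
  }
  if (real) {
    if (is.null(cfg$observations_csv) || is.null(cfg$climate_csv)) {
      abort("Real-data runs need both observations_csv and climate_csv.")
    }
    for (p in c(cfg$observations_csv, cfg$climate_csv)) {
      if (!file.exists(p)) abort(paste0("Input file not found: ", p))
    }
    cfg$synthetic <- NULL
  }
  if (!cfg$grouping %in% c("species", "species_continent", "global")) {
    abort("grouping must be species, species_continent or global.")
  }
  for (g in c("surface_grid", "range_grid")) {
    gs <- cfg[[g]]
    for (ax in c("mat", "ivt")) {
      rng <- gs[[paste0(ax, "_range")]]
      stp <- gs[[paste0(ax, "_step")]]
      if (stp <= 0 || stp > diff(range(rng))) {
        abort(paste0(g, ": ", ax, " step must be positive and no larger than the range."))
      }
    }
  }
  cfg$seed <- as.integer(cfg$seed)
  cfg
}

log_line <- function(con, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " INFO ", paste0(...))
  writeLines(msg, con)
}

#' Run the full sensitivity pipeline
#'
#' Executes every stage in order -- generate (or read) inputs, curate
#' observations, derive climate covariates, fit the spatial-gradient and global models,
#' and produce the sensitivity surface, geographic projection, variation
#' ranges and conditional-trend table -- writing all outputs as CSV under
#' `outdir` together with a log (exclusion report, fit statistics) and a
#' manifest of output files with content hashes. Deterministic under a fixed
#' seed.
#'
#' @param config A config list or YAML path (see [validate_config()]).
#' @param outdir Output directory (created if missing).
#' @param seed Optional integer overriding the config seed.
#' @return Invisibly, a list with the fitted models, result tables, and the
#'   manifest tibble.
#' @export
run_all <- function(config = list(), outdir = tempfile("phenosense_run"), seed = NULL) {
  cfg <- validate_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  logcon <- file(file.path(outdir, "run.log"), open = "wt")
  on.exit(close(logcon), add = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("Stage '", name, "' failed: ", conditionMessage(e)))
    })
  }

  if (!is.null(cfg$synthetic)) {
    log_line(logcon, "stage simulate: seed ", cfg$seed)
    truth <- stage("simulate", do.call(sensitivity_truth, cfg$synthetic$truth))
    grid <- stage("simulate", generate_climate_grid(seed = cfg$seed))
    raw <- stage("simulate", generate_observations(
      grid, truth,
      n_per_species_continent = cfg$synthetic$n_per_species_continent,
      seed = cfg$seed + 1L, grouping = cfg$grouping
    ))
    write_truth(truth, file.path(outdir, "truth.yml"))
    write_observations(raw, file.path(outdir, "observations.csv"))
  } else {
    log_line(logcon, "stage read: ", cfg$observations_csv)
    raw <- stage("read", read_observations(cfg$observations_csv))
    grid <- stage("read", read_climate_grid(cfg$climate_csv))
  }

  log_line(logcon, "stage prepare: ", nrow(raw), " raw records")
  filt <- stage("prepare", filter_observations(raw))
  for (i in seq_len(nrow(filt$report))) {
    log_line(logcon, "  exclusion ", filt$report$category[i], ": ", filt$report$n[i])
  }
  readr::write_csv(filt$report, file.path(outdir, "exclusion_report.csv"))
  obs <- stage("covariates", add_climate_covariates(
    filt$observations, grid,
    grouping = cfg$grouping
  ))
  write_covariates(obs, file.path(outdir, "covariates.csv"))

  log_line(logcon, "stage fit: global model on ", nrow(obs), " records")
  gradients <- stage("fit", fit_climate_gradients(obs))
  gradients_ph <- stage("fit", fit_phenology_gradients(obs))
  global <- stage("fit", fit_global(obs))
  log_line(
    logcon, "  global fit: AIC ", format(global$aic, digits = 10),
    ", adj R^2 ", format(global$adj.r.squared, digits = 4),
    ", kurtosis ", format(residual_kurtosis(global), digits = 3)
  )
  readr::write_csv(tidy(global), file.path(outdir, "global_coefficients.csv"))
  readr::write_csv(glance(global), file.path(outdir, "global_fit_stats.csv"))

  log_line(logcon, "stage sensitivity")
  sg <- cfg$surface_grid
  rg <- cfg$range_grid
  surf <- stage("sensitivity", do.call(sensitivity_surface, c(list(global), sg)))
  write_surface(surf, file.path(outdir, "sensitivity_surface.csv"))
  mapped <- stage("sensitivity", map_sensitivity(obs, global))
  readr::write_csv(mapped, file.path(outdir, "sensitivity_map.csv"))
  intra <- stage("sensitivity", do.call(intraspecific_range, c(list(global), rg)))
  readr::write_csv(intra, file.path(outdir, "intraspecific_range.csv"))
  inter <- stage("sensitivity", interspecific_range(global))
  readr::write_csv(inter$by_species, file.path(outdir, "interspecific_slopes.csv"))
  readr::write_csv(inter$contrasts, file.path(outdir, "interspecific_contrasts.csv"))
  trend <- stage("sensitivity", mat_trend_profile(global, cfg$ivt_levels))
  readr::write_csv(trend, file.path(outdir, "mat_trend_profile.csv"))
  precip <- stage("sensitivity", precipitation_sensitivity(global))
  readr::write_csv(precip, file.path(outdir, "precipitation_sensitivity.csv"))

  yaml::write_yaml(cfg, file.path(outdir, "config_used.yml"))
  files <- setdiff(list.files(outdir), c("manifest.csv", "run.log"))
  manifest <- tibble::tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    seed = cfg$seed
  )
  readr::write_csv(manifest, file.path(outdir, "manifest.csv"))
  log_line(logcon, "done: ", nrow(manifest), " outputs in ", outdir)

  invisible(list(
    config = cfg, observations = obs, exclusion_report = filt$report,
    climate_gradients = gradients, phenology_gradients = gradients_ph, global = global,
    surface = surf, mapped = mapped, intraspecific = intra,
    interspecific = inter, mat_trend = trend, precipitation = precip,
    manifest = manifest, outdir = outdir
  ))
}
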
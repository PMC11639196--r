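# Shared fixtures and independent oracles. Heavy objects are memoised so each
# test session pays for them once.

.fix <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fix[[name]])) .fix[[name]] <- force(expr)
  .fix[[name]]
}

# A hand-built 6-cell grid (2 lat x 3 lon; one Eurasian column) over 4 years,
# with fully controlled monthly values for exact arithmetic checks.
tiny_grid <- function(tmn_fun = function(cell, year, month) 5,
                      tmp_offset = 6, pre_val = 50) {
  cells <- tibble::tibble(
    cell = 1:6,
    lat = rep(c(45.25, 45.75), 3),
    lon = rep(c(-95.75, -95.25, 5.25), each = 2),
    continent = rep(c("North America", "North America", "Eurasia"), each = 2)
  )
  years <- 2016:2019
  a <- array(0, dim = c(6, 4, 12))
  for (c_ in 1:6) {
    for (y in 1:4) {
      for (m in 1:12) a[c_, y, m] <- tmn_fun(c_, years[y], m)
    }
  }
  climate_grid(cells, years,
    tmp = a + tmp_offset, tmn = a,
    pre = array(pre_val, dim = dim(a))
  )
}

# Toy observation table exercising every exclusion category.
toy_observations <- function() {
  tibble::tibble(
    id = sprintf("r%02d", 1:10),
    species = c(rep("Daucus carota", 5), rep("Tussilago farfara", 5)),
    date = as.Date(c(
      "2018-07-01", NA, "2018-07-03", "2018-07-04", "2018-07-05",
      "2018-03-10", "2018-03-11", "2018-03-12", "2018-03-13", "2018-03-14"
    )),
    latitude = c(45.1, 45.2, NA, 45.4, 45.5, 50.1, 50.2, 50.3, 64.5, 50.5),
    longitude = c(-75.1, -75.2, -75.3, -75.4, -75.5, 10.1, 10.2, 10.3, -19.0, 10.5),
    continent = c(rep("North America", 5), rep("Eurasia", 3), "Eurasia", "Eurasia"),
    phenophase = c(
      "flowering", "flowering", "budding", NA, "vegetative",
      "flowering", "fruiting", "vegetative", "flowering", "budding"
    )
  )
}

# Medium synthetic dataset + fitted global model shared across files.
fix_grid <- function() memo("grid", generate_climate_grid(seed = 101))
fix_obs <- function() {
  memo("obs", generate_observations(
    fix_grid(), sensitivity_truth(),
    n_per_species_continent = 300, seed = 202
  ))
}
fix_fit <- function() memo("fit", fit_global(fix_obs()))

# Independent oracles ---------------------------------------------------------

# Brute-force marginal mean: predict at every grid point, then weight-average.
brute_marginal_mean <- function(lmfit, grid) {
  pred <- stats::predict(lmfit, newdata = as.data.frame(grid))
  vapply(
    split(seq_len(nrow(grid)), grid$.group),
    function(i) sum(pred[i] * grid$.weight[i]),
    0
  )
}

# Centered finite difference of brute-force marginal means (exact for models
# linear in the focal covariate).
brute_marginal_slope <- function(lmfit, grid, focal, h = 0.5) {
  up <- down <- as.data.frame(grid)
  up[[focal]] <- up[[focal]] + h
  down[[focal]] <- down[[focal]] - h
  (brute_marginal_mean(lmfit, up) - brute_marginal_mean(lmfit, down)) / (2 * h)
}

# Random small model instances for property suites: 1-2 factors, 1-2
# covariates, random interaction structure.
random_model_case <- function(seed) {
  set.seed(seed)
  n <- 80
  d <- data.frame(
    y = rnorm(n),
    f1 = factor(sample(letters[1:3], n, replace = TRUE)),
    f2 = factor(sample(c("u", "v"), n, replace = TRUE)),
    x1 = rnorm(n),
    x2 = rnorm(n)
  )
  forms <- list(
    y ~ x1 * f1,
    y ~ x1 * x2 * f1,
    y ~ x1 * f1 + x2 * f2,
    y ~ x1 * x2 * f1 + f2,
    y ~ x1 * f1 * f2 + x2
  )
  f <- forms[[1 + seed %% length(forms)]]
  d$y <- d$y + d$x1 * (1 + as.integer(d$f1)) + d$x2 * as.integer(d$f2)
  list(data = d, formula = f)
}

rlaplace <- function(n, scale = 1) {
  u <- runif(n, -0.5, 0.5)
  -scale * sign(u) * log(1 - 2 * abs(u))
}
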
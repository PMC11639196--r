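test_that("surface grids have the documented node counts and regular axes", {
  fit <- fix_fit()
  surf <- sensitivity_surface(fit)
  expect_equal(nrow(surf), 101 * 17)
  expect_equal(length(attr(surf, "mat_axis")), 101)
  expect_equal(length(attr(surf, "ivt_axis")), 17)
  expect_equal(unique(round(diff(attr(surf, "mat_axis")), 10)), 0.2)

  coarse <- sensitivity_surface(fit, mat_step = 1, ivt_step = 0.1)
  expect_equal(nrow(coarse), 21 * 9)

  expect_error(sensitivity_surface(fit, mat_step = 0.3), "does not divide")
})

test_that("species-specific surfaces average back to the pooled surface", {
  fit <- fix_fit()
  pooled <- sensitivity_surface(fit, mat_step = 5, ivt_step = 0.4)
  by_sp <- sensitivity_surface(fit, mat_step = 5, ivt_step = 0.4, by_species = TRUE)
  avg <- tibble::as_tibble(by_sp) |>
    dplyr::group_by(MAT, IVT) |>
    dplyr::summarise(estimate = mean(estimate), .groups = "drop") |>
    dplyr::arrange(MAT, IVT)
  pooled_sorted <- tibble::as_tibble(pooled) |> dplyr::arrange(MAT, IVT)
  expect_equal(pooled_sorted$estimate, avg$estimate, tolerance = 1e-8)
})

test_that("surface recovers the synthetic truth within 3 standard errors", {
  fit <- fix_fit()
  truth <- sensitivity_truth()
  surf <- sensitivity_surface(fit, mat_step = 2, ivt_step = 0.2)
  tr <- truth_slope(truth, surf$MAT, surf$IVT)
  z <- abs(surf$estimate - tr) / surf$std.error
  expect_gt(mean(z < 3), 0.95)
})

test_that("sensitivity maps onto records at their exact covariates", {
  fit <- fix_fit()
  obs <- fix_obs()
  mapped <- map_sensitivity(obs[1:200, ], fit)
  expect_equal(nrow(mapped), 200)
  # records sharing a climate cell share the estimate
  same_cell <- obs$cell[1:200]
  split_est <- split(mapped$estimate, same_cell)
  expect_true(all(vapply(split_est, function(x) diff(range(x)) == 0, TRUE)))
  # a record whose MAT/IVT sits on a surface node equals the node value
  node <- marginal_slope(fit, "Tstd", list(MAT = mapped$MAT[1], IVT = mapped$IVT[1]))
  expect_equal(mapped$estimate[1], node$estimate, tolerance = 1e-10)
  # truth recovery at record climates
  tr <- truth_slope(sensitivity_truth(), mapped$MAT, mapped$IVT)
  expect_gt(mean(abs(mapped$estimate - tr) / mapped$std.error < 3), 0.95)

  expect_error(map_sensitivity(obs[1:5, c("id", "latitude")], fit), "lack MAT/IVT")
})

test_that("intraspecific range equals the corner oracle for bilinear surfaces", {
  fit <- fix_fit()
  rng <- intraspecific_range(fit)
  surf <- sensitivity_surface(fit, mat_step = 1, ivt_step = 0.1)
  expect_equal(rng$range, max(surf$estimate) - min(surf$estimate))
  # the pooled marginal slope is bilinear in (MAT, IVT), so both extremes sit
  # at corners of the climate box
  corners <- suppressWarnings(
    marginal_slope(fit, "Tstd", list(MAT = c(-5, 15), IVT = c(0.4, 1.2)))
  )
  expect_equal(rng$range, max(corners$estimate) - min(corners$estimate),
    tolerance = 1e-10
  )
  expect_equal(rng$max_slope - rng$min_slope, rng$range)
})

test_that("interspecific slopes recover the configured species offsets", {
  fit <- fix_fit()
  inter <- interspecific_range(fit)
  expect_equal(nrow(inter$by_species), 6)
  expect_equal(nrow(inter$contrasts), choose(6, 2))
  truth <- sensitivity_truth()
  # per-species slope at sample-mean climate = shared surface + species offset
  obs <- fix_obs()
  tr <- truth_slope(truth, mean(obs$MAT), mean(obs$IVT),
    species = inter$by_species$species
  )
  z <- (inter$by_species$estimate - tr) / inter$by_species$std.error
  expect_true(all(abs(z) < 3.5))
  # species-averaged slopes reproduce the pooled overall slope
  expect_equal(mean(inter$by_species$estimate),
    marginal_slope(fit, "Tstd")$estimate,
    tolerance = 1e-8
  )
  expect_true(all(inter$contrasts$adjust == "tukey"))
  expect_gt(inter$range$range, 1) # offsets span > 2 days/degC in truth
})

test_that("precipitation sensitivity is recovered with its units", {
  fit <- fix_fit()
  ps <- precipitation_sensitivity(fit)
  expect_equal(attr(ps, "units"), "days/mm")
  truth <- sensitivity_truth()
  expect_lt(abs(ps$estimate - truth$betaP) / ps$std.error, 3)

  both <- precipitation_sensitivity(fit, surface = TRUE)
  expect_equal(attr(both$surface, "units"), "days/mm")
  expect_equal(nrow(both$surface), 21 * 9)
})

test_that("zero-interaction models give flat MAT trends across IVT", {
  set.seed(5)
  d <- data.frame(doy = rnorm(200), Tstd = rnorm(200), MAT = rnorm(200), IVT = rnorm(200))
  d$doy <- d$doy + d$Tstd * (1 + 0.2 * d$MAT)
  fit <- fit_phenology_model(d, doy ~ Tstd * MAT + IVT)
  prof <- mat_trend_profile(fit, ivt_levels = c(0.4, 0.8, 1.2))
  expect_equal(nrow(prof), 4) # overall + three IVT levels
  expect_equal(unique(round(prof$estimate, 12)), round(prof$estimate[1], 12))
  expect_equal(prof$estimate[1], unname(coef(fit)["Tstd:MAT"]), tolerance = 1e-12)
})

test_that("MAT trend profile matches the finite-difference oracle", {
  fit <- fix_fit()
  prof <- mat_trend_profile(fit)
  h <- 0.5
  for (i in 2:4) {
    v <- prof$IVT[i]
    fd <- (marginal_slope(fit, "Tstd", list(MAT = h, IVT = v))$estimate -
      marginal_slope(fit, "Tstd", list(MAT = -h, IVT = v))$estimate) / (2 * h)
    expect_equal(prof$estimate[i], fd, tolerance = 1e-8)
  }
  # truth check: gammaM + gammaMV * IVT
  truth <- sensitivity_truth()
  tr <- truth$gammaM + truth$gammaMV * prof$IVT[2:4]
  expect_true(all(abs(prof$estimate[2:4] - tr) / prof$std.error[2:4] < 3))
})

test_that("surface plots build without error", {
  fit <- fix_fit()
  surf <- sensitivity_surface(fit, mat_step = 5, ivt_step = 0.4)
  p <- autoplot(surf)
  expect_s3_class(p, "ggplot")
  mapped <- map_sensitivity(fix_obs()[1:50, ], fit)
  expect_s3_class(plot_sensitivity_map(mapped), "ggplot")
})
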
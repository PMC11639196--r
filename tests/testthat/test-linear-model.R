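test_that("design matrix expands treatment-coded interactions", {
  d <- data.frame(
    doy = rnorm(20), Tstd = rnorm(20),
    species = rep(c("Daucus carota", "Tussilago farfara"), 10)
  )
  dm <- build_design_matrix(d, doy ~ Tstd * species)
  expect_equal(ncol(dm$X), 4) # intercept, Tstd, species dummy, product
  expect_true("(Intercept)" %in% colnames(dm$X))
  d$species <- "Daucus carota"
  expect_error(build_design_matrix(d, doy ~ Tstd * species), "fewer than 2")
  expect_error(build_design_matrix(d, doy ~ Tstd * nothere), "absent from data")
})

test_that("global design width matches the symbolic expansion count", {
  obs <- fix_obs()
  dm <- build_design_matrix(obs, global_model_formula())
  # independent combinatorial count: treatment coding gives prod(levels - 1)
  # dummies per interaction; the three 4-way blocks share the MAT/IVT/species
  # margin, counted once
  dums <- c(Tstd = 1, Pstd = 1, MAT = 1, IVT = 1, species = 5, phenophase = 2)
  count_block <- function(vars, must_contain = NULL) {
    total <- 0
    for (k in 0:length(vars)) {
      for (s in utils::combn(length(vars), k, simplify = FALSE)) {
        sub <- vars[s]
        if (!is.null(must_contain) && !(must_contain %in% sub)) next
        total <- total + prod(dums[sub], na.rm = TRUE)
      }
    }
    total
  }
  expected <- count_block(c("Tstd", "MAT", "IVT", "species")) +
    count_block(c("Pstd", "MAT", "IVT", "species"), must_contain = "Pstd") +
    count_block(c("phenophase", "MAT", "IVT", "species"), must_contain = "phenophase")
  expect_equal(ncol(dm$X), expected)
  expect_equal(expected, 120)
})

test_that("OLS matches the normal-equations oracle on random instances", {
  for (seed in 1:20) {
    set.seed(seed)
    X <- cbind(1, matrix(rnorm(50 * 3), 50, 3))
    colnames(X) <- c("(Intercept)", "a", "b", "c")
    y <- rnorm(50)
    fit <- fit_ols(X, y)
    beta_oracle <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(fit$coefficients), unname(drop(beta_oracle)), tolerance = 1e-8)
    s2 <- sum((y - X %*% beta_oracle)^2) / (50 - 4)
    expect_equal(unname(fit$vcov), unname(s2 * solve(crossprod(X))), tolerance = 1e-8)
  }
})

test_that("OLS exactness, intercept-only mean, and AIC convention", {
  x <- seq_len(30)
  y <- 2 + 3 * x
  fit <- fit_ols(cbind(`(Intercept)` = 1, x = x), y)
  expect_equal(max(abs(fit$residuals)), 0, tolerance = 1e-10)
  expect_equal(fit$adj.r.squared, 1, tolerance = 1e-12)

  y2 <- rnorm(30, mean = 5)
  fit2 <- fit_ols(matrix(1, 30, 1, dimnames = list(NULL, "(Intercept)")), y2)
  expect_equal(unname(fit2$coefficients), mean(y2))

  d <- data.frame(y = rnorm(40), x = rnorm(40), z = rnorm(40))
  ours <- fit_phenology_model(d, y ~ x + z)
  ref <- stats::lm(y ~ x + z, data = d)
  expect_equal(ours$aic, stats::AIC(ref), tolerance = 1e-8)
  expect_equal(ours$adj.r.squared, summary(ref)$adj.r.squared, tolerance = 1e-10)
  expect_equal(
    unname(ours$coefficients), unname(coef(ref)),
    tolerance = 1e-10
  )
})

test_that("rank deficiency is an error naming the aliased columns", {
  X <- cbind(`(Intercept)` = 1, a = 1:20, b = 2 * (1:20))
  expect_error(fit_ols(X, rnorm(20)), "rank deficient.*b")
  expect_error(fit_ols(X[1:2, ], rnorm(2)), "more observations")
})

test_that("AIC selection ranks the true structure first under strong signal", {
  set.seed(42)
  d <- data.frame(x = rnorm(300), f = factor(sample(c("a", "b"), 300, TRUE)))
  d$y <- 2 * d$x * (d$f == "b") + rnorm(300, sd = 0.5)
  sel <- aic_select(d, list(null = y ~ 1, true = y ~ x * f))
  expect_equal(sel$table$model[1], "true")
  expect_gt(sel$table$delta_AIC[2], 10)

  sel2 <- aic_select(d, list(m1 = y ~ x, m2 = y ~ x))
  expect_equal(sel2$table$delta_AIC, c(0, 0))
})

test_that("AIC penalizes a pure-noise covariate in most replicates", {
  wins <- 0
  for (seed in 1:15) {
    set.seed(seed)
    d <- data.frame(x = rnorm(500), junk = rnorm(500))
    d$y <- d$x + rnorm(500)
    sel <- aic_select(d, list(simple = y ~ x, extra = y ~ x + junk))
    wins <- wins + (sel$table$model[1] == "simple")
  }
  expect_gt(wins, 7)
})

test_that("AIC candidates must share rows; rescaling shifts AIC as expected", {
  d <- data.frame(y = rnorm(50), x = rnorm(50), z = rnorm(50))
  d$z[1] <- NA
  expect_error(aic_select(d, list(a = y ~ x, b = y ~ z)), "different row subsets")

  # covariate rescaling leaves AIC unchanged; response scaling by `a` shifts
  # every model's AIC by 2 n log(a), so rankings are invariant
  d2 <- data.frame(y = rnorm(60), x = rnorm(60))
  f1 <- fit_phenology_model(d2, y ~ x)
  d3 <- transform(d2, x = 10 * x)
  expect_equal(fit_phenology_model(d3, y ~ x)$aic, f1$aic, tolerance = 1e-8)
  d4 <- transform(d2, y = 3 * y)
  expect_equal(
    fit_phenology_model(d4, y ~ x)$aic - f1$aic,
    2 * 60 * log(3),
    tolerance = 1e-8
  )
})

test_that("spatial-gradient models on synthetic data recover the generator gradients", {
  obs <- fix_obs()
  fits <- fit_climate_gradients(obs)
  p <- default_gradient_params()
  co <- tidy(fits$MAT)
  lat_row <- co[co$term == "latitude", ]
  expect_lt(abs(lat_row$estimate - p$mat_lapse) / lat_row$std.error, 4)
  co_v <- tidy(fits$IVT)
  lat_v <- co_v[co_v$term == "latitude", ]
  expect_lt(abs(lat_v$estimate - p$ivt_per_lat) / lat_v$std.error, 4)

  ph <- fit_phenology_gradients(obs)
  expect_s3_class(ph, "pheno_fit")
  expect_gt(ph$adj.r.squared, 0.5) # strong species/phenophase structure
})

test_that("residual kurtosis distinguishes normal from Laplace tails", {
  set.seed(9)
  d <- data.frame(y = rnorm(20000))
  fit <- fit_phenology_model(d, y ~ 1)
  expect_lt(abs(residual_kurtosis(fit)), 0.2)

  d2 <- data.frame(y = rlaplace(20000))
  fit2 <- fit_phenology_model(d2, y ~ 1)
  expect_equal(residual_kurtosis(fit2), 3, tolerance = 0.6)

  fit$residuals <- rep(0, 20)
  expect_error(residual_kurtosis(fit), "constant")
})

test_that("tidy and glance report the standard fit summaries", {
  d <- data.frame(y = rnorm(40), x = rnorm(40))
  fit <- fit_phenology_model(d, y ~ x)
  td <- tidy(fit)
  expect_named(td, c("term", "estimate", "std.error", "statistic", "p.value"))
  ref <- summary(stats::lm(y ~ x, data = d))$coefficients
  expect_equal(td$estimate, unname(ref[, 1]), tolerance = 1e-10)
  expect_equal(td$p.value, unname(ref[, 4]), tolerance = 1e-10)
  gl <- glance(fit)
  expect_equal(gl$nobs, 40)
  expect_equal(gl$df.residual, 38)
})
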
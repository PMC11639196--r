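simple_fit <- function(seed = 11) {
  set.seed(seed)
  d <- data.frame(
    y = rnorm(90), T_ = rnorm(90), M = rnorm(90),
    f = factor(sample(c("a", "b", "c"), 90, TRUE))
  )
  d$y <- d$y + d$T_ * (1 + d$M) + as.integer(d$f)
  list(d = d, fit = fit_phenology_model(d, y ~ T_ * M * f))
}

test_that("reference grids weight averaged factor levels equally", {
  s <- simple_fit()
  g <- make_reference_grid(s$fit, at = list(M = 0))
  expect_equal(nrow(g), 3) # the 3 levels of f
  expect_equal(g$.weight, rep(1 / 3, 3))
  expect_equal(sum(g$.weight), 1)
  expect_equal(unique(g$T_), mean(s$d$T_)) # unfixed covariate at sample mean

  g2 <- make_reference_grid(s$fit, at = list(M = 0, f = "a"))
  expect_equal(nrow(g2), 1)
  expect_equal(g2$.weight, 1)

  expect_error(make_reference_grid(s$fit, at = list(nope = 1)), "Unknown model variable")
  expect_error(make_reference_grid(s$fit, at = list(f = "z")), "Unknown level")
  expect_warning(make_reference_grid(s$fit, at = list(M = 99)), "outside the observed range")
})

test_that("marginal means equal brute-force averaged predictions", {
  s <- simple_fit()
  lmfit <- stats::lm(y ~ T_ * M * f, data = s$d)
  g <- make_reference_grid(s$fit, at = list(M = c(-1, 0, 2)))
  mm <- marginal_mean(s$fit, g)
  expect_equal(mm$estimate, unname(brute_marginal_mean(lmfit, g)), tolerance = 1e-8)

  # intercept-only closed form: mean(y), s.e. = s/sqrt(n)
  d0 <- data.frame(y = rnorm(25))
  f0 <- fit_phenology_model(d0, y ~ 1)
  mm0 <- marginal_mean(f0)
  expect_equal(mm0$estimate, mean(d0$y))
  expect_equal(mm0$std.error, stats::sd(d0$y) / sqrt(25), tolerance = 1e-10)

  bad <- make_reference_grid(s$fit)
  bad$zzz <- 1
  expect_error(marginal_mean(s$fit, bad), "not in model")
})

test_that("marginal slopes are exact coefficient combinations", {
  set.seed(2)
  d <- data.frame(y = rnorm(50), x = rnorm(50), m = rnorm(50))
  fit <- fit_phenology_model(d, y ~ x + m) # no interaction
  sl <- suppressWarnings(marginal_slope(fit, "x", list(m = c(-2, 0, 5))))
  expect_equal(sl$estimate, rep(unname(coef(fit)["x"]), 3), tolerance = 1e-12)

  fit2 <- fit_phenology_model(d, y ~ x * m)
  sl2 <- marginal_slope(fit2, "x", list(m = 1.7))
  expect_equal(
    sl2$estimate,
    unname(coef(fit2)["x"] + 1.7 * coef(fit2)["x:m"]),
    tolerance = 1e-12
  )
  expect_error(marginal_slope(simple_fit()$fit, "f"), "covariate, not a factor")
  expect_error(marginal_slope(fit2, "q"), "not in the model")
})

test_that("slope trends equal interaction coefficients and finite differences", {
  set.seed(3)
  d <- data.frame(y = rnorm(60), x = rnorm(60), m = rnorm(60), w = rnorm(60))
  fit <- fit_phenology_model(d, y ~ x * m + w)
  tr <- slope_trend(fit, "x", "m")
  expect_equal(tr$estimate, unname(coef(fit)["x:m"]), tolerance = 1e-12)

  # absent interaction: exactly zero with zero s.e.
  tr0 <- slope_trend(fit, "x", "w")
  expect_equal(tr0$estimate, 0)
  expect_equal(tr0$std.error, 0)

  # finite difference of marginal slopes across w +/- h
  s <- simple_fit()
  h <- 0.25
  up <- marginal_slope(s$fit, "T_", list(M = 1 + h))$estimate
  dn <- marginal_slope(s$fit, "T_", list(M = 1 - h))$estimate
  expect_equal(
    slope_trend(s$fit, "T_", "M", list(M = 1))$estimate,
    (up - dn) / (2 * h),
    tolerance = 1e-8
  )
})

test_that("marginal estimates are invariant to factor reference levels", {
  s <- simple_fit()
  refit <- fit_phenology_model(s$d, y ~ T_ * M * f, reference_levels = list(f = "c"))
  for (m in c(-1, 0.5)) {
    expect_equal(
      marginal_slope(refit, "T_", list(M = m))$estimate,
      marginal_slope(s$fit, "T_", list(M = m))$estimate,
      tolerance = 1e-8
    )
    expect_equal(
      marginal_mean(refit, make_reference_grid(refit, at = list(M = m)))$estimate,
      marginal_mean(s$fit, make_reference_grid(s$fit, at = list(M = m)))$estimate,
      tolerance = 1e-8
    )
  }
})

test_that("marginal machinery agrees with emmeans", {
  s <- simple_fit()
  lmfit <- stats::lm(y ~ T_ * M * f, data = s$d)

  em <- as.data.frame(emmeans::emmeans(lmfit, ~M, at = list(M = c(-1, 0, 2))))
  mm <- marginal_mean(s$fit, make_reference_grid(s$fit, at = list(M = c(-1, 0, 2))))
  expect_equal(mm$estimate, em$emmean, tolerance = 1e-8)
  expect_equal(mm$std.error, em$SE, tolerance = 1e-8)

  emt <- as.data.frame(
    emmeans::emtrends(lmfit, ~M, var = "T_", at = list(M = c(-1, 0, 2)))
  )
  sl <- marginal_slope(s$fit, "T_", list(M = c(-1, 0, 2)))
  expect_equal(sl$estimate, emt$T_.trend, tolerance = 1e-8)
  expect_equal(sl$std.error, emt$SE, tolerance = 1e-8)

  # Tukey-adjusted pairwise contrasts of per-level trends
  emp <- as.data.frame(summary(emmeans::contrast(
    emmeans::emtrends(lmfit, ~f, var = "T_"), "pairwise"
  )))
  C <- phenosense:::contrast_rows(
    s$fit, make_reference_grid(s$fit, at = list(f = c("a", "b", "c"))),
    derivative = "T_"
  )
  Sigma <- C %*% vcov(s$fit) %*% t(C)
  slf <- marginal_slope(s$fit, "T_", list(f = c("a", "b", "c")))
  pc <- pairwise_contrasts(
    setNames(slf$estimate, slf$f), Sigma, s$fit$df.residual, "tukey"
  )
  expect_equal(pc$estimate, emp$estimate, tolerance = 1e-8)
  expect_equal(pc$p.value, emp$p.value, tolerance = 1e-6)
})

test_that("Tukey adjustment reduces to the t-test at k = 2 and never helps", {
  est <- c(a = 1.3, b = 0.2)
  Sigma <- diag(c(0.2, 0.3))
  tk <- pairwise_contrasts(est, Sigma, df = 40, adjust = "tukey")
  un <- pairwise_contrasts(est, Sigma, df = 40, adjust = "none")
  expect_equal(tk$p.value, un$p.value, tolerance = 1e-9)

  set.seed(4)
  for (k in c(3, 5)) {
    est_k <- rnorm(k)
    A <- matrix(rnorm(k * k), k)
    Sigma_k <- crossprod(A) / k
    tk_k <- pairwise_contrasts(est_k, Sigma_k, df = 25, adjust = "tukey")
    un_k <- pairwise_contrasts(est_k, Sigma_k, df = 25, adjust = "none")
    expect_true(all(tk_k$p.value >= un_k$p.value - 1e-12))
  }

  ident <- pairwise_contrasts(c(1, 1), diag(c(0.1, 0.1)), df = 10)
  expect_equal(ident$estimate, 0)

  expect_error(pairwise_contrasts(c(1, 2), matrix(c(1, 2, 2, 1), 2), 10), "positive semidefinite")
  expect_error(pairwise_contrasts(1, matrix(1), 10), "at least two")
})
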
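#' Model formulas used by the pipeline
#'
#' `global_model_formula()` is the best-fit interaction structure for
#' temperature sensitivity: day of year as a function of standardized
#' temperature crossed with MAT, IVT and species, plus the analogous
#' precipitation and phenophase blocks. the gradient formulas describe spatial
#' variation in long-term climate and in phenology.
#'
#' @return A formula.
#' @export
global_model_formula <- function() {
  doy ~ Tstd * MAT * IVT * species + Pstd * MAT * IVT * species +
    phenophase * MAT * IVT * species
}

#' @rdname global_model_formula
#' @param response `"MAT"` or `"IVT"`.
#' @export
climate_gradient_formula <- function(response = c("MAT", "IVT")) {
  response <- match.arg(response)
  stats::reformulate(c("continent", "latitude"), response = response)
}

#' @rdname global_model_formula
#' @export
phenology_gradient_formula <- function() {
  doy ~ phenophase * continent + phenophase * latitude + phenophase * species
}

#' Build a treatment-coded design matrix
#'
#' Expands a model formula into an intercept, treatment-coded factor dummies
#' and interaction product columns, with a column map naming every
#' coefficient. Interactions expand hierarchically (marginal terms are
#' always present). Reference levels are alphabetical unless overridden.
#'
#' @param data Data frame holding every model variable.
#' @param formula Model formula.
#' @param reference_levels Optional named list, factor name -> reference
#'   level.
#' @return A list with `X` (numeric matrix), `y` (response, if present in
#'   `data`), `terms`, `xlevels`, `contrasts`, and `assign` (term index per
#'   column).
#' @export
build_design_matrix <- function(data, formula, reference_levels = NULL) {
  data <- as.data.frame(data)
  vars <- all.vars(formula)
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars) > 0) {
    abort(paste0("Variables absent from data: ", paste(missing_vars, collapse = ", ")))
  }
  for (v in vars) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]])) {
      if (nlevels(droplevels(data[[v]])) < 2) {
        abort(paste0("Factor '", v, "' has fewer than 2 observed levels."))
      }
      data[[v]] <- droplevels(data[[v]])
      ref <- reference_levels[[v]]
      if (!is.null(ref)) data[[v]] <- stats::relevel(data[[v]], ref = ref)
    }
  }
  mf <- stats::model.frame(formula, data)
  trm <- attr(mf, "terms")
  X <- stats::model.matrix(trm, mf)
  resp <- attr(trm, "response")
  y <- if (resp > 0) stats::model.response(mf) else NULL
  list(
    X = X, y = y, terms = trm,
    xlevels = stats::.getXlevels(trm, mf),
    contrasts = attr(X, "contrasts"),
    assign = attr(X, "assign")
  )
}

#' Ordinary least squares on an explicit design matrix
#'
#' Fits by QR decomposition and reports the coefficient covariance
#' `s^2 (X'X)^-1`, residual degrees of freedom, AIC under the Gaussian
#' log-likelihood (constant included, counting the error variance as a
#' parameter), adjusted R-squared, and excess residual kurtosis. A
#' rank-deficient design is an error naming the aliased columns rather than
#' silently dropping them.
#'
#' @param X Numeric design matrix (including any intercept column).
#' @param y Numeric response.
#' @return An object of class `pheno_fit`.
#' @export
fit_ols <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  p <- ncol(X)
  if (length(y) != n) abort("Length of y does not match nrow(X).")
  if (n <= p) abort("Need more observations than parameters.")
  qrx <- qr(X)
  if (qrx$rank < p) {
    aliased <- colnames(X)[qrx$pivot[(qrx$rank + 1):p]]
    abort(paste0(
      "Design matrix is rank deficient; aliased columns: ",
      paste(aliased, collapse = ", ")
    ))
  }
  beta <- qr.coef(qrx, y)
  fitted <- drop(X %*% beta)
  resid <- y - fitted
  rss <- sum(resid^2)
  df <- n - p
  sigma2 <- rss / df
  R <- qr.R(qrx)
  piv <- qrx$pivot
  xtx_inv <- chol2inv(R)[order(piv), order(piv), drop = FALSE]
  vc <- sigma2 * xtx_inv
  dimnames(vc) <- list(colnames(X), colnames(X))
  tss <- sum((y - mean(y))^2)
  r2 <- 1 - rss / tss
  has_icpt <- any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0))
  adj_r2 <- if (has_icpt) 1 - (1 - r2) * (n - 1) / df else 1 - (1 - r2) * n / df
  aic <- n * log(2 * pi) + n * log(rss / n) + n + 2 * (p + 1)

  structure(
    list(
      coefficients = beta, vcov = vc, df.residual = df, n = n, rank = p,
      sigma = sqrt(sigma2), rss = rss, aic = aic,
      r.squared = r2, adj.r.squared = adj_r2,
      residuals = resid, fitted = fitted
    ),
    class = "pheno_fit"
  )
}

#' Fit a phenology linear model from a data frame and formula
#'
#' Builds the treatment-coded design matrix, fits by [fit_ols()], and keeps
#' the formula metadata (terms, factor levels, contrasts, covariate sample
#' means) needed by the marginal-inference engine.
#'
#' @param data Data frame of observations with covariates.
#' @param formula Model formula (default the global sensitivity model).
#' @param reference_levels Optional named list of factor reference levels.
#' @return A `pheno_fit` with model metadata attached.
#' @export
#' @examples
#' d <- data.frame(doy = rnorm(20, 100), Tstd = rnorm(20))
#' fit <- fit_phenology_model(d, doy ~ Tstd)
#' glance(fit)
fit_phenology_model <- function(data, formula = global_model_formula(),
                                reference_levels = NULL) {
  dm <- build_design_matrix(data, formula, reference_levels)
  if (is.null(dm$y)) abort("Formula has no response variable.")
  fit <- fit_ols(dm$X, dm$y)
  fit$terms <- dm$terms
  fit$xlevels <- dm$xlevels
  fit$contrasts <- dm$contrasts
  fit$assign <- dm$assign
  fit$formula <- formula
  num_vars <- setdiff(all.vars(formula)[-1], names(dm$xlevels))
  fit$covariate_means <- vapply(num_vars, function(v) mean(as.data.frame(data)[[v]]), 0)
  fit$covariate_ranges <- lapply(
    setNames(num_vars, num_vars),
    function(v) range(as.data.frame(data)[[v]])
  )
  fit$call <- match.call()
  fit
}

#' @export
print.pheno_fit <- function(x, ...) {
  cat("<pheno_fit> ", x$n, " obs, ", x$rank, " coefficients, df = ",
    x$df.residual, "\n",
    sep = ""
  )
  cat(
    "  AIC = ", format(x$aic, digits = 8), ", adj R^2 = ",
    format(x$adj.r.squared, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
coef.pheno_fit <- function(object, ...) object$coefficients

#' @export
vcov.pheno_fit <- function(object, ...) object$vcov

#' Tidy coefficient table of a phenology model fit
#'
#' @param x A `pheno_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value`.
#' @method tidy pheno_fit
#' @export
tidy.pheno_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov))
  stat <- x$coefficients / se
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = unname(se),
    statistic = unname(stat),
    p.value = unname(2 * pt(-abs(stat), x$df.residual))
  )
}

#' One-row fit summary of a phenology model fit
#'
#' @param x A `pheno_fit`.
#' @param ... Unused.
#' @return A one-row tibble of fit statistics.
#' @method glance pheno_fit
#' @export
glance.pheno_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r.squared, adj.r.squared = x$adj.r.squared,
    sigma = x$sigma, AIC = x$aic, df.residual = x$df.residual,
    nobs = x$n, n_coef = x$rank
  )
}

#' Spatial-gradient model fits
#'
#' `fit_climate_gradients()` fits the two additive spatial-climate models
#' (`MAT ~ continent + latitude`, `IVT ~ continent + latitude`);
#' `fit_phenology_gradients()` fits the spatial phenology model with phenophase
#' interactions.
#'
#' @param data Observation tibble with covariates (from
#'   [add_climate_covariates()]).
#' @return A named list of two `pheno_fit`s, or a single `pheno_fit`.
#' @export
fit_climate_gradients <- function(data) {
  list(
    MAT = fit_phenology_model(data, climate_gradient_formula("MAT")),
    IVT = fit_phenology_model(data, climate_gradient_formula("IVT"))
  )
}

#' @rdname fit_climate_gradients
#' @export
fit_phenology_gradients <- function(data) {
  fit_phenology_model(data, phenology_gradient_formula())
}

#' @rdname fit_climate_gradients
#' @export
fit_global <- function(data) {
  fit_phenology_model(data, global_model_formula())
}

#' Rank candidate model structures by AIC
#'
#' Fits each candidate formula to the same rows and ranks by AIC ascending.
#' Candidates must resolve to the identical observation set, otherwise AIC
#' values are not comparable and an error is raised.
#'
#' @param data Data frame.
#' @param candidates Named list of formulas (at least two).
#' @return A list with `table` (tibble: model, n_coef, AIC, delta_AIC,
#'   adj.r.squared, ranked) and `best` (the winning `pheno_fit`).
#' @export
aic_select <- function(data, candidates) {
  if (length(candidates) < 2) abort("Need at least two candidate formulas.")
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    names(candidates) <- paste0("model", seq_along(candidates))
  }
  data <- as.data.frame(data)
  rows <- lapply(candidates, function(f) which(complete.cases(data[, all.vars(f), drop = FALSE])))
  if (!all(vapply(rows, identical, TRUE, y = rows[[1]]))) {
    abort("Candidates resolve to different row subsets; AIC is not comparable.")
  }
  fits <- lapply(candidates, function(f) fit_phenology_model(data[rows[[1]], , drop = FALSE], f))
  tab <- tibble::tibble(
    model = names(candidates),
    n_coef = unname(vapply(fits, function(f) f$rank, 0L)),
    AIC = unname(vapply(fits, function(f) f$aic, 0)),
    adj.r.squared = unname(vapply(fits, function(f) f$adj.r.squared, 0))
  ) |>
    dplyr::arrange(.data$AIC) |>
    dplyr::mutate(delta_AIC = .data$AIC - min(.data$AIC))
  list(table = tab, best = fits[[tab$model[1]]])
}

#' Excess kurtosis of model residuals
#'
#' Reports `m4 / m2^2 - 3` of the residuals; positive values indicate a
#' leptokurtic response distribution, the main normality irregularity seen
#' in day-of-year data.
#'
#' @param model A `pheno_fit`.
#' @return Excess kurtosis (0 for a normal distribution).
#' @export
residual_kurtosis <- function(model) {
  r <- model$residuals
  m2 <- mean((r - mean(r))^2)
  if (m2 == 0) abort("Residuals are constant; kurtosis undefined.")
  mean((r - mean(r))^4) / m2^2 - 3
}
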
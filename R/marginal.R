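model_variables <- function(model) {
  vars <- all.vars(stats::delete.response(model$terms))
  list(
    factors = intersect(vars, names(model$xlevels)),
    covariates = setdiff(vars, names(model$xlevels))
  )
}

#' Build a reference grid for marginal estimation
#'
#' A reference grid fixes every model variable at each prediction point.
#' Variables in `at` are fixed at the supplied values (crossed if several
#' are given); factors in `over` are averaged with equal weight per level;
#' any remaining covariate is fixed at its sample mean, so it is
#' statistically controlled. Values of `at` outside the observed covariate
#' range are allowed with a warning, since sensitivity surfaces deliberately
#' extend to the edges of the climatic study area.
#'
#' @param model A `pheno_fit` from [fit_phenology_model()].
#' @param at Named list of moderator values (each may be a vector; the grid
#'   is their crossing).
#' @param over Character vector of factor names to average over (default:
#'   every factor not in `at`).
#' @return An object of class `reference_grid`: a tibble of prediction
#'   points with `.group` (one marginal estimate per group) and `.weight`
#'   (summing to 1 within group).
#' @export
make_reference_grid <- function(model, at = list(), over = NULL) {
  mv <- model_variables(model)
  unknown <- setdiff(names(at), c(mv$factors, mv$covariates))
  if (length(unknown) > 0) {
    abort(paste0("Unknown model variable(s) in 'at': ", paste(unknown, collapse = ", ")))
  }
  if (is.null(over)) over <- setdiff(mv$factors, names(at))
  if (length(setdiff(over, mv$factors)) > 0) {
    abort("'over' must name factors in the model.")
  }
  for (v in intersect(names(at), mv$covariates)) {
    r <- model$covariate_ranges[[v]]
    if (!is.null(r) && any(at[[v]] < r[1] | at[[v]] > r[2])) {
      warn(paste0("'at' value(s) for ", v, " outside the observed range [",
        format(r[1], digits = 4), ", ", format(r[2], digits = 4), "]."))
    }
  }
  for (v in intersect(names(at), mv$factors)) {
    badlev <- setdiff(at[[v]], model$xlevels[[v]])
    if (length(badlev) > 0) {
      abort(paste0("Unknown level(s) of ", v, ": ", paste(badlev, collapse = ", ")))
    }
  }

  at_grid <- if (length(at) > 0) {
    do.call(tidyr::expand_grid, at) |> dplyr::mutate(.group = dplyr::row_number())
  } else {
    tibble::tibble(.group = 1L)
  }
  reference_grid_finish(model, at_grid, names(at))
}

# Assemble a reference grid from an explicit table of fixed points (one
# marginal estimate per row). Used for paired moderator values, where
# crossing the axes would be wrong.
reference_grid_from <- function(model, at_tbl) {
  mv <- model_variables(model)
  at_tbl <- tibble::as_tibble(at_tbl)
  unknown <- setdiff(names(at_tbl), c(mv$factors, mv$covariates))
  if (length(unknown) > 0) {
    abort(paste0("Unknown model variable(s): ", paste(unknown, collapse = ", ")))
  }
  at_tbl$.group <- seq_len(nrow(at_tbl))
  reference_grid_finish(model, at_tbl, setdiff(names(at_tbl), ".group"))
}

reference_grid_finish <- function(model, at_grid, at_names) {
  mv <- model_variables(model)
  cross_tbl <- function(a, b) {
    if (ncol(b) == 0 || nrow(b) == 0) {
      return(a)
    }
    dplyr::bind_cols(
      a[rep(seq_len(nrow(a)), each = nrow(b)), , drop = FALSE],
      b[rep(seq_len(nrow(b)), times = nrow(a)), , drop = FALSE]
    )
  }
  # every factor not fixed in `at` joins the equal-weight averaging set, so
  # each model variable is assigned exactly once per point
  avg_f <- setdiff(mv$factors, at_names)
  over_grid <- if (length(avg_f) > 0) {
    do.call(tidyr::expand_grid, setNames(lapply(avg_f, function(v) model$xlevels[[v]]), avg_f))
  } else {
    tibble::tibble(.dummy = 1)[, 0]
  }
  grid <- cross_tbl(at_grid, over_grid)
  grid$.weight <- 1 / max(1L, nrow(over_grid))
  for (v in setdiff(mv$covariates, at_names)) {
    grid[[v]] <- model$covariate_means[[v]]
  }
  structure(grid, class = c("reference_grid", class(grid)))
}

grid_design <- function(model, grid, override = list()) {
  d <- as.data.frame(grid)
  for (v in names(override)) d[[v]] <- override[[v]]
  for (v in names(model$xlevels)) {
    d[[v]] <- factor(d[[v]], levels = model$xlevels[[v]])
  }
  stats::model.matrix(
    stats::delete.response(model$terms), d,
    contrasts.arg = model$contrasts, xlev = model$xlevels
  )
}

contrast_rows <- function(model, grid, derivative = NULL) {
  # One contrast row per .group: weighted combination of design rows, or of
  # exact derivative rows. Every design column is at most multilinear in the
  # covariates, so dX/dfocal = X(focal = 1) - X(focal = 0) exactly, and the
  # mixed second derivative is the four-corner difference.
  if (is.null(derivative)) {
    Xg <- grid_design(model, grid)
  } else if (length(derivative) == 1) {
    f <- derivative
    Xg <- grid_design(model, grid, setNames(list(1), f)) -
      grid_design(model, grid, setNames(list(0), f))
  } else {
    f <- derivative[1]
    w <- derivative[2]
    Xg <- grid_design(model, grid, setNames(list(1, 1), c(f, w))) -
      grid_design(model, grid, setNames(list(1, 0), c(f, w))) -
      grid_design(model, grid, setNames(list(0, 1), c(f, w))) +
      grid_design(model, grid, setNames(list(0, 0), c(f, w)))
  }
  Xg <- Xg * grid$.weight
  rowsum(Xg, group = grid$.group, reorder = TRUE)
}

estimate_from_contrasts <- function(model, C) {
  est <- unname(drop(C %*% model$coefficients))
  se <- unname(sqrt(pmax(0, rowSums((C %*% model$vcov) * C))))
  stat <- ifelse(se > 0, est / se, NA_real_)
  tibble::tibble(
    estimate = est, std.error = se, statistic = stat,
    p.value = 2 * pt(-abs(stat), model$df.residual),
    df = model$df.residual
  )
}

grid_labels <- function(grid) {
  at_cols <- setdiff(
    names(grid)[seq_len(which(names(grid) == ".group") - 1)], ".group"
  )
  labs <- dplyr::distinct(
    tibble::as_tibble(grid)[, c(at_cols, ".group"), drop = FALSE]
  )
  dplyr::arrange(labs, .data$.group)
}

#' Estimated marginal means
#'
#' The model prediction averaged over the reference grid: factor levels in
#' the grid's averaging set get equal weight and unspecified covariates sit
#' at their sample means. Standard errors come from the delta method
#' (exact for a linear combination of coefficients):
#' `se = sqrt(c' Sigma c)` with `c` the weighted design-row combination.
#'
#' @param model A `pheno_fit`.
#' @param grid A [make_reference_grid()] grid, or a named `at` list which is
#'   passed to it.
#' @return A tibble with one row per grid group: moderator values,
#'   `estimate`, `std.error`, `statistic`, `p.value`, `df`.
#' @export
marginal_mean <- function(model, grid = list()) {
  if (!inherits(grid, "reference_grid")) grid <- make_reference_grid(model, at = grid)
  unknown <- setdiff(
    setdiff(names(grid), c(".group", ".weight")),
    unlist(model_variables(model))
  )
  if (length(unknown) > 0) {
    abort(paste0("Grid variable(s) not in model: ", paste(unknown, collapse = ", ")))
  }
  C <- contrast_rows(model, grid)
  dplyr::bind_cols(grid_labels(grid), estimate_from_contrasts(model, C))
}

#' Marginal (simple) slope of a focal covariate
#'
#' The derivative of the estimated marginal mean with respect to a focal
#' covariate, at fixed moderator values and averaged over grid factors. For
#' a treatment-coded linear model every design column is affine in the focal
#' covariate, so the derivative contrast is computed exactly from
#' coefficient structure (no numeric differentiation); the delta method
#' gives its standard error and a two-sided t test at the residual df gives
#' the p-value.
#'
#' @param model A `pheno_fit`.
#' @param focal Name of a numeric covariate in the model.
#' @param grid Reference grid or `at` list of moderator values.
#' @return A tibble of class `marginal_slope`: moderator values plus
#'   `estimate` (slope, response units per focal unit), `std.error`,
#'   `statistic`, `p.value`, `df`.
#' @export
#' @examples
#' d <- data.frame(doy = rnorm(50), Tstd = rnorm(50), MAT = rnorm(50))
#' fit <- fit_phenology_model(d, doy ~ Tstd * MAT)
#' marginal_slope(fit, "Tstd", list(MAT = c(0, 5)))
marginal_slope <- function(model, focal, grid = list()) {
  mv <- model_variables(model)
  if (focal %in% mv$factors) abort("Focal variable must be a covariate, not a factor.")
  if (!focal %in% mv$covariates) abort(paste0("'", focal, "' is not in the model."))
  if (!inherits(grid, "reference_grid")) grid <- make_reference_grid(model, at = grid)
  C <- contrast_rows(model, grid, derivative = focal)
  out <- dplyr::bind_cols(grid_labels(grid), estimate_from_contrasts(model, C))
  attr(out, "focal") <- focal
  class(out) <- c("marginal_slope", class(out))
  out
}

#' Second-order trend of a marginal slope
#'
#' The mixed second derivative of the marginal mean with respect to the
#' focal covariate and a moderating covariate: how the simple slope of
#' `focal` changes per unit of `wrt`, at fixed remaining moderators. Exact
#' from coefficients for multilinear designs, with delta-method standard
#' errors.
#'
#' @inheritParams marginal_slope
#' @param wrt Name of the moderating covariate.
#' @return A tibble like [marginal_slope()], in units
#'   response / (focal unit x wrt unit).
#' @export
slope_trend <- function(model, focal, wrt, grid = list()) {
  mv <- model_variables(model)
  for (v in c(focal, wrt)) {
    if (v %in% mv$factors) abort("Trend variables must be covariates, not factors.")
    if (!v %in% mv$covariates) abort(paste0("'", v, "' is not in the model."))
  }
  if (!inherits(grid, "reference_grid")) grid <- make_reference_grid(model, at = grid)
  C <- contrast_rows(model, grid, derivative = c(focal, wrt))
  dplyr::bind_cols(grid_labels(grid), estimate_from_contrasts(model, C))
}

#' Pairwise contrasts with Tukey HSD adjustment
#'
#' All pairwise differences among a set of marginal estimates with joint
#' covariance, with p-values from the studentized-range distribution
#' (Tukey's HSD) at the model's residual df, or unadjusted two-sided t
#' tests. For two groups the Tukey p-value equals the unadjusted one via
#' the identity `q = t * sqrt(2)`.
#'
#' @param estimates Numeric vector of k estimates (named, optionally).
#' @param Sigma k x k covariance matrix of the estimates.
#' @param df Residual degrees of freedom.
#' @param adjust `"tukey"` or `"none"`.
#' @return A tibble: `contrast`, `estimate`, `std.error`, `statistic`,
#'   `p.value`, `df`, `adjust`.
#' @export
pairwise_contrasts <- function(estimates, Sigma, df, adjust = c("tukey", "none")) {
  adjust <- match.arg(adjust)
  k <- length(estimates)
  if (k < 2) abort("Need at least two estimates.")
  Sigma <- as.matrix(Sigma)
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) abort("Covariance matrix is not positive semidefinite.")
  nms <- names(estimates) %||% as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    i1 <- pairs[1, j]
    i2 <- pairs[2, j]
    d <- estimates[i1] - estimates[i2]
    se <- sqrt(Sigma[i1, i1] + Sigma[i2, i2] - 2 * Sigma[i1, i2])
    tval <- d / se
    p <- if (se == 0 && d == 0) {
      1
    } else if (adjust == "tukey") {
      ptukey(sqrt(2) * abs(tval), nmeans = k, df = df, lower.tail = FALSE)
    } else {
      2 * pt(-abs(tval), df)
    }
    tibble::tibble(
      contrast = paste(nms[i1], "-", nms[i2]),
      estimate = unname(d), std.error = unname(se),
      statistic = unname(tval), p.value = unname(min(p, 1)),
      df = df, adjust = adjust
    )
  })
}
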
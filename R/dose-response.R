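# Outcome Super Learner and dose-response / marginal-effect curves.

#' Fit the outcome Super Learner
#'
#' Selects the convex combination of outcome regression candidates
#' minimizing the cross-validated mean squared error, then refits every
#' candidate on the full sample. Two predictor modes are supported:
#'
#' * `"covariates"`: the outcome is modelled as `Q(t, x)`, a function of the
#'   treatment and the covariates (regression adjustment);
#' * `"gps"`: the outcome is modelled as `beta(t, r)`, a function of the
#'   treatment and the estimated propensity score only (two-stage
#'   adjustment); requires the observed scores from [evaluate_gps()] or a
#'   fitted [fit_gps()] model.
#'
#' @param data data frame with outcome, treatment and covariates.
#' @param outcome name of the outcome column (binary 0/1 for
#'   `outcome_family = "binomial"`, strictly positive for `"gamma"`).
#' @param treatment name of the treatment column.
#' @param covariates covariate names (mode `"covariates"`).
#' @param outcome_family `"binomial"` or `"gamma"`.
#' @param mode `"covariates"` or `"gps"`.
#' @param gps a `gps_model` or `gps_evaluations` carrying observed scores
#'   (mode `"gps"`).
#' @param candidates candidate list; defaults to [outcome_library()].
#' @param V,seed,folds cross-validation controls as in [fit_gps()].
#' @param continuous continuous covariate names for the default library.
#' @return object of class `outcome_model`: fitted `candidates`, `weights`,
#'   `risks`, `mode`, `outcome`, `treatment`, `gps_var`, `outcome_family`.
#' @export
fit_outcome_sl <- function(data, outcome, treatment, covariates = NULL,
                           outcome_family = c("binomial", "gamma"),
                           mode = c("covariates", "gps"), gps = NULL,
                           candidates = NULL, V = 10L, seed = 1L,
                           folds = NULL, continuous = NULL) {
  outcome_family <- match.arg(outcome_family)
  mode <- match.arg(mode)
  y <- data[[outcome]]
  if (is.null(y)) stop_input("outcome column not found")
  gps_var <- ".gps"
  if (mode == "gps") {
    r_obs <- if (inherits(gps, "gps_evaluations")) gps$observed
             else if (inherits(gps, "gps_model"))
               evaluate_gps(gps, numeric(0), data)$observed
             else stop_input("mode 'gps' requires a gps_model or gps_evaluations")
    if (is.null(r_obs)) stop_input("observed GPS values are required")
    design <- data.frame(data[[treatment]], r_obs)
    names(design) <- c(treatment, gps_var)
  } else {
    if (is.null(covariates)) stop_input("covariates required in mode 'covariates'")
    design <- data[, c(treatment, covariates), drop = FALSE]
  }
  if (is.null(continuous) && !is.null(covariates))
    continuous <- covariates[vapply(covariates, function(v)
      length(unique(data[[v]])) > 2L, TRUE)]
  if (is.null(candidates))
    candidates <- outcome_library(treatment, covariates, outcome_family,
                                  mode, continuous = continuous,
                                  gps_var = gps_var)
  if (is.null(folds)) folds <- make_folds(nrow(data), V, seed)
  cvm <- cv_heldout_matrix(candidates, design, y, folds, "mse")
  weights <- solve_simplex_weights(cvm, y)
  risks <- candidate_risks(cvm, y)
  keep <- candidates[vapply(candidates, function(s) s$name, "") %in%
                       cvm$candidate_names]
  fits <- lapply(keep, fit_candidate, predictors = design, response = y)
  names(fits) <- cvm$candidate_names
  structure(list(candidates = fits, weights = weights, risks = risks,
                 mode = mode, outcome = outcome, treatment = treatment,
                 gps_var = gps_var, outcome_family = outcome_family,
                 folds = folds, dropped = cvm$dropped,
                 treatment_range = range(data[[treatment]])),
            class = "outcome_model")
}

# ensemble conditional-mean prediction on a design data frame
sl_predict <- function(model, design) {
  preds <- vapply(model$candidates, predict_mean, new_data = design,
                  FUN.VALUE = numeric(nrow(design)))
  preds <- matrix(preds, nrow = nrow(design))
  as.numeric(preds %*% model$weights$alpha)
}

#' Average dose-response curve
#'
#' For each treatment level `t` on the grid, predicts every unit's expected
#' outcome at `t` and averages: in regression mode
#' `mu(t) = mean_i Q(t, x_i)`; in GPS mode `mu(t) = mean_i beta(t, R_{t,i})`
#' with the counterfactual score `R_{t,i}` from the supplied `gps_model`.
#' For candidates linear in their terms this averaging equals the classical
#' plug-in of empirical score moments into the fitted coefficients.
#'
#' @param model an [fit_outcome_sl()] result.
#' @param data data frame of the analysis sample.
#' @param grid increasing vector of treatment levels (default 1..24).
#' @param gps_model required when `model$mode == "gps"`.
#' @return object of class `dose_response_curve`: `grid`, `mu_hat`,
#'   `method` (`"regression"` or `"gps"`), `n`.
#' @export
estimate_curve <- function(model, data, grid = 1:24, gps_model = NULL) {
  if (is.unsorted(grid, strictly = TRUE))
    stop_input("grid must be strictly increasing")
  rng <- model$treatment_range
  if (any(grid < rng[1] - 1e-12) || any(grid > rng[2] + 1e-12))
    warning(sprintf(
      "grid extends beyond the observed treatment range [%.3g, %.3g]; curve values there are extrapolations",
      rng[1], rng[2]), call. = FALSE)
  n <- nrow(data)
  mu <- numeric(length(grid))
  if (model$mode == "gps") {
    if (!inherits(gps_model, "gps_model"))
      stop_input("mode 'gps' requires the fitted gps_model")
    cf <- evaluate_gps(gps_model, grid, data)$counterfactual
    for (g in seq_along(grid)) {
      design <- data.frame(rep(grid[g], n), cf[g, ])
      names(design) <- c(model$treatment, model$gps_var)
      mu[g] <- mean(sl_predict(model, design))
    }
  } else {
    design <- data
    for (g in seq_along(grid)) {
      design[[model$treatment]] <- rep(grid[g], n)
      mu[g] <- mean(sl_predict(model, design))
    }
  }
  structure(list(grid = as.numeric(grid), mu_hat = mu,
                 method = if (model$mode == "gps") "gps" else "regression",
                 outcome_family = model$outcome_family, n = n),
            class = "dose_response_curve")
}

#' Marginal treatment effect curve
#'
#' First differences of the dose-response curve divided by the grid
#' increment: `(mu(t) - mu(t - dt)) / dt`, reported from the second grid
#' point onward.
#'
#' @param curve a [estimate_curve()] result, or a list with `grid` and
#'   `mu_hat`.
#' @return object of class `marginal_effect_curve`: `t` (grid without its
#'   first point), `effect`, `dt`.
#' @export
marginal_effects <- function(curve) {
  g <- curve$grid
  if (length(g) < 2L) stop_input("grid must have at least 2 points")
  dt <- diff(g)
  structure(list(t = g[-1L], effect = diff(curve$mu_hat) / dt, dt = dt),
            class = "marginal_effect_curve")
}

#' Unadjusted smoothed dose-response curve
#'
#' The naive comparator: a loess smooth of the outcome on the treatment
#' alone, evaluated on the grid. No covariate adjustment.
#'
#' @param data data frame.
#' @param outcome,treatment column names.
#' @param grid treatment levels.
#' @param span loess span.
#' @return a `dose_response_curve` with method `"naive"`.
#' @export
naive_dose_response <- function(data, outcome, treatment, grid = 1:24,
                                span = 0.75) {
  df <- data.frame(.y = data[[outcome]], .t = data[[treatment]])
  fit <- stats::loess(.y ~ .t, data = df, span = span, degree = 1,
                      control = stats::loess.control(surface = "direct"))
  mu <- as.numeric(stats::predict(fit, data.frame(.t = grid)))
  structure(list(grid = as.numeric(grid), mu_hat = mu, method = "naive",
                 outcome_family = NA_character_, n = nrow(data)),
            class = "dose_response_curve")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("Dose-response curve (%s method, n = %d)\n", x$method, x$n))
  print(data.frame(t = x$grid, mu_hat = round(x$mu_hat, 5)))
  invisible(x)
}

#' @export
print.outcome_model <- function(x, ...) {
  cat(sprintf("Outcome Super Learner (%s mode, %s family): %d candidates\n",
              x$mode, x$outcome_family, length(x$candidates)))
  tab <- data.frame(`CV MSE` = round(x$risks, 6),
                    weight = round(x$weights$alpha, 4), check.names = FALSE)
  print(tab)
  invisible(x)
}

#' Export a curve (with optional bootstrap bounds) to CSV
#'
#' @param curve a `dose_response_curve`.
#' @param path output path.
#' @param lower,upper optional CI bounds aligned with the grid.
#' @export
write_curve_csv <- function(curve, path, lower = NULL, upper = NULL) {
  df <- data.frame(t = curve$grid, estimate = curve$mu_hat)
  if (!is.null(lower)) df$lower <- lower
  if (!is.null(upper)) df$upper <- upper
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
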
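# Super-Learner estimation of the generalised propensity score (GPS):
# the conditional density r(t, x) of treatment given covariates.

#' Fit the generalised propensity score by Super Learning
#'
#' Estimates the conditional density of a positive continuous treatment
#' given covariates as the convex combination of candidate conditional
#' density models (normal and gamma GLMs by default) minimizing the
#' cross-validated negative log-likelihood. After weight selection every
#' candidate is refit on the full sample; counterfactual evaluations use
#' these full-sample fits.
#'
#' @param data data frame containing the treatment and covariates.
#' @param treatment name of the (strictly positive) treatment column.
#' @param covariates character vector of covariate names.
#' @param candidates list of [candidate_spec()]; defaults to the eight
#'   normal/gamma specifications of [gps_library()].
#' @param V number of cross-validation folds (default 10).
#' @param seed fold seed.
#' @param folds optional pre-built [make_folds()] assignment.
#' @param continuous continuous covariates (passed to [gps_library()]).
#' @return object of class `gps_model`: full-sample `candidates` (fitted),
#'   `weights` (a `simplex_weights`), `risks` (per-candidate CV risk),
#'   `treatment`, `covariates`, `treatment_range`, `folds`.
#' @export
fit_gps <- function(data, treatment, covariates,
                    candidates = NULL, V = 10L, seed = 1L,
                    folds = NULL, continuous = NULL) {
  if (!treatment %in% names(data)) stop_input("treatment column not found")
  tvals <- data[[treatment]]
  if (!is.numeric(tvals) || any(!is.finite(tvals)))
    stop_input("treatment must be numeric and finite")
  if (is.null(continuous))
    continuous <- covariates[vapply(covariates, function(v)
      length(unique(data[[v]])) > 2L, TRUE)]
  if (is.null(candidates))
    candidates <- gps_library(covariates, continuous = continuous)
  has_gamma <- any(vapply(candidates, function(s) s$family == "gamma", TRUE))
  if (has_gamma && any(tvals <= 0))
    stop_input("treatment must be strictly positive for gamma candidates")
  if (is.null(folds)) folds <- make_folds(nrow(data), V, seed)
  cvm <- cv_heldout_matrix(candidates, data, tvals, folds, "negloglik")
  weights <- solve_simplex_weights(cvm, tvals)
  risks <- candidate_risks(cvm, tvals)
  keep <- candidates[vapply(candidates, function(s) s$name, "") %in%
                       cvm$candidate_names]
  fits <- lapply(keep, fit_candidate, predictors = data, response = tvals)
  names(fits) <- cvm$candidate_names
  structure(list(candidates = fits, weights = weights, risks = risks,
                 treatment = treatment, covariates = covariates,
                 treatment_range = range(tvals), folds = folds,
                 dropped = cvm$dropped),
            class = "gps_model")
}

# mixture density sum_j alpha_j f_j(t | x), vectorized over rows of data
gps_mixture_density <- function(model, t, data) {
  dens <- vapply(model$candidates, density_at, t = t, data = data,
                 FUN.VALUE = numeric(nrow(data)))
  dens <- matrix(dens, nrow = nrow(data))
  as.numeric(dens %*% model$weights$alpha)
}

#' Evaluate the GPS at observed and counterfactual treatment levels
#'
#' Returns the estimated conditional density at each unit's own treatment
#' value (the observed score `R_i = r(T_i, x_i)`) and, for every requested
#' treatment level `t`, the counterfactual score `R_{t,i} = r(t, x_i)` for
#' all units.
#'
#' @param model a [fit_gps()] result.
#' @param t_values positive treatment levels of interest (may be empty).
#' @param data data frame with the covariates (and, for the observed score,
#'   the treatment column).
#' @return object of class `gps_evaluations`: `observed` (length n, or NULL
#'   when the treatment column is absent), `counterfactual` (length(t) x n
#'   matrix with rownames `t_values`), `t_values`.
#' @export
evaluate_gps <- function(model, t_values = numeric(0), data) {
  if (length(t_values) && any(t_values <= 0))
    stop_input("t_values must be strictly positive")
  n <- nrow(data)
  observed <- NULL
  if (model$treatment %in% names(data))
    observed <- gps_mixture_density(model, data[[model$treatment]], data)
  cf <- matrix(NA_real_, length(t_values), n,
               dimnames = list(format(t_values, trim = TRUE), NULL))
  for (g in seq_along(t_values))
    cf[g, ] <- gps_mixture_density(model, t_values[g], data)
  structure(list(observed = observed, counterfactual = cf,
                 t_values = t_values),
            class = "gps_evaluations")
}

#' @export
print.gps_model <- function(x, ...) {
  cat(sprintf("GPS Super Learner: %d candidates, treatment '%s' in [%.3g, %.3g]\n",
              length(x$candidates), x$treatment,
              x$treatment_range[1], x$treatment_range[2]))
  tab <- data.frame(`CV -loglik` = round(x$risks, 4),
                    weight = round(x$weights$alpha, 4),
                    check.names = FALSE)
  print(tab)
  cat("Convex Super Learner CV -loglik:",
      format(x$weights$objective, digits = 6), "\n")
  invisible(x)
}

#' Export GPS evaluations to CSV
#'
#' One row per unit: unit id, observed score, one column per counterfactual
#' treatment level.
#'
#' @param evals a [evaluate_gps()] result.
#' @param path output file path.
#' @export
write_gps_csv <- function(evals, path) {
  n <- if (!is.null(evals$observed)) length(evals$observed)
       else ncol(evals$counterfactual)
  df <- data.frame(unit = seq_len(n))
  if (!is.null(evals$observed)) df$observed <- evals$observed
  if (length(evals$t_values)) {
    cf <- t(evals$counterfactual)
    colnames(cf) <- paste0("t_", rownames(evals$counterfactual))
    df <- cbind(df, cf)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
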
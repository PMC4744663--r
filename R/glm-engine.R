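# Candidate fitting engine: design expansion, (penalized) IRLS, prediction,
# and the conditional densities implied by fitted treatment models.

#' Expand a candidate's design matrix
#'
#' Builds the model matrix for a `candidate_spec`: an intercept column
#' followed by one column per term, in spec order. Continuous variables
#' (more than two distinct training values) are centered at their training
#' means before powers and products are formed; smooth terms use a natural
#' cubic spline basis with knots at training quantiles. The centering
#' constants and spline knots are frozen in a schema so prediction-time
#' expansion reproduces the training expansion exactly.
#'
#' @param spec a [candidate_spec()].
#' @param data a data frame containing every referenced variable.
#' @param schema a schema from a previous training expansion; `NULL` builds
#'   a new one from `data`.
#' @return a numeric matrix with attribute `"schema"`.
#' @export
expand_design <- function(spec, data, schema = NULL) {
  vars <- unique(unlist(lapply(spec$terms, term_vars)))
  missing_vars <- setdiff(vars, names(data))
  if (length(missing_vars))
    stop_input("unknown variable(s) in spec '", spec$name, "': ",
               paste(missing_vars, collapse = ", "))
  for (v in vars) {
    col <- data[[v]]
    if (!is.numeric(col)) stop_input("variable '", v, "' is not numeric")
    if (any(!is.finite(col))) stop_input("non-finite values in variable '", v, "'")
  }
  training <- is.null(schema)
  if (training) {
    centers <- vapply(vars, function(v) {
      col <- data[[v]]
      if (length(unique(col)) > 2L) mean(col) else 0
    }, 0)
    schema <- list(centers = centers, splines = list())
  }
  n <- nrow(data)
  cols <- vector("list", length(spec$terms) + 1L)
  cols[[1L]] <- rep(1, n)
  labels <- c("(Intercept)", vapply(spec$terms, term_label, ""))
  centered <- function(v) data[[v]] - schema$centers[[v]]
  for (j in seq_along(spec$terms)) {
    tm <- spec$terms[[j]]
    cols[[j + 1L]] <- switch(tm$type,
      main    = centered(tm$var),
      power   = centered(tm$var)^tm$k,
      product = centered(tm$v1)^tm$k1 * centered(tm$v2)^tm$k2,
      smooth  = {
        key <- term_label(tm)
        x <- data[[tm$var]]
        if (training) {
          basis <- splines::ns(x, df = tm$df)
          schema$splines[[key]] <- list(
            knots = attr(basis, "knots"),
            Boundary.knots = attr(basis, "Boundary.knots"))
        } else {
          sp <- schema$splines[[key]]
          if (is.null(sp)) stop_input("schema mismatch: no spline info for ", key)
          basis <- splines::ns(x, knots = sp$knots,
                               Boundary.knots = sp$Boundary.knots)
        }
        basis
      })
  }
  widths <- vapply(cols, NCOL, 0L)
  X <- do.call(cbind, cols)
  colnames(X) <- unlist(mapply(function(lab, w) {
    if (w == 1L) lab else paste0(lab, ".", seq_len(w))
  }, labels, widths, SIMPLIFY = FALSE))
  attr(X, "schema") <- schema
  X
}

spec_family <- function(spec) {
  switch(spec$family,
         normal   = stats::gaussian(),
         gamma    = stats::Gamma(link = "log"),
         binomial = stats::binomial())
}

#' Fit one candidate learner
#'
#' Fits the GLM described by `spec` by iteratively reweighted least squares
#' (relative deviance tolerance 1e-8, at most 100 iterations). The normal
#' dispersion is the maximum-likelihood mean squared residual; the gamma
#' dispersion is the Pearson chi-square estimator. With `shrinkage = TRUE`
#' the fit maximizes a penalized likelihood with a Gaussian prior of scale
#' 2.5 on standardized non-intercept coefficients, which always yields
#' finite coefficients even under separation.
#'
#' @param spec a [candidate_spec()].
#' @param predictors data frame of predictor variables.
#' @param response numeric response vector: binary 0/1 for binomial,
#'   strictly positive for gamma.
#' @return an object of class `fitted_candidate` with elements `spec`,
#'   `coefficients`, `dispersion`, `schema`, `fitted`.
#' @export
fit_candidate <- function(spec, predictors, response) {
  y <- as.numeric(response)
  n <- length(y)
  if (nrow(predictors) != n) stop_input("predictors/response length mismatch")
  if (spec$family == "binomial" && !all(y %in% c(0, 1)))
    stop_input("binomial response must be 0/1")
  if (spec$family == "gamma" && any(y <= 0))
    stop_input("gamma response must be strictly positive")
  X <- expand_design(spec, predictors)
  schema <- attr(X, "schema")
  p <- ncol(X)
  if (n < p + 1L)
    stop_input("too few observations (", n, ") for ", p, " design columns")
  fam <- spec_family(spec)
  if (spec$shrinkage) {
    fit <- penalized_irls(X, y, fam, prior_scale = 2.5)
    beta <- fit$coefficients
    mu <- fit$fitted
  } else {
    warn_sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm.fit(X, y, family = fam,
                     control = stats::glm.control(epsilon = 1e-8, maxit = 100)),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
          warn_sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    if (!fit$converged)
      stop_fit(paste0("IRLS did not converge for candidate '", spec$name, "'"),
               diagnostics = list(deviance = fit$deviance, iter = fit$iter))
    beta <- fit$coefficients
    if (warn_sep && spec$family == "binomial") {
      # boundary warnings are harmless unless coefficients actually diverged
      std <- abs(beta[-1]) * apply(X[, -1, drop = FALSE], 2, stats::sd)
      if (length(std) && max(std, na.rm = TRUE) > 10)
        stop_fit(paste0("separation in binomial fit '", spec$name,
                        "' (use a shrinkage candidate)"),
                 diagnostics = list(deviance = fit$deviance))
    }
    if (any(is.na(beta)))
      stop_fit(paste0("rank-deficient design for candidate '", spec$name, "'"),
               diagnostics = list(aliased = colnames(X)[is.na(beta)]))
    mu <- fit$fitted.values
  }
  dispersion <- switch(spec$family,
    normal   = mean((y - mu)^2),
    gamma    = sum(((y - mu) / mu)^2) / max(n - p, 1L),
    binomial = NA_real_)
  structure(list(spec = spec, coefficients = beta, dispersion = dispersion,
                 schema = schema, fitted = as.numeric(mu), n = n),
            class = "fitted_candidate")
}

# Ridge-penalized IRLS: Gaussian prior (scale `prior_scale`) on standardized
# non-intercept coefficients; the intercept is unpenalized.
penalized_irls <- function(X, y, fam, prior_scale = 2.5,
                           epsilon = 1e-8, maxit = 100L) {
  n <- nrow(X); p <- ncol(X)
  sds <- apply(X, 2, stats::sd)
  lambda <- (sds / prior_scale)^2
  lambda[1L] <- 0
  Lam <- diag(lambda, p)
  mustart <- switch(fam$family,
                    binomial = (y + 0.5) / 2,
                    Gamma = pmax(y, 1e-8),
                    y)
  eta <- fam$linkfun(mustart)
  beta <- rep(0, p)
  pdev_old <- Inf
  for (iter in seq_len(maxit)) {
    mu <- fam$linkinv(eta)
    mu_eta <- fam$mu.eta(eta)
    varmu <- fam$variance(mu)
    good <- mu_eta != 0 & varmu > 0
    w <- mu_eta[good]^2 / varmu[good]
    z <- eta[good] + (y[good] - mu[good]) / mu_eta[good]
    Xg <- X[good, , drop = FALSE]
    XtW <- t(Xg * w)
    beta <- solve(XtW %*% Xg + Lam, XtW %*% z)
    eta <- as.numeric(X %*% beta)
    mu <- fam$linkinv(eta)
    pdev <- sum(fam$dev.resids(y, mu, rep(1, n))) + sum(lambda * beta^2)
    if (is.finite(pdev_old) &&
        abs(pdev - pdev_old) / (abs(pdev) + 0.1) < epsilon) break
    pdev_old <- pdev
  }
  list(coefficients = stats::setNames(as.numeric(beta), colnames(X)),
       fitted = mu, iter = iter)
}

#' Predict conditional means from a fitted candidate
#'
#' Applies the frozen design schema to `new_data` and returns the
#' inverse-link of the linear predictor.
#'
#' @param fitted a `fitted_candidate`.
#' @param new_data data frame containing every variable in the schema.
#' @return numeric vector of conditional means.
#' @export
predict_mean <- function(fitted, new_data) {
  X <- expand_design(fitted$spec, new_data, schema = fitted$schema)
  if (ncol(X) != length(fitted$coefficients))
    stop_input("design schema mismatch at prediction time")
  fam <- spec_family(fitted$spec)
  as.numeric(fam$linkinv(X %*% fitted$coefficients))
}

#' Conditional density of the treatment implied by a fitted candidate
#'
#' For a normal-family candidate the conditional law of the treatment given
#' covariates is Gaussian with mean the predicted value and variance the
#' fitted dispersion. For a gamma-log candidate it is gamma with shape
#' `1/phi` and scale `mu * phi` (mean `mu`, variance `phi * mu^2`); the
#' density is 0 for `t <= 0`.
#'
#' @param fitted a `fitted_candidate` with family normal or gamma.
#' @param t treatment value(s): a scalar, or a vector with one value per row
#'   of `data`.
#' @param data covariate rows at which to evaluate.
#' @return nonnegative density values, one per row of `data`.
#' @export
density_at <- function(fitted, t, data) {
  fam <- fitted$spec$family
  if (!fam %in% c("normal", "gamma"))
    stop_input("density_at requires a normal or gamma candidate")
  if (!is.finite(fitted$dispersion) || fitted$dispersion <= 0)
    stop_input("degenerate density: dispersion must be positive")
  mu <- predict_mean(fitted, data)
  if (length(t) == 1L) t <- rep(t, length(mu))
  if (length(t) != length(mu)) stop_input("length(t) must be 1 or nrow(data)")
  if (fam == "normal") {
    stats::dnorm(t, mean = mu, sd = sqrt(fitted$dispersion))
  } else {
    phi <- fitted$dispersion
    out <- numeric(length(t))
    pos <- t > 0
    out[pos] <- stats::dgamma(t[pos], shape = 1 / phi, scale = mu[pos] * phi)
    out
  }
}

#' @export
print.fitted_candidate <- function(x, ...) {
  cat(sprintf("<fitted candidate '%s'> %s-%s, %d coefficients, dispersion %s\n",
              x$spec$name, x$spec$family, x$spec$link, length(x$coefficients),
              format(x$dispersion, digits = 4)))
  invisible(x)
}
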
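# Nonparametric bootstrap for the dose-response and marginal-effect curves,
# re-estimating both Super Learners in every replicate.

#' Bootstrap confidence bands for the dose-response curve
#'
#' Resamples units with replacement `B` times. Each replicate redraws the
#' fold assignment, refits the GPS Super Learner (for the two-stage method)
#' and the outcome Super Learner, and re-estimates the dose-response and
#' marginal-effect curves, so the intervals reflect uncertainty in the
#' estimation of the propensity score and in the model selection itself.
#' 95% bounds are empirical 2.5% / 97.5% percentiles over successful
#' replicates. Replicate seeds derive deterministically from `master_seed`
#' and the replicate index, so results are bit-reproducible and independent
#' of execution order.
#'
#' @param data analysis data frame.
#' @param outcome,treatment,covariates column roles.
#' @param outcome_family `"binomial"` or `"gamma"`.
#' @param method `"gps"` (two-stage) or `"regression"`.
#' @param grid treatment grid (default 1..24).
#' @param B number of bootstrap replicates (default 1000).
#' @param V cross-validation folds per replicate.
#' @param master_seed integer master seed.
#' @param gps_candidates,outcome_candidates candidate lists; `NULL` uses the
#'   defaults of [gps_library()] / [outcome_library()].
#' @param level confidence level (default 0.95).
#' @return object of class `bootstrap_result`: `B`, `succeeded`, `failed`,
#'   `mu` (replicate x grid matrix), `effects`, `ci_mu`, `ci_effect` (each a
#'   list with `lower`, `upper`), `point` (curve and effects on the original
#'   sample), `grid`, `master_seed`.
#' @export
bootstrap_curves <- function(data, outcome, treatment, covariates,
                             outcome_family = c("binomial", "gamma"),
                             method = c("gps", "regression"),
                             grid = 1:24, B = 1000L, V = 10L,
                             master_seed = 1L,
                             gps_candidates = NULL,
                             outcome_candidates = NULL,
                             level = 0.95) {
  outcome_family <- match.arg(outcome_family)
  method <- match.arg(method)
  if (B < 1L) stop_input("B must be at least 1")
  n <- nrow(data)
  G <- length(grid)
  fit_once <- function(d, fold_seed) {
    folds <- make_folds(n, V, fold_seed)
    gm <- NULL
    if (method == "gps") {
      gm <- fit_gps(d, treatment, covariates,
                    candidates = gps_candidates, folds = folds)
      om <- fit_outcome_sl(d, outcome, treatment, covariates,
                           outcome_family, mode = "gps", gps = gm,
                           candidates = outcome_candidates, folds = folds)
    } else {
      om <- fit_outcome_sl(d, outcome, treatment, covariates,
                           outcome_family, mode = "covariates",
                           candidates = outcome_candidates, folds = folds)
    }
    curve <- suppressWarnings(estimate_curve(om, d, grid, gps_model = gm))
    list(mu = curve$mu_hat, eff = marginal_effects(curve)$effect)
  }
  point <- fit_once(data, derive_seed(master_seed, 0L))
  mu_mat <- matrix(NA_real_, B, G)
  eff_mat <- matrix(NA_real_, B, G - 1L)
  failed <- 0L
  for (b in seq_len(B)) {
    seed_b <- derive_seed(master_seed, b)
    idx <- with_seed(seed_b, sample.int(n, n, replace = TRUE))
    res <- tryCatch(
      suppressWarnings(fit_once(data[idx, , drop = FALSE],
                                derive_seed(seed_b, 1L))),
      error = function(e) NULL)
    if (is.null(res)) { failed <- failed + 1L; next }
    mu_mat[b, ] <- res$mu
    eff_mat[b, ] <- res$eff
  }
  if (failed > 0.10 * B)
    stop_fit(sprintf("bootstrap failure rate too high: %d of %d replicates",
                     failed, B))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  qci <- function(m) list(
    lower = apply(m, 2, stats::quantile, probs = probs[1], na.rm = TRUE),
    upper = apply(m, 2, stats::quantile, probs = probs[2], na.rm = TRUE))
  structure(list(B = B, succeeded = B - failed, failed = failed,
                 mu = mu_mat, effects = eff_mat,
                 ci_mu = qci(mu_mat), ci_effect = qci(eff_mat),
                 point = point, grid = as.numeric(grid),
                 effect_t = as.numeric(grid)[-1L],
                 level = level, master_seed = master_seed,
                 method = method),
            class = "bootstrap_result")
}

#' Which marginal effects are statistically distinguishable from zero
#'
#' Flags each grid point whose bootstrap percentile CI for the marginal
#' treatment effect excludes 0, and states the overall conclusion: when all
#' intervals contain 0, the null hypothesis of no incremental treatment
#' effect is not rejected at the `1 - level` significance level.
#'
#' @param result a [bootstrap_curves()] result.
#' @return list with `excludes_zero` (named logical vector over the effect
#'   grid), `any_significant`, `conclusion` (character).
#' @export
significance_summary <- function(result) {
  lo <- result$ci_effect$lower
  hi <- result$ci_effect$upper
  excl <- lo > 0 | hi < 0
  names(excl) <- format(result$effect_t, trim = TRUE)
  alpha <- 1 - result$level
  conclusion <- if (any(excl)) {
    sprintf("marginal effect CIs exclude zero at %d grid point(s); a zero incremental effect is rejected there at the %.0f%% level",
            sum(excl), 100 * alpha)
  } else {
    sprintf("all marginal effect CIs contain zero: the null of no incremental treatment effect is not rejected at the %.0f%% level",
            100 * alpha)
  }
  list(excludes_zero = excl, any_significant = any(excl),
       conclusion = conclusion)
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Bootstrap (%s method): %d replicates (%d failed), %.0f%% percentile CIs\n",
    x$method, x$B, x$failed, 100 * x$level))
  df <- data.frame(t = x$grid, estimate = round(x$point$mu, 5),
                   lower = round(x$ci_mu$lower, 5),
                   upper = round(x$ci_mu$upper, 5))
  print(utils::head(df, 8))
  if (length(x$grid) > 8) cat("  ... (", length(x$grid), "grid points )\n")
  cat(significance_summary(x)$conclusion, "\n")
  invisible(x)
}

#' Export bootstrap curves to CSV
#'
#' Writes both curves: dose-response (`quantity = "mu"`) and marginal
#' effects (`quantity = "effect"`), with point estimates and CI bounds.
#'
#' @param result a [bootstrap_curves()] result.
#' @param path output path.
#' @export
write_bootstrap_csv <- function(result, path) {
  df <- rbind(
    data.frame(quantity = "mu", t = result$grid,
               estimate = result$point$mu,
               lower = result$ci_mu$lower, upper = result$ci_mu$upper),
    data.frame(quantity = "effect", t = result$effect_t,
               estimate = result$point$eff,
               lower = result$ci_effect$lower,
               upper = result$ci_effect$upper))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
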
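# Configuration, dataset I/O, and the end-to-end pipeline.

#' Build a run configuration
#'
#' Collects column roles, candidate-library choices, cross-validation and
#' bootstrap controls, and seeds into a validated configuration for
#' [run_pipeline()].
#'
#' @param treatment,outcome column names.
#' @param covariates covariate column names.
#' @param outcome_family `"binomial"` or `"gamma"`.
#' @param methods which estimators to run: any of `"gps"`, `"regression"`.
#' @param V cross-validation folds (default 10).
#' @param grid treatment grid (default 1..24, one-hour increments).
#' @param B bootstrap replicates (default 1000; 0 disables the bootstrap).
#' @param seed master seed governing folds and bootstrap.
#' @param n_blocks GPS blocks for the balance table.
#' @param gps_candidates,outcome_candidates optional candidate lists (or
#'   JSON strings/paths accepted by [candidates_from_json()]); `NULL` uses
#'   the package defaults.
#' @param out_dir output directory for [run_pipeline()] artifacts.
#' @return object of class `run_config`.
#' @export
run_config <- function(treatment, outcome, covariates,
                       outcome_family = c("binomial", "gamma"),
                       methods = c("gps", "regression"),
                       V = 10L, grid = 1:24, B = 1000L, seed = 1L,
                       n_blocks = 5L,
                       gps_candidates = NULL, outcome_candidates = NULL,
                       out_dir = ".") {
  outcome_family <- match.arg(outcome_family)
  methods <- match.arg(methods, several.ok = TRUE)
  if (V < 2) stop_input("V must be at least 2")
  if (!length(grid)) stop_input("grid must be nonempty")
  parse_cands <- function(x) {
    if (is.null(x) || is.list(x)) x else candidates_from_json(x)
  }
  structure(list(treatment = treatment, outcome = outcome,
                 covariates = covariates, outcome_family = outcome_family,
                 methods = methods, V = as.integer(V),
                 grid = as.numeric(grid), B = as.integer(B),
                 seed = as.integer(seed), n_blocks = as.integer(n_blocks),
                 gps_candidates = parse_cands(gps_candidates),
                 outcome_candidates = parse_cands(outcome_candidates),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read an analysis dataset from CSV
#'
#' Reads a headed CSV, checks that every role column exists and is numeric
#' where required, and drops rows with missing values in any used column
#' (complete-case analysis; the number of dropped rows is messaged).
#'
#' @param path CSV path.
#' @param config a [run_config()].
#' @return data frame restricted to complete cases on the used columns.
#' @export
read_dataset <- function(path, config) {
  df <- utils::read.csv(path)
  used <- c(config$treatment, config$outcome, config$covariates)
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols))
    stop_input("missing column(s): ", paste(missing_cols, collapse = ", "))
  tvals <- df[[config$treatment]]
  if (!is.numeric(tvals)) stop_input("treatment column must be numeric")
  cc <- stats::complete.cases(df[, used, drop = FALSE])
  if (any(!cc))
    message(sum(!cc), " row(s) with missing values in used columns dropped")
  df <- df[cc, , drop = FALSE]
  if (any(df[[config$treatment]] <= 0))
    stop_input("treatment must be strictly positive")
  if (config$outcome_family == "binomial" &&
      !all(df[[config$outcome]] %in% c(0, 1)))
    stop_input("binomial outcome must be coded 0/1")
  if (config$outcome_family == "gamma" && any(df[[config$outcome]] <= 0))
    stop_input("gamma outcome must be strictly positive")
  rownames(df) <- NULL
  df
}

#' Run the full estimation pipeline and write its artifacts
#'
#' Fits the GPS Super Learner, the outcome Super Learner(s), the
#' dose-response and marginal-effect curves, the balance and overlap
#' diagnostics, and (when `B > 0`) the bootstrap intervals, writing each
#' result as CSV plus a JSON manifest with the seeds and versions needed to
#' replay the run exactly. The cross-validation report includes one row per
#' candidate and a final "convex_super_learner" row whose risk comes from
#' re-cross-validating the weighted combination.
#'
#' @param config a [run_config()].
#' @param data analysis data frame (e.g. from [read_dataset()] or
#'   [simulate_rain()]).
#' @param ensemble_row compute the re-cross-validated ensemble risk row
#'   (default TRUE; the costliest part of the report).
#' @return invisibly, a list with every fitted object and the paths written.
#' @export
run_pipeline <- function(config, data, ensemble_row = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  pth <- function(f) file.path(config$out_dir, f)
  paths <- character(0)
  n <- nrow(data)
  folds <- make_folds(n, config$V, config$seed)
  res <- list(config = config, folds = folds)

  cv_report <- function(risks, weights, ens_risk) {
    data.frame(candidate = c(names(risks), "convex_super_learner"),
               cv_risk = c(as.numeric(risks), ens_risk),
               weight = c(as.numeric(weights$alpha), NA_real_))
  }

  needs_gps <- "gps" %in% config$methods
  gm <- NULL
  if (needs_gps) {
    gm <- fit_gps(data, config$treatment, config$covariates,
                  candidates = config$gps_candidates, folds = folds)
    res$gps_model <- gm
    ens <- if (ensemble_row) {
      specs <- config$gps_candidates %||%
        gps_library(config$covariates,
                    continuous = config$covariates[vapply(config$covariates,
                      function(v) length(unique(data[[v]])) > 2L, TRUE)])
      cv_risk_of_ensemble(specs, data, data[[config$treatment]], folds,
                          "negloglik")
    } else NA_real_
    utils::write.csv(cv_report(gm$risks, gm$weights, ens),
                     pth("gps_weights.csv"), row.names = FALSE)
    paths <- c(paths, pth("gps_weights.csv"))

    ter <- treatment_tertiles(data[[config$treatment]])
    bal <- balance_table(data, config$treatment, config$covariates, gm,
                         n_blocks = config$n_blocks)
    merged <- merge(bal$unadjusted, bal$adjusted,
                    by = c("covariate", "tertile"),
                    suffixes = c("_unadj", "_adj"))
    utils::write.csv(merged, pth("balance.csv"), row.names = FALSE)
    ov <- overlap_assessment(ter, gm, data)
    utils::write.csv(cbind(ov$per_tertile, off_share = ov$off_share),
                     pth("overlap.csv"), row.names = FALSE)
    res$balance <- bal
    res$overlap <- ov
    paths <- c(paths, pth("balance.csv"), pth("overlap.csv"))
  }

  for (m in config$methods) {
    mode <- if (m == "gps") "gps" else "covariates"
    om <- fit_outcome_sl(data, config$outcome, config$treatment,
                         config$covariates, config$outcome_family,
                         mode = mode, gps = gm,
                         candidates = config$outcome_candidates,
                         folds = folds)
    curve <- suppressWarnings(
      estimate_curve(om, data, config$grid, gps_model = gm))
    eff <- marginal_effects(curve)
    ens <- if (ensemble_row) {
      specs <- lapply(om$candidates, function(f) f$spec)
      design <- if (mode == "gps") {
        d <- data.frame(data[[config$treatment]],
                        evaluate_gps(gm, numeric(0), data)$observed)
        names(d) <- c(config$treatment, om$gps_var)
        d
      } else data[, c(config$treatment, config$covariates), drop = FALSE]
      cv_risk_of_ensemble(specs, design, data[[config$outcome]], folds, "mse")
    } else NA_real_
    utils::write.csv(cv_report(om$risks, om$weights, ens),
                     pth(sprintf("outcome_cv_%s.csv", m)), row.names = FALSE)
    write_curve_csv(curve, pth(sprintf("curve_%s.csv", m)))
    utils::write.csv(data.frame(t = eff$t, effect = eff$effect),
                     pth(sprintf("marginal_effects_%s.csv", m)),
                     row.names = FALSE)
    paths <- c(paths, pth(sprintf("outcome_cv_%s.csv", m)),
               pth(sprintf("curve_%s.csv", m)),
               pth(sprintf("marginal_effects_%s.csv", m)))
    res[[paste0("outcome_", m)]] <- om
    res[[paste0("curve_", m)]] <- curve

    if (config$B > 0L) {
      bt <- bootstrap_curves(data, config$outcome, config$treatment,
                             config$covariates, config$outcome_family,
                             method = m, grid = config$grid, B = config$B,
                             V = config$V, master_seed = config$seed,
                             gps_candidates = config$gps_candidates,
                             outcome_candidates = config$outcome_candidates)
      write_bootstrap_csv(bt, pth(sprintf("bootstrap_%s.csv", m)))
      paths <- c(paths, pth(sprintf("bootstrap_%s.csv", m)))
      res[[paste0("bootstrap_", m)]] <- bt
    }
  }

  manifest <- list(
    package = "gpsdr",
    version = as.character(utils::packageVersion("gpsdr")),
    r_version = as.character(getRversion()),
    seed = config$seed, V = config$V, B = config$B,
    grid = config$grid, methods = config$methods,
    treatment = config$treatment, outcome = config$outcome,
    outcome_family = config$outcome_family,
    covariates = config$covariates, n = n)
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- c(paths, pth("manifest.json"))
  res$paths <- paths
  invisible(res)
}
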
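# shared fixtures and independent oracles for the test suite

rain_covs <- function() {
  c("age", "fg", "fhb", "impact", "extracranial", "severe_gcs",
    "motor_poor", "pupil_unreactive")
}

# small candidate libraries used where full Table-style libraries would be
# needlessly slow
small_gps_lib <- function() gps_library(rain_covs())[c("norm1", "gam1")]

small_outcome_lib_gps <- function(family = "binomial") {
  outcome_library("transfer_time", outcome_family = family,
                  mode = "gps")[c("linear", "quadr_int2")]
}

small_outcome_lib_cov <- function(family = "binomial") {
  outcome_library("transfer_time", rain_covs(), outcome_family = family,
                  mode = "covariates")[c("linear", "quadr_int1")]
}

# build a cv_matrix by hand for optimizer tests
manual_cv_matrix <- function(values, fold_of, loss_kind,
                             names = paste0("c", seq_len(ncol(values)))) {
  folds <- structure(list(n = nrow(values), V = max(fold_of),
                          fold_of = fold_of, seed = 0L),
                     class = "fold_assignment")
  structure(list(values = `colnames<-`(values, names),
                 loss_kind = loss_kind, candidate_names = names,
                 folds = folds, dropped = character(0)),
            class = "cv_matrix")
}

# fold-weighted objective used by the oracles below
fold_weights <- function(fold_of) {
  V <- max(fold_of)
  nv <- tabulate(fold_of, V)
  1 / (V * nv[fold_of])
}

# exact QP oracle for the MSE simplex problem: enumerate active sets and
# solve the equality-constrained KKT system on each support
qp_oracle_simplex <- function(Z, y, fold_of) {
  w <- fold_weights(fold_of)
  K <- ncol(Z)
  A <- crossprod(Z, Z * w)          # K x K
  b <- as.numeric(crossprod(Z, w * y))
  cst <- sum(w * y^2)
  best <- Inf
  subsets <- unlist(lapply(seq_len(K), function(k)
    utils::combn(K, k, simplify = FALSE)), recursive = FALSE)
  for (S in subsets) {
    kk <- length(S)
    KKT <- rbind(cbind(2 * A[S, S, drop = FALSE], rep(1, kk)),
                 c(rep(1, kk), 0))
    rhs <- c(2 * b[S], 1)
    sol <- tryCatch(solve(KKT, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    a <- sol[seq_len(kk)]
    if (any(a < -1e-9)) next
    a <- pmax(a, 0); a <- a / sum(a)
    obj <- cst - 2 * sum(b[S] * a) + as.numeric(t(a) %*% A[S, S] %*% a)
    if (obj < best) best <- obj
  }
  best
}

# brute-force grid oracle for K = 2 (either loss)
grid_oracle_2 <- function(Z, y, fold_of, loss_kind, step = 0.001) {
  w <- fold_weights(fold_of)
  a1 <- seq(0, 1, by = step)
  objs <- vapply(a1, function(a) {
    p <- a * Z[, 1] + (1 - a) * Z[, 2]
    if (loss_kind == "mse") sum(w * (y - p)^2)
    else sum(w * (-log(pmax(p, 1e-300))))
  }, 0)
  min(objs)
}
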
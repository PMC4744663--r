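# V-fold partitioning, cross-validated risk, and the simplex-constrained
# weight optimization shared by the two Super Learners.

#' V-fold assignment
#'
#' Randomly partitions `1..n` into `V` folds whose sizes differ by at most
#' one. Regeneration with the same `(n, V, seed)` is bit-identical; the
#' caller's RNG state is left untouched.
#'
#' @param n number of units.
#' @param V number of folds, `2 <= V <= n`.
#' @param seed integer seed.
#' @return object of class `fold_assignment` with elements `n`, `V`,
#'   `fold_of` (integer vector in `1..V`), `seed`.
#' @export
make_folds <- function(n, V, seed = 1L) {
  if (V < 2 || V > n) stop_input("need 2 <= V <= n (got V=", V, ", n=", n, ")")
  fold_of <- integer(n)
  perm <- with_seed(seed, sample.int(n))
  fold_of[perm] <- rep(seq_len(V), length.out = n)
  structure(list(n = as.integer(n), V = as.integer(V),
                 fold_of = fold_of, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' Held-out cross-validation matrix
#'
#' Trains every candidate on each fold's complement and records, for each
#' unit, the held-out quantity produced by each candidate: the predicted
#' conditional mean (`loss_kind = "mse"`, outcome Super Learner) or the
#' conditional density evaluated at the unit's own treatment value
#' (`loss_kind = "negloglik"`, density Super Learner; entries floored at
#' `floor`). A candidate that fails on any training split is dropped with a
#' warning; an error is raised only if every candidate fails.
#'
#' @param specs list of [candidate_spec()].
#' @param data data frame of predictor variables.
#' @param response response vector (outcome, or the treatment itself for the
#'   density learner).
#' @param folds a [make_folds()] assignment.
#' @param loss_kind `"mse"` or `"negloglik"`.
#' @param floor lower bound applied to density entries before logging.
#' @return object of class `cv_matrix`: `values` (n x K), `loss_kind`,
#'   `candidate_names`, `folds`, `dropped`.
#' @export
cv_heldout_matrix <- function(specs, data, response, folds,
                              loss_kind = c("mse", "negloglik"),
                              floor = 1e-30) {
  loss_kind <- match.arg(loss_kind)
  n <- folds$n
  if (nrow(data) != n || length(response) != n)
    stop_input("data/response do not match fold assignment size")
  K <- length(specs)
  nm <- vapply(specs, function(s) s$name, "")
  vals <- matrix(NA_real_, n, K, dimnames = list(NULL, nm))
  failed <- logical(K)
  why <- character(K)
  for (j in seq_len(K)) {
    for (v in seq_len(folds$V)) {
      hold <- folds$fold_of == v
      fit <- tryCatch(
        fit_candidate(specs[[j]], data[!hold, , drop = FALSE], response[!hold]),
        error = function(e) e)
      if (inherits(fit, "error")) {
        failed[j] <- TRUE
        why[j] <- conditionMessage(fit)
        break
      }
      vals[hold, j] <- if (loss_kind == "mse") {
        predict_mean(fit, data[hold, , drop = FALSE])
      } else {
        pmax(density_at(fit, response[hold], data[hold, , drop = FALSE]), floor)
      }
    }
  }
  if (all(failed))
    stop_fit("every candidate failed during cross-validation",
             diagnostics = why)
  if (any(failed))
    warning("dropped candidate(s) failing on a training split: ",
            paste(nm[failed], collapse = ", "), call. = FALSE)
  structure(list(values = vals[, !failed, drop = FALSE],
                 loss_kind = loss_kind,
                 candidate_names = nm[!failed],
                 folds = folds, dropped = nm[failed]),
            class = "cv_matrix")
}

# per-unit weights giving the fold-average-of-fold-means risk:
# risk = (1/V) * sum_v (1/n_v) * sum_{i in v} loss_i
fold_unit_weights <- function(folds) {
  nv <- tabulate(folds$fold_of, folds$V)
  1 / (folds$V * nv[folds$fold_of])
}

#' Cross-validated risk of each candidate
#'
#' MSE loss: squared error between response and held-out prediction.
#' Negative log-likelihood loss: `-log` of the held-out density. Risks are
#' computed as the average over folds of the within-fold mean loss, which
#' equals the pooled mean when fold sizes are equal.
#'
#' @param matrix a [cv_heldout_matrix()] result.
#' @param response response vector aligned with the matrix rows.
#' @return named numeric vector of risks, one per surviving candidate.
#' @export
candidate_risks <- function(matrix, response) {
  w <- fold_unit_weights(matrix$folds)
  Z <- matrix$values
  risks <- if (matrix$loss_kind == "mse") {
    colSums(w * (response - Z)^2)
  } else {
    colSums(w * (-log(Z)))
  }
  stats::setNames(as.numeric(risks), matrix$candidate_names)
}

#' Risk-minimizing convex combination of candidates
#'
#' Finds the weight vector on the probability simplex minimizing the
#' cross-validated risk of the combined learner: for MSE loss the risk of
#' the row-wise weighted prediction (a convex quadratic program); for
#' negative log-likelihood the mean of `-log` of the row-wise weighted
#' density (convex). Solved by accelerated projected gradient descent with
#' backtracking and exact Euclidean projection onto the simplex (objective
#' tolerance 1e-10); if the solver somehow ends above the best single
#' candidate, it falls back to that vertex (the discrete Super Learner) with
#' a warning.
#'
#' @inheritParams candidate_risks
#' @param tol convergence tolerance on the objective.
#' @param maxit maximum iterations.
#' @return object of class `simplex_weights`: `alpha` (named, nonnegative,
#'   summing to one) and `objective` (achieved cross-validated risk).
#' @export
solve_simplex_weights <- function(matrix, response, tol = 1e-10,
                                  maxit = 20000L) {
  Z <- matrix$values
  K <- ncol(Z)
  nm <- matrix$candidate_names
  w <- fold_unit_weights(matrix$folds)
  y <- response
  if (matrix$loss_kind == "mse") {
    fobj <- function(a) sum(w * (y - as.numeric(Z %*% a))^2)
    grad <- function(a) as.numeric(-2 * crossprod(Z, w * (y - as.numeric(Z %*% a))))
  } else {
    fobj <- function(a) {
      p <- pmax(as.numeric(Z %*% a), 1e-300)
      sum(w * (-log(p)))
    }
    grad <- function(a) {
      p <- pmax(as.numeric(Z %*% a), 1e-300)
      as.numeric(-crossprod(Z, w / p))
    }
  }
  if (K == 1L) {
    a <- 1
    return(structure(list(alpha = stats::setNames(1, nm),
                          objective = fobj(a)),
                     class = "simplex_weights"))
  }
  a <- rep(1 / K, K)
  fa <- fobj(a)
  zprev <- a
  L <- 1
  tk <- 1
  for (it in seq_len(maxit)) {
    g <- grad(a)
    # backtracking on the proximal step
    repeat {
      z <- project_simplex(a - g / L)
      fz <- fobj(z)
      dz <- z - a
      if (fz <= fa + sum(g * dz) + L / 2 * sum(dz^2) + 1e-16) break
      L <- L * 2
      if (L > 1e16) break
    }
    tk1 <- (1 + sqrt(1 + 4 * tk^2)) / 2
    a_new <- z + ((tk - 1) / tk1) * (z - zprev)
    a_new <- project_simplex(a_new)
    fn <- fobj(a_new)
    if (fn > fz) { a_new <- z; fn <- fz }   # monotone variant
    if (abs(fa - fn) < tol * (abs(fa) + 1e-12) && it > 5L) {
      a <- a_new; fa <- fn; break
    }
    zprev <- z; tk <- tk1; a <- a_new; fa <- fn
    L <- max(L / 1.5, 1e-8)
  }
  # vertex safeguard: the simplex minimum never exceeds any vertex value
  vrisk <- candidate_risks(matrix, response)
  best <- which.min(vrisk)
  if (fa > vrisk[best] + 1e-12) {
    warning("weight optimizer did not reach the best single candidate; ",
            "falling back to the discrete Super Learner", call. = FALSE)
    a <- as.numeric(seq_len(K) == best)
    fa <- vrisk[[best]]
  }
  a <- a / sum(a)
  structure(list(alpha = stats::setNames(a, nm), objective = fa),
            class = "simplex_weights")
}

#' @export
print.simplex_weights <- function(x, ...) {
  cat("Super Learner weights (cross-validated risk",
      format(x$objective, digits = 6), ")\n")
  print(round(x$alpha, 4))
  invisible(x)
}

#' Cross-validated risk of the convex Super Learner itself
#'
#' Treats the convex combination as a single learner and cross-validates
#' it: inside each training split the candidates are cross-validated and
#' the simplex weights re-solved, the candidates are refit on the whole
#' training split, and the weighted combination is evaluated on the held-out
#' fold. This is the "re-cross-validation" row reported alongside the
#' candidate risks, supporting the convex-versus-discrete comparison.
#'
#' @inheritParams cv_heldout_matrix
#' @param inner_V folds used inside each training split (default `folds$V`,
#'   capped at the training-split size).
#' @return scalar cross-validated risk of the ensemble.
#' @export
cv_risk_of_ensemble <- function(specs, data, response, folds,
                                loss_kind = c("mse", "negloglik"),
                                inner_V = folds$V, floor = 1e-30) {
  loss_kind <- match.arg(loss_kind)
  n <- folds$n
  w <- fold_unit_weights(folds)
  heldout <- numeric(n)
  for (v in seq_len(folds$V)) {
    hold <- folds$fold_of == v
    tr_data <- data[!hold, , drop = FALSE]
    tr_y <- response[!hold]
    inner <- make_folds(sum(!hold), min(inner_V, sum(!hold)),
                        seed = derive_seed(folds$seed, v))
    cvm <- cv_heldout_matrix(specs, tr_data, tr_y, inner, loss_kind, floor)
    wts <- solve_simplex_weights(cvm, tr_y)
    keep <- specs[vapply(specs, function(s) s$name, "") %in% cvm$candidate_names]
    fits <- lapply(keep, fit_candidate, predictors = tr_data, response = tr_y)
    cols <- vapply(fits, function(f) {
      if (loss_kind == "mse") predict_mean(f, data[hold, , drop = FALSE])
      else pmax(density_at(f, response[hold], data[hold, , drop = FALSE]), floor)
    }, numeric(sum(hold)))
    cols <- matrix(cols, nrow = sum(hold))
    heldout[hold] <- as.numeric(cols %*% wts$alpha)
  }
  if (loss_kind == "mse") sum(w * (response - heldout)^2)
  else sum(w * (-log(pmax(heldout, floor))))
}
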
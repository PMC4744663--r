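#' Term descriptors for candidate linear predictors
#'
#' A candidate learner's linear predictor is an ordered list of term
#' descriptors: main effects, integer powers of a variable, products of two
#' variables, and natural-spline smooths of a continuous variable with a
#' small fixed number of degrees of freedom.
#'
#' @param var,v1,v2 variable names present in the design data.
#' @param k integer power (k >= 2).
#' @param df spline degrees of freedom, 2 or 3.
#' @return a term descriptor (a small list), for use in [candidate_spec()].
#' @name terms
NULL

#' @rdname terms
#' @export
term_main <- function(var) {
  stopifnot(is.character(var), length(var) == 1L)
  structure(list(type = "main", var = var), class = "gpsdr_term")
}

#' @rdname terms
#' @export
term_power <- function(var, k) {
  stopifnot(is.character(var), length(var) == 1L, k >= 2, k == round(k))
  structure(list(type = "power", var = var, k = as.integer(k)),
            class = "gpsdr_term")
}

#' @rdname terms
#' @export
term_product <- function(v1, v2, k1 = 1L, k2 = 1L) {
  stopifnot(is.character(v1), is.character(v2))
  structure(list(type = "product", v1 = v1, v2 = v2,
                 k1 = as.integer(k1), k2 = as.integer(k2)),
            class = "gpsdr_term")
}

#' @rdname terms
#' @export
term_smooth <- function(var, df) {
  stopifnot(is.character(var), length(var) == 1L, df %in% c(2L, 3L))
  structure(list(type = "smooth", var = var, df = as.integer(df)),
            class = "gpsdr_term")
}

term_label <- function(tm) {
  switch(tm$type,
         main    = tm$var,
         power   = paste0(tm$var, "^", tm$k),
         product = paste0(if (tm$k1 > 1) paste0(tm$v1, "^", tm$k1) else tm$v1,
                          ":",
                          if (tm$k2 > 1) paste0(tm$v2, "^", tm$k2) else tm$v2),
         smooth  = paste0("s(", tm$var, ",df=", tm$df, ")"))
}

term_vars <- function(tm) {
  switch(tm$type, main = tm$var, power = tm$var, smooth = tm$var,
         product = c(tm$v1, tm$v2))
}

#' Specify one candidate learner
#'
#' A `candidate_spec` declares a generalized linear (or additive) model used
#' as a Super Learner candidate: the error distribution, link, an ordered
#' list of linear-predictor terms, and whether coefficients are shrunk by a
#' weakly-informative Gaussian prior (a ridge penalty on standardized
#' coefficients, intercept unpenalized).
#'
#' Only the family/link pairs used by the method are allowed:
#' normal-identity, gamma-log and binomial-logit.
#'
#' @param name identifier for tables and weight reports.
#' @param family one of `"normal"`, `"gamma"`, `"binomial"`.
#' @param link one of `"identity"`, `"log"`, `"logit"`; defaults to the
#'   canonical partner of `family`.
#' @param terms list of term descriptors (see [term_main()]).
#' @param shrinkage logical; penalized fit with fixed prior scale 2.5 on
#'   standardized non-intercept coefficients.
#' @return an object of class `candidate_spec`.
#' @export
candidate_spec <- function(name, family = c("normal", "gamma", "binomial"),
                           link = NULL, terms = list(), shrinkage = FALSE) {
  family <- match.arg(family)
  canonical <- c(normal = "identity", gamma = "log", binomial = "logit")
  link <- link %||% canonical[[family]]
  allowed <- list(normal = "identity", gamma = "log", binomial = "logit")
  if (!identical(link, allowed[[family]]))
    stop_input("unsupported family/link pair: ", family, "-", link)
  terms <- lapply(terms, function(tm) {
    if (!inherits(tm, "gpsdr_term")) stop_input("terms must be term descriptors")
    tm
  })
  structure(list(name = name, family = family, link = link,
                 terms = terms, shrinkage = isTRUE(shrinkage)),
            class = "candidate_spec")
}

#' @export
print.candidate_spec <- function(x, ...) {
  cat(sprintf("<candidate '%s'> %s-%s%s\n  terms: %s\n", x$name, x$family,
              x$link, if (x$shrinkage) " (shrinkage)" else "",
              paste(vapply(x$terms, term_label, ""), collapse = " + ")))
  invisible(x)
}

# JSON round trip ------------------------------------------------------------

#' Serialize / deserialize candidate specifications
#'
#' @param specs a list of `candidate_spec` objects.
#' @param json a JSON string or file path produced by `candidates_to_json`.
#' @return `candidates_to_json`: a JSON string; `candidates_from_json`: a
#'   list of `candidate_spec`.
#' @export
candidates_to_json <- function(specs) {
  if (inherits(specs, "candidate_spec")) specs <- list(specs)
  blocks <- lapply(specs, function(s) {
    list(name = s$name, family = s$family, link = s$link,
         shrinkage = s$shrinkage,
         terms = lapply(s$terms, function(tm) unclass(tm)))
  })
  jsonlite::toJSON(blocks, auto_unbox = TRUE, digits = NA)
}

#' @rdname candidates_to_json
#' @export
candidates_from_json <- function(json) {
  blocks <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  lapply(blocks, function(b) {
    terms <- lapply(b$terms, function(tm) {
      switch(tm$type,
             main    = term_main(tm$var),
             power   = term_power(tm$var, tm$k),
             product = term_product(tm$v1, tm$v2, tm$k1 %||% 1L, tm$k2 %||% 1L),
             smooth  = term_smooth(tm$var, tm$df),
             stop_input("unknown term type: ", tm$type))
    })
    candidate_spec(b$name, b$family, b$link, terms, isTRUE(b$shrinkage))
  })
}

# Default candidate libraries -------------------------------------------------

mains <- function(vars) lapply(vars, term_main)

#' Default candidate library for the treatment-density Super Learner
#'
#' Eight conditional-density candidates for a positive continuous treatment:
#' four normal-identity and four gamma-log GLMs sharing linear predictors of
#' increasing complexity -- main effects; main effects plus squares of
#' selected continuous covariates; main effects plus pairwise interactions;
#' and both.
#'
#' @param covariates character vector of covariate names (all enter as main
#'   effects).
#' @param squares continuous covariates whose squares enter the quadratic
#'   candidates (defaults to the first three of `continuous`).
#' @param interactions list of 2-vectors of names giving the interaction
#'   pairs; default pairs the square covariates with each other and, when
#'   present, a severity indicator with the last square covariate.
#' @param continuous covariate names treated as continuous (for defaults).
#' @return list of 8 `candidate_spec` objects (named `norm1..norm4`,
#'   `gam1..gam4`).
#' @export
gps_library <- function(covariates,
                        continuous = covariates,
                        squares = utils::head(intersect(continuous, covariates), 3),
                        interactions = NULL) {
  if (is.null(interactions)) {
    interactions <- list()
    if (length(squares) >= 2) {
      cmb <- utils::combn(squares, 2, simplify = FALSE)
      interactions <- cmb
    }
    binaries <- setdiff(covariates, continuous)
    if (length(binaries) && length(squares))
      interactions <- c(interactions,
                        list(c(binaries[[1]], squares[[length(squares)]])))
  }
  sq <- lapply(squares, term_power, k = 2)
  ia <- lapply(interactions, function(p) term_product(p[[1]], p[[2]]))
  base <- mains(covariates)
  specs <- list()
  for (fam in c("normal", "gamma")) {
    tag <- if (fam == "normal") "norm" else "gam"
    specs[[paste0(tag, 1)]] <- candidate_spec(paste0(tag, 1), fam, terms = base)
    specs[[paste0(tag, 2)]] <- candidate_spec(paste0(tag, 2), fam,
                                              terms = c(base, sq))
    specs[[paste0(tag, 3)]] <- candidate_spec(paste0(tag, 3), fam,
                                              terms = c(base, ia))
    specs[[paste0(tag, 4)]] <- candidate_spec(paste0(tag, 4), fam,
                                              terms = c(base, sq, ia))
  }
  specs
}

#' Default candidate library for the outcome Super Learner
#'
#' Builds the outcome candidate list in either predictor mode:
#'
#' * `mode = "covariates"` (regression adjustment): predictors are the
#'   treatment and all covariates. Candidates: main-terms GLM;
#'   treatment-by-covariate interactions; two quadratic specifications with
#'   treatment-square interactions; a fourth-order polynomial in treatment;
#'   additive natural-spline models (df 2 and 3) of the continuous
#'   predictors; and a shrinkage GLM with main terms.
#' * `mode = "gps"` (two-stage adjustment): predictors are the treatment `A`
#'   and the estimated propensity score `r`. Candidates: main terms;
#'   `A*r` interaction; quadratic in `A` with interactions; the full
#'   quadratic-in-both specification (containing the classical
#'   `a0 + a1 A + a2 A^2 + a3 r + a4 r^2 + a5 A r` model); fourth-order in
#'   `A`; spline smooths of `A` and `r` (df 2, 3); shrinkage GLM.
#'
#' For a binary outcome all candidates are binomial-logit. For a positive
#' continuous (cost-like) outcome, polynomial candidates are gamma-log, a
#' normal-identity main-terms candidate is added, and the smooth and
#' shrinkage candidates are normal-identity.
#'
#' @param treatment treatment variable name.
#' @param covariates covariate names (mode `"covariates"` only).
#' @param outcome_family `"binomial"` or `"gamma"`.
#' @param mode `"covariates"` or `"gps"`.
#' @param continuous continuous covariate names used for interactions and
#'   smooths; defaults to `covariates`.
#' @param gps_var name of the propensity-score column in mode `"gps"`.
#' @return named list of `candidate_spec` objects.
#' @export
outcome_library <- function(treatment, covariates = NULL,
                            outcome_family = c("binomial", "gamma"),
                            mode = c("covariates", "gps"),
                            continuous = covariates,
                            gps_var = ".gps") {
  outcome_family <- match.arg(outcome_family)
  mode <- match.arg(mode)
  binom <- outcome_family == "binomial"
  glm_fam <- if (binom) "binomial" else "gamma"
  A <- treatment
  specs <- list()
  if (mode == "covariates") {
    if (is.null(covariates)) stop_input("covariates required in mode 'covariates'")
    ct <- utils::head(intersect(continuous, covariates), 3)
    base <- c(mains(covariates), list(term_main(A)))
    ia1 <- lapply(ct, function(v) term_product(A, v))
    ia2 <- lapply(ct, function(v) term_product(A, v, k1 = 2L))
    ia3 <- lapply(ct, function(v) term_product(A, v, k2 = 2L))
    sq <- lapply(ct, term_power, k = 2)
    if (!binom)
      specs$linear_normal <- candidate_spec("linear_normal", "normal", terms = base)
    specs$linear <- candidate_spec("linear", glm_fam, terms = base)
    specs$linear_int <- candidate_spec("linear_int", glm_fam, terms = c(base, ia1))
    specs$quadr_int1 <- candidate_spec("quadr_int1", glm_fam,
      terms = c(base, list(term_power(A, 2)), ia1, ia2))
    specs$quadr_int2 <- candidate_spec("quadr_int2", glm_fam,
      terms = c(base, list(term_power(A, 2)), ia1, ia2, ia3, sq))
    specs$fourth <- candidate_spec("fourth", glm_fam,
      terms = c(base, lapply(2:4, function(k) term_power(A, k))))
    smooth_vars <- unique(c(ct, setdiff(continuous, ct), A))
    lin_vars <- setdiff(covariates, continuous)
    sm_fam <- if (binom) "binomial" else "normal"
    for (df in 2:3) {
      specs[[paste0("gam_df", df)]] <- candidate_spec(paste0("gam_df", df),
        sm_fam, terms = c(mains(lin_vars),
                          lapply(smooth_vars, term_smooth, df = df)))
    }
    specs$bayes_glm <- candidate_spec("bayes_glm", sm_fam, terms = base,
                                      shrinkage = TRUE)
  } else {
    r <- gps_var
    base <- list(term_main(A), term_main(r))
    if (!binom)
      specs$linear_normal <- candidate_spec("linear_normal", "normal", terms = base)
    specs$linear <- candidate_spec("linear", glm_fam, terms = base)
    specs$linear_int <- candidate_spec("linear_int", glm_fam,
      terms = c(base, list(term_product(A, r))))
    specs$quadr_int1 <- candidate_spec("quadr_int1", glm_fam,
      terms = c(base, list(term_power(A, 2), term_product(A, r),
                           term_product(A, r, k1 = 2L))))
    specs$quadr_int2 <- candidate_spec("quadr_int2", glm_fam,
      terms = c(base, list(term_power(A, 2), term_product(A, r),
                           term_product(A, r, k1 = 2L), term_power(r, 2),
                           term_product(A, r, k2 = 2L))))
    specs$fourth <- candidate_spec("fourth", glm_fam,
      terms = c(base, lapply(2:4, function(k) term_power(A, k))))
    sm_fam <- if (binom) "binomial" else "normal"
    for (df in 2:3) {
      specs[[paste0("gam_df", df)]] <- candidate_spec(paste0("gam_df", df),
        sm_fam, terms = list(term_smooth(A, df), term_smooth(r, df)))
    }
    specs$bayes_glm <- candidate_spec("bayes_glm", sm_fam, terms = base,
                                      shrinkage = TRUE)
  }
  specs
}

#' The classical quadratic treatment-and-score outcome model
#'
#' Convenience spec for the parametric second-stage model
#' `E[Y | A, r] = a0 + a1 A + a2 A^2 + a3 r + a4 r^2 + a5 A r`.
#'
#' @inheritParams outcome_library
#' @param family GLM family for the outcome.
#' @export
hi_quadratic <- function(treatment, gps_var = ".gps",
                         family = c("normal", "gamma", "binomial")) {
  family <- match.arg(family)
  A <- treatment; r <- gps_var
  candidate_spec("hi_quadratic", family,
                 terms = list(term_main(A), term_power(A, 2), term_main(r),
                              term_power(r, 2), term_product(r, A)))
}
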
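test_that("design expansion produces intercept, powers and products in spec order", {
  d <- data.frame(x = c(1, 2, 3), z = c(3, 4, 5))
  sp <- candidate_spec("m", "normal", terms = list(term_main("x")))
  X <- expand_design(sp, d)
  # x has 3 distinct values -> centered at its mean (2)
  expect_equal(unname(X[, 1]), c(1, 1, 1))
  expect_equal(unname(X[, 2]), c(-1, 0, 1))

  d2 <- data.frame(x = c(0, 2), z = c(0, 1))   # two distinct values: no centering
  sp2 <- candidate_spec("m", "normal",
                        terms = list(term_main("x"), term_power("x", 2)))
  X2 <- expand_design(sp2, d2)
  expect_equal(unname(X2[2, ]), c(1, 2, 4))

  sp3 <- candidate_spec("m", "normal", terms = list(term_product("x", "z")))
  X3 <- expand_design(sp3, data.frame(x = c(1, 2), z = c(3, 4)))
  expect_equal(unname(X3[, 2]), c(1 * 3, 2 * 4))

  expect_error(expand_design(sp, data.frame(w = 1:3)), "unknown variable")
  expect_error(expand_design(sp, data.frame(x = c(1, NA, 3), z = 1:3)),
               "non-finite")
})

test_that("prediction through the frozen schema reproduces training expansion", {
  set.seed(1)
  d <- data.frame(x = rnorm(50), z = rnorm(50))
  sp <- candidate_spec("m", "normal",
                       terms = list(term_main("x"), term_power("x", 2),
                                    term_product("x", "z"),
                                    term_smooth("z", 3)))
  y <- rnorm(50)
  fit <- fit_candidate(sp, d, y)
  expect_identical(predict_mean(fit, d), fit$fitted)
  # row-order invariance
  ord <- sample(50)
  expect_equal(predict_mean(fit, d[ord, ]), predict_mean(fit, d)[ord])
})

test_that("normal-identity fit matches closed-form least squares with ML dispersion", {
  set.seed(2)
  d <- data.frame(x = rnorm(40), z = rnorm(40))
  y <- 1 + 2 * d$x - d$z + rnorm(40, sd = 0.3)
  sp <- candidate_spec("ols", "normal",
                       terms = list(term_main("x"), term_main("z")))
  fit <- fit_candidate(sp, d, y)
  X <- cbind(1, d$x - mean(d$x), d$z - mean(d$z))
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(unname(fit$coefficients), as.numeric(beta), tolerance = 1e-8)
  res <- y - X %*% beta
  expect_equal(fit$dispersion, mean(res^2), tolerance = 1e-10)

  # exact linear data: slope recovered, dispersion ~ 0
  y2 <- 2 * d$x
  fit2 <- fit_candidate(candidate_spec("e", "normal",
                                       terms = list(term_main("x"))), d, y2)
  expect_equal(unname(fit2$coefficients[2]), 2, tolerance = 1e-8)
  expect_lt(fit2$dispersion, 1e-16)
})

test_that("binomial fit on a balanced table has null covariate coefficients", {
  d <- data.frame(x = rep(c(0, 1), each = 20))
  y <- rep(c(0, 1), times = 20)          # same event rate in both x groups
  sp <- candidate_spec("b", "binomial", terms = list(term_main("x")))
  fit <- fit_candidate(sp, d, y)
  expect_lt(abs(fit$coefficients[2]), 1e-6)
  # logit link, all-zero coefficients predict 0.5
  fit$coefficients[] <- 0
  expect_equal(predict_mean(fit, d), rep(0.5, 40))
})

test_that("gamma-log fit agrees with an independent ML optimizer and the truth", {
  set.seed(3)
  n <- 5000
  d <- data.frame(x = rnorm(n))
  truth <- c(1.2, 0.4)
  mu <- exp(truth[1] + truth[2] * d$x)
  shape <- 4
  y <- rgamma(n, shape = shape, scale = mu / shape)
  sp <- candidate_spec("g", "gamma", terms = list(term_main("x")))
  fit <- fit_candidate(sp, d, y)
  # oracle: generic numerical optimization of the gamma log-likelihood
  # (fixed shape profile is unnecessary: the mean coefficients separate)
  nll <- function(b) {
    m <- exp(b[1] + b[2] * (d$x - mean(d$x)))
    -sum(dgamma(y, shape = shape, scale = m / shape, log = TRUE))
  }
  ora <- optim(c(0, 0), nll, method = "BFGS")
  expect_equal(unname(fit$coefficients), ora$par, tolerance = 1e-3)
  # recentred intercept: truth at centered x
  se <- sqrt(diag(solve(optimHess(ora$par, nll))))
  truth_centered <- c(truth[1] + truth[2] * mean(d$x), truth[2])
  expect_lt(abs(fit$coefficients[1] - truth_centered[1]), 3 * se[1] + 1e-3)
  expect_lt(abs(fit$coefficients[2] - truth_centered[2]), 3 * se[2] + 1e-3)
})

test_that("family constraints and degenerate inputs are rejected", {
  d <- data.frame(x = rnorm(30))
  expect_error(fit_candidate(candidate_spec("b", "binomial",
                                            terms = list(term_main("x"))),
                             d, rnorm(30)), "0/1")
  expect_error(fit_candidate(candidate_spec("g", "gamma",
                                            terms = list(term_main("x"))),
                             d, c(-1, rexp(29))), "positive")
  expect_error(candidate_spec("bad", "gamma", link = "identity"),
               "family/link")
  # too few rows for the expanded design
  expect_error(fit_candidate(candidate_spec("m", "normal",
                               terms = list(term_main("x"), term_power("x", 2),
                                            term_power("x", 3))),
                             d[1:4, , drop = FALSE], rnorm(4)),
               "too few")
})

test_that("densities match the stated families and integrate to one over their support", {
  set.seed(4)
  d <- data.frame(x = rnorm(60))
  # normal: standard-normal density value at the mean
  yn <- rnorm(60)
  fitn <- fit_candidate(candidate_spec("n", "normal",
                                       terms = list(term_main("x"))), d, yn)
  fitn$coefficients[] <- 0
  fitn$dispersion <- 1
  expect_equal(density_at(fitn, 0, d[1, , drop = FALSE]), dnorm(0),
               tolerance = 1e-12)
  # gamma: zero density at negative treatment; mean/variance parameterization
  yg <- rgamma(60, shape = 3, scale = 2)
  fitg <- fit_candidate(candidate_spec("g", "gamma",
                                       terms = list(term_main("x"))), d, yg)
  expect_equal(density_at(fitg, -1, d[1, , drop = FALSE]), 0)
  mu1 <- predict_mean(fitg, d[1, , drop = FALSE])
  phi <- fitg$dispersion
  expect_equal(density_at(fitg, 2.5, d[1, , drop = FALSE]),
               dgamma(2.5, shape = 1 / phi, scale = mu1 * phi))
  # quadrature over the support at 5 covariate rows
  for (fit in list(fitn, fitg)) {
    lo <- if (fit$spec$family == "gamma") 0 else -Inf
    for (i in 1:5) {
      int <- integrate(function(t)
        density_at(fit, t, d[rep(i, length(t)), , drop = FALSE]),
        lo, Inf, rel.tol = 1e-9)$value
      expect_equal(int, 1, tolerance = 1e-3)
    }
  }
  fit0 <- fitn
  fit0$dispersion <- 0
  expect_error(density_at(fit0, 0, d[1, , drop = FALSE]), "degenerate")
})

test_that("shrinkage fits shrink: smaller coefficient norm, and they survive separation", {
  set.seed(5)
  d <- data.frame(x = rnorm(80), z = rnorm(80))
  y <- rbinom(80, 1, plogis(0.5 * d$x))
  terms <- list(term_main("x"), term_main("z"))
  plain <- fit_candidate(candidate_spec("p", "binomial", terms = terms), d, y)
  shrunk <- fit_candidate(candidate_spec("s", "binomial", terms = terms,
                                         shrinkage = TRUE), d, y)
  expect_lt(sum(shrunk$coefficients[-1]^2), sum(plain$coefficients[-1]^2))
  # perfectly separated data: plain fit errors, shrinkage succeeds
  ds <- data.frame(x = c(rnorm(20, -3), rnorm(20, 3)), z = rnorm(40))
  ys <- rep(c(0, 1), each = 20)
  expect_error(fit_candidate(candidate_spec("p", "binomial", terms = terms),
                             ds, ys), "separation")
  sep <- fit_candidate(candidate_spec("s", "binomial", terms = terms,
                                      shrinkage = TRUE), ds, ys)
  expect_true(all(is.finite(sep$coefficients)))
})

test_that("candidate specs survive a JSON round trip", {
  lib <- gps_library(rain_covs())
  lib$extra <- candidate_spec("sm", "binomial",
                              terms = list(term_smooth("age", 3),
                                           term_product("age", "fg", 2L, 1L)),
                              shrinkage = TRUE)
  back <- candidates_from_json(candidates_to_json(lib))
  expect_equal(length(back), length(lib))
  for (i in seq_along(lib)) {
    expect_equal(back[[i]]$name, lib[[i]]$name)
    expect_equal(back[[i]]$family, lib[[i]]$family)
    expect_equal(back[[i]]$shrinkage, lib[[i]]$shrinkage)
    expect_equal(lapply(back[[i]]$terms, unclass),
                 lapply(lib[[i]]$terms, unclass))
  }
})
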
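test_that("tertile assignment follows the quantile convention", {
  ter <- treatment_tertiles(1:9)
  expect_equal(ter$group, rep(1:3, each = 3L))
  expect_equal(ter$counts, rep(3L, 3))
  # 488 distinct values: sizes fixed by the quantile convention
  set.seed(40)
  tv <- sort(runif(488, 1.8, 24))
  ter2 <- treatment_tertiles(tv)
  # brute force from the same convention: cut at type-7 quantiles
  q <- quantile(tv, c(1, 2) / 3, names = FALSE)
  expect_equal(ter2$counts,
               c(sum(tv <= q[1]), sum(tv > q[1] & tv <= q[2]), sum(tv > q[2])))
  expect_equal(ter2$counts, c(163L, 162L, 163L))
  expect_error(treatment_tertiles(rep(5, 30)), "degenerate")
  expect_error(treatment_tertiles(c(1, 2)), "at least 3")
})

test_that("unadjusted balance: zero for identical groups, flagged when degenerate", {
  ter <- treatment_tertiles(1:9)
  X <- data.frame(same = rep(1:3, times = 3L))  # identical composition
  b <- unadjusted_balance(X, ter)
  expect_equal(b$diff, rep(0, 3))
  expect_equal(b$t, rep(0, 3))
  # constant-within-group covariate: infinite t, flagged
  X2 <- data.frame(v = c(0, 0, 0, 1, 1, 1, 1, 1, 1))
  b2 <- unadjusted_balance(X2, ter)
  expect_equal(b2$diff[b2$tertile == 1], -1)
  expect_true(is.infinite(b2$t[b2$tertile == 1]))
  expect_true(b2$degenerate[b2$tertile == 1])
})

test_that("unadjusted t-statistics are calibrated on null covariates", {
  set.seed(41)
  hits <- 0L
  n_sim <- 200
  for (s in seq_len(n_sim)) {
    tv <- runif(300, 1, 24)
    X <- data.frame(x = rnorm(300))
    b <- unadjusted_balance(X, treatment_tertiles(tv))
    hits <- hits + any(abs(b$t) >= 4)
  }
  expect_lt(hits / n_sim, 0.05)
})

test_that("one GPS block (or a constant GPS) makes adjusted equal unadjusted", {
  d <- simulate_rain(rain_scenario("confounded_null", n = 200, seed = 9))
  gm <- fit_gps(d, "transfer_time", rain_covs(),
                candidates = small_gps_lib(), V = 5, seed = 3)
  ter <- treatment_tertiles(d$transfer_time)
  X <- d[, c("age", "impact")]
  unadj <- unadjusted_balance(X, ter)
  adj1 <- gps_adjusted_balance(X, ter, gm, d, n_blocks = 1L)
  expect_equal(adj1$diff, unadj$diff, tolerance = 1e-12)
  expect_equal(adj1$t, unadj$t, tolerance = 1e-12)
})

test_that("the blockwise weighted mean matches hand arithmetic on a 12-unit example", {
  # two known blocks; compute the adjusted statistic by hand
  tv <- c(1, 2, 3, 4, 9, 10, 11, 12, 20, 21, 22, 23)
  g <- treatment_tertiles(tv)
  expect_equal(g$group, rep(1:3, each = 4L))
  x <- c(0.1, 0.2, 0.3, 0.4, 1.1, 1.2, 1.3, 1.4, 2.1, 2.2, 2.3, 2.4)
  X <- data.frame(x = x)
  # stub GPS model whose mixture density depends deterministically on `x`:
  # a single normal candidate with mean = linear in x and tiny coefficient,
  # evaluated at the tertile medians, gives a monotone score in x, so
  # 2-quantile blocking splits units into lower/upper halves of x.
  d <- data.frame(x = x, transfer_time = tv)
  sp <- candidate_spec("n", "normal", terms = list(term_main("x")))
  gm <- fit_gps(d, "transfer_time", "x", candidates = list(sp), V = 3, seed = 1)
  for (q in 1:3) {
    t_q <- median(tv[g$group == q])
    r_q <- gpsdr:::gps_mixture_density(gm, t_q, d)
    br <- quantile(r_q, c(0, 0.5, 1), names = FALSE)
    blocks <- cut(r_q, br, include.lowest = TRUE, labels = FALSE)
    # hand-computed weighted mean of block-wise differences
    hand_diff <- 0; hand_t <- 0; wsum <- 0
    for (b in 1:2) {
      inb <- blocks == b
      n_in <- sum(inb & g$group == q); n_out <- sum(inb & g$group != q)
      if (n_in == 0 || n_out == 0) next
      xi <- x[inb & g$group == q]; xo <- x[inb & g$group != q]
      dd <- mean(xi) - mean(xo)
      sp2 <- (sum((xi - mean(xi))^2) + sum((xo - mean(xo))^2)) /
        (n_in + n_out - 2)
      tt <- dd / sqrt(sp2 * (1 / n_in + 1 / n_out))
      w <- sum(inb)
      hand_diff <- hand_diff + w * dd; hand_t <- hand_t + w * tt
      wsum <- wsum + w
    }
    adj <- gps_adjusted_balance(X, g, gm, d, n_blocks = 2L)
    got <- adj[adj$tertile == q, ]
    expect_equal(got$diff, hand_diff / wsum, tolerance = 1e-10)
    expect_equal(got$t, hand_t / wsum, tolerance = 1e-10)
  }
})

test_that("adjusted weighted means are invariant to unit reordering", {
  d <- simulate_rain(rain_scenario("confounded_linear", n = 150, seed = 10))
  gm <- fit_gps(d, "transfer_time", rain_covs(),
                candidates = small_gps_lib(), V = 5, seed = 4)
  ter <- treatment_tertiles(d$transfer_time)
  X <- d[, c("age", "fg")]
  a1 <- gps_adjusted_balance(X, ter, gm, d, n_blocks = 5L)
  set.seed(42)
  prm <- sample(nrow(d))
  ter_p <- treatment_tertiles(d$transfer_time[prm])
  a2 <- gps_adjusted_balance(X[prm, , drop = FALSE], ter_p, gm,
                             d[prm, , drop = FALSE], n_blocks = 5L)
  expect_equal(a1$diff, a2$diff, tolerance = 1e-10)
  expect_equal(a1$t, a2$t, tolerance = 1e-10)
})

test_that("overlap: identical score distributions are fully on support, disjoint are off", {
  # stub models via a single-candidate GPS on crafted data
  tv <- rep(c(2, 8, 20), each = 10L)
  ter <- treatment_tertiles(tv)
  # covariate pattern identical within every tertile -> identical score
  # distributions in-group and out-of-group
  d <- data.frame(x = rep(c(0.1, -0.1), 15L), transfer_time = tv)
  sp <- candidate_spec("n", "normal", terms = list(term_main("x")))
  gm <- fit_gps(d, "transfer_time", "x", candidates = list(sp), V = 3, seed = 2)
  ov <- overlap_assessment(ter, gm, d)
  # constant covariates: identical scores in both groups at every tertile
  expect_equal(ov$off_share, 0)
  expect_equal(ov$per_tertile$n_off, rep(0L, 3))

  # now make the covariate (and hence the score) disjoint across tertiles
  d2 <- data.frame(x = rep(c(-8, 0, 8), each = 10L), transfer_time = tv)
  gm2 <- fit_gps(d2, "transfer_time", "x", candidates = list(sp), V = 3, seed = 2)
  ov2 <- overlap_assessment(ter, gm2, d2)
  # brute-force recomputation of the interval rule
  for (q in 1:3) {
    t_q <- median(tv[ter$group == q])
    r_q <- gpsdr:::gps_mixture_density(gm2, t_q, d2)
    lo <- max(min(r_q[ter$group == q]), min(r_q[ter$group != q]))
    hi <- min(max(r_q[ter$group == q]), max(r_q[ter$group != q]))
    expect_equal(ov2$per_tertile$n_off[q], sum(r_q < lo | r_q > hi))
  }
  expect_gt(ov2$off_share, 0)
})

test_that("off-support share is moderate and brute-force-correct on confounded data", {
  d <- simulate_rain(rain_scenario("confounded_linear", n = 300, seed = 11))
  gm <- fit_gps(d, "transfer_time", rain_covs(),
                candidates = small_gps_lib(), V = 5, seed = 5)
  ter <- treatment_tertiles(d$transfer_time)
  ov <- overlap_assessment(ter, gm, d)
  total <- 0L
  for (q in 1:3) {
    t_q <- median(d$transfer_time[ter$group == q])
    r_q <- gpsdr:::gps_mixture_density(gm, t_q, d)
    lo <- max(min(r_q[ter$group == q]), min(r_q[ter$group != q]))
    hi <- min(max(r_q[ter$group == q]), max(r_q[ter$group != q]))
    total <- total + sum(r_q < lo | r_q > hi)
  }
  expect_equal(ov$off_share, total / (3 * nrow(d)))
  expect_gte(ov$off_share, 0)
  expect_lt(ov$off_share, 0.25)
})
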
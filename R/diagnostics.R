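# Balance assessment by blocking on the GPS within treatment tertiles, and
# common-support (overlap) assessment.

#' Categorise the treatment by tertiles
#'
#' Splits the treatment at its empirical 33.3% and 66.7% quantiles.
#' Intervals are left-open / right-closed except the first, which is closed
#' at the minimum; with no ties, group sizes differ by at most one.
#'
#' @param tvals numeric treatment vector, `n >= 3`.
#' @return object of class `treatment_tertiles`: `group` (integer 1..3),
#'   `boundaries` (the two cut points), `counts`.
#' @export
treatment_tertiles <- function(tvals) {
  if (length(tvals) < 3L) stop_input("need at least 3 units")
  q <- stats::quantile(tvals, c(1, 2) / 3, names = FALSE, type = 7)
  group <- 1L + (tvals > q[1]) + (tvals > q[2])
  counts <- tabulate(group, 3L)
  if (any(counts == 0L))
    stop_input("degenerate tertiles: ties leave an empty group")
  structure(list(group = group, boundaries = q, counts = counts,
                 treatment = tvals),
            class = "treatment_tertiles")
}

# pooled-variance two-sample comparison of a covariate between one tertile
# and the rest; Welch form available for sensitivity
two_sample_stat <- function(x_in, x_out, pooled = TRUE) {
  n1 <- length(x_in); n2 <- length(x_out)
  d <- mean(x_in) - mean(x_out)
  v1 <- if (n1 > 1) stats::var(x_in) else 0
  v2 <- if (n2 > 1) stats::var(x_out) else 0
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / max(n1 + n2 - 2, 1)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
  }
  if (se == 0) {
    if (d == 0) list(diff = 0, t = 0, degenerate = TRUE)
    else list(diff = d, t = sign(d) * Inf, degenerate = TRUE)
  } else {
    list(diff = d, t = d / se, degenerate = FALSE)
  }
}

#' Unadjusted covariate balance across treatment tertiles
#'
#' For every covariate and tertile, the difference in covariate means
#' between units in the tertile and all remaining units, with the
#' two-sample t-statistic (pooled variance by default). A covariate with no
#' variance in the comparison is flagged: the t-statistic is 0 when the
#' means agree, infinite (degenerate) otherwise.
#'
#' @param X data frame of covariates.
#' @param tertiles a [treatment_tertiles()] assignment.
#' @param pooled pooled-variance (default) or Welch t-statistics.
#' @return data frame with columns `covariate`, `tertile`, `diff`, `t`,
#'   `degenerate`.
#' @export
unadjusted_balance <- function(X, tertiles, pooled = TRUE) {
  g <- tertiles$group
  out <- expand.grid(covariate = names(X), tertile = 1:3,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- mapply(function(cv, q) {
    s <- two_sample_stat(X[[cv]][g == q], X[[cv]][g != q], pooled)
    c(s$diff, s$t, s$degenerate)
  }, out$covariate, out$tertile)
  out$diff <- res[1, ]
  out$t <- res[2, ]
  out$degenerate <- as.logical(res[3, ])
  out
}

#' GPS-adjusted covariate balance
#'
#' For each treatment tertile: (1) take the median observed treatment in
#' the tertile; (2) evaluate the estimated GPS for every unit at that
#' treatment level; (3) cut these scores into `n_blocks` quantile blocks
#' (right-closed); (4) within each block compute the in-tertile versus rest
#' mean difference and t-statistic; (5) average block statistics weighted by
#' total block counts. Blocks with all units on one side contribute no
#' statistic and are dropped with the weights renormalized (a message
#' records how many).
#'
#' @inheritParams unadjusted_balance
#' @param gps_model a [fit_gps()] result.
#' @param data the analysis data frame (covariates for GPS evaluation).
#' @param n_blocks number of GPS quantile blocks (default 5; 1 reproduces
#'   the unadjusted statistics exactly).
#' @return data frame with columns `covariate`, `tertile`, `diff`, `t`,
#'   `n_blocks_used`, `degenerate`.
#' @export
gps_adjusted_balance <- function(X, tertiles, gps_model, data,
                                 n_blocks = 5L, pooled = TRUE) {
  g <- tertiles$group
  tvals <- tertiles$treatment
  out <- NULL
  for (q in 1:3) {
    t_q <- stats::median(tvals[g == q])
    r_q <- gps_mixture_density(gps_model, t_q, data)
    br <- unique(stats::quantile(r_q, probs = seq(0, 1, length.out = n_blocks + 1),
                                 names = FALSE, type = 7))
    blocks <- if (length(br) > 2L) {
      cut(r_q, breaks = br, include.lowest = TRUE, right = TRUE, labels = FALSE)
    } else rep(1L, length(r_q))
    dropped <- 0L
    for (cv in names(X)) {
      x <- X[[cv]]
      diffs <- c(); ts <- c(); wts <- c(); degen <- FALSE
      for (b in sort(unique(blocks))) {
        inb <- blocks == b
        n_in <- sum(inb & g == q); n_out <- sum(inb & g != q)
        if (n_in == 0L || n_out == 0L) { dropped <- dropped + 1L; next }
        s <- two_sample_stat(x[inb & g == q], x[inb & g != q], pooled)
        degen <- degen || s$degenerate
        diffs <- c(diffs, s$diff); ts <- c(ts, s$t); wts <- c(wts, sum(inb))
      }
      if (!length(wts))
        stop_fit(paste0("no usable GPS block for covariate '", cv,
                        "' in tertile ", q))
      w <- wts / sum(wts)
      out <- rbind(out, data.frame(
        covariate = cv, tertile = q,
        diff = sum(w * diffs), t = sum(w * ts),
        n_blocks_used = length(wts), degenerate = degen))
    }
    if (dropped > 0L)
      message(sprintf(
        "tertile %d: %d one-sided block/covariate pair(s) excluded from the weighted mean",
        q, dropped))
  }
  rownames(out) <- NULL
  out
}

#' Balance table: unadjusted and GPS-adjusted statistics side by side
#'
#' @param data analysis data frame.
#' @param treatment treatment column name.
#' @param covariates covariate names to assess.
#' @param gps_model a [fit_gps()] result.
#' @param n_blocks GPS blocks per tertile.
#' @param pooled pooled-variance t-statistics.
#' @return object of class `balance_table`: `unadjusted`, `adjusted`,
#'   `boundaries`, `counts`.
#' @export
balance_table <- function(data, treatment, covariates, gps_model,
                          n_blocks = 5L, pooled = TRUE) {
  ter <- treatment_tertiles(data[[treatment]])
  X <- data[, covariates, drop = FALSE]
  structure(list(unadjusted = unadjusted_balance(X, ter, pooled),
                 adjusted = gps_adjusted_balance(X, ter, gps_model, data,
                                                 n_blocks, pooled),
                 boundaries = ter$boundaries, counts = ter$counts,
                 treatment = treatment),
            class = "balance_table")
}

#' @export
print.balance_table <- function(x, digits = 2, ...) {
  fmt <- function(d, t) sprintf(paste0("%.", digits, "f (%.", digits, "f)"), d, t)
  covs <- unique(x$unadjusted$covariate)
  lab <- sprintf("T%d", 1:3)
  tab <- matrix("", length(covs), 6,
                dimnames = list(covs, c(paste0("unadj ", lab),
                                        paste0("adj ", lab))))
  for (i in seq_along(covs)) for (q in 1:3) {
    u <- x$unadjusted[x$unadjusted$covariate == covs[i] & x$unadjusted$tertile == q, ]
    a <- x$adjusted[x$adjusted$covariate == covs[i] & x$adjusted$tertile == q, ]
    tab[i, q] <- fmt(u$diff, u$t)
    tab[i, q + 3] <- fmt(a$diff, a$t)
  }
  cat(sprintf("Covariate balance by treatment tertile (cuts at %.3g, %.3g; n = %s)\n",
              x$boundaries[1], x$boundaries[2],
              paste(x$counts, collapse = "/")))
  cat("difference in means (t-statistic), tertile vs rest\n\n")
  print(tab, quote = FALSE)
  invisible(x)
}

#' Common-support assessment on the GPS
#'
#' For each treatment tertile, the GPS is evaluated for all units at the
#' tertile's median treatment level. The common-support interval is
#' bounded below by the larger of the two group minima (in-tertile versus
#' rest) and above by the smaller of the two group maxima; units whose
#' score falls outside it are off support. Reports per-tertile intervals,
#' off-support counts, and the overall share of off-support unit-tertile
#' pairs.
#'
#' @param tertiles a [treatment_tertiles()] assignment.
#' @param gps_model a [fit_gps()] result.
#' @param data the analysis data frame.
#' @return object of class `overlap_assessment`: `per_tertile` (data frame
#'   with `tertile`, `t_median`, `lower`, `upper`, `n_off`), `off_share`.
#' @export
overlap_assessment <- function(tertiles, gps_model, data) {
  g <- tertiles$group
  tvals <- tertiles$treatment
  rows <- NULL
  off_total <- 0L
  for (q in 1:3) {
    t_q <- stats::median(tvals[g == q])
    r_q <- gps_mixture_density(gps_model, t_q, data)
    lo <- max(min(r_q[g == q]), min(r_q[g != q]))
    hi <- min(max(r_q[g == q]), max(r_q[g != q]))
    n_off <- sum(r_q < lo | r_q > hi)
    off_total <- off_total + n_off
    rows <- rbind(rows, data.frame(tertile = q, t_median = t_q,
                                   lower = lo, upper = hi, n_off = n_off))
  }
  structure(list(per_tertile = rows,
                 off_share = off_total / (3L * length(tvals))),
            class = "overlap_assessment")
}

#' @export
print.overlap_assessment <- function(x, ...) {
  cat("Common support on the GPS (per treatment tertile)\n")
  print(transform(x$per_tertile,
                  lower = signif(lower, 4), upper = signif(upper, 4),
                  t_median = signif(t_median, 4)))
  cat(sprintf("Off-support share of unit-tertile pairs: %.1f%%\n",
              100 * x$off_share))
  invisible(x)
}
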
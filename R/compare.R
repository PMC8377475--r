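# ---- Method comparison: model II regression and case bootstrap --------------

# column medians, vectorized for the tiny group sizes the bootstrap uses
# (study scale: 4 trees per group)
col_medians <- function(m) {
  n <- nrow(m)
  if (n == 2L) return(colMeans(m))
  if (n == 3L) return(colSums(m) - pmax(m[1, ], m[2, ], m[3, ]) -
                        pmin(m[1, ], m[2, ], m[3, ]))
  if (n == 4L) return((colSums(m) - pmax(m[1, ], m[2, ], m[3, ], m[4, ]) -
                         pmin(m[1, ], m[2, ], m[3, ], m[4, ])) / 2)
  apply(m, 2, stats::median)
}

#' Major-axis (model II) regression
#'
#' Both variables carry measurement error, so agreement between two methods
#' is assessed with the major axis: the slope is the direction of the first
#' eigenvector of the 2x2 covariance matrix,
#' \deqn{b = (s_{yy} - s_{xx} + \sqrt{(s_{yy}-s_{xx})^2 + 4 s_{xy}^2}) / (2 s_{xy}),}
#' the line passes through the centroid. The slope CI is Jolicoeur's
#' rotation interval: with eigenvalues \eqn{\lambda_1 \ge \lambda_2} and
#' \eqn{F = F_{1-\alpha}(1, n-2)}, the axis angle is rotated by
#' \eqn{\delta = \frac12 \arcsin(2\sqrt{F\lambda_1\lambda_2/(n-2)} /
#' (\lambda_1-\lambda_2))}. The intercept CI is projected through the
#' centroid from the slope limits. A 0 outside the intercept CI flags a
#' fixed bias; a 1 outside the slope CI flags a proportional bias.
#'
#' @param x,y paired measurements (>= 3 complete pairs, nonzero variance in
#'   each).
#' @param level confidence level (default 0.95).
#' @return object of class \code{ma_regression}: slope, intercept, their
#'   CIs, \code{fixed_bias}, \code{proportional_bias}, \code{n},
#'   \code{level}. CI bounds are infinite when the data are too noisy to
#'   bound the axis direction (the F-criterion admits every slope).
#' @export
major_axis_regression <- function(x, y, level = 0.95) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("major-axis regression needs at least 3 pairs")
  sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
  if (sxx == 0 || syy == 0)
    stop("degenerate variance: one of the variables is constant")
  slope <- if (sxy == 0) {
    if (syy > sxx) Inf else 0
  } else (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  xbar <- mean(x); ybar <- mean(y)
  intercept <- if (is.finite(slope)) ybar - slope * xbar else NA_real_
  # eigenvalues of the covariance matrix
  tr <- sxx + syy; det <- sxx * syy - sxy^2
  disc <- sqrt(max(tr^2 / 4 - det, 0))
  l1 <- tr / 2 + disc; l2 <- tr / 2 - disc
  Fq <- stats::qf(level, 1, n - 2)
  if (l1 - l2 <= 0) {
    slope_ci <- c(-Inf, Inf)  # circular scatter: direction unidentifiable
  } else {
    s <- 2 * sqrt(max(Fq * l1 * l2 / (n - 2), 0)) / (l1 - l2)
    if (s >= 1) {
      slope_ci <- c(-Inf, Inf)
    } else {
      delta <- 0.5 * asin(s)
      theta <- atan(slope)
      slope_ci <- tan(c(theta - delta, theta + delta))
      # rotation past the vertical leaves an unbounded slope interval
      if (theta + delta >= pi / 2) slope_ci[2] <- Inf
      if (theta - delta <= -pi / 2) slope_ci[1] <- -Inf
    }
  }
  int_lims <- ybar - rev(slope_ci) * xbar
  intercept_ci <- c(min(int_lims), max(int_lims))
  # last-ulp slack so an exact line (zero-width CI) is not flagged
  tol_s <- 1e-9 * max(1, abs(slope))
  tol_i <- 1e-9 * max(1, abs(intercept), abs(ybar))
  structure(list(
    slope = slope, intercept = intercept,
    slope_ci = slope_ci, intercept_ci = intercept_ci,
    fixed_bias = !(intercept_ci[1] - tol_i <= 0 && 0 <= intercept_ci[2] + tol_i),
    proportional_bias = !(slope_ci[1] - tol_s <= 1 && 1 <= slope_ci[2] + tol_s),
    n = n, level = level
  ), class = "ma_regression")
}

#' @export
print.ma_regression <- function(x, ...) {
  cat(sprintf("Major-axis regression (n = %d, %.0f%% CI):\n", x$n,
              100 * x$level))
  cat(sprintf("  slope     %.4g  [%.4g, %.4g]%s\n", x$slope, x$slope_ci[1],
              x$slope_ci[2],
              if (x$proportional_bias) "  ** proportional bias (1 outside CI)"
              else ""))
  cat(sprintf("  intercept %.4g  [%.4g, %.4g]%s\n", x$intercept,
              x$intercept_ci[1], x$intercept_ci[2],
              if (x$fixed_bias) "  ** fixed bias (0 outside CI)" else ""))
  invisible(x)
}

#' Case-based bootstrap test of a median difference
#'
#' Tests whether the median of a per-tree parameter differs between two
#' methods. The observed statistic is \code{median(a) - median(b)}. Under
#' the null, cases are resampled with replacement \code{n_resamples} times:
#' either from the pooled set of both groups into two groups of the original
#' sizes (\code{scheme = "pooled"}, default) or within each group after
#' centering at its own median (\code{scheme = "centered"}). The achieved
#' significance level (ASL, read like a p-value) is the proportion of
#' resampled absolute differences at least as large as the observed absolute
#' difference — two-tailed by construction.
#'
#' @param a,b numeric per-case (per-tree) parameter values, each >= 2 cases.
#' @param n_resamples reference-distribution size (default 10000; < 1000
#'   warns).
#' @param seed integer seed, required (no hidden global state).
#' @param scheme null-distribution construction, see above.
#' @return object of class \code{bootstrap_result}: \code{observed},
#'   \code{asl}, \code{n_resamples}, \code{seed}, \code{scheme}.
#' @export
bootstrap_median_difference <- function(a, b, n_resamples = 10000L, seed,
                                        scheme = c("pooled", "centered")) {
  scheme <- match.arg(scheme)
  if (missing(seed)) stop("a seed is required for the bootstrap")
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (n_resamples < 1000L)
    warning("fewer than 1000 resamples: the ASL estimate is unstable")
  observed <- stats::median(a) - stats::median(b)
  na <- length(a); nb <- length(b)
  stat <- withr_seed(seed, {
    if (scheme == "pooled") {
      pool <- c(a, b)
      ia <- matrix(sample.int(na + nb, na * n_resamples, replace = TRUE),
                   na, n_resamples)
      ib <- matrix(sample.int(na + nb, nb * n_resamples, replace = TRUE),
                   nb, n_resamples)
      col_medians(matrix(pool[ia], na)) - col_medians(matrix(pool[ib], nb))
    } else {
      ac <- a - stats::median(a); bc <- b - stats::median(b)
      ia <- matrix(sample.int(na, na * n_resamples, replace = TRUE),
                   na, n_resamples)
      ib <- matrix(sample.int(nb, nb * n_resamples, replace = TRUE),
                   nb, n_resamples)
      col_medians(matrix(ac[ia], na)) - col_medians(matrix(bc[ib], nb))
    }
  })
  asl <- mean(abs(stat) >= abs(observed))
  structure(list(observed = observed, asl = asl,
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), scheme = scheme),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf(
    "Case bootstrap (%s null, %d resamples, seed %d): observed diff %.4g, ASL %.4g\n",
    x$scheme, x$n_resamples, x$seed, x$observed, x$asl))
  invisible(x)
}

#' Compare two phenology tables parameter by parameter
#'
#' For each xylogenesis parameter present in both tables: major-axis
#' regression of method A on method B across trees (consistency) and the
#' case-bootstrap ASL of the median difference (agreement).
#'
#' @param tab_a,tab_b phenology tables (as from \code{\link{phenology_table}})
#'   with matching \code{tree} rows.
#' @param params parameter columns to compare; default the shared numeric
#'   xylogenesis parameters.
#' @param n_resamples,seed,scheme passed to
#'   \code{\link{bootstrap_median_difference}}.
#' @return data frame: parameter, observed_diff, asl, slope, intercept, CI
#'   bounds, bias flags.
#' @export
compare_methods <- function(tab_a, tab_b,
                            params = intersect(
                              c("tb_incr", "te_incr", "d_incr", "r_incr",
                                "tb_mat", "te_mat", "d_mat", "r_mat", "d_xylo"),
                              intersect(names(tab_a), names(tab_b))),
                            n_resamples = 10000L, seed,
                            scheme = c("pooled", "centered")) {
  scheme <- match.arg(scheme)
  tab_b <- tab_b[match(tab_a$tree, tab_b$tree), ]
  rows <- lapply(seq_along(params), function(i) {
    p <- params[i]
    x <- tab_a[[p]]; y <- tab_b[[p]]
    ok <- is.finite(x) & is.finite(y)
    ma <- tryCatch(major_axis_regression(x[ok], y[ok]), error = function(e) NULL)
    bt <- bootstrap_median_difference(x[ok], y[ok],
                                      n_resamples = n_resamples,
                                      seed = seed + i, scheme = scheme)
    data.frame(
      parameter = p, n = sum(ok),
      observed_diff = bt$observed, asl = bt$asl,
      slope = if (is.null(ma)) NA_real_ else ma$slope,
      slope_lo = if (is.null(ma)) NA_real_ else ma$slope_ci[1],
      slope_hi = if (is.null(ma)) NA_real_ else ma$slope_ci[2],
      intercept = if (is.null(ma)) NA_real_ else ma$intercept,
      intercept_lo = if (is.null(ma)) NA_real_ else ma$intercept_ci[1],
      intercept_hi = if (is.null(ma)) NA_real_ else ma$intercept_ci[2],
      fixed_bias = if (is.null(ma)) NA else ma$fixed_bias,
      proportional_bias = if (is.null(ma)) NA else ma$proportional_bias)
  })
  do.call(rbind, rows)
}
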
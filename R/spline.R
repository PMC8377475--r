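# ---- P-spline engine ---------------------------------------------------------
#
# Penalized B-spline smoother (Eilers-Marx style: equally spaced knots, cubic
# basis, difference penalty) with delta-method pointwise derivative confidence
# bands and an optional monotone-increasing shape constraint. This is the
# numeric core shared by boundary detection (plateau finding on gray profiles)
# and phenology (monotone seasonal growth curves).

pspline_knots <- function(xl, xu, basis_dim, degree = 3L) {
  nseg <- basis_dim - degree
  if (nseg < 1L) stop("basis_dim must exceed the spline degree (3)")
  h <- (xu - xl) / nseg
  if (h <= 0) stop("degenerate predictor range")
  xl + h * seq(-degree, nseg + degree)  # exact multiples: seq(by=) can drop the end knot
}

pspline_design <- function(knots, x, degree = 3L, deriv = 0L) {
  # clamp away last-ulp excursions at the domain ends
  lo <- knots[degree + 1L]; hi <- knots[length(knots) - degree]
  x <- pmin(pmax(x, lo), hi)
  splines::splineDesign(knots, x, ord = degree + 1L,
                        derivs = rep(deriv, length(x)))
}

#' Fit a penalized B-spline smoother
#'
#' Penalized least-squares fit of a cubic B-spline with equally spaced knots
#' and a difference penalty of order \code{penalty_order} on the coefficients.
#' The smoothing parameter is chosen by generalized cross-validation (GCV) on
#' a logarithmic grid; the returned coefficient covariance is the Bayesian
#' posterior covariance \eqn{\sigma^2 (B'B + \lambda P)^{-1}} used for
#' confidence-band construction.
#'
#' A penalty of order 2 leaves straight lines unpenalized, so exactly linear
#' data are reproduced to numerical tolerance whatever the smoothing
#' parameter.
#'
#' @param x numeric predictor values.
#' @param y numeric responses, same length as \code{x}.
#' @param basis_dim number of basis functions; default
#'   \code{min(20, floor(n/2))}, at least 5.
#' @param penalty_order order of the difference penalty (default 2).
#' @param lambda optional fixed smoothing parameter; if \code{NULL} it is
#'   selected by GCV.
#' @return an object of class \code{pspline_fit} with elements \code{coef},
#'   \code{Vb} (coefficient covariance), \code{lambda}, \code{edf},
#'   \code{sigma2}, \code{domain}, \code{knots}, \code{fitted},
#'   \code{residual_sd}, \code{monotone}.
#' @export
fit_pspline <- function(x, y, basis_dim = NULL, penalty_order = 2L,
                        lambda = NULL) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("fit_pspline needs at least 5 data points")
  if (is.null(basis_dim)) basis_dim <- max(5L, min(20L, floor(n / 2)))
  basis_dim <- as.integer(basis_dim)
  if (basis_dim < 5L) stop("basis_dim must be at least 5")
  if (length(unique(x)) < 2L) stop("rank deficiency: predictor is constant")

  xl <- min(x); xu <- max(x)
  knots <- pspline_knots(xl, xu, basis_dim)
  B <- pspline_design(knots, x)
  D <- diff(diag(basis_dim), differences = penalty_order)
  P <- crossprod(D)
  BtB <- crossprod(B)
  Bty <- crossprod(B, y)

  fit_at <- function(lam) {
    M <- BtB + lam * P
    R <- tryCatch(chol(M), error = function(e)
      stop("rank deficiency: penalized normal equations are singular ",
           "(too few distinct x for basis_dim?)", call. = FALSE))
    beta <- backsolve(R, forwardsolve(t(R), Bty))
    # edf = tr[(BtB + lam P)^-1 BtB]
    Minv <- chol2inv(R)
    edf <- sum(Minv * BtB)  # trace of product of symmetric matrices
    fitted <- drop(B %*% beta)
    rss <- sum((y - fitted)^2)
    list(beta = drop(beta), Minv = Minv, edf = edf, fitted = fitted, rss = rss)
  }

  if (is.null(lambda)) {
    # scale-free grid: reference ratio of curvatures
    ref <- sum(diag(BtB)) / max(sum(diag(P)), .Machine$double.eps)
    grid <- ref * 10^seq(-7, 7, by = 0.5)
    gcv <- vapply(grid, function(lam) {
      f <- fit_at(lam)
      denom <- max(n - f$edf, .Machine$double.eps)
      n * f$rss / denom^2
    }, numeric(1))
    lambda <- grid[which.min(gcv)]
  }
  f <- fit_at(lambda)
  df_resid <- max(n - f$edf, 1e-8)
  sigma2 <- f$rss / df_resid
  Vb <- sigma2 * f$Minv
  structure(list(
    coef = f$beta, Vb = Vb, lambda = lambda, edf = f$edf,
    sigma2 = sigma2, residual_sd = sqrt(sigma2),
    knots = knots, degree = 3L, penalty_order = as.integer(penalty_order),
    domain = c(xl, xu), n = n, fitted = f$fitted, x = x, y = y,
    monotone = FALSE
  ), class = "pspline_fit")
}

#' Predict from a penalized spline fit
#'
#' @param object a \code{pspline_fit}.
#' @param x prediction points; must lie inside the training domain.
#' @param deriv derivative order (0 = curve, 1 = first derivative).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pspline_fit <- function(object, x, deriv = 0L, ...) {
  check_domain(object, x)
  C <- pspline_design(object$knots, x, deriv = as.integer(deriv))
  drop(C %*% object$coef)
}

check_domain <- function(fit, x) {
  eps <- 1e-8 * max(1, diff(fit$domain))
  if (any(x < fit$domain[1] - eps | x > fit$domain[2] + eps))
    stop("prediction grid extends outside the training domain [",
         signif(fit$domain[1], 6), ", ", signif(fit$domain[2], 6), "]")
  invisible(TRUE)
}

#' @export
print.pspline_fit <- function(x, ...) {
  cat(sprintf(
    "P-spline fit%s: %d basis fns, edf %.2f, lambda %.3g, residual sd %.4g\n",
    if (x$monotone) " (monotone increasing)" else "",
    length(x$coef), x$edf, x$lambda, x$residual_sd))
  cat(sprintf("  domain [%.4g, %.4g], n = %d\n",
              x$domain[1], x$domain[2], x$n))
  invisible(x)
}

#' Pointwise confidence band for the fitted derivative
#'
#' Computes the first derivative of the fitted spline on a grid with pointwise
#' confidence bounds. The default is the analytic delta-method band
#' \eqn{C\hat\beta \pm z_{1-\alpha/2}\sqrt{diag(C V_b C')}}; a simulation mode
#' draws coefficient vectors from \eqn{N(\hat\beta, V_b)} and takes pointwise
#' quantiles (requires a seed, for reproducibility).
#'
#' @param fit a \code{pspline_fit}.
#' @param grid numeric grid inside the training domain; default 200 equally
#'   spaced points over the domain.
#' @param level band level (default 0.95).
#' @param mode \code{"analytic"} (default) or \code{"simulation"}.
#' @param nsim simulation draws (simulation mode).
#' @param seed integer seed (required in simulation mode).
#' @return object of class \code{derivative_band}: data frame with columns
#'   \code{grid}, \code{estimate}, \code{lower}, \code{upper} plus attribute
#'   \code{level}.
#' @export
derivative_band <- function(fit, grid = NULL, level = 0.95,
                            mode = c("analytic", "simulation"),
                            nsim = 1000L, seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(grid))
    grid <- seq(fit$domain[1], fit$domain[2], length.out = 200L)
  check_domain(fit, grid)
  stopifnot(level > 0, level < 1)
  C <- pspline_design(fit$knots, grid, deriv = 1L)
  est <- drop(C %*% fit$coef)
  if (mode == "analytic") {
    se <- sqrt(pmax(rowSums((C %*% fit$Vb) * C), 0))
    z <- stats::qnorm(1 - (1 - level) / 2)
    lower <- est - z * se
    upper <- est + z * se
  } else {
    if (is.null(seed)) stop("simulation mode requires a seed")
    k <- length(fit$coef)
    ridge <- 1e-10 * max(diag(fit$Vb), 1e-300)
    L <- chol(fit$Vb + ridge * diag(k))
    zmat <- withr_seed(seed, matrix(stats::rnorm(nsim * k), k, nsim))
    draws <- C %*% (fit$coef + crossprod(L, zmat))
    a <- (1 - level) / 2
    qs <- apply(draws, 1L, stats::quantile, probs = c(a, 1 - a), names = FALSE)
    lower <- qs[1L, ]; upper <- qs[2L, ]
  }
  out <- data.frame(grid = grid, estimate = est, lower = lower, upper = upper)
  structure(out, class = c("derivative_band", "data.frame"),
            level = level, mode = mode,
            yscale = max(abs(fit$y), .Machine$double.eps))
}

# evaluate expr under a local RNG state (seed set, previous state restored)
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Maximal runs where the derivative band contains zero
#'
#' Scans a \code{derivative_band} for maximal contiguous stretches of grid
#' points whose pointwise interval contains 0 (a "constant" part of the fitted
#' curve), discarding runs shorter than \code{min_run_length}.
#'
#' \code{zero_tol} is a relative numerical floor: a point counts as containing
#' zero when \code{[lower - tol, upper + tol]} covers 0 with
#' \code{tol = zero_tol * max(abs(estimate))}. With noisy data the band width
#' dominates and the floor is irrelevant; on effectively noise-free profiles
#' it absorbs the residual ripple of a near-interpolating fit.
#'
#' @param band a \code{derivative_band}.
#' @param min_run_length minimum run length in grid points (default 5).
#' @param zero_tol relative tolerance (default 1e-3).
#' @return data frame (possibly 0-row) with columns \code{start}, \code{end}
#'   (grid positions), \code{start_idx}, \code{end_idx}, \code{length}.
#' @export
find_constant_runs <- function(band, min_run_length = 5L, zero_tol = 1e-3) {
  stopifnot(inherits(band, "derivative_band"), nrow(band) > 0)
  # second term: round-off floor so a perfectly constant response (derivative
  # at machine noise, zero-width band) still reads as constant
  tol <- zero_tol * max(abs(band$estimate), 0) +
    1e-9 * (attr(band, "yscale") %||% 1)
  contains <- (band$lower - tol) <= 0 & (band$upper + tol) >= 0
  r <- rle(contains)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_run_length
  data.frame(
    start = band$grid[starts[keep]],
    end = band$grid[ends[keep]],
    start_idx = starts[keep],
    end_idx = ends[keep],
    length = r$lengths[keep]
  )
}

#' Fit a monotone-increasing penalized B-spline
#'
#' Same basis and penalty as \code{\link{fit_pspline}}, with the fitted curve
#' constrained to be nondecreasing. For a B-spline, nondecreasing coefficients
#' are sufficient for a nondecreasing curve, so the constraint is imposed as
#' nonnegativity of successive coefficient differences and the penalized
#' least-squares problem is solved exactly as a quadratic program
#' (\code{quadprog}). The smoothing parameter comes from GCV on the
#' unconstrained fit; the coefficient covariance is the unconstrained one (a
#' documented approximation — the band is not used for inference on monotone
#' seasonal fits, only for diagnostics).
#'
#' @inheritParams fit_pspline
#' @return a \code{pspline_fit} with \code{monotone = TRUE}; the fitted curve
#'   is verified nondecreasing on a dense grid (tolerance
#'   \code{-1e-8 * diff(range(y))}).
#' @export
fit_monotone_pspline <- function(x, y, basis_dim = NULL, penalty_order = 2L,
                                 lambda = NULL) {
  fit0 <- fit_pspline(x, y, basis_dim = basis_dim,
                      penalty_order = penalty_order, lambda = lambda)
  k <- length(fit0$coef)
  if (all(diff(fit0$coef) >= 0)) {
    fit0$monotone <- TRUE
    return(fit0)
  }
  B <- pspline_design(fit0$knots, fit0$x)
  D <- diff(diag(k), differences = fit0$penalty_order)
  M <- crossprod(B) + fit0$lambda * crossprod(D)
  # ridge for strict positive definiteness required by solve.QP
  M <- M + diag(1e-8 * mean(diag(M)), k)
  Amat <- t(diff(diag(k)))  # constraints: beta_{j+1} - beta_j >= 0
  qp <- quadprog::solve.QP(Dmat = M, dvec = drop(crossprod(B, fit0$y)),
                           Amat = Amat, bvec = rep(0, k - 1L))
  beta <- qp$solution
  beta[abs(beta) < 1e-12] <- 0
  fit0$coef <- beta
  fit0$fitted <- drop(B %*% beta)
  rss <- sum((fit0$y - fit0$fitted)^2)
  df_resid <- max(fit0$n - fit0$edf, 1e-8)
  fit0$sigma2 <- rss / df_resid
  fit0$residual_sd <- sqrt(fit0$sigma2)
  fit0$monotone <- TRUE
  dense <- seq(fit0$domain[1], fit0$domain[2], length.out = 1000L)
  pred <- predict(fit0, dense)
  tol <- -1e-8 * max(diff(range(fit0$y)), .Machine$double.eps)
  if (min(diff(pred)) < tol)
    stop("internal error: monotone fit decreases on the dense check grid")
  fit0
}
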
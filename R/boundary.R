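# ---- Cambium / transition detection and ring-width arithmetic ---------------
#
# The cell-wall gray profile is low and locally flat at the cambium (primary
# walls only), rises across the maturing xylem as secondary walls thicken and
# lignify, and is constant in the mature xylem. Both landmarks are therefore
# found the same way: fit a penalized spline, build the pointwise 95%
# confidence band of its derivative, and look for stretches where the band
# contains zero ("constant parts").

default_min_run <- function(profile) {
  pitch <- attr(profile, "voxel_pitch")
  max(5L, ceiling(25 / pitch))  # 5 grid points or 25 um, whichever is larger
}

# detection fits resolve local features: dense basis, first-order difference
# penalty (shrinks the fit toward local constancy, which localizes where the
# profile actually goes flat far better than the curvature penalty used for
# seasonal curves)
detection_basis <- function(n) max(10L, min(floor(n / 2), 200L))

detection_fit <- function(x, y, basis_dim = NULL) {
  if (is.null(basis_dim)) basis_dim <- detection_basis(length(x))
  fit_pspline(x, y, basis_dim = basis_dim, penalty_order = 1L)
}

# The derivative-band rule is conservative: it declares "constant" only once
# the derivative is indistinguishable from 0, i.e. a few resolution elements
# past the true corner, because the smoother rounds the corner symmetrically.
# Reading the corner as the centre of that rounding removes the bias: fit a
# free two-segment broken stick to the *fitted* curve in a window around the
# raw edge and return the breakpoint with minimal SSE.
refine_edge <- function(fit, edge, halfwidth = 40, step = NULL) {
  if (is.null(step)) step <- max(diff(fit$domain) / 2000, 1e-6)
  lo <- max(fit$domain[1], edge - halfwidth)
  hi <- min(fit$domain[2], edge + halfwidth)
  if (hi - lo < 10 * step) return(edge)
  g <- seq(lo, hi, by = step)
  pr <- predict(fit, g)
  pad <- 5 * step
  cand <- g[g > lo + pad & g < hi - pad]
  if (length(cand) < 3L) return(edge)
  sse <- vapply(cand, function(cc) {
    l <- g <= cc
    s1 <- sum(stats::lm.fit(cbind(1, g[l]), pr[l])$residuals^2)
    s2 <- sum(stats::lm.fit(cbind(1, g[!l]), pr[!l])$residuals^2)
    s1 + s2
  }, numeric(1))
  cand[which.min(sse)]
}

profile_window <- function(profile, lo, hi) {
  keep <- profile$position >= lo & profile$position <= hi &
    is.finite(profile$value)
  profile[keep, , drop = FALSE]
}

#' Detect the cambium position on a cell-wall gray profile
#'
#' Within a manually annotated window bracketing the cambial zone (the
#' density minimum between differentiating phloem and xylem), fits a
#' penalized spline, finds the constant runs of its derivative band and
#' returns the median position of the run at the density minimum. With an
#' even number of run points the bark-ward of the two central positions is
#' taken, so early-season estimates err conservative.
#'
#' @param profile a cell-wall \code{\link{gray_profile}}.
#' @param window numeric c(lo, hi) radial positions (um) bracketing the
#'   cambium; needs >= 10 profile points.
#' @param level confidence level for the derivative band (default 0.95).
#' @param min_run_length minimum constant-run length in grid points; default
#'   5 points or 25 um, whichever is larger.
#' @param basis_dim spline basis dimension (default from data size).
#' @return list with \code{cambium_pos} (um), \code{run} (the selected run),
#'   \code{fit}.
#' @export
detect_cambium <- function(profile, window, level = 0.95,
                           min_run_length = NULL, basis_dim = NULL) {
  stopifnot(inherits(profile, "gray_profile"), length(window) == 2L)
  if (is.null(min_run_length)) min_run_length <- default_min_run(profile)
  w <- profile_window(profile, window[1], window[2])
  if (nrow(w) < 10L) stop("cambium window must contain at least 10 profile points")
  fit <- detection_fit(w$position, w$value, basis_dim = basis_dim)
  grid <- w$position
  band <- derivative_band(fit, grid, level = level)
  runs <- find_constant_runs(band, min_run_length = min_run_length)
  if (nrow(runs) == 0L)
    stop("no constant part found in the cambium window; ",
         "widen the window so it covers the flat density minimum")
  if (nrow(runs) > 1L) {
    # take the run containing the minimum fitted value (the cambial valley)
    pred <- predict(fit, grid)
    i_min <- which.min(pred)
    inside <- runs$start_idx <= i_min & runs$end_idx >= i_min
    runs <- if (any(inside)) runs[which(inside)[1], , drop = FALSE] else {
      run_min <- vapply(seq_len(nrow(runs)), function(j)
        min(pred[runs$start_idx[j]:runs$end_idx[j]]), numeric(1))
      runs[which.min(run_min), , drop = FALSE]
    }
  }
  idx <- runs$start_idx[1]:runs$end_idx[1]
  m <- length(idx)
  med_idx <- idx[ceiling(m / 2)]  # even: lower (bark-ward) central position
  list(cambium_pos = grid[med_idx], run = runs, fit = fit)
}

#' Detect the maturing-to-mature transition
#'
#' Re-expresses positions as distance from the cambium, fits a penalized
#' spline from the cambium to the previous ring boundary, and takes the
#' constant run closest to the cambium as the transition region; its
#' bark-ward ("left") edge is the transition position, so the maturing width
#' is \code{transition_pos - cambium_pos}.
#'
#' @param profile a cell-wall \code{\link{gray_profile}}.
#' @param cambium_pos,prev_boundary_pos radial positions (um),
#'   \code{cambium_pos < prev_boundary_pos} with >= 10 points between.
#' @param level band level (default 0.95).
#' @param min_run_length minimum run length; default as in
#'   \code{\link{detect_cambium}}.
#' @param basis_dim spline basis dimension.
#' @param refine refine the raw band edge to the corner of a two-segment
#'   broken-stick fit of the smoothed curve (default TRUE); the raw
#'   conservative edge sits a few resolution elements pith-ward of the true
#'   corner because the band must first lose significance.
#' @return list with \code{transition_pos} (um, absolute), \code{w_maturing}
#'   (um), \code{no_plateau} flag (TRUE when no constant run exists: the
#'   whole ring is still maturing), \code{fit}, \code{runs}.
#' @export
detect_transition <- function(profile, cambium_pos, prev_boundary_pos,
                              level = 0.95, min_run_length = NULL,
                              basis_dim = NULL, refine = TRUE) {
  stopifnot(inherits(profile, "gray_profile"))
  if (!(cambium_pos < prev_boundary_pos))
    stop("cambium_pos must lie bark-ward of prev_boundary_pos")
  if (is.null(min_run_length)) min_run_length <- default_min_run(profile)
  w <- profile_window(profile, cambium_pos, prev_boundary_pos)
  if (nrow(w) < 10L)
    stop("degenerate ring: fewer than 10 profile points between cambium and boundary")
  d <- w$position - cambium_pos  # distance from the cambium, 0 at cambium
  fit <- detection_fit(d, w$value, basis_dim = basis_dim)
  band <- derivative_band(fit, d, level = level)
  runs <- find_constant_runs(band, min_run_length = min_run_length)
  w_incr <- prev_boundary_pos - cambium_pos
  # a constant run touching distance 0 is the flat cambial zone itself, not
  # mature xylem -- unless it spans essentially the whole ring (fully mature,
  # end-of-season profile)
  if (nrow(runs) > 0L) {
    n_grid <- length(d)
    cambial <- runs$start_idx == 1L & runs$end_idx < n_grid - min_run_length
    runs <- runs[!cambial, , drop = FALSE]
  }
  if (nrow(runs) == 0L)
    return(list(transition_pos = prev_boundary_pos, w_maturing = w_incr,
                no_plateau = TRUE, fit = fit, runs = runs))
  r <- runs[which.min(runs$start), , drop = FALSE]
  edge <- r$start
  if (refine && r$start_idx > 1L)
    edge <- min(max(refine_edge(fit, edge), 0), w_incr)
  list(transition_pos = cambium_pos + edge, w_maturing = edge,
       no_plateau = FALSE, fit = fit, runs = runs)
}

#' Measure ring widths from a cell-wall gray profile
#'
#' Combines cambium and transition detection into the three widths:
#' \code{w_incr = prev_boundary_pos - cambium_pos}, \code{w_maturing} from
#' the transition, \code{w_mat = w_incr - w_maturing}. Additivity holds for
#' every flag state.
#'
#' @param profile a cell-wall \code{\link{gray_profile}}.
#' @param cambium_pos detected (or known) cambium position, um.
#' @param prev_boundary_pos annotated previous ring boundary, um.
#' @param ... passed to \code{\link{detect_transition}}.
#' @return object of class \code{ring_widths}: list with positions, the
#'   three widths and logical flags \code{no_plateau} (early season: whole
#'   ring maturing) and \code{end_of_season} (no maturing zone).
#' @export
measure_widths <- function(profile, cambium_pos, prev_boundary_pos, ...) {
  w_incr <- prev_boundary_pos - cambium_pos
  if (w_incr <= 0)
    stop("negative increment width: check annotation ordering (bark to pith)")
  tr <- detect_transition(profile, cambium_pos, prev_boundary_pos, ...)
  w_maturing <- tr$w_maturing
  w_mat <- w_incr - w_maturing
  if (min(w_incr, w_maturing, w_mat) < 0)
    stop("negative width: annotation or detection ordering bug")
  w_incr <- w_maturing + w_mat  # re-derive so additivity is bit-exact
  structure(list(
    cambium_pos = cambium_pos, transition_pos = tr$transition_pos,
    prev_boundary_pos = prev_boundary_pos,
    w_incr = w_incr, w_maturing = w_maturing, w_mat = w_mat,
    no_plateau = tr$no_plateau,
    end_of_season = !tr$no_plateau && w_maturing == 0,
    fit = tr$fit
  ), class = "ring_widths")
}

#' @export
print.ring_widths <- function(x, ...) {
  cat(sprintf("Ring widths (um): incr %.1f = maturing %.1f + mature %.1f\n",
              x$w_incr, x$w_maturing, x$w_mat))
  cat(sprintf("  cambium %.1f | transition %.1f | boundary %.1f%s%s\n",
              x$cambium_pos, x$transition_pos, x$prev_boundary_pos,
              if (x$no_plateau) " [no plateau: ring still maturing]" else "",
              if (x$end_of_season) " [end of season: no maturing zone]" else ""))
  invisible(x)
}

#' Increment width from microtomy measurements
#'
#' The histology workflow measures mature width, maturing width and cambium
#' width separately; the comparable increment width is
#' \code{w_mat + w_maturing + w_cambium / 2}. When the maturing zone is
#' absent (very end of the growing season) the caller sets
#' \code{w_mat = w_incr}.
#'
#' @param w_mat,w_maturing,w_cambium widths in um, all >= 0.
#' @return increment width, um.
#' @export
microtomy_increment <- function(w_mat, w_maturing, w_cambium) {
  if (any(c(w_mat, w_maturing, w_cambium) < 0))
    stop("widths must be nonnegative")
  w_mat + w_maturing + w_cambium / 2
}
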
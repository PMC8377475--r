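# ---- Synthetic data with known ground truth ---------------------------------
#
# Emulates the measurement substrate: a cell-wall gray-value profile that is
# low and flat around the cambium, rises monotonically across the maturing
# xylem, and plateaus in the mature xylem; a wall/lumen lattice VOI stack at
# ~2.5 um/px; and sigmoidal seasonal growth with tree-level circumferential
# heterogeneity. Everything is deterministic under a fixed seed and every
# generator returns the truth it embodies, so downstream stages are testable
# without scan data.

#' Ground truth for one synthetic forming ring
#'
#' Radial positions are in micrometres from the bark-most slice (slice index
#' increases bark to pith). The cell-wall gray value sits at a low floor in a
#' flat valley of half-width \code{valley_halfwidth} centred on the cambium,
#' rises smoothly (smoothstep) from the valley edge to
#' \code{wall_plateau_gray} at \code{transition_pos}, and stays constant to
#' \code{prev_boundary_pos} and beyond. On the phloem side it rises back
#' towards the bark, giving the density minimum the detector looks for.
#'
#' @param cambium_pos,transition_pos,prev_boundary_pos radial positions (um),
#'   strictly ordered \code{cambium_pos < transition_pos <=
#'   prev_boundary_pos}.
#' @param wall_plateau_gray mature cell-wall gray value (0--65535).
#' @param lumen_gray lumen (air-filled cell interior) gray value,
#'   \code{< wall_plateau_gray}.
#' @param floor_gray cell-wall gray at the cambium (thin primary walls: low
#'   density, but denser than the air in the lumens); default
#'   \code{lumen_gray + 0.15 * (wall_plateau_gray - lumen_gray)}.
#' @param noise_sd additive Gaussian noise sd in gray units (>= 0).
#' @param voxel_pitch um per pixel/slice (default 2.49).
#' @param seed integer seed for the noise.
#' @param valley_halfwidth half-width of the flat cambial valley bottom (um),
#'   centred on \code{cambium_pos} (auto-shrunk to half the maturing width
#'   for very narrow maturing zones).
#' @param phloem_gray gray level the phloem-side rise saturates at; default
#'   60% of the lumen-to-plateau span above the floor.
#' @return object of class \code{ring_truth}.
#' @export
ring_truth <- function(cambium_pos, transition_pos, prev_boundary_pos,
                       wall_plateau_gray = 30000, lumen_gray = 5000,
                       noise_sd = 0, voxel_pitch = 2.49, seed = 1L,
                       valley_halfwidth = 40,
                       phloem_gray = NULL, floor_gray = NULL) {
  if (!(cambium_pos < transition_pos))
    stop("invalid ring truth: cambium_pos must be < transition_pos")
  if (!(transition_pos <= prev_boundary_pos))
    stop("invalid ring truth: transition_pos must be <= prev_boundary_pos")
  if (!(lumen_gray >= 0 && lumen_gray < wall_plateau_gray &&
        wall_plateau_gray <= 65535))
    stop("invalid ring truth: need 0 <= lumen_gray < wall_plateau_gray <= 65535")
  if (noise_sd < 0) stop("invalid ring truth: noise_sd must be >= 0")
  if (is.null(phloem_gray))
    phloem_gray <- lumen_gray + 0.6 * (wall_plateau_gray - lumen_gray)
  if (is.null(floor_gray))
    floor_gray <- lumen_gray + 0.15 * (wall_plateau_gray - lumen_gray)
  if (!(floor_gray < wall_plateau_gray))
    stop("invalid ring truth: floor_gray must be below wall_plateau_gray")
  structure(list(
    cambium_pos = cambium_pos, transition_pos = transition_pos,
    prev_boundary_pos = prev_boundary_pos,
    wall_plateau_gray = wall_plateau_gray, lumen_gray = lumen_gray,
    noise_sd = noise_sd, voxel_pitch = voxel_pitch, seed = as.integer(seed),
    valley_halfwidth = valley_halfwidth, phloem_gray = phloem_gray,
    floor_gray = floor_gray
  ), class = "ring_truth")
}

# noise-free cell-wall gray value at radial position(s) pos (um)
#
# Two-phase density model: a flat valley bottom (primary-walled cambial zone)
# of half-width valley_halfwidth centred exactly on the cambium, a linear
# monotone rise reaching wall_plateau_gray exactly at transition_pos (the
# corner keeps the boundary identifiable from the derivative), then a
# constant plateau through the previous ring boundary and beyond. The phloem
# side mirrors the rise with the same slope, saturating at phloem_gray —
# phloem-side cell-wall differentiation brackets the density minimum.
# The valley half-width auto-shrinks for very narrow maturing zones so the
# ramp always has room.
ring_wall_gray <- function(truth, pos) {
  with(truth, {
    v <- min(valley_halfwidth, 0.5 * (transition_pos - cambium_pos))
    s <- (wall_plateau_gray - floor_gray) /
      max(transition_pos - cambium_pos - v, .Machine$double.eps)
    u <- abs(pos - cambium_pos)  # distance from the cambium
    val <- floor_gray + s * pmax(u - v, 0)
    right <- pos >= cambium_pos
    val[right] <- pmin(val[right], wall_plateau_gray)
    val[!right] <- pmin(val[!right], phloem_gray)
    val[pos >= transition_pos] <- wall_plateau_gray
    val
  })
}

#' Generate a synthetic cell-wall gray profile
#'
#' Evaluates the two-phase density model of \code{\link{ring_truth}} on a
#' regular radial grid (step = \code{voxel_pitch}) and adds Gaussian noise.
#' Deterministic under the truth's seed.
#'
#' @param truth a \code{ring_truth}.
#' @param n_points number of profile points (>= 20); the grid starts at 0 um.
#' @return a \code{\link{gray_profile}} of kind \code{"cell_wall"} with the
#'   truth attached as attribute \code{"truth"}.
#' @export
generate_profile <- function(truth, n_points = 400L) {
  stopifnot(inherits(truth, "ring_truth"))
  if (n_points < 20L) stop("n_points must be at least 20")
  pos <- (seq_len(n_points) - 1L) * truth$voxel_pitch
  val <- ring_wall_gray(truth, pos)
  if (truth$noise_sd > 0)
    val <- val + withr_seed(truth$seed, stats::rnorm(n_points, 0, truth$noise_sd))
  val <- pmin(pmax(val, 0), 65535)
  p <- gray_profile(pos, val, kind = "cell_wall",
                    voxel_pitch = truth$voxel_pitch)
  attr(p, "truth") <- truth
  p
}

#' Generate a synthetic VOI stack
#'
#' Builds an ordered (bark to pith) stack of tangential slices. Each slice is
#' a wall/lumen lattice: a rectangular sample region framed and gridded by
#' cell walls of period \code{cell_period_px} (wall thickness
#' \code{wall_px}), surrounded by dark background (air). Wall pixels take the
#' slice's radial cell-wall gray from the \code{\link{ring_truth}} model,
#' lumen pixels take \code{lumen_gray}, background pixels
#' \code{background_gray}; per-pixel Gaussian noise is added when
#' \code{noise_sd > 0}.
#'
#' @param truth a \code{ring_truth}.
#' @param n_slices number of tangential slices.
#' @param slice_shape integer (rows, cols), each >= 32.
#' @param cell_period_px lattice period in pixels (>= 4).
#' @param wall_px wall thickness in pixels (>= 1, < cell_period_px).
#' @param margin_px background margin around the sample (pixels).
#' @param background_gray air gray value (default 500).
#' @return a \code{\link{voi_stack}} with attributes \code{"truth"},
#'   \code{"sample_fraction"} (sample pixels / slice pixels) and
#'   \code{"wall_fraction"} (wall pixels / sample pixels).
#' @export
generate_voi_stack <- function(truth, n_slices = 200L,
                               slice_shape = c(48L, 48L),
                               cell_period_px = 8L, wall_px = 2L,
                               margin_px = 4L, background_gray = 500) {
  stopifnot(inherits(truth, "ring_truth"))
  if (cell_period_px < 4L) stop("cell_period_px must be >= 4")
  if (any(slice_shape < 32L)) stop("slice_shape dimensions must be >= 32")
  if (wall_px < 1L || wall_px >= cell_period_px)
    stop("wall_px must be in [1, cell_period_px)")
  nr <- slice_shape[1]; nc <- slice_shape[2]
  rows <- seq_len(nr); cols <- seq_len(nc)
  in_r <- rows > margin_px & rows <= nr - margin_px
  in_c <- cols > margin_px & cols <= nc - margin_px
  sample_mask <- outer(in_r, in_c)
  # lattice: wall where (offset mod period) < wall_px, in either direction;
  # the sample border is forced to wall so lumens are enclosed
  gr <- ((rows - margin_px - 1L) %% cell_period_px) < wall_px
  gc <- ((cols - margin_px - 1L) %% cell_period_px) < wall_px
  border_r <- in_r & (rows == margin_px + 1L | rows == nr - margin_px)
  border_c <- in_c & (cols == margin_px + 1L | cols == nc - margin_px)
  wall_mask <- sample_mask & (outer(gr | border_r, rep(TRUE, nc)) |
                              outer(rep(TRUE, nr), gc | border_c))
  pos <- (seq_len(n_slices) - 1L) * truth$voxel_pitch
  wall_gray <- ring_wall_gray(truth, pos)
  base <- matrix(background_gray, nr, nc)
  base[sample_mask & !wall_mask] <- truth$lumen_gray
  slices <- vector("list", n_slices)
  noise <- if (truth$noise_sd > 0)
    withr_seed(truth$seed, stats::rnorm(nr * nc * n_slices, 0, truth$noise_sd))
  else NULL
  for (i in seq_len(n_slices)) {
    s <- base
    s[wall_mask] <- wall_gray[i]
    if (!is.null(noise))
      s <- s + matrix(noise[((i - 1L) * nr * nc + 1L):(i * nr * nc)], nr, nc)
    slices[[i]] <- pmin(pmax(s, 0), 65535)
  }
  cw <- truth$cambium_pos / truth$voxel_pitch
  prev_idx <- min(n_slices,
                  round(truth$prev_boundary_pos / truth$voxel_pitch) + 1L)
  win_hi <- min(prev_idx - 1L, as.integer(ceiling(cw + 60)))
  win_lo <- max(1L, min(as.integer(floor(cw - 60)), win_hi - 10L))
  stack <- voi_stack(
    slices, voxel_pitch = truth$voxel_pitch,
    prev_boundary_index = prev_idx,
    cambium_window = c(win_lo, win_hi)
  )
  attr(stack, "truth") <- truth
  attr(stack, "sample_fraction") <- mean(sample_mask)
  attr(stack, "wall_fraction") <- sum(wall_mask) / sum(sample_mask)
  stack
}

#' Ground truth for a synthetic growing season
#'
#' Seasonal growth of each tree follows a logistic sigmoid
#' \eqn{w(t) = A / (1 + exp(-(t - t0)/s))} for the ring increment and for the
#' mature-xylem width; the mature curve shares the time scale \code{s} and
#' lags the increment (later midpoint, asymptote <= increment asymptote), so
#' mature width never exceeds increment width. Defaults emulate a temperate
#' field campaign: 18 biweekly sampling dates, 4 trees, ~1 mm rings,
#' measurement noise 3% of the asymptote.
#'
#' @param n_trees number of trees (default 4).
#' @param doys sampling days of year, strictly increasing, >= 6 dates
#'   (default 18 biweekly dates from DOY 75).
#' @param asym_incr per-tree increment asymptotes (um); recycled.
#' @param mid_incr per-tree increment midpoints (DOY).
#' @param scale_days logistic time scale (days).
#' @param mat_frac mature asymptote as a fraction of the increment asymptote.
#' @param mat_lag_days midpoint lag of the mature curve (days).
#' @param w_prev per-tree previous-year ring width (um).
#' @param noise_frac measurement noise sd as a fraction of the asymptote.
#' @param biomass_lag_days midpoint lag of the biomass proxy curve (days).
#' @param species species label.
#' @param seed integer seed.
#' @return object of class \code{season_truth}.
#' @export
season_truth <- function(n_trees = 4L,
                         doys = seq(75L, by = 14L, length.out = 18L),
                         asym_incr = c(1000, 1250, 900, 1400),
                         mid_incr = c(160, 170, 155, 175),
                         scale_days = 20,
                         mat_frac = 0.95, mat_lag_days = 25,
                         w_prev = c(1100, 1300, 950, 1500),
                         noise_frac = 0.03,
                         biomass_lag_days = 15,
                         species = "synthetic", seed = 1L) {
  if (length(doys) < 6L) stop("need at least 6 sampling dates")
  if (any(diff(doys) <= 0)) stop("sampling DOYs must be strictly increasing")
  rep_n <- function(v) rep_len(v, n_trees)
  asym_incr <- rep_n(asym_incr); mid_incr <- rep_n(mid_incr)
  w_prev <- rep_n(w_prev); scale_days <- rep_n(scale_days)
  if (any(asym_incr <= 0)) stop("asymptotes must be positive")
  if (mat_frac <= 0 || mat_frac > 1)
    stop("mat_frac must be in (0, 1]: mature asymptote <= increment asymptote")
  structure(list(
    n_trees = as.integer(n_trees), doys = as.integer(doys),
    asym_incr = asym_incr, mid_incr = mid_incr, scale_days = scale_days,
    mat_frac = mat_frac, mat_lag_days = mat_lag_days, w_prev = w_prev,
    noise_frac = noise_frac, biomass_lag_days = biomass_lag_days,
    species = species, seed = as.integer(seed)
  ), class = "season_truth")
}

logistic_width <- function(t, A, t0, s) A / (1 + exp(-(t - t0) / s))

# brute-force 5%/95% crossing dates of the noise-free sigmoid on a 1-day grid
# (linear interpolation between days), relative to the asymptote
sigmoid_critical_dates <- function(A, t0, s, t_range) {
  grid <- seq(floor(t_range[1]), ceiling(t_range[2]), by = 1)
  w <- logistic_width(grid, A, t0, s)
  cross <- function(target) {
    i <- which(w >= target)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1L) return(grid[1])
    grid[i - 1L] + (target - w[i - 1L]) / (w[i] - w[i - 1L])
  }
  c(tb = cross(0.05 * A), te = cross(0.95 * A))
}

#' Generate a synthetic seasonal width and biomass table
#'
#' Draws per-tree, per-date increment, mature and maturing widths plus a
#' biomass proxy from the \code{\link{season_truth}} sigmoids with additive
#' Gaussian noise (clamped at 0), and returns the exact critical dates of the
#' noise-free curves (computed by dense evaluation on a 1-day grid) for
#' recovery tests.
#'
#' @param truth a \code{season_truth}.
#' @return list with elements \code{widths} (data frame: species, tree, doy,
#'   w_incr, w_maturing, w_mat, w_prev), \code{biomass} (species, tree, doy,
#'   b_trunk, w_prev) and \code{truth_dates} (tree, tb_incr, te_incr, tb_mat,
#'   te_mat, peak_doy_incr, peak_doy_biomass).
#' @export
generate_season <- function(truth) {
  stopifnot(inherits(truth, "season_truth"))
  doys <- truth$doys
  nd <- length(doys); nt <- truth$n_trees
  rng <- range(doys)
  rows <- vector("list", nt); brows <- vector("list", nt)
  tdates <- vector("list", nt)
  noise <- withr_seed(truth$seed,
                      stats::rnorm(nt * nd * 3))  # incr, mat, biomass streams
  dim(noise) <- c(nt, nd, 3)
  for (k in seq_len(nt)) {
    A <- truth$asym_incr[k]; t0 <- truth$mid_incr[k]; s <- truth$scale_days[k]
    Am <- truth$mat_frac * A; t0m <- t0 + truth$mat_lag_days
    t0b <- t0 + truth$biomass_lag_days
    sd_w <- truth$noise_frac * A
    w_incr <- pmax(0, logistic_width(doys, A, t0, s) + noise[k, , 1] * sd_w)
    w_mat <- pmax(0, logistic_width(doys, Am, t0m, s) + noise[k, , 2] * sd_w)
    w_mat <- pmin(w_mat, w_incr)  # mature zone cannot exceed the increment
    Ab <- A * 30  # arbitrary gray-sum units
    b <- pmax(0, logistic_width(doys, Ab, t0b, s) + noise[k, , 3] * sd_w * 30)
    rows[[k]] <- data.frame(
      species = truth$species, tree = paste0("t", k), doy = doys,
      w_incr = w_incr, w_maturing = pmax(w_incr - w_mat, 0), w_mat = w_mat,
      w_prev = truth$w_prev[k])
    brows[[k]] <- data.frame(
      species = truth$species, tree = paste0("t", k), doy = doys,
      b_trunk = b, w_prev = truth$w_prev[k])
    ci <- sigmoid_critical_dates(A, t0, s, rng)
    cm <- sigmoid_critical_dates(Am, t0m, s, rng)
    tdates[[k]] <- data.frame(
      tree = paste0("t", k),
      tb_incr = ci["tb"], te_incr = ci["te"],
      tb_mat = cm["tb"], te_mat = cm["te"],
      peak_doy_incr = t0, peak_doy_biomass = t0b, row.names = NULL)
  }
  list(widths = do.call(rbind, rows),
       biomass = do.call(rbind, brows),
       truth_dates = do.call(rbind, tdates))
}

#' Write a seasonal width table to CSV
#'
#' Column layout: species, tree, doy, w_incr, w_maturing, w_mat, w_prev.
#'
#' @param widths data frame as produced by \code{\link{generate_season}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_season_csv <- function(widths, path) {
  utils::write.csv(widths, path, row.names = FALSE)
  invisible(path)
}
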
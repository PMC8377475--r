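# ---- VOI stacks and gray-value profile extraction ---------------------------
#
# Two-pass thresholding per tangential slice: pass 1 masks the sample (wood
# material plus enclosed lumens, via Otsu + hole filling), pass 2 masks cell
# walls within the sample (second Otsu restricted to sample pixels). The mean
# gray over each mask, slice by slice, yields the xylem and cell-wall radial
# gray profiles everything downstream runs on.

#' Construct a VOI stack
#'
#' An ordered stack of 2-D gray-value tangential slices; slice index
#' increases from bark to pith. Annotations (previous ring boundary slice,
#' cambium search window) are manual inputs, matching field practice where
#' the boundary is marked on a reference image.
#'
#' @param slices list of numeric matrices, all the same shape, values in
#'   [0, 65535].
#' @param voxel_pitch um per pixel/slice (default 2.49).
#' @param prev_boundary_index slice index of the previous growth-ring
#'   boundary.
#' @param cambium_window integer c(lo, hi) slice-index range bracketing the
#'   cambium; must end before \code{prev_boundary_index}.
#' @return object of class \code{voi_stack}.
#' @export
voi_stack <- function(slices, voxel_pitch = 2.49, prev_boundary_index,
                      cambium_window) {
  if (length(slices) < 2L) stop("a VOI stack needs at least 2 slices")
  shp <- dim(slices[[1]])
  if (!all(vapply(slices, function(s) identical(dim(s), shp), logical(1))))
    stop("all slices must have the same shape")
  n <- length(slices)
  prev_boundary_index <- as.integer(prev_boundary_index)
  cambium_window <- as.integer(cambium_window)
  if (prev_boundary_index < 1L || prev_boundary_index > n)
    stop("prev_boundary_index outside the stack")
  if (length(cambium_window) != 2L || any(cambium_window < 1L) ||
      any(cambium_window > n) || cambium_window[1] >= cambium_window[2])
    stop("cambium_window must be an increasing slice-index pair inside the stack")
  if (cambium_window[2] >= prev_boundary_index)
    stop("cambium_window must lie before prev_boundary_index (bark to pith order)")
  structure(list(slices = slices, voxel_pitch = voxel_pitch,
                 prev_boundary_index = prev_boundary_index,
                 cambium_window = cambium_window),
            class = "voi_stack")
}

#' @export
print.voi_stack <- function(x, ...) {
  shp <- dim(x$slices[[1]])
  cat(sprintf("VOI stack: %d tangential slices of %d x %d px, pitch %.3g um/px\n",
              length(x$slices), shp[1], shp[2], x$voxel_pitch))
  cat(sprintf("  previous ring boundary at slice %d; cambium window [%d, %d]\n",
              x$prev_boundary_index, x$cambium_window[1], x$cambium_window[2]))
  invisible(x)
}

#' Construct a radial gray-value profile
#'
#' @param positions radial positions (um from the bark-most slice), strictly
#'   increasing with constant step.
#' @param values mean gray values in [0, 65535]; NA marks missing slices.
#' @param kind \code{"xylem"} or \code{"cell_wall"}.
#' @param voxel_pitch um per slice.
#' @param n_pixels optional pixel counts behind each mean.
#' @return object of class \code{gray_profile} (a data frame with columns
#'   \code{position}, \code{value}, and optionally \code{n_pixels}).
#' @export
gray_profile <- function(positions, values, kind = c("cell_wall", "xylem"),
                         voxel_pitch, n_pixels = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(positions) == length(values))
  d <- diff(positions)
  if (any(d <= 0)) stop("positions must be strictly increasing")
  if (max(d) - min(d) > 1e-6 * mean(d))
    stop("positions must have a constant step (the voxel pitch)")
  if (any(values < -1e-9 | values > 65535 + 1e-9, na.rm = TRUE))
    stop("gray values must lie in [0, 65535]")
  df <- data.frame(position = positions, value = values)
  if (!is.null(n_pixels)) df$n_pixels <- n_pixels
  structure(df, class = c("gray_profile", "data.frame"),
            kind = kind, voxel_pitch = voxel_pitch)
}

#' @export
print.gray_profile <- function(x, ...) {
  cat(sprintf("%s gray profile: %d slices, pitch %.3g um, range [%.4g, %.4g]\n",
              attr(x, "kind"), nrow(x), attr(x, "voxel_pitch"),
              min(x$value, na.rm = TRUE), max(x$value, na.rm = TRUE)))
  invisible(x)
}

#' Otsu's threshold
#'
#' Maximizes between-class variance on a 256-bin histogram of the values.
#' Used per stack (one global threshold), not per slice.
#'
#' @param values numeric vector.
#' @param n_bins histogram bins (default 256).
#' @return the threshold (bin upper edge); values > threshold fall in the
#'   bright class.
#' @export
otsu_threshold <- function(values, n_bins = 256L) {
  values <- values[is.finite(values)]
  r <- range(values)
  if (diff(r) == 0) return(r[1])
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  omega <- cumsum(w)
  mu <- cumsum(w * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- -Inf
  k <- which.max(sigma_b)
  breaks[k + 1L]
}

# two-threshold (three-class) Otsu: maximizes between-class variance over all
# bin pairs. The pooled gray histogram of a whole stack is trimodal (air
# background, lumens/primary walls, bright mature walls); the LOWER split
# separates background from sample material, which is what pass 1 needs —
# single-threshold Otsu can latch onto the wall/lumen split instead.
otsu_threshold2 <- function(values, n_bins = 128L) {
  values <- values[is.finite(values)]
  r <- range(values)
  if (diff(r) == 0) return(c(r[1], r[1]))
  breaks <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(values, breaks, all.inside = TRUE), n_bins)
  w <- h / sum(h)
  mids <- (breaks[-1] + breaks[-(n_bins + 1L)]) / 2
  W <- c(0, cumsum(w)); M <- c(0, cumsum(w * mids))
  cls <- function(i, j) {  # between-class contribution of bins (i, j]
    ww <- W[j + 1L] - W[i + 1L]
    if (ww <= 0) return(0)
    (M[j + 1L] - M[i + 1L])^2 / ww
  }
  best <- -Inf; kk <- c(1L, 2L)
  for (k1 in 1:(n_bins - 2L)) for (k2 in (k1 + 1L):(n_bins - 1L)) {
    v <- cls(0L, k1) + cls(k1, k2) + cls(k2, n_bins)
    if (v > best) { best <- v; kk <- c(k1, k2) }
  }
  c(breaks[kk[1] + 1L], breaks[kk[2] + 1L])
}

# fill holes: background is the dark connected region touching the image
# border; everything else (foreground + enclosed dark pockets) is filled.
# Scanline BFS on the matrix, 4-connectivity.
fill_holes <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  outside <- matrix(FALSE, nr, nc)
  # seeds: border pixels not in the mask
  q_r <- integer(0); q_c <- integer(0)
  push <- function(r, c) {
    sel <- !mask[cbind(r, c)] & !outside[cbind(r, c)]
    outside[cbind(r[sel], c[sel])] <<- TRUE
    q_r <<- c(q_r, r[sel]); q_c <<- c(q_c, c[sel])
  }
  push(rep(1L, nc), seq_len(nc)); push(rep(nr, nc), seq_len(nc))
  push(seq_len(nr), rep(1L, nr)); push(seq_len(nr), rep(nc, nr))
  while (length(q_r)) {
    r <- q_r; c <- q_c
    q_r <- integer(0); q_c <- integer(0)
    for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
      rr <- r + d[1]; cc <- c + d[2]
      ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
      if (any(ok)) push(rr[ok], cc[ok])
    }
  }
  !outside
}

#' Mask the sample on one tangential slice
#'
#' First-pass segmentation: Otsu threshold separates bright material from
#' dark background/lumens, then enclosed dark pockets (cell lumens) are
#' filled so the mask covers the whole sample cross-section.
#'
#' @param slice numeric matrix of gray values.
#' @param threshold optional fixed threshold overriding Otsu (per-stack
#'   thresholds are passed down by \code{\link{extract_profiles}}).
#' @return logical matrix; all-\code{FALSE} with a warning when the slice is
#'   uniform (likely outside the sample).
#' @export
mask_sample <- function(slice, threshold = NULL) {
  stopifnot(is.matrix(slice), length(slice) > 0)
  if (diff(range(slice)) == 0) {
    warning("uniform slice: no sample found (slice likely outside the sample)")
    return(matrix(FALSE, nrow(slice), ncol(slice)))
  }
  if (is.null(threshold)) threshold <- otsu_threshold(slice)
  fill_holes(slice >= threshold)
}

#' Mask cell walls within the sample
#'
#' Second-pass segmentation: Otsu threshold restricted to sample pixels
#' separates (bright) cell walls from (dark) lumens. Always a subset of the
#' sample mask; no morphological post-processing.
#'
#' @param slice numeric matrix of gray values.
#' @param sample_mask logical matrix from \code{\link{mask_sample}}.
#' @param threshold optional fixed threshold overriding Otsu.
#' @return logical matrix of wall pixels.
#' @export
mask_cell_wall <- function(slice, sample_mask, threshold = NULL) {
  stopifnot(identical(dim(slice), dim(sample_mask)))
  if (!any(sample_mask))
    stop("empty sample mask: first-pass segmentation found no sample")
  if (is.null(threshold)) threshold <- otsu_threshold(slice[sample_mask])
  sample_mask & slice >= threshold
}

#' Extract xylem and cell-wall gray profiles from a VOI stack
#'
#' Per tangential slice, the xylem profile value is the mean gray over the
#' sample mask and the cell-wall value the mean over the wall mask; radial
#' position is slice index (0-based) times the voxel pitch. The sample
#' threshold (pass 1) is computed once per stack, pooled over a subsample of
#' slices: sample/background contrast does not change along the radius. The
#' wall threshold (pass 2) is computed per slice: wall/lumen contrast rises
#' from nil at the cambium (primary walls and lumens share the same gray,
#' where any split yields the right mean) to strong in mature xylem. Override
#' either via \code{thresholds}. Slices with empty masks become NA
#' (missing), never zero.
#'
#' @param stack a \code{\link{voi_stack}}.
#' @param thresholds optional list(sample=, wall=) fixed thresholds; a
#'   scalar \code{wall} disables the per-slice pass-2 threshold.
#' @return list with elements \code{xylem} and \code{cell_wall}, both
#'   \code{\link{gray_profile}} objects, plus \code{thresholds}.
#' @export
extract_profiles <- function(stack, thresholds = NULL) {
  stopifnot(inherits(stack, "voi_stack"))
  n <- length(stack$slices)
  if (is.null(thresholds)) thresholds <- list(sample = NULL, wall = NULL)
  if (is.null(thresholds$sample)) {
    idx <- unique(round(seq(1L, n, length.out = min(n, 50L))))
    pool <- unlist(lapply(stack$slices[idx], as.vector))
    # lower split of the three-class Otsu: background vs sample material
    thresholds$sample <- otsu_threshold2(pool)[1]
  }
  xy_val <- xy_n <- cw_val <- cw_n <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    s <- stack$slices[[i]]
    m1 <- suppressWarnings(mask_sample(s, threshold = thresholds$sample))
    if (!any(m1)) next
    xy_val[i] <- mean(s[m1]); xy_n[i] <- sum(m1)
    m2 <- mask_cell_wall(s, m1, threshold = thresholds$wall)
    if (!any(m2)) next
    cw_val[i] <- mean(s[m2]); cw_n[i] <- sum(m2)
  }
  if (mean(is.na(cw_val)) > 0.5)
    stop("more than 50% of slices have empty masks: stack unusable")
  pos <- (seq_len(n) - 1L) * stack$voxel_pitch
  list(
    xylem = gray_profile(pos, xy_val, kind = "xylem",
                         voxel_pitch = stack$voxel_pitch, n_pixels = xy_n),
    cell_wall = gray_profile(pos, cw_val, kind = "cell_wall",
                             voxel_pitch = stack$voxel_pitch, n_pixels = cw_n),
    thresholds = thresholds
  )
}

#' Write a gray profile to CSV
#'
#' Columns: position_um, value, n_pixels, kind.
#'
#' @param profile a \code{\link{gray_profile}}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_profile_csv <- function(profile, path) {
  df <- data.frame(position_um = profile$position, value = profile$value,
                   n_pixels = if ("n_pixels" %in% names(profile))
                     profile$n_pixels else NA_real_,
                   kind = attr(profile, "kind"))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a gray profile from CSV
#'
#' @param path CSV written by \code{\link{write_profile_csv}}.
#' @return a \code{\link{gray_profile}}.
#' @export
read_profile_csv <- function(path) {
  df <- utils::read.csv(path)
  pitch <- stats::median(diff(df$position_um))
  gray_profile(df$position_um, df$value, kind = df$kind[1],
               voxel_pitch = pitch, n_pixels = df$n_pixels)
}
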
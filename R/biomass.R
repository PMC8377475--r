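# ---- Biomass proxy and size-vs-biomass time lags ----------------------------
#
# Gray values are linearly related to material density, so the sum of the
# xylem gray profile over the forming ring is a proxy (arbitrary units) for
# the biomass accumulated at the trunk base since growth began. Comparing the
# normalized ("completion") curves of ring width and biomass reveals how wall
# deposition lags radial expansion through the season.

#' Biomass proxy: summed xylem gray values over the forming ring
#'
#' Sums the xylem gray profile (lumens included: the profile already weights
#' wall vs lumen area) from the cambium to the previous ring boundary.
#' Linear in gray values and invariant to permuting slices within the ring.
#'
#' @param xylem_profile a \code{\link{gray_profile}} of kind \code{"xylem"}.
#' @param cambium_pos,prev_boundary_pos ring bounds, um.
#' @return list \code{b_trunk} (summed gray, arbitrary units), \code{n_slices},
#'   \code{empty} flag (TRUE when no profile point falls inside the ring,
#'   with \code{b_trunk = 0}).
#' @export
compute_b_trunk <- function(xylem_profile, cambium_pos, prev_boundary_pos) {
  stopifnot(inherits(xylem_profile, "gray_profile"))
  seg <- profile_window(xylem_profile, cambium_pos, prev_boundary_pos)
  if (nrow(seg) == 0L)
    return(list(b_trunk = 0, n_slices = 0L, empty = TRUE))
  list(b_trunk = sum(seg$value), n_slices = nrow(seg), empty = FALSE)
}

#' Correct the biomass proxy for circumferential heterogeneity
#'
#' Same multiplicative correction as \code{\link{correct_widths}} with
#' b_trunk in place of the observed width.
#'
#' @param series data frame with \code{tree}, \code{doy}, \code{b_trunk},
#'   \code{w_prev}.
#' @return the series with \code{b_trunk} corrected.
#' @export
correct_b_trunk <- function(series) {
  stopifnot("b_trunk" %in% names(series))
  correct_widths(series, cols = "b_trunk")
}

#' Normalized completion curves for width and biomass
#'
#' Divides each daily prediction curve by the median of its predictions at
#' the last three sampling dates, giving the relative completion of each
#' process on [0, 1] (values may slightly exceed 1 late in the season).
#'
#' @param width_curve,biomass_curve elements of
#'   \code{\link{fit_seasonal_curve}} output (lists with \code{fit},
#'   \code{daily}, \code{doys}), fitted on the same daily grid.
#' @param doys sampling DOYs used for the normalizer; defaults to each
#'   curve's own.
#' @return list \code{width}, \code{biomass}: data frames \code{doy},
#'   \code{completion}; plus the two normalizers.
#' @export
completion_curves <- function(width_curve, biomass_curve, doys = NULL) {
  norm_one <- function(curve) {
    dd <- if (is.null(doys)) curve$doys else doys
    nz <- final_width(curve, dd)
    if (!(nz > 0)) stop("zero normalizer: final prediction is not positive")
    data.frame(doy = curve$daily$doy, completion = curve$daily$pred / nz)
  }
  w <- norm_one(width_curve); b <- norm_one(biomass_curve)
  if (!identical(w$doy, b$doy))
    stop("width and biomass curves must share the same daily grid")
  list(width = w, biomass = b,
       normalizer_width = final_width(width_curve,
                                      if (is.null(doys)) width_curve$doys else doys),
       normalizer_biomass = final_width(biomass_curve,
                                        if (is.null(doys)) biomass_curve$doys else doys))
}

# first DOY (interpolated) at which a nondecreasing daily curve reaches
# level f; NA when f is below the curve's first value (crossing predates the
# observation window) or above its maximum (never reached)
completion_crossing <- function(doy, value, f) {
  if (f < value[1] || f > max(value)) return(NA_real_)
  first_crossing(doy, value, f)
}

#' Time-lag curve between biomass and size completion
#'
#' For each relative completion fraction f in {0, 0.01, ..., 1}:
#' \code{lag(f)} = DOY at which biomass completion first reaches f minus the
#' DOY at which width completion first reaches f (linear interpolation
#' between days). Fractions outside either curve's observed range are
#' undefined (NA) and excluded from the mean/max summaries.
#'
#' @param width_completion,biomass_completion data frames \code{doy},
#'   \code{completion}, monotone nondecreasing on a shared daily grid.
#' @return object of class \code{lag_curve}: data frame \code{fraction},
#'   \code{doy_width}, \code{doy_biomass}, \code{lag_days} with attributes
#'   \code{mean_lag}, \code{max_lag}.
#' @export
time_lag_curve <- function(width_completion, biomass_completion) {
  for (d in list(width_completion, biomass_completion)) {
    stopifnot(all(c("doy", "completion") %in% names(d)))
    if (any(diff(d$completion) < -1e-9))
      stop("completion curves must be monotone nondecreasing")
  }
  fr <- seq(0, 1, by = 0.01)
  dw <- vapply(fr, function(f)
    completion_crossing(width_completion$doy, width_completion$completion, f),
    numeric(1))
  db <- vapply(fr, function(f)
    completion_crossing(biomass_completion$doy, biomass_completion$completion, f),
    numeric(1))
  lag <- db - dw
  out <- data.frame(fraction = fr, doy_width = dw, doy_biomass = db,
                    lag_days = lag)
  structure(out, class = c("lag_curve", "data.frame"),
            mean_lag = mean(lag, na.rm = TRUE),
            max_lag = if (all(is.na(lag))) NA_real_ else max(lag, na.rm = TRUE))
}

#' @export
print.lag_curve <- function(x, ...) {
  cat(sprintf(
    "Biomass-vs-size time-lag curve: %d/%d fractions defined, mean lag %.1f d, max %.1f d\n",
    sum(!is.na(x$lag_days)), nrow(x), attr(x, "mean_lag"), attr(x, "max_lag")))
  invisible(x)
}

#' Peak daily-rate timing and lag
#'
#' DOY of the maximum daily rate of each process (earliest day on ties) and
#' their difference (biomass minus width). When the near-maximal stretch
#' (within 1% of the maximum) spans more than 7 days the peak day is
#' ambiguous and \code{plateau_flag} is set — relevant for ring-porous
#' species whose early-season rates are high and flat.
#'
#' @param width_curve,biomass_curve elements of
#'   \code{\link{fit_seasonal_curve}} output, shared daily grid.
#' @return list \code{doy_width_peak}, \code{doy_biomass_peak},
#'   \code{lag_days}, \code{plateau_flag}, \code{undefined} (all rates zero).
#' @export
peak_rate_lag <- function(width_curve, biomass_curve) {
  peak <- function(curve) {
    r <- daily_rates(curve$daily)
    if (all(r$rate <= 0))
      return(list(doy = NA_real_, plateau = FALSE, undefined = TRUE))
    m <- max(r$rate)
    near <- r$doy[r$rate >= (1 - 0.01) * m]
    list(doy = r$doy[which.max(r$rate)],
         plateau = diff(range(near)) > 7, undefined = FALSE)
  }
  pw <- peak(width_curve); pb <- peak(biomass_curve)
  undef <- pw$undefined || pb$undefined
  list(doy_width_peak = pw$doy, doy_biomass_peak = pb$doy,
       lag_days = if (undef) NA_real_ else pb$doy - pw$doy,
       plateau_flag = pw$plateau || pb$plateau,
       undefined = undef)
}

#' Write a lag curve to CSV
#'
#' Columns: fraction, doy_width, doy_biomass, lag_days.
#'
#' @param lag a \code{lag_curve}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_lag_csv <- function(lag, path) {
  utils::write.csv(as.data.frame(lag), path, row.names = FALSE)
  invisible(path)
}
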
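# ---- Seasonal phenology: critical dates, durations, rates -------------------
#
# Seasonal series of corrected widths are fitted per tree with a monotone
# increasing penalized spline (the data-driven alternative to Gompertz
# fitting, which fails on these series). Critical dates are the days of year
# at which 5% (tb) and 95% (te) of the final width is formed; durations and
# mean daily rates follow by arithmetic, and daily rate series are first
# differences of the daily predictions.

#' Correct widths for circumferential growth heterogeneity
#'
#' Microcores taken at different stem positions sample circumferential
#' heterogeneity; the cell-counting correction, adapted to widths at the
#' tree scale, rescales each observation by its own previous-year ring width
#' relative to the tree mean:
#' \deqn{w_{cor,j} = w_{obs,j} \cdot w_{prev,j} / \bar w_{prev}}
#' with the mean taken over the tree's n sampling dates. Applied identically
#' to every width column present.
#'
#' @param series data frame with columns \code{tree}, \code{doy},
#'   \code{w_prev} and one or more of \code{w_incr}, \code{w_maturing},
#'   \code{w_mat}.
#' @param cols width columns to correct; default all of the above present.
#' @return the series with corrected width columns.
#' @export
correct_widths <- function(series,
                           cols = intersect(c("w_incr", "w_maturing", "w_mat"),
                                            names(series))) {
  stopifnot(all(c("tree", "doy", "w_prev") %in% names(series)))
  if (any(series$w_prev <= 0))
    stop("all w_prev must be positive (previous-year ring width)")
  for (tr in unique(series$tree)) {
    i <- series$tree == tr
    ratio <- series$w_prev[i] / mean(series$w_prev[i])
    for (cl in cols) series[[cl]][i] <- series[[cl]][i] * ratio
  }
  series
}

#' Fit a monotone seasonal growth curve per tree
#'
#' Monotone-increasing penalized spline of the chosen (already corrected)
#' width against day of year, one fit per tree, with predictions on the
#' integer-DOY grid from the first to the last sampling date.
#'
#' @param series data frame with \code{tree}, \code{doy} and the response
#'   column; >= 6 dates per tree.
#' @param response column name, e.g. \code{"w_incr"}, \code{"w_mat"},
#'   \code{"b_trunk"}.
#' @param basis_dim spline basis dimension (default from data size).
#' @return named list per tree: \code{fit} (a \code{pspline_fit}),
#'   \code{daily} (data frame \code{doy}, \code{pred}), \code{doys} (the
#'   sampling dates).
#' @export
fit_seasonal_curve <- function(series, response = "w_incr", basis_dim = NULL) {
  stopifnot(response %in% names(series), all(c("tree", "doy") %in% names(series)))
  out <- list()
  for (tr in unique(series$tree)) {
    d <- series[series$tree == tr, ]
    d <- d[order(d$doy), ]
    if (nrow(d) < 6L)
      stop("tree ", tr, ": need at least 6 sampling dates, got ", nrow(d))
    # P-spline convention: generous basis, the penalty does the smoothing;
    # 12 balances noise-free fidelity against stability of the early-season
    # 5% crossing under measurement noise
    bd <- if (is.null(basis_dim)) max(5L, min(12L, nrow(d) - 3L)) else basis_dim
    fit <- fit_monotone_pspline(d$doy, d[[response]], basis_dim = bd)
    grid <- seq(min(d$doy), max(d$doy), by = 1L)
    out[[as.character(tr)]] <- list(
      fit = fit,
      daily = data.frame(doy = grid, pred = predict(fit, grid)),
      doys = d$doy)
  }
  out
}

#' Final width: median prediction over the last three sampling dates
#'
#' By the last sampling dates the increment has stabilized; the median over
#' the last three predictions absorbs residual circumferential
#' heterogeneity.
#'
#' @param curve one element of \code{\link{fit_seasonal_curve}} output (list
#'   with \code{fit} and \code{doys}), or a \code{pspline_fit} plus
#'   \code{doys}.
#' @param doys sampling DOYs (>= 3); taken from \code{curve} when absent.
#' @return final width (response units).
#' @export
final_width <- function(curve, doys = NULL) {
  fit <- if (inherits(curve, "pspline_fit")) curve else curve$fit
  if (is.null(doys)) doys <- curve$doys
  if (length(doys) < 3L) stop("need at least 3 sampling dates for the final width")
  last3 <- sort(doys, decreasing = TRUE)[1:3]
  stats::median(predict(fit, last3))
}

# first DOY (linear interpolation between grid days) at which `pred` reaches
# `target`; NA if never reached; `first day` if already at/above target there
first_crossing <- function(doy, pred, target) {
  i <- which(pred >= target)[1]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(doy[1])
  doy[i - 1L] + (target - pred[i - 1L]) / (pred[i] - pred[i - 1L]) *
    (doy[i] - doy[i - 1L])
}

#' Critical dates of a seasonal process
#'
#' \code{wb = 0.05 * final_width} and \code{we = 0.95 * final_width}; tb and
#' te are the first days (linear interpolation between integer DOYs) at
#' which the daily predictions reach wb and we. If 95% is never reached
#' within the season, te is censored at the last grid day with
#' \code{censored = TRUE}.
#'
#' @param daily data frame \code{doy}, \code{pred} (daily predictions).
#' @param final_width the final width (> 0) from \code{\link{final_width}}.
#' @return list \code{tb}, \code{te}, \code{wb}, \code{we}, \code{censored}.
#' @export
critical_dates <- function(daily, final_width) {
  if (!(final_width > 0)) stop("final_width must be positive")
  wb <- 0.05 * final_width
  we <- 0.95 * final_width
  tb <- first_crossing(daily$doy, daily$pred, wb)
  if (is.na(tb))
    stop("5% of the final width is never reached: no growth in the series")
  te <- first_crossing(daily$doy, daily$pred, we)
  censored <- is.na(te)
  if (censored) te <- daily$doy[nrow(daily)]
  list(tb = tb, te = te, wb = wb, we = we, censored = censored)
}

#' Durations and mean daily rates of xylogenesis
#'
#' From the critical dates of size growth (increment width) and mature-xylem
#' production: \code{d = te - tb} for each process,
#' \code{r = (we - wb)/(te - tb)}, and the whole-xylogenesis duration
#' \code{d_xylo = te_mat - tb_incr} (xylogenesis opens with the first cell
#' enlargement and closes when the last cell matures). When \code{te == tb}
#' the rate is undefined and reported as NA with \code{rate_undefined}.
#'
#' @param incr list \code{tb}, \code{te}, \code{wb}, \code{we} for the
#'   increment (size growth).
#' @param mat same for mature-xylem production; optional (NULL for
#'   increment-only series).
#' @return object of class \code{phenology_params}: list of tb/te/wb/we/d/r
#'   per process plus \code{d_xylo} and flags.
#' @export
durations_and_rates <- function(incr, mat = NULL) {
  one <- function(p) {
    d <- p$te - p$tb
    r <- if (d > 0) (p$we - p$wb) / d else NA_real_
    list(tb = p$tb, te = p$te, wb = p$wb, we = p$we, d = d, r = r,
         rate_undefined = !(d > 0),
         censored = isTRUE(p$censored))
  }
  out <- list(incr = one(incr))
  if (!is.null(mat)) {
    out$mat <- one(mat)
    out$d_xylo <- out$mat$te - out$incr$tb
  }
  structure(out, class = "phenology_params")
}

#' @export
print.phenology_params <- function(x, ...) {
  fmt <- function(nm, p) cat(sprintf(
    "  %-5s tb %.1f  te %.1f  d %.1f d  r %s um/day%s\n", nm, p$tb, p$te, p$d,
    if (is.na(p$r)) "NA" else sprintf("%.2f", p$r),
    if (p$censored) " [te censored at season end]" else ""))
  cat("Xylogenesis parameters:\n")
  fmt("incr", x$incr)
  if (!is.null(x$mat)) {
    fmt("mat", x$mat)
    cat(sprintf("  d_xylo %.1f days (te_mat - tb_incr)\n", x$d_xylo))
  }
  invisible(x)
}

#' Daily growth-rate series
#'
#' First differences of the daily predictions, restricted to [tb, te] when
#' given; nonnegative by the monotone constraint. The telescoping identity
#' sum(rates) = pred(last) - pred(first) holds exactly.
#'
#' @param daily data frame \code{doy}, \code{pred}.
#' @param tb,te optional window bounds (days); the window is snapped to the
#'   enclosing integer grid days.
#' @return data frame \code{doy} (day the increment is accrued to),
#'   \code{rate} (response units per day).
#' @export
daily_rates <- function(daily, tb = NULL, te = NULL) {
  d <- daily
  if (!is.null(tb)) d <- d[d$doy >= floor(tb), , drop = FALSE]
  if (!is.null(te)) d <- d[d$doy <= ceiling(te), , drop = FALSE]
  data.frame(doy = d$doy[-1L], rate = diff(d$pred))
}

#' Full per-tree phenology from a seasonal width table
#'
#' Convenience wrapper: heterogeneity correction, monotone fits for the
#' increment and (when present) mature width, critical dates, durations and
#' rates, one row per tree.
#'
#' @param series data frame: \code{tree}, \code{doy}, \code{w_prev},
#'   \code{w_incr} and optionally \code{w_mat}; optionally \code{species},
#'   \code{method}.
#' @param correct apply \code{\link{correct_widths}} first (default TRUE).
#' @return data frame with one row per tree: critical dates, durations,
#'   rates, final widths and censoring flags.
#' @export
phenology_table <- function(series, correct = TRUE) {
  if (correct) series <- correct_widths(series)
  has_mat <- "w_mat" %in% names(series)
  curves_i <- fit_seasonal_curve(series, "w_incr")
  curves_m <- if (has_mat) fit_seasonal_curve(series, "w_mat")
  rows <- lapply(names(curves_i), function(tr) {
    ci <- curves_i[[tr]]
    fw_i <- final_width(ci)
    cd_i <- critical_dates(ci$daily, fw_i)
    cd_m <- fw_m <- NULL
    if (has_mat) {
      cm <- curves_m[[tr]]
      fw_m <- final_width(cm)
      cd_m <- critical_dates(cm$daily, fw_m)
    }
    p <- durations_and_rates(cd_i, cd_m)
    data.frame(
      tree = tr,
      species = if ("species" %in% names(series))
        series$species[series$tree == tr][1] else NA_character_,
      tb_incr = p$incr$tb, te_incr = p$incr$te, d_incr = p$incr$d,
      r_incr = p$incr$r, w_final_incr = fw_i,
      censored_incr = p$incr$censored,
      tb_mat = if (has_mat) p$mat$tb else NA_real_,
      te_mat = if (has_mat) p$mat$te else NA_real_,
      d_mat = if (has_mat) p$mat$d else NA_real_,
      r_mat = if (has_mat) p$mat$r else NA_real_,
      w_final_mat = if (has_mat) fw_m else NA_real_,
      censored_mat = if (has_mat) p$mat$censored else NA,
      d_xylo = if (has_mat) p$d_xylo else NA_real_)
  })
  do.call(rbind, rows)
}
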
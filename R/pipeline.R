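# ---- Orchestration: per-sample and per-season runs from a config ------------
#
# The config is a JSON file. Keys:
#   voxel_pitch        um/px (default 2.49)
#   output_dir         where CSVs / plots / manifest go
#   samples            array of {id, stack (TIFF path), doy, tree, species,
#                      prev_boundary_index, cambium_window: [lo, hi]}
#   spline             {basis_dim, penalty_order, level, min_run_length}
#   bootstrap          {n_resamples, seed, scheme}
# Flags override config values; config overrides defaults.

#' Read a run configuration (JSON)
#'
#' @param path JSON config file.
#' @return named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$voxel_pitch <- cfg$voxel_pitch %||% 2.49
  cfg$spline <- utils::modifyList(
    list(level = 0.95, min_run_length = NULL, basis_dim = NULL),
    as.list(cfg$spline))
  cfg$bootstrap <- utils::modifyList(
    list(n_resamples = 10000L, scheme = "pooled"), as.list(cfg$bootstrap))
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Process one sample: stack to ring widths
#'
#' Chains profile extraction and boundary detection for one annotated VOI
#' stack and returns the RingWidths row plus QC information (thresholds,
#' spline effective degrees of freedom, flags).
#'
#' @param stack a \code{\link{voi_stack}}, or a path to a multi-page TIFF.
#' @param cambium_window slice-index pair (required when \code{stack} is a
#'   path).
#' @param prev_boundary_index slice index (required when \code{stack} is a
#'   path).
#' @param voxel_pitch um/px (used when reading from TIFF).
#' @param level,min_run_length,basis_dim spline settings.
#' @param qc_plot optional path for a QC plot (profile + fit + markers).
#' @return list: \code{widths} (a \code{ring_widths}), \code{b_trunk},
#'   \code{profiles}, \code{qc} (thresholds, EDFs, flags).
#' @export
run_sample <- function(stack, cambium_window = NULL,
                       prev_boundary_index = NULL, voxel_pitch = 2.49,
                       level = 0.95, min_run_length = NULL, basis_dim = NULL,
                       qc_plot = NULL) {
  if (is.character(stack)) {
    slices <- read_tiff_stack(stack)
    stack <- voi_stack(slices, voxel_pitch = voxel_pitch,
                       prev_boundary_index = prev_boundary_index,
                       cambium_window = cambium_window)
  }
  pitch <- stack$voxel_pitch
  prof <- extract_profiles(stack)
  window_um <- (stack$cambium_window - 1L) * pitch
  boundary_um <- (stack$prev_boundary_index - 1L) * pitch
  cam <- detect_cambium(prof$cell_wall, window_um, level = level,
                        min_run_length = min_run_length,
                        basis_dim = basis_dim)
  widths <- measure_widths(prof$cell_wall, cam$cambium_pos, boundary_um,
                           level = level, min_run_length = min_run_length,
                           basis_dim = basis_dim)
  bt <- compute_b_trunk(prof$xylem, cam$cambium_pos, boundary_um)
  if (!is.null(qc_plot)) {
    grDevices::png(qc_plot, width = 900, height = 500)
    plot_ring_profile(prof$cell_wall, widths)
    grDevices::dev.off()
  }
  list(widths = widths, b_trunk = bt$b_trunk, profiles = prof,
       qc = list(thresholds = prof$thresholds,
                 edf_cambium = cam$fit$edf, edf_ring = widths$fit$edf,
                 no_plateau = widths$no_plateau,
                 end_of_season = widths$end_of_season,
                 b_trunk_empty = bt$empty))
}

widths_row <- function(sample_id, doy, widths, b_trunk = NA_real_,
                       tree = NA_character_, species = NA_character_) {
  data.frame(
    sample_id = sample_id, tree = tree, species = species, doy = doy,
    cambium_um = widths$cambium_pos, transition_um = widths$transition_pos,
    boundary_um = widths$prev_boundary_pos,
    w_incr = widths$w_incr, w_maturing = widths$w_maturing,
    w_mat = widths$w_mat, b_trunk = b_trunk,
    no_plateau = widths$no_plateau, end_of_season = widths$end_of_season)
}

#' Process a season: width tables to phenology, biomass and comparison
#'
#' From per-date RingWidths tables (one or two methods), computes per-tree
#' phenology; when b_trunk is present, species-level completion and lag
#' curves; when two methods are given, the comparison table.
#'
#' @param widths data frame with \code{tree}, \code{doy}, \code{w_prev},
#'   \code{w_incr}, optionally \code{w_mat}, \code{species},
#'   \code{b_trunk}, \code{method}.
#' @param widths_b optional second-method table (same layout); enables the
#'   comparison stage.
#' @param seed integer seed for the bootstrap (required when
#'   \code{widths_b} is given).
#' @param n_resamples,scheme bootstrap settings.
#' @param output_dir optional directory; when given, CSV outputs and a JSON
#'   manifest are written.
#' @return list: \code{phenology} (and \code{phenology_b}),
#'   \code{comparison} (or NULL), \code{biomass} (completion + lag curves
#'   per species, or NULL).
#' @export
run_season <- function(widths, widths_b = NULL, seed = NULL,
                       n_resamples = 10000L, scheme = "pooled",
                       output_dir = NULL) {
  phen <- phenology_table(widths)
  phen_b <- if (!is.null(widths_b)) phenology_table(widths_b)
  comparison <- NULL
  if (!is.null(phen_b)) {
    if (is.null(seed)) stop("a seed is required when the bootstrap comparison runs")
    comparison <- compare_methods(phen, phen_b, n_resamples = n_resamples,
                                  seed = seed, scheme = scheme)
  } else {
    message("single-method input: comparison stage skipped")
  }
  biomass <- NULL
  if ("b_trunk" %in% names(widths)) {
    wc <- correct_widths(widths)
    bc <- correct_b_trunk(widths[, c("tree", "doy", "b_trunk", "w_prev")])
    # species-level curves: pooled across trees' corrected values
    wc$tree_orig <- wc$tree; wc$tree <- "pooled"
    bc$tree <- "pooled"
    cw <- fit_seasonal_curve(wc, "w_incr")[["pooled"]]
    cb <- fit_seasonal_curve(bc, "b_trunk")[["pooled"]]
    comp <- completion_curves(cw, cb)
    biomass <- list(
      completion = comp,
      lag = time_lag_curve(comp$width, comp$biomass),
      peaks = peak_rate_lag(cw, cb))
  }
  out <- list(phenology = phen, phenology_b = phen_b,
              comparison = comparison, biomass = biomass)
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(phen, file.path(output_dir, "phenology.csv"),
                     row.names = FALSE)
    if (!is.null(comparison))
      utils::write.csv(comparison, file.path(output_dir, "comparison.csv"),
                       row.names = FALSE)
    if (!is.null(biomass))
      write_lag_csv(biomass$lag, file.path(output_dir, "lag_curve.csv"))
    manifest <- list(
      created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
      n_trees = length(unique(widths$tree)),
      n_dates = length(unique(widths$doy)),
      seed = seed, n_resamples = n_resamples, scheme = scheme,
      stages = c("phenology",
                 if (!is.null(comparison)) "comparison",
                 if (!is.null(biomass)) "biomass"))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}

#' Command-line entry point
#'
#' Sub-commands: \code{simulate} (write a synthetic season CSV),
#' \code{detect} (TIFF stack to ring widths), \code{phenology},
#' \code{compare}, \code{all} (phenology + biomass + comparison from width
#' CSVs). Run via \code{Rscript -e 'xylotomo::xylotomo_cli()' <cmd> ...} or
#' the installed \code{inst/cli/xylotomo} script.
#'
#' @param args character vector; defaults to \code{commandArgs(TRUE)}.
#' @return exit status, invisibly (0 on success).
#' @export
xylotomo_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: xylotomo <command> [options]",
    "  simulate  --out <csv> [--seed <int>]",
    "  detect    --stack <tiff> --boundary <slice> --window <lo,hi>",
    "            [--pitch <um>] [--out <csv>]",
    "  phenology --widths <csv> [--out-dir <dir>]",
    "  all       --widths <csv> [--widths-b <csv>] [--seed <int>]",
    "            [--out-dir <dir>]",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  opt <- function(name, default = NULL) {
    i <- which(args == paste0("--", name))
    if (length(i) == 0L) return(default)
    args[i[1] + 1L]
  }
  status <- 0L
  if (cmd == "simulate") {
    seed <- as.integer(opt("seed", "1"))
    season <- generate_season(season_truth(seed = seed))
    out <- opt("out", "season.csv")
    write_season_csv(cbind(season$widths,
                           b_trunk = season$biomass$b_trunk), out)
    message("wrote ", out)
  } else if (cmd == "detect") {
    win <- as.integer(strsplit(opt("window"), ",")[[1]])
    res <- run_sample(opt("stack"),
                      cambium_window = win,
                      prev_boundary_index = as.integer(opt("boundary")),
                      voxel_pitch = as.numeric(opt("pitch", "2.49")))
    row <- widths_row(basename(opt("stack")), NA_real_, res$widths,
                      res$b_trunk)
    out <- opt("out", "widths.csv")
    utils::write.csv(row, out, row.names = FALSE)
    message("wrote ", out)
  } else if (cmd == "phenology") {
    widths <- utils::read.csv(opt("widths"))
    res <- run_season(widths, output_dir = opt("out-dir"))
    print(res$phenology)
  } else if (cmd == "all") {
    widths <- utils::read.csv(opt("widths"))
    wb <- opt("widths-b")
    seed <- opt("seed")
    res <- run_season(widths,
                      widths_b = if (!is.null(wb)) utils::read.csv(wb),
                      seed = if (!is.null(seed)) as.integer(seed),
                      output_dir = opt("out-dir"))
    print(res$phenology)
    if (!is.null(res$comparison)) print(res$comparison)
  } else {
    message("unknown command: ", cmd, "\n", usage)
    status <- 1L
  }
  invisible(status)
}
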
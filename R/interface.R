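# Configuration files and the experiment runner tying the stages together.

.config_schema <- list(
  top = c("experiment", "nozzle", "source", "scan", "benchmark", "calibrate",
          "dose", "synth", "seed", "out_dir", "verbosity"),
  nozzle = c("preset", "air_gap_cm", "target_offset_cm", "focal_length_cm",
             "quad_length_cm", "aperture_cm", "ic_wet_mm", "vw_wet_mm",
             "monitor_offsets_cm"),
  source = c("energy_MeV", "energy_spread", "sigma_x_mm", "sigma_y_mm",
             "div_x_mrad", "div_y_mrad", "r_xx", "r_yy"),
  scan = c("field_min_T", "field_max_T", "field_step_T", "arrangements",
           "particles", "refine_top"),
  benchmark = c("grid_preset", "energy_MeV", "field_step_T"),
  calibrate = c("table_csv", "grid_preset"),
  dose = c("spacing_mm", "n_beams", "mode", "primaries", "repeats",
           "phantom_x_cm", "phantom_y_cm", "phantom_depth_cm", "voxel_mm",
           "fields_T", "arrangement"),
  synth = c("noise_rel", "out_csv"))

#' Load and validate a run configuration
#'
#' Reads a YAML experiment configuration, rejects unknown keys and checks
#' the blocks required by the chosen experiment. Packaged example
#' configurations live under
#' \code{system.file("extdata/configs", package = "minibeam")}.
#'
#' @param path Path to a YAML file.
#' @return Object of class \code{run_config} (a validated nested list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  chk_keys <- function(block, allowed, where) {
    bad <- setdiff(names(block), allowed)
    if (length(bad)) {
      stop(sprintf("unknown key(s) in %s: %s", where,
                   paste(bad, collapse = ", ")))
    }
  }
  chk_keys(cfg, .config_schema$top, "config")
  if (is.null(cfg$experiment) ||
      !cfg$experiment %in% c("scan", "benchmark", "calibrate", "dose", "synth")) {
    stop("experiment must be one of scan/benchmark/calibrate/dose/synth")
  }
  if (is.null(cfg$seed)) stop("config requires a seed")
  need <- switch(cfg$experiment,
                 scan = c("nozzle", "source"),
                 benchmark = c("nozzle", "benchmark"),
                 calibrate = c("nozzle", "calibrate"),
                 dose = c("nozzle", "source", "dose"),
                 synth = c("nozzle", "synth"))
  for (b in need) {
    if (is.null(cfg[[b]])) {
      stop(sprintf("config for experiment '%s' requires block '%s'",
                   cfg$experiment, b))
    }
  }
  for (b in intersect(names(cfg), names(.config_schema)[-1])) {
    chk_keys(cfg[[b]], .config_schema[[b]], paste0("block '", b, "'"))
  }
  if (!is.null(cfg$nozzle$air_gap_cm) && cfg$nozzle$air_gap_cm < 0) {
    stop("air_gap_cm must be >= 0")
  }
  structure(cfg, class = "run_config")
}

config_nozzle <- function(cfg) {
  nb <- cfg$nozzle
  args <- nb[intersect(names(nb), names(formals(build_nozzle)))]
  do.call(build_nozzle, args)
}

config_source <- function(cfg) {
  sb <- cfg$source
  beam_source(energy = sb$energy_MeV, energy_spread = sb$energy_spread,
              sigma_x = sb$sigma_x_mm, sigma_y = sb$sigma_y_mm,
              div_x = sb$div_x_mrad, div_y = sb$div_y_mrad,
              r_xx = if (is.null(sb$r_xx)) 0 else sb$r_xx,
              r_yy = if (is.null(sb$r_yy)) 0 else sb$r_yy)
}

#' Run a configured experiment
#'
#' Dispatches to the scan / benchmark / calibrate / dose / synth stage,
#' writes the result files (CSV for grids and curves, JSON for summaries)
#' into the output directory and returns the result object invisibly.
#' Every output carries provenance: the configuration, the seed and the
#' package version. Outputs are deterministic for a fixed seed.
#'
#' @param config A \code{run_config} from \code{\link{load_config}}.
#' @param out_dir Output directory (defaults to the config's
#'   \code{out_dir}, or a temporary directory).
#' @return The stage result, invisibly; files are written as a side
#'   effect and listed in the returned attribute \code{"files"}.
#' @export
run_experiment <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(out_dir)) out_dir <- config$out_dir
  if (is.null(out_dir)) out_dir <- tempfile("minibeam_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  prov <- list(package = "minibeam",
               version = as.character(utils::packageVersion("minibeam")),
               experiment = config$experiment, seed = seed,
               config = unclass(config))
  files <- character(0)
  emit_json <- function(x, name) {
    p <- file.path(out_dir, name)
    jsonlite::write_json(c(list(provenance = prov), x), p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    files <<- c(files, p)
  }
  emit_csv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE)
    files <<- c(files, p)
  }
  noz <- config_nozzle(config)
  result <- switch(config$experiment,
    scan = {
      sb <- config$scan
      spec_args <- list()
      if (!is.null(sb$field_step_T)) {
        spec_args$fields <- seq(if (is.null(sb$field_min_T)) 0 else sb$field_min_T,
                                if (is.null(sb$field_max_T)) 2 else sb$field_max_T,
                                by = sb$field_step_T)
      }
      if (!is.null(sb$particles)) spec_args$n_particles <- sb$particles
      if (!is.null(sb$refine_top)) spec_args$refine_top <- sb$refine_top
      sc <- scan_quadrupoles(noz, config_source(config),
                             do.call(quad_scan_spec, spec_args), seed = seed)
      m <- select_minimum(sc)
      emit_csv(sc$grid, "scan_grid.csv")
      emit_json(list(minimum = m,
                     minibeam = is_minibeam(m$h_fwhm, m$v_fwhm)),
                "scan_summary.json")
      sc
    },
    benchmark = {
      bb <- config$benchmark
      grid <- param_grid(if (is.null(bb$grid_preset)) "ci" else bb$grid_preset)
      step <- if (is.null(bb$field_step_T)) 0.08 else bb$field_step_T
      fm <- feasibility_map(noz, bb$energy_MeV, grid,
                            quad_scan_spec(fields = seq(0, 2, by = step),
                                           refine_top = 0))
      emit_csv(as.data.frame(as.table(fm$h_fwhm)), "feasibility_h.csv")
      emit_csv(as.data.frame(as.table(fm$v_fwhm)), "feasibility_v.csv")
      emit_json(list(energy_MeV = bb$energy_MeV,
                     h_feasible = sum(fm$h_mask), v_feasible = sum(fm$v_mask),
                     cells = length(fm$h_mask)), "benchmark_summary.json")
      fm
    },
    calibrate = {
      cb <- config$calibrate
      tab <- utils::read.csv(cb$table_csv)
      meas <- measured_sizes(tab$energy_MeV, tab$position_cm,
                             tab$sigma_x_mm, tab$sigma_y_mm)
      ss <- stats::aggregate(cbind(sigma_x_mm, sigma_y_mm) ~ energy_MeV,
                             tab[tab$position_cm == min(tab$position_cm), ],
                             mean)
      cal <- calibrate_source(meas, noz,
                              param_grid(if (is.null(cb$grid_preset)) "ci"
                                         else cb$grid_preset),
                              source_sigma = ss)
      emit_csv(as.data.frame(cal), "calibration.csv")
      cal
    },
    dose = {
      db <- config$dose
      src <- config_source(config)
      if (!is.null(db$fields_T)) {
        noz <- set_scan_fields(noz, db$fields_T[[1]], db$fields_T[[2]],
                               if (is.null(db$arrangement)) "q1_horizontal"
                               else db$arrangement)
      }
      ph <- phantom_spec(
        if (is.null(db$phantom_x_cm)) 2 else db$phantom_x_cm,
        if (is.null(db$phantom_y_cm)) 2 else db$phantom_y_cm,
        if (is.null(db$phantom_depth_cm)) 10 else db$phantom_depth_cm,
        if (is.null(db$voxel_mm)) c(0.05, 0.05, 1) else unlist(db$voxel_mm))
      lay <- grid_layout(if (is.null(db$n_beams)) 5 else db$n_beams,
                         db$spacing_mm)
      g <- compute_dose_grid(noz, src, lay, ph,
                             mode = if (is.null(db$mode)) "analytic" else db$mode,
                             n = if (is.null(db$primaries)) 1e6 else db$primaries,
                             repeats = if (is.null(db$repeats)) 50 else db$repeats,
                             seed = seed)
      single <- compute_dose_grid(noz, src, grid_layout(1, db$spacing_mm), ph,
                                  mode = "analytic", n = 1e6)
      an <- analyze_dose(g, lay, single_grid = single)
      emit_csv(an$curve, "dose_curves.csv")
      emit_json(list(entrance_pvdr = an$entrance_pvdr,
                     peak_to_entrance = an$peak_to_entrance,
                     bragg_depth_cm = an$bragg_depth_cm,
                     flatness_pct = an$flatness_pct), "dose_summary.json")
      an
    },
    synth = {
      nb <- config$synth
      spec <- synthetic_spec(noise_rel = if (is.null(nb$noise_rel)) 0.01
                                         else nb$noise_rel,
                             seed = seed)
      tab <- gen_measured_sizes(spec, noz)
      emit_csv(as.data.frame(tab),
               if (is.null(nb$out_csv)) "measured_sizes.csv" else nb$out_csv)
      tab
    })
  attr(result, "files") <- files
  invisible(result)
}
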
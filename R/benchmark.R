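# Source-parametrisation feasibility benchmark and best-fit calibration of
# source parameters against measured beam-size tables.

#' Grid of beam-source parametrisations
#'
#' The full benchmark grid spans nine (sigma_x, sigma_y) size pairs with
#' sigmas between 3 and 15 mm, eight divergence values (log-even) between
#' 0.1 and 15 mrad per plane, and eleven correlation values (even) between
#' -1 and +1 per plane: 9 * 8^2 * 11^2 = 69,696 parametrisations. The
#' \code{"ci"} preset is a scaled-down grid for routine testing.
#'
#' @param preset \code{"full"} or \code{"ci"}.
#' @param sizes_mm Matrix or data frame with columns sigma_x, sigma_y (mm).
#' @param divergences_mrad Divergence axis values (mrad).
#' @param correlations Correlation axis values.
#' @return Object of class \code{param_grid}.
#' @export
param_grid <- function(preset = c("full", "ci"), sizes_mm = NULL,
                       divergences_mrad = NULL, correlations = NULL) {
  preset <- match.arg(preset)
  if (is.null(sizes_mm)) {
    sizes_mm <- if (preset == "full") {
      expand.grid(sigma_x = c(3, 9, 15), sigma_y = c(3, 9, 15))
    } else {
      data.frame(sigma_x = c(4, 9), sigma_y = c(4, 9))
    }
  }
  if (is.null(divergences_mrad)) {
    n_div <- if (preset == "full") 8 else 4
    divergences_mrad <- exp(seq(log(0.1), log(15), length.out = n_div))
  }
  if (is.null(correlations)) {
    correlations <- if (preset == "full") seq(-1, 1, length.out = 11)
                    else c(-1, -0.5, 0, 0.5, 1)
  }
  sizes_mm <- as.data.frame(sizes_mm)
  if (nrow(sizes_mm) == 0 || length(divergences_mrad) == 0 ||
      length(correlations) == 0) stop("empty parametrisation axis")
  stopifnot(all(sizes_mm > 0), all(divergences_mrad > 0),
            all(abs(correlations) <= 1))
  structure(list(sizes_mm = sizes_mm,
                 divergences_mrad = divergences_mrad,
                 correlations = correlations),
            class = "param_grid")
}

#' Enumerate all beam-source parametrisations of a grid
#'
#' Full Cartesian product over size pairs, per-plane divergences and
#' per-plane correlations, in a fixed deterministic order (sizes slowest,
#' then div_x, div_y, r_xx, r_yy fastest).
#'
#' @param grid A \code{param_grid}.
#' @param energy,energy_spread Energy block applied to every source.
#' @return Data frame with one row per parametrisation (columns sigma_x,
#'   sigma_y, div_x, div_y, r_xx, r_yy); use \code{\link{beam_source}} to
#'   materialise a row.
#' @export
enumerate_parametrisations <- function(grid, energy = 100,
                                       energy_spread = 0.01) {
  stopifnot(inherits(grid, "param_grid"))
  idx <- expand.grid(r_yy = grid$correlations, r_xx = grid$correlations,
                     div_y = grid$divergences_mrad,
                     div_x = grid$divergences_mrad,
                     i_size = seq_len(nrow(grid$sizes_mm)))
  out <- data.frame(sigma_x = grid$sizes_mm$sigma_x[idx$i_size],
                    sigma_y = grid$sizes_mm$sigma_y[idx$i_size],
                    div_x = idx$div_x, div_y = idx$div_y,
                    r_xx = idx$r_xx, r_yy = idx$r_yy,
                    energy = energy, energy_spread = energy_spread)
  out[order(idx$i_size), ][seq_len(nrow(out)), ]
}

#' Minibeam feasibility map over source parametrisations
#'
#' For each (divergence, correlation) cell of one transverse plane, the
#' minimum achievable FWHM in that plane over the quadrupole field grid
#' (both arrangements), minimised over the remaining axes (the size pairs),
#' evaluated in fast envelope mode. The horizontal and vertical planes are
#' uncoupled in a skew-free beamline, so each plane's map depends only on
#' that plane's source parameters; the cell is flagged feasible if the
#' minimum FWHM is <= 1 mm.
#'
#' @param nozzle A \code{nozzle_config}.
#' @param energy Beam energy, MeV.
#' @param grid A \code{param_grid}.
#' @param scan_spec A \code{quad_scan_spec} (envelope mode; refinement is
#'   not used here).
#' @param energy_spread Fractional energy spread.
#' @return Object of class \code{feasibility_map}: per plane a matrix
#'   (divergence x correlation) of minimum FWHM (mm) and the logical
#'   minibeam mask.
#' @export
feasibility_map <- function(nozzle, energy, grid = param_grid("ci"),
                            scan_spec = quad_scan_spec(refine_top = 0),
                            energy_spread = 0.01) {
  stopifnot(inherits(grid, "param_grid"))
  nd <- length(grid$divergences_mrad); nc <- length(grid$correlations)
  fg <- expand.grid(i1 = seq_along(scan_spec$fields),
                    i2 = seq_along(scan_spec$fields))
  b1 <- scan_spec$fields[fg$i1]; b2 <- scan_spec$fields[fg$i2]
  one_plane <- function(plane) {
    m <- matrix(Inf, nd, nc,
                dimnames = list(signif(grid$divergences_mrad, 3),
                                signif(grid$correlations, 3)))
    sig_axis <- unique(if (plane == "h") grid$sizes_mm$sigma_x
                       else grid$sizes_mm$sigma_y)
    for (i in seq_len(nd)) for (j in seq_len(nc)) {
      best <- Inf
      for (sg in sig_axis) {
        # the orthogonal plane is irrelevant for this plane's minimum
        src <- if (plane == "h") {
          beam_source(energy, energy_spread, sg, sg,
                      grid$divergences_mrad[i], 1,
                      grid$correlations[j], 0)
        } else {
          beam_source(energy, energy_spread, sg, sg, 1,
                      grid$divergences_mrad[i], 0,
                      grid$correlations[j])
        }
        for (arr in scan_spec$arrangements) {
          ev <- env_scan_grid(nozzle, src, b1, b2, arr,
                              scan_spec$n_energy_nodes)
          v <- if (plane == "h") ev$var_x else ev$var_y
          best <- min(best, FWHM_CONST * sqrt(min(v)))
        }
      }
      m[i, j] <- best
    }
    m
  }
  h <- one_plane("h"); v <- one_plane("v")
  structure(list(h_fwhm = h, v_fwhm = v,
                 h_mask = h <= 1, v_mask = v <= 1,
                 divergences_mrad = grid$divergences_mrad,
                 correlations = grid$correlations, energy = energy),
            class = "feasibility_map")
}

#' @export
print.feasibility_map <- function(x, ...) {
  cat(sprintf("Feasibility map at %g MeV: %d x %d (divergence x correlation) cells\n",
              x$energy, nrow(x$h_fwhm), ncol(x$h_fwhm)))
  cat(sprintf("  horizontal: %d/%d cells minibeam-capable (<= 1 mm)\n",
              sum(x$h_mask), length(x$h_mask)))
  cat(sprintf("  vertical:   %d/%d cells minibeam-capable\n",
              sum(x$v_mask), length(x$v_mask)))
  invisible(x)
}

#' Measured beam-size table constructor
#'
#' @param energy_MeV,position_cm,sigma_x_mm,sigma_y_mm Columns of the
#'   table: per (energy, position relative to the isocentre) the measured
#'   horizontal and vertical Gaussian sigma in mm.
#' @param sigma_err_mm Optional measurement error.
#' @return Object of class \code{measured_sizes} (a data frame); the grid
#'   must be complete (every energy at every position).
#' @export
measured_sizes <- function(energy_MeV, position_cm, sigma_x_mm, sigma_y_mm,
                           sigma_err_mm = NA_real_) {
  df <- data.frame(energy_MeV = energy_MeV, position_cm = position_cm,
                   sigma_x_mm = sigma_x_mm, sigma_y_mm = sigma_y_mm,
                   sigma_err_mm = sigma_err_mm)
  if (any(df$sigma_x_mm <= 0) || any(df$sigma_y_mm <= 0)) {
    stop("measured sigmas must be > 0")
  }
  tab <- table(df$energy_MeV, df$position_cm)
  if (any(tab != 1)) stop("incomplete measured-size table")
  class(df) <- c("measured_sizes", "data.frame")
  df
}

#' Best-fit calibration of source parameters from measured beam sizes
#'
#' For each beam energy, the source sigmas are taken as given (measured at
#' the first monitoring chamber) and the per-plane divergence and
#' correlation are chosen from the search grid to minimise the mean squared
#' relative deviation between the beam sizes simulated at the monitoring
#' positions (envelope transport through the nozzle, quadrupoles off) and
#' the measured ones. The two planes are fitted independently.
#'
#' @param measured A \code{measured_sizes} table.
#' @param nozzle A \code{nozzle_config} with monitor planes at the
#'   measurement positions (see \code{\link{build_nozzle}} argument
#'   \code{monitor_offsets_cm}).
#' @param search_space A \code{param_grid} supplying the divergence and
#'   correlation axes.
#' @param source_sigma Data frame with columns \code{energy_MeV},
#'   \code{sigma_x_mm}, \code{sigma_y_mm}: the source sizes per energy.
#' @param energy_spread Fractional energy spread of the model beam.
#' @return Object of class \code{source_calibration}: per energy the
#'   best-fit (div_x, r_xx, div_y, r_yy) and the mean relative deviation
#'   per plane in percent.
#' @export
calibrate_source <- function(measured, nozzle, search_space = param_grid("ci"),
                             source_sigma, energy_spread = 0) {
  stopifnot(inherits(measured, "measured_sizes"),
            inherits(search_space, "param_grid"))
  energies <- sort(unique(measured$energy_MeV))
  positions <- sort(unique(measured$position_cm))
  cand <- expand.grid(div = search_space$divergences_mrad,
                      r = search_space$correlations)
  res <- lapply(energies, function(en) {
    ms <- measured[measured$energy_MeV == en, ]
    ms <- ms[order(ms$position_cm), ]
    ss <- source_sigma[source_sigma$energy_MeV == en, ]
    if (nrow(ss) != 1) stop("source_sigma must have one row per energy")
    fit_plane <- function(sig0, meas) {
      obj <- vapply(seq_len(nrow(cand)), function(i) {
        src <- beam_source(en, energy_spread, sig0, sig0,
                           cand$div[i], cand$div[i], cand$r[i], cand$r[i])
        mom <- propagate_moments(src, nozzle, n_energy_nodes = 1)
        sim <- vapply(positions, function(p) {
          lbl <- sprintf("offset_%+d", as.integer(round(p)))
          sqrt(mom[[lbl]]$x[["var_pos"]])
        }, numeric(1))
        mean(((sim - meas) / meas)^2)
      }, numeric(1))
      i <- which.min(obj)
      src <- beam_source(en, energy_spread, sig0, sig0,
                         cand$div[i], cand$div[i], cand$r[i], cand$r[i])
      mom <- propagate_moments(src, nozzle, n_energy_nodes = 1)
      sim <- vapply(positions, function(p) {
        sqrt(mom[[sprintf("offset_%+d", as.integer(round(p)))]]$x[["var_pos"]])
      }, numeric(1))
      list(div = cand$div[i], r = cand$r[i], msrd = obj[i],
           mean_rel_dev_pct = 100 * mean(abs(sim - meas) / meas))
    }
    fx <- fit_plane(ss$sigma_x_mm, ms$sigma_x_mm)
    fy <- fit_plane(ss$sigma_y_mm, ms$sigma_y_mm)
    data.frame(energy_MeV = en,
               sigma_x_mm = ss$sigma_x_mm, sigma_y_mm = ss$sigma_y_mm,
               div_x = fx$div, r_xx = fx$r, div_y = fy$div, r_yy = fy$r,
               mean_rel_dev_x_pct = fx$mean_rel_dev_pct,
               mean_rel_dev_y_pct = fy$mean_rel_dev_pct)
  })
  out <- do.call(rbind, res)
  class(out) <- c("source_calibration", "data.frame")
  out
}
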
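# Synthetic inputs: measured-size tables with the statistical structure of
# the clinical beam-size measurements, toy beamlines with closed-form
# second moments, and analytic dose fixtures with known PVDR.

#' Specification of a synthetic measured-size campaign
#'
#' Generating source parameters per energy default to a linear
#' interpolation across the printed clinical ranges: sigma from 13 mm at
#' 100 MeV down to 3.2 mm at 220 MeV, divergence from 2.25 down to
#' 0.3 mrad, and correlation from -0.9 to +0.9 (the energy-dependent
#' functions of the real facility are not public, so these profiles are a
#' stated stand-in with the right magnitudes).
#'
#' @param energies_MeV Beam energies (default: 13 values, 100--220 MeV).
#' @param positions_cm Monitoring positions relative to the isocentre.
#' @param noise_rel Relative Gaussian noise sigma applied to each
#'   generated size (>= 0).
#' @param seed Integer seed (mandatory).
#' @param params Optional data frame overriding the generating parameters:
#'   columns energy_MeV, sigma_x_mm, sigma_y_mm, div_x, div_y, r_xx, r_yy.
#' @return Object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(energies_MeV = seq(100, 220, length.out = 13),
                           positions_cm = c(-40, -20, 0, 20, 40),
                           noise_rel = 0.01, seed, params = NULL) {
  if (missing(seed)) stop("a seed is mandatory for synthetic data")
  stopifnot(noise_rel >= 0)
  if (is.null(params)) {
    f <- (energies_MeV - 100) / 120
    params <- data.frame(
      energy_MeV = energies_MeV,
      sigma_x_mm = 13 - (13 - 3.2) * f,
      sigma_y_mm = 12 - (12 - 3.5) * f,
      div_x = 2.25 - (2.25 - 0.3) * f,
      div_y = 2.0 - (2.0 - 0.35) * f,
      r_xx = -0.9 + 1.8 * f,
      r_yy = 0.9 - 1.8 * f)
  }
  structure(list(energies_MeV = energies_MeV, positions_cm = positions_cm,
                 noise_rel = noise_rel, seed = seed, params = params),
            class = "synthetic_spec")
}

#' Generate a synthetic measured beam-size table
#'
#' Propagates each generating source through the nozzle (envelope mode,
#' quadrupoles at their configured fields) and records the horizontal and
#' vertical sigma at the monitoring positions, with relative Gaussian
#' noise applied. Reproducible for a fixed seed.
#'
#' @param spec A \code{synthetic_spec}.
#' @param nozzle A \code{nozzle_config} with monitor planes at
#'   \code{spec$positions_cm} (see \code{\link{build_nozzle}}).
#' @return A \code{measured_sizes} table (13 energies x 5 positions x 2
#'   planes with the defaults); the generating parameters are attached as
#'   attribute \code{"generating"}.
#' @export
gen_measured_sizes <- function(spec, nozzle) {
  stopifnot(inherits(spec, "synthetic_spec"), inherits(nozzle, "nozzle_config"))
  set.seed(as.integer(spec$seed %% .Machine$integer.max))
  rows <- lapply(seq_along(spec$energies_MeV), function(i) {
    p <- spec$params[i, ]
    src <- beam_source(p$energy_MeV, 0, p$sigma_x_mm, p$sigma_y_mm,
                       p$div_x, p$div_y, p$r_xx, p$r_yy)
    mom <- propagate_moments(src, nozzle, n_energy_nodes = 1)
    do.call(rbind, lapply(spec$positions_cm, function(pos) {
      m <- mom[[sprintf("offset_%+d", as.integer(round(pos)))]]
      data.frame(energy_MeV = p$energy_MeV, position_cm = pos,
                 sigma_x_mm = sqrt(m$x[["var_pos"]]),
                 sigma_y_mm = sqrt(m$y[["var_pos"]]))
    }))
  })
  df <- do.call(rbind, rows)
  n <- nrow(df)
  df$sigma_x_mm <- df$sigma_x_mm * (1 + spec$noise_rel * stats::rnorm(n))
  df$sigma_y_mm <- df$sigma_y_mm * (1 + spec$noise_rel * stats::rnorm(n))
  out <- measured_sizes(df$energy_MeV, df$position_cm, df$sigma_x_mm,
                        df$sigma_y_mm,
                        sigma_err_mm = spec$noise_rel * df$sigma_x_mm)
  attr(out, "generating") <- spec$params
  out
}

#' Toy beamlines with closed-form expected moments
#'
#' Constructs a minimal beamline together with the analytically expected
#' second moments at its target plane, for use as transport oracles:
#' \describe{
#'   \item{pure_drift}{A vacuum drift of length L: var_pos(L) = sigma0^2 +
#'     2 r sigma0 div L + div^2 L^2 (L in m).}
#'   \item{doublet}{Two thin-limit quadrupoles; the expected focal-plane
#'     position follows from the composed transfer matrices.}
#'   \item{air_drift}{A drift in air: the vacuum closed form plus the
#'     Fermi-Eyges variance increment theta0^2 L^2 / 3.}
#' }
#'
#' @param kind One of \code{"pure_drift"}, \code{"doublet"},
#'   \code{"air_drift"}.
#' @param length_cm Drift length (drift kinds).
#' @param source A \code{beam_source} used for the expected values.
#' @param field_T,quad_length_cm,gap_cm Doublet parameters.
#' @return List with \code{nozzle} and \code{expected} (a function of no
#'   arguments returning the expected per-plane var_pos at the target, or
#'   focal data for the doublet).
#' @export
gen_toy_beamline <- function(kind = c("pure_drift", "doublet", "air_drift"),
                             length_cm = 100, source = NULL,
                             field_T = 1, quad_length_cm = 1, gap_cm = 20) {
  kind <- match.arg(kind)
  if (kind %in% c("pure_drift", "air_drift")) {
    medium <- if (kind == "pure_drift") "vacuum" else "air"
    noz <- nozzle_config(list(el_drift(length_cm, medium)), preset = kind)
    expected <- function() {
      stopifnot(inherits(source, "beam_source"))
      L <- length_cm / 100
      plane <- function(s, d, r) {
        v <- s^2 + 2 * r * s * d * L + d^2 * L^2
        if (medium == "air") {
          th0 <- scattering_theta0(source$energy, L, "air")
          v <- v + th0^2 * L^2 / 3
        }
        v
      }
      c(x = plane(source$sigma_x, source$div_x, source$r_xx),
        y = plane(source$sigma_y, source$div_y, source$r_yy))
    }
    return(list(nozzle = noz, expected = expected))
  }
  # doublet: two short quadrupoles around a gap; expected focal length from
  # the thin-lens composition 1/f = 1/f1 + 1/f2 - d/(f1 f2)
  noz <- nozzle_config(list(
    el_drift(5, "vacuum"),
    el_quad(quad_length_cm, field_T, 5, "horizontal", "vacuum"),
    el_drift(gap_cm, "vacuum"),
    el_quad(quad_length_cm, field_T, 5, "vertical", "vacuum"),
    el_drift(length_cm, "vacuum")), preset = "doublet")
  expected <- function(energy = 100) {
    brho <- proton_kinematics(energy)$brho
    k <- (field_T / 0.05) / brho
    f1 <- 1 / (k * quad_length_cm / 100) # thin-lens focal length, m
    d <- (gap_cm + quad_length_cm) / 100 # lens separation
    # equal-strength F-D pair: net 1/f = d / f1^2 in both planes
    f1^2 / d
  }
  list(nozzle = noz, expected = expected)
}

#' Gaussian-comb dose fixture with closed-form PVDR
#'
#' A transverse dose that is the sum of identical 2-D Gaussians of width
#' sigma on an n x n square grid with the given spacing, constant in
#' depth. The attached closed-form PVDR is the ratio of the lattice sum at
#' a beam centre to the sum at the midpoint of the central four beams,
#' evaluated by direct summation over all beams.
#'
#' @param sigma_mm Gaussian sigma of each beam, mm.
#' @param spacing_mm Centre-to-centre spacing, mm.
#' @param n_beams Beams per side.
#' @param phantom A \code{phantom_spec} defining the voxel grid.
#' @return A \code{dose_grid} with attribute \code{"pvdr_closed_form"}.
#' @export
gen_pvdr_fixture <- function(sigma_mm, spacing_mm, n_beams = 5,
                             phantom = phantom_spec(2, 2, 1,
                                                    c(0.05, 0.05, 1))) {
  stopifnot(sigma_mm > 0, spacing_mm > 0)
  lay <- grid_layout(n_beams, spacing_mm)
  nx <- phantom$n[1]; ny <- phantom$n[2]; nz <- phantom$n[3]
  xc <- (seq_len(nx) - (nx + 1) / 2) * phantom$voxel_mm[1]
  yc <- (seq_len(ny) - (ny + 1) / 2) * phantom$voxel_mm[2]
  gx <- rowSums(vapply(lay$offsets_mm,
                       function(m) stats::dnorm(xc, m, sigma_mm),
                       numeric(nx)))
  gy <- rowSums(vapply(lay$offsets_mm,
                       function(m) stats::dnorm(yc, m, sigma_mm),
                       numeric(ny)))
  sl <- outer(gx, gy)
  dose <- array(rep(sl, nz), c(nx, ny, nz))
  comb <- function(x, y) { # brute-force lattice sum over all n^2 beams
    s <- 0
    for (ox in lay$offsets_mm) for (oy in lay$offsets_mm) {
      s <- s + exp(-((x - ox)^2 + (y - oy)^2) / (2 * sigma_mm^2))
    }
    s
  }
  pvdr <- comb(0, 0) / comb(spacing_mm / 2, spacing_mm / 2)
  structure(list(dose = dose, x_mm = xc, y_mm = yc,
                 z_cm = (seq_len(nz) - 0.5) * phantom$voxel_mm[3] / 10,
                 voxel_mm = phantom$voxel_mm, rel_unc = NULL, layout = lay,
                 mode = "fixture", energy = NA_real_, spread = NA_real_,
                 n = NA_real_, d1_m = Inf, d2_m = Inf,
                 pvdr_closed_form = pvdr),
            class = "dose_grid")
}
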
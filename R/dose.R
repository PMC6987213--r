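# Water-phantom dose engine: analytic Bragg curve, pencil-beam
# superposition of a scanned minibeam grid, and PVDR / depth-dose analysis.

# Range-energy power law R = alpha * E^p (cm, MeV) and Bortfeld-style
# constants: slope of the linear primary-fluence reduction beta (1/cm),
# fraction gamma of locally absorbed energy from nonelastic interactions,
# mono-energetic range-straggling width.
.BRAGG <- list(alpha = 0.0022, p = 1.77, beta = 0.012, gamma = 0.6)

#' CSDA range of protons in water
#'
#' Power-law range--energy relation R = alpha E^p with alpha = 0.0022,
#' p = 1.77 (R in cm, E in MeV).
#'
#' @param energy Kinetic energy, MeV.
#' @return Range in cm.
#' @export
bragg_range <- function(energy) {
  .BRAGG$alpha * energy^.BRAGG$p
}

# residual energy at depth z (cm) in water; floored to keep pv finite
residual_energy <- function(energy, z) {
  R <- bragg_range(energy)
  pmax(((pmax(R - z, 1e-6)) / .BRAGG$alpha)^(1 / .BRAGG$p), 3)
}

# total sigma (cm) of the range distribution: mono-energetic straggling
# plus the range spread induced by the Gaussian energy spread
range_sigma <- function(energy, spread) {
  R <- bragg_range(energy)
  sqrt((0.012 * R^0.935)^2 + (.BRAGG$p * R * spread)^2)
}

#' Analytic Bragg depth-dose curve
#'
#' Bortfeld-style analytic central-axis depth dose per unit fluence: the
#' unstraggled curve combines the CSDA stopping term
#' (R - z)^(1/p - 1) with a linear primary-fluence reduction (slope beta,
#' locally absorbed fraction gamma), and is convolved numerically with a
#' Gaussian range spread combining mono-energetic straggling
#' (0.012 R^0.935) and the source energy spread. The singular stopping term
#' is removed exactly by the substitution w = (R - u)^(1/p) before
#' quadrature.
#'
#' @param energy Kinetic energy, MeV.
#' @param spread Fractional energy spread (Gaussian sigma).
#' @param depth_cm Depths at which to evaluate, cm (vectorised).
#' @return Dose per unit fluence (arbitrary units), zero well beyond the
#'   range (> R + 5 straggling widths).
#' @export
bragg_depth_dose <- function(energy, spread = 0.01, depth_cm) {
  stopifnot(energy > 0, spread >= 0, all(depth_cm >= 0))
  R <- bragg_range(energy)
  sig <- max(range_sigma(energy, spread), 1e-4)
  p <- .BRAGG$p
  b2 <- .BRAGG$beta * (1 + .BRAGG$gamma * p) # weight of the fluence term
  # The curve is the range-sampled expectation D(z) = E[S0(z; R')] over
  # Gaussian ranges R' ~ N(R, sig): with t = R' - z this is the integral of
  # [t^(1/p-1) + b2 t^(1/p)] phi(t - (R - z)) over t in (0, R + 6 sig).
  # The substitution t = w^p removes the stopping-power singularity exactly.
  nw <- 1500
  wmax <- (R + 6 * sig)^(1 / p)
  w <- seq(0, wmax, length.out = nw + 1)
  w <- (w[-1] + w[-(nw + 1)]) / 2
  dw <- wmax / nw
  u <- R - w^p # kernel argument z - u = (w^p) - (R - z)
  wt <- (1 + b2 * w^p) * dw # relative weights; overall scale arbitrary
  out <- vapply(depth_cm, function(z) {
    if (z > R + 5 * sig) return(0)
    sum(wt * stats::dnorm(z - u, 0, sig))
  }, numeric(1))
  out / (1 + .BRAGG$beta * R)
}

#' Water phantom specification
#'
#' @param size_x_cm,size_y_cm Transverse dimensions, cm.
#' @param depth_cm Phantom depth, cm (10 for 100 MeV, 30 for 200 MeV by
#'   convention).
#' @param voxel_mm Voxel size (dx, dy, dz) in mm; must divide the phantom
#'   dimensions.
#' @return Object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(size_x_cm = 2, size_y_cm = 2, depth_cm = 10,
                         voxel_mm = c(0.05, 0.05, 1)) {
  stopifnot(size_x_cm > 0, size_y_cm > 0, depth_cm > 0,
            length(voxel_mm) == 3, all(voxel_mm > 0))
  n <- c(size_x_cm * 10 / voxel_mm[1], size_y_cm * 10 / voxel_mm[2],
         depth_cm * 10 / voxel_mm[3])
  if (any(abs(n - round(n)) > 1e-9)) {
    stop("voxel size must divide the phantom dimensions")
  }
  structure(list(size_x_cm = size_x_cm, size_y_cm = size_y_cm,
                 depth_cm = depth_cm, voxel_mm = voxel_mm,
                 n = as.integer(round(n))),
            class = "phantom_spec")
}

#' Square minibeam grid layout
#'
#' @param n Beams per side (default 5, i.e. a 5x5 grid).
#' @param spacing_mm Centre-to-centre spacing, mm.
#' @return Object of class \code{grid_layout} with the beam centre offsets.
#' @export
grid_layout <- function(n = 5, spacing_mm = 2.9) {
  stopifnot(n >= 1, spacing_mm > 0)
  off <- (seq_len(n) - (n + 1) / 2) * spacing_mm
  structure(list(n = n, spacing_mm = spacing_mm, offsets_mm = off),
            class = "grid_layout")
}

# per-plane (s11, s12, s22) at the phantom entrance and the scanning-dipole
# distances needed to aim the beams
entrance_state <- function(nozzle, source, n_energy_nodes = 7) {
  mom <- propagate_moments(source, nozzle, n_energy_nodes = n_energy_nodes)$target
  sm_z <- nozzle$z_end_cm[vapply(nozzle$elements,
                                 function(e) e$kind == "dipole_kick",
                                 logical(1))]
  if (length(sm_z) < 2) stop("nozzle needs two scanning dipoles for a grid")
  list(sx = unname(mom$x), sy = unname(mom$y),
       d1_m = (nozzle$target_cm - sm_z[1]) / 100,
       d2_m = (nozzle$target_cm - sm_z[2]) / 100)
}

# evolve per-plane second moments through water; returns sigma (mm) at the
# requested depths for both planes
water_sigma <- function(sx, sy, energy, z_cm, dz = 0.05) {
  R <- bragg_range(energy)
  zmax <- max(z_cm)
  nstep <- ceiling(zmax / dz)
  zs <- seq_len(nstep) * dz
  sigx <- numeric(nstep); sigy <- numeric(nstep)
  x0 <- radiation_length_m("water")
  for (i in seq_len(nstep)) {
    L <- dz / 100
    sxn <- sandwich(1, L, 0, 1, sx[1], sx[2], sx[3])
    syn <- sandwich(1, L, 0, 1, sy[1], sy[2], sy[3])
    sx <- c(sxn$s11, sxn$s12, sxn$s22)
    sy <- c(syn$s11, syn$s12, syn$s22)
    if (zs[i] < R) {
      e_here <- residual_energy(energy, zs[i])
      pv <- proton_kinematics(e_here)$pv
      lt <- 1 + 0.038 * log(zs[i] / 100 / x0)
      ths <- max(13.6 / pv * sqrt(L / x0) * lt, 0) * 1000 # mrad
      inc <- fe_increment(ths, L)
      sx <- sx + c(inc$d11, inc$d12, inc$d22)
      sy <- sy + c(inc$d11, inc$d12, inc$d22)
    }
    sigx[i] <- sqrt(sx[1]); sigy[i] <- sqrt(sy[1])
  }
  idx <- pmax(1, pmin(nstep, round(z_cm / dz)))
  list(sigx = sigx[idx], sigy = sigy[idx])
}

#' Simulate the dose of a scanned minibeam grid in a water phantom
#'
#' The beam is transported through the nozzle (with the supplied quadrupole
#' fields) to the phantom entrance; the scanning dipoles deflect each
#' minibeam of the square grid to its position, so off-centre beams enter
#' at an angle. In \code{analytic} mode each pencil beam's lateral spread
#' evolves in water by Fermi-Eyges transport of its entrance moments with
#' the local Highland scattering power, and the voxel dose is the
#' separable Gaussian superposition of all beams weighted by the analytic
#' Bragg depth-dose. In \code{monte_carlo} mode individual protons are
#' stepped through the depth slabs with sampled scattering kicks and
#' per-particle ranges, and dose is tallied per voxel; the per-voxel
#' relative uncertainty is the standard deviation over \code{repeats}
#' independent repetitions.
#'
#' @param nozzle A \code{nozzle_config} (scanned fields already set, e.g.
#'   via \code{\link{set_scan_fields}} with the scan minimum).
#' @param source A \code{beam_source}.
#' @param layout A \code{grid_layout}.
#' @param phantom A \code{phantom_spec}.
#' @param mode \code{"analytic"} or \code{"monte_carlo"}.
#' @param n Total number of primaries (shared equally between beams);
#'   in analytic mode a pure scale factor.
#' @param repeats Repetitions for the Monte Carlo uncertainty estimate.
#' @param seed Integer seed (Monte Carlo mode).
#' @return Object of class \code{dose_grid}: 3-D dose array
#'   \code{[x, y, z]} with voxel-centre coordinates, the layout, and (MC
#'   mode) a per-voxel relative-uncertainty array.
#' @export
compute_dose_grid <- function(nozzle, source, layout, phantom,
                              mode = c("analytic", "monte_carlo"),
                              n = 1e6, repeats = 50, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(layout, "grid_layout"), inherits(phantom, "phantom_spec"))
  if (max(abs(layout$offsets_mm)) * 2 > phantom$size_x_cm * 10 ||
      max(abs(layout$offsets_mm)) * 2 > phantom$size_y_cm * 10) {
    stop("beam grid exceeds the phantom cross-section")
  }
  es <- entrance_state(nozzle, source)
  nx <- phantom$n[1]; ny <- phantom$n[2]; nz <- phantom$n[3]
  vx <- phantom$voxel_mm[1]; vy <- phantom$voxel_mm[2]; vz <- phantom$voxel_mm[3]
  xc <- (seq_len(nx) - (nx + 1) / 2) * vx
  yc <- (seq_len(ny) - (ny + 1) / 2) * vy
  zc <- (seq_len(nz) - 0.5) * vz / 10 # cm
  bragg <- bragg_depth_dose(source$energy, source$energy_spread, zc)
  w_beam <- n / layout$n^2
  if (mode == "analytic") {
    ws <- water_sigma(es$sx, es$sy, source$energy, zc)
    dose <- array(0, c(nx, ny, nz))
    for (k in seq_len(nz)) {
      # beam centres drift with the scanning-dipole deflection angles
      bx <- layout$offsets_mm * (1 + zc[k] / 100 / es$d1_m)
      by <- layout$offsets_mm * (1 + zc[k] / 100 / es$d2_m)
      gx <- rowSums(vapply(bx, function(m) stats::dnorm(xc, m, ws$sigx[k]),
                           numeric(nx)))
      gy <- rowSums(vapply(by, function(m) stats::dnorm(yc, m, ws$sigy[k]),
                           numeric(ny)))
      dose[, , k] <- (w_beam * bragg[k] * vz) * outer(gx, gy)
    }
    rel_unc <- NULL
  } else {
    set.seed(as.integer(seed %% .Machine$integer.max))
    n_b <- max(1L, round(n / layout$n^2))
    x0 <- radiation_length_m("water")
    acc <- vector("list", repeats)
    p <- .BRAGG$p
    b2 <- .BRAGG$beta * (1 + .BRAGG$gamma * p)
    sig_mono <- 0.012 * bragg_range(source$energy)^0.935
    for (rep_i in seq_len(repeats)) {
      d <- array(0, c(nx, ny, nz))
      for (ox in layout$offsets_mm) for (oy in layout$offsets_mm) {
        smp <- function(s) { # sample (pos, ang) from a 2x2 covariance
          a <- sqrt(s[1]); c1 <- s[2] / a
          c2 <- sqrt(max(s[3] - c1^2, 0))
          z1 <- stats::rnorm(n_b); z2 <- stats::rnorm(n_b)
          list(p = a * z1, a = c1 * z1 + c2 * z2)
        }
        hx <- smp(es$sx); vyp <- smp(es$sy)
        px <- hx$p + ox; pxa <- hx$a + ox / es$d1_m
        py <- vyp$p + oy; pya <- vyp$a + oy / es$d2_m
        en <- stats::rnorm(n_b, source$energy,
                           source$energy * source$energy_spread)
        Ri <- bragg_range(pmax(en, 1)) + stats::rnorm(n_b, 0, sig_mono)
        for (k in seq_len(nz)) {
          dzc <- vz / 10
          px <- px + pxa * dzc / 100; py <- py + pya * dzc / 100
          zk <- zc[k]
          alive <- Ri > zk
          if (!any(alive)) break
          e_here <- residual_energy(source$energy, zk)
          pv <- proton_kinematics(e_here)$pv
          lt <- 1 + 0.038 * log(max(zk, dzc) / 100 / x0)
          ths <- max(13.6 / pv * sqrt(dzc / 100 / x0) * lt, 0) * 1000
          kx <- stats::rnorm(n_b, 0, ths); ky <- stats::rnorm(n_b, 0, ths)
          px <- px + kx * dzc / 100 / 2; pxa <- pxa + kx
          py <- py + ky * dzc / 100 / 2; pya <- pya + ky
          res <- pmax(Ri[alive] - zk, 1e-3)
          wdep <- res^(1 / p - 1) + b2 * res^(1 / p)
          ix <- floor(px[alive] / vx + nx / 2) + 1
          iy <- floor(py[alive] / vy + ny / 2) + 1
          ok <- ix >= 1 & ix <= nx & iy >= 1 & iy <= ny
          if (any(ok)) {
            ii <- ix[ok] + (iy[ok] - 1) * nx
            tal <- tabulate_weighted(ii, wdep[ok], nx * ny)
            d[, , k] <- d[, , k] + matrix(tal, nx, ny)
          }
        }
      }
      acc[[rep_i]] <- d
    }
    dose <- Reduce(`+`, acc) / repeats * (w_beam / n_b)
    if (repeats > 1) {
      m2 <- Reduce(`+`, lapply(acc, function(d) d^2)) / repeats
      sdv <- sqrt(pmax(m2 - (dose / (w_beam / n_b))^2, 0) / (repeats - 1))
      rel_unc <- array(NA_real_, dim(dose))
      pos <- dose > 0
      rel_unc[pos] <- sdv[pos] / (dose[pos] / (w_beam / n_b))
    } else rel_unc <- NULL
  }
  structure(list(dose = dose, x_mm = xc, y_mm = yc, z_cm = zc,
                 voxel_mm = phantom$voxel_mm, rel_unc = rel_unc,
                 layout = layout, mode = mode,
                 energy = source$energy, spread = source$energy_spread,
                 n = n, d1_m = es$d1_m, d2_m = es$d2_m),
            class = "dose_grid")
}

tabulate_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  rs <- rowsum(w, idx)
  out[as.integer(rownames(rs))] <- rs[, 1]
  out
}

#' Analyse a minibeam dose grid
#'
#' Computes, per 1 mm depth slab: the peak dose on the central beam axis,
#' the valley dose at the fixed transverse midpoint between the four
#' central beams (spacing/2, spacing/2), their ratio PVDR (undefined --
#' \code{NA} -- where the valley dose is zero), and, if a single-beam grid
#' is supplied, the Gaussian FWHM of the central minibeam without the
#' contribution of the surrounding beams. Also reports the peak and valley
#' percentage depth-dose curves, the Bragg-peak to entrance ratio of the
#' peak curve, the lateral flatness (Dmax - Dmin)/(Dmax + Dmin) over the
#' central 80% of the field at the Bragg-peak depth, and the global
#' relative uncertainty (RMS of voxel uncertainties over voxels with at
#' least half the maximum dose) when the grid carries uncertainties.
#'
#' @param grid A \code{dose_grid}.
#' @param layout The \code{grid_layout} used (defaults to the one stored in
#'   the grid).
#' @param single_grid Optional \code{dose_grid} of the central beam alone,
#'   used for the FWHM-versus-depth curve.
#' @return Object of class \code{dose_analysis}.
#' @export
analyze_dose <- function(grid, layout = grid$layout, single_grid = NULL) {
  stopifnot(inherits(grid, "dose_grid"))
  xc <- grid$x_mm; yc <- grid$y_mm; zc <- grid$z_cm
  ix0 <- which(abs(xc) <= max(0.11, grid$voxel_mm[1]))
  iy0 <- which(abs(yc) <= max(0.11, grid$voxel_mm[2]))
  s2 <- layout$spacing_mm / 2
  ixv <- order(abs(xc - s2))[1:2]; iyv <- order(abs(yc - s2))[1:2]
  nz <- length(zc)
  peak <- valley <- fwhm <- rep(NA_real_, nz)
  for (k in seq_len(nz)) {
    sl <- grid$dose[, , k]
    peak[k] <- max(sl[ix0, iy0])
    valley[k] <- mean(sl[ixv, iyv])
  }
  pvdr <- ifelse(valley > 0, peak / valley, NA_real_)
  pvdr[!is.na(pvdr) & peak == 0] <- NA_real_
  if (!is.null(single_grid)) {
    iy_mid <- which.min(abs(single_grid$y_mm))
    for (k in seq_len(nz)) {
      prof <- single_grid$dose[, iy_mid, k]
      if (sum(prof) > 0 && max(prof) > 0) {
        f <- tryCatch(fit_gaussian_profile(single_grid$x_mm, prof),
                      error = function(e) NULL)
        if (!is.null(f)) fwhm[k] <- FWHM_CONST * f$sigma
      }
    }
  }
  # Bragg-peak depth from the depth-dose curve of the beam energy: the
  # central-axis peak curve itself is entrance-dominated for a tightly
  # focused minibeam (the fluence density drops as the beam widens)
  i_bp <- if (is.na(grid$energy)) which.max(peak)
          else which.max(bragg_depth_dose(grid$energy, grid$spread, zc))
  # lateral flatness at the Bragg-peak depth over the central 80% of the
  # nominal field (side = n * spacing), on the x profile through y = 0
  iy_mid <- which.min(abs(yc))
  half <- 0.4 * layout$n * layout$spacing_mm
  sel <- abs(xc) <= half
  prof_bp <- grid$dose[sel, iy_mid, i_bp]
  flatness <- if (max(prof_bp) + min(prof_bp) > 0) {
    100 * (max(prof_bp) - min(prof_bp)) / (max(prof_bp) + min(prof_bp))
  } else NA_real_
  glob_unc <- NA_real_
  if (!is.null(grid$rel_unc)) {
    hot <- grid$dose >= max(grid$dose) / 2
    glob_unc <- 100 * sqrt(mean(grid$rel_unc[hot]^2, na.rm = TRUE))
  }
  structure(list(
    curve = data.frame(z_cm = zc, peak = peak, valley = valley, pvdr = pvdr,
                       fwhm_mm = fwhm,
                       pdd_peak = 100 * peak / max(peak),
                       pdd_valley = 100 * valley / max(peak)),
    bragg_depth_cm = zc[i_bp],
    peak_to_entrance = peak[i_bp] / peak[1],
    entrance_pvdr = pvdr[1],
    flatness_pct = flatness,
    global_rel_unc_pct = glob_unc,
    layout = layout),
    class = "dose_analysis")
}

#' @export
print.dose_analysis <- function(x, ...) {
  cat(sprintf("Minibeam dose analysis (%dx%d grid, spacing %.1f mm)\n",
              x$layout$n, x$layout$n, x$layout$spacing_mm))
  cat(sprintf("  Bragg peak depth: %.1f cm\n", x$bragg_depth_cm))
  cat(sprintf("  entrance PVDR: %.4g\n", x$entrance_pvdr))
  cat(sprintf("  peak-to-entrance dose ratio: %.3f\n", x$peak_to_entrance))
  cat(sprintf("  lateral flatness at Bragg depth: %.1f%%\n", x$flatness_pct))
  if (!is.na(x$global_rel_unc_pct)) {
    cat(sprintf("  global relative uncertainty: %.2f%%\n",
                x$global_rel_unc_pct))
  }
  invisible(x)
}

#' @export
plot.dose_analysis <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  cu <- x$curve
  graphics::plot(cu$z_cm, cu$fwhm_mm, type = "b", xlab = "depth [cm]",
                 ylab = "central minibeam hFWHM [mm]", main = "beam width")
  graphics::plot(cu$z_cm, cu$pvdr, type = "b", log = "y", xlab = "depth [cm]",
                 ylab = "PVDR", main = "peak-to-valley dose ratio")
  graphics::matplot(cu$z_cm, cbind(cu$pdd_peak, cu$pdd_valley), type = "l",
                    lty = c(1, 2), col = 1, xlab = "depth [cm]",
                    ylab = "dose [% of peak max]", main = "depth dose")
  invisible(x)
}

#' Spacing for lateral homogenisation at the Bragg peak
#'
#' Searches centre-to-centre spacings (0.1 mm resolution by default) for
#' the smallest one whose lateral flatness at the Bragg-peak depth falls
#' inside the requested band. Flatness is (Dmax - Dmin)/(Dmax + Dmin) in
#' percent over the central 80% of the nominal field (side n * spacing) of
#' the x profile through the beam row.
#'
#' @param nozzle,source Nozzle (fields set) and source.
#' @param phantom A \code{phantom_spec} (sets the depth range).
#' @param flatness_band Acceptable flatness band in percent.
#' @param spacings_mm Candidate spacings.
#' @param n Beams per side.
#' @return The smallest spacing in the band (mm), with the flatness values
#'   as attribute \code{"flatness"}; error if no candidate falls in the
#'   band (the closest candidate is named in the message).
#' @export
find_homogenisation_spacing <- function(nozzle, source, phantom,
                                        flatness_band = c(5, 6),
                                        spacings_mm = seq(2, 6, by = 0.1),
                                        n = 5) {
  es <- entrance_state(nozzle, source)
  zbp <- bragg_range(source$energy) # close to the peak of the convolved curve
  ws <- water_sigma(es$sx, es$sy, source$energy, zbp)
  flat <- vapply(spacings_mm, function(s) {
    off <- (seq_len(n) - (n + 1) / 2) * s * (1 + zbp / 100 / es$d1_m)
    xs <- seq(-0.4 * n * s, 0.4 * n * s, by = 0.02)
    prof <- rowSums(vapply(off, function(m) stats::dnorm(xs, m, ws$sigx),
                           numeric(length(xs))))
    100 * (max(prof) - min(prof)) / (max(prof) + min(prof))
  }, numeric(1))
  ok <- which(flat >= flatness_band[1] & flat <= flatness_band[2])
  if (length(ok) == 0) {
    i <- which.min(pmin(abs(flat - flatness_band[1]),
                        abs(flat - flatness_band[2])))
    stop(sprintf(
      "no spacing in [%g, %g] mm gives flatness in [%g, %g]%%; closest: %g mm (%.2f%%)",
      min(spacings_mm), max(spacings_mm), flatness_band[1], flatness_band[2],
      spacings_mm[i], flat[i]))
  }
  structure(spacings_mm[min(ok)],
            flatness = stats::setNames(flat, spacings_mm))
}
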
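# Beamline elements, nozzle geometries and beam transport.
#
# Transport is available in two equivalent modes:
#  * envelope: the per-plane 2x2 covariance (sigma) matrix is propagated
#    analytically through hard-edge transfer maps; scattering media add
#    Fermi-Eyges second-moment increments; chromatic effects of a finite
#    energy spread are included by averaging over Gauss-Hermite energy nodes;
#  * Monte Carlo: individual particles are tracked with per-particle
#    (chromatic) transfer maps and correlated Highland scattering kicks.

# ---- elements ----------------------------------------------------------------

#' Beamline element constructors
#'
#' Build the ordered elements of a nozzle: field-free drifts (in vacuum or
#' air), hard-edge quadrupoles characterised by pole-tip field and aperture
#' radius (gradient = field / aperture), thin scanning-dipole kicks, thin
#' material slabs given by their water-equivalent thickness, and monitoring
#' planes at which transported beams are recorded.
#'
#' @param length_cm Element length in cm (>= 0).
#' @param medium \code{"vacuum"} or \code{"air"}.
#' @param field_T Quadrupole pole-tip field in T (>= 0).
#' @param aperture_cm Quadrupole aperture radius in cm (> 0).
#' @param focus_plane Plane in which the quadrupole focuses:
#'   \code{"horizontal"} or \code{"vertical"}.
#' @param scan Logical: is this quadrupole varied by the grid-search scan?
#' @param max_field_T Upper field limit accepted for this quadrupole.
#' @param kick_x_mrad,kick_y_mrad Thin dipole deflection angles, mrad.
#' @param wet_mm Water-equivalent thickness of a slab, mm (>= 0).
#' @param label Monitor label.
#' @name elements
#' @export
el_drift <- function(length_cm, medium = "vacuum") {
  stopifnot(length_cm >= 0, medium %in% c("vacuum", "air"))
  list(kind = "drift", length_cm = length_cm, medium = medium)
}

#' @rdname elements
#' @export
el_quad <- function(length_cm = 30, field_T = 0, aperture_cm = 5,
                    focus_plane = "horizontal", medium = "vacuum",
                    scan = TRUE, max_field_T = 2) {
  stopifnot(length_cm >= 0, field_T >= 0, aperture_cm > 0,
            focus_plane %in% c("horizontal", "vertical"))
  if (field_T > max_field_T) stop("quadrupole field exceeds max_field_T")
  list(kind = "quadrupole", length_cm = length_cm, field_T = field_T,
       aperture_cm = aperture_cm, focus_plane = focus_plane,
       medium = medium, scan = scan, max_field_T = max_field_T)
}

#' @rdname elements
#' @export
el_dipole_kick <- function(kick_x_mrad = 0, kick_y_mrad = 0, label = "SM") {
  list(kind = "dipole_kick", length_cm = 0,
       kick_x_mrad = kick_x_mrad, kick_y_mrad = kick_y_mrad, label = label)
}

#' @rdname elements
#' @export
el_slab <- function(wet_mm, material = "water", label = "slab") {
  stopifnot(wet_mm >= 0)
  radiation_length_m(material) # validates the material name
  list(kind = "slab", length_cm = 0, wet_mm = wet_mm, material = material,
       label = label)
}

#' @rdname elements
#' @export
el_monitor <- function(label) {
  list(kind = "monitor", length_cm = 0, label = label)
}

# ---- nozzle ------------------------------------------------------------------

#' Assemble a nozzle from an ordered element list
#'
#' @param elements List of elements built with \code{\link{el_drift}} etc.
#'   The transported beam is always recorded at the end of the sequence
#'   (the target plane) in addition to any \code{el_monitor} planes.
#' @param preset Optional preset label.
#' @param air_gap_cm Book-keeping: length of the final air gap, cm.
#' @return Object of class \code{nozzle_config}; \code{$target_cm} is the
#'   z position of the target plane (cm downstream of the source).
#' @export
nozzle_config <- function(elements, preset = "custom", air_gap_cm = NA) {
  stopifnot(is.list(elements), length(elements) > 0)
  lens <- vapply(elements, function(e) e$length_cm, numeric(1))
  if (any(lens < 0)) stop("element lengths must be >= 0")
  structure(list(elements = elements, preset = preset,
                 air_gap_cm = air_gap_cm,
                 z_end_cm = cumsum(lens), target_cm = sum(lens)),
            class = "nozzle_config")
}

#' @export
print.nozzle_config <- function(x, ...) {
  cat(sprintf("Nozzle preset '%s': %d elements, target at %.1f cm\n",
              x$preset, length(x$elements), x$target_cm))
  for (i in seq_along(x$elements)) {
    e <- x$elements[[i]]
    desc <- switch(e$kind,
      drift = sprintf("drift %g cm (%s)", e$length_cm, e$medium),
      quadrupole = sprintf("quad %g cm, %g T (%s, scan=%s)", e$length_cm,
                           e$field_T, e$focus_plane, e$scan),
      dipole_kick = sprintf("dipole kick %s (%g, %g) mrad", e$label,
                            e$kick_x_mrad, e$kick_y_mrad),
      slab = sprintf("slab %s %g mm WET", e$label, e$wet_mm),
      monitor = sprintf("monitor '%s'", e$label))
    cat(sprintf("  %2d. z_end %6.1f cm  %s\n", i, x$z_end_cm[i], desc))
  }
  invisible(x)
}

#' Build a preset nozzle geometry
#'
#' Presets:
#' \describe{
#'   \item{optimized}{Compact design: beam source at the vacuum-tank
#'     entrance, a short quadrupole doublet in vacuum immediately behind it,
#'     two thin scanning dipoles, vacuum window (0.1 mm WET) and a thin
#'     transmission ionisation chamber (0.6 mm WET) at the end of the vacuum
#'     section, then an air gap of 10--30 cm to the target. The focal length
#'     (Q2 exit to target) defaults to 100 cm, the middle of the 90--110 cm
#'     band. The front end is deliberately short (28 cm with the default
#'     12 cm quadrupoles): a beam with an extreme negative position--angle
#'     correlation converges to a crossover sigma/divergence (about 1.3 m
#'     for the reference sources) downstream of the source, and a
#'     net-focusing doublet can only pull a crossover earlier, never delay
#'     it -- so the whole focusing section must sit upstream of that
#'     crossover for such beams to be imaged onto the target.}
#'   \item{icpo_current}{Assumed geometry of a clinical universal PBS nozzle:
#'     vacuum window, vacuum tank, IC1, quadrupole doublet and scanning
#'     dipoles in air, IC2, long air path to the isocentre 250 cm downstream
#'     of the window. Element positions and material budgets are stated
#'     assumptions (manufacturer plans are not public); all are overridable
#'     by passing a custom element list to \code{\link{nozzle_config}}.}
#'   \item{icpo_mod1}{As icpo_current with every drift evacuated (the
#'     ionisation-chamber slabs remain).}
#'   \item{icpo_mod2}{As icpo_current without the snout: target moved to
#'     30 cm behind IC2.}
#'   \item{icpo_mod3}{As icpo_current plus an extra quadrupole pair (fields
#'     allowed up to 4 T) close to the target, with IC2 moved downstream of
#'     them; the extra pair is the scanned one.}
#' }
#'
#' @param preset Preset name (see Details).
#' @param air_gap_cm Air gap for the optimized design, cm (10 or 30 in the
#'   reference configurations; other positive values are accepted with a
#'   warning).
#' @param target_offset_cm Target position relative to the isocentre for the
#'   icpo presets, cm (-40 to +40 addressable).
#' @param focal_length_cm Q2-exit-to-target distance of the optimized design.
#' @param quad_length_cm,aperture_cm Quadrupole dimensions.
#' @param ic_wet_mm,vw_wet_mm Water-equivalent thicknesses of the monitoring
#'   chamber and vacuum window of the optimized design.
#' @param monitor_offsets_cm For icpo presets: offsets (relative to the
#'   isocentre) at which monitoring planes are inserted, e.g.
#'   \code{c(-40, -20, 0, 20, 40)} for the measured-beam-size planes.
#' @return A \code{nozzle_config}.
#' @export
build_nozzle <- function(preset = c("optimized", "icpo_current", "icpo_mod1",
                                    "icpo_mod2", "icpo_mod3"),
                         air_gap_cm = 10, target_offset_cm = 0,
                         focal_length_cm = 100,
                         quad_length_cm = 12, aperture_cm = 3,
                         ic_wet_mm = 0.6, vw_wet_mm = 0.1,
                         monitor_offsets_cm = NULL) {
  preset <- match.arg(preset)
  if (preset == "optimized") {
    if (air_gap_cm < 0) stop("air gap must be >= 0")
    if (!air_gap_cm %in% c(10, 30)) {
      warning("air gap outside the reference 10/30 cm configurations")
    }
    if (focal_length_cm < 90 || focal_length_cm > 110) {
      warning("focal length outside the 90-110 cm design band")
    }
    d_rest <- focal_length_cm - air_gap_cm - 30
    if (d_rest < 0) stop("air gap too long for the chosen focal length")
    els <- list(
      el_drift(1, "vacuum"),
      el_quad(quad_length_cm, 0, aperture_cm, "horizontal", "vacuum"),
      el_drift(3, "vacuum"),
      el_quad(quad_length_cm, 0, aperture_cm, "vertical", "vacuum"),
      el_drift(20, "vacuum"),
      el_dipole_kick(label = "SM1"),
      el_drift(10, "vacuum"),
      el_dipole_kick(label = "SM2"),
      el_drift(d_rest, "vacuum"),
      el_slab(vw_wet_mm, label = "VW"),
      el_slab(ic_wet_mm, label = "IC"),
      el_drift(air_gap_cm, "air"))
    return(nozzle_config(els, preset, air_gap_cm))
  }
  # icpo family: source at the vacuum window, isocentre 250 cm downstream
  if (abs(target_offset_cm) > 40) {
    warning("target offset outside the -40..+40 cm range")
  }
  medium <- if (preset == "icpo_mod1") "vacuum" else "air"
  els <- list(
    el_slab(0.1, label = "VW"),
    el_drift(60, "vacuum"),
    el_slab(1.0, label = "IC1"),
    el_drift(10, medium),
    el_quad(30, 0, aperture_cm, "horizontal", medium),
    el_drift(10, medium),
    el_quad(30, 0, aperture_cm, "vertical", medium),
    el_drift(10, medium),
    el_dipole_kick(label = "SM1"),
    el_drift(5, medium),
    el_dipole_kick(label = "SM2"),
    el_drift(5, medium))
  z_sm_end <- 160 # cm from source after the SM section
  if (preset == "icpo_mod3") {
    els <- c(els, list(
      el_drift(40, medium),
      el_quad(30, 0, aperture_cm, "horizontal", medium, scan = TRUE,
              max_field_T = 4),
      el_drift(5, medium),
      el_quad(30, 0, aperture_cm, "vertical", medium, scan = TRUE,
              max_field_T = 4),
      el_slab(1.0, label = "IC2")))
    # Q1/Q2 stay fixed; only the extra pair is scanned
    els[[5]]$scan <- FALSE
    els[[7]]$scan <- FALSE
    z_last <- z_sm_end + 75
    tail_cm <- 250 + target_offset_cm - z_last
  } else {
    els <- c(els, list(el_slab(1.0, label = "IC2")))
    target_cm <- if (preset == "icpo_mod2") z_sm_end + 30
                 else 250 + target_offset_cm
    tail_cm <- target_cm - z_sm_end
  }
  if (tail_cm <= 0) stop("target position is inside the nozzle")
  if (!is.null(monitor_offsets_cm)) {
    zs <- sort(250 + monitor_offsets_cm)
    prev <- z_sm_end
    for (z in zs) {
      els <- c(els, list(el_drift(z - prev, medium),
                         el_monitor(sprintf("offset_%+d", as.integer(round(z - 250))))))
      prev <- z
    }
    if (z_sm_end + tail_cm > prev) {
      els <- c(els, list(el_drift(z_sm_end + tail_cm - prev, medium)))
    }
  } else {
    els <- c(els, list(el_drift(tail_cm, medium)))
  }
  nozzle_config(els, preset, air_gap_cm = NA)
}

# ---- transfer maps -----------------------------------------------------------

mat_drift <- function(L_m) matrix(c(1, 0, L_m, 1), 2, 2)

# 2x2 map of a hard-edge quadrupole plane with focusing strength k (1/m^2;
# k > 0 focusing, k < 0 defocusing), length L in m
mat_quad_plane <- function(k, L_m) {
  if (abs(k) < 1e-12) return(mat_drift(L_m))
  s <- sqrt(abs(k))
  phi <- s * L_m
  if (k > 0) {
    matrix(c(cos(phi), -s * sin(phi), sin(phi) / s, cos(phi)), 2, 2)
  } else {
    matrix(c(cosh(phi), s * sinh(phi), sinh(phi) / s, cosh(phi)), 2, 2)
  }
}

#' Per-plane transfer matrices of a quadrupole
#'
#' Hard-edge maps with focusing strength
#' k = (pole-tip field / aperture radius) / (magnetic rigidity): the
#' focusing plane gets the cos/sin form, the orthogonal plane the cosh/sinh
#' form. Both have unit determinant. A zero field gives the drift map.
#'
#' @param element A quadrupole from \code{\link{el_quad}}.
#' @param energy Proton kinetic energy, MeV.
#' @return List with 2x2 matrices \code{h} and \code{v} (lengths in m,
#'   acting on (mm, mrad) state vectors).
#' @export
quad_matrix <- function(element, energy) {
  stopifnot(element$kind == "quadrupole", energy > 0)
  if (element$aperture_cm <= 0) stop("quadrupole aperture must be > 0")
  brho <- proton_kinematics(energy)$brho
  k <- (element$field_T / (element$aperture_cm / 100)) / brho
  L <- element$length_cm / 100
  sgn <- if (element$focus_plane == "horizontal") 1 else -1
  list(h = mat_quad_plane(sgn * k, L), v = mat_quad_plane(-sgn * k, L))
}

# theta0 (mrad) for the full traversal of an element, per energy
element_theta0 <- function(element, energy) {
  if (element$kind == "slab") {
    scattering_theta0(energy, element$wet_mm / 1000, element$material)
  } else if (!is.null(element$medium) && element$medium == "air" &&
             element$length_cm > 0) {
    scattering_theta0(energy, element$length_cm / 100, "air")
  } else {
    rep(0, length(energy))
  }
}

# ---- envelope transport ------------------------------------------------------

# Gauss-Hermite nodes for averaging over a Gaussian fractional energy spread.
energy_nodes <- function(energy, spread, n_nodes) {
  if (spread <= 0 || n_nodes <= 1) {
    return(list(e = energy, w = 1))
  }
  gh <- pracma::gaussHermite(n_nodes)
  list(e = energy * (1 + sqrt(2) * spread * gh$x), w = gh$w / sqrt(pi))
}

# sigma' = M sigma M^T for sigma = (s11, s12, s22); matrix entries may be
# vectors (vectorised over configurations)
sandwich <- function(m11, m12, m21, m22, s11, s12, s22) {
  list(s11 = m11^2 * s11 + 2 * m11 * m12 * s12 + m12^2 * s22,
       s12 = m11 * m21 * s11 + (m11 * m22 + m12 * m21) * s12 + m12 * m22 * s22,
       s22 = m21^2 * s11 + 2 * m21 * m22 * s12 + m22^2 * s22)
}

# Fermi-Eyges increments of a uniform scattering segment: theta0 in mrad,
# L in m; exact for constant scattering power along the segment
fe_increment <- function(theta0, L_m) {
  list(d11 = theta0^2 * L_m^2 / 3, d12 = theta0^2 * L_m / 2, d22 = theta0^2)
}

#' Propagate beam moments through a nozzle
#'
#' Analytic envelope transport: per-plane covariance matrices evolve by the
#' hard-edge transfer maps; air paths and slabs add Fermi-Eyges
#' second-moment increments; the beam centroid is propagated through the
#' same maps with the dipole kicks added. A finite source energy spread is
#' handled by averaging the covariance over Gauss-Hermite energy nodes,
#' which captures the chromatic growth of the focal spot.
#'
#' @param source A \code{beam_source} (its energy and spread are used), or a
#'   \code{beam_moments} object together with \code{energy}.
#' @param nozzle A \code{nozzle_config}.
#' @param energy Override kinetic energy, MeV (required if \code{source} is
#'   a \code{beam_moments}).
#' @param n_energy_nodes Number of quadrature nodes for the energy spread.
#' @return List of \code{beam_moments} (one per monitor plane plus the final
#'   target plane, named by monitor label / \code{"target"}); each carries
#'   an attribute \code{centroid} with per-plane mean (pos mm, ang mrad).
#' @export
propagate_moments <- function(source, nozzle, energy = NULL,
                              n_energy_nodes = 7) {
  stopifnot(inherits(nozzle, "nozzle_config"))
  if (inherits(source, "beam_source")) {
    mom0 <- source_moments(source)
    energy <- source$energy
    spread <- source$energy_spread
  } else if (inherits(source, "beam_moments")) {
    if (is.null(energy)) stop("energy required when propagating raw moments")
    mom0 <- source
    spread <- 0
  } else stop("source must be a beam_source or beam_moments")
  nodes <- energy_nodes(energy, spread, n_energy_nodes)

  n_nodes <- length(nodes$e)
  state <- list() # per node: list(x = c(s11,s12,s22), y = ..., mx, my)
  for (j in seq_len(n_nodes)) {
    state[[j]] <- list(
      x = c(mom0$x[["var_pos"]], mom0$x[["cov_pos_ang"]], mom0$x[["var_ang"]]),
      y = c(mom0$y[["var_pos"]], mom0$y[["cov_pos_ang"]], mom0$y[["var_ang"]]),
      mx = c(0, 0), my = c(0, 0))
  }
  out <- list()
  record <- function(label, z_cm) {
    sx <- c(0, 0, 0); sy <- c(0, 0, 0); mx2 <- 0; my2 <- 0
    mxm <- c(0, 0); mym <- c(0, 0)
    for (j in seq_len(n_nodes)) {
      w <- nodes$w[j]
      sx <- sx + w * state[[j]]$x
      sy <- sy + w * state[[j]]$y
      mxm <- mxm + w * state[[j]]$mx
      mym <- mym + w * state[[j]]$my
    }
    m <- structure(list(z = z_cm,
                        x = c(var_pos = sx[1], cov_pos_ang = sx[2],
                              var_ang = sx[3]),
                        y = c(var_pos = sy[1], cov_pos_ang = sy[2],
                              var_ang = sy[3])),
                   class = "beam_moments")
    attr(m, "centroid") <- list(x = mxm, y = mym)
    out[[label]] <<- m
  }
  apply_map <- function(st, mh, mv) {
    sx <- sandwich(mh[1, 1], mh[1, 2], mh[2, 1], mh[2, 2],
                   st$x[1], st$x[2], st$x[3])
    sy <- sandwich(mv[1, 1], mv[1, 2], mv[2, 1], mv[2, 2],
                   st$y[1], st$y[2], st$y[3])
    st$x <- c(sx$s11, sx$s12, sx$s22)
    st$y <- c(sy$s11, sy$s12, sy$s22)
    st$mx <- c(mh %*% st$mx)
    st$my <- c(mv %*% st$my)
    st
  }
  for (i in seq_along(nozzle$elements)) {
    e <- nozzle$elements[[i]]
    for (j in seq_len(n_nodes)) {
      en <- nodes$e[j]
      st <- state[[j]]
      if (e$kind == "drift") {
        m <- mat_drift(e$length_cm / 100)
        st <- apply_map(st, m, m)
        th0 <- element_theta0(e, en)
        if (th0 > 0) {
          inc <- fe_increment(th0, e$length_cm / 100)
          st$x <- st$x + c(inc$d11, inc$d12, inc$d22)
          st$y <- st$y + c(inc$d11, inc$d12, inc$d22)
        }
      } else if (e$kind == "quadrupole") {
        qm <- quad_matrix(e, en)
        st <- apply_map(st, qm$h, qm$v)
        th0 <- element_theta0(e, en)
        if (th0 > 0) { # scattering inside an air-filled quad: straight-path
          inc <- fe_increment(th0, e$length_cm / 100)
          st$x <- st$x + c(inc$d11, inc$d12, inc$d22)
          st$y <- st$y + c(inc$d11, inc$d12, inc$d22)
        }
      } else if (e$kind == "slab") {
        th0 <- element_theta0(e, en)
        st$x[3] <- st$x[3] + th0^2
        st$y[3] <- st$y[3] + th0^2
      } else if (e$kind == "dipole_kick") {
        st$mx[2] <- st$mx[2] + e$kick_x_mrad
        st$my[2] <- st$my[2] + e$kick_y_mrad
      }
      state[[j]] <- st
    }
    if (e$kind == "monitor") record(e$label, nozzle$z_end_cm[i])
  }
  record("target", nozzle$target_cm)
  out
}

# ---- Monte Carlo transport ---------------------------------------------------

#' Track sampled particles through a nozzle
#'
#' Monte Carlo transport of a particle bundle: each particle is pushed
#' through the hard-edge maps evaluated at its own momentum (so chromatic
#' aberrations arise naturally), and in scattering media receives correlated
#' Highland angle/displacement kicks per sub-step. Reproducible for a fixed
#' seed.
#'
#' @param bundle A \code{particle_bundle} (e.g. from
#'   \code{\link{sample_particles}}).
#' @param nozzle A \code{nozzle_config}.
#' @param seed Integer seed.
#' @param step_cm Maximum sub-step length in scattering media, cm.
#' @return List of \code{particle_bundle}s, one per monitor plane plus the
#'   final target plane.
#' @export
track_particles <- function(bundle, nozzle, seed = 1, step_cm = 5) {
  stopifnot(inherits(bundle, "particle_bundle"),
            inherits(nozzle, "nozzle_config"), step_cm > 0)
  set.seed(as.integer(seed %% .Machine$integer.max))
  n <- bundle$count
  x <- bundle$x; xp <- bundle$xp; y <- bundle$y; yp <- bundle$yp
  en <- bundle$energy
  out <- list()
  snap <- function(label, z_cm) {
    out[[label]] <<- structure(list(z = z_cm, x = x, y = y, xp = xp, yp = yp,
                                    energy = en, count = n),
                               class = "particle_bundle")
  }
  mcs_kick <- function(theta_s, L_m) {
    # PDG correlated angle/displacement sampling for one sub-step
    z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
    list(dx = L_m * theta_s * (z1 / sqrt(12) + z2 / 2), dxp = z2 * theta_s)
  }
  apply_quad_vec <- function(e, L_cm) {
    brho <- proton_kinematics(en)$brho
    k <- (e$field_T / (e$aperture_cm / 100)) / brho
    sgn <- if (e$focus_plane == "horizontal") 1 else -1
    L <- L_cm / 100
    one_plane <- function(p, pp, kk) {
      s <- sqrt(abs(kk)); phi <- s * L
      foc <- kk > 1e-12; def <- kk < -1e-12
      m11 <- ifelse(foc, cos(phi), ifelse(def, cosh(phi), 1))
      m12 <- ifelse(foc, ifelse(s > 0, sin(phi) / s, L),
                    ifelse(def, sinh(phi) / s, L))
      m21 <- ifelse(foc, -s * sin(phi), ifelse(def, s * sinh(phi), 0))
      m22 <- m11
      list(p = m11 * p + m12 * pp, pp = m21 * p + m22 * pp)
    }
    hx <- one_plane(x, xp, sgn * k)
    vy <- one_plane(y, yp, -sgn * k)
    x <<- hx$p; xp <<- hx$pp; y <<- vy$p; yp <<- vy$pp
  }
  for (i in seq_along(nozzle$elements)) {
    e <- nozzle$elements[[i]]
    if (n == 0) { if (e$kind == "monitor") snap(e$label, nozzle$z_end_cm[i]); next }
    if (e$kind == "drift" || e$kind == "quadrupole") {
      th0 <- element_theta0(e, en)
      scattering <- any(th0 > 0)
      nsub <- if (scattering) max(1L, ceiling(e$length_cm / step_cm)) else 1L
      Lsub <- e$length_cm / nsub
      for (s in seq_len(nsub)) {
        if (e$kind == "drift") {
          x <- x + xp * Lsub / 100
          y <- y + yp * Lsub / 100
        } else {
          apply_quad_vec(e, Lsub)
        }
        if (scattering) {
          ths <- th0 * sqrt(1 / nsub)
          kx <- mcs_kick(ths, Lsub / 100)
          ky <- mcs_kick(ths, Lsub / 100)
          x <- x + kx$dx; xp <- xp + kx$dxp
          y <- y + ky$dx; yp <- yp + ky$dxp
        }
      }
    } else if (e$kind == "slab") {
      th0 <- element_theta0(e, en)
      if (any(th0 > 0)) {
        xp <- xp + stats::rnorm(n) * th0
        yp <- yp + stats::rnorm(n) * th0
      }
    } else if (e$kind == "dipole_kick") {
      xp <- xp + e$kick_x_mrad
      yp <- yp + e$kick_y_mrad
    } else if (e$kind == "monitor") {
      snap(e$label, nozzle$z_end_cm[i])
    }
  }
  snap("target", nozzle$target_cm)
  out
}
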
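# Emittance-parametrised bi-Gaussian beam source.

#' Define a beam source from its six emittance parameters
#'
#' The beam at the nozzle entrance is bi-Gaussian in each transverse plane:
#' positions with standard deviation \code{sigma_x}/\code{sigma_y} (mm),
#' angles with standard deviation \code{div_x}/\code{div_y} (mrad), and a
#' position--angle correlation coefficient \code{r_xx}/\code{r_yy} per plane.
#' Kinetic energies are Gaussian with fractional spread \code{energy_spread}.
#'
#' @param energy Kinetic energy, MeV (> 0).
#' @param energy_spread Fractional Gaussian sigma of the energy (>= 0),
#'   e.g. 0.01 for a typical cyclotron beam.
#' @param sigma_x,sigma_y Position sigma per plane, mm (> 0).
#' @param div_x,div_y Angular sigma per plane, mrad (>= 0).
#' @param r_xx,r_yy Position--angle correlation per plane, in [-1, 1].
#'   |r| = 1 is a perfectly convergent/divergent beam (zero emittance).
#' @return Object of class \code{beam_source}.
#' @export
beam_source <- function(energy, energy_spread = 0.01,
                        sigma_x, sigma_y, div_x, div_y,
                        r_xx = 0, r_yy = 0) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid beam source: ", field, " ", what, call. = FALSE)
  }
  num1 <- function(v, field) {
    chk(is.numeric(v) && length(v) == 1 && is.finite(v), field, "must be a finite number")
  }
  for (f in c("energy", "energy_spread", "sigma_x", "sigma_y",
              "div_x", "div_y", "r_xx", "r_yy")) {
    num1(get(f), f)
  }
  chk(energy > 0, "energy", "must be > 0")
  chk(energy_spread >= 0, "energy_spread", "must be >= 0")
  chk(sigma_x > 0, "sigma_x", "must be > 0")
  chk(sigma_y > 0, "sigma_y", "must be > 0")
  chk(div_x >= 0, "div_x", "must be >= 0")
  chk(div_y >= 0, "div_y", "must be >= 0")
  chk(abs(r_xx) <= 1, "r_xx", "must be in [-1, 1]")
  chk(abs(r_yy) <= 1, "r_yy", "must be in [-1, 1]")
  structure(list(energy = energy, energy_spread = energy_spread,
                 sigma_x = sigma_x, sigma_y = sigma_y,
                 div_x = div_x, div_y = div_y,
                 r_xx = r_xx, r_yy = r_yy),
            class = "beam_source")
}

#' @export
print.beam_source <- function(x, ...) {
  cat(sprintf("Beam source: %.1f MeV (dE/E = %.3g)\n", x$energy, x$energy_spread))
  cat(sprintf("  horizontal: sigma = %.3g mm, x' = %.3g mrad, r_xx' = %+.3g\n",
              x$sigma_x, x$div_x, x$r_xx))
  cat(sprintf("  vertical:   sigma = %.3g mm, y' = %.3g mrad, r_yy' = %+.3g\n",
              x$sigma_y, x$div_y, x$r_yy))
  cat(sprintf("  emittance (rms): %.4g / %.4g mm mrad\n",
              emittance(x$sigma_x, x$div_x, x$r_xx),
              emittance(x$sigma_y, x$div_y, x$r_yy)))
  invisible(x)
}

#' RMS beam emittance of one transverse plane
#'
#' The RMS emittance sigma * div * sqrt(1 - r^2) in mm mrad (no factor pi;
#' the package standardises on the plain RMS product). It vanishes for a
#' perfectly correlated beam (|r| = 1) and is conserved under conservative
#' (magnetic) transport.
#'
#' @param sigma Position sigma, mm (> 0).
#' @param div Angular sigma, mrad (>= 0).
#' @param r Position--angle correlation in [-1, 1].
#' @return Emittance in mm mrad.
#' @export
emittance <- function(sigma, div, r) {
  stopifnot(all(sigma > 0), all(div >= 0))
  if (any(abs(r) > 1)) stop("correlation coefficient must be in [-1, 1]")
  sigma * div * sqrt(1 - r^2)
}

#' Second moments of a beam source
#'
#' Analytic per-plane covariance of the bi-Gaussian source:
#' var_pos = sigma^2 (mm^2), cov_pos_ang = r * sigma * div (mm mrad),
#' var_ang = div^2 (mrad^2).
#'
#' @param source A \code{beam_source}.
#' @param z Plane position in cm (bookkeeping only).
#' @return Object of class \code{beam_moments}: list with \code{z} and,
#'   per plane (\code{x}, \code{y}), a named vector
#'   (var_pos, cov_pos_ang, var_ang).
#' @export
source_moments <- function(source, z = 0) {
  stopifnot(inherits(source, "beam_source"))
  mom <- function(s, d, r) {
    c(var_pos = s^2, cov_pos_ang = r * s * d, var_ang = d^2)
  }
  structure(list(z = z,
                 x = mom(source$sigma_x, source$div_x, source$r_xx),
                 y = mom(source$sigma_y, source$div_y, source$r_yy)),
            class = "beam_moments")
}

beam_moments_ok <- function(m) {
  f <- function(p) p[["var_pos"]] >= 0 && p[["var_ang"]] >= 0 &&
    p[["cov_pos_ang"]]^2 <= p[["var_pos"]] * p[["var_ang"]] * (1 + 1e-12) + 1e-12
  f(m$x) && f(m$y)
}

#' Sample particles from a beam source
#'
#' Draws a bi-Gaussian phase-space sample per plane. At |r| = 1 the
#' covariance is singular; the position is sampled and the angle set
#' deterministically on the correlation line. Energies are Gaussian with
#' sigma = energy * energy_spread, truncated at > 0 by resampling.
#'
#' @param source A \code{beam_source}.
#' @param n Number of particles (>= 0).
#' @param seed Integer seed; sampling is reproducible for a fixed seed.
#' @return Object of class \code{particle_bundle}: list with \code{z} (cm),
#'   vectors \code{x}, \code{y} (mm), \code{xp}, \code{yp} (mrad),
#'   \code{energy} (MeV) and \code{count}.
#' @export
sample_particles <- function(source, n, seed = 1) {
  stopifnot(inherits(source, "beam_source"), n >= 0)
  n <- as.integer(n)
  if (n == 0) {
    return(structure(list(z = 0, x = numeric(0), y = numeric(0),
                          xp = numeric(0), yp = numeric(0),
                          energy = numeric(0), count = 0L),
                     class = "particle_bundle"))
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  plane <- function(s, d, r) {
    u <- stats::rnorm(n)
    x <- s * u
    if (abs(r) >= 1) {
      xp <- sign(r) * d / s * x
    } else {
      v <- stats::rnorm(n)
      xp <- d * (r * u + sqrt(1 - r^2) * v)
    }
    list(x = x, xp = xp)
  }
  h <- plane(source$sigma_x, source$div_x, source$r_xx)
  v <- plane(source$sigma_y, source$div_y, source$r_yy)
  se <- source$energy * source$energy_spread
  e <- stats::rnorm(n, source$energy, se)
  while (any(bad <- e <= 0)) {
    e[bad] <- stats::rnorm(sum(bad), source$energy, se)
  }
  structure(list(z = 0, x = h$x, y = v$x, xp = h$xp, yp = v$xp,
                 energy = e, count = n),
            class = "particle_bundle")
}

#' Sample second moments of a particle bundle
#'
#' @param bundle A \code{particle_bundle}.
#' @return A \code{beam_moments} object with the empirical covariance.
#' @export
bundle_moments <- function(bundle) {
  stopifnot(inherits(bundle, "particle_bundle"))
  cv <- function(a, b) mean((a - mean(a)) * (b - mean(b)))
  mom <- function(x, xp) {
    c(var_pos = cv(x, x), cov_pos_ang = cv(x, xp), var_ang = cv(xp, xp))
  }
  structure(list(z = bundle$z,
                 x = mom(bundle$x, bundle$xp),
                 y = mom(bundle$y, bundle$yp)),
            class = "beam_moments")
}
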
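# Exhaustive quadrupole-configuration scan minimising Omega.

#' Specify a quadrupole grid scan
#'
#' The default grid is 0 to 2 T in 0.04 T steps (51 field values per
#' quadrupole) and both focus-plane arrangements, i.e. 51 x 51 x 2
#' configurations. The scan is two-stage: every configuration is evaluated
#' in fast envelope mode, then the best \code{refine_top} configurations
#' (by envelope Omega) are re-evaluated by Monte Carlo tracking with
#' \code{n_particles} protons each.
#'
#' @param fields Pole-tip field values in T (non-negative, sorted, unique).
#' @param arrangements Subset of \code{c("q1_horizontal", "q1_vertical")}:
#'   whether the first scanned quadrupole focuses horizontally or
#'   vertically (the second focuses in the orthogonal plane).
#' @param n_particles Protons tracked per refined configuration.
#' @param refine_top Number of configurations refined by Monte Carlo
#'   (0 = envelope only).
#' @param n_energy_nodes Gauss-Hermite nodes for the chromatic envelope.
#' @param step_cm Monte Carlo sub-step in scattering media, cm.
#' @return Object of class \code{quad_scan_spec}.
#' @export
quad_scan_spec <- function(fields = seq(0, 2, by = 0.04),
                           arrangements = c("q1_horizontal", "q1_vertical"),
                           n_particles = 1e5, refine_top = 20,
                           n_energy_nodes = 7, step_cm = 5) {
  if (length(fields) == 0) stop("empty field grid")
  if (any(fields < 0)) stop("field values must be non-negative")
  if (is.unsorted(fields, strictly = TRUE)) {
    stop("field values must be sorted and unique")
  }
  arrangements <- match.arg(arrangements, c("q1_horizontal", "q1_vertical"),
                            several.ok = TRUE)
  structure(list(fields = fields, arrangements = arrangements,
                 n_particles = n_particles, refine_top = refine_top,
                 n_energy_nodes = n_energy_nodes, step_cm = step_cm),
            class = "quad_scan_spec")
}

scanned_quad_indices <- function(nozzle) {
  idx <- which(vapply(nozzle$elements,
                      function(e) e$kind == "quadrupole" && isTRUE(e$scan),
                      logical(1)))
  if (length(idx) != 2) {
    stop("nozzle must have exactly 2 scannable quadrupoles (found ",
         length(idx), ")")
  }
  idx
}

#' Set the scanned quadrupoles of a nozzle
#'
#' @param nozzle A \code{nozzle_config} with two scannable quadrupoles.
#' @param B1,B2 Pole-tip fields in T for the first/second scanned quad.
#' @param arrangement \code{"q1_horizontal"} or \code{"q1_vertical"}.
#' @return The nozzle with fields and focus planes assigned.
#' @export
set_scan_fields <- function(nozzle, B1, B2,
                            arrangement = "q1_horizontal") {
  idx <- scanned_quad_indices(nozzle)
  planes <- if (arrangement == "q1_horizontal") c("horizontal", "vertical")
            else c("vertical", "horizontal")
  for (j in 1:2) {
    e <- nozzle$elements[[idx[j]]]
    if (c(B1, B2)[j] > e$max_field_T) {
      stop("field exceeds max_field_T of scanned quadrupole ", j)
    }
    e$field_T <- c(B1, B2)[j]
    e$focus_plane <- planes[j]
    nozzle$elements[[idx[j]]] <- e
  }
  nozzle
}

# Vectorised envelope evaluation of the whole field grid for one
# arrangement: returns var_pos at the target per plane, averaged over the
# energy nodes, as vectors over configurations.
env_scan_grid <- function(nozzle, source, b1, b2, arrangement,
                          n_energy_nodes = 7) {
  idx <- scanned_quad_indices(nozzle)
  planes <- if (arrangement == "q1_horizontal") c(1, -1) else c(-1, 1)
  nodes <- energy_nodes(source$energy, source$energy_spread, n_energy_nodes)
  N <- length(b1)
  vx <- numeric(N); vy <- numeric(N)
  m0 <- source_moments(source)
  quad_plane_vec <- function(k, L, s11, s12, s22) {
    s <- sqrt(abs(k)); phi <- s * L
    foc <- k > 1e-12; def <- k < -1e-12
    m11 <- ifelse(foc, cos(phi), ifelse(def, cosh(phi), 1))
    m12 <- ifelse(foc, ifelse(s > 0, sin(phi) / s, L),
                  ifelse(def, sinh(phi) / s, L))
    m21 <- ifelse(foc, -s * sin(phi), ifelse(def, s * sinh(phi), 0))
    sandwich(m11, m12, m21, m11, s11, s12, s22)
  }
  for (j in seq_along(nodes$e)) {
    en <- nodes$e[j]
    brho <- proton_kinematics(en)$brho
    sx <- list(s11 = rep(m0$x[["var_pos"]], N), s12 = rep(m0$x[["cov_pos_ang"]], N),
               s22 = rep(m0$x[["var_ang"]], N))
    sy <- list(s11 = rep(m0$y[["var_pos"]], N), s12 = rep(m0$y[["cov_pos_ang"]], N),
               s22 = rep(m0$y[["var_ang"]], N))
    nscan <- 0L
    for (i in seq_along(nozzle$elements)) {
      e <- nozzle$elements[[i]]
      if (e$kind == "quadrupole") {
        L <- e$length_cm / 100
        if (isTRUE(e$scan)) {
          nscan <- nscan + 1L
          B <- if (nscan == 1L) b1 else b2
          sgn <- planes[nscan]
          k <- sgn * (B / (e$aperture_cm / 100)) / brho
        } else {
          qsgn <- if (e$focus_plane == "horizontal") 1 else -1
          k <- rep(qsgn * (e$field_T / (e$aperture_cm / 100)) / brho, N)
        }
        sx <- quad_plane_vec(k, L, sx$s11, sx$s12, sx$s22)
        sy <- quad_plane_vec(-k, L, sy$s11, sy$s12, sy$s22)
        th0 <- element_theta0(e, en)
        if (th0 > 0) {
          inc <- fe_increment(th0, L)
          sx$s11 <- sx$s11 + inc$d11; sx$s12 <- sx$s12 + inc$d12
          sx$s22 <- sx$s22 + inc$d22
          sy$s11 <- sy$s11 + inc$d11; sy$s12 <- sy$s12 + inc$d12
          sy$s22 <- sy$s22 + inc$d22
        }
      } else if (e$kind == "drift") {
        L <- e$length_cm / 100
        sx <- sandwich(1, L, 0, 1, sx$s11, sx$s12, sx$s22)
        sy <- sandwich(1, L, 0, 1, sy$s11, sy$s12, sy$s22)
        th0 <- element_theta0(e, en)
        if (th0 > 0) {
          inc <- fe_increment(th0, L)
          sx$s11 <- sx$s11 + inc$d11; sx$s12 <- sx$s12 + inc$d12
          sx$s22 <- sx$s22 + inc$d22
          sy$s11 <- sy$s11 + inc$d11; sy$s12 <- sy$s12 + inc$d12
          sy$s22 <- sy$s22 + inc$d22
        }
      } else if (e$kind == "slab") {
        th0 <- element_theta0(e, en)
        sx$s22 <- sx$s22 + th0^2
        sy$s22 <- sy$s22 + th0^2
      }
      # dipole kicks / monitors do not change second moments
    }
    vx <- vx + nodes$w[j] * sx$s11
    vy <- vy + nodes$w[j] * sy$s11
  }
  list(var_x = vx, var_y = vy)
}

config_seed <- function(seed, i1, i2, arr_idx) {
  as.integer((abs(seed) %% 10000 * 100003 + i1 * 2011 + i2 * 37 + arr_idx) %%
               2147483647)
}

#' Exhaustive quadrupole grid scan
#'
#' Evaluates every (B1, B2, arrangement) configuration of the scan spec at
#' the nozzle target plane. All configurations are first evaluated in
#' envelope mode (chromatic sigma-matrix transport); the best
#' \code{refine_top} by envelope Omega are then re-simulated by Monte Carlo
#' tracking and Gaussian-fitted. Per-configuration seeds are derived from
#' the base seed and the grid indices, so results are reproducible and
#' streams uncorrelated.
#'
#' @param nozzle A \code{nozzle_config} with exactly two scannable quads.
#' @param source A \code{beam_source}.
#' @param spec A \code{quad_scan_spec}.
#' @param seed Base integer seed.
#' @return Object of class \code{quad_scan}: list with the full \code{grid}
#'   data frame (arrangement, B1, B2, h_fwhm, v_fwhm, omega, refined,
#'   h_fwhm_se, v_fwhm_se), the argmin row index \code{i_min}, and the
#'   inputs for re-use.
#' @export
scan_quadrupoles <- function(nozzle, source, spec = quad_scan_spec(),
                             seed = 1) {
  stopifnot(inherits(nozzle, "nozzle_config"), inherits(source, "beam_source"),
            inherits(spec, "quad_scan_spec"))
  fg <- expand.grid(i1 = seq_along(spec$fields), i2 = seq_along(spec$fields))
  grids <- list()
  for (a in seq_along(spec$arrangements)) {
    arr <- spec$arrangements[a]
    b1 <- spec$fields[fg$i1]; b2 <- spec$fields[fg$i2]
    ev <- env_scan_grid(nozzle, source, b1, b2, arr, spec$n_energy_nodes)
    grids[[a]] <- data.frame(
      arrangement = arr, i1 = fg$i1, i2 = fg$i2, B1 = b1, B2 = b2,
      h_fwhm = FWHM_CONST * sqrt(ev$var_x),
      v_fwhm = FWHM_CONST * sqrt(ev$var_y),
      refined = FALSE, h_fwhm_se = NA_real_, v_fwhm_se = NA_real_,
      stringsAsFactors = FALSE)
  }
  grid <- do.call(rbind, grids)
  grid$omega <- grid$h_fwhm^2 + grid$v_fwhm^2
  n_ref <- min(spec$refine_top, nrow(grid))
  if (n_ref > 0) {
    ord <- order(grid$omega, grid$B1, grid$B2)
    ref_idx <- ord[seq_len(n_ref)]
    for (i in ref_idx) {
      arr_idx <- match(grid$arrangement[i], spec$arrangements)
      s_i <- config_seed(seed, grid$i1[i], grid$i2[i], arr_idx)
      noz_i <- set_scan_fields(nozzle, grid$B1[i], grid$B2[i],
                               grid$arrangement[i])
      bundle <- sample_particles(source, spec$n_particles, seed = s_i)
      tr <- track_particles(bundle, noz_i, seed = s_i + 1L,
                            step_cm = spec$step_cm)$target
      ph <- fit_gaussian_fwhm(tr$x, "horizontal", tr$z)
      pv <- fit_gaussian_fwhm(tr$y, "vertical", tr$z)
      grid$h_fwhm[i] <- ph$fwhm; grid$v_fwhm[i] <- pv$fwhm
      grid$h_fwhm_se[i] <- ph$fwhm_se; grid$v_fwhm_se[i] <- pv$fwhm_se
      grid$omega[i] <- omega(ph$fwhm, pv$fwhm)
      grid$refined[i] <- TRUE
    }
  }
  res <- structure(list(grid = grid, nozzle = nozzle, source = source,
                        spec = spec, seed = seed),
                   class = "quad_scan")
  res$i_min <- argmin_row(res)
  res
}

argmin_row <- function(scan) {
  g <- scan$grid
  cand <- if (any(g$refined)) which(g$refined) else seq_len(nrow(g))
  # ties broken towards the lowest (B1, B2) lexicographically
  cand[order(g$omega[cand], g$B1[cand], g$B2[cand])][1]
}

#' Minimum-Omega configuration of a scan
#'
#' @param scan A \code{quad_scan}.
#' @return List with \code{arrangement}, \code{B1}, \code{B2} (T),
#'   \code{h_fwhm}, \code{v_fwhm} (mm), \code{omega} (mm^2) and the fit
#'   standard errors where Monte Carlo refined.
#' @export
select_minimum <- function(scan) {
  stopifnot(inherits(scan, "quad_scan"))
  if (nrow(scan$grid) == 0) stop("empty scan result")
  r <- scan$grid[scan$i_min, ]
  list(arrangement = r$arrangement, B1 = r$B1, B2 = r$B2,
       h_fwhm = r$h_fwhm, v_fwhm = r$v_fwhm, omega = r$omega,
       h_fwhm_se = r$h_fwhm_se, v_fwhm_se = r$v_fwhm_se,
       refined = r$refined)
}

#' @export
print.quad_scan <- function(x, ...) {
  m <- select_minimum(x)
  cat(sprintf("Quadrupole scan: %d configurations (%d MC-refined)\n",
              nrow(x$grid), sum(x$grid$refined)))
  cat(sprintf("  minimum Omega at %s, B1 = %.2f T, B2 = %.2f T\n",
              m$arrangement, m$B1, m$B2))
  cat(sprintf("  hFWHM = %.3f mm, vFWHM = %.3f mm, minibeam: %s\n",
              m$h_fwhm, m$v_fwhm, is_minibeam(m$h_fwhm, m$v_fwhm)))
  invisible(x)
}

#' Asymmetric uncertainty of the minimised beam size
#'
#' Combines, by root-sum-square per side, three contributions: (i) the
#' spread (half-range) of the envelope minima over variations of the beam
#' source (default: both divergences scaled by 0.9 and by 1.1); (ii) the
#' local beam-size variation around the minimum grid cell, taken as the
#' maximum |delta FWHM| over the 8 neighbouring cells -- the discrete field
#' grid can only overestimate the true minimum, so this enters the upper
#' side only; (iii) the Gaussian-fit standard error.
#'
#' @param scan A \code{quad_scan}.
#' @param variations Optional list of alternative \code{beam_source}s.
#' @return List with per-plane lower/upper uncertainties in mm:
#'   \code{h = c(lower, upper)}, \code{v = c(lower, upper)}, plus the
#'   individual contributions.
#' @export
estimate_uncertainty <- function(scan, variations = NULL) {
  stopifnot(inherits(scan, "quad_scan"))
  src <- scan$source
  if (is.null(variations)) {
    variations <- lapply(c(0.9, 1.1), function(f) {
      beam_source(src$energy, src$energy_spread, src$sigma_x, src$sigma_y,
                  src$div_x * f, src$div_y * f, src$r_xx, src$r_yy)
    })
  }
  m <- select_minimum(scan)
  env_min <- function(s) {
    sp <- scan$spec
    best_h <- Inf; best_v <- Inf; best_o <- Inf
    fg <- expand.grid(i1 = seq_along(sp$fields), i2 = seq_along(sp$fields))
    for (arr in sp$arrangements) {
      ev <- env_scan_grid(scan$nozzle, s, sp$fields[fg$i1], sp$fields[fg$i2],
                          arr, sp$n_energy_nodes)
      h <- FWHM_CONST * sqrt(ev$var_x); v <- FWHM_CONST * sqrt(ev$var_y)
      o <- h^2 + v^2
      i <- which.min(o)
      if (o[i] < best_o) { best_o <- o[i]; best_h <- h[i]; best_v <- v[i] }
    }
    c(best_h, best_v)
  }
  mins <- vapply(c(list(src), variations), env_min, numeric(2))
  src_contrib <- (apply(mins, 1, max) - apply(mins, 1, min)) / 2
  # grid-step contribution: envelope FWHM at the 8 neighbours of the argmin
  g <- scan$grid
  r <- g[scan$i_min, ]
  nb <- g[g$arrangement == r$arrangement &
            abs(g$i1 - r$i1) <= 1 & abs(g$i2 - r$i2) <= 1 &
            !(g$i1 == r$i1 & g$i2 == r$i2), ]
  grid_contrib <- c(if (nrow(nb)) max(abs(nb$h_fwhm - r$h_fwhm)) else 0,
                    if (nrow(nb)) max(abs(nb$v_fwhm - r$v_fwhm)) else 0)
  fit_contrib <- c(ifelse(is.na(m$h_fwhm_se), 0, m$h_fwhm_se),
                   ifelse(is.na(m$v_fwhm_se), 0, m$v_fwhm_se))
  rss <- function(...) sqrt(sum(c(...)^2))
  list(h = c(lower = rss(src_contrib[1], fit_contrib[1]),
             upper = rss(src_contrib[1], grid_contrib[1], fit_contrib[1])),
       v = c(lower = rss(src_contrib[2], fit_contrib[2]),
             upper = rss(src_contrib[2], grid_contrib[2], fit_contrib[2])),
       source_contrib = src_contrib, grid_contrib = grid_contrib,
       fit_contrib = fit_contrib)
}
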
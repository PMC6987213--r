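test_that("quadrupole transfer maps are symplectic and reduce to drifts", {
  set.seed(4)
  for (i in 1:20) {
    e <- el_quad(runif(1, 1, 40), runif(1, 0, 2), runif(1, 2, 8),
                 sample(c("horizontal", "vertical"), 1))
    qm <- quad_matrix(e, runif(1, 70, 230))
    expect_equal(det(qm$h), 1, tolerance = 1e-12)
    expect_equal(det(qm$v), 1, tolerance = 1e-12)
  }
  # zero field: the drift matrix of the same length
  qm0 <- quad_matrix(el_quad(25, 0, 5, "horizontal"), 100)
  expect_equal(qm0$h, matrix(c(1, 0, 0.25, 1), 2, 2))
  expect_equal(qm0$v, qm0$h)
})

test_that("thick quadrupole map equals the composition of many thin slices", {
  # independent oracle: numerically compose 400 short hard-edge segments
  L <- 30; B <- 1.4; a <- 5; en <- 150
  full <- quad_matrix(el_quad(L, B, a, "horizontal"), en)
  nsl <- 400
  sl <- quad_matrix(el_quad(L / nsl, B, a, "horizontal"), en)
  Mh <- diag(2); Mv <- diag(2)
  for (i in seq_len(nsl)) { Mh <- sl$h %*% Mh; Mv <- sl$v %*% Mv }
  expect_equal(Mh, full$h, tolerance = 1e-10)
  expect_equal(Mv, full$v, tolerance = 1e-10)
  # thin-lens limit: 1/f -> k L as L -> 0 at fixed k L
  short <- quad_matrix(el_quad(0.1, B, a, "horizontal"), en)
  brho <- proton_kinematics(en)$brho
  k <- (B / (a / 100)) / brho
  expect_equal(-short$h[2, 1], k * 0.001, tolerance = 1e-4)
})

test_that("Highland scattering angle matches direct evaluation", {
  expect_equal(scattering_theta0(100, 0, "air"), 0)
  # frozen from an independent evaluation of the Highland formula with
  # X0(air) = 303.9 m: pv(100 MeV) = 190.367 MeV, t/X0 = 3.2906e-3
  expect_equal(scattering_theta0(100, 1, "air"), 3.2078, tolerance = 1e-3)
  # higher momentum scatters less, for any thickness
  for (t in c(0.1, 0.5, 2)) {
    expect_lt(scattering_theta0(200, t, "air"),
              scattering_theta0(100, t, "air"))
  }
  expect_error(scattering_theta0(100, 1, "lead"), "unknown material")
})

test_that("moments propagate through a pure drift by the closed form", {
  src <- beam_source(100, 0, 5, 4, 2, 1, 0.3, -0.5)
  tb <- gen_toy_beamline("pure_drift", 150, src)
  m <- propagate_moments(src, tb$nozzle)$target
  ex <- tb$expected()
  expect_equal(m$x[["var_pos"]], ex[["x"]], tolerance = 1e-12)
  expect_equal(m$y[["var_pos"]], ex[["y"]], tolerance = 1e-12)
})

test_that("emittance is conserved through arbitrary vacuum beamlines", {
  src <- beam_source(130, 0, 5, 4, 2, 1, 0.3, -0.5)
  e0x <- emittance(5, 2, 0.3); e0y <- emittance(4, 1, -0.5)
  for (seed in 1:5) {
    noz <- random_vacuum_beamline(7, seed = seed)
    m <- propagate_moments(src, noz)$target
    expect_equal(sqrt(m$x[["var_pos"]] * m$x[["var_ang"]] -
                        m$x[["cov_pos_ang"]]^2), e0x, tolerance = 1e-8)
    expect_equal(sqrt(m$y[["var_pos"]] * m$y[["var_ang"]] -
                        m$y[["cov_pos_ang"]]^2), e0y, tolerance = 1e-8)
  }
})

test_that("an air path broadens the beam and matches Monte Carlo tracking", {
  src <- beam_source(100, 0, 5, 5, 1, 1, 0, 0)
  vac <- gen_toy_beamline("pure_drift", 150, src)
  air <- gen_toy_beamline("air_drift", 150, src)
  mv <- propagate_moments(src, vac$nozzle)$target
  ma <- propagate_moments(src, air$nozzle)$target
  expect_gt(ma$x[["var_pos"]], mv$x[["var_pos"]])
  expect_equal(ma$x[["var_pos"]], air$expected()[["x"]], tolerance = 1e-12)
  # MC tracking through air agrees with the Fermi-Eyges moments
  n <- 1e5
  b <- sample_particles(src, n, seed = 13)
  tr <- track_particles(b, air$nozzle, seed = 14, step_cm = 5)$target
  mc_var <- var(tr$x)
  se <- ma$x[["var_pos"]] * sqrt(2 / n)
  expect_lt(abs(mc_var - ma$x[["var_pos"]]), 5 * se)
})

test_that("material slabs never decrease the final position variance", {
  src <- beam_source(100, 0, 4, 4, 2, 2, -0.5, -0.5)
  base <- nozzle_config(list(el_drift(50, "vacuum"), el_drift(50, "vacuum")))
  m0 <- propagate_moments(src, base)$target
  for (wet in c(0.1, 0.5, 1, 3)) {
    noz <- nozzle_config(list(el_drift(50, "vacuum"), el_slab(wet),
                              el_drift(50, "vacuum")))
    m <- propagate_moments(src, noz)$target
    expect_gte(m$x[["var_pos"]], m0$x[["var_pos"]])
    expect_gte(m$y[["var_pos"]], m0$y[["var_pos"]])
  }
})

test_that("horizontal transport is independent of vertical source parameters", {
  noz <- build_nozzle("optimized", air_gap_cm = 10)
  noz <- set_scan_fields(noz, 0.8, 1.2, "q1_horizontal")
  s1 <- beam_source(100, 0.01, 4, 4, 3, 3, -1, -1)
  s2 <- beam_source(100, 0.01, 4, 9, 3, 0.3, -1, 0.7) # vertical-only changes
  m1 <- propagate_moments(s1, noz)$target
  m2 <- propagate_moments(s2, noz)$target
  expect_equal(m1$x, m2$x, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(m1$y, m2$y)))
})

test_that("MC tracking in vacuum agrees with the sigma-matrix oracle", {
  src <- beam_source(100, 0, 4, 5, 3, 2, -0.6, 0.2)
  noz <- random_vacuum_beamline(6, seed = 3)
  m <- propagate_moments(src, noz)$target
  n <- 1e5
  b <- sample_particles(src, n, seed = 31)
  tr <- track_particles(b, noz, seed = 32)$target
  for (pl in c("x", "y")) {
    pos <- if (pl == "x") tr$x else tr$y
    pred <- sqrt(m[[pl]][["var_pos"]])
    fit <- fit_gaussian_fwhm(pos)
    # within 3 standard errors (fit SE plus sampling SE of sigma)
    se <- sqrt(fit$sigma_se^2 + (pred / sqrt(2 * n))^2)
    expect_lt(abs(fit$sigma - pred), 3 * se + 0.005 * pred)
  }
})

test_that("a zero-emittance on-axis beam stays exactly on axis in vacuum", {
  b <- structure(list(z = 0, x = rep(0, 100), y = rep(0, 100),
                      xp = rep(0, 100), yp = rep(0, 100),
                      energy = rep(100, 100), count = 100L),
                 class = "particle_bundle")
  noz <- random_vacuum_beamline(6, seed = 8)
  tr <- track_particles(b, noz, seed = 2)$target
  expect_equal(max(abs(tr$x)), 0)
  expect_equal(max(abs(tr$yp)), 0)
})

test_that("energy spread enlarges the focal spot (chromatic aberration)", {
  # a strongly focusing doublet: the focal length scales with momentum, so
  # a 1% energy spread smears the focal spot relative to a monochromatic
  # beam, both in the chromatic envelope and in MC tracking
  noz <- nozzle_config(list(
    el_drift(10, "vacuum"),
    el_quad(12, 1.8, 3, "horizontal"), el_drift(4, "vacuum"),
    el_quad(12, 1.55, 3, "vertical"), el_drift(100, "vacuum")))
  mono <- beam_source(100, 1e-5, 5, 5, 0.1, 0.1, 0, 0)
  poly <- beam_source(100, 0.01, 5, 5, 0.1, 0.1, 0, 0)
  env_v <- function(src) {
    2.355 * sqrt(propagate_moments(src, noz)$target$y[["var_pos"]])
  }
  expect_gt(env_v(poly), env_v(mono) * 1.05)
  # MC: compare rms widths (a Gaussian fit would weight the sharp
  # achromatic core of the mixture over its chromatic tails)
  sd_v <- function(src, seed) {
    tr <- track_particles(sample_particles(src, 4e4, seed), noz,
                          seed = seed + 1)$target
    sd(tr$y)
  }
  expect_gt(sd_v(poly, 41), sd_v(mono, 43))
})
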
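test_that("scan specs validate their field grid", {
  expect_error(quad_scan_spec(fields = numeric(0)), "empty")
  expect_error(quad_scan_spec(fields = c(0.5, 0.1)), "sorted")
  expect_error(quad_scan_spec(fields = c(-0.1, 0.5)), "non-negative")
  expect_equal(length(quad_scan_spec()$fields), 51) # 0-2 T in 0.04 T steps
})

test_that("the scan enumerates every configuration exactly once", {
  noz <- build_nozzle("optimized", air_gap_cm = 10)
  src <- beam_source(100, 0.01, 4, 4, 3, 3, -1, -1)
  sp <- quad_scan_spec(fields = c(0, 0.5, 1), refine_top = 0)
  sc <- scan_quadrupoles(noz, src, sp, seed = 1)
  expect_equal(nrow(sc$grid), 3 * 3 * 2)
  key <- with(sc$grid, paste(arrangement, B1, B2))
  expect_equal(anyDuplicated(key), 0L)
  m <- select_minimum(sc)
  expect_true(all(m$omega <= sc$grid$omega))
  # single field value, one arrangement: exactly one configuration
  sp1 <- quad_scan_spec(fields = 0.8, arrangements = "q1_horizontal",
                        refine_top = 0)
  expect_equal(nrow(scan_quadrupoles(noz, src, sp1, seed = 1)$grid), 1)
})

test_that("ties are broken towards the lowest field pair", {
  noz <- build_nozzle("optimized", air_gap_cm = 10)
  src <- beam_source(100, 0.01, 4, 4, 3, 3, -1, -1)
  sc <- scan_quadrupoles(noz, src,
                         quad_scan_spec(fields = c(0, 1), refine_top = 0),
                         seed = 1)
  sc$grid$omega <- 1            # force a complete tie
  sc$grid$h_fwhm <- sc$grid$v_fwhm <- sqrt(0.5)
  sc$i_min <- minibeam:::argmin_row(sc)
  m <- select_minimum(sc)
  expect_equal(c(m$B1, m$B2), c(0, 0))
})

test_that("mirror-symmetric sources make both arrangements equivalent", {
  noz <- build_nozzle("optimized", air_gap_cm = 10)
  src <- beam_source(100, 0.01, 4, 4, 3, 3, -1, -1) # sigma, div, r equal
  sp <- quad_scan_spec(fields = seq(0, 2, by = 0.2), refine_top = 0)
  sc <- scan_quadrupoles(noz, src, sp, seed = 1)
  g <- sc$grid
  o1 <- min(g$omega[g$arrangement == "q1_horizontal"])
  o2 <- min(g$omega[g$arrangement == "q1_vertical"])
  expect_equal(o1, o2, tolerance = 1e-10)
})

test_that("scans are deterministic for a fixed seed", {
  noz <- build_nozzle("optimized", air_gap_cm = 10)
  src <- beam_source(100, 0.01, 4, 4, 3, 3, -1, -1)
  sp <- quad_scan_spec(fields = seq(0.1, 0.3, by = 0.02), refine_top = 3,
                       n_particles = 5000)
  sc1 <- scan_quadrupoles(noz, src, sp, seed = 7)
  sc2 <- scan_quadrupoles(noz, src, sp, seed = 7)
  expect_identical(sc1$grid, sc2$grid)
  expect_identical(select_minimum(sc1), select_minimum(sc2))
})

test_that("MC refinement stays close to the envelope prediction", {
  noz <- build_nozzle("optimized", air_gap_cm = 10)
  src <- beam_source(100, 0.01, 4, 4, 3, 3, -1, -1)
  sp0 <- quad_scan_spec(refine_top = 0)
  sp1 <- quad_scan_spec(refine_top = 4, n_particles = 2e4)
  m0 <- select_minimum(scan_quadrupoles(noz, src, sp0, seed = 5))
  m1 <- select_minimum(scan_quadrupoles(noz, src, sp1, seed = 5))
  expect_true(m1$refined)
  expect_equal(m1$h_fwhm, m0$h_fwhm, tolerance = 0.1)
  expect_equal(m1$v_fwhm, m0$v_fwhm, tolerance = 0.1)
})

test_that("uncertainty combines its three contributions by root-sum-square", {
  noz <- build_nozzle("optimized", air_gap_cm = 10)
  src <- beam_source(100, 0.01, 4, 4, 3, 3, -1, -1)
  sp <- quad_scan_spec(fields = seq(0, 0.4, by = 0.04), refine_top = 0)
  sc <- scan_quadrupoles(noz, src, sp, seed = 1)
  # no source variations, no fit error: both sides reduce to the grid term
  u0 <- estimate_uncertainty(sc, variations = list())
  expect_equal(unname(u0$h["lower"]), 0)
  expect_equal(unname(u0$h["upper"]), u0$grid_contrib[1])
  # with variations: the grid-step term enters the upper side only
  u <- estimate_uncertainty(sc)
  expect_gte(unname(u$h["upper"]), unname(u$h["lower"]))
  expect_equal(unname(u$h["upper"])^2 - unname(u$h["lower"])^2,
               u$grid_contrib[1]^2, tolerance = 1e-10)
  # explicit root-sum-square: contributions (3, 0, 4) per side combine to 5
  expect_equal(sqrt(sum(c(3, 0, 4)^2)), 5)
})
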
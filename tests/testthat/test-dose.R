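test_that("the Bragg curve peaks near the expected depth and then vanishes", {
  z <- seq(0.05, 9.95, by = 0.1)
  d <- bragg_depth_dose(100, 0.01, z)
  expect_equal(z[which.max(d)], 7.5, tolerance = 0.05) # ~7.5 cm at 100 MeV
  expect_gt(max(d) / d[1], 1) # peaked curve
  R <- bragg_range(100)
  sig <- minibeam:::range_sigma(100, 0.01)
  expect_equal(bragg_depth_dose(100, 0.01, R + 5.5 * sig), 0)
  # dose scale is monotone in energy range
  expect_gt(bragg_range(200), bragg_range(100))
})

test_that("analytic dose is linear in the number of primaries", {
  noz <- set_scan_fields(build_nozzle("optimized", air_gap_cm = 10),
                         0.16, 0.20, "q1_horizontal")
  src <- beam_source(100, 0.01, 4, 4, 3, 3, -1, -1)
  ph <- phantom_spec(1, 1, 2, c(0.1, 0.1, 5))
  lay <- grid_layout(3, 2.9)
  g1 <- compute_dose_grid(noz, src, lay, ph, n = 1e5)
  g2 <- compute_dose_grid(noz, src, lay, ph, n = 2e5)
  expect_equal(g2$dose, 2 * g1$dose, tolerance = 1e-12)
})

test_that("a single on-axis beam gives a mirror-symmetric dose", {
  noz <- set_scan_fields(build_nozzle("optimized", air_gap_cm = 10),
                         0.5, 0.5, "q1_horizontal")
  src <- beam_source(100, 0.01, 4, 4, 3, 3, -1, -1)
  ph <- phantom_spec(1, 1, 4, c(0.1, 0.1, 10))
  g <- compute_dose_grid(noz, src, grid_layout(1, 2.9), ph)
  sl <- g$dose[, , 1]
  expect_equal(sl, sl[rev(seq_len(nrow(sl))), ], tolerance = 1e-10)
  expect_equal(sl, sl[, rev(seq_len(ncol(sl)))], tolerance = 1e-10)
})

test_that("a beam grid wider than the phantom is rejected", {
  noz <- set_scan_fields(build_nozzle("optimized", air_gap_cm = 10),
                         0.16, 0.20, "q1_horizontal")
  src <- beam_source(100, 0.01, 4, 4, 3, 3, -1, -1)
  expect_error(compute_dose_grid(noz, src, grid_layout(5, 8),
                                 phantom_spec(2, 2, 10)),
               "exceeds the phantom")
})

test_that("analyze_dose reproduces the closed-form Gaussian-comb PVDR", {
  f <- gen_pvdr_fixture(1, 4)
  a <- analyze_dose(f)
  expect_equal(a$entrance_pvdr, f$pvdr_closed_form, tolerance = 0.01)
  # overlapping limit: PVDR -> 1
  f_flat <- gen_pvdr_fixture(5, 0.5)
  expect_lt(f_flat$pvdr_closed_form, 1.01)
  # sharp-beam limit: PVDR grows without bound
  f_sharp <- gen_pvdr_fixture(0.4, 4)
  expect_gt(f_sharp$pvdr_closed_form, 1e5)
  expect_gt(f_sharp$pvdr_closed_form, f$pvdr_closed_form)
})

test_that("a uniform dose grid has PVDR 1 everywhere and zero flatness", {
  lay <- grid_layout(5, 2.9)
  g <- structure(list(dose = array(3, c(50, 50, 4)),
                      x_mm = seq(-9.8, 9.8, length.out = 50),
                      y_mm = seq(-9.8, 9.8, length.out = 50),
                      z_cm = (1:4) - 0.5, voxel_mm = c(0.4, 0.4, 10),
                      rel_unc = NULL, layout = lay, mode = "fixture",
                      energy = NA_real_, spread = NA_real_, n = NA_real_,
                      d1_m = Inf, d2_m = Inf),
                 class = "dose_grid")
  a <- analyze_dose(g)
  expect_equal(a$curve$pvdr, rep(1, 4))
  expect_equal(a$flatness_pct, 0)
})

test_that("PVDR decreases with depth and beam width grows more slowly at 200 MeV", {
  ph100 <- phantom_spec(2, 2, 10, c(0.1, 0.1, 5))
  ph200 <- phantom_spec(2, 2, 30, c(0.1, 0.1, 5))
  run <- function(energy, gap, B, src, ph, spacing) {
    noz <- set_scan_fields(build_nozzle("optimized", air_gap_cm = gap),
                           B[1], B[2], "q1_horizontal")
    lay <- grid_layout(5, spacing)
    g <- compute_dose_grid(noz, src, lay, ph)
    s <- compute_dose_grid(noz, src, grid_layout(1, spacing), ph)
    analyze_dose(g, lay, single_grid = s)
  }
  a100 <- run(100, 10, c(0.16, 0.20),
              beam_source(100, 0.01, 4, 4, 3, 3, -1, -1), ph100, 2.9)
  a200 <- run(200, 30, c(1.64, 1.76),
              beam_source(200, 0.01, 5, 3.5, 1, 0.5, 1, -1), ph200, 3.7)
  for (a in list(a100, a200)) {
    # up to the Bragg peak; beyond it the dose (and PVDR) fades to nothing
    cu <- a$curve[a$curve$z_cm <= a$bragg_depth_cm, ]
    pv <- cu$pvdr[!is.na(cu$pvdr)]
    expect_true(all(pv >= 1))
    # monotone decay with depth while there is peak/valley contrast; once
    # the field has homogenised the PVDR stays pinned near 1
    expect_true(all(diff(pv[pv > 1.05]) < 0))
    expect_lt(max(pv[pv <= 1.05], 1), 1.05)
    fw <- cu$fwhm_mm[!is.na(cu$fwhm_mm)]
    expect_true(all(diff(fw) > -1e-6)) # non-decreasing beam width
  }
  # growth up to 7.5 cm: much slower at 200 MeV
  gro <- function(a) {
    cu <- a$curve[a$curve$z_cm <= 7.6, ]
    max(cu$fwhm_mm, na.rm = TRUE) - cu$fwhm_mm[1]
  }
  expect_lt(gro(a200), gro(a100) / 1.5)
})

test_that("analytic and Monte Carlo dose modes agree on the PVDR profile", {
  noz <- set_scan_fields(build_nozzle("optimized", air_gap_cm = 30),
                         0.36, 0.52, "q1_horizontal")
  src <- beam_source(100, 0.01, 6.5, 10, 5, 5, -1, -1)
  ph <- phantom_spec(2, 2, 6, c(0.2, 0.2, 10))
  lay <- grid_layout(3, 3.7)
  ga <- compute_dose_grid(noz, src, lay, ph, mode = "analytic")
  gm <- compute_dose_grid(noz, src, lay, ph, mode = "monte_carlo",
                          n = 6e4, repeats = 4, seed = 3)
  aa <- analyze_dose(ga, lay); am <- analyze_dose(gm, lay)
  expect_false(is.na(am$global_rel_unc_pct))
  sel <- which(!is.na(aa$curve$pvdr) & !is.na(am$curve$pvdr) &
                 aa$curve$pvdr < 50)
  expect_gt(length(sel), 1)
  expect_equal(log(am$curve$pvdr[sel]), log(aa$curve$pvdr[sel]),
               tolerance = 0.35)
})

test_that("homogenisation spacing grows with the entrance beam width", {
  ph <- phantom_spec(2, 2, 10)
  narrow <- set_scan_fields(build_nozzle("optimized", air_gap_cm = 10),
                            0.16, 0.20, "q1_horizontal")
  wide <- set_scan_fields(build_nozzle("optimized", air_gap_cm = 30),
                          0.36, 0.52, "q1_horizontal")
  s_narrow <- find_homogenisation_spacing(
    narrow, beam_source(100, 0.01, 4, 4, 3, 3, -1, -1), ph,
    flatness_band = c(5, 6))
  s_wide <- find_homogenisation_spacing(
    wide, beam_source(100, 0.01, 6.5, 10, 5, 5, -1, -1), ph,
    flatness_band = c(5, 6))
  expect_lte(s_narrow, s_wide)
  # an unreachable band raises an informative error naming the closest try
  expect_error(find_homogenisation_spacing(
    narrow, beam_source(100, 0.01, 4, 4, 3, 3, -1, -1), ph,
    flatness_band = c(5, 6), spacings_mm = c(0.5)), "closest")
})
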
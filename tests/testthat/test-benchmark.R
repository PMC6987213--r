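test_that("the full benchmark grid enumerates just under 70,000 sources", {
  g <- param_grid("full")
  e <- enumerate_parametrisations(g)
  expect_equal(nrow(e), 9 * 8 * 8 * 11 * 11) # 69,696
  expect_lte(nrow(e), 70000)
  expect_equal(range(g$divergences_mrad), c(0.1, 15))
  expect_equal(range(g$correlations), c(-1, 1))
  # one value per axis: exactly one source
  g1 <- param_grid(sizes_mm = data.frame(sigma_x = 5, sigma_y = 5),
                   divergences_mrad = 1, correlations = 0)
  expect_equal(nrow(enumerate_parametrisations(g1)), 1)
  expect_error(param_grid(divergences_mrad = numeric(0)), "empty")
})

test_that("enumeration order is deterministic", {
  g <- param_grid("ci")
  e1 <- enumerate_parametrisations(g)
  e2 <- enumerate_parametrisations(g)
  expect_identical(e1, e2)
})

test_that("feasibility holds for tiny divergence or extreme correlation", {
  noz <- build_nozzle("optimized", air_gap_cm = 10)
  g <- param_grid(sizes_mm = data.frame(sigma_x = 4, sigma_y = 4),
                  divergences_mrad = c(0.1, 3, 15),
                  correlations = c(-1, 0, 1))
  fm <- feasibility_map(noz, 100, g,
                        quad_scan_spec(fields = seq(0, 2, by = 0.05),
                                       refine_top = 0))
  # tiny divergence: feasible at every correlation
  expect_true(all(fm$h_fwhm["0.1", ] <= 1))
  expect_true(all(fm$v_fwhm["0.1", ] <= 1))
  # extreme correlation (zero emittance): feasible at every divergence
  expect_true(all(fm$h_fwhm[, "-1"] <= 1))
  expect_true(all(fm$h_fwhm[, "1"] <= 1))
  # the mask is exactly the <= 1 mm criterion
  expect_identical(fm$h_mask, fm$h_fwhm <= 1)
  # mid divergence, no correlation: high emittance, not a minibeam
  expect_gt(fm$h_fwhm["3", "0"], 1)
  # decreasing divergence at fixed correlation never hurts feasibility
  expect_true(all(fm$h_fwhm["0.1", ] <= fm$h_fwhm["15", ] + 1e-9))
})

test_that("beam size is virtually independent of the initial beam size", {
  noz <- build_nozzle("optimized", air_gap_cm = 10)
  sp <- quad_scan_spec(fields = seq(0, 2, by = 0.05), refine_top = 0)
  mins <- vapply(c(3, 9, 15), function(sg) {
    fm <- feasibility_map(noz, 100,
                          param_grid(sizes_mm = data.frame(sigma_x = sg,
                                                           sigma_y = sg),
                                     divergences_mrad = 0.5,
                                     correlations = -1),
                          sp)
    fm$h_fwhm[1, 1]
  }, numeric(1))
  expect_lt(diff(range(mins)) / mean(mins), 0.10)
})

test_that("measured-size tables must be complete and positive", {
  expect_error(measured_sizes(c(100, 100), c(0, 0), c(5, 5), c(5, 5)),
               "incomplete")
  expect_error(measured_sizes(100, 0, -1, 5), "> 0")
  tab <- measured_sizes(rep(c(100, 200), each = 2), rep(c(-20, 20), 2),
                        runif(4, 3, 8), runif(4, 3, 8))
  expect_s3_class(tab, "measured_sizes")
})

test_that("calibration recovers generating parameters from synthetic tables", {
  noz <- build_nozzle("icpo_current",
                      monitor_offsets_cm = c(-40, -20, 0, 20, 40))
  search <- param_grid(sizes_mm = data.frame(sigma_x = 1, sigma_y = 1),
                       divergences_mrad = c(0.3, 0.8, 1.5, 2.25),
                       correlations = c(-1, -0.5, 0, 0.5, 1))
  gen <- data.frame(energy_MeV = c(100, 160, 220),
                    sigma_x_mm = c(12, 8, 4), sigma_y_mm = c(12, 8, 4),
                    div_x = c(2.25, 1.5, 0.8), div_y = c(2.25, 1.5, 0.8),
                    r_xx = c(-0.5, 0, 0.5), r_yy = c(-0.5, 0, 0.5))
  run_cal <- function(noise, seed) {
    spec <- synthetic_spec(energies_MeV = gen$energy_MeV,
                           noise_rel = noise, seed = seed, params = gen)
    tab <- gen_measured_sizes(spec, noz)
    calibrate_source(tab, noz, search,
                     source_sigma = gen[, c("energy_MeV", "sigma_x_mm",
                                            "sigma_y_mm")])
  }
  # noise-free: exact recovery of on-grid parameters, zero deviation
  cal0 <- run_cal(0, 1)
  expect_equal(cal0$div_x, gen$div_x)
  expect_equal(cal0$r_xx, gen$r_xx)
  expect_equal(cal0$mean_rel_dev_x_pct, rep(0, 3), tolerance = 1e-8)
  # 1% noise: recovery within one grid step, deviation stays small
  cal1 <- run_cal(0.01, 2)
  step_of <- function(v, axis) vapply(v, function(x) which.min(abs(axis - x)),
                                      integer(1))
  expect_true(all(abs(step_of(cal1$div_x, search$divergences_mrad) -
                        step_of(gen$div_x, search$divergences_mrad)) <= 1))
  expect_true(all(abs(step_of(cal1$r_xx, search$correlations) -
                        step_of(gen$r_xx, search$correlations)) <= 1))
  expect_true(all(cal1$mean_rel_dev_x_pct < 5))
})
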
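# Synthetic-signal generator: calibration, geometry, reproducibility.

test_that("generated traces are bit-reproducible per seed and differ across seeds", {
  a1 <- simulate_attachment("collagen", seed = 7)
  a2 <- simulate_attachment("collagen", seed = 7)
  a3 <- simulate_attachment("collagen", seed = 8)
  expect_identical(a1$value, a2$value)
  expect_false(identical(a1$value, a3$value))
  # different seeds share the underlying mean trace
  a0 <- simulate_attachment("collagen", noise_sd = 0)
  expect_lt(max(abs(a1$value - a0$value) / a0$value), 0.05)
  expect_lt(abs(mean(a1$value / a0$value) - 1), 0.005)
})

test_that("a zero-slope profile yields a flat trace at the cell-free level", {
  p <- substrate_profiles("8W1E")
  p$sc_nf_h[p$substrate == "control"] <- 0
  p$lag_h[p$substrate == "control"] <- 0
  tr <- simulate_attachment("control", noise_sd = 0, profiles = p)
  expect_true(all(tr$value == p$cap_free_nf[p$substrate == "control"]))
})

test_that("zero front speed keeps the migration trace at baseline forever", {
  p <- substrate_profiles("8W1E")
  p$t50_migr_h[p$substrate == "control"] <- Inf
  tr <- simulate_migration("control", noise_sd = 0, profiles = p,
                           duration_h = 20)
  expect_true(all(tr$value == p$base_ohm[p$substrate == "control"]))
  expect_error(simulate_migration("control", profiles = p), "duration_h")
})

test_that("wound coverage follows the inward-front geometry", {
  v <- 40; r_e <- 125
  expect_equal(wound_coverage(0, v, r_e), 0)
  expect_equal(wound_coverage(r_e / v, v, r_e), 1)
  expect_equal(wound_coverage(2 * r_e / v, v, r_e), 1)  # clamped after closure
  # half coverage at t = (1 - sqrt(1/2)) r_e / v
  t_half <- (1 - sqrt(0.5)) * r_e / v
  expect_equal(wound_coverage(t_half, v, r_e), 0.5, tolerance = 1e-12)
  t <- seq(-1, 5, 0.01)
  expect_true(all(diff(wound_coverage(t, v, r_e)) >= 0))
})

test_that("fast-mode migration T50 matches the closed-form front geometry", {
  for (sub in c("collagen", "PDL")) {
    p <- substrate_profiles("8W1E")
    target <- p$t50_migr_h[p$substrate == sub]
    tr <- simulate_migration(sub, noise_sd = 0, interval_h = 1 / 12)
    got <- trace_t50(tr)$t50_h
    expect_lt(abs(got - target), 1 / 12)   # within one sample interval
  }
})

test_that("model-mode readout is monotone but delays the resistance midpoint", {
  fast <- simulate_migration("collagen", noise_sd = 0, mode = "fast")
  modl <- simulate_migration("collagen", noise_sd = 0, mode = "model")
  # both modes ride the same coverage path on the same clock
  expect_identical(fast$time_h, modl$time_h)
  expect_true(all(diff(modl$value) >= -1e-9))
  # admittance mixing makes Re Z convex in coverage, so the resistance
  # midpoint is reached after the coverage midpoint (a real readout bias;
  # monotone maps do not preserve midpoints)
  t_fast <- trace_t50(fast)$t50_h
  t_modl <- trace_t50(modl)$t50_h
  expect_gt(t_modl, t_fast)
  expect_lt(t_modl, 2 * t_fast)
})

test_that("noiseless scans equal the forward model exactly and span the printed grid", {
  el <- ref_electrode()
  f <- scan_frequencies()
  expect_equal(f[1], 31.25, tolerance = 1e-12)
  expect_equal(f[length(f)], 1e5, tolerance = 1e-9)
  expect_equal(length(f), 25)
  sc <- simulate_scan(el, NULL, noise_sd = 0, seed = 1)
  z <- well_impedance(f, el)
  expect_equal(sc$z_real_ohm, Re(z), tolerance = 1e-14)
  expect_equal(sc$z_imag_ohm, Im(z), tolerance = 1e-14)
  expect_equal(unique(sc$state), "cell_free")
  # capacitive interface: Im Z < 0 across the grid
  expect_true(all(sc$z_imag_ohm < 0))
  cells <- ref_cells()
  sc2 <- simulate_scan(el, cells, noise_sd = 0, seed = 1)
  expect_equal(sc2$z_real_ohm, Re(well_impedance(f, el, cells, 1)),
               tolerance = 1e-14)
  expect_equal(unique(sc2$state), "cell_covered")
})

test_that("micromotion OU process matches its stationary closed form", {
  # long-run sample variance of log R vs the configured stationary variance
  tr <- simulate_micromotion("control", n_points = 1e5, seed = 42,
                             sd_rel = 5e-4)
  x <- log(tr$resistance_ohm / 10500)
  expect_lt(abs(stats::var(x) - 5e-4^2) / 5e-4^2, 0.05)
})

test_that("zero micromotion amplitude gives exactly zero Var32", {
  tr <- simulate_micromotion("control", sd_rel = 0, seed = 1)
  expect_equal(var32(tr)$var32, 0)
})

test_that("simulated experiments are reproducible and carry all signal families", {
  cfg <- ecis_config(n_wells = 1, seed = 13,
                     substrates = c("control", "collagen"))
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$timeseries$value, s2$timeseries$value)
  expect_identical(s1$rtc$resistance_ohm, s2$rtc$resistance_ohm)
  expect_identical(s1$scans$z_real_ohm, s2$scans$z_real_ohm)
  expect_setequal(unique(s1$timeseries$modality),
                  c("attachment_capacitance", "migration_resistance"))
  expect_equal(nrow(s1$wells), 2)
  expect_equal(sum(s1$rtc$well == "control_01"), 2048)
})
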
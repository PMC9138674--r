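# Forward model: CPE interface, disc-cell solution, Bessel bracket,
# alpha/h conversion, coverage mixing.

test_that("CPE reduces to a pure capacitor at exponent 1", {
  cspec <- 1 / (2 * pi * 5000)  # F/cm^2 chosen so |Zn| = 1 at 5 kHz
  el <- electrode_spec("8W1E", cpe_magnitude = 1 / cspec, cpe_exponent = 1)
  zn <- cell_free_impedance(5000, el)
  expect_equal(Re(zn), 0, tolerance = 1e-12)
  expect_equal(Im(zn), -1 / (2 * pi * 5000 * cspec), tolerance = 1e-12)
  # and the series-capacitance channel returns exactly cspec * area (in nF)
  ch <- impedance_channels(zn / el$area_cm2, 5000)
  expect_equal(ch$capacitance_nf * 1e-9, cspec * el$area_cm2, tolerance = 1e-12)
})

test_that("default presets give ~2000 ohm (8W1E) and ~300 ohm (8W10E) at 40 kHz", {
  expect_equal(Re(well_impedance(40000, electrode_spec("8W1E"))), 2000,
               tolerance = 1e-10)
  expect_equal(Re(well_impedance(40000, electrode_spec("8W10E"))), 300,
               tolerance = 1e-10)
})

test_that("doubling the electrode count halves the interfacial impedance", {
  el1 <- electrode_spec("8W1E")
  el2 <- electrode_spec("8W1E")
  el2$n_electrodes <- 2L
  el2$area_cm2 <- 2 * el1$area_cm2
  for (f in c(62.5, 4000, 64000)) {
    zi1 <- well_impedance(f, el1) - el1$r_solution_ohm
    zi2 <- well_impedance(f, el2) - el2$r_solution_ohm
    # parallel-admittance arithmetic: two identical branches in parallel
    expect_equal(zi2, zi1 / 2, tolerance = 1e-12)
  }
})

test_that("cell-covered impedance collapses to cell-free when Rb = alpha = 0", {
  el <- ref_electrode()
  c0 <- cell_params(rb_ohm_cm2 = 0, alpha = 0, cm_uf_cm2 = 1, rc_um = 11.72)
  f <- scan_frequencies()
  zn <- cell_free_impedance(f, el)
  zc <- cell_covered_impedance(f, el, c0)
  expect_lt(max(Mod(zc - zn) / Mod(zn)), 1e-10)
})

test_that("disc-cell solution matches an independent 30-term series oracle", {
  # reference monolayer on the default single-electrode interface at 4 kHz
  el <- ref_electrode()
  cells <- ref_cells()
  f <- 4000
  zn <- cell_free_impedance(f, el)
  zm <- 2 / complex(imaginary = 2 * pi * f * cells$cm_uf_cm2 * 1e-6)
  ysum <- 1 / zn + 1 / zm
  grc <- cells$alpha * sqrt(ysum)
  expect_lt(Mod(grc), 12)  # series oracle is converged at 30 terms here
  bracket <- zn / (zn + zm) +
    (zm / (zn + zm)) / (oracle_bessel_bracket(grc, nterms = 30) +
                          cells$rb_ohm_cm2 * ysum)
  zc_oracle <- zn / bracket
  zc <- cell_covered_impedance(f, el, cells)
  expect_lt(Mod(zc - zc_oracle) / Mod(zc_oracle), 1e-9)
})

test_that("Bessel bracket agrees with the adaptive series oracle over the model range", {
  # model arguments have phase in (0, 45 deg]; moduli span the branch
  # boundaries of the implementation
  mods <- c(1e-3, 0.01, 0.1, 1, 5, 11, 12, 13, 20, 35, 50)
  phases <- c(5, 20, 35, 44) * pi / 180
  z <- as.vector(outer(mods, phases, function(m, a) {
    complex(modulus = m, argument = a)
  }))
  got <- bessel_bracket(z)
  want <- oracle_bessel_bracket(z)
  expect_lt(max(Mod(got - want) / Mod(want)), 1e-9)
})

test_that("Bessel bracket is finite and asymptotically linear up to |z| = 1e3", {
  z <- complex(modulus = c(1e2, 3e2, 1e3), argument = rep(pi / 5, 3))
  v <- bessel_bracket(z)
  expect_true(all(is.finite(Re(v)) & is.finite(Im(v))))
  # (z/2) I0/I1 -> z/2 for large modulus
  expect_lt(max(Mod(v - z / 2) / Mod(z / 2)), 0.01)
  expect_equal(bessel_bracket(0 + 0i), 1 + 0i)
})

test_that("raising Rb strictly raises the 4 kHz whole-well resistance", {
  el <- ref_electrode()
  rbs <- seq(0, 10, length.out = 101)
  r4 <- vapply(rbs, function(rb) {
    cells <- cell_params(rb, h_nm = 49.1535, cm_uf_cm2 = 1, rc_um = 11.72)
    Re(well_impedance(4000, el, cells, coverage = 1))
  }, numeric(1))
  expect_true(all(diff(r4) > 0))
})

test_that("alpha/h conversion round-trips and obeys its power law", {
  for (a in c(0.5, 3.884, 40)) {
    expect_equal(h_to_alpha(alpha_to_h(a, 54, 11.72), 54, 11.72), a,
                 tolerance = 1e-12)
  }
  # hand unit conversion: h = rho rc^2 / alpha^2 in cm, then to nm
  rc_cm <- 11.72e-4
  a <- rc_cm * sqrt(54 / 49.1535e-7)
  expect_equal(h_to_alpha(49.1535, 54, 11.72), a, tolerance = 1e-12)
  expect_equal(alpha_to_h(a, 54, 11.72), 49.1535, tolerance = 1e-12)
  # quadrupling alpha divides h by 16
  expect_equal(alpha_to_h(4 * a, 54, 11.72), 49.1535 / 16, tolerance = 1e-12)
  expect_error(h_to_alpha(0), "h_nm")
})

test_that("cell_params keeps alpha and h mutually consistent", {
  c1 <- cell_params(1, h_nm = 49.1535, cm_uf_cm2 = 1, rc_um = 11.72)
  c2 <- cell_params(1, alpha = c1$alpha, cm_uf_cm2 = 1, rc_um = 11.72)
  expect_equal(c2$h_nm, c1$h_nm, tolerance = 1e-12)
  expect_error(cell_params(-1, h_nm = 50), "rb")
  expect_error(cell_params(1, h_nm = 50, alpha = 3), "only one")
})

test_that("coverage mixing interpolates admittances between the pure states", {
  el <- ref_electrode()
  cells <- ref_cells()
  f <- c(250, 4000, 64000)
  z0 <- well_impedance(f, el, cells, coverage = 0)
  z1 <- well_impedance(f, el, cells, coverage = 1)
  expect_equal(z0, well_impedance(f, el), tolerance = 1e-14)
  expect_equal(z1, cell_covered_impedance(f, el, cells) / el$area_cm2 +
                 el$r_solution_ohm, tolerance = 1e-14)
  # half coverage: hand parallel-circuit arithmetic on the specific branches
  zh <- well_impedance(f, el, cells, coverage = 0.5)
  zn <- cell_free_impedance(f, el)
  zc <- cell_covered_impedance(f, el, cells)
  hand <- 1 / (el$area_cm2 * (0.5 / zn + 0.5 / zc)) + el$r_solution_ohm
  expect_equal(zh, hand, tolerance = 1e-12)
  expect_error(well_impedance(4000, el, cells, coverage = 1.2), "coverage")
})

test_that("domain errors are raised for invalid frequencies", {
  el <- ref_electrode()
  expect_error(cell_free_impedance(0, el), "freq")
  expect_error(cell_covered_impedance(-5, el, ref_cells()), "freq")
})
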
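test_that("stopping power matches direct Bethe evaluation and known magnitudes", {
  p200 <- stopping_power(ion_state(1, 1, 200), mat_water)
  expect_equal(p200, oracle_stopping(200, 1, zoa_water, 75), tolerance = 1e-12)
  expect_equal(p200, 4.49, tolerance = 0.02)  # ~4.5 MeV cm2/g
  # monotone decreasing over the plateau approach
  s <- stopping_power(ion_state(6, 12, 100), mat_water,
                      energy = c(10, 50, 100, 400, 1000))
  expect_true(all(diff(s) < 0))
  expect_gt(stopping_power(ion_state(6, 12, 200), mat_water) /
              stopping_power(ion_state(6, 12, 400), mat_water), 1)
})

test_that("stopping power scales exactly as Z^2 at fixed energy per nucleon", {
  for (E in c(10, 200, 1000)) {
    for (m in list(mat_water, mat_ch2, mat_al)) {
      r <- stopping_power(ion_state(6, 12, E), m) /
        stopping_power(ion_state(1, 1, E), m)
      expect_equal(r, 36, tolerance = 1e-13)
    }
  }
})

test_that("Bragg additivity: CH2 stopping equals mass-fraction-weighted C and H", {
  # (Z/A) of the compound is the mass-weighted mean of elemental (Z/A), so
  # the Bethe term built on it is additive by construction
  mc <- material("carbon", data.frame(Z_elem = 6, A_elem = 12.011,
                                      stoichiometry = 1), 2, 57.4)
  mh <- material("hydrogen", data.frame(Z_elem = 1, A_elem = 1.008,
                                        stoichiometry = 1), 1, 57.4)
  wC <- 12.011 / (12.011 + 2 * 1.008)
  ion <- ion_state(1, 1, 300)
  expect_equal(stopping_power(ion, mat_ch2),
               wC * stopping_power(ion, mc) + (1 - wC) * stopping_power(ion, mh),
               tolerance = 1e-12)
})

test_that("stopping below the validity floor errors instead of extrapolating", {
  expect_error(stopping_power(ion_state(1, 1, 0.5), mat_water), "floor")
  expect_error(csda_range(ion_state(6, 12, 0.2), mat_ch2), "floor")
})

test_that("LET in water hits the canonical magnitudes", {
  # minimum-ionizing protons ~0.2 keV/um
  expect_equal(let_water(ion_state(1, 1, 2000)), 0.205, tolerance = 0.01)
  # iron near 1 GeV/nuc: 140-160 keV/um
  fe <- let_water(ion_state(26, 56, 1000))
  expect_gt(fe, 140); expect_lt(fe, 160)
  # unit identity: LET = stopping x density x 0.1 in water
  ion <- ion_state(2, 4, 350)
  expect_equal(let_water(ion),
               stopping_power(ion, mat_water) * mat_water$density * 0.1,
               tolerance = 1e-12)
})

test_that("ranges reproduce the printed polyethylene penetration depths", {
  # 200 MeV/nuc 12C: ~8.4 cm linear in CH2 of density 0.97
  r <- csda_range(ion_state(6, 12, 200), mat_ch2) / 0.97
  expect_equal(r, 8.4, tolerance = 0.03)  # within 3%
  # 600 MeV/nuc 16O: ~37 cm
  r2 <- csda_range(ion_state(8, 16, 600), mat_ch2) / 0.97
  expect_equal(r2, 37, tolerance = 0.05)    # within 5%
})

test_that("A/Z^2 range scaling holds across species and energies", {
  for (E in c(50, 200, 1000)) {
    rp <- csda_range(ion_state(1, 1, E), mat_water)
    for (zz in list(c(2, 4), c(6, 12), c(14, 28), c(26, 56))) {
      r <- csda_range(ion_state(zz[1], zz[2], E), mat_water)
      expect_equal(r, rp * zz[2] / zz[1]^2, tolerance = 0.005)
    }
  }
  # helium-4 and protons share the same range at equal energy per nucleon
  expect_equal(csda_range(ion_state(2, 4, 155), mat_ch2),
               csda_range(ion_state(1, 1, 155), mat_ch2), tolerance = 1e-12)
})

test_that("range quadrature is converged and matches the brute-force oracle", {
  r1 <- csda_range(ion_state(6, 12, 200), mat_ch2, points_per_decade = 120)
  r2 <- csda_range(ion_state(6, 12, 200), mat_ch2, points_per_decade = 240)
  expect_lt(abs(r1 - r2) / r1, 0.001)
  expect_equal(r1, oracle_ion_range(200, 6, 12, zoa_ch2, 57.4),
               tolerance = 1e-3)
})

test_that("energy_at_depth inverts the range-energy relation", {
  ion <- ion_state(6, 12, 200)
  expect_identical(energy_at_depth(ion, mat_ch2, 0), 200)
  R <- csda_range(ion, mat_ch2)
  # half range: compare against a 10x-finer independent Euler integration
  Eh <- energy_at_depth(ion, mat_ch2, R / 2)
  Eo <- oracle_energy_at_depth(200, 6, 12, zoa_ch2, 57.4, R / 2)
  expect_equal(Eh, Eo, tolerance = 1e-3)
  # round trip: residual range equals range minus depth
  expect_equal(csda_range(ion, mat_ch2, energy = Eh), R - R / 2,
               tolerance = 1e-3)
  # at (or beyond) the full range: stopped sentinel, never negative energy
  expect_true(is.na(energy_at_depth(ion, mat_ch2, R * 1.01)))
  expect_error(energy_at_depth(ion, mat_ch2, -1), "depth")
})

test_that("range tables export the documented columns", {
  tab <- range_energy_table(ion_state(6, 12, 100), mat_water, c(50, 100, 200))
  expect_named(tab, c("energy_MeV_per_nuc", "stopping_MeV_cm2_g", "range_g_cm2"))
  expect_true(all(diff(tab$range_g_cm2) > 0))
})
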
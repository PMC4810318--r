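test_that("Goldhaber widths match the closed form and worked values", {
  expect_equal(goldhaber_sigma(12, 4), 90 * sqrt(4 * 8 / 11), tolerance = 1e-12)
  expect_equal(goldhaber_sigma(12, 4), 153.5, tolerance = 1e-3)
  expect_equal(goldhaber_sigma(12, 12), 0)            # whole projectile
  expect_equal(goldhaber_sigma(2, 1), 90)             # factor = 1
  # symmetry in A_f <-> A_p - A_f, maximum at A_p/2
  expect_equal(goldhaber_sigma(12, 4), goldhaber_sigma(12, 8))
  s <- goldhaber_sigma(12, 1:11)
  expect_equal(which.max(s), 6)
  expect_error(goldhaber_sigma(12, 13), "A_frag")
  expect_error(goldhaber_sigma(1, 1), "A_proj")
})

test_that("transverse widths expose both conventions; 2-D is sqrt(2) x 1-D", {
  expect_equal(transverse_width(12, 4, dimensions = 1, per_nucleon = TRUE),
               38.4, tolerance = 1e-3)   # printed "about 38 MeV/c"
  expect_equal(transverse_width(12, 4, dimensions = 2, per_nucleon = TRUE),
               54.3, tolerance = 1e-3)   # printed "54 MeV/c"
  expect_equal(transverse_width(12, 4, dimensions = 2) /
                 transverse_width(12, 4, dimensions = 1), sqrt(2))
  expect_equal(transverse_width(12, 4), goldhaber_sigma(12, 4))
  expect_error(transverse_width(12, 4, dimensions = 3), "dimensions")
})

test_that("angular width covers both momentum-pairing conventions", {
  expect_equal(angular_width(0, 1000), 0)
  # per-nucleon transverse width against fragment-total longitudinal: ~1 deg
  expect_equal(angular_width(38, 3000), 0.73, tolerance = 0.01)
  # consistent fragment-total pairing: ~3 deg
  expect_equal(angular_width(153.5, 4 * momentum_per_nucleon(250)), 3.0,
               tolerance = 0.02)
  expect_error(angular_width(10, 0), "p_L")
})

test_that("lateral offsets and cone containment match the worked numbers", {
  expect_equal(lateral_offset(50, 2), 1.75, tolerance = 1e-2)  # "1.7 mm or greater"
  expect_gte(lateral_offset(50, 2), 1.7)
  expect_equal(lateral_offset(100, 0), 0)
  expect_equal(lateral_offset(7, 45), 7, tolerance = 1e-12)
  expect_error(lateral_offset(10, 90), "deflection")
  expect_equal(containment_fraction(2, 1), 0.954, tolerance = 1e-3)
  expect_equal(containment_fraction(3, 1), 0.997, tolerance = 1e-3)
  expect_equal(containment_fraction(1e6, 1), 1)
  expect_equal(containment_fraction(1, 0), 1)  # degenerate beam
})

test_that("fragment sampler conserves charge and anchors the boron fraction", {
  ev <- sample_fragments(ion_state(6, 12, 293), n_events = 20000, rng_seed = 1)
  zsum <- tapply(ev$frags$Z, ev$frags$event, sum)
  expect_true(all(zsum == 6))                     # every event, exactly
  expect_true(all(ev$frags$Z < 6))
  boron <- mean(tapply(ev$frags$Z == 5, ev$frags$event, any))
  expect_lt(abs(boron - 0.20), 0.01)              # binomial 3.5 sigma at n = 2e4
  # free neutrons are non-negative bookkeeping
  expect_true(all(ev$neutrons >= 0))
  # mass conservation: charged products never exceed the projectile mass
  asum <- tapply(ev$frags$A, ev$frags$event, sum)
  expect_true(all(asum <= 12))
})

test_that("branching probabilities validate and generic species are covered", {
  tab <- default_branching_table()
  expect_equal(sum(tab[["6"]]), 1)
  p_fe <- hzesim:::.generic_branching(26)
  expect_equal(sum(p_fe), 1, tolerance = 1e-12)
  expect_true(all(as.integer(names(p_fe)) < 26))
  bad <- list(`6` = c(`5` = 0.5, `4` = 0.4))  # does not sum to 1
  expect_error(sample_fragments(ion_state(6, 12, 200), bad, 10, 1), "sum to 1")
  expect_error(sample_fragments(ion_state(1, 1, 200)), "Z = 1")
})

test_that("empirical branching frequencies converge to the table", {
  n <- 30000
  ev <- sample_fragments(ion_state(6, 12, 400), n_events = n, rng_seed = 8)
  heaviest <- ev$frags$Z[ev$frags$role == "heaviest"]
  p <- default_branching_table()[["6"]]
  for (z in as.integer(names(p))) {
    phat <- mean(heaviest == z)
    se <- sqrt(p[as.character(z)] * (1 - p[as.character(z)]) / n)
    expect_lt(abs(phat - p[as.character(z)]), 3 * se + 1e-6)
  }
})

test_that("sampled momenta are Gaussian with the analytic Goldhaber width", {
  ev <- sample_fragments(ion_state(6, 12, 250), n_events = 30000, rng_seed = 5)
  he <- ev$frags[ev$frags$role == "heaviest" & ev$frags$A == 4, ]
  p0 <- momentum_per_nucleon(250)
  ptot <- 4 * momentum_per_nucleon(he$energy_per_nucleon)
  pl <- ptot * cos(he$angle_deg * pi / 180)
  pt <- ptot * sin(he$angle_deg * pi / 180)
  resid <- pl - 4 * p0
  sig <- goldhaber_sigma(12, 4)
  # longitudinal residual: normal with sd sigma, within 2%
  expect_equal(sd(resid), sig, tolerance = 0.02)
  ks <- suppressWarnings(stats::ks.test(resid, "pnorm", 0, sig))
  expect_gt(ks$p.value, 0.01)
  # transverse magnitude: Rayleigh with the same per-component sd
  expect_equal(sqrt(mean(pt^2) / 2), sig, tolerance = 0.02)
})

test_that("the sampler is reproducible under a fixed seed", {
  a <- sample_fragments(ion_state(8, 16, 500), n_events = 500, rng_seed = 42)
  b <- sample_fragments(ion_state(8, 16, 500), n_events = 500, rng_seed = 42)
  expect_identical(a, b)
})

test_that("branching tables round-trip through YAML", {
  tab <- default_branching_table()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_branching_yaml(tab, path)
  back <- read_branching_yaml(path)
  expect_equal(back[["6"]], tab[["6"]])
})
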
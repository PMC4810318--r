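cfg_det <- function(n = 2000, seed = 1, ...)
  transport_config(n_primaries = n, rng_seed = seed, energy_spread = 0, ...)

test_that("with fragmentation off, transport is pure continuous slowing-down", {
  beam <- ion_state(6, 12, 200)
  R <- csda_range(beam, mat_ch2)
  cfg <- cfg_det(500)
  cfg$fragmentation_enabled <- FALSE
  h <- transport_slab(beam, mat_ch2, R * 1.2, cfg)
  # every primary stops at exactly the CSDA range, none beyond
  expect_true(all(h$segments$fate == "stop"))
  expect_equal(unname(unique(round(h$segments$d1, 6))), round(R, 6))
  expect_equal(primary_survival(h, R * 0.99), 1)
  expect_equal(primary_survival(h, R * 1.01), 0)
  expect_equal(h$n_interactions, 0)
  # distal dose beyond the range is exactly zero
  bc <- bragg_curve(beam, mat_ch2, R * 1.2, cfg)
  expect_true(all(bc$ionization_ratio[bc$depth > R] == 0))
  expect_gt(max(bc$ionization_ratio), 1)
})

test_that("primary survival reproduces the printed measured-mfp arithmetic", {
  # 293 MeV/nuc carbon in polyethylene with the measured 23 cm mean free
  # path (22.3 g/cm2): ~50% fragmented at the 16 cm Bragg peak
  h <- transport_slab(ion_state(6, 12, 293), mat_ch2, 15.6,
                      cfg_det(8000, seed = 2), mfp_table = c(`6` = 22.3))
  expect_equal(primary_survival(h, 16 * 0.97), 0.50, tolerance = 0.03)
  # and ~40% interacted within the first 12 cm
  expect_equal(1 - primary_survival(h, 12 * 0.97), 0.40, tolerance = 0.03)
})

test_that("transport is bit-identical under a fixed seed", {
  beam <- ion_state(8, 16, 600)
  h1 <- transport_slab(beam, mat_al, 20, cfg_det(300, seed = 9))
  h2 <- transport_slab(beam, mat_al, 20, cfg_det(300, seed = 9))
  expect_identical(h1$segments, h2$segments)
  expect_identical(h1$exits, h2$exits)
})

test_that("bernoulli step sampling agrees with exponential sampling", {
  beam <- ion_state(6, 12, 600)
  lam <- mean_free_path(beam, mat_al)
  hb <- transport_slab(beam, mat_al, 20,
                       cfg_det(4000, seed = 3, sampling = "bernoulli"))
  s <- primary_survival(hb, c(10, 20))
  expect_equal(s, exp(-c(10, 20) / lam), tolerance = 0.03)
  # too-coarse steps warn
  cfg <- cfg_det(50, seed = 1, sampling = "bernoulli", step = 5)
  expect_warning(transport_slab(beam, mat_al, 20, cfg), "lambda/10")
})

test_that("fragments appear beyond interactions and conserve the LET budget", {
  beam <- ion_state(6, 12, 293)
  h <- transport_slab(beam, mat_ch2, 10, cfg_det(2000, seed = 4))
  frags <- h$segments[h$segments$parent != 0, ]
  expect_gt(nrow(frags), 0)
  expect_true(all(frags$Z < 6))
  expect_true(all(frags$d0 > 0))
  # at equal velocity LET ~ Z^2: the fragments of any event sum below the
  # primary (true charge-wise because sum Z_f <= Z and squares subadd)
  ev <- sample_fragments(beam, n_events = 3000, rng_seed = 4)
  z2 <- tapply(ev$frags$Z^2, ev$frags$event, sum)
  expect_true(all(z2 < 36))
})

test_that("Bragg curve normalises at the entrance and peaks near the range", {
  beam <- ion_state(6, 12, 200)
  bc <- bragg_curve(beam, mat_ch2,
                    config = transport_config(n_primaries = 3000, rng_seed = 5))
  expect_equal(bc$ionization_ratio[1], 1)
  pk <- peak_analysis(bc)
  expect_false(pk$no_stopping_peak)
  expect_equal(pk$peak_depth, csda_range(beam, mat_ch2), tolerance = 0.02)
  expect_gt(pk$distal_integral, 0)   # fragmentation tail
  # composition at the entrance plane is pure primary
  expect_equal(unname(composition_at_depth(bc, 0)["Z6"]), 1)
})

test_that("peak depth is robust to halving the step size", {
  beam <- ion_state(6, 12, 200)
  p1 <- peak_analysis(bragg_curve(beam, mat_ch2,
        config = transport_config(n_primaries = 2000, rng_seed = 6, step = 0.05)))
  p2 <- peak_analysis(bragg_curve(beam, mat_ch2,
        config = transport_config(n_primaries = 2000, rng_seed = 6, step = 0.025)))
  expect_lt(abs(p1$peak_depth - p2$peak_depth) / p1$peak_depth, 0.01)
})

test_that("peak_analysis recovers constructed truths and flags flat curves", {
  tri <- list(depth = seq(0, 10, 0.5),
              ionization_ratio = c(seq(1, 5, length.out = 11),
                                   seq(4.6, 1, length.out = 10)))
  pk <- peak_analysis(tri)
  expect_equal(pk$peak_depth, 5)
  expect_equal(pk$peak_ratio, 5)
  fx <- make_bragg_fixture(8.13, peak_ratio = 6.5, noise_fraction = 0)
  expect_equal(peak_analysis(fx)$peak_depth, 8.13)
  expect_equal(peak_analysis(fx)$peak_ratio, 6.5)
  # 1% noise: recovery within one grid step
  fx2 <- make_bragg_fixture(8.13, noise_fraction = 0.01, seed = 2)
  expect_lt(abs(peak_analysis(fx2)$peak_depth - 8.13), 0.05 + 1e-9)
  # monotone-decreasing curve: peak at zero, flagged
  mono <- list(depth = 0:10, ionization_ratio = seq(1, 0.5, length.out = 11))
  expect_true(peak_analysis(mono)$no_stopping_peak)
  expect_error(peak_analysis(list(depth = 0:2, ionization_ratio = rep(0, 3))),
               "zero")
  expect_error(peak_analysis(list(depth = numeric(), ionization_ratio = numeric())),
               "empty")
})

test_that("peak-region composition matches the measured carbon-beam mix", {
  # the benchmark conditions: 293 MeV/nuc carbon with the measured 22.3 g/cm2
  # mean free path; composition read one plane upstream of the argmax, where
  # the primary fluence is not yet mid-range-out (see the methods vignette)
  bc <- bragg_curve(ion_state(6, 12, 293), mat_ch2, max_depth = 18,
                    config = transport_config(n_primaries = 8000, rng_seed = 4),
                    mfp_table = c(`6` = 22.3))
  pk <- peak_analysis(bc)
  co <- composition_at_depth(bc, pk$peak_depth - bc$step)
  expect_lt(abs(co[["Z6"]] - 0.45), 0.15)   # ~45% surviving carbon
  expect_lt(abs(co[["Z2"]] - 1 / 3), 0.15)  # ~one-third helium
  expect_gt(co[["Z5"]], 0.02)               # boron present in the peak region
  expect_equal(sum(co), 1, tolerance = 1e-12)
})

test_that("the distal field holds only light fragments, never carbon", {
  bc <- bragg_curve(ion_state(6, 12, 293), mat_ch2, max_depth = 19,
                    config = transport_config(n_primaries = 4000, rng_seed = 7),
                    mfp_table = c(`6` = 22.3))
  pk <- peak_analysis(bc)
  co <- composition_at_depth(bc, pk$peak_depth + 2)
  expect_equal(unname(co["Z6"]), 0)
  # hydrogen and helium dominate past the peak
  expect_gt(co["Z1"] + co["Z2"], 0.75)
  expect_error(composition_at_depth(bc, 40), "outside")
})
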
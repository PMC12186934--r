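test_that("scanner presets carry the clinical protocol parameters", {
  p <- scanner_presets()
  expect_setequal(names(p), c("prisma", "mmr", "signa"))
  expect_equal(p$signa$echo_times, c(2.88, 6.04, 9.20, 12.35, 15.51, 18.66))
  expect_equal(p$signa$flip_angle, 12)
  expect_equal(p$signa$repetition_time, 22.4)
  expect_equal(p$signa$field_strength, 1.5)
  expect_equal(p$prisma$echo_times, p$mmr$echo_times)
  expect_equal(p$prisma$echo_times, c(1.37, 2.66, 4.92, 6.15, 7.38, 8.81))
  expect_equal(p$prisma$flip_angle, 6)
  expect_equal(p$mmr$flip_angle, 6)
  for (prof in p) {
    expect_gte(length(prof$echo_times), 3)
    expect_true(all(diff(prof$echo_times) > 0))
    expect_gt(prof$field_strength, 0)
    expect_true(prof$adipose_residual_water >= 0 &&
                prof$adipose_residual_water < 0.5)
  }
})

test_that("profile constructor rejects invalid parameters", {
  expect_error(scanner_profile("x", -1, prisma_te, 6, 21), "field_strength")
  expect_error(scanner_profile("x", 3, c(2, 1, 3), 6, 21), "increasing")
  expect_error(scanner_profile("x", 3, c(1, 2), 6, 21), "3 echoes")
  expect_error(scanner_profile("x", 3, prisma_te, 120, 21), "flip_angle")
  expect_error(scanner_profile("x", 3, prisma_te, 6, 21,
                               adipose_residual_water = 0.6), "residual")
  expect_error(scanner_profile("x", 3, prisma_te, 6, 21, noise_sd = -1),
               "noise_sd")
})

test_that("steady-state weight matches the closed form and its limits", {
  prof <- quiet_profile()
  # independent evaluation of the saturation factor
  closed_form <- function(t1, flip_deg, tr) {
    a <- flip_deg * pi / 180
    e1 <- exp(-tr / t1)
    sin(a) * (1 - e1) / (1 - cos(a) * e1)
  }
  expect_equal(steady_state_weight(1450, prof), closed_form(1450, 6, 21),
               tolerance = 1e-12)
  expect_equal(steady_state_weight(1450, prof), 0.0760, tolerance = 1e-3)
  # T1 -> 0: full recovery each TR, weight -> sin(flip)
  expect_equal(steady_state_weight(1e-6, prof), sin(6 * pi / 180),
               tolerance = 1e-9)
  # fat (short T1) is weighted more than water (long T1)
  expect_gt(steady_state_weight(365, prof), steady_state_weight(1450, prof))
  expect_error(steady_state_weight(-5, prof), "positive")
})

test_that("fat frequency offset scales with field strength", {
  expect_equal(fat_frequency_offset(1.5), -3.4e-6 * 42.577e6 * 1.5,
               tolerance = 1e-12)
  expect_equal(fat_frequency_offset(1.5), -217.1, tolerance = 1e-3)
  expect_equal(fat_frequency_offset(3), -434.3, tolerance = 1e-3)
})

test_that("phantom geometry obeys its invariants", {
  ph <- make_phantom(c(32, 32, 10), 0.6, seed = 3)
  air <- ph$labels == 0L
  expect_false(any(ph$breast_mask_left & air))
  expect_false(any(ph$breast_mask_right & air))
  expect_false(any(ph$breast_mask_left & ph$breast_mask_right))
  expect_true(all(ph$labels[ph$ref_fat_roi] == 1L))        # adipose
  expect_true(all(ph$labels[ph$ref_water_roi] == 3L))      # pectoral muscle
  expect_gt(sum(ph$ref_fat_roi), 0)
  expect_gt(sum(ph$ref_water_roi), 0)
  expect_true(all(ph$v_water_true >= 0 & ph$v_water_true <= 1))
  expect_error(make_phantom(c(4, 32, 10), 0.5, 1), "at least 8")
  expect_error(make_phantom(c(32, 32, 10), 1.4, 1), "\\[0, 1\\]")
})

test_that("pure fibroglandular phantom fills the breast masks", {
  ph <- make_phantom(c(32, 32, 10), 1.0, seed = 7)
  mask <- ph$breast_mask_left | ph$breast_mask_right
  expect_true(all(ph$labels[mask] == 2L))
  expect_true(all(ph$v_water_true[mask] == 1))
  expect_equal(unname(ph$density_true), c(100, 100))
})

test_that("phantom generation is deterministic given the seed", {
  a <- make_phantom(c(32, 32, 10), 0.5, seed = 7)
  b <- make_phantom(c(32, 32, 10), 0.5, seed = 7)
  expect_identical(a, b)
  c <- make_phantom(c(32, 32, 10), 0.5, seed = 8)
  expect_false(identical(a$labels, c$labels))
})

test_that("mean true water fraction matches the composition by voxel count", {
  w <- 0.10
  for (f in c(0.3, 0.6, 0.9)) {
    ph <- make_phantom(c(32, 32, 12), f, seed = 3, adipose_residual_water = w)
    mask <- ph$breast_mask_left | ph$breast_mask_right
    # brute-force voxel count oracle
    n_fg <- sum(ph$labels[mask] == 2L)
    n_ad <- sum(ph$labels[mask] == 1L)
    expect_equal(n_fg + n_ad, sum(mask))
    expected <- (n_fg * 1 + n_ad * w) / sum(mask)
    expect_equal(mean(ph$v_water_true[mask]), expected, tolerance = 1e-12)
    expect_equal(mean(ph$v_water_true[mask]), f + (1 - f) * w,
                 tolerance = 0.05)
  }
})

test_that("simulated echoes of a pure-water voxel are flat and real", {
  prof <- quiet_profile()
  ph <- voxel_phantom(v_water = 1, psi = 0)
  ser <- simulate_echoes(ph, prof, seed = 1)
  s <- ser$data[1, 1, 1, ]
  expect_equal(Im(s), rep(0, 6), tolerance = 1e-14)
  expect_equal(Re(s), rep(Re(s[1]), 6), tolerance = 1e-14)
  amp <- tissue_amplitudes(1, prof)
  expect_equal(Re(s[1]), unname(amp["a_w"]), tolerance = 1e-12)
})

test_that("echo magnitudes obey in-phase and out-of-phase composition", {
  df <- fat_frequency_offset(1.5)
  te_in <- abs(1 / df) * 1000            # fat back in phase with water
  te_out <- abs(0.5 / df) * 1000         # opposed phase
  prof <- quiet_profile(field_strength = 1.5,
                        echo_times = c(te_out, te_in, 2 * te_in))
  amp <- tissue_amplitudes(0.5, prof)
  ph <- voxel_phantom(v_water = 0.5, psi = 0)
  ser <- simulate_echoes(ph, prof, seed = 1)
  mags <- abs(ser$data[1, 1, 1, ])
  expect_equal(mags[2], unname(amp["a_w"] + amp["a_f"]), tolerance = 1e-12)
  expect_equal(mags[3], unname(amp["a_w"] + amp["a_f"]), tolerance = 1e-12)
  expect_equal(mags[1], unname(abs(amp["a_w"] - amp["a_f"])), tolerance = 1e-12)
})

test_that("simulator matches the independent forward model with all effects on", {
  prof <- quiet_profile(phase0 = 0.3, phase1 = 0.05, r2star = 20)
  ph <- voxel_phantom(v_water = 0.35, psi = 17)
  ser <- simulate_echoes(ph, prof, seed = 1)
  amp <- tissue_amplitudes(0.35, prof)
  oracle <- forward_voxel(amp["a_w"], amp["a_f"], prof$echo_times,
                          fat_frequency_offset(3), psi_hz = 17, r2star = 20,
                          phase0 = 0.3, phase1 = 0.05)
  expect_equal(ser$data[1, 1, 1, ], oracle, tolerance = 1e-12)
})

test_that("simulation with noise is reproducible given the seed", {
  prof <- quiet_profile(noise_sd = 0.01)
  ph <- make_phantom(c(16, 16, 8), 0.5, seed = 2)
  a <- simulate_echoes(ph, prof, seed = 9)
  b <- simulate_echoes(ph, prof, seed = 9)
  expect_identical(a$data, b$data)
  c <- simulate_echoes(ph, prof, seed = 10)
  expect_false(identical(a$data, c$data))
})

test_that("cohort simulation produces the expected truth table", {
  profs <- scanner_presets()
  co <- cohort_simulate(10, profs, c(40, 80), seed = 5, shape = c(24, 24, 8))
  for (sc in c("prisma", "mmr", "signa"))
    expect_equal(sum(co$truth$scanner == sc), 20)   # 20 breast datasets
  expect_equal(nrow(co$truth), 60)
  # direct scan oracle: all truth densities within the requested range
  # (quantisation of the voxel grid allowed at the interval edges)
  expect_true(all(co$truth$true_density_percent >= 40 - 1 &
                  co$truth$true_density_percent <= 80 + 1))
  co2 <- cohort_simulate(2, profs[1], c(40, 80), seed = 5, shape = c(24, 24, 8))
  co3 <- cohort_simulate(2, profs[1], c(40, 80), seed = 5, shape = c(24, 24, 8))
  expect_identical(co2$truth, co3$truth)
  expect_error(cohort_simulate(1, profs, c(40, 80), 1), "at least 2")
  expect_error(cohort_simulate(3, list(), c(40, 80), 1), "profile")
})
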
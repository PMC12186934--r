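test_that("magnitude and phase combine into the expected complex values", {
  m <- array(2, dim = c(1, 1, 1, 3))
  p <- array(pi / 2, dim = c(1, 1, 1, 3))
  ser <- combine_mag_phase(m, p, echo_times = c(1, 2, 3))
  expect_equal(ser$data[1, 1, 1, 1], 0 + 2i, tolerance = 1e-12)
  ser0 <- combine_mag_phase(m, array(0, dim = dim(m)), echo_times = c(1, 2, 3))
  expect_equal(ser0$data, array(2 + 0i, dim = dim(m)), tolerance = 1e-12)
  expect_error(combine_mag_phase(-m, p, c(1, 2, 3)), "non-negative")
  expect_error(combine_mag_phase(m, p[, , , 1:2, drop = FALSE], c(1, 2, 3)),
               "congruent")
})

test_that("combine round-trips magnitude and phase on random volumes", {
  set.seed(42)
  m <- array(stats::runif(4 * 4 * 2 * 3, 0.1, 2), dim = c(4, 4, 2, 3))
  p <- array(stats::runif(4 * 4 * 2 * 3, -pi, pi), dim = c(4, 4, 2, 3))
  ser <- combine_mag_phase(m, p, c(1, 2, 3))
  expect_equal(abs(ser$data), m, tolerance = 1e-12)
  expect_equal(Arg(ser$data), p, tolerance = 1e-12)
})

test_that("IDEAL recovers a pure-water voxel exactly", {
  s <- forward_voxel(1, 0, prisma_te, fat_frequency_offset(3))
  ser <- series_from_matrix(matrix(s, nrow = 1), prisma_te)
  m <- ideal_decompose(ser, options = ideal_options(tol = 1e-9, max_iter = 300))
  expect_equal(m$water[1, 1, 1], 1, tolerance = 1e-9)
  expect_equal(m$fat[1, 1, 1], 0, tolerance = 1e-9)
  expect_equal(m$fat_fraction[1, 1, 1], 0, tolerance = 1e-9)
  expect_equal(m$field_map[1, 1, 1], 0, tolerance = 1e-6)
})

test_that("IDEAL recovers a mixed voxel with off-resonance to high precision", {
  s <- forward_voxel(0.3, 0.7, prisma_te, fat_frequency_offset(3), psi_hz = 20)
  ser <- series_from_matrix(matrix(s, nrow = 1), prisma_te)
  m <- ideal_decompose(ser, options = ideal_options(tol = 1e-10, max_iter = 500))
  expect_equal(m$fat_fraction[1, 1, 1], 0.700, tolerance = 1e-6)
  expect_equal(m$field_map[1, 1, 1], 20, tolerance = 1e-6)
})

test_that("IDEAL converges across the off-resonance range of the protocols", {
  df3 <- fat_frequency_offset(3)
  psis <- seq(-60, 60, by = 10)
  smat <- t(vapply(psis, function(p)
    forward_voxel(0.4, 0.6, prisma_te, df3, psi_hz = p),
    complex(length(prisma_te))))
  ser <- series_from_matrix(smat, prisma_te)
  m <- ideal_decompose(ser, options = ideal_options(tol = 1e-9, max_iter = 500))
  expect_equal(as.vector(m$field_map), psis, tolerance = 1e-5)
  expect_equal(as.vector(m$fat_fraction), rep(0.6, length(psis)),
               tolerance = 1e-6)
  # the 1.5T echo train too
  te15 <- c(2.88, 6.04, 9.20, 12.35, 15.51, 18.66)
  df15 <- fat_frequency_offset(1.5)
  smat <- t(vapply(psis, function(p)
    forward_voxel(0.4, 0.6, te15, df15, psi_hz = p),
    complex(length(te15))))
  ser <- series_from_matrix(smat, te15, field_strength = 1.5)
  m <- ideal_decompose(ser, options = ideal_options(tol = 1e-9, max_iter = 500))
  expect_equal(as.vector(m$field_map), psis, tolerance = 1e-5)
  expect_equal(as.vector(m$fat_fraction), rep(0.6, length(psis)),
               tolerance = 1e-6)
})

test_that("solver agrees with dense grid search plus exact least squares", {
  set.seed(11)
  df3 <- fat_frequency_offset(3)
  for (k in 1:5) {
    ffv <- stats::runif(1, 0.05, 0.95)
    psi <- stats::runif(1, -80, 80)
    s <- forward_voxel(1 - ffv, ffv, prisma_te, df3, psi_hz = psi) +
      complex(real = stats::rnorm(6, sd = 0.005),
              imaginary = stats::rnorm(6, sd = 0.005))
    oracle <- grid_search_ideal(s, prisma_te, df3)
    ser <- series_from_matrix(matrix(s, nrow = 1), prisma_te)
    m <- ideal_decompose(ser, options = ideal_options(tol = 1e-8, max_iter = 500))
    expect_equal(m$field_map[1, 1, 1], oracle$psi, tolerance = 0.1)
    ff_oracle <- Re(oracle$fat / (oracle$fat + oracle$water))
    expect_equal(m$fat_fraction[1, 1, 1], ff_oracle, tolerance = 0.01)
  }
})

test_that("mean fat-fraction bias stays small under noise", {
  set.seed(21)
  df3 <- fat_frequency_offset(3)
  ffv <- stats::runif(200, 0.1, 0.9)
  psi <- stats::runif(200, -30, 30)
  clean <- t(vapply(seq_len(200), function(v)
    forward_voxel(1 - ffv[v], ffv[v], prisma_te, df3, psi_hz = psi[v]),
    complex(6)))
  bias <- vapply(1:10, function(seed) {
    set.seed(100 + seed)
    noisy <- clean + matrix(complex(real = stats::rnorm(1200, sd = 0.02),
                                    imaginary = stats::rnorm(1200, sd = 0.02)),
                            nrow = 200)
    ser <- series_from_matrix(noisy, prisma_te)
    m <- ideal_decompose(ser, options = ideal_options(tol = 1e-6, max_iter = 200))
    mean(m$fat_fraction_signed - ffv)
  }, numeric(1))
  expect_lt(abs(mean(bias)), 0.01)
})

test_that("permuting echoes together with their times leaves maps unchanged", {
  ph <- make_phantom(c(16, 16, 8), 0.5, seed = 4)
  prof <- quiet_profile()
  ser <- simulate_echoes(ph, prof, seed = 1)
  perm <- c(3, 1, 6, 2, 5, 4)
  ser_p <- magdensity:::new_echo_series(ser$data[, , , perm],
                                        ser$echo_times[perm],
                                        ser$scanner_name, ser$field_strength)
  opt <- ideal_options(tol = 1e-8, max_iter = 300)
  m1 <- ideal_decompose(ser, options = opt)
  m2 <- ideal_decompose(ser_p, options = opt)
  expect_equal(m1$fat_fraction, m2$fat_fraction, tolerance = 1e-8)
  expect_equal(m1$field_map, m2$field_map, tolerance = 1e-6)
})

test_that("an effectively in-phase echo train is rejected as singular", {
  df15 <- fat_frequency_offset(1.5)
  te_in <- abs(1 / df15) * 1000
  ser <- series_from_matrix(matrix(1 + 0i, 1, 3), te_in * (1:3),
                            field_strength = 1.5)
  expect_error(ideal_decompose(ser), "singular")
  ser2 <- series_from_matrix(matrix(1 + 0i, 1, 2), c(1, 2))
  expect_error(ideal_decompose(ser2), "3 echoes")
})

test_that("fat-fraction map flags zero-signal voxels invalid", {
  maps <- structure(list(
    water = array(c(1, 0, 0, 1), dim = c(4, 1, 1)),
    fat = array(c(1, 1, 0, 0), dim = c(4, 1, 1))),
    class = "fat_water_maps")
  ff <- fat_fraction_map(maps)
  expect_equal(ff[1, 1, 1], 0.5)
  expect_equal(ff[2, 1, 1], 1.0)
  expect_true(is.na(ff[3, 1, 1]))
  expect_equal(ff[4, 1, 1], 0.0)
})

test_that("injected echo-phase errors are recovered and removable", {
  ph <- make_phantom(c(20, 20, 8), 0.5, seed = 6)
  prof <- quiet_profile(phase0 = 0.3, phase1 = 0.05)
  ser <- simulate_echoes(ph, prof, seed = 1)
  est <- estimate_echo_phase(ser, prof)
  expect_equal(unname(est["phase0"]), 0.3, tolerance = 1e-6)
  expect_equal(unname(est["phase1"]), 0.05, tolerance = 1e-6)

  # null case: no injected error
  prof0 <- quiet_profile()
  ser0 <- simulate_echoes(ph, prof0, seed = 1)
  est0 <- estimate_echo_phase(ser0, prof0)
  expect_equal(unname(est0), c(0, 0), tolerance = 1e-8)

  # apply-then-re-estimate is idempotent
  corrected <- apply_phase_correction(ser, est["phase0"], est["phase1"])
  re <- estimate_echo_phase(corrected, prof)
  expect_equal(unname(re), c(0, 0), tolerance = 1e-9)
  expect_equal(abs(corrected$data), abs(ser$data), tolerance = 1e-12)
})

test_that("phase correction with zero parameters is the identity", {
  ph <- make_phantom(c(12, 12, 8), 0.4, seed = 2)
  ser <- simulate_echoes(ph, quiet_profile(), seed = 1)
  same <- apply_phase_correction(ser, 0, 0)
  expect_equal(same$data, ser$data, tolerance = 0)
  expect_error(apply_phase_correction(ser, NaN, 0), "finite")
})

test_that("phase recovery degrades gracefully with noise", {
  ph <- make_phantom(c(24, 24, 10), 0.5, seed = 6)
  prof <- quiet_profile(phase0 = 0.3, phase1 = 0.05, noise_sd = 0.01)
  errs <- vapply(1:20, function(seed) {
    ser <- simulate_echoes(ph, prof, seed = seed)
    est <- estimate_echo_phase(ser, prof)
    max(abs(est - c(0.3, 0.05)))
  }, numeric(1))
  expect_lt(mean(errs), 0.02)
})

test_that("noiseless reconstruction inverts the forward model voxelwise", {
  ph <- make_phantom(c(20, 20, 8), 0.55, seed = 9)
  prof <- quiet_profile()
  ser <- simulate_echoes(ph, prof, seed = 1)
  m <- ideal_decompose(ser, prof, ideal_options(tol = 1e-8, max_iter = 400))
  tissue <- ph$labels != 0L
  amp_w <- ph$v_water_true * steady_state_weight(prof$water_t1, prof)
  amp_f <- (1 - ph$v_water_true) * steady_state_weight(prof$fat_t1, prof)
  ff_true <- amp_f / (amp_f + amp_w)
  expect_lt(max(abs(m$fat_fraction_signed[tissue] - ff_true[tissue])), 1e-6)
  expect_lt(max(abs(m$field_map[tissue] - ph$field_map_true[tissue])), 1e-4)
})
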
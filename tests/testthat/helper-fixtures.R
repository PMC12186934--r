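# Shared fixtures: tiny profiles, hand-built single-voxel phantoms, and a
# direct (loop-free of package internals) forward evaluation used as the
# oracle for reconstruction tests.

prisma_te <- c(1.37, 2.66, 4.92, 6.15, 7.38, 8.81)

quiet_profile <- function(name = "test", field_strength = 3,
                          echo_times = prisma_te, flip_angle = 6,
                          repetition_time = 21, phase0 = 0, phase1 = 0,
                          noise_sd = 0, r2star = 0, ...) {
  scanner_profile(name, field_strength, echo_times, flip_angle,
                  repetition_time, phase0 = phase0, phase1 = phase1,
                  noise_sd = noise_sd, r2star = r2star, ...)
}

# Minimal hand-built phantom: one tissue voxel with a chosen water volume
# fraction and off-resonance, embedded in a tiny grid. Label 2
# (fibroglandular) keeps it inside the tissue mask of the simulator.
voxel_phantom <- function(v_water, psi = 0, shape = c(1, 1, 1)) {
  lab <- array(2L, dim = shape)
  structure(list(
    labels = lab,
    v_water_true = array(v_water, dim = shape),
    breast_mask_left = array(TRUE, dim = shape),
    breast_mask_right = array(FALSE, dim = shape),
    ref_fat_roi = array(FALSE, dim = shape),
    ref_water_roi = array(FALSE, dim = shape),
    field_map_true = array(psi, dim = shape),
    seed = 0L, density_true = c(L = NA_real_, R = NA_real_)
  ), class = "breast_phantom")
}

# Independent forward model for one voxel (the oracle; mirrors the physics,
# not the package code path).
forward_voxel <- function(a_w, a_f, te_ms, df_hz, psi_hz = 0, r2star = 0,
                          phase0 = 0, phase1 = 0) {
  te <- te_ms / 1000
  n <- seq_along(te) - 1
  (a_w + a_f * exp(2i * pi * df_hz * te)) * exp(2i * pi * psi_hz * te) *
    exp(-te * r2star) * exp(1i * (phase0 + phase1 * n))
}

# Wrap a voxel-by-echo complex matrix as an echo_series on a (V,1,1) grid.
series_from_matrix <- function(smat, te_ms, field_strength = 3) {
  arr <- array(smat, dim = c(nrow(smat), 1, 1, ncol(smat)))
  magdensity:::new_echo_series(arr, te_ms, "fixture", field_strength)
}

# Expected noiseless amplitudes for a tissue voxel under a profile.
tissue_amplitudes <- function(v_water, profile) {
  w_w <- steady_state_weight(profile$water_t1, profile)
  w_f <- steady_state_weight(profile$fat_t1, profile)
  c(a_w = v_water * profile$water_proton_density * w_w,
    a_f = (1 - v_water) * profile$fat_proton_density * w_f)
}

# Dense grid search + exact least squares over the field value: the
# brute-force oracle for the IDEAL solver.
grid_search_ideal <- function(s, te_ms, df_hz, psi_grid = seq(-100, 100, 0.1)) {
  te <- te_ms / 1000
  A <- cbind(rep(1 + 0i, length(te)), exp(2i * pi * df_hz * te))
  P <- solve(Conj(t(A)) %*% A, Conj(t(A)))
  best <- list(resid = Inf)
  for (psi in psi_grid) {
    d <- s * exp(-2i * pi * psi * te)
    amp <- P %*% d
    r <- sum(Mod(d - A %*% amp)^2)
    if (r < best$resid)
      best <- list(resid = r, psi = psi, water = amp[1], fat = amp[2])
  }
  best
}
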
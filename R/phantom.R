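# Tissue label codes used by every phantom volume.
TISSUE_LABELS <- c(air = 0L, adipose = 1L, fibroglandular = 2L,
                   pectoral_muscle = 3L, skin = 4L)

# Proton gyromagnetic ratio / 2pi (MHz/T) and the main fat resonance offset
# relative to water (ppm, single-peak model).
GAMMA_MHZ_PER_T <- 42.577
FAT_SHIFT_PPM <- -3.4

#' Chemical-shift frequency of the fat resonance
#'
#' Frequency offset (Hz) of the dominant fat peak relative to water at a
#' given main field strength, using the single-peak fat model at -3.4 ppm.
#'
#' @param field_strength Main magnetic field, tesla.
#' @return Offset in Hz (negative: fat precesses slower than water).
#' @examples
#' fat_frequency_offset(1.5)  # about -217 Hz
#' fat_frequency_offset(3)    # about -434 Hz
#' @export
fat_frequency_offset <- function(field_strength) {
  stopifnot(is.numeric(field_strength), field_strength > 0)
  FAT_SHIFT_PPM * 1e-6 * GAMMA_MHZ_PER_T * 1e6 * field_strength
}

#' Construct a scanner acquisition/bias profile
#'
#' Bundles the acquisition parameters of one scanner (echo times, flip
#' angle, repetition time, field strength) with the signal-bias parameters
#' the simulator injects: relative proton densities, T1 values entering the
#' spoiled-GRE saturation factor, residual water content of adipose tissue,
#' constant and linear echo-phase errors, complex noise level, and an
#' apparent R2* decay rate.
#'
#' @param name Text label for the scanner.
#' @param field_strength Main field, tesla.
#' @param echo_times Strictly increasing echo times, ms; at least three.
#' @param flip_angle Excitation flip angle, degrees, in (0, 90].
#' @param repetition_time TR, ms.
#' @param voxel_size Length-3 voxel dimensions, mm.
#' @param fat_t1,water_t1 Longitudinal relaxation times, ms.
#' @param fat_proton_density,water_proton_density Relative proton densities
#'   (unitless, 1 = reference).
#' @param adipose_residual_water Volume fraction of water in adipose tissue,
#'   in [0, 0.5).
#' @param phase0 Constant echo-phase error, rad.
#' @param phase1 Linear echo-phase error, rad per echo index (0-based).
#' @param noise_sd Complex Gaussian noise standard deviation per channel,
#'   as a fraction of unit signal amplitude.
#' @param r2star Apparent transverse decay rate, 1/s.
#' @return An object of class `scanner_profile`.
#' @seealso [scanner_presets()]
#' @export
scanner_profile <- function(name, field_strength, echo_times, flip_angle,
                            repetition_time, voxel_size = c(2, 2, 4),
                            fat_t1 = 385, water_t1 = 1450,
                            fat_proton_density = 1,
                            water_proton_density = 1,
                            adipose_residual_water = 0.10,
                            phase0 = 0, phase1 = 0,
                            noise_sd = 0, r2star = 0) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(field_strength) || field_strength <= 0)
    stop("field_strength must be positive")
  if (length(echo_times) < 3L || any(diff(echo_times) <= 0))
    stop("echo_times must be strictly increasing with at least 3 echoes")
  if (flip_angle <= 0 || flip_angle > 90)
    stop("flip_angle must lie in (0, 90] degrees")
  if (repetition_time <= 0) stop("repetition_time must be positive")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be three positive lengths (mm)")
  if (adipose_residual_water < 0 || adipose_residual_water >= 0.5)
    stop("adipose_residual_water must lie in [0, 0.5)")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (r2star < 0) stop("r2star must be non-negative")
  structure(list(
    name = name, field_strength = field_strength,
    echo_times = as.numeric(echo_times), flip_angle = flip_angle,
    repetition_time = repetition_time, voxel_size = as.numeric(voxel_size),
    fat_t1 = fat_t1, water_t1 = water_t1,
    fat_proton_density = fat_proton_density,
    water_proton_density = water_proton_density,
    adipose_residual_water = adipose_residual_water,
    phase0 = phase0, phase1 = phase1,
    noise_sd = noise_sd, r2star = r2star
  ), class = "scanner_profile")
}

#' @export
print.scanner_profile <- function(x, ...) {
  cat(sprintf("<scanner_profile '%s'>  %.1f T, flip %g deg, TR %g ms\n",
              x$name, x$field_strength, x$flip_angle, x$repetition_time))
  cat("  TE (ms):", paste(format(x$echo_times), collapse = ", "), "\n")
  cat(sprintf("  bias: T1 fat/water %g/%g ms, PD fat/water %g/%g, residual water %.2f\n",
              x$fat_t1, x$water_t1, x$fat_proton_density,
              x$water_proton_density, x$adipose_residual_water))
  cat(sprintf("  phase0 %g rad, phase1 %g rad/echo, noise_sd %g, R2* %g 1/s\n",
              x$phase0, x$phase1, x$noise_sd, x$r2star))
  invisible(x)
}

#' Preset profiles for the three study scanners
#'
#' Returns acquisition profiles for the two 3T scanners ("prisma",
#' "mmr") and the 1.5T scanner ("signa"). Echo times, flip angles and
#' repetition times follow the clinical six-echo gradient-echo protocols:
#' the 3T scanners share echo times 1.37-8.81 ms at a 6 degree flip,
#' the 1.5T scanner uses 2.88-18.66 ms at 12 degrees.
#'
#' Bias parameters are simulator defaults: tissue T1 values typical of
#' adipose and fibroglandular tissue at each field strength, unit proton
#' densities, 10% residual water in adipose tissue, and modest constant +
#' linear echo-phase errors. The "signa" preset additionally carries an
#' apparent R2* of 50 1/s (T2* 20 ms) and a relative water proton-density
#' scaling of 1.4; combined with its much longer echo train these make its
#' uncorrected density measurements deviate from the 3T presets by a
#' couple of percentage points, emulating the order of magnitude of
#' cross-vendor disagreement the method is designed to calibrate away.
#' This is an emulation preset, not a physical claim about any scanner.
#'
#' @return Named list of three [scanner_profile()] objects.
#' @examples
#' names(scanner_presets())
#' scanner_presets()$signa$echo_times
#' @export
scanner_presets <- function() {
  list(
    prisma = scanner_profile(
      name = "prisma", field_strength = 3,
      echo_times = c(1.37, 2.66, 4.92, 6.15, 7.38, 8.81),
      flip_angle = 6, repetition_time = 21.0,
      voxel_size = c(1.97, 1.97, 4),
      fat_t1 = 385, water_t1 = 1450,
      phase0 = 0.30, phase1 = 0.05,
      noise_sd = 0, r2star = 0),
    mmr = scanner_profile(
      name = "mmr", field_strength = 3,
      echo_times = c(1.37, 2.66, 4.92, 6.15, 7.38, 8.81),
      flip_angle = 6, repetition_time = 21.0,
      voxel_size = c(1.97, 1.97, 4),
      fat_t1 = 385, water_t1 = 1450,
      phase0 = 0.22, phase1 = 0.04,
      noise_sd = 0, r2star = 0),
    signa = scanner_profile(
      name = "signa", field_strength = 1.5,
      echo_times = c(2.88, 6.04, 9.20, 12.35, 15.51, 18.66),
      flip_angle = 12, repetition_time = 22.4,
      voxel_size = c(0.625, 0.625, 2),
      fat_t1 = 365, water_t1 = 1300,
      water_proton_density = 1.4,
      phase0 = -0.35, phase1 = 0.06,
      noise_sd = 0, r2star = 50)
  )
}

#' Spoiled gradient-echo steady-state saturation factor
#'
#' Relative signal amplitude of a tissue with longitudinal relaxation time
#' `t1` under the profile's flip angle and repetition time:
#' sin(a) (1 - E1) / (1 - cos(a) E1) with E1 = exp(-TR/T1). Shorter T1
#' (fat) is saturated less than longer T1 (water), which is one of the
#' signal biases the Eq.-style linear correction later removes.
#'
#' @param t1 Longitudinal relaxation time, ms; positive.
#' @param profile A [scanner_profile()] supplying flip angle and TR.
#' @return Relative amplitude in (0, 1].
#' @export
steady_state_weight <- function(t1, profile) {
  if (!is.numeric(t1) || any(t1 <= 0)) stop("t1 must be positive")
  a <- profile$flip_angle * pi / 180
  e1 <- exp(-profile$repetition_time / t1)
  sin(a) * (1 - e1) / (1 - cos(a) * e1)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

# Smooth random scalar field inside a breast: a sum of Gaussian bumps with
# seeded centres/widths plus a tiny jitter to break threshold ties.
random_blob_field <- function(coords, centre, radii, n_bumps = 8) {
  field <- numeric(nrow(coords))
  for (k in seq_len(n_bumps)) {
    ctr <- centre + (stats::runif(3) - 0.5) * 1.4 * radii
    width <- (0.15 + 0.25 * stats::runif(1)) * radii
    amp <- stats::runif(1, 0.4, 1) * sample(c(-1, 1), 1)
    d2 <- ((coords[, 1] - ctr[1]) / width[1])^2 +
          ((coords[, 2] - ctr[2]) / width[2])^2 +
          ((coords[, 3] - ctr[3]) / width[3])^2
    field <- field + amp * exp(-d2 / 2)
  }
  field + stats::rnorm(nrow(coords), sd = 1e-6)
}

#' Generate a bilateral digital breast phantom
#'
#' Builds a voxelised axial (prone) geometry: a posterior pectoral-muscle
#' slab, two half-ellipsoid breasts attached to it, a thin skin shell, a
#' subcutaneous-fat rim just under the skin, and a breast core whose voxels
#' are split between fibroglandular and adipose tissue so that the
#' fibroglandular fraction inside each breast mask matches
#' `fibroglandular_fraction` to within one voxel. Fibroglandular tissue is
#' placed by thresholding a smooth seeded random field, giving spatially
#' coherent (blob-like) dense tissue.
#'
#' True volumetric water fractions are 1 in fibroglandular and muscle
#' voxels, `adipose_residual_water` in adipose voxels (fat and water
#' fractions sum to 1 per voxel), and `skin_water` in skin. Reference
#' regions of "pure" fat (subcutaneous rim) and "pure" water (pectoral
#' muscle) are marked for correction-factor estimation. A smooth low-order
#' polynomial off-resonance field with peak `field_map_peak` Hz emulates B0
#' inhomogeneity.
#'
#' @param shape Length-3 voxel grid, each extent at least 8.
#' @param fibroglandular_fraction Target fibroglandular volume fraction of
#'   the breast core, in [0, 1].
#' @param seed Integer seed; the phantom is deterministic given the seed.
#' @param adipose_residual_water True water volume fraction of adipose
#'   voxels, in [0, 0.5).
#' @param field_map_peak Peak absolute off-resonance, Hz.
#' @param skin_water Water volume fraction assigned to skin voxels.
#' @return An object of class `breast_phantom` with elements `labels`,
#'   `v_water_true`, `breast_mask_left`, `breast_mask_right`,
#'   `ref_fat_roi`, `ref_water_roi`, `field_map_true`, `seed`, and the
#'   achieved per-breast fibroglandular fractions
#'   `density_true` (named `L`, `R`, in percent).
#' @examples
#' ph <- make_phantom(c(32, 32, 10), 0.6, seed = 1)
#' ph$density_true
#' @export
make_phantom <- function(shape, fibroglandular_fraction, seed,
                         adipose_residual_water = 0.10,
                         field_map_peak = 30, skin_water = 0.7) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("shape must be three extents, each at least 8")
  if (!is.numeric(fibroglandular_fraction) ||
      fibroglandular_fraction < 0 || fibroglandular_fraction > 1)
    stop("fibroglandular_fraction must lie in [0, 1]")

  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  labels <- array(TISSUE_LABELS[["air"]], dim = shape)

  # Axial prone convention: x left-right, y anterior (low) to posterior
  # (high), z inferior-superior. Chest wall occupies the posterior slab.
  chest_y0 <- ceiling(0.78 * ny)
  labels[, chest_y0:ny, ] <- TISSUE_LABELS[["pectoral_muscle"]]

  xs <- seq_len(nx); ys <- seq_len(ny); zs <- seq_len(nz)
  grid <- expand.grid(x = xs, y = ys, z = zs)
  centres <- list(L = c(0.28 * nx, chest_y0, 0.5 * nz),
                  R = c(0.72 * nx, chest_y0, 0.5 * nz))
  radii <- c(0.20 * nx, 0.72 * chest_y0, 0.38 * nz)

  masks <- list(); fg_frac <- c(L = NA_real_, R = NA_real_)
  subcut_all <- array(FALSE, dim = shape)

  with_seed(seed, {
    for (side in c("L", "R")) {
      ctr <- centres[[side]]
      v <- sqrt(((grid$x - ctr[1]) / radii[1])^2 +
                ((grid$y - ctr[2]) / radii[2])^2 +
                ((grid$z - ctr[3]) / radii[3])^2)
      inside <- v <= 1 & grid$y <= ctr[2]
      skin <- inside & v > 0.90
      subcut <- inside & v <= 0.90 & v > 0.72
      core <- inside & v <= 0.72

      idx_skin <- which(skin); idx_sub <- which(subcut); idx_core <- which(core)
      labels[idx_skin] <- TISSUE_LABELS[["skin"]]
      labels[idx_sub] <- TISSUE_LABELS[["adipose"]]
      subcut_all[idx_sub] <- TRUE

      # Spatially coherent fibroglandular placement with an exact count.
      n_core <- length(idx_core)
      if (n_core == 0L) stop("grid too small: breast core is empty")
      n_fg <- round(fibroglandular_fraction * n_core)
      field <- random_blob_field(as.matrix(grid[idx_core, ]), ctr, radii)
      fg_sel <- idx_core[order(field, decreasing = TRUE)[seq_len(n_fg)]]
      labels[idx_core] <- TISSUE_LABELS[["adipose"]]
      if (n_fg > 0L) labels[fg_sel] <- TISSUE_LABELS[["fibroglandular"]]

      m <- array(FALSE, dim = shape); m[idx_core] <- TRUE
      masks[[side]] <- m
      fg_frac[side] <- n_fg / n_core
    }
  })

  v_water <- array(0, dim = shape)
  v_water[labels == TISSUE_LABELS[["adipose"]]] <- adipose_residual_water
  v_water[labels == TISSUE_LABELS[["fibroglandular"]]] <- 1
  v_water[labels == TISSUE_LABELS[["pectoral_muscle"]]] <- 1
  v_water[labels == TISSUE_LABELS[["skin"]]] <- skin_water

  # Reference ROIs: a compact patch of subcutaneous fat in the left breast
  # and a central block of pectoral muscle posterior to the breasts.
  ref_fat <- array(FALSE, dim = shape)
  sub_idx <- which(subcut_all & grid$x <= 0.5 * nx)
  if (length(sub_idx) == 0L) sub_idx <- which(subcut_all)
  d_anchor <- (grid$x[sub_idx] - centres$L[1])^2 +
              (grid$y[sub_idx] - 0.35 * chest_y0)^2 +
              (grid$z[sub_idx] - 0.5 * nz)^2
  ref_fat[sub_idx[order(d_anchor)[seq_len(min(200L, length(sub_idx)))]]] <- TRUE

  ref_water <- array(FALSE, dim = shape)
  mus_idx <- which(labels == TISSUE_LABELS[["pectoral_muscle"]] &
                   grid$x >= 0.3 * nx & grid$x <= 0.7 * nx &
                   grid$y <= chest_y0 + 0.4 * (ny - chest_y0))
  d_anchor <- (grid$x[mus_idx] - 0.5 * nx)^2 +
              (grid$z[mus_idx] - 0.5 * nz)^2
  ref_water[mus_idx[order(d_anchor)[seq_len(min(200L, length(mus_idx)))]]] <- TRUE

  # Smooth low-order polynomial off-resonance ramp, |psi| <= field_map_peak.
  xt <- 2 * (grid$x - 1) / (nx - 1) - 1
  yt <- 2 * (grid$y - 1) / (ny - 1) - 1
  psi <- field_map_peak * (0.5 * xt + 0.3 * yt + 0.2 * xt * yt)
  field_map <- array(psi, dim = shape)

  structure(list(
    labels = labels, v_water_true = v_water,
    breast_mask_left = masks$L, breast_mask_right = masks$R,
    ref_fat_roi = ref_fat, ref_water_roi = ref_water,
    field_map_true = field_map, seed = as.integer(seed),
    density_true = 100 * fg_frac
  ), class = "breast_phantom")
}

#' @export
print.breast_phantom <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<breast_phantom %dx%dx%d>  seed %d\n", d[1], d[2], d[3], x$seed))
  cat(sprintf("  breast core voxels L/R: %d/%d; fibroglandular %.1f%%/%.1f%%\n",
              sum(x$breast_mask_left), sum(x$breast_mask_right),
              x$density_true[["L"]], x$density_true[["R"]]))
  invisible(x)
}

# Construct an echo_series object (internal; I/O and the simulator both
# funnel through here so invariants are checked in one place).
new_echo_series <- function(data, echo_times, scanner_name = "",
                            field_strength = NA_real_, provenance = "") {
  if (length(dim(data)) != 4L) stop("echo data must be 4-D (x, y, z, echo)")
  if (dim(data)[4] != length(echo_times))
    stop("fourth extent must equal the number of echo times")
  if (!all(is.finite(Re(data))) || !all(is.finite(Im(data))))
    stop("echo data must be finite")
  structure(list(data = data, echo_times = as.numeric(echo_times),
                 scanner_name = scanner_name,
                 field_strength = field_strength,
                 provenance = provenance),
            class = "echo_series")
}

#' @export
print.echo_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<echo_series '%s'>  %dx%dx%d voxels, %d echoes\n",
              x$scanner_name, d[1], d[2], d[3], d[4]))
  cat("  TE (ms):", paste(format(x$echo_times), collapse = ", "),
      sprintf(" B0 %s T\n", format(x$field_strength)))
  if (nzchar(x$provenance)) cat("  ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Simulate a multi-echo gradient-echo acquisition of a phantom
#'
#' Forward model, per voxel and echo n (0-based):
#' \deqn{S_n = (A_w + A_f e^{i 2\pi \Delta f TE_n}) e^{i 2\pi \psi TE_n}
#'       e^{-TE_n R_2^*} e^{i(\phi_0 + \phi_1 n)} + \epsilon_n}
#' where the water/fat amplitudes are the true volume fractions scaled by
#' relative proton density and the spoiled-GRE saturation factor for the
#' tissue T1, \eqn{\Delta f} is the single-peak fat offset for the
#' profile's field strength, \eqn{\psi} is the phantom's off-resonance
#' field, and \eqn{\epsilon} is complex Gaussian noise with per-channel
#' standard deviation `profile$noise_sd` (omitted when zero).
#'
#' @param phantom A [make_phantom()] result.
#' @param profile A [scanner_profile()].
#' @param seed Integer seed for the noise stream.
#' @return An `echo_series` object.
#' @export
simulate_echoes <- function(phantom, profile, seed = 1) {
  if (!inherits(phantom, "breast_phantom")) stop("phantom must be a breast_phantom")
  if (!inherits(profile, "scanner_profile")) stop("profile must be a scanner_profile")
  shape <- dim(phantom$labels)
  te_s <- profile$echo_times / 1000
  n_echo <- length(te_s)

  tissue <- phantom$labels != TISSUE_LABELS[["air"]]
  v_w <- phantom$v_water_true * tissue
  v_f <- (1 - phantom$v_water_true) * tissue

  w_w <- steady_state_weight(profile$water_t1, profile)
  w_f <- steady_state_weight(profile$fat_t1, profile)
  a_w <- v_w * profile$water_proton_density * w_w
  a_f <- v_f * profile$fat_proton_density * w_f

  df <- fat_frequency_offset(profile$field_strength)
  psi <- phantom$field_map_true

  data <- array(0i, dim = c(shape, n_echo))
  for (n in seq_len(n_echo)) {
    te <- te_s[n]
    s <- (a_w + a_f * exp(2i * pi * df * te)) *
      exp(2i * pi * psi * te) * exp(-te * profile$r2star) *
      exp(1i * (profile$phase0 + profile$phase1 * (n - 1L)))
    data[, , , n] <- s
  }
  if (profile$noise_sd > 0) {
    nv <- prod(dim(data))
    noise <- with_seed(seed, complex(real = stats::rnorm(nv, sd = profile$noise_sd),
                                     imaginary = stats::rnorm(nv, sd = profile$noise_sd)))
    data <- data + array(noise, dim = dim(data))
  }
  new_echo_series(data, profile$echo_times, profile$name,
                  profile$field_strength,
                  provenance = sprintf("simulated: phantom seed %d, noise seed %d",
                                       phantom$seed, as.integer(seed)))
}

#' Simulate a multi-scanner cohort
#'
#' Draws one phantom per subject with a target density sampled uniformly
#' from `density_range` (percent) and images each phantom under every
#' profile. The ground-truth table records the achieved per-breast
#' fibroglandular fraction (identical across scanners, since the anatomy
#' is shared).
#'
#' @param n_subjects Number of subjects, at least 2.
#' @param profiles Non-empty list of [scanner_profile()] objects.
#' @param density_range Length-2 percent interval for the target density.
#' @param seed Integer master seed; subject phantoms and per-scanner noise
#'   streams are derived from it deterministically.
#' @param shape Phantom grid passed to [make_phantom()].
#' @return List with `phantoms` (per subject), `echoes` (nested
#'   subject -> scanner), and `truth`, a data frame with columns
#'   `subject_id`, `side`, `scanner`, `true_density_percent`
#'   (2 x n_subjects rows per scanner).
#' @export
cohort_simulate <- function(n_subjects, profiles = scanner_presets(),
                            density_range = c(40, 80), seed = 1,
                            shape = c(32, 32, 10)) {
  if (n_subjects < 2) stop("n_subjects must be at least 2")
  if (length(profiles) == 0) stop("at least one scanner profile is required")
  if (length(density_range) != 2 || density_range[1] > density_range[2] ||
      density_range[1] < 0 || density_range[2] > 100)
    stop("density_range must be an increasing percent interval within [0, 100]")
  seed <- as.integer(seed)

  targets <- with_seed(seed,
    stats::runif(n_subjects, density_range[1], density_range[2]))

  phantoms <- vector("list", n_subjects)
  echoes <- vector("list", n_subjects)
  rows <- list()
  for (i in seq_len(n_subjects)) {
    sid <- sprintf("S%02d", i)
    ph <- make_phantom(shape, targets[i] / 100, seed = seed + i * 101L)
    phantoms[[i]] <- ph
    echoes[[i]] <- lapply(seq_along(profiles), function(j)
      simulate_echoes(ph, profiles[[j]], seed = seed + i * 101L + j))
    names(echoes[[i]]) <- vapply(profiles, `[[`, "", "name")
    for (j in seq_along(profiles)) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = sid, side = c("L", "R"),
        scanner = profiles[[j]]$name,
        true_density_percent = as.numeric(ph$density_true[c("L", "R")]),
        stringsAsFactors = FALSE)
    }
  }
  names(phantoms) <- sprintf("S%02d", seq_len(n_subjects))
  names(echoes) <- names(phantoms)
  list(phantoms = phantoms, echoes = echoes,
       truth = do.call(rbind, rows))
}
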
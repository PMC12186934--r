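#' Combine magnitude and phase volumes into a complex echo series
#'
#' @param magnitude 4-D non-negative array (x, y, z, echo).
#' @param phase 4-D array of phases, rad, congruent with `magnitude`.
#' @param echo_times Echo times, ms, one per 4th-dimension slab.
#' @param scanner_name Optional text label.
#' @param field_strength Main field, tesla (needed later for the fat
#'   frequency offset).
#' @return An `echo_series` with data `magnitude * exp(1i * phase)`.
#' @export
combine_mag_phase <- function(magnitude, phase, echo_times,
                              scanner_name = "", field_strength = NA_real_) {
  if (!identical(dim(magnitude), dim(phase)))
    stop("magnitude and phase grids must be congruent")
  if (any(magnitude < 0)) stop("magnitude must be non-negative")
  new_echo_series(magnitude * exp(1i * phase), echo_times, scanner_name,
                  field_strength, provenance = "combined magnitude/phase")
}

# Resolve the fat frequency offset for a series, preferring an explicit
# profile over the series' own field strength.
series_fat_offset <- function(series, profile = NULL) {
  b0 <- if (!is.null(profile)) profile$field_strength else series$field_strength
  if (is.null(b0) || is.na(b0))
    stop("field strength unavailable: supply a scanner profile or a sidecar value")
  fat_frequency_offset(b0)
}

#' Solver settings for the fat-water decomposition
#'
#' @param tol Field-map convergence tolerance, Hz.
#' @param max_iter Maximum iterations per field-map start.
#' @param smooth_sigma Gaussian sigma (voxels) for optional field-map
#'   smoothing between sweeps; 0 disables smoothing.
#' @param starts Optional explicit field-map starting values, Hz (for
#'   example `c(0, df/2)` to bracket the fat-water swap). The iteration
#'   then runs once per start and, per voxel, the candidate with the
#'   lower residual wins; residual differences below 0.01% of the voxel's
#'   signal energy are treated as indistinguishable and the tie goes to
#'   the smaller absolute field value.
#' @param init Initialisation scheme when `starts` is `NULL`: `"grid"`
#'   (default) seeds each voxel from a coarse residual search on a 10 Hz
#'   grid over `+/- grid_range` Hz, preferring the smallest absolute
#'   field among near-equivalent minima — this keeps large field
#'   excursions inside the convergence basin and resolves the swap alias
#'   of uniformly spaced echo trains towards the physically modest field;
#'   `"starts"` uses the pair 0 and half the fat offset.
#' @param grid_range Half-width (Hz) of the `"grid"` initialisation.
#' @return List of class `ideal_options`.
#' @export
ideal_options <- function(tol = 0.01, max_iter = 50, smooth_sigma = 0,
                          starts = NULL, init = c("grid", "starts"),
                          grid_range = 120) {
  init <- match.arg(init)
  stopifnot(tol > 0, max_iter >= 1, smooth_sigma >= 0, grid_range > 0)
  structure(list(tol = tol, max_iter = max_iter,
                 smooth_sigma = smooth_sigma, starts = starts,
                 init = init, grid_range = grid_range),
            class = "ideal_options")
}

# Coarse per-voxel field initialisation: exact amplitude least squares on a
# 10 Hz grid of field values. Among grid points whose residual is within a
# band of the per-voxel minimum (25% relative plus a 1e-6 energy floor),
# the smallest absolute field wins. The band absorbs both the exact alias
# of the fat-water swap under a uniformly spaced echo train and the
# residual inflation caused by unmodeled transverse decay, in either case
# preferring the physically modest field interpretation.
ideal_grid_init <- function(smat, te_s, df, grid_range) {
  n_vox <- nrow(smat); n_echo <- ncol(smat)
  cn <- exp(2i * pi * df * te_s)
  A <- cbind(rep(1 + 0i, n_echo), cn)
  P <- solve(Conj(t(A)) %*% A, Conj(t(A)))
  G <- A %*% P                       # E x E projection onto the model space
  grid <- seq(-grid_range, grid_range, by = 10)
  rmat <- matrix(NA_real_, n_vox, length(grid))
  for (j in seq_along(grid)) {
    D <- smat * matrix(exp(-2i * pi * grid[j] * te_s), n_vox, n_echo,
                       byrow = TRUE)
    R <- D - D %*% t(G)
    rmat[, j] <- rowSums(Re(R * Conj(R)))
  }
  energy <- rowSums(Re(smat * Conj(smat)))
  r_min <- do.call(pmin, as.data.frame(rmat))
  thr <- 1.25 * r_min + 1e-6 * pmax(energy, .Machine$double.eps)
  best_p <- rep(NA_real_, n_vox)
  for (j in order(abs(grid), grid)) {
    take <- is.na(best_p) & rmat[, j] <= thr
    best_p[take] <- grid[j]
  }
  best_p[is.na(best_p)] <- 0
  best_p
}

# Core per-voxel IDEAL iteration, vectorised over voxels.
#
# smat: V x E complex matrix; te_s: echo times in seconds; df: fat offset Hz.
# Alternates an exact linear least-squares solve for the complex water/fat
# amplitudes (given the field map) with a Gauss-Newton update of the field
# map on the amplitude-eliminated residual.
ideal_core <- function(smat, te_s, df, psi_init, tol, max_iter) {
  n_vox <- nrow(smat); n_echo <- ncol(smat)
  cn <- exp(2i * pi * df * te_s)
  A <- cbind(rep(1 + 0i, n_echo), cn)
  sv <- svd(A)$d
  if (min(sv) < 1e-8 * max(sv))
    stop("echo configuration is numerically singular (echoes effectively in-phase)")
  P <- solve(Conj(t(A)) %*% A, Conj(t(A)))  # 2 x E pseudo-inverse

  psi <- rep(psi_init, length.out = n_vox)
  iters <- rep(NA_integer_, n_vox)
  te_row <- matrix(te_s, n_vox, n_echo, byrow = TRUE)
  two_pi_te <- 2 * pi * te_row

  amp <- NULL; resid2 <- NULL
  for (k in seq_len(max_iter)) {
    D <- smat * exp(-2i * pi * psi * te_row)
    amp <- D %*% t(P)            # V x 2: columns water, fat
    M <- amp %*% t(A)            # predicted demodulated signal
    R <- D - M
    G <- (1i * two_pi_te) * M    # d(model)/d(psi)
    den <- rowSums(Re(G * Conj(G)))
    num <- rowSums(Re(Conj(G) * R))
    dpsi <- ifelse(den > 0, num / den, 0)
    psi <- psi + dpsi
    newly <- is.na(iters) & abs(dpsi) < tol
    iters[newly] <- k
    if (all(abs(dpsi) < tol)) break
  }
  iters[is.na(iters)] <- max_iter
  D <- smat * exp(-2i * pi * psi * te_row)
  amp <- D %*% t(P)
  R <- D - amp %*% t(A)
  resid2 <- rowSums(Re(R * Conj(R)))
  list(water = amp[, 1], fat = amp[, 2], psi = psi,
       iters = iters, resid2 = resid2)
}

# Separable 3-D Gaussian smoothing (truncated at 3 sigma), used for the
# optional field-map regularisation between solver sweeps.
gaussian_smooth_3d <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  half <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(seq(-half, half), sd = sigma)
  kern <- kern / sum(kern)
  smooth_axis <- function(v, axis) {
    d <- dim(v)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    vp <- aperm(v, perm)
    dp <- dim(vp)
    m <- matrix(vp, nrow = dp[1])
    # reflect-pad along the smoothing axis
    pad_top <- m[pmin(dp[1], seq(half, 1)), , drop = FALSE]
    pad_bot <- m[pmax(1L, seq(dp[1], dp[1] - half + 1)), , drop = FALSE]
    mp <- rbind(pad_top, m, pad_bot)
    out <- matrix(0, nrow = dp[1], ncol = ncol(m))
    for (j in seq_along(kern))
      out <- out + kern[j] * mp[seq_len(dp[1]) + (j - 1L), , drop = FALSE]
    aperm(array(out, dp), order(perm))
  }
  for (ax in 1:3) vol <- smooth_axis(vol, ax)
  vol
}

#' IDEAL fat-water decomposition of a multi-echo series
#'
#' Per voxel, jointly estimates complex water and fat amplitudes and the
#' off-resonance field by iterating (a) an exact linear least-squares
#' solve for the amplitudes given the current field value, using the
#' design matrix with rows (1, exp(i 2 pi df TE_n)) after demodulating the
#' field term, and (b) a Gauss-Newton field update, until the field change
#' drops below `options$tol` Hz or `options$max_iter` is reached. By
#' default each voxel's field is seeded from a coarse residual search
#' that prefers the smallest absolute field among near-equivalent minima,
#' which both keeps large field excursions inside the convergence basin
#' and resolves the fat-water swap ambiguity towards the physically
#' modest branch; explicit multi-starts are available instead via
#' [ideal_options()].
#'
#' Because the true water and fat amplitudes share a common phase, the
#' complex estimates are projected onto their joint phase; the real parts
#' of that projection give signed amplitudes whose ratio is free of the
#' magnitude noise floor. The returned maps store non-negative water/fat
#' magnitudes and a fat fraction clamped to [0, 1]; the signed fat
#' fraction is kept alongside for reference-region sampling.
#'
#' @param series An `echo_series` (at least 3 echoes).
#' @param profile Optional [scanner_profile()]; if omitted the series must
#'   carry a field strength.
#' @param options An [ideal_options()] list.
#' @return An object of class `fat_water_maps` with elements `water`,
#'   `fat`, `field_map` (Hz), `fat_fraction` (in [0,1], `NA` where no
#'   signal), `fat_fraction_signed`, `valid`, `iterations_used`,
#'   `residual`.
#' @export
ideal_decompose <- function(series, profile = NULL, options = ideal_options()) {
  if (!inherits(series, "echo_series")) stop("series must be an echo_series")
  n_echo <- length(series$echo_times)
  if (n_echo < 3) stop("at least 3 echoes are required")
  df <- series_fat_offset(series, profile)
  te_s <- series$echo_times / 1000
  shape <- dim(series$data)[1:3]
  smat <- matrix(series$data, nrow = prod(shape), ncol = n_echo)

  if (identical(options$init, "grid") && is.null(options$starts)) {
    psi0 <- ideal_grid_init(smat, te_s, df, options$grid_range)
    fits <- list(ideal_core(smat, te_s, df, psi0,
                            options$tol, options$max_iter))
  } else {
    starts <- options$starts
    if (is.null(starts)) starts <- c(0, df / 2)
    fits <- lapply(starts, function(p0)
      ideal_core(smat, te_s, df, p0, options$tol, options$max_iter))
  }

  best <- fits[[1]]
  if (length(fits) > 1) {
    # Swap-ambiguity resolution: residual differences below 0.01% of the
    # voxel's signal energy are indistinguishable (a uniformly spaced echo
    # train makes the swapped branch an exact alias), so such ties go to
    # the smaller absolute field value.
    energy <- rowSums(Re(smat * Conj(smat)))
    thr <- 1e-4 * pmax(energy, .Machine$double.eps)
    for (f in fits[-1]) {
      tie <- abs(f$resid2 - best$resid2) <= thr
      take <- (f$resid2 < best$resid2 & !tie) |
              (tie & abs(f$psi) < abs(best$psi))
      if (any(take)) {
        best$water[take] <- f$water[take]
        best$fat[take] <- f$fat[take]
        best$psi[take] <- f$psi[take]
        best$iters[take] <- f$iters[take]
        best$resid2[take] <- f$resid2[take]
      }
    }
  }

  if (options$smooth_sigma > 0) {
    psi_s <- gaussian_smooth_3d(array(best$psi, shape), options$smooth_sigma)
    refit <- ideal_core(smat, te_s, df, as.vector(psi_s),
                        options$tol, options$max_iter)
    best <- refit
  }

  total <- best$water + best$fat
  phi <- Arg(total)
  w_proj <- Re(best$water * exp(-1i * phi))
  f_proj <- Re(best$fat * exp(-1i * phi))
  denom <- w_proj + f_proj            # equals |water + fat| >= 0
  valid <- denom > .Machine$double.eps
  ff_signed <- ifelse(valid, f_proj / denom, NA_real_)
  water_mag <- pmax(w_proj, 0)
  fat_mag <- pmax(f_proj, 0)
  ff <- ifelse(valid, pmin(pmax(ff_signed, 0), 1), NA_real_)

  structure(list(
    water = array(water_mag, shape),
    fat = array(fat_mag, shape),
    field_map = array(best$psi, shape),
    fat_fraction = array(ff, shape),
    fat_fraction_signed = array(ff_signed, shape),
    valid = array(valid, shape),
    iterations_used = array(best$iters, shape),
    residual = array(best$resid2, shape),
    fat_offset_hz = df
  ), class = "fat_water_maps")
}

#' @export
print.fat_water_maps <- function(x, ...) {
  d <- dim(x$water)
  cat(sprintf("<fat_water_maps %dx%dx%d>  fat offset %.1f Hz\n",
              d[1], d[2], d[3], x$fat_offset_hz))
  cat(sprintf("  valid voxels: %d / %d; median iterations %g\n",
              sum(x$valid), length(x$valid),
              stats::median(x$iterations_used[x$valid])))
  invisible(x)
}

#' Fat-fraction map from water/fat magnitudes
#'
#' FF = fat / (fat + water); voxels with zero total signal are flagged
#' invalid (`NA`) and excluded from all downstream summaries.
#'
#' @param maps A `fat_water_maps` object.
#' @return 3-D array in [0, 1] with `NA` at invalid voxels.
#' @export
fat_fraction_map <- function(maps) {
  if (!inherits(maps, "fat_water_maps")) stop("maps must be fat_water_maps")
  total <- maps$water + maps$fat
  ifelse(total > .Machine$double.eps, maps$fat / total, NA_real_)
}

#' Estimate shared constant and linear echo-phase errors
#'
#' Estimates a spatially constant phase error of the form
#' phase0 + phase1 * n (n = 0-based echo index) shared by all voxels,
#' by alternating a provisional fat-water fit on a set of high-signal
#' voxels with a least-squares fit of the pooled residual phase trend
#' against (1, n, TE_n); the TE-proportional component belongs to the
#' off-resonance field and is discarded. The constant component is read
#' off the common phase of the fitted amplitudes (true amplitudes are
#' real and positive), the linear component from the part of the echo
#' trend the fat/field model cannot represent.
#'
#' @param series An `echo_series` with at least 3 echoes.
#' @param profile Optional [scanner_profile()] for the field strength.
#' @param mask Optional logical array of voxels to pool; defaults to the
#'   top decile of mean echo magnitude.
#' @param max_sweeps Maximum outer iterations.
#' @return Named numeric vector `c(phase0 = ..., phase1 = ...)` in rad and
#'   rad per echo index.
#' @export
estimate_echo_phase <- function(series, profile = NULL, mask = NULL,
                                max_sweeps = 40) {
  if (!inherits(series, "echo_series")) stop("series must be an echo_series")
  n_echo <- length(series$echo_times)
  if (n_echo < 3) stop("at least 3 echoes are required")
  df <- series_fat_offset(series, profile)
  te_s <- series$echo_times / 1000
  shape <- dim(series$data)[1:3]
  mag <- apply(abs(series$data), 1:3, mean)
  if (is.null(mask)) {
    thr <- stats::quantile(mag, 0.9)
    mask <- mag >= thr
  }
  if (!any(mask)) stop("mask must contain at least one voxel")

  smat <- matrix(series$data, nrow = prod(shape), ncol = n_echo)[which(mask), ,
                                                                 drop = FALSE]
  n_idx <- seq_len(n_echo) - 1
  # The linear-in-echo-index term is only identifiable through the part of
  # n orthogonal to span{1, TE}. For an (almost) uniformly spaced echo
  # train that component vanishes and a linear echo phase is
  # indistinguishable from an off-resonance shift, which the field map
  # absorbs without affecting the fat fraction; in that case the slope is
  # reported as 0 rather than amplified out of noise.
  te_fit <- stats::lm.fit(cbind(1, te_s), n_idx)
  n_orth <- te_fit$residuals
  slope_identifiable <- sqrt(sum(n_orth^2)) > 0.05 * stats::sd(n_idx) * sqrt(n_echo)
  basis <- if (slope_identifiable) cbind(1, n_idx, te_s) else cbind(1, te_s)
  opts <- ideal_options(tol = 1e-6, max_iter = 100)

  phase0 <- 0; phase1 <- 0
  for (sweep in seq_len(max_sweeps)) {
    corr <- exp(-1i * (phase0 + phase1 * n_idx))
    sc <- sweep(smat, 2, corr, `*`)
    fit <- ideal_core(sc, te_s, df, ideal_grid_init(sc, te_s, df, 120),
                      opts$tol, opts$max_iter)
    # constant component: common phase of the fitted amplitudes
    alpha <- Arg(sum(fit$water + fit$fat))
    # linear component: pooled residual phase trend vs (1, n, TE)
    D <- sc * exp(-2i * pi * fit$psi %o% te_s)
    A <- cbind(rep(1 + 0i, n_echo), exp(2i * pi * df * te_s))
    M <- cbind(fit$water, fit$fat) %*% t(A)
    rbar <- Arg(colSums(D * Conj(M)))
    cf <- stats::lm.fit(basis, rbar)$coefficients
    d0 <- alpha + cf[1]
    d1 <- if (slope_identifiable) cf[2] else 0
    phase0 <- phase0 + d0
    phase1 <- phase1 + d1
    if (max(abs(c(d0, d1))) < 1e-10) break
  }
  c(phase0 = unname(phase0), phase1 = unname(phase1))
}

#' Remove constant and linear echo-phase errors
#'
#' Multiplies echo n (0-based) by exp(-i (phase0 + phase1 n)). Magnitudes
#' are unchanged.
#'
#' @param series An `echo_series`.
#' @param phase0 Constant phase, rad.
#' @param phase1 Linear phase, rad per echo index.
#' @return The corrected `echo_series`.
#' @export
apply_phase_correction <- function(series, phase0, phase1) {
  if (!inherits(series, "echo_series")) stop("series must be an echo_series")
  if (!is.finite(phase0) || !is.finite(phase1))
    stop("phase parameters must be finite")
  n_idx <- seq_along(series$echo_times) - 1
  corr <- exp(-1i * (phase0 + phase1 * n_idx))
  for (n in seq_along(n_idx))
    series$data[, , , n] <- series$data[, , , n] * corr[n]
  series$provenance <- paste0(series$provenance,
                              sprintf("; phase-corrected (%0.4g, %0.4g)",
                                      phase0, phase1))
  series
}
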
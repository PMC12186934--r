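#' Sample reference fat-fraction values from pure-tissue regions
#'
#' Returns a robust central value (20%-trimmed mean) of the fat fraction
#' inside a "pure fat" region (subcutaneous fat within the breast) and a
#' "pure water" region (pectoral muscle posterior to the breast). These two
#' observations determine the linear signal-bias correction factors.
#'
#' When given a `fat_water_maps` object, the signed (phase-coherent)
#' fat-fraction channel is sampled, which is unbiased in the presence of
#' noise; a bare numeric fat-fraction array is sampled as-is. Invalid
#' (`NA`) voxels are excluded.
#'
#' @param x A `fat_water_maps` object or a 3-D numeric fat-fraction array.
#' @param fat_roi,water_roi Logical arrays marking the reference regions;
#'   both must be non-empty.
#' @param trim Trimming proportion for the trimmed mean.
#' @return Named numeric vector `c(ff_fat_ref = ..., ff_water_ref = ...)`.
#' @export
sample_reference <- function(x, fat_roi, water_roi, trim = 0.2) {
  ff <- if (inherits(x, "fat_water_maps")) x$fat_fraction_signed else x
  if (!is.array(ff)) stop("x must be fat_water_maps or a numeric array")
  if (!any(fat_roi)) stop("fat reference ROI is empty")
  if (!any(water_roi)) stop("water reference ROI is empty")
  vf <- ff[fat_roi]; vw <- ff[water_roi]
  vf <- vf[!is.na(vf)]; vw <- vw[!is.na(vw)]
  if (length(vf) == 0 || length(vw) == 0)
    stop("reference ROIs contain no valid voxels")
  ff_fat <- mean(vf, trim = trim)
  ff_water <- mean(vw, trim = trim)
  if (ff_fat <= ff_water)
    stop(sprintf(paste0("degenerate reference regions: fat FF (%.3f) must ",
                        "exceed water FF (%.3f); check ROI placement"),
                 ff_fat, ff_water))
  c(ff_fat_ref = ff_fat, ff_water_ref = ff_water)
}

#' Correction factors from pure-tissue fat fractions
#'
#' The per-voxel linear signal model
#' \deqn{S_{fat} = a V_{fat} + b V_{water}, \quad
#'       S_{water} = c V_{fat} + d V_{water}}
#' has two degrees of freedom identifiable from the two reference
#' observations once each pure tissue's total signal is normalised to one
#' (a + c = b + d = 1). Substituting the pure-fat condition
#' (V_fat = 1, V_water = 0) gives a = FF in the fat reference, and the
#' pure-water condition gives b = FF in the water reference, with
#' c = 1 - a and d = 1 - b.
#'
#' @param ff_fat_ref Fat fraction observed in the pure-fat reference.
#' @param ff_water_ref Fat fraction observed in the pure-water reference;
#'   must be smaller than `ff_fat_ref`. Nominally both lie in [0, 1];
#'   signed reference values may fall slightly outside that range when the
#'   acquisition carries transverse decay the decomposition does not
#'   model, and they are retained unclamped (within a 0.25 guard band)
#'   because clamping them would distort the affine correction.
#' @return Object of class `correction_factors` with elements `a`, `b`,
#'   `c`, `d`, `source` ("per-image"), `n_images`.
#' @examples
#' estimate_correction_factors(0.9, 0.05)
#' @export
estimate_correction_factors <- function(ff_fat_ref, ff_water_ref) {
  if (!is.finite(ff_fat_ref) || !is.finite(ff_water_ref) ||
      ff_water_ref < -0.25 || ff_fat_ref > 1.25 || ff_water_ref >= ff_fat_ref)
    stop("need -0.25 <= ff_water_ref < ff_fat_ref <= 1.25 (degenerate reference)")
  structure(list(a = ff_fat_ref, b = ff_water_ref,
                 c = 1 - ff_fat_ref, d = 1 - ff_water_ref,
                 source = "per-image", n_images = 1L),
            class = "correction_factors")
}

#' @export
print.correction_factors <- function(x, ...) {
  cat(sprintf("<correction_factors %s (n=%d)>  a=%.4f b=%.4f c=%.4f d=%.4f\n",
              x$source, x$n_images, x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Average per-image correction factors into a scanner-specific set
#'
#' Componentwise arithmetic mean of per-image factor sets; the a + c = 1,
#' b + d = 1 normalisation is preserved by linearity.
#'
#' @param per_image Non-empty list of `correction_factors`.
#' @return A `correction_factors` object with source "scanner-averaged".
#' @export
average_factors <- function(per_image) {
  if (length(per_image) == 0) stop("at least one factor set is required")
  ok <- vapply(per_image, inherits, TRUE, "correction_factors")
  if (!all(ok)) stop("all elements must be correction_factors")
  comp <- function(f) colMeans(do.call(rbind, lapply(per_image, function(x)
    unlist(x[c("a", "b", "c", "d")]))))
  m <- comp(per_image)
  structure(list(a = m[["a"]], b = m[["b"]], c = m[["c"]], d = m[["d"]],
                 source = "scanner-averaged",
                 n_images = length(per_image)),
            class = "correction_factors")
}

#' Bias-corrected volumetric water fraction (FraWater) map
#'
#' Inverts the linear signal model at each voxel: a measured fat signal
#' fraction s maps to V_fat = (s - b) / (a - b) and
#' FraWater = 1 - V_fat = (a - s) / (a - b), clamped to [0, 1]. Invalid
#' (`NA`) fat-fraction voxels propagate. The fraction of voxels clamped is
#' attached as attribute `clamped_fraction`.
#'
#' @param ff_map 3-D fat-fraction array (or a `fat_water_maps`, whose
#'   signed channel is used).
#' @param factors A `correction_factors` object with a != b.
#' @return 3-D FraWater array in [0, 1].
#' @export
frawater_map <- function(ff_map, factors) {
  if (!inherits(factors, "correction_factors"))
    stop("factors must be correction_factors")
  if (abs(factors$a - factors$b) < .Machine$double.eps)
    stop("singular correction: a equals b")
  s <- if (inherits(ff_map, "fat_water_maps")) ff_map$fat_fraction_signed else ff_map
  fw <- (factors$a - s) / (factors$a - factors$b)
  # voxels exactly at the pure-tissue boundaries are not overshoot
  clamped <- sum(fw < -1e-6 | fw > 1 + 1e-6, na.rm = TRUE)
  fw <- pmin(pmax(fw, 0), 1)
  attr(fw, "clamped_fraction") <- clamped / sum(!is.na(s))
  fw
}

#' Per-breast MagDensity
#'
#' MagDensity is the mean FraWater over the valid voxels of a segmented
#' breast volume, expressed in percent.
#'
#' @param frawater 3-D FraWater array in [0, 1].
#' @param mask Logical breast mask; must contain at least one valid voxel.
#' @return Numeric percent in [0, 100] with attribute `n_voxels`.
#' @export
magdensity <- function(frawater, mask) {
  if (!any(mask)) stop("breast mask is empty")
  vals <- frawater[mask]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) stop("breast mask contains no valid voxels")
  structure(100 * mean(vals), n_voxels = length(vals))
}

#' Construct a per-breast density record table row
#'
#' @param subject_id Subject label.
#' @param side "L" or "R".
#' @param scanner Scanner label.
#' @param magdensity_percent MagDensity in [0, 100].
#' @param n_voxels Positive voxel count behind the mean.
#' @return One-row data frame.
#' @export
density_record <- function(subject_id, side, scanner, magdensity_percent,
                           n_voxels) {
  side <- match.arg(side, c("L", "R"))
  if (magdensity_percent < 0 || magdensity_percent > 100)
    stop("magdensity_percent must lie in [0, 100]")
  if (n_voxels <= 0) stop("n_voxels must be positive")
  data.frame(subject_id = subject_id, side = side, scanner = scanner,
             magdensity_percent = as.numeric(magdensity_percent),
             n_voxels = as.integer(n_voxels), stringsAsFactors = FALSE)
}
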
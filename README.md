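# magdensity

Quantitative MRI-based breast density, reproducibly, across scanners.

Breast density — the proportion of fibroglandular (water-rich) tissue in
the breast — is a major breast-cancer risk factor, but mammographic
assessment is qualitative, 2-D and observer-dependent. Chemical-shift
encoded (Dixon) fat–water MRI offers a quantitative alternative:
**MagDensity**, the mean bias-corrected volumetric water fraction
(*FraWater*) over a segmented breast, in percent. For MagDensity to be
clinically usable, it must agree across scanner models, vendors and
field strengths; residual disagreement must be removable by calibration.

This package implements the full measurement and harmonization chain for
researchers in quantitative breast imaging, with a digital phantom so
that every stage is testable against known ground truth:

- **phantom** — bilateral digital breast anatomy (adipose,
  fibroglandular, subcutaneous fat, pectoral muscle, skin) and a
  multi-echo spoiled gradient-echo simulator with scanner-specific
  signal bias: proton-density and T1 weighting
  (sin α (1−E₁)/(1−cos α E₁), E₁ = e^(−TR/T1)), residual water in
  adipose tissue, B0 inhomogeneity, R2\* decay, constant + linear
  echo-phase errors, complex Gaussian noise. Presets encode two 3T
  scanners (six echoes, 1.37–8.81 ms, 6°) and a 1.5T scanner
  (2.88–18.66 ms, 12°).
- **recon** — combination of magnitude/phase images into complex data,
  estimation and removal of constant/linear echo-phase errors, and
  IDEAL fat–water decomposition: per voxel, alternating exact linear
  least squares for complex water/fat amplitudes with Gauss–Newton
  field-map updates, fat modeled as a single peak at −3.4 ppm.
- **density** — correction factors (a, b, c, d) of the linear signal
  model S_fat = a·V_fat + b·V_water, S_water = c·V_fat + d·V_water,
  estimated from "pure" reference regions (subcutaneous fat, pectoral
  muscle), averaged per scanner; FraWater = (a − s)/(a − b); MagDensity
  per breast.
- **harmonize** — paired agreement statistics (mean differences,
  two-tailed paired t-tests, Pearson correlation, Bland–Altman limits
  of agreement) and leave-one-out linear calibration that removes
  cross-scanner bias without leaking a subject's own data into her
  calibration model.

I/O uses NIfTI volumes with YAML sidecars (echo times, field strength)
and CSV density tables; reports are written as JSON.

## Worked example

Simulate one subject, reconstruct, correct the signal bias, and measure:

```r
library(magdensity)
presets <- scanner_presets()
ph <- make_phantom(c(48, 48, 12), fibroglandular_fraction = 0.62, seed = 11)
ser <- simulate_echoes(ph, presets$prisma, seed = 1)
est <- estimate_echo_phase(ser, presets$prisma)
ser <- apply_phase_correction(ser, est["phase0"], est["phase1"])
maps <- ideal_decompose(ser, presets$prisma, ideal_options(tol = 1e-5, max_iter = 200))
ref <- sample_reference(maps, ph$ref_fat_roi, ph$ref_water_roi)
cf <- estimate_correction_factors(ref["ff_fat_ref"], ref["ff_water_ref"])
print(cf)
#> <correction_factors per-image (n=1)>  a=0.9186 b=-0.0000 c=0.0814 d=1.0000
fw <- frawater_map(maps, cf)
md <- magdensity(fw, ph$breast_mask_left)
#> MagDensity (left breast): 62.01%  [truth 62.01%]
```

The factor a = 0.919 says a pure-fat voxel shows a fat signal fraction
of only ~0.92 under this protocol's T1 weighting and the 10% residual
water of adipose tissue; the affine correction maps that reference to
FraWater 0 and pure water to 1, after which the per-breast mean recovers
the simulated 62.0% density.

Cross-scanner agreement and calibration on a per-breast density table
(here with a synthetic 4-point vendor offset):

```r
rep <- study_report(density_table)
print(rep)
#> -- before calibration --
#> <agreement mmr vs signa>  n=20
#>   mean delta +3.529 pp; t=12.4497, p=1.389e-10; r=0.9947
#>   Bland-Altman bias +3.529 pp, LoA [1.044, 6.014]
#> ...
#> -- after leave-one-out calibration of signa against mmr --
#> <agreement mmr vs signa_calibrated>  n=20
#>   mean delta +0.065 pp; t=0.1997, p=0.8439; r=0.9930
```

The mean difference of ~3.5 percentage points (t-test p < 0.001)
vanishes after leave-one-out calibration (+0.07 pp, p = 0.84) while the
correlation stays above 0.99. `run_study()` composes the entire chain —
cohort simulation, per-scanner reconstruction, factor estimation,
density, agreement report — from one seed.

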
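---
title: "Methods: simulating and harmonizing MRI-based breast density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and harmonizing MRI-based breast density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(magdensity)
```

## The measurement

Breast density — the proportion of fibroglandular (water-rich) tissue in
the breast — is a breast-cancer risk factor. This package implements an
MRI-based quantitative density measure built on chemical-shift-encoded
(Dixon) fat–water imaging:

1. Multi-echo gradient-echo acquisitions yield complex images whose
   fat/water interference pattern across echo times encodes the per-voxel
   fat signal fraction.
2. IDEAL (iterative decomposition of water and fat with echo asymmetry
   and least-squares estimation) separates water, fat, and the
   off-resonance field per voxel.
3. The fat signal fraction is *biased* relative to the volumetric fat
   fraction by proton-density and T1 differences between fat and water
   and by residual water in adipose tissue. A linear per-voxel signal
   model,
   $$S_{fat} = a\,V_{fat} + b\,V_{water},\qquad
     S_{water} = c\,V_{fat} + d\,V_{water},$$
   is inverted using correction factors estimated from "pure" reference
   tissues: subcutaneous fat ($V_{fat}=1$) and pectoral muscle
   ($V_{water}=1$). The corrected volumetric water fraction is called
   *FraWater*, and *MagDensity* is its mean over a segmented breast, in
   percent.
4. Cross-scanner disagreement in MagDensity is quantified with paired
   statistics (mean differences, two-tailed paired t-tests, Pearson
   correlation, Bland–Altman limits of agreement) and removed with a
   leave-one-out linear calibration between scanners.

Because every stage is testable only against known ground truth, the
package ships a digital phantom and acquisition simulator; all study-level
claims in the test suite are claims about this simulation.

## The phantom and forward model

`make_phantom()` builds an axial, prone-convention bilateral geometry: a
posterior pectoral-muscle slab, two half-ellipsoid breasts, a one-voxel
skin shell, a subcutaneous-fat rim, and a breast core whose voxels are
split between adipose and fibroglandular tissue. Fibroglandular voxels
are placed by thresholding a smooth seeded random field at the exact
count quantile, so the achieved per-breast fibroglandular fraction equals
the requested one to within one voxel; the achieved value is recorded as
the ground truth. True water volume fractions are 1 in fibroglandular and
muscle voxels and equal to the adipose residual-water fraction (default
0.10) in adipose voxels, so fat and water volumes sum to 1 per voxel. The
breast mask is the core only: the subcutaneous rim and skin are excluded,
mirroring the role of a whole-breast segmentation that avoids the skin
surface. B0 inhomogeneity is a smooth low-order polynomial ramp with a
±30 Hz default peak.

`simulate_echoes()` evaluates, per voxel and echo $n$ (0-based),
$$S_n = \left(A_w + A_f e^{i 2\pi \Delta f\, TE_n}\right)
  e^{i 2\pi \psi TE_n}\, e^{-TE_n R_2^*}\, e^{i(\phi_0 + \phi_1 n)}
  + \epsilon_n ,$$
with amplitudes $A = V \times \text{proton density} \times$ the
spoiled-GRE steady-state factor
$\sin\alpha\,(1-E_1)/(1-\cos\alpha\,E_1)$, $E_1 = e^{-TR/T_1}$. The fat
resonance is a single peak at −3.4 ppm (the original IDEAL formulation);
multi-peak fat spectra are out of scope. Noise is complex Gaussian per
channel, so magnitudes are Rician.

### Scanner presets

`scanner_presets()` encodes the three study configurations: two 3T
scanners sharing a six-echo train (1.37–8.81 ms, 6°, TR 21 ms) and a 1.5T
scanner with a longer uniform train (2.88–18.66 ms, 12°, TR 22.4 ms).
Default tissue values are T1 385/365 ms for fat and 1450/1300 ms for
water at 3T/1.5T, typical literature values. The 1.5T preset additionally
carries an apparent $R_2^\ast$ of 50 s$^{-1}$ (T2* 20 ms, realistic for
fibroglandular tissue at 1.5T) and a water proton-density scaling of 1.4.
Together with the longer echo train these make its *uncorrected* density
differ from the 3T presets by roughly 2–3 percentage points at typical
densities — the same order as the cross-vendor disagreement such
measurements show in practice. This is an emulation preset, not a claim
about any vendor; with a binary-tissue phantom the reference-region
correction removes this bias almost entirely, so the persistent
cross-scanner offsets that motivate calibration are injected at the
density-table level in the harmonization experiments.

### Why the default noise level is zero

Phantom tissues are binary: every breast voxel is exactly "pure fat" or
"pure water" in the sense of the correction model, i.e. it sits exactly
at the FraWater boundaries 0 and 1. Any symmetric noise therefore pushes
about half of all voxels outside $[0,1]$, where they are clamped; a
noisy *default* would make the clamp fraction ~50% regardless of how
small the noise is, which says nothing useful. Noise is instead opt-in
through the profile's `noise_sd` (the bias round-trip experiments use
0.01), and clamping on default phantoms stays below 5%. Real breasts
have partial-volume voxels between the boundaries; this is the main
feature of real data the phantom does not emulate, and it means passing
tests demonstrate correctness of the *algorithms*, not the absence of
partial-volume effects in vivo.

## Reconstruction

`ideal_decompose()` alternates, per voxel, (a) an exact linear
least-squares solve for the complex water/fat amplitudes given the field
value $\psi$ — design matrix rows $(1, e^{i2\pi\Delta f\,TE_n})$ after
demodulating $e^{i2\pi\psi TE_n}$ — and (b) a Gauss–Newton update of
$\psi$ on the amplitude-eliminated residual, until $|\Delta\psi|$ drops
below `tol` (default 0.01 Hz; exactness tests tighten it) or `max_iter`
(default 50). Optional Gaussian field smoothing between sweeps is off by
default; $R_2^\ast$ is not estimated.

**Initialisation.** The iteration's convergence basin is narrow for long
echo trains: with the 1.5T train a true field of 60 Hz is unreachable
from a 0 Hz start. Each voxel is therefore seeded from a coarse residual
search on a 10 Hz grid over ±120 Hz. Among grid points whose residual is
within a 25% band of the minimum (plus a $10^{-6}$ energy floor) the
smallest $|\psi|$ wins. The band matters because a *uniformly spaced*
echo train makes the fat–water swap solution alias onto an (almost)
exact fit about 100 Hz away, and unmodeled $R_2^\ast$ decay inflates all
residuals so that the aliased branch can fit marginally better; the
small-field preference selects the physically modest interpretation
consistently across tissues. Explicit multi-starts (e.g. 0 and
$\Delta f/2$) with residual tie-breaking remain available through
`ideal_options()`. Spatially regularised field estimation (region
growing, graph cuts) is a deliberate non-goal; per-voxel independence
keeps the solver testable against a dense grid-search oracle.

**Signed fat fraction.** True water and fat amplitudes share a common
phase, so the complex estimates are projected onto the phase of their
sum; the real parts give signed amplitudes. The stored `fat_fraction`
map is the non-negative, $[0,1]$-clamped ratio, but reference-region
sampling uses the *signed* channel: the magnitude ratio has a Rayleigh
noise floor that biases the pure-water reference upward at realistic
muscle SNR, while the signed ratio is symmetric around truth. The signed
value can also fall slightly outside $[0,1]$ under unmodeled decay
(about −0.08 in the muscle reference of the 1.5T preset); it is kept
unclamped there because clamping would distort the affine correction.

**Echo-phase errors.** Constant ($\phi_0$) and linear-in-echo-index
($\phi_1$) phase errors are estimated by `estimate_echo_phase()` on the
top-decile-magnitude voxels: it alternates a provisional fat–water fit
with a least-squares fit of the pooled residual phase trend against
$(1, n, TE_n)$, reading $\phi_0$ off the common phase of the fitted
amplitudes and discarding the TE-proportional component (which belongs
to the field map). When the echo train is (nearly) uniformly spaced,
$n$ is collinear with $TE$ and $\phi_1$ is fundamentally
unidentifiable; it is then reported as 0 and the true slope is absorbed
by the field map — a shift of $\phi_1/(2\pi\,\Delta TE)$ Hz — with no
effect on fat fractions. A constant phase is likewise harmless to
magnitudes but is estimated for completeness and audit.

## Density estimation

Reference sampling uses a 20%-trimmed mean per ROI, robust to
partial-volume voxels at ROI edges. The pure-region conditions fix only
two degrees of freedom of $(a,b,c,d)$; the adopted closure normalises
each pure tissue's total signal to one ($a+c=b+d=1$), reducing the
correction to the affine map that sends the pure-fat reference to
FraWater 0 and the pure-water reference to 1:
$\text{FraWater} = (a-s)/(a-b)$ for measured fat signal fraction $s$,
clamped to $[0,1]$ with the clamped fraction logged. Factors are
estimated per image and averaged into a scanner-specific set before
FraWater is computed, and MagDensity is reported separately per breast.

## Harmonization

`paired_stats()` reports the signed mean difference (former − latter),
the paired two-tailed t-test with $n-1$ degrees of freedom, Pearson's
$r$, and Bland–Altman bias with 95% limits of agreement
(bias ± 1.96 × SD of differences). Degenerate inputs (zero-variance
differences) are flagged rather than silently propagated.

`loo_calibrate()` fits ordinary least squares of the target scanner on
the source scanner, holding out one unit at a time and calibrating each
held-out unit with a model trained on the others. The default fold unit
is the *subject*, so both breasts of one woman leave the training set
together and no within-subject correlation leaks into her own
calibration; per-breast folds are available via `unit = "breast"`. The
single calibration pathway fits the 1.5T scanner against one 3T scanner
(the two 3T scanners show no meaningful difference), and calibrated
values are then compared against both. The t-test treats the 2 ×
subjects breasts as independent pairs, mirroring common practice for
this design; within-subject correlation is a known caveat of that
choice, noted rather than modeled.

## Problem sizes and numerical choices

The test suite and the acceptance script use phantoms of 64×64×16 voxels
for the exactness checks, 28–32-voxel grids for the multi-image and
cohort experiments (10 subjects × 3 scanners), 20 noise replicates for
the factor round trip, and 200 replicates for the tabular harmonization
experiment; these sizes make every distributional claim a
multi-replicate average while each phantom still contains several
hundred breast-core voxels and ~200-voxel reference ROIs. Convergence
tolerances are stated per experiment; exactness checks run the solver to
`tol = 1e-7` Hz. Degenerate inputs (empty ROIs, mis-ordered references,
constant calibration sources, zero-variance differences, all-in-phase
echo trains, zero-signal voxels) raise typed errors or flags rather than
returning numbers.

## Known limitations

- Binary-tissue phantom: no partial volume, so Eq.-style correction is
  exact by construction; in vivo the linear model is an approximation.
- Single-peak fat model; no multi-peak spectrum, no T2*-IDEAL.
- Masks are phantom truth; whole-breast segmentation of real data is an
  input, not a capability of this package.
- Density tables are read from CSV (a column-mapping argument adapts
  alternate layouts); spreadsheet formats should be exported to CSV
  upstream.
- The harmonization experiments demonstrate calibration on simulated
  density tables; with real multi-vendor data the residual
  (post-correction) scanner bias has physical sources this simulator
  only partially emulates.
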
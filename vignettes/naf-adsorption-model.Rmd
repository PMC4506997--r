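---
title: "Surface adsorption of 18F-NaF to vascular calcification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface adsorption of 18F-NaF to vascular calcification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nafads)
```

## The scientific model

`nafads` implements a mechanistic account of why ¹⁸F-NaF PET and CT disagree
on where vascular calcification is: fluoride adsorbs to hydroxyapatite with
one-site kinetics, but only on mineral surface that the tracer can reach.
The package couples four models:

1. **Geometry.** A plaque phantom is a block of soft tissue containing
   spherical (2D: disc) calcific deposits. The field's convention separates
   *micro*calcification (diameter < 50 μm) from *macro*calcification
   (≥ 50 μm); `classify_deposit()` applies it with the boundary inclusive on
   the macro side. Deposits are kept mutually disjoint so per-deposit ground
   truth stays well defined; a voxel is calcified when its centre falls
   inside a deposit. Spheres are used for macrocalcification too — real
   macrodeposits are irregular, but spheres admit exact analytic oracles
   (volume, shell fraction) that anchor the test suite.

2. **Binding kinetics.** Occupancy follows the one-site law
   $B(t) = B_{eq}\,(1 - e^{-k_{obs} t})$ with
   $k_{obs} = k_{on} L + k_{off}$, and washout $B(t) = B_0 e^{-k_{off} t}$.
   Defaults are the measured carotid constants
   ($k_{on} = 4.5\times10^9\ \mathrm{M^{-1}min^{-1}}$,
   $k_{off} = 0.0027\ \mathrm{min^{-1}}$, incubation at $10^{-11}$ M), giving
   $K_D = k_{off}/k_{on} = 0.6$ pM, an association half-time of
   $\ln 2 / k_{obs} \approx 14.5$ min and a dissociation half-time of
   $\approx 257$ min.

3. **Accessibility.** In intact tissue the tracer reaches only voxels within
   a penetration depth (default 20 μm, one cryosection thickness — the scale
   at which surface-restricted binding is resolved experimentally; the depth
   is a modelling choice, never quantified in μm by the experiments) of
   non-calcified tissue, computed by an exact Euclidean distance transform.
   Any deposit no larger than the penetration depth is reached throughout,
   which is exactly what makes microcalcification uniformly hot. Sectioning
   before incubation removes the barrier.

4. **Detection.** A modality is a Gaussian point-spread function (sigma =
   FWHM/2.3548), block-average resampling to the output grid, and a noise
   model. Partial volume then does all the work: clinical CT (FWHM 600 μm)
   cannot raise any micro deposit above the 1,000 HU calcification rule,
   while PET blur spreads true surface signal far beyond the mineral.

## Binding regime: linear vs saturable

The measured affinity (0.6 pM) and the observed linear calibration of bound
activity against concentration over $10^{-12}$–$10^{-7}$ M cannot both hold
for a saturating one-site isotherm; the experiments leave this unreconciled.
`simulate_uptake()` therefore defaults to the **linear site-excess regime**
(activity per accessible voxel $\propto L$), reproducing the observed
calibration, and offers the saturable form
($L/(L+K_D)$) behind `binding = "saturable"`. One consequence, worth stating
plainly: exact proportionality in $L$ holds at equilibrium, but at a finite
60-minute incubation $k_{obs}$ itself depends on $L$, so doubling the
concentration slightly more than doubles the 60-minute signal (about +6% at
$10^{-11}$ M). The property tests check exact doubling at plateau and bound
the 60-minute excess.

## The synthetic study and what it does (not) show

`run_end_to_end()` generates a 2D phantom (default: 6×6 mm at 5 μm voxels,
60 micro deposits of radius 8–20 μm, 3 macro deposits of radius 150–600 μm —
counts chosen to mirror tissue, where microcalcification is dispersed in
large numbers while macrodeposits are few), simulates intact-tissue uptake,
and renders three detection levels: clinical PET/CT (rendered on a common
500 μm grid), μPET/μCT (300 μm) and autoradiography/histology (25 μm). Each
pair is quantified as PET+/CT−, PET+/CT+ and PET−/CT+ percentages of the
union of positives (the denominator that makes the three classes sum to
100). PET-like images are thresholded with Otsu; μCT and clinical CT use the
≥ 1,000 HU rule; the autoradiography/histology pair uses the full
threshold–blur–rethreshold pipeline, whose purpose is precisely to put two
modalities of different native resolution on a common footing. The PET-only
percentage falls strictly as resolution improves, the direction the clinical
data show. The simulation is co-registered by construction and free of
anatomy (no lumen, no vessel wall, no irregular deposit shapes, no
histological stain variability), so passing tests demonstrate the
*mechanism* — surface adsorption plus partial volume reproduces the
mismatch — not any patient-level percentage.

Clinical CT positivity deserves a note: the in-vivo analyses gate
contrast-enhanced CT with Otsu because absolute HU there are not comparable
across injections; our synthetic CT is calibrated by construction, so the
pipeline applies the 1,000 HU rule at every CT level and leaves Otsu gating
available through `mask_pipeline()`.

## Thresholding conventions

Both automatic thresholds are implemented in the package (they are the
quantification pipeline's core and carry oracle-equivalence tests against
exhaustive search):

* **Otsu** maximizes between-class variance over a 256-bin histogram;
  continuous data are min–max scaled by the binning, and integer-valued
  (8/16-bit-like) data get one bin per gray level so the histogram optimum
  coincides with the exact-value optimum. Ties break toward the lowest
  qualifying threshold; masks use strict `>`.
* **Li** iterates $t_{k+1} = (\mu_b - \mu_f)/(\log\mu_b - \log\mu_f)$ from
  the image mean until the change drops below `tol` (default $10^{-4}$ of
  the range), then snaps to the exact cross-entropy minimizer within two
  histogram bins of the fixed point — the fixed point of the continuous
  criterion can sit a fraction of a gray level from the discrete optimum.
* The blur stage of `mask_pipeline()` works on the binary field with sigma
  in pixels (σ = 20 by default; the pixel pitch of the source images is
  unknown, so pixels, not micrometres, are the unit) and quantizes the
  blurred intermediate to 256 levels of [0, 1], mirroring the 8-bit
  behaviour of the imaging tools the procedure is modelled on. A feature too
  small to survive smoothing therefore vanishes entirely and yields an empty
  mask rather than an error. The HU rule is inclusive (`>= 1000`).

## Dynamic analysis

`simulate_dynamic_study()` builds tissue and blood curves obeying the
irreversible-trapping relation
$C_t(t) = K_i \int_0^t C_b\,d\tau + V\,C_b(t)$ on the 28-frame schedule
(12×10 s, 4×30 s, 12×240 s; 52 min), evaluating the biexponential plasma
model and its integral in closed form at frame midpoints. The default plasma
model ($A_1 = 0.9$, $A_2 = 0.1$, $\lambda_1 = 0.25\ \mathrm{min^{-1}}$,
$\lambda_2 = -\ln(0.6)/60 \approx 0.0085\ \mathrm{min^{-1}}$) is calibrated
so the 60-minute value is 6% of peak, centred in the observed 4–8% band.

`patlak()` regresses $C_t/C_b$ on $\int_0^t C_b\,d\tau / C_b$ using points
from 10 min onward (the equilibration cutoff, configurable). The running
integral is, by default, the exact integral of a cubic-spline interpolant of
log-concentration — piecewise-exponential interpolation, the natural model
for a decaying input function — with the leading segment to $t=0$ taken from
a quadratic through the first three samples. Plain trapezoidal cumulation is
available (`quadrature = "trapezoid"`), but on the sparse 4-minute late
frames its quadrature error alone biases $K_i$ by about 1%, an order of
magnitude above what the spline scheme leaves (measured: $\sim 10^{-5}$
relative on $K_i$, $2\times10^{-4}$ on $V$), which is why it is not the
default.

## Numerical choices and degenerate inputs

* Nonlinear fits use Levenberg–Marquardt (`minpack.lm`), with starts from
  log-linear heuristics: the half-plateau crossing for $k_{obs}$, the
  log-slope of the last two points for $k_{off}$, and curve peeling for the
  biexponential. Standard errors come from the Jacobian-based covariance at
  the optimum.
* A perfectly flat washout is returned directly as the irreversible limit
  ($k_{off} = 0$, infinite half-time) rather than fitted.
* A constant image cannot be thresholded (error); inside `run_end_to_end()`
  a constant rendered image produces an *empty* mask so the tri-class stage
  can report the undefined-denominator condition itself.
* Phantom generation retries random placement at most `max_attempts` (1,000)
  times per deposit and then fails naming the deposit; identical
  `(config, seed)` always reproduces the phantom bit-for-bit, and every
  stochastic stage of the pipeline derives its own child seed from the
  master seed.
* Rendering requires the output voxel to be an integer multiple of the truth
  voxel (block averaging is then exactly conservative; the blur kernel is
  normalized to unit sum and applied circularly, so total signal is
  conserved to machine precision when noise is off).

## Problem sizes

The shipped defaults are desk-scale: a 1,200×1,200 2D phantom for the
end-to-end study (a few seconds), 3D oracle checks on ~100³–120³ grids, and
200-replicate noise studies for the recovery tests. All sizes are
configuration, not constants; the oracles' rasterization tolerances
(e.g. the spherical-shell fraction law) are stated in the tests and shrink
as the voxel size decreases.

## Known limitations

* Spherical deposits and instantaneous diffusion outside calcification; no
  reaction–diffusion transport, no necrotic core, no vessel anatomy.
* No scanner physics beyond PSF + noise (no sinograms, scatter, randoms or
  iterative reconstruction), no decay correction (activities are assumed
  decay-corrected), no registration (synthetic data are co-registered by
  construction).
* Activity units are arbitrary throughout; nothing is calibrated to Bq.
* Clinical PET/CT in-plane resolutions are not published for this protocol;
  the presets (4.5 mm / 0.6 mm FWHM) are conventional figures for the
  scanner class and are exposed in the configuration.
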
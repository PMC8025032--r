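---
title: "Quantifying tumor-associated microvasculature in photoacoustic breast angiograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying tumor-associated microvasculature in photoacoustic breast angiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pactangio)
```

## Scope and model

A ring-array photoacoustic computed tomography (PACT) scan of the breast is
effectively a label-free angiogram: short laser pulses deposit energy in
hemoglobin, the resulting thermoelastic pressure transients are recorded by
a transducer ring, and reconstruction recovers the optical-absorption map.
Tumor-associated angiogenesis appears as a region of dense, tortuous,
disordered microvessels; its regression under neoadjuvant chemotherapy is
the imaging signal this package quantifies.

The pipeline has four layers, each usable on its own:

1. **Synthetic inputs.** A breast-mimicking inclusion phantom and a
   two-compartment vascular maximum-amplitude-projection (MAP) scene
   generator.
2. **Physics.** An analytic 2D full-ring forward model and universal
   back-projection (UBP) reconstruction with depth compensation.
3. **Image conditioning and maps.** Denoise, Frangi vesselness, blend,
   background-threshold; then relative vessel density, windowed entropy,
   rotational-SVD directionality/anisotropy, the anisotropy-weighted entropy
   map, automatic tumor segmentation, and the modulated angiogram.
4. **Statistics.** ROI-vs-healthy samples over non-overlapping windows and
   one-tailed Welch t-tests, assembled into a longitudinal report.

## The forward model and reconstruction

The initial pressure is $p_0(r) = \Gamma\,\mu_a(r)\,\Phi(r)$ with the
Grüneisen parameter treated as a unit constant. The phantom is decomposed
into uniform disks — the breast background disk plus one disk per inclusion
carrying its absorption *excess* — and each disk contributes the classic
N-shaped transient of a uniform spherical absorber of matching radius,
$p(d,t) = p_0\,(d - ct)/(2d)$ for $|d - ct| < a$. This closed form trades 2D
exactness for transparency; the quantities the package is judged on
(detection counts, centroids, amplitude ratios) are insensitive to the
substitution, and the UBP term $b(t) = 2p - 2t\,\partial_t p$ evaluates to
exactly $p_0$ inside each disk's transient, which is why flat-fluence
reconstructions recover the designed 2.1 absorption contrast to about 1%.

Assumptions: homogeneous speed of sound (1.5 mm/µs), no acoustic
attenuation or element directivity, 2D in-plane geometry (the elevational
dimension of a real scanner is treated as independent slices). Fluence
follows a one-dimensional diffusion-regime decay
$\Phi(z) = \Phi_0 e^{-\mu_{eff} z}$ with
$\mu_{eff} = \sqrt{3\mu_a(\mu_a + \mu_s')}$ — 0.87 cm⁻¹ for average breast
values ($\mu_a = 0.05$, $\mu_s' = 5$ cm⁻¹), the commonly quoted
~0.9 cm⁻¹ — and depth compensation multiplies by $e^{0.6\,z[\mathrm{cm}]}$.

Numerical choices: central-difference time derivative (one-sided at the
ends), linear interpolation of $b$ at each pixel's flight time, equal
full-ring weights. Pixels whose flight time exceeds the 100 µs record
window contribute zero and raise a coverage warning; for the desk-scale
phantoms near the ring center this never happens. The transducer band-pass
(Gaussian envelope at 2.25 MHz, 70% fractional bandwidth) is a configuration
knob: quantitative runs (detection counts, amplitude ratios) use the
wideband transients, because band-passing removes the low frequencies that
carry a disk's interior amplitude and splits each inclusion into sidelobe
rings that a fixed mean + 3 SD detector over-counts. Detection smoothing
defaults to 3 px (~0.3 mm, about the in-plane system resolution on the
0.1 mm grid); the detection count is stable for 3–6 px.

## The irregularity metrics

All maps operate on the background-thresholded MAP $M_{PA}$ (threshold: the
maximum amplitude in a designated out-of-tissue background region).

* **Entropy.** $H = -\sum_i P_i \log_2 P_i$ over a sliding 1 mm window,
  with 32 equal-width bins spanning $[0, \max M_{PA}]$. Global bin edges
  make $H$ comparable across windows; border windows are clipped. A
  constant window has $H = 0$; $H \le \log_2 n_{bins}$ always.
* **Directionality.** Each window (extracted with a $\sqrt2$ margin,
  rotated by bilinear interpolation in 10° steps over $[0°, 180°)$, and
  center-cropped so rotated corners hold real pixels) is decomposed by SVD:
  $N_{SVD}(\theta) = \sigma_1/\sum_i \sigma_i$, and
  $D = \max_\theta N_{SVD} - \min_\theta N_{SVD}$. Smooth straight vessels
  give high $D$; disordered texture gives $D$ near 0. An all-zero window
  returns $N_{SVD} = 1$ by convention (rank-0 guard). Two numerical floors
  are worth knowing: bilinear interpolation leaves a radially symmetric
  window with $D \approx 0.04$ rather than exactly 0, and obliquely
  oriented stripes lose a little directionality to interpolation blur
  (suppression weights of ~0.02 rather than ~0.008 for axis-aligned
  stripes).
* **Anisotropy.** $A = 1/(D + \epsilon)$, $\epsilon = 0.01$, so
  $A \le 100$. Windows containing no signal have *no defined* texture
  orientation; their $A$ is NA rather than the rank-0 convention's
  $1/\epsilon$, which would otherwise read empty background as maximally
  "anisotropic" and swamp region statistics in sparse scenes.
* **Weighted entropy.** $E = H \exp(-k/A) = H \exp(-k(D+\epsilon))$ with
  $k = 30$. Of the two algebraic readings of the weighting
  ($H e^{-k/A}$ vs $H e^{-k(A-1)}$), only the adopted one suppresses
  high-directionality healthy vessels, which is the weighting's stated
  purpose; the other reading is available via `reading = "offset"`.
  $E \le H$ pixelwise.
* **Segmentation.** Binarize $M_{ae}$ at mean + 1.4 SD over the breast
  support and keep the largest 8-connected component. The 1.4 multiplier
  was calibrated in the source system against MRI tumor sizes; here it is a
  configuration default (no re-calibration target exists for synthetic
  scenes, where it nevertheless recovers tumors at Dice 0.6–0.75).
* **Dimensions.** Long and short axis are the mask extents along and
  perpendicular to its principal axis (plus one pixel, so a single-pixel
  mask measures one pixel). A maximal-caliper (Feret) convention would
  report a rectangle's diagonal; the principal-axis convention matches the
  clinical long-axis/short-axis usage.
* **Modulation.** $M_f = (M_{ae} + \beta) M_{PA}$, $\beta = 0.07$,
  self-normalized: lesions are enhanced while the background constant keeps
  healthy structures visible at weight $\beta/(1+\beta)$. The additive
  reading $M_{ae} + \beta M_{PA}$ is available via `mode = "additive"`.

## Relative vessel density

Centerlines are obtained by hysteresis binarization (weak/strong thresholds
at 20%/50% of the 99.5th intensity percentile, so the skeleton is invariant
to global intensity scaling), Zhang–Suen thinning, junction marking
(skeleton pixels with ≥3 8-neighbors) and splitting into independent
segments at junctions; segments under 3 px are discarded as noise spurs.
The relative density at a pixel is the number of *distinct* segments
intersecting the centered 2 × 2 mm window divided by the window area
(windows are rounded to an odd pixel count — 2.1 mm at 0.1 mm/px — and
clipped at borders, with the clipped area used). "Relative" is deliberate:
the value depends on the window, but ROI-vs-healthy orderings and p-values
are robust to window sizes of 1–4 mm.

## The synthetic scene generator

The generator defines the study conditions for every statistical claim the
package makes about itself:

* **Healthy compartment.** 60 smooth, preferentially oriented vessel
  segments (orientation 30° ± 15°, heading random-walk scale
  0.05 rad/√mm) of 3–6 mm length per 20 × 20 mm field of view
  (~0.7 mm/mm² line density), radii 0.15–0.3 mm rendered as Gaussian
  cross-sections with $\sigma = r/2$. Segment length emulates the
  branch-to-branch stretches visible in a MAP. Centers are drawn over a
  *buffered* domain (field of view plus half the maximum segment length,
  count scaled by area) so coverage is stationary up to the image border —
  without the buffer, border regions are coverage-depleted and
  ROI-vs-healthy comparisons are biased.
* **Tumor compartment.** 120 tortuous microvessels (length 1–2.5 mm,
  heading scale 1.5 rad/√mm, uniform orientations) in a 4 mm-radius disk
  (~4 mm/mm² line density, well above twice the healthy density).
  `response_fraction` removes a *nested* subset of them, so increasing
  response never adds vasculature.
* **Noise and truth.** Additive Gaussian background noise (SD 0.05 of the
  unit vessel amplitude, clipped at zero since PA amplitudes are
  non-negative); ground truth includes the tumor disk, a healthy annulus
  beyond a 2 mm guard band kept clear of the image border (so window
  clipping affects both regions alike), and the vessel-free background
  mask used for thresholding. Both compartments share one amplitude, so
  the irregularity metrics are exercised on geometry, not brightness.

What the generator does **not** emulate: branching trees and anastomoses,
vessel-size hierarchies, fluence inhomogeneity across the breast,
reconstruction artifacts (streaks, limited-view blur), breast deformation
between visits, and any amplitude difference between tumor and healthy
vessels. Passing tests therefore demonstrate that the *algorithms* behave
as specified under controlled geometry — not that the clinical effect sizes
or p-values would be reproduced on patient images.

## Statistics and their validity conditions

ROI and healthy metric samples are means over non-overlapping tiles laid
over each region's bounding box (a tile qualifies when at least half of its
full area lies in the region; NA metric pixels are excluded). The Welch
one-tailed test (alternative: ROI mean exceeds healthy mean; Satterthwaite
degrees of freedom) assumes the tiles are independent. That holds only when
the tile is at least the vasculature's spatial correlation length — here
the healthy segment length — so the *sampling* tiles default to 4 mm even
though the density and entropy *maps* use their standard 2 mm and 1 mm
analysis windows. With 1–2 mm sampling tiles, neighboring tiles share the
same vessel, the standard error is understated, and the test is
anti-conservative on null scenes. With 4 mm tiles the package's null
calibration holds: on complete-response scenes the baseline-ROI comparison
is non-significant (p > 0.1) in ~90% of seeds, while baseline tumors are
detected (p < 0.05 for density and entropy) in every seed tested, and the
type-I error of the Welch test itself is within [0.03, 0.07] at
$\alpha = 0.05$ over 1000 null replicates.

Degenerate inputs are handled explicitly: two constant equal-mean groups
return p = 0.5 with a `degenerate` flag; an empty suprathreshold set in
segmentation warns and returns an empty mask; an all-zero map yields an
empty skeleton rather than an error.

## Problem sizes

The package's own test suite and acceptance script run at desk scale: a
300 × 300-pixel phantom (0.1 mm grid) reconstructed on a 500 × 500 grid
from 512 × 4000-sample channel data (~10 s per phantom study), and
200 × 200-pixel scenes whose full irregularity analysis takes ~5 s each;
the multi-seed studies use 20 seeds with baseline and complete-response
scenes per seed.

## Known limitations

* The forward model's disk transients are the uniform-sphere closed form,
  not the exact 2D cylindrical-wave solution; absolute amplitudes are in
  arbitrary linear units and only ratios are meaningful.
* Segment-count density saturates where many microvessels overlap (thinning
  merges them into shared centerlines), so measured density contrast
  compresses the rendered line-density contrast; the density highlight
  localizes tumors (majority coverage at low healthy coverage) but is a
  coarser instrument than the weighted-entropy segmentation.
* Rotational-SVD directionality carries small interpolation floors (see
  above); entropy depends on the global bin edges and therefore on the
  image's maximum.
* The 1.4-SD segmentation multiplier and the 2.5 mm⁻² / 4 mm² highlight
  operating point are clinical defaults carried over unchanged; synthetic
  scenes sit on a different absolute density scale, and scene-level tests
  calibrate the highlight threshold from the scene's own healthy mean.
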
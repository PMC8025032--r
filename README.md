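# pactangio

Quantification of tumor-associated microvasculature in photoacoustic breast
angiograms.

## The problem

Photoacoustic computed tomography (PACT) maps optical absorption — in the
breast dominated by hemoglobin — at acoustic resolution, so a ring-array PACT
scan of the breast is a label-free angiogram. Breast cancer announces itself
in such angiograms through angiogenesis: a region of unusually dense,
tortuous, disordered microvessels. When a tumor responds to neoadjuvant
chemotherapy (NAC), that microvasculature regresses, which makes quantitative
angiogram analysis a candidate noninvasive marker of treatment response for
radiologists and imaging scientists who cannot rely on size measurements
alone.

`pactangio` implements the full quantification chain as a tested R package,
together with the synthetic inputs needed to exercise it end to end without
any patient data:

* a breast-mimicking **inclusion phantom** (seven absorbing "tumors" of 1 to
  3.5 mm diameter, absorption contrast 2.1 at 2 cm depth) and a
  **vascular-scene generator** with healthy and tumor compartments and a
  controllable response fraction;
* a desk-scale 2D **full-ring forward model** (512 elements, 220 mm ring,
  analytic N-shaped transients, optional 2.25 MHz band-pass) with
  **universal back-projection** (UBP) reconstruction,
  `b(t) = 2p(t) − 2t·dp/dt`, and depth compensation `e^(0.6·depth[cm])`;
* angiogram conditioning: denoising, multiscale Hessian (Frangi)
  vesselness, 0.35/0.65 blending, background thresholding;
* **relative vessel density**: skeletonize, split centerlines into
  independent vessels at junctions, drop segments under 3 px, count distinct
  vessels per 2 × 2 mm window divided by the window area;
* **vascular irregularity** maps: windowed Shannon entropy
  `H = −Σ Pᵢ log₂ Pᵢ`; rotational-SVD directionality
  `D = max_θ N_SVD(θ) − min_θ N_SVD(θ)` with
  `N_SVD = σ₁/Σσᵢ` over window rotations 0–170°; anisotropy
  `A = 1/(D + ε)`; and the anisotropy-weighted entropy
  `E = H·exp(−k/A)` (k = 30, ε = 0.01) that suppresses smooth directional
  healthy vessels;
* automatic **tumor segmentation** (threshold `mean + 1.4·SD` of the
  weighted-entropy map, largest 8-connected component) with long-axis /
  short-axis measurements, and lesion-enhanced modulation
  `M_f = (M_ae + β)·M_PA` (β = 0.07);
* **ROI-vs-healthy statistics**: metric samples over non-overlapping
  windows, one-tailed Welch t-tests (null: the tumor ROI mean does not
  exceed the healthy mean), amplitude ratios, and a longitudinal report
  across imaging time points.

## Worked example

Simulate a baseline (T1) scene with an 8 mm tumor and its complete-response
counterpart (T3), condition both, and compare the tumor ROI against healthy
tissue:

```r
library(pactangio)

breast <- optical_properties(mu_a = 0.05, mu_s_prime = 5)
effective_attenuation(breast)   # 0.87 cm^-1 -- the ~0.9 cm^-1 breast figure

scene <- make_vascular_scene(vascular_scene_spec(seed = 1))
after <- make_vascular_scene(vascular_scene_spec(seed = 1, response_fraction = 1))
prep  <- function(s) preprocess_map(s$map, background_region = s$truth$background_mask)
roi   <- roi_definition(scene$truth$tumor_mask, scene$truth$healthy_mask)
longitudinal_report(list(T1 = prep(scene), T3 = prep(after)), roi)
```

```
ROI-vs-healthy longitudinal report
  time_point     metric n_roi mean_roi  se_roi n_healthy mean_healthy se_healthy        t    df p_one_tailed
1         T1    density     4   0.8689 0.10375         7       0.3704    0.07289  3.93185 5.966    3.892e-03
2         T1    entropy     4   3.8138 0.04961         7       2.1781    0.35192  4.60241 6.236    1.668e-03
3         T1 anisotropy     4  14.9379 0.72175         7       5.6159    0.57261 10.11818 6.648    1.398e-05
4         T3    density     4   0.4687 0.12611         7       0.4248    0.08497  0.28846 5.750    3.916e-01
5         T3    entropy     4   2.4881 0.36065         7       2.2240    0.35926  0.51873 7.979    3.090e-01
6         T3 anisotropy     4   5.7689 0.43636         7       5.7360    0.56739  0.04589 8.941    4.822e-01

Tumor dimensions (automatic segmentation)
  time_point la_cm sa_cm el_cm volume_cm3    method
1         T1 0.808 0.695    NA     0.2045 ellipsoid
2         T3 0.302 0.147    NA     0.0034 ellipsoid
```

At baseline every vascular metric is significantly elevated in the tumor ROI
(one-tailed Welch p < 0.004; relative density 0.87 vs 0.37 mm⁻², entropy 3.8
vs 2.2 bits, anisotropy 14.9 vs 5.6), and the automatically segmented long
axis, 0.81 cm, matches the 0.8 cm tumor that was rendered. After complete
response the same ROI is statistically indistinguishable from healthy tissue
(all p > 0.3) and only a 0.3 cm residual of crossing healthy vessels is
segmented — the pattern that distinguishes complete from partial response.

`run_pipeline(pact_config(seed = 1), output_dir = "out")` runs the whole
chain — phantom simulation, reconstruction, detection, a three-time-point
scene series, and the report — and writes the detection and metric CSVs.

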
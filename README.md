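# pbct — propagation-based phase-contrast breast CT

`pbct` is an R package for studying how reconstruction algorithms shape
image quality in low-dose propagation-based phase-contrast computed
tomography (PB-CT) of the breast. In PB-CT a quasi-plane monochromatic
synchrotron beam traverses the sample and propagates freely (here over an
effective distance R' = R₁R₂/(R₁+R₂) ≈ 5.75 m) before detection, turning
X-ray phase shifts into measurable intensity fringes; single-image TIE-Hom
(Paganin) retrieval — a Fourier low-pass `1/(1 + πγλR'|u|²)` parameterized
by γ = δ/β — converts the fringed projections back into line integrals of
the imaginary refractive-index decrement β (attenuation μ = 4πβ/λ).

The package provides, as tested and seeded components:

* a **synthetic-data module**: voxelized breast-like phantoms
  (adipose/glandular tissue plus micro-calcifications, given as β at
  32 keV) and a forward simulator (contact, transport-of-intensity, or
  Fresnel propagation; Poisson photon noise; flat and dark fields);
* **preprocessing**: flat/dark correction, Paganin retrieval (default
  γ = 275, the "half retrieval" setting), projected-β conversion;
* three **reconstruction algorithms**: FBP with a Hamming (or ram-lak)
  filter; a regularized direct-Fourier **gridding** method whose single
  noise-to-signal parameter (default 0.05) controls Wiener-style low-pass
  damping; and **cSART**, a customized SART with a ramp-up/ramp-down
  relaxation schedule, random projection ordering and a periodic 3D
  bilateral filter `(1-w)·x + w·bilateral(x)`;
* the **objective quality suite**: 5-bin-histogram boundary contrast C,
  flat-region SNR, CNR = C×SNR, noise-based spatial resolution via the
  MTF second moment (`Res = sqrt((4/d)·m₂)`, Gaussian-calibrated so
  Res = 2σ) and the intrinsic-quality proxy SNR/Res^1.5 ∝ Qs =
  SNR/(Res^1.5·√D);
* the cSART **tuning procedure**: the 1800-point parameter grid
  (σ_xy,z ∈ 1..10 px, σ_v ∈ 0.01..0.20, w ∈ 0.04..0.20), a noise-power-
  spectrum peak gate against FBP (±15%), and Pareto/Qs best-record
  selection;
* **thick-slice production**: slab stitching, calcification-preserving
  30-pixel rebinning with threshold β = 2×10⁻¹⁰, 12-bit linear mapping of
  β ∈ [5×10⁻¹¹, 7×10⁻¹⁰] onto 0..4095, and bit-exact DICOM series export;
* **reader-study statistics**: paired t-tests with Bonferroni-adjusted
  α = 0.05/3 ≈ 0.017, two-way absolute-agreement ICC(A,1) with reliability
  bands, Cronbach's alpha with leave-one-out, and visual grading
  characteristics AUC (`(#{r>0} + ½#{r=0})/N` for relative ratings) with a
  two-level reader/case bootstrap.

See `vignettes/pbct-methods.Rmd` for the models, parameter rationale and
numerical conventions.

## Worked example

A desk-scale comparison study — one 128×128 slice of a breast-like phantom,
360 projections over 180°, Poisson noise, phase retrieval at γ = 275, all
three reconstructions, metrics measured in automatically placed ROIs:

```r
library(pbct)
geom <- scan_geometry(angles_deg = seq(0, 179.5, by = 0.5))
geom
#> PB-CT scan geometry
#>   energy: 32 keV (lambda = 0.3875 A)
#>   source-detector 143 m, sample-detector 6 m (R' = 5.748 m)
#>   detector pitch 100 um, 360 angles over [0, 179.5] deg

cmp <- run_comparison(seed = 1)
cmp
#> PB-CT comparison study (seed 1, hash 5df6703b)
#>  slice         metric   fbp gridding  csart
#>      1       contrast 0.234    0.206 0.1862
#>      1            snr 5.838    7.781 8.5070
#>      1            cnr 1.366    1.603 1.5842
#>      1         res_px 1.754    1.755 1.5109
#>      1 snr_over_res15 2.513    3.347 4.5806
```

Reading the table: cSART attains the highest flat-region SNR (8.51) and the
best resolution (1.51 px), hence by far the best information-per-photon
proxy SNR/Res^1.5; the regularized gridding method sits between cSART and
FBP in SNR; FBP keeps the highest boundary contrast (0.234) — the sharpest
tissue interfaces at the cost of the most noise.

Reader statistics work the same way on rating tables
(case × reader scores in −2..+2 against a reference):

```r
vg <- vgc_auc(simulate_rating_table(pair_shift = 0.8, seed = 901)$score,
              rep(1:7, each = 10), rep(1:10, 7), seed = 902)
vg
#> AUC_VGC = 0.843 (95% CI 0.757-0.914, p = 0 vs 0.5; 2000 resamples, 7 readers)
```

An AUC of 0.5 denotes equivalence of the compared image sets; 0.843 means
the test images were rated clearly better, with the confidence interval from
2000 two-level bootstrap resamples of readers and cases.

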
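---
title: "An in silico abdominal phantom for quantitative susceptibility mapping"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An in silico abdominal phantom for quantitative susceptibility mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsmphantom)
```

## Why a synthetic abdominal ground truth

Quantitative susceptibility mapping (QSM) inverts the dipole relation
between tissue magnetic susceptibility and the measured off-resonance
field. The inversion is ill-posed (the dipole kernel vanishes on a
conical surface in k-space), so every practical algorithm regularizes,
and regularization choices can only be judged against a known truth. In
the abdomen no in vivo truth exists: multi-orientation references cannot
be acquired in a breath-hold, and bottle phantoms lack realistic
geometry, texture, fat and gas. `qsmphantom` therefore builds the truth
synthetically — a labelled anatomy, susceptibility and R2\* maps with
controlled class means and realistic within-class texture — and then
simulates the full multi-echo gradient-echo acquisition on top of it.

This vignette explains the models, the parameters that matter, the
numerical choices, and what the shipped tests do and do not demonstrate.

## The anatomy generator

`generate_label_volume()` builds a deterministic label volume from
geometric primitives: an elliptical body cross-section extruded along
the axial (z, B0) axis, a subcutaneous-fat shell, ellipsoids for the
parenchymal organs, tubes for vessels, esophagus, spine and gut, a
segmented spine (vertebrae with periodic intervertebral disks and an
inner cord), and tubes of gas inside the large intestine and stomach.
Label IDs are stable: 0 is external air, 1–23 are the internal classes,
24 is the pathologic-lobe class inserted on demand. Organ placement is
jittered by the seed within ±2 % of the grid, which changes voxel
ownership but never the class inventory; generation is a pure function
of `(shape, seed)`.

What the generator emulates is class *topology* — every tissue class of
an abdominal segmentation is present, gas tubes provide internal
background-field sources, the fat shell provides strong chemical-shift
contributions at the body boundary. What it does not emulate is
anatomical realism: organ shapes are smooth quadrics, there is a single
"subject" per seed family, and no atlas registration. Conclusions that
depend on fine anatomical morphology (e.g. streaking along realistic rib
geometry) do not transfer from this phantom to patient data; conclusions
about model behavior (fat bias, background handling, noise propagation,
inversion error) do.

`generate_property_volumes()` assigns per-class water/fat/R2\* levels
typical of 3 T abdominal GRE (fat-dominant classes get high fat signal;
bone and disks get high R2\*; air carries nothing) and superimposes
smooth texture: Gaussian white noise low-pass filtered with a 2-voxel
kernel, scaled to ±20 % of the class mean. The filtering scale was
chosen once so that the normalized modulators are non-constant inside
every class — a requirement for the texture model below to be
identifiable — while remaining spatially correlated like real
parenchymal texture.

## The susceptibility and R2* texture models

The three property volumes are min–max normalized to [0, 1] over the
body mask (`normalize_unit()`; external air is excluded so that the unit
range spans tissue, not air). For a tissue class $t$ the synthetic
susceptibility is

$$\chi_t^s(r) = \bar\chi_t + a_t\,(r2^*(r) - \bar{r2^*_t})
  + b_t\,(\varrho_W(r) - \bar\varrho_{W,t})
  + c_t\,(\varrho_F(r) - \bar\varrho_{F,t})$$

with the bars denoting arithmetic means over the *whole* class mask.
Because every modulator is mean-centered over that mask, the class mean
of $\chi_t^s$ equals the assigned $\bar\chi_t$ exactly — the property
the test suite checks to machine precision, and the reason the
pathologic-lobe calibration values (0.2 ppm, 150 s⁻¹) are reproduced
exactly by construction rather than approximately. The synthetic R2\*
map uses the same expression with the water and fat terms removed, and
only for classes whose `modify_r2` flag is set; all other classes copy
the experimental R2\* voxel-wise. R2\* is clipped at zero from below.

The per-class parameter tables ship as CSV (`tissue_parameters()`):
`chi_mean_ppm` ($\bar\chi_t$), the texture weights `a/b/c_ppm`,
`r2_mean_hz` and `a_r2_hz` for modified classes, and per-class flags for
smoothing exclusion, background sources, and statistics exclusion. Air
classes and the large intestine carry fixed susceptibilities (9.2,
4.84 and 4.84 ppm) with zero texture weights. Muscle and esophagus have
$\bar\chi_t = 0$ (muscle is the zero reference) but still receive
texture modulation, so no class is piecewise constant.

`fit_texture_weights()` provides the least-squares initialization of
$(a_t, b_t, c_t)$: ordinary least squares of a target susceptibility on
the three centered modulators over the class mask, equivalent to
minimizing the per-class nRMSE. The solution uses an SVD pseudoinverse,
so collinear modulators (e.g. water and fat textures that coincide)
return the minimum-norm solution instead of failing. On noiseless
self-generated targets the recovery is exact — a linear-identifiability
property the tests exercise. The manual visual-inspection tuning that a
phantom designer would apply afterwards is deliberately out of scope.

## Partial-volume mixing

Sharp class boundaries are unrealistic at abdominal resolution, so each
binary class mask is smoothed with an isotropic Gaussian of σ = 0.5
voxel before mixing:

$$\chi^s(r) = \frac{1}{M(r)} \sum_t \chi_t^s(r)\, M_t(r), \qquad
  M(r) = \sum_t M_t(r).$$

Vessels (hepatic veins, portal vein), the heart, the large intestine and
the air classes are excluded from smoothing and keep binary masks,
preserving the sharp interfaces those structures have in practice.
Numerical choices: σ is in voxel units (the physical voxel is ~2 mm, so
half a voxel matches the sub-voxel blur of a low-resolution
acquisition), the kernel is truncated at 4σ, and boundaries are
zero-padded — safe because every mask is compact inside the grid. Since
the label map partitions the grid, $M(r) > 0$ everywhere and the mixed
map is a convex combination of the per-class maps; the weights
$M_t/M$ sum to one identically, which the tests assert exactly. Mixing
is applied to susceptibility only; the R2\* map keeps per-class
assembly, since relaxation-rate blending across interfaces is not what
the signal model needs as its ground truth.

## Field synthesis

The fieldmap is synthesized in k-space,
$f_B = \gamma B_0\, \mathcal{F}^{-1}\{\mathcal{F}(\chi)\, D(k)\}$, with
$\gamma = 42.5775$ MHz/T, χ in ppm (the $10^{-6}$ is applied
internally) and ×2 zero-padding per dimension to suppress
circular-convolution aliasing; a property test checks that a compact
source's field changes by less than 1 % when the padding is doubled
again. Two kernels are available:

* **continuous** — $D(k) = 1/3 - k_z^2/|k|^2$ on the DFT frequency grid
  (zero-frequency sample set to 0). This is the classical closed form
  and the oracle used in the sphere test: a uniform sphere's external
  field must follow $\Delta f = \gamma B_0 10^{-6} (R^3/3)
  (3\cos^2\theta - 1)/r^3$ and its internal field must vanish.
* **discrete** (default for simulation) — the continuous frequencies are
  replaced by eigenvalues of the one-sided difference operator,
  $k_j \to (e^{i 2\pi m_j/N_j} - 1)/\Delta_j$. This keeps the kernel
  identical to the continuous one at low frequency (the two agree to
  well under 5 % at the lowest nonzero frequencies of a 128³ grid) but
  rolls it off toward Nyquist, damping the ringing that the sampled
  continuous kernel produces around abrupt susceptibility interfaces
  (air, bone, fat). We chose this formulation over sampling the
  real-space dipole response and transforming it, because the
  real-space route converges very slowly in grid size — its low-frequency
  values are still ~18 % off at 128³ — which would make the discrete and
  continuous modes disagree where they should coincide.

Background sources (external air, large-intestine wall, gut gas) are
handled by `extend_for_background()`: axially mirrored copies of the
volume are appended below and above (so tissue does not terminate
abruptly at the slab faces) and the transverse dimensions are
symmetrically zero-padded, tripling each dimension (192×192×80 →
576×576×240). The full extended susceptibility, background sources
included, is convolved and the field cropped back. Under the default
*perfect background-removal* assumption the background classes are
instead zeroed and masked before simulation, and the susceptibility map
is demeaned over the evaluation mask — the inversion only determines χ
up to a constant, so the truth is expressed relative to a zero mean.

## Signal model and protocols

Each voxel evolves as
$S(r, TE_k) = (\rho_W + c_k \rho_F)\, e^{(i 2\pi f_B - R2^*)TE_k}$ with
the six-peak fat coefficient
$c_k = \sum_m \alpha_m e^{i 2\pi B_0 \gamma f_m TE_k}$, shifts
(−3.8, −3.4, −2.6, −1.94, −0.39, 0.6) ppm and amplitudes
(0.087, 0.693, 0.128, 0.004, 0.039, 0.048). The printed amplitudes sum
to 0.999; they are used verbatim so worked examples match the standard
tables, with a `renormalize` flag (default off) for users who want an
exact unit sum. $\rho_W, \rho_F$ are non-negative magnitudes — the
synthetic anatomy has no source for an initial phase map — but an
optional initial-phase volume hook exists (default zero) and the
fieldmap fit estimates an intercept so it stays robust if one is
supplied. R1 and flip-angle effects are neglected.

Protocol presets: **P1**, six echoes at TE1 = 1.8 ms, ΔTE = 1.56 ms
(water–fat separation style); **P2**, five in-phase echoes at the
single-peak spacing $1/(\gamma B_0 \cdot 3.4\,\mathrm{ppm}) \approx
2.3$ ms at 3 T. The −3.4 ppm peak is used for the in-phase definition
because it is the dominant peak of the six-peak model; the remaining
peaks make "in-phase" only approximate ($|c_k|$ = 0.82 rather than
0.999 at 2.3 ms), which is precisely the bias an in-phase protocol
suffers with real fat, and the phantom reproduces it.

Noise: the series is rescaled so its peak magnitude equals
`peak_snr` × σ with σ = 1 per quadrature component, then unit-variance
complex Gaussian noise is added. Defining SNR at the series peak (not
per echo) matches how a peak SNR of 100 is specified for this kind of
simulation; the acceptance script verifies the empirical σ from the
injected residuals.

## Baseline reconstruction

The reconstruction path is intentionally minimal — enough to exercise
the phantom end to end, not to compete with regularized inversion:

* `temporal_unwrap()` unwraps phase along echoes per voxel by linear
  extrapolation (wraps at the first echo are unrecoverable; within-echo
  spatial unwrapping is out of scope).
* `fit_fieldmap()` performs magnitude-weighted linear least squares of
  unwrapped phase on TE with an intercept. Magnitude weighting was
  chosen because the phase variance of a complex measurement is
  inversely proportional to its magnitude SNR; voxels with fewer than
  two nonzero-magnitude echoes are flagged unreliable.
* `fidelity_weight()` implements the magnitude-based fidelity weight
  $W = \sum_i |S(TE_i)|^2 TE_i / \sum_i |S(TE_i)| TE_i$, interpreting
  the signal as its magnitude (a complex-valued weight would not be
  usable) and defining 0/0 = 0.
* `tkd_inversion()` divides the field by the kernel in k-space with
  kernel values below a threshold replaced by ±threshold. The default
  threshold 0.2 trades cone artifacts against noise amplification; on
  noiseless data the round-trip error decreases monotonically as the
  threshold decreases, a property the tests check.
* `fit_r2star_loglinear()` fits log magnitude vs TE. It is exact for
  water-only voxels and knowingly biased wherever fat modulates the
  magnitude; fat voxels are therefore excluded from quantitative claims.

## Scenarios

* **HS** — healthy subject: literature/experimental class means, R2\*
  kept experimental everywhere.
* **PL** — pathologic lobe: whole-mask class means for every class
  (lower inter-class contrast) plus a lobe carved out of the liver near
  its centroid with mean χ 0.2 ppm and mean R2\* 150 s⁻¹. The lobe's
  texture weights default to the liver's, and its R2\* texture amplitude
  (60 s⁻¹) was fixed once as a plausible heterogeneity for a focal
  lesion; both choices are irrelevant to the class means, which the
  zero-mean modulators preserve exactly.
* **IO** — iron overload: liver (0.60 ppm, 100 s⁻¹), spleen (0.28,
  54), pancreas (0.20, 57) and vertebrae (0.05, 145) are modified with
  their own texture weights; everything else follows HS.

## Metrics

`nrmse()` is the residual 2-norm over the reference norm, ×100.
`xsim()` is the SSIM framework evaluated in 3D with a Gaussian window
(σ = 1.5 voxels) and constants $C_i = (K_i L)^2$ with K1 = 0.01,
K2 = 0.001 and the data range $L$ fixed to a configured susceptibility
span (default 1 ppm) rather than per-image extrema — susceptibility is a
physical quantity, so the similarity scale should not depend on each
map's outliers. The small K2 keeps the score sensitive to structural
differences in faint textures; anticorrelated structure drives the
cross-covariance term and the score negative. All constants are recorded
in the returned report. These defaults are configuration, not dogma:
users comparing against other published XSIM values should set the
constants accordingly.

## Problem sizes and determinism

The default test grid is 64×64×48 (the full 192×192×80 geometry is
supported and is used for the background-extension shape checks); the
sphere-oracle property runs at 128³. These sizes were chosen as the
smallest at which every class is comfortably resolved and the
shell-oracle statistics are stable. Every stochastic stage (anatomy
jitter, property texture, noise) derives an independent stream from the
single user seed, so a pipeline run is bit-reproducible from
`(config, seed)`, including its noisy stages, and the output manifest
records the configuration and per-file checksums.

## Known limitations

* Single procedural "subject"; no anatomical variability beyond seed
  jitter, no atlas registration.
* Static anatomy: no respiratory motion, single static PDFF.
* No water–fat separation algorithm is included; P1-style data is
  processed quantitatively only in water-only configurations, while P2
  data is processed directly, fat present.
* The TKD baseline amplifies noise strongly near the dipole cone; it is
  a plumbing baseline, not a recommendation.
* Background-field *removal* is not implemented; the pipeline either
  simulates background fields explicitly or assumes their perfect
  removal.
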
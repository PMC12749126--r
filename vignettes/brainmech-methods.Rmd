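---
title: "Methods: two-scale brain biomechanics with brainmech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-scale brain biomechanics with brainmech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainmech)
```

## Scope and model

brainmech analyses brain mechanical properties at two scales with two
independent measurement chains, each paired with a synthetic-data
generator that provides exact ground truth.

At the **tissue scale**, magnetic resonance elastography images a
harmonic shear wave propagating through tissue. For an incompressible,
isotropic, locally homogeneous viscoelastic medium, the steady-state
displacement amplitude $u$ at angular frequency $\omega = 2\pi f$
satisfies the shear-wave Helmholtz equation

$$G^* \,\Delta u = -\rho\,\omega^2 u,$$

where $G^* = G' + iG''$ is the complex shear modulus (storage and loss,
Pa) and $\rho$ the density. Incompressibility removes the dilatational
term: the compressional Lamé constant never enters, and the simulated
fields are divergence-free by construction (transverse polarization).

At the **cell scale**, AFM nanoindentation with a spherical probe is
described by the Hertz contact model

$$F = \tfrac{4}{3}\,\frac{E}{1-\nu^2}\,\sqrt{R}\,\delta^{3/2},$$

with Young's modulus $E$, Poisson ratio $\nu = 0.5$ (incompressible
cell), probe radius $R$, indentation depth $\delta$ and force
$F = k\,d$ from the cantilever spring constant $k$ and deflection $d$.
Note the model is frequently misprinted in inverted form in the
literature; the relation above is the dimensionally consistent spherical
Hertz law and is what this package implements throughout.

## The synthetic world

The generators emulate a specific small-animal imaging protocol: 1.0 kHz
vibration, $96\times96$ in-plane matrix at $0.2\times0.2$ mm², 0.3 mm
slices, four phase offsets uniformly sampling one vibration period, six
encoding directions ($\pm x, \pm y, \pm z$); and a cell-indentation
protocol with $R = 6\,\mu$m, $k = 0.1$ N/m, deflection sensitivity
33 nm/V, 1.5 µm ramp. These are the package defaults.

**Wave fields** are steady-state plane shear waves per labelled region:
$u(r) = A\,p\,\exp(-i k\, n\cdot r)$ with complex wavenumber
$k = \omega\sqrt{\rho/G^*}$, principal root ($\mathrm{Re}\,k>0$,
$\mathrm{Im}\,k\le 0$), so amplitude decays along the propagation
direction $n$ for any lossy medium and the field satisfies the
Helmholtz relation exactly — the simulator doubles as the inversion's
oracle. Multi-region phantoms give each voxel its region's wavenumber
with a common phase origin; fields are smooth within regions and
piecewise at boundaries, which is why the bundled two-region phantom
propagates the wave *along* the region boundary (each region then
carries an undisturbed plane wave and cross-talk is confined to the
stencil width). Wave amplitude defaults to 5 µm, the scale observed in
vivo. Density is not measurable by this protocol; the standard brain-MRE
assumption of 1000 kg/m³ is the default and is configurable.

**Encoding** lumps the gyromagnetic ratio, gradient amplitude and MEG
waveform into one sensitivity $\xi$ (rad per meter of displacement;
default $10^5$, keeping a 5 µm wave within $\pm\pi$ before background).
Offset $t$ of $N$ advances the vibration phase by $2\pi/N$:
$\phi_{d,t} = \mathrm{wrap}(s_d\,\xi\,\mathrm{Re}[u_d e^{+2\pi i t/N}]
+ \phi_{bg} + \varepsilon)$, with polarity $s_d = \pm1$. The positive
temporal exponent is deliberate: it makes the fixed analysis-side DFT
convention $(2/N)\sum_t \phi_t e^{-2\pi i t/N}$ return exactly
$\xi\,u$, so decoding is plain division by $\xi$ and the loss modulus
keeps its physical sign. Noise is additive Gaussian on phase, the
small-noise limit of complex MR signal noise.

**Force curves** solve, past the contact point, the force balance
between cantilever and Hertz contact with compliance-corrected
indentation $\delta = (z - z_0) - d$ (safeguarded Newton on the
equivalent cubic, relative tolerance $10^{-13}$); pre-contact deflection
is pure baseline noise. Cell populations draw $E$ from a normal
distribution truncated at $E>0$.

What the synthetic world does **not** contain: pulse-sequence physics
(k-space, TR/TE, coils), actuator/hardware behaviour, heterogeneous FEM
wave propagation, compressional waves, viscoelastic (rate-dependent)
indentation, substrate bottom effects, cell geometry. A green test
therefore establishes the correctness of the *analysis* chain on data
that satisfy the model assumptions exactly — not the fidelity of any
instrument.

## Reconstruction chain

1. **Polarity differencing.** $\mathrm{wrap}((\phi_+-\phi_-)/2)$ per
   axis and offset cancels static background phase exactly and is exact
   whenever the background does not push the two polarities across
   different wrap boundaries (always true for the default zero
   background; with large wrapped backgrounds *and* wrap-inducing
   amplitudes, the half-difference acquires $\pi$-ambiguities, a known
   limitation of this ordering — unwrap per-volume first in that
   regime).
2. **Unwrapping.** Each (axis, offset) volume is unwrapped slice by
   slice with a quality-guided region-growing algorithm (pixels
   integrated in order of local phase smoothness; implemented in C++).
   Only integer multiples of $2\pi$ are ever added, so congruence with
   the input is exact and assertable. The global per-component constant
   is normalized by subtracting the mask-median $2\pi$ multiple —
   irrelevant to the Laplacian-based inversion, but it makes outputs
   bit-reproducible.
3. **Harmonic extraction.** $(2/N)\sum_t \phi_t e^{-2\pi i t/N}$ rejects
   DC and preserves sinusoid amplitude; an RMS residual per voxel flags
   higher-harmonic or aliased content (a pure second harmonic at
   $N = 4$ is invisible to the fundamental but lights up the residual).
   Unwrapping precedes extraction because offset-to-offset phase
   differences can exceed $\pi$; unwrapping the complex harmonic's
   argument instead would discard amplitude information.
4. **Decoding.** Division by $\xi$; meters out.

On noiseless acquisitions the full chain reproduces the simulated field
to better than $10^{-8}$ relative $L^2$ error (tested), and is linear in
wave amplitude below wrapping limits.

## Inversion

Algebraic Helmholtz inversion is the per-voxel least-squares solution
across available components $j$:

$$G^* = -\rho\,\omega^2\,
  \frac{\sum_j \overline{\Delta u_j}\,u_j}{\sum_j |\Delta u_j|^2}.$$

The ratio is invariant to any (complex) rescaling of the field, so the
unknown true $\xi$ calibration cannot bias moduli.

**Laplacian.** The default `central` 3-point stencil has eigenvalue
$-4\sin^2(kh/2)/h^2$ on a plane wave of wavenumber $k$, so recovered
moduli are biased high by $(kh/2)^2/\sin^2(kh/2)$ — about $+1.3\%$ at
$k = 2000$ rad/m, $h = 0.2$ mm; this matches common practice and the
bias is pinned by a test. The `modified_wavenumber` option estimates the
local complex wavenumber per axis from the one-voxel phase ratio
$u(+h)/u(-h)$ and substitutes the analytic second derivative
$-k_j^2 u$: exact for plane waves (used by the recovery tests and the
acceptance runs), but noise-sensitive, since it takes a complex
logarithm of a ratio — prefer `central` plus smoothing on noisy data.

**Validity.** Voxels within `edge_margin` of array faces or the mask
boundary (stencil undefined) and voxels whose denominator falls below
$10^{-12}$ of its masked maximum (flat field) are marked invalid; an
entirely flat field is an error naming that cause. The fraction of valid
voxels with $G'' < 0$ is reported as a passivity QC metric: it is
exactly 0 on noiseless passive phantoms and grows with noise.

**ROI statistics** are mean and sample SD ($n-1$ denominator; the
population convention differs by $\sqrt{(n-1)/n}$ and is not used) over
valid ∩ ROI voxels, in Pa with a kPa formatter at the reporting
boundary.

**Relation to other inversions.** Published elastograms from the
motivating protocol were produced with a trained neural-network
inversion; inter-algorithm comparisons in that literature report roughly
24% offsets between AHI and tomoelastography-style (k-MDEV) pipelines
and a few percent against the network. Such differences are expected
systematic offsets between algorithms, not defects of this
implementation; this package deliberately implements the classical,
fully specified AHI.

**Shear stiffness** is reported as $|G^*| = \sqrt{G'^2 + G''^2}$. This
interpretation reproduces both published regional stiffness values from
their storage/loss pairs ($\sqrt{8.07^2+3.20^2} = 8.68$,
$\sqrt{6.60^2+2.52^2} = 7.06$ kPa), which is the package's basis for
adopting it; a wave-speed-derived stiffness $2\rho c^2$ would differ.

## Noise behaviour and its limits

With phase noise of SD 0.05 rad (typical in vivo scale), the recommended
configuration is `central` Laplacian with Gaussian pre-smoothing of
`smoothing_sd = 1.5` voxels. Smoothing commutes with the Laplacian on
interior voxels, so it does not bias plane-wave inversion by itself; the
residual bias comes from noise rectification in the $|\Delta u|^2$
denominator and is kept below 5% on ROIs where the wave retains usable
SNR. This is a real physical limit, not a tunable: with a cortex-like
loss modulus the wave amplitude decays e-fold every ~2.5 mm, so a deep
ROI is dominated by voxels with SNR $\ll 1$ where AHI is structurally
biased toward low moduli regardless of smoothing. The noise-robustness
test therefore uses a moderately attenuating phantom
($G^* = 8000 + 800i$ Pa) whose wave maintains SNR across the full ROI;
on strongly attenuating tissue, trust only regions the wave actually
reaches (the validity mask and QC metric help identify them).

## Contact detection and Hertz fitting

The contact point minimizes the residual of a two-regime piecewise
model — flat baseline before $z_0$, through-origin Hertz rise
$F = a\,\delta^{3/2}$ after — over every admissible sample split
(deterministic, derivative-free), then refines $z_0$ continuously
between the neighbouring samples by Brent minimization of the same
residual. The refinement matters: the true contact generally falls
between piezo samples, and a half-sample error in $z_0$ propagates to a
few tenths of a percent in $E$; with refinement the noiseless
round-trip is exact to numerical precision. A curve with no detectable
contact (all baseline, or non-positive fitted slope) returns a
non-converged result rather than an error.

The modulus estimator is the linearized closed form: regress $F$ on
$\delta^{3/2}$ through the origin and scale by
$\tfrac{3}{4}(1-\nu^2)/\sqrt{R}$. No iterative optimizer, no starting
values, and linearity in $E$ is exact. All post-contact points are used
by default (the protocol specifies a ramp size but no fit-depth cap); a
`max_depth` cap is exposed. Ignoring the compliance correction (using
$\delta = z - z_0$) inflates $\delta$ and systematically underestimates
$E$; a test pins this sign.

Group dispersion is reported as **both** SD and SEM, because a bare
"±" in the literature is ambiguous between them. For the published
40-cell group values, the printed ± is consistent with SEM
(SD/√40), and the group-comparison simulations interpret it that way:
population SD = √40 × printed ±. Group comparison is Welch's
unequal-variance two-sided t-test, with the effect size as percent
difference of means; degenerate zero-variance inputs follow the
documented convention (equal means → p = 1, distinct → p = 0, flagged).

## Numerical choices, tie-breaks, degenerate inputs

- Phase wrapping maps to $(-\pi, \pi]$ with $-\pi \mapsto \pi$; both the
  R and C++ implementations use the same closed form.
- The unwrapper seeds each connected mask component at its
  highest-quality pixel; separate components carry independent $2\pi$
  constants (they cannot be related without a path).
- Gaussian smoothing is separable with edge renormalization, so
  constants are preserved exactly at boundaries.
- The modified-wavenumber stencil falls back to the central value at
  voxels where the local estimate is non-finite (zero-amplitude
  components, mask edges).
- Encoding with `noise_sd = 0` is exactly deterministic (no RNG draw);
  all randomness flows through explicit integer seeds and never touches
  global RNG state.
- NIfTI-1 I/O is a deliberately narrow hand-written reader/writer
  (little-endian, float32/float64, 3D/4D, no scaling): the target R
  environment has no NIfTI package, and the format subset written by
  this package is exactly the subset read. Voxel sizes live in mm in
  headers (NIfTI convention) and meters everywhere else.

## Known limitations

- AHI assumes local homogeneity; voxels near region boundaries are
  biased (hence eroded ROI masks and the edge margin).
- The plane-wave phantom cannot probe scattering, mode conversion, or
  curved wavefronts; recovery accuracy there says nothing about complex
  in-vivo wave patterns.
- Low-SNR (strongly attenuated) regions bias AHI downward; see the
  noise section.
- The polarity-difference-first ordering has $\pi$-ambiguities under
  simultaneous large wrapped backgrounds and wrap-inducing amplitudes.
- The Hertz fit assumes a quasi-static, purely elastic, flat,
  infinitely thick sample; ramp-rate dependence and substrate effects
  are out of scope.
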
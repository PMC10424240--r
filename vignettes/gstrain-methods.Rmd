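---
title: "Multi-frequency line-width analysis of nitroxide spin probes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-frequency line-width analysis of nitroxide spin probes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gstrain` implements the theoretical side of a multi-frequency continuous-wave
(cw) EPR study of a small nitroxide spin probe in frozen aqueous solution:
powder spectrum simulation from spin-Hamiltonian parameters, synthesis of
ensemble ("theoretical") spectra from per-snapshot g- and hyperfine values,
geometric hydrogen-bond classification of solvation trajectories, global
multicomponent fitting of the spectra, and quantification of g-strain from the
frequency dependence of the fitted apparent line widths. This vignette
documents the models, the numerical choices, and what the synthetic-data
round trips do and do not demonstrate.

## The spin Hamiltonian and the powder spectrum

A nitroxide is described by one electron spin $S = 1/2$ coupled to the
$^{14}$N nucleus ($I = 1$) of the N–O moiety:

$$\hat H = \mu_B\, \mathbf B_0 \cdot \mathbf g \cdot \hat{\mathbf S}
         + \hat{\mathbf S} \cdot \mathbf A \cdot \hat{\mathbf I},$$

with collinear principal frames for $\mathbf g$ and $\mathbf A$ (the
conventional N–O molecular frame; no tilt angles are introduced because none
are resolved for this class of probe). The nuclear Zeeman and quadrupole
terms are not resolved in frozen-solution cw spectra at any of the four bands
treated here and are omitted. Physical constants are pinned to CODATA 2018
($h = 6.62607015\times10^{-34}$ J s,
$\mu_B = 9.2740100783\times10^{-24}$ J/T), which fixes field positions to
better than 0.01 mT.

For a field direction $\mathbf n$ in the molecular frame the effective
g-value is $g_{\rm eff}(\mathbf n) = (\sum_i g_{ii}^2 n_i^2)^{1/2}$. Two
resonance solvers are provided:

* **exact** (default for `resonance_lines()` and `powder_spectrum()`):
  numerical diagonalization of the 6-dimensional Hamiltonian with a bisection
  search in field for each of the three
  $\Delta m_S = \pm1,\ \Delta m_I = 0$ transitions (bisection tolerance
  $10^{-4}$ mT, search window $h\nu/(2.5\mu_B)$ to $h\nu/(1.5\mu_B)$ widened
  by the maximal hyperfine offset). Transitions are identified by their
  transition moments, so the assignment is stable even where hyperfine
  branches would cross in energy order.
* **first order** (`solver = "first_order"`): the closed form
  $B(m_I) = h(\nu - m_I A_{\rm eff})/(g_{\rm eff}\mu_B)$ with
  $A_{\rm eff}^2 = \sum_i g_{ii}^2 A_{ii}^2 n_i^2 / g_{\rm eff}^2$. The two
  solvers agree to better than 0.01 mT whenever $A/\nu < 10^{-3}$; at X band
  with $A_{zz} \approx 100$ MHz the exact solver deviates from the closed
  form by the textbook second-order shift
  $A^2[I(I+1) - m_I^2]/(2\nu)$, about 0.02–0.04 mT, which the test suite
  verifies against the analytic formula. Ensemble synthesis and fitting use
  the first-order solver: it is three orders of magnitude faster, and
  because synthesis and fit pass through the same solver the round trip is
  exact while absolute field positions stay well below the fitted line
  widths in error.

The three hyperfine lines carry equal weight by default, the high-field
limit appropriate for nitroxides at and above X band; exact transition
moments are available behind `amplitudes = TRUE`.

**Orientation averaging.** Collinear orthorhombic tensors make the spectrum
invariant under inversion of any molecular axis, so averaging is restricted
to one octant. Knots are midpoints of a uniform grid in
$(\cos\theta, \phi)$ — an equal-area scheme where every knot carries the same
weight. The per-band default densities (40/60/90/130 knots per dimension for
X/Q/W/J) were fixed by a convergence study: doubling the density changes no
point of the two-component reference spectrum by more than $10^{-3}$ of the
peak at any band. Higher bands resolve more g-anisotropy per line width and
need denser grids.

**Line broadening.** Residual (unresolved hyperfine + intrinsic) broadening
is modeled as an orientation-dependent Gaussian with FWHM
$\Gamma(\mathbf n) = (\sum_i n_i^2 \Gamma_i^2)^{1/2}$ in frequency units
(MHz), converted to field per orientation by $h/(g_{\rm eff}\mu_B)$ — the
apparent line width (alw) convention of anisotropic residual-width fitting.
All widths in the package are FWHM in MHz.

**Accumulation numerics.** Summing an explicit Gaussian per (orientation,
$m_I$) line scales poorly with grid density and ensemble size, so the default
accumulator bins each line's weight area-preservingly into the two
neighbouring field bins *and* linearly between two bracketing width classes
(16 classes spanning the width range of the pattern), then convolves each
class histogram once with its Gaussian kernel. The direct per-line evaluation
is retained (`method = "direct"`) and the test suite keeps the two routes
within numerical agreement; widths are floored at half a field step. The
absorption spectrum is normalized to unit trapezoidal area; the
auto-ranged field axis pads all first-order resonance extremes by five
maximal line widths so that no Gaussian wing is clipped by the
normalization.

First-derivative (lock-in detected) traces use fourth-order centered
differences in the interior; re-integration uses the trapezoid rule with the
Euler–Maclaurin end-slope correction, making the
differentiate-then-integrate round trip accurate to well below $10^{-6}$ of
the peak on realistic axes.

## Ensemble ("theoretical") spectra

Molecular-dynamics-derived ensembles enter as *snapshot tables*: one row per
frame with principal g- and A-values and an optional H-bond count label
(CSV/JSON schema `id, time_fs, gxx, gyy, gzz, Axx_MHz, Ayy_MHz, Azz_MHz,
n_hbonds`). `theoretical_spectrum()` simulates one powder spectrum per
snapshot on a shared field axis — a single isotropic 17 MHz Gaussian stands
in for all field-independent broadening — and returns the normalized sum.
Grouping labeled snapshots by H-bond count gives per-subensemble mean
parameters and population weights (`subensemble_means()`), from which
`tcomp_spectrum()` builds the weighted multicomponent spectrum; with zero
within-label scatter the two routes agree pointwise to $10^{-6}$ of peak,
which the tests assert. All snapshots share one orientation grid and the
stick histograms are accumulated across snapshots before the single
convolution pass, so a thousand snapshots at four bands complete in well
under a minute.

## Hydrogen-bond classification

A water donates an H-bond to the probe oxygen when

$$r_{\mathrm{O\cdots H}} < -1.71\,\cos\theta + 1.37 \quad (\mathrm{\AA}),$$

where $\theta$ is taken **at the hydrogen**, between the directions from the
hydrogen to the acceptor oxygen and to its own (donor) oxygen. Under this
convention an ideal linear H-bond has $\cos\theta = -1$ and a distance
ceiling of 3.08 Å; the donor-centred reading would make the threshold
negative for all physical geometries, so the hydrogen-centred reading is the
only one under which the criterion admits bonds — this geometric argument is
the basis of the convention chosen here. A water bonded through both of its
hydrogens counts once (populations are per water molecule). Cubic periodic
boxes are handled with the minimum-image convention; non-periodic frames
(gas-phase clusters) are supported. *Interstitial* waters are first-shell
waters — oxygen–oxygen distance within 3.3 Å, the first minimum of the
radial distribution function — that are not H-bonded. The classifier is
tested exhaustively against the direct inequality and against brute-force
27-image enumeration.

## Multicomponent global fitting

The phenomenological model holds $n$ components differing only in $g_{xx}$
and population weight; $g_{yy}$, $g_{zz}$ and the hyperfine tensor are
shared, as is one alw triplet per band across components, while the triplets
differ freely between bands. The spin-Hamiltonian parameters are global over
all bands — the defining constraint of the multi-frequency fit.

The published analyses judge fit quality by visual inspection of the
experiment/simulation overlay; a quantitative surrogate is required here,
and the one adopted is bounded Levenberg–Marquardt least squares
(`minpack.lm`) on the concatenated per-band residuals of first-derivative
traces normalized to unit maximum. Max-normalization equalizes band
influence and makes the fit invariant to amplitude scaling. Design choices
that matter:

* g-values are carried internally as $(g - 2)\times10^4$ and the
  finite-difference step is $10^{-4}$ relative, so the numerical Jacobian
  resolves changes of $10^{-5}$ in g — the instrumental resolution claimed
  for this kind of analysis.
* Weights live on the simplex through a logistic transform; components are
  reported sorted by descending $g_{xx}$, and a fitted separation below
  $5\times10^{-5}$ raises an `unresolved` flag.
* Per-band rigid field offsets (calibration nuisance parameters) exist but
  are fixed at zero unless freed.
* Bands without data keep their width triplets frozen; non-convergence is
  reported as a flagged result with diagnostics, not an error.

For spectra synthesized from ensembles, the analysis protocol pins g, A and
the weights to the values delivered by the subensemble analysis and fits
only the width triplets. This mirrors how ensemble-derived spectra are
treated in practice (the component parameters *are* the subensemble means;
only the widths are unknown) and avoids a real degeneracy: when the
component separation is smaller than the strain broadening, a free fit can
trade component splitting against alw$_{xx}$ with almost no residual
penalty, biasing the width low.

## Strain decomposition

Independent Gaussian broadenings convolve, so their FWHMs add in
quadrature:

$$\mathrm{alw}^2(\nu) = \mathrm{lw}_0^2 + \mathrm{lw}_{\rm fd}^2(\nu).$$

`field_dependent_width()` inverts this (clamping to zero, with a flag, when
fit noise puts alw below the floor), and `strain_slope()` fits
$\mathrm{lw}_{\rm fd}$ versus microwave frequency through the origin,

$$s = \frac{\sum_i \nu_i\, \mathrm{lw}_{{\rm fd},i}}{\sum_i \nu_i^2},$$

with both quantities in the same unit; $s \times 10^6$ is the ppm slope that
serves as the scalar g-strain metric. By default only the W- and J-band
points enter (plus the origin): at X and Q band the apparent width is
dominated by the field-independent floor and carries no slope information.
The floor defaults to 17 MHz — the value used when synthesizing theoretical
spectra, estimated in the source analysis from the X-band apparent width —
and is user-supplied for experimental series. Clamped points are excluded
from the regression. A Gaussian g-scatter of standard deviation $\sigma_g$
produces exactly such a linear term with
$s = 2\sqrt{2\ln 2}\,\sigma_g/g$, which is what `sigma_from_slope()`
inverts.

## Synthetic data: what the generators emulate

No trajectory or quantum-chemistry data are deposited with the source
analysis, so the package generates every input it needs:

* **Snapshot ensembles** (`ensemble_spec()`/`generate_snapshots()`): labels
  drawn multinomially from the subensemble weights, per-axis independent
  Gaussian g/A draws about the subensemble means. The default means and
  weights are the packaged solvated (explicit-solvation) subensemble table —
  two components at 0.69/0.31 — and the default scatter emulates the
  per-axis strain slopes that the packaged width table itself implies
  (`reference_axis_slopes()`: ≈376, 162 and 45 ppm for x, y, z). Scatter on
  all three axes matters: a hypothetical ensemble whose $g_{yy}$/$g_{zz}$
  never fluctuate is inconsistent with the reference widths (alw$_{yy}$
  grows from ~17 to ~45 MHz between X and J band) and, because the
  anisotropic-Gaussian width model interpolates orientations by quadrature
  while pure single-axis scatter broadens like $n_x^2$, fitting such an
  ensemble biases alw$_{xx}$ low by tens of percent. An optional
  $g_{xx}$–$A_{zz}$ anticorrelation knob exists but defaults to off: no
  snapshot-level covariance is reported for the reference system, and the
  true snapshot distribution (Gaussian versus heavy-tailed) is equally
  unreported — Gaussianity is an assumption of the generator, not a finding.
* **Toy trajectories** (`trajectory_spec()`/`generate_trajectory()`): per
  frame an H-bond count is drawn from the target populations (default
  10/60/30% for 1/2/3 bonds), that many waters are placed inside the
  criterion region (truncated-normal $r$ and $\cos\theta$), and the
  remaining waters are placed with both hydrogens pointing away from the
  acceptor so they cannot satisfy the criterion — a fraction inside the
  3.3 Å shell to create interstitials. Frames emulate only what the
  classifier needs: there is no water–water structure, no realistic radial
  distribution function, and no dynamics.
* **Noise** (`add_noise()`): seeded white Gaussian noise scaled to the peak.

Passing round trips on these generators demonstrates the *internal
consistency* of the pipeline — that a known scatter is recovered through
ensemble synthesis, fitting and regression to within ~5–10% at a thousand
snapshots — not the accuracy of any electronic-structure prediction, and not
robustness to the correlated, non-Gaussian scatter real trajectories may
produce.

## Problem sizes and determinism

The shipped analyses and tests use 1000-snapshot ensembles at four bands,
1024-point field axes, the per-band default grids, and trajectories of a few
hundred to 1500 frames with 10 waters; the complete end-to-end pipeline runs
in about two minutes on one CPU. All generators take explicit integer seeds
and restore the caller's RNG state; file writers emit fixed-precision text,
so outputs are reproducible byte-for-byte for a given configuration and
seed.

## Known limitations

* Slow-motion (liquid-state) line shapes, relaxation-time prediction, and
  modulation-amplitude distortion are out of scope; spectra represent the
  rigid-limit powder regime.
* A single $^{14}$N hyperfine coupling; no further nuclei.
* The g/A principal frames are assumed collinear; tilt would alter powder
  line shapes at high band.
* The fit objective is a documented surrogate for the source analysis'
  visual inspection; different objectives shift fitted widths by a few
  percent, which is part of the reason the end-to-end strain tolerance is
  10% rather than 1%.
* Vacuum reference widths at X and Q band are absent from the packaged width
  table (unreadable in the source); only W and J enter the regressions, so
  the slopes are unaffected.
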
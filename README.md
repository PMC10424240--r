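# gstrain

Multi-frequency EPR line-width and g-strain analysis of nitroxide spin
probes.

## The problem

Frozen-solution cw EPR spectra of nitroxide radicals broaden with microwave
frequency because the molecules in the ensemble do not share one g-tensor:
solvation structure (hydrogen bonds to the N–O oxygen) and internal
configurational dynamics scatter the principal g-values, most strongly
g_xx. At a fixed band this *g-strain* is invisible under the
field-independent broadening from unresolved hyperfine couplings; across
bands it reveals itself as a linear growth of the apparent Gaussian line
width (alw) with frequency. `gstrain` implements the full analysis chain
used to quantify this effect for a small pH-sensitive nitroxide in water:

1. **Powder spectrum simulation** for S = 1/2 coupled to one ¹⁴N (I = 1)
   under the spin Hamiltonian
   `H = μB·B₀·g·S + S·A·I` (collinear tensors; nuclear Zeeman and
   quadrupole neglected), with exact matrix-diagonalization and first-order
   closed-form resonance solvers and anisotropic Gaussian broadening
   Γ(n) = (Σᵢ nᵢ²Γᵢ²)^½ (FWHM, MHz).
2. **Ensemble spectra**: normalized sums of per-snapshot spectra from
   trajectory-derived g/A tables, and H-bond subensemble component spectra.
3. **H-bond classification** of solvation frames at the nitroxide oxygen by
   the geometric criterion r(O···H) < −1.71 cos θ + 1.37 Å (θ at the
   hydrogen), population statistics, and first-shell "interstitial" waters
   (within 3.3 Å, not bonded).
4. **Global multicomponent fitting** of the four-band spectra: per-component
   g_xx and weights, shared g_yy/g_zz/A, one apparent line-width triplet per
   band (bounded Levenberg–Marquardt on max-normalized first-derivative
   residuals).
5. **Strain quantification**: the field-independent floor lw₀ is removed in
   quadrature, alw² = lw₀² + lw_fd², and the field-dependent part is
   regressed through the origin against frequency; the slope in ppm,
   s = Σνᵢ·lw_fd,ᵢ / Σνᵢ² × 10⁶, is the scalar g-strain metric.

A synthetic-data module generates every input the pipeline needs — labeled
snapshot ensembles with controlled subensemble structure and g-scatter, toy
solvation trajectories with prescribed H-bond populations, and noisy
pseudo-experimental spectra — so all analyses run without external data.

## Worked example

Strain slopes from the packaged per-band apparent line widths (17 MHz
field-independent floor, weighted component means, through-origin regression
over the origin + W + J points):

```r
library(gstrain)
strain_slopes_by_series(alw_reference(), axis = "xx", lw0 = 17)
#>  series slope_ppm
#>  ecrism  335.0261
#>     exp  186.2026
#>    qmmm  376.3821
#>     vac  529.3051
```

The experimental series carries 186 ppm of g_xx strain; the solvated
explicit-solvation ensemble (`qmmm`) roughly doubles it, and the vacuum
ensemble is larger still — the strain mostly survives removal of the
solvent, pointing at the probe's internal dynamics as its main origin.

A complete synthetic round trip — generate 1000 snapshots at the solvated
subensemble means with g-scatter emulating a 376 ppm slope, sum per-snapshot
spectra at the X/Q/W/J bands, fit the width triplets, and regress:

```r
spec  <- ensemble_spec()                       # means, weights, scatter
snaps <- generate_snapshots(spec, n = 1000, seed = 2026)
theo  <- lapply(unname(band_frequencies),
                function(f) theoretical_spectrum(snaps, f))
sm    <- subensemble_means(snaps)
init  <- multicomponent_model(
  g_xx = sm$gxx, weights = sm$weight,
  g_yy = weighted.mean(sm$gyy, sm$weight),
  g_zz = weighted.mean(sm$gzz, sm$weight),
  A    = apply(sm[c("Axx_MHz", "Ayy_MHz", "Azz_MHz")], 2, weighted.mean,
               w = sm$weight),
  alw  = data.frame(band = names(band_frequencies),
                    frequency_GHz = unname(band_frequencies),
                    alw_xx = 20, alw_yy = 20, alw_zz = 20))
fit <- global_fit(theo, init, fixed = c("gxx1", "gxx2", "eta1", "gyy",
                                        "gzz", "Axx", "Ayy", "Azz"))
extract_alw(fit)
#>  band frequency_GHz   alw_xx   alw_yy   alw_zz
#>     X        9.7671 17.34422 16.95662 17.11314
#>     Q       33.6615 19.16265 17.89249 16.75289
#>     W       93.9930 36.84600 22.76586 17.80185
#>     J      262.8436 91.97862 46.41439 21.06953
alw <- extract_alw(fit)
strain_slope(alw$frequency_GHz, alw$alw_xx, lw0 = 17)$slope_ppm
#> [1] 344.3105
```

The fitted widths stay at the 17 MHz floor at X band and grow with
frequency along x (and, more weakly, y), and the regression recovers the
generated slope to within ten percent — the finite ensemble (1000 draws) and
the surrogate fit objective account for the residual deviation.

The numbered drivers under `analysis/` run these studies end to end and
write their tables and spectra under `results/`:

```sh
Rscript analysis/01_strain_from_reference_widths.R
Rscript analysis/02_simulate_multifrequency.R
Rscript analysis/03_hbond_populations.R
Rscript analysis/04_ensemble_fit_strain.R
```

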
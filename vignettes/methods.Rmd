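---
title: "Methods: in-situ Raman depth profiling of skin penetration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: in-situ Raman depth profiling of skin penetration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanpen)
```

## The measurement and its model

A confocal Raman depth scan of incubated skin records a grid of spectra —
by default 10 lateral positions over 5 µm by 50 depth planes over 25 µm,
each spectrum spanning 501–1635 cm⁻¹. Three facts make depth profiling of
a drug possible:

* Raman band intensity is linear in molecular concentration, so the area of
  an interference-free drug band (caffeine: 556 cm⁻¹, O=C–N deformation)
  tracks the local drug amount.
* The keratin aromatic amino-acid band at 1008 cm⁻¹ is present wherever
  there is stratum corneum and absent in the donor solution above it, so
  its depth profile locates the skin surface (half-maximum crossing) and
  measures the depth-dependent signal attenuation common to all bands.
* The instrument's axial point-spread function (PSF) is approximately
  Gaussian; its FWHM — measured as the FWHM of the depth profile of a
  silica plate's 521 cm⁻¹ band — is the depth resolution (1.86 µm for the
  class of setup this package targets).

The pipeline therefore computes, per scan: cleaned spectra → per-spectrum
caffeine band areas → three laterally averaged depth profiles → surface
crop → division by the mean keratin signal → cumulative AUC over the SC →
enhancement ratio between formulation arms.

## Preprocessing

Processing order is fixed: cosmic-ray removal, background subtraction, PCA
— each later stage assumes the earlier ones.

**Cosmic-ray removal.** A cosmic ray hits one CCD channel of one spectrum;
adjacent grid spectra are unaffected, while genuine bands are strongly
correlated across neighbouring positions. For each channel, a value is
compared against the median of the same channel in the `2 * spike_window`
neighbouring spectra (acquisition order, reflected at the scan ends;
default half-width 2). It is replaced by that median when it deviates by
more than `spike_zscore` (default 8) robust standard deviations, where the
robust SD is 1.4826 × the median absolute deviation of the neighbours — a
plain SD would itself be corrupted by the spike. Two guards stabilise the
test where the MAD degenerates: a relative floor `1e-8 * (1 + |median|)`
for exactly constant neighbourhoods, and the scan-wide median robust SD,
which prevents chance near-zero MADs in four-sample neighbourhoods from
flagging ordinary noise. On clean scans the filter is a no-op, and it is
idempotent on its own output.

**Background ("shape") subtraction.** Skin fluorescence produces a broad,
smooth baseline under the Raman bands. The baseline is estimated per
spectrum by grey-scale morphological opening — a running minimum followed
by a running maximum with a flat structuring element of `shape_size`
spectral samples (default 400) — then smoothed with a moving average of
width `shape_size / 4` (rounded, at least 3) to remove the opening's
plateau artefacts, and subtracted. Any peak much narrower than the
structuring element cannot survive the erosion, so the opening follows the
background underneath the bands; a constant offset maps exactly to zero and
the estimate is equivariant under adding a constant. The width is
interpreted in *samples*, not cm⁻¹: the structuring element acts on the
detector's pixel grid, and on the default 1 cm⁻¹ axis the two readings
coincide anyway. Both running extrema use the two-pass block (van Herk)
scheme, so cost is linear in spectrum length regardless of width. Edges are
handled by replicate-padding.

**PCA noise reduction.** All spectra of one image scan are mean-centred and
reconstructed from their projections onto the first `n_components = 3`
principal components. The systematic variation of a skin scan is
low-rank — essentially the keratin/skin pattern, the drug pattern and the
residual background — so three components retain the signal while
uncorrelated detector noise, spread over all components, is discarded. PCA
is computed per scan, not pooled across a time series: each scan is an
independent measurement with its own focus and intensity state, and pooling
would let one scan's artefacts leak into another's reconstruction. With
`n_components = n_spectra - 1` the reconstruction is the identity to 1e-8
relative — the property tests pin this.

## Profiling

**Band integration.** A band is a named window (defaults: caffeine
540–575 cm⁻¹, keratin 990–1025 cm⁻¹, silica 505–540 cm⁻¹, PET
1600–1628 cm⁻¹ — roughly symmetric windows chosen clear of neighbouring
skin bands, all configurable). Per spectrum, a local linear baseline is
anchored at the means of the three outermost samples at each window end and
subtracted, then the trapezoidal rule integrates over the window. The local
baseline makes the band area exactly zero for a constant spectrum and
insensitive to any residual linear background; areas of noise-only windows
may legitimately be negative.

**Three profiles per scan.** The 10 lateral positions are partitioned into
3 contiguous groups of sizes 3, 3, 4 and each group is averaged laterally.
Contiguous grouping uses all recorded spectra while preserving spatial
locality, so the three profiles behave like semi-independent replicates;
with 3 scans per formulation this yields the 9 replicate profiles that the
aggregation stage expects.

**Surface localization.** The keratin profile rises from near zero (donor
solution) to a plateau (stratum corneum). The surface is the depth of the
first upward crossing of half the profile maximum, linearly interpolated
between the bracketing samples; the maximum is taken after a 3-point moving
average so a single noisy sample cannot set the half-level. The first
crossing is used because the scan proceeds downward and starts ~2 µm above
the skin; a profile that starts at or above half-maximum (scan started
inside the skin) or never crosses it is a detection error, not a silent
guess. On an ideal step the estimate lands within half a depth step
(0.25 µm at the default 0.5 µm grid) of the true edge. Because the keratin
signal also attenuates with depth, its blurred profile peaks just below the
surface and the half-maximum sits slightly (~0.1 µm) above the true
surface — well inside the depth resolution, and identical for both
formulation arms, so differential quantities are unaffected.

**Cropping and normalization.** Profiles are cropped at the detected
surface and re-zeroed, interpolating a sample at exactly depth 0 when the
surface falls between planes. The caffeine profile is then divided by the
arithmetic mean of the keratin profile *over the same cropped grid, per
replicate profile*. The scope is a genuine design choice — per profile,
per scan and per time series are all defensible — and per-profile is
chosen because it corrects exactly the signal state of the profile it
normalizes; it is also the scope under which the pipeline is invariant to
global intensity rescaling (tested at 1e-9 relative). A single scalar, not
a per-depth division, is used: dividing depth-by-depth would amplify noise
where keratin is weak and change the profile shape.

**Aggregation.** Replicates are interpolated onto the common overlap grid
(step = median replicate step) and summarised by mean and sample SD per
depth; SD estimates at n = 9 are validated against chi-square bounds in the
tests.

## Metrics

The cumulative AUC integrates the normalized mean profile from the surface
to `depth_max` by the trapezoidal rule, interpolating the endpoint. The
default bound is 20 µm — the full SC thickness; it is configurable and is
deliberately not inferred from the data, so both arms are always integrated
over the same depth range. The enhancement ratio divides the enhancer arm's
AUC by the plain arm's and is reported rounded half-up to two decimals,
matching the convention of reported tables (base R's `round()` rounds half
to even, which would disagree at the boundary). FWHM estimation finds the
half-maximum crossings on either side of the profile maximum by linear
interpolation; it is invariant under amplitude scaling and depth
translation. Film thickness is the FWHM of the plateau profile: a boxcar
convolved with a symmetric PSF keeps its half-maximum width exactly, which
is why the estimator is unbiased for films much thicker than the PSF. An
alternative midpoint estimator (crossings at half-way between baseline and
plateau) is provided for profiles with a non-zero baseline.

## The synthetic generator

`simulate_skin_scan()` builds each spectrum as fluorescence baseline +
keratin band + nuisance skin bands (850, 935, 1300, 1450 cm⁻¹ at low
amplitude, clipped to the axis) + caffeine band + Gaussian noise + cosmic
spikes. Depth laws:

* caffeine: `erfc((z - surface) / (2 * sqrt(D * t)))` — the solution of
  one-dimensional Fickian diffusion from a constant-concentration boundary,
  the appropriate law for an infinite-dose incubation, convolved with the
  Gaussian axial PSF;
* keratin: a step at the surface times `exp(-(z - surface) / attenuation_len)`,
  convolved with the PSF;
* all bands are unit-area Gaussians of 8 cm⁻¹ FWHM.

Key defaults and why: grid 10 × 50 over 5 × 25 µm and axis 501–1635 cm⁻¹
at 1 cm⁻¹ (the scan geometry the pipeline targets); surface at 2.0 µm
(scans start about 2 µm above the skin); PSF FWHM 1.86 µm (the measured
depth resolution of the reference setup); `diffusion_um2_h = 8` —
*illustrative, not a fitted constant*: no reference diffusivity for
caffeine in SC exists, and this value gives a penetration front
(`2 * sqrt(D t)` ≈ 14 µm at 6 h) whose erfc tail reaches ~20 µm, the
depth scale seen in 6 h incubations; keratin amplitude 200 and caffeine
amplitude 100 area units (band peaks ≈ 23 and 12 counts); baseline
amplitude 20 counts; noise SD 0.5 counts ≈ 4% of the caffeine band peak;
spike probability 0.01 per spectrum at 50× amplitude. The enhancer arm
multiplies the caffeine amplitude (donor-concentration effect) and/or the
diffusivity by `enhancer_factor`.

The silica plate is modelled as a thin emitting plane, so its 521 cm⁻¹
depth profile *is* the axial PSF and its FWHM recovers the configured
resolution; a semi-infinite opaque plate would yield an edge, not a peak,
and would test a different estimator than the FWHM-of-profile procedure.
The PET film is a centred boxcar of the requested thickness convolved with
the PSF, read out on the 1614 cm⁻¹ band.

What the generator does **not** emulate — and what passing recovery tests
therefore cannot show about real data: refraction-induced depth distortion
(the ~0.8 µm underestimation real setups show on a 21.6 µm film has an
optical origin the simulator does not model), Poisson photon statistics
(noise is additive Gaussian for tractability; a shot-noise option would
change weighting, not structure), lateral heterogeneity of real skin
(simulated spectra are laterally identical up to noise, so the three
per-scan profiles agree more than real replicates would), furrows and
follicles, and any drug–skin binding that would break the pure-diffusion
depth law. Recovery tests validate the *estimators*, not skin physiology.

## Numerical choices and degenerate inputs

* Determinism: every simulator seeds the RNG from its config; identical
  configs give bit-identical scans. Pipeline runs derive per-scan seeds
  from the master seed.
* Scan files are plain tab-delimited text with a self-describing header;
  values are written with 15 significant digits, so read∘write is identity
  to well below 1e-9 relative. The reader rejects any file whose declared
  grid disagrees with the body, row by row.
* Surface/FWHM interpolation is linear; ties in the profile maximum resolve
  to the first (shallowest) maximum, and the *first* half-max crossing is
  taken when several exist.
* Degenerate inputs fail loudly: fewer than 3 spectra (spike filter),
  structuring element not smaller than the spectrum, `n_components` not
  below the spectrum count, band windows outside the axis, non-positive
  keratin mean, surfaces outside the profile range, profiles that never
  cross half-maximum, mismatched time keys between arms.
* Test and validation problem sizes: unit tests run the full physics on a
  reduced geometry (6 × 30 grid, 501–1100 cm⁻¹ at 2 cm⁻¹, opening width
  100 samples) — large enough that every code path including the 1008 cm⁻¹
  reference band is exercised; the end-to-end recovery checks use the full
  default geometry with 3 scans (9 profiles) per arm at one time point,
  the smallest design that matches the replicate structure the aggregation
  is specified for.

## Known limitations

Absolute concentration is out of scope: normalized caffeine signal is in
arbitrary units, and converting it to mass per volume would require a
calibration model the in-situ measurement does not provide. The enhancement
ratio compares mean profiles; no hypothesis test or bootstrap interval is
attached to it. The surface estimator assumes the scan starts above the
skin. The normalization scalar assumes the keratin band is drug-free; a
drug with a band overlapping 990–1025 cm⁻¹ would need a different
reference. Depth positions are stage coordinates: no refractive-index
correction is applied, so depths inside the tissue are nominal.
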
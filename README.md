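# ramanpen

Confocal Raman microscopy (CRM) depth profiling of drug penetration into the
stratum corneum (SC), the outermost 15–20 µm of skin that forms its main
permeation barrier. In-situ CRM records a hyperspectral image scan — a grid
of Raman spectra over a few micrometres of width and ~25 µm of depth — while
the skin is incubated with a formulation. Because Raman band intensity
scales linearly with molecular concentration, the area of a drug band versus
depth is a penetration profile, and comparing two formulations at matched
time points quantifies the effect of a penetration enhancer without any
destructive sectioning.

`ramanpen` implements the complete analysis from raw scans to enhancement
ratios, for pharmaceutical scientists comparing topical formulations:

1. **Spectral cleaning** — cosmic-ray spikes are replaced by the median of
   the same CCD channel in adjacent grid spectra (robust z-score test,
   1.4826 × MAD); the fluorescence background is removed per spectrum by a
   morphological-opening ("shape") baseline of width 400 spectral samples;
   noise is reduced by reconstructing every spectrum from the first three
   principal components of the scan.
2. **Depth profiles** — the caffeine band at 556 cm⁻¹ (O=C–N deformation,
   free of skin interference) is integrated per spectrum by the trapezoidal
   rule above a local linear baseline; the 10 lateral positions are split
   into 3 groups, giving 3 profiles per scan.
3. **Surface localization and normalization** — the skin surface is the
   depth where the keratin 1008 cm⁻¹ ring-breathing profile first crosses
   half of its maximum; profiles are cropped there and the caffeine signal
   is divided by the arithmetic mean of the keratin profile, correcting
   signal attenuation in deeper skin.
4. **Metrics** — cumulative AUC of the mean profile over depth
   (trapezoidal, default bound 20 µm) per arm and time point; the
   enhancement ratio is `AUC(enhancer) / AUC(plain)`. Setup validation:
   axial resolution as the FWHM of a silica 521 cm⁻¹ depth profile, and
   film thickness as the plateau FWHM of a PET 1614 cm⁻¹ profile.
5. **Synthetic scans** — a generator with known ground truth (erfc
   diffusion profile for the drug, step × exponential attenuation for
   keratin, Gaussian axial PSF, fluorescence baseline, noise, cosmic
   spikes) emulates caffeine-incubated skin, a silica plate and a PET film,
   so the whole chain is testable without instrument data.

## Worked example

```r
library(ramanpen)

# a simulated 2 h caffeine incubation scan (10 x 50 spectra, 501-1635 1/cm)
cfg <- synthetic_config(seed = 42, incubation_h = 2)
res <- simulate_skin_scan(cfg)
res$scan
#> <depth_scan> 10 lateral x 50 depth x 1135 wavenumbers
#>   lateral: 0..4.5 (n=10) um
#>   depth:   0..24.5 (n=50) um
#>   shifts:  501..1635 (n=1135) 1/cm

# clean, profile, crop, normalize
pre <- preprocess_scan(res$scan)
profiles <- scan_to_profiles(pre)
round(attr(profiles, "surface_um"), 3)
#> [1] 1.890 1.899 1.890          # true simulated surface: 2.0 um
profiles[[1]]
#> <depth_profile> band=caffeine state=normalized, 47 depths [0, 22.6101] um
cumulative_auc(profiles[[1]], 20)
#> [1] 4.357                      # arbitrary units * um

# enhancement ratios directly from cumulative AUC pairs
enhancement_ratio(c(4222, 6841), c(3499, 3447), digits = 2)
#> [1] 1.21 1.98

# axial resolution check on a simulated silica plate (PSF FWHM 1.86 um)
sil <- simulate_silica_scan(synthetic_config(seed = 42,
  noise_sd = 0.02 * band_peak_height(100)))
fwhm(extract_profile(split_lateral_groups(sil, 1)[[1]],
                     default_bands()$silica))
#> <resolution_result> FWHM = 1.820 um (band silica)
```

The detected surfaces sit ~0.1 µm above the simulated 2.0 µm surface (the
keratin profile peaks just below the surface before attenuating, which
pulls the half-maximum slightly up); the recovered resolution matches the
configured PSF within the sampling error of the 0.5 µm depth grid.

`run_pipeline(run_config(...))` wires the whole chain — both formulation
arms, several time points, replicate scans — into one reproducible run
whose YAML config, mean-profile CSVs and enhancement table (CSV/JSON) are
written to an output directory.

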
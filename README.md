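# mtfrc

Depth-resolved lateral resolution estimation inside arbitrarily shaped
features of 3D fluorescence-microscopy Z-stacks, using mean tiled Fourier
ring correlation (mtFRC).

## The problem and who this is for

In thick specimens, image quality degrades with depth and is often
non-uniform within a single optical section — different tissue thickness
and light scattering make one part of a slice sharp and another blurry, so
a single whole-image resolution number is misleading. This package is for
microscopists who want an objective, physically interpretable resolution
metric (minimum resolvable distance, in µm) as a function of depth,
restricted to a user-drawn feature of interest: comparing imaging
modalities or laser powers, tuning acquisitions until a target structure
is resolvable, or validating an instrument against bead standards.

## The method

Fourier ring correlation (FRC) between two registered images of the same
scene, with Fourier transforms F₁ and F₂:

    FRC(r) = Re Σᵢ∈R F₁(rᵢ)·F₂(rᵢ)* / sqrt( Σᵢ∈R |F₁(rᵢ)|² · Σᵢ∈R |F₂(rᵢ)|² )

per integer Fourier ring r. Shared signal correlates, independent noise
does not; the first ring where the curve drops below the fixed 1/7 cut-off
gives the crossing frequency f_c = r/(N·p), and the resolution is d = 1/f_c.
A "single image" mode splits one image into four decimated sub-images
(pixel size doubled) and averages the FRC resolution of the two diagonal
sub-image pairs, so no second acquisition is needed.

For each Z-slice, the ROI polygon is covered with non-overlapping 64×64 px
tiles; mtFRC is the mean resolution over tiles that contain correlating
spatial frequencies, reported against stage depth. Depths where fewer than
95% of tiles correlate are kept in tables but excluded from plots. A
rolling-block mode evaluates a block on every ROI pixel for high-detail
resolution colourmaps (median-smoothed, rendered on a fixed 0–7+ µm
scale), and a bead workflow cross-validates FRC against Gaussian-fit FWHM
(FWHM = 2√(2 ln 2)·σ) of sub-diffraction beads.

## Worked example

Synthetic six-slice stack whose blur grows with depth and whose intensity
decays (a stand-in for a real acquisition read with `read_stack()` /
`read_rois()`):

```r
library(mtfrc)
st  <- make_depth_stack(n_slices = 6, size = 256, seed = 42,
                        sigma_of_z = function(z) 0.5 + 0.5 * z,
                        intensity_decay_length = 80, z_step = 10)
roi <- roi_set(setNames(rep(list(cbind(c(0, 256, 256, 0),
                                       c(0, 0, 256, 256))), 6), 0:5))
fit <- mtfrc(st, roi)
fit
```

```
Mean tiled FRC depth profile
  mode: single-image FRC, tile 64 px, cut-off 0.1429, validity >= 0.95
  6 depth(s), 6 reported

 z_index depth_um mtfrc_um n_tiles n_valid fraction_valid reported
       0        0   0.5260      16      16              1     TRUE
       1       10   0.5825      16      16              1     TRUE
       2       20   0.6280      16      16              1     TRUE
       3       30   0.7021      16      16              1     TRUE
       4       40   0.7729      16      16              1     TRUE
       5       50   0.9037      16      16              1     TRUE
```

Each row is one depth: `mtfrc_um` is the mean minimum resolvable distance
over the 16 ROI tiles (lower = better), degrading from 0.53 µm at the
surface to 0.90 µm at 50 µm depth as the simulated blur and intensity
decay bite. `plot(fit)` draws the reported rows; `write_profile_csv(fit,
...)` exports all of them. Sampling helpers follow Abbe's formula:

```r
abbe_resolution(488, 0.7)   # 349  (nm, confocal at NA 0.7)
nyquist_pixel_size(349)     # 174.5 (nm)
```

A command-line front end wrapping these functions (profile, colourmap,
bead report, fixture generation) ships at `inst/cli/mtfrc.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/mtfrc.R", package = "mtfrc"))')" \
  profile --stack stack.tif --rois rois.zip --pixel-size 0.0946 \
  --z-step 10 --tile-size 64 --out outdir/
```

See `vignettes/mtfrc-methods.Rmd` for the model, assumptions, parameter
guidance and limitations.

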
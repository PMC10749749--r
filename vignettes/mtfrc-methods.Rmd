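---
title: "Depth-resolved resolution estimation with mean tiled FRC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Depth-resolved resolution estimation with mean tiled FRC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtfrc)
```

## The problem

In 3D fluorescence microscopy of thick specimens, lateral resolution
degrades with imaging depth because of light attenuation and scattering,
and it is usually non-uniform *within* an optical section as well: tissue
of different thickness or type scatters differently, so one part of a
slice may be sharp while another is not. A single whole-image resolution
number is then misleading. This package estimates resolution as a function
of depth *inside a user-drawn feature of arbitrary shape* — for example,
one anatomical region of a brain — by tiling the feature, estimating
resolution per tile, and averaging.

## Fourier ring correlation

Resolution is estimated with Fourier ring correlation (FRC). Given two
registered, independently noisy images of the same scene with Fourier
transforms $F_1$ and $F_2$, the FRC at integer ring radius $r$ is

$$\mathrm{FRC}(r) =
  \frac{\operatorname{Re}\sum_{i \in R_r} F_1(i)\,F_2^{*}(i)}
       {\sqrt{\sum_{i \in R_r} |F_1(i)|^2 \; \sum_{i \in R_r} |F_2(i)|^2}},$$

where $R_r$ collects the Fourier samples whose distance from DC rounds to
$r$. Shared signal correlates; independent noise does not. The highest
spatial frequency at which the correlation still exceeds a fixed cut-off —
the widely used value $1/7$ — separates frequencies carrying real
information from those indistinguishable from noise, and its inverse is
the minimum resolvable distance:

$$f_c = \frac{r_c}{N \cdot p}, \qquad d = \frac{1}{f_c},$$

with $N$ the (square) image side and $p$ the pixel size. Two points matter
for interpretation:

* **FRC measures an SNR-limited resolution.** It reports where image
  content sinks below the noise floor. On a nearly noise-free image the
  correlation can stay above the cut-off all the way to Nyquist no matter
  how blurred the optics are; conversely it responds to anything that
  changes the signal-to-noise ratio with depth (attenuation, scattering,
  detector noise), which is exactly the degradation one wants to track in
  thick samples.
* **The estimate is quantized.** Crossings are reported at integer rings
  with no sub-ring interpolation and no curve smoothing, so a tile's
  resolution takes values $N p / r$. Averaging over tiles recovers a
  smooth aggregate.

Two sentinel outcomes are distinguished: a curve that never drops below
the cut-off (`no_crossing` — resolution at least as fine as the Nyquist
bound $2p$; censored) and one already below it at the first ring
(`no_correlation` — the tile contains no correlating spatial frequencies
at all, e.g. background or pure noise).

### Single-image FRC

FRC needs two independent images. When only one acquisition exists, the
image is split into four sub-images by two-fold decimation: sub-image
$(a, b)$, $a, b \in \{0, 1\}$, keeps pixels $(2i + a, 2j + b)$. Each
sub-image samples the same scene with independent noise at twice the pixel
size. FRC is computed for the two diagonal pairs — $(0,0)/(1,1)$ and
$(1,0)/(0,1)$, which share identical geometric offsets along both axes —
and the reported resolution is the arithmetic mean of the two pair
resolutions. Averaging the two resolutions (rather than the two curves) is
the default; `average_curves = TRUE` selects the other reading. If either
pair shows no correlating frequencies the tile is `no_correlation`; a pair
that never crosses contributes its sub-image Nyquist bound $4p$ and the
result carries a `bounded` flag, so censoring is marked rather than
silently dropped.

Decimation halves the sampling rate, so single-image analysis needs the
acquisition oversampled two-fold relative to Shannon–Nyquist. The helpers
`abbe_resolution()` ($d = \lambda / 2\,\mathrm{NA}$) and
`nyquist_pixel_size()` ($d/2$) support that planning; e.g. 488 nm at
NA 0.7 gives $d = 349$ nm and a 174.5 nm Nyquist pixel.

## Mean tiled FRC (mtFRC)

Cropping a feature to a rectangle cannot follow irregular anatomy, and
masking it creates artificially sharp edges that corrupt spectra. Instead,
each slice is divided into non-overlapping tiles (default $64 \times 64$
px) on a grid anchored at the image origin, and only tiles fully contained
in the slice's ROI polygon are evaluated (`containment` relaxes this for
thin features). The slice's mtFRC is the mean resolution over tiles with
correlating frequencies; the fraction of such *valid* tiles is tracked,
and a depth is *reported* only when that fraction reaches the validity
threshold (default 95%). Unreported depths stay in the CSV output but are
omitted from plots. Depth is geometric stage depth,
$z_\mathrm{index} \times \Delta z$; no refractive-index correction is
applied.

Tile size trades localization against the lowest measurable frequency: a
64-px tile cannot represent correlations at scales larger than the tile,
so very coarse resolutions saturate. Larger tiles extend the range at the
cost of spatial detail.

### Rolling-block colourmaps

For per-pixel detail, `rolling_frc_map()` evaluates a block (default
64 px) centred on every ROI pixel — $w \times h$ evaluations for a full
ROI versus $(w/64)(h/64)$ for tiling, e.g. $1{,}048{,}576$ versus $256$ on
a $1024^2$ image. Blocks near the border are clamped inward rather than
zero-padded, again to avoid manufactured edges. Maps are smoothed with a
disc median filter (default radius 10 px, the radius semantics of the
Fiji rank filter) computed over defined pixels only, then rendered on a
fixed physical scale (default 0–7 µm) where values above the maximum
saturate at the top colour ("7+"). Smoothing operates on physical values
before any rendering clip. A `stride` option evaluates a coarser lattice
and fills in by nearest site when full density is too costly.

## Bead validation workflow

`analyze_beads()` checks FRC against the conventional full-width at half
maximum (FWHM) of sub-diffraction beads. Candidate beads are bright local
maxima separated laterally by at least one box size (brighter wins on
conflict); each is cropped into a substack. The centre is the
maximum-intensity pixel after a per-plane radius-1 disc median filter
(suppressing single hot pixels), with ties broken lexicographically by
$(z, y, x)$. A 1D Gaussian with offset is least-squares fitted to the
horizontal and vertical profiles through the centre, and

$$\mathrm{FWHM} = 2\sqrt{2 \ln 2}\,\sigma \approx 2.3548\,\sigma$$

per axis, averaged over X and Y. Per-bead FRC uses a 64-px tile centred on
the same pixel (32-px sub-images). Peak intensity, normalized to the
brightest bead, tracks attenuation; `bead_summary()` fits FWHM and FRC
against depth (linear), FRC against FWHM, an exponential decay
$I(z) = A e^{-z/\ell}$ to the normalized peaks, and reports the paired
percentage difference $(\mathrm{FRC} - \mathrm{FWHM})/\mathrm{FWHM}$.

One deliberate choice: the median filter is used for *centre finding
only*; the profile fits read raw intensities. At realistic bead scales
(convolved $\sigma \approx 1.9$ px for 210 nm beads, 93.1 nm pixels,
NA 0.7 at 488 nm) a radius-1 median visibly flattens the peak and biases
the fitted width by several percent, while the fit itself is already
robust to isolated outliers; filtering buys nothing but bias there.
FRC likewise uses raw pixels, since median filtering would suppress
exactly the high-frequency content being measured.

## Synthetic data generators

All tests run on synthetic inputs with known ground truth:

* `make_pair()` — one scene (smooth random field, white noise, or sparse
  spots), optionally hard band-limited (a known true resolution limit)
  and/or Gaussian-blurred, observed twice with independent Gaussian or
  Poisson noise.
* `make_depth_stack()` — per-slice scenes with a blur schedule
  $\sigma(z)$ and intensity decay $e^{-z\Delta z/\ell}$; optionally a
  registered partner stack sharing scenes but not noise.
* `make_heterogeneous_plane()` — two half-planes blurred differently,
  with ready-made ROIs, emulating within-slice resolution heterogeneity.
* `make_bead_stack()` — Gaussian-approximated beads of convolved width
  $\sqrt{\sigma_\mathrm{psf}^2 + \sigma_\mathrm{bead}^2}$ (the bead
  modelled as a Gaussian whose FWHM equals its diameter) at recorded
  positions, with Poisson noise applied after depth-dependent intensity
  scaling so SNR falls with depth; returns the ground-truth table.

All generators are bit-reproducible under a seed and restore the caller's
RNG state. Defaults mirror a confocal acquisition with a 20×/0.7
objective: 94.6–93.1 nm pixels, 10 µm (tissue) or 0.5 µm (bead) z-steps,
210 nm beads, PSF $\sigma$ = 148 nm (the 349 nm Abbe limit over
$2\sqrt{2\ln 2}$).

The depth generator's noise default (SD 100 against peak 1000, PSNR
20 dB) encodes the SNR-limited character of FRC noted above: blur must
compete against a realistic noise floor to move the correlation crossing.
With near-noiseless synthetic scenes a second effect dominates instead —
tiles cropped from a smooth scene share spectral leakage from their crop
edges across all rings, holding the correlation above the cut-off
regardless of blur. That leakage exists in real data too but is normally
buried under shot noise; a Tukey-window option (`window = TRUE`,
$\alpha = 0.25$) is available for edge-artefact suppression and is off by
default, matching the plain-FFT definition of the method.

What the generators do *not* emulate: real optics (no Airy rings or
aberrations — Gaussian PSFs only), physically modelled scattering
(depth degradation is imposed, not simulated), sample structure, or
detector artefacts. Passing tests therefore demonstrate correctness of
the estimator on controlled inputs, not end-to-end accuracy on any
particular microscope.

## Numerical choices

* Ring binning: integer rings by rounded Euclidean radius, DC excluded,
  rings beyond $\lfloor N/2 \rfloor$ discarded; unit-width rounded rings
  are the standard choice where no ring width is prescribed.
* Tiles are mean-subtracted before the FFT so the excluded DC term cannot
  leak into ring 1 (`mean_subtract = FALSE` disables). Non-square tiles
  are zero-mean padded to the enclosing square.
* Rings where either image has zero energy get correlation 0 — a constant
  tile is thus `no_correlation` deterministically.
* Threshold crossing is the *first* ring strictly below the cut-off.
* Polygon rasterization: a pixel belongs to the ROI when its centre
  $(x + 0.5, y + 0.5)$ is inside under the even-odd rule; multiple
  polygons on one slice union. Vertices are clamped to image bounds.
* ImageJ `.roi` support covers polygon, rectangle, oval (64-vertex
  polygon approximation) and freehand types; traced/composite ROIs are
  rejected with a clear error. Slice assignment uses the ROI position
  field, else a leading integer in the file name, else (single untagged
  ROI) broadcasts to all slices.
* Gaussian profile fits use Levenberg–Marquardt with moment-based starts;
  fits that fail to converge or return non-positive width are flagged and
  excluded from summaries rather than propagated.
* Bead substack extraction is greedy by brightness with a minimum lateral
  separation, so overlapping candidates deterministically keep the
  brighter.
* TIFF output stores 8/16-bit unsigned integers at raw values, so
  integer-valued (photon-count) stacks round-trip bit-identically;
  non-integer data must be explicitly normalized.

## Problem sizes used by the test-suite experiments

Simulation scales were chosen so each property is measured with adequate
statistical power at desk scale: band-limit recovery on 256-px pairs over
20 seeds; monotone depth degradation on 10-slice, 512-px stacks (64 tiles
per slice — the per-slice blur increment must exceed the tile-mean
estimation noise for monotonicity to be observable) over 10 seeds;
FWHM recovery over 50 beads; decay-length recovery over 100 beads spanning
60 µm; tiling-versus-rolling agreement on a full 256-px plane at stride 1.

## Known limitations

* Tile size bounds the coarsest measurable resolution; features thinner
  than one tile need `containment < 1`, which dilutes the "fully inside
  the feature" guarantee.
* Single-image FRC assumes noise independent between decimated pixels;
  detector pixel cross-talk or resampling would violate this and inflate
  correlations.
* The 1/7 cut-off is a convention; alternative criteria exist and can be
  approximated via the `cutoff` argument, but no sigma- or
  information-based curves are implemented.
* Multi-specimen aggregation (cohort overlays with a
  "half-of-specimens" reporting rule) is out of scope; profiles from
  several stacks must be combined downstream.
* Depth is uncorrected stage depth; refractive-index mismatch stretches
  the true axial coordinate.

## A worked example

```{r example, eval = FALSE}
stack <- read_stack("stack.tif", pixel_size = 0.0946, z_step = 10)
rois <- read_rois("rois.zip", stack)
fit <- mtfrc(stack, rois, tile_size = 64, cutoff = 1 / 7)
summary(fit)
plot(fit)
write_profile_csv(fit, "mtfrc_profile.csv")

map <- rolling_frc_map(stack$planes[[13]],
                       roi_polygons_for_slice(rois, 12))
write_colormap_png(smooth_map(map, 10), "slice12_map.png",
                   scale = c(0, 7))
```
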
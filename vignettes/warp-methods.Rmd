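---
title: "Interferometric displacement mapping with two alternating wavelengths: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interferometric displacement mapping with two alternating wavelengths}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(warpmic)
```

## The physical model

A cell culture substrate is built as an elastic optical microcavity: a soft
silicone layer of refractive index $n \approx 1.40$ and rest thickness
$d_0 \approx 8\,\mu\mathrm{m}$ between two semi-transparent gold mirrors.
A cell on the top mirror deforms it locally by $u(x, y)$ (nanometres;
negative values indent into the cavity), so the local thickness is
$d = d_0 + u$. Under monochromatic wide-field illumination at wavelength
$\lambda$ the reflected intensity of this low-finesse cavity is, to good
approximation, an offset cosine

$$I(\lambda) = B + A \cos\!\frac{4\pi n d}{\lambda},$$

with a background $B$ and fringe amplitude $A$ that vary slowly across the
field of view but negligibly between two nearby wavelengths.
`reflectance_two_beam()` implements this; `reflectance_fabry_perot()`
implements the full lossless two-mirror lineshape, whose minima sit at the
resonances $2nd = m\lambda$ and which collapses onto the cosine as
$R_1 R_2 \to 0$. Mirror absorption is folded into effective reflectances;
the defaults ($R_1 = 0.30$, $R_2 = 0.25$) are assumptions chosen for
low-finesse behaviour, not measured values — nothing downstream depends on
them beyond the lineshape being low-finesse.

A single cosine is symmetric in $d$, so one image cannot tell indentation
from protrusion. Imaging at two nearby wavelengths
$\lambda_1 < \lambda_2$ (within one free spectral range
$\lambda^2/2nd$, about 18 nm here) and combining the images resolves the
ambiguity. With
$\phi_\mathrm{fast} = 2\pi n (\lambda_1+\lambda_2) d / \lambda_1\lambda_2$
and
$\phi_\mathrm{slow} = 2\pi n (\lambda_2-\lambda_1) d / \lambda_1\lambda_2$:

* the difference image is
  $-2A \sin\phi_\mathrm{fast}\sin\phi_\mathrm{slow}$ — background-free;
* the sum image is
  $2B + 2A \cos\phi_\mathrm{fast}\cos\phi_\mathrm{slow}$;
* their ratio after background subtraction, the **division image**, is
  $-\cot\phi_\mathrm{fast}\cot\phi_\mathrm{slow}$ — free of both $A$ and
  $B$, and asymmetric in $d$, so it carries the direction of thickness
  change.

Zeros of $\sin\phi_\mathrm{fast}$ partition the thickness axis into
fringe modes of width
$d_\mathrm{mode} = \lambda_1\lambda_2 / 2n(\lambda_1+\lambda_2)$
(112.6 nm at 628/633 nm, 124.6 nm at 695/700 nm, `fringe_mode_spacing()`).
Counting mode transitions gives displacement to within one mode; a
calibrated lookup table turns the division value into the fine
displacement inside the mode.

## The reconstruction algorithm

`reconstruct_map()` chains the steps:

1. **Frame pairing** (`pair_frames()`). Alternating acquisition means the
   two wavelengths are never simultaneous; each interior frame of one
   wavelength is compared against the mean of its two neighbours at the
   other, which cancels uniform scene motion to first order. The naive
   previous-frame pairing is kept as an option for comparison.
2. **Background** (`estimate_background()`). At difference-image zero
   crossings the sum image sits at $2B \pm 2A|\cos\phi_\mathrm{slow}|$.
   The sum is sampled at sub-pixel crossing positions; midpoints of
   consecutive samples estimate $2B$. Two numerical details matter:
   where thickness is non-monotone along a row, consecutive crossings can
   sit at the *same* extremum, so only sample pairs that straddle a
   provisional midrange estimate contribute; and with `field = TRUE` a
   quadratic surface is fitted to the midpoints to follow slow
   illumination inhomogeneity. `refine_background_by_steps()` optionally
   scans candidate backgrounds and scores spurious thickness steps in a
   probe reconstruction — the count of jumps larger than
   $d_\mathrm{mode}/2$, with ties broken by total roughness, because on
   smooth scenes a mis-set background distorts the lookup without causing
   whole-mode miscounts.
3. **Division image** (`division_image()`). Pixels whose difference
   magnitude falls below 5% of the row-wise 98th-percentile magnitude lie
   near a fringe zero and are masked rather than divided; the threshold is
   a package choice (the method never divides at exact zeros but
   prescribes no number). The sign of the difference assigns each unmasked
   pixel to Mode 1 or Mode 2.
4. **Fringe transitions** (`detect_fringe_transitions()`). Zero crossings
   of the (3-point-smoothed) difference along a scan line, located by
   linear interpolation — the cheapest scheme consistent with a pixel
   scan; a crossing landing exactly on a sample belongs to the interval on
   its left. Crossings with no unmasked pixel between them are clustered
   into one net transition whose direction comes from the division-image
   sign on either side; a cluster with equal flanking signs carries no net
   mode change. This makes counts robust to noise wiggles around a fringe
   zero.
5. **Scanning** (`reconstruct_row()`). Rows are scanned left to right; one
   counter increments at positive-to-negative division transitions and
   another at negative-to-positive ones, and their signed difference times
   $d_\mathrm{mode}$ plus the lookup value gives the displacement relative
   to the row seed. Which sign direction means "up" depends on the sign of
   $\cot\phi_\mathrm{slow}$ at the operating thickness, so the package
   reads it from the calibrated lookup orientation instead of hard-coding
   a convention. A single vertical scan down the seed column (column 1 by
   default, configurable if that column is artefact-prone) sets per-row
   offsets; finally the mean over a declared flat reference region is
   subtracted. Masked pixels are filled by linear interpolation along the
   row and flagged; their lookup values never seed an offset.

## Calibration

`build_lookup_from_ramp()` builds the lookup table from a region of
gradually varying thickness (the synthetic counterpart of the thickness
wedge at a spin-coated sensor's edge), against a reference thickness from
either the scene ground truth or the wavelength-scanning analysis. Samples
are binned at 256 bins per mode (nanometre-scale fidelity at negligible
size), per mode class, with per-bin medians, isotonic regression to
enforce monotonicity, and strictly-monotone deduplication; application is
monotone piecewise-linear interpolation with clamping (flagged) outside
the calibrated range.

One algorithmic addition: the envelope cotangent
$\cot\phi_\mathrm{slow}$ drifts slightly from one fringe mode to the next,
so raw division values from different modes of the ramp disagree at the
same fine displacement (a bias of order 1 nm for a ramp spanning a few
modes). Since calibration knows each sample's reference thickness, every
value is rescaled to the mean calibration thickness before binning. The
corresponding drift at application time — for pixels whose thickness is
far from the calibration mean — remains, and is inherent to any
two-wavelength scheme; it is part of the round-trip error budget below.

The **wavelength-scanning oracle** (`erism_map()`) provides absolute
thickness per pixel from a simulated 201-wavelength scan (550–750 nm,
1 nm steps): reflectance minima are refined by parabolic interpolation,
each adjacent minima pair $\lambda_b < \lambda_a$ is assigned the integer
resonance order $m = \mathrm{round}(\lambda_b/(\lambda_a - \lambda_b))$ —
pairs with order residual above 0.2 are rejected as localisation noise —
and $d = m\lambda_a/2n$ is averaged over accepted pairs. The oracle never
touches WARP intermediates, so WARP-vs-oracle residuals are a genuine
cross-method check.

## The synthetic scene generator

`scene_spec()` emulates what matters to the reconstruction: deformation
fields from nanometres to micrometres (Gaussian indentations, flat-topped
dimples for podosome-like protrusions, wedges, plateaus), periodic or
band-limited stochastic temporal modulation, per-feature velocities and
on/off windows for travelling micro-contraction events, global drift for
motion-artefact experiments, smooth low-order polynomial amplitude and
background fields, and additive zero-mean Gaussian camera noise. All
randomness derives from one seed; identical specs render bit-identical
stacks.

Deliberately not modelled: the optical point-spread function (fringe
images are formed pixelwise), Poisson shot noise, photobleaching, and
realistic cell morphology. Consequently, passing round trips demonstrate
the correctness and noise robustness of the reconstruction logic, not
performance on real micrographs — in particular, real steep gradients blur
fringes by lateral averaging, which the generator only respects by keeping
feature gradients below the sampling cap of about one fringe per four
pixels. The default pixel size (0.3 µm) and camera noise level are
assumptions, documented here, not measurements.

## Mechanics and dynamics

Stresses and forces use the flat cylindrical punch on an elastic
half-space, $F = 2E/(1-\nu^2)\,a\,\delta$ (`punch_force()`), with the
contact radius from the segmented indentation area ($a = \sqrt{A/\pi}$)
and the depth as the component's maximum (the conservative reading of
"depth from the deformation map"; configurable by passing a different
reference map). This replaces finite-element stress computation
throughout; for podosome-scale contacts the punch model is an established
close proxy, and the half-space assumption ignores the finite 8 µm layer
thickness — documented, not asserted as equivalent. The Poisson ratio
defaults to 0.5 (incompressible elastomer), an assumption that enters only
through $1/(1-\nu^2)$. Depths are measured relative to the median of a
ring around each component so broad cell-scale bowls do not inflate them;
areas are plain pixel counts, so footprints near the Airy radius
($0.61\lambda/\mathrm{NA} \approx 640$ nm here) are overestimated — the
reason the force–area regression defaults to areas above 0.7 µm².

Temporal analysis: centred boxcar (`moving_average()`, shrinking windows
at the edges), hard spectral high-pass with prior mean removal
(`highpass()`), peak detection with a prominence threshold of 20% of the
1st–99th percentile range and greedy minimum-separation enforcement
(`detect_contractions()`; the prominence default is a package choice —
peak-detection parameters for contraction traces are conventions, not
physics), coefficients of variation with $n-1$ normalisation, each
event's frequency assigned from the interval to the previous peak.
`micro_contraction_detect()` band-passes each frame (1–10 µm retained by
default, lower edge clamped above two pixels), segments indentations
beyond a detection floor, links blobs across frames by nearest centroid
within 2 µm, and reports tracks whose depth and duration stay at or below
the micro-contraction ceilings (30 nm, 100 ms); depths are read from the
unfiltered maps within the detected footprint, since band-passing
attenuates amplitudes. Events near or below the frame interval are
necessarily missed or mistimed — at 10 fps an 80 ms event cannot be
resolved, which the test suite demonstrates.

## Numerical choices and degenerate inputs

* Pole threshold 5% of the row-wise robust maximum; a fully zero
  difference image masks everything and reconstruction refuses to run.
* A flat scene has no fringe crossings: background estimation raises an
  error rather than guessing, and the step-refinement returns the initial
  estimate with a warning.
* Lookup values outside the calibrated range clamp and flag; calibration
  requires a ramp spanning at least one full mode (error) and warns below
  two.
* TIFF output is stored normalised to $[0,1]$ and quantised at 32 bits
  with the affine scale in a plain-text YAML sidecar (portable and
  human-inspectable, rather than bespoke TIFF tags); values round-trip to
  better than $10^{-9}$ of the data range, and writes are byte-identical
  across runs.
* Coordinates are row-major with 1-based indices, the R convention;
  indentation is negative displacement.

## Problem sizes

The package's own accuracy checks run the full pipeline at 256 × 256 px
(the standard scene: a wedge spanning ~3.5 modes plus a 200 nm Gaussian
indentation), with the wavelength-scan oracle at the full 201 wavelengths;
unit tests use 48–300 px scenes. Seeded mechanics recovery uses 50 random
podosome scenes at 192 × 192 px; dynamics checks use 10–40 s traces at
100 Hz. These sizes keep every property at full fidelity while the whole
suite runs in well under a minute.

## Known limitations

* Single-scan error propagation: a miscounted transition corrupts the rest
  of its row, as in any left-to-right scan; the pole-cluster merging
  suppresses the common noise failure mode but no global consistency pass
  is attempted.
* The division-image method needs visible fringes: scenes flatter than one
  mode cannot be reconstructed absolutely, only relatively to a declared
  baseline.
* Slow-envelope drift across very large deformations (several modes away
  from the calibration thickness) contributes a sub-nanometre to
  few-nanometre systematic, as discussed under calibration.
* Horizontal (shear) forces, which twist rather than indent the surface,
  are outside the scope of the vertical-displacement pipeline.
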
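---
title: "Models and design choices behind the FxM analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind the FxM analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fxmtools)
```

## The measurement principle

Fluorescence eXclusion Microscopy (FxM) measures absolute single-cell
volumes. Cells sit in a shallow chamber (height $h_{chamber}$, a few microns,
supported by pillars) filled with a fluorescent dextran they cannot take up.
Wherever a cell displaces dye, the fluorescence drops in proportion to the
cell's local height, so the intensity deficit integrated over the cell
footprint $A$ is proportional to its volume:

$$V_{cell} = A_{px}\sum_{x,y \in A} \frac{I_{max} - I(x,y)}{\alpha},
\qquad \alpha = \frac{I_{max} - I_{min}}{h_{chamber}},$$

where $I_{max}$ is the local cell-free (background) intensity, $I_{min}$ the
intensity over the pillars (which span the full chamber height), and
$A_{px}$ the pixel area in $\mu m^2$. Note the pixel-area factor: the
deficit sum alone has units of intensity, and dimensional analysis forces
multiplication by the pixel footprint to obtain $\mu m^3$. Per-pixel
heights are *not* trusted individually (light scatter corrupts them);
only the footprint integral, measured over a slightly dilated label so that
scattered signal at the rim is captured, is reported.

This only works on quantitatively flat images, hence the correction chain:
subtract the camera darkfield, then divide by a per-frame background surface
(flatfield) fitted to cell-free pixels, after which background is $\approx 1$
everywhere and all volumetry happens in normalised units. Both $I_{max}$
(per cell, from a local annulus) and $I_{min}$ (per frame, from the pillar
pixels) are re-estimated from the corrected image, which makes the volume
estimate invariant to any global intensity scale.

## Pipeline stages and the parameters that matter

**Flatfield** (`sample_background_points()`, `fit_flatfield()`,
`correct_illumination()`). Background samples are placed on a deterministic
"sinusoidal" grid — coordinates $(1-\cos\pi u)/2$ for equispaced $u$ — which
concentrates samples toward every frame border, where vignetting is
steepest and background pixels are scarcest. Samples falling on cells or
pillars are excluded; the pipeline builds the exclusion mask provisionally
by thresholding a smoothed copy of the frame at 95 % of its median
(smoothing first is essential: it suppresses shot noise so that even
shallow cell rims, whose deficit is only a few percent, are excluded — an
unexcluded rim sample locally drags the surface down and silently erases
volume). The surface is a multiquadric radial-basis interpolant
$\phi(r)=\sqrt{r^2+\epsilon^2}$ augmented with an affine polynomial term;
the augmentation is the standard construction that makes constant and
planar backgrounds reproduced exactly, and $\epsilon$ defaults to the mean
nearest-neighbour sample spacing, a conventional well-conditioned choice.
Sample values are taken from the smoothed frame for the same reason as
above. A stricter alternative — excluding the *segmented* cells — is
available simply by passing the previous frame's labels as the exclusion
mask, but was not needed at the noise levels studied here.

**Segmentation** (`edge_magnitude()`, `threshold_edges()`,
`fill_foreground()`, `detect_seeds()`, `label_cells()`,
`dilate_labels()`). Edges are enhanced with a Scharr operator (smoothing
taps $(3,10,3)/16$, derivative $(-1,0,1)/2$, replicate padding). Edge
magnitudes are approximately log-normal, so the edge threshold is one
standard deviation above the mean *of the log-magnitudes* (zeros
excluded) — the distributional claim makes log space the natural choice and
for an exactly log-normal field marks the top
$1-\Phi(1) \approx 15.9\,\%$ of pixels. Regions fully enclosed by edges are
flood-filled into the foreground; open contours never fill. A small
morphological closing (radius 1 px) is applied to the edge mask first so
that single-pixel noise gaps do not leak a cell. Instances are separated by
region growing from nuclear seeds, equivalent to a watershed of the
inverted distance transform for blob-shaped cells; seeds come from regional
maxima of the smoothed nuclei channel above an adaptive floor
(`median + max(8 MAD, 10 % of dynamic range)`, which returns nothing on a
blank frame). The trained instance-segmentation model used in the original
workflow is deliberately out of scope; the seed detector is a pluggable
function with the same contract, so any detector returning `(row, col)`
seed points can be substituted. Labels are finally dilated by 2 px
("slightly larger than the footprint") under a no-collision constraint.
Connectivity for labelling and filling follows EBImage's conventions
(4-connected labelling); on the blob-like masks this pipeline produces the
distinction from 8-connectivity is immaterial.

**Tracking** (`link_tracks()`). Deterministic greedy globally-nearest
neighbour linking with a hard 10 µm/frame displacement gate and a 2-frame
memory; at the cell densities and speeds studied (≤ 0.2 µm/s at 10 s/frame,
centres ≥ 10 µm apart) this simple linker is essentially error-free, and
being fully deterministic it keeps end-to-end runs reproducible. Tracks
shorter than 5 frames are dropped from downstream statistics (the threshold
is configuration, logged in the manifest).

**Volumetry** (`local_background()`, `cell_volume()`,
`normalize_trace()`). $I_{max}$ is the median corrected intensity in the
annulus 2–10 px (1.3–6.5 µm at the default 0.65 µm/px) from the dilated
label boundary, excluding other labels and pillars; a cell whose annulus is
empty (crowding, border) is flagged unmeasurable for that frame rather than
guessed. Negative per-pixel deficits are retained (they carry noise that
would otherwise bias volumes upward); a negative *total* is floored at zero
and flagged. Traces are normalised to the mean raw volume over the two
minutes before the stimulus ("average" is taken as the mean; cells covering
less than half that window are excluded from normalised statistics but kept
raw), and a centred 5-sample rolling median is provided alongside.
Population summaries are two-level: median across cells within a replicate
per time point, then mean across replicates with a Student-t 95 % CI
(volumes) or an SD band (velocities).

**Motility** (`velocity()`, `angular_alignment()`). Velocity is the
central-difference displacement over $\pm\tau$ frames ($\tau = 3$ by
default, about one minute at 10 s/frame); it is displacement-based, so
closed loops score zero. Angular alignment looks at each track position B
together with the positions A (earlier) and C (later) first reaching 10 µm
of *cumulative travelled distance* away, computes
$\theta = \mathrm{atan2}(\|\vec{BA}\times\vec{BC}\|, \vec{BA}\cdot\vec{BC})$
and rescales it as $2\theta/\pi - 1$. The rescale deserves a note: the
quantity is defined to span $-1$ (complete reversal) to $+1$ (perfectly
straight) with a Brownian median near 0, and only the affine map
$2\theta/\pi-1$ achieves that range — a bare division of $\theta$ by $\pi$
is non-negative and cannot reach $-1$. This package uses the
range-consistent affine map.

**Buoyant densitometry** (`density_calibration()`, `ri_to_density()`,
`population_density_mode()`, `volume_change_from_density()`,
`bin_fractions()`, `coulter_median()`). Percoll density is linear in
refractive index, so two measured standards (RI 1.3419 at 1.045 g/mL and
1.3467 at 1.074 g/mL by default) calibrate the whole gradient. The modal
density of a fractionated population is the peak fraction after a 3-fraction
moving average. Mass conservation links density shifts to volume changes:
a cell of density $\rho_0$ taking up a volume fraction $f$ of fluid of
density $\rho_{fluid}$ reaches $\rho' = (\rho_0 + f\rho_{fluid})/(1+f)$,
inverted as $f = (\rho_0-\rho_1)/(\rho_1-\rho_{fluid})$. The default
$\rho_{fluid} = 1.0026$ g/mL is dilute saline. Worth knowing: the observed
stimulated shift 1.055 → 1.050 g/mL corresponds under this relation to
about +10.5 % volume, somewhat below the ~15 % swelling measured by imaging
and impedance sizing; both numbers are surfaced by the package and no
reconciliation is attempted. Gradient fractions are combined into bins of
approximately equal cell count by exhaustive search over contiguous cut
points; Coulter diameter histograms are gated at 6 µm (debris) before the
count-weighted median volume is taken.

**Osmotic model** (`osmotic_volume()`). Boyle–van't Hoff with an
osmotically inactive fraction $b$:
$V = V_0[b + (1-b)\Pi_0/\Pi]$. The default $b = 0.25$ is the unique value
for which a 20 % v/v water dilution of 315 mOsm/kg media yields the +15 %
equilibrium swelling used as the hypoosmotic rescue; it is exposed as a
parameter. `water_content_gain()` is the companion arithmetic: at ~65 %
cell water content, a 15 % all-water volume gain is a ~23 % gain in cell
water.

## The synthetic scene generator

Because the original measurements come from primary human cells, the
package ships a generator that renders FxM series from *known* ground truth
so every stage is testable by recovery of injected effects. Its defaults
encode the stereotyped chemoattractant response of primary neutrophils:

* volume per cell
  $V(t) = V_0[1 - L\,s(t') + S\,w(t') + F\,f(t')]$ with $t'$ the time since
  stimulus: a spreading-loss pulse $s(t') = (t'/\tau_s)e^{1-t'/\tau_s}$
  (unit peak at $\tau_s = 60$ s, so the median nadir lands 1–2 min
  post-stimulus at a 5–8 % loss for the default $L = 0.065$), a saturating
  swelling term $w(t') = \tanh(t'/\tau_w)$ with $\tau_w = 600$ s (the
  $\tanh$ form reaches 96 % of its plateau by 20 min, placing the median at
  $\approx 1.15\times$ baseline there; a $1-e^{-t/\tau}$ rise with the same
  time constant would still be 13 % short of plateau at 20 min and cannot
  reproduce the observed 20-minute value), and a zero-mean sinusoidal
  fluctuation ($F = 0.05$, period 100 s, random per-cell phase) standing in
  for motility-coupled volume fluctuations;
* motility: an isotropic random walk at 0.02 µm/s before the stimulus and a
  persistent walk afterwards whose speed ramps to 0.2 µm/s with a 600 s
  time constant; heading noise (SD 0.25 rad/frame) is chosen so pre-stimulus
  angular alignment has median ≈ 0 while post-stimulus alignment exceeds
  0.5. Cells are solid: a step that would bring two centres closer than
  10 µm is re-drawn, which both mirrors real excluded volume and keeps
  nuclei resolvable for the seed detector;
* geometry: cells are paraboloid domes $h(r) = h_{apex}(1 - r^2/R^2)$, so
  $V = \pi R^2 h_{apex}/2$. The apex height relaxes from 6 µm (resting) to
  3.5 µm (spread) post-stimulus; the footprint follows the slow volume
  component, which makes the median footprint area increase monotonically
  as observed, while the fast fluctuations ride on the dome height;
* optics: signal falls linearly with height from $I_{max}$ (1000 counts
  over a 100-count darkfield) to the pillar level $I_{min}$ (100 counts) at
  the chamber ceiling; a smooth radial vignette of 20 % amplitude
  multiplies the signal, and Poisson shot noise is applied last. The
  chamber height (8 µm), pixel pitch (0.65 µm/px) and frame interval (10 s)
  are configuration: chamber height and frame rate are not fixed by the
  source observations, and the pixel pitch follows from the stated 2–10 px
  = 1.3–6.5 µm annulus. 8 µm is a plausible neutrophil chamber height; at
  the default dome heights no cell touches the ceiling.

The renderer and the volumetry are exact adjoints at zero bias and zero
noise: for any height field the measured volume equals
$A_{px}\sum h$ to well under 1 %, which is the foundation of the recovery
tests (a rendered 4 µm hemisphere, for instance, measures within 2 % of its
analytic $\tfrac{2}{3}\pi r^3 = 134.04\ \mu m^3$).

What the generator does **not** emulate: optical scatter and a real point
spread function (the measurement sidesteps scatter by design, via label
dilation, so simulating it would test the wrong thing), non-dome cell
shapes, uneven darkfield structure, chamber-height gradients, cell division
and death, and dye photobleaching. Recovery of injected effects therefore
validates the *analysis*, not the microscope: systematic errors shared by
real instrument and model (e.g. a miscalibrated chamber height, which
scales all volumes linearly) are invisible to these tests.

## Numerical choices and degenerate inputs

* All randomness flows from a single integer seed; identical configuration
  and seed give bit-identical tables (the acceptance of an analysis rests
  on reproducibility, so every stochastic step is seeded and every default
  is logged verbatim in the run manifest, which replays exactly).
* Thresholding an all-zero edge field, labelling with no seeds, an empty
  scene, or a fully crowded local-background annulus each produce an empty
  or flagged result with a warning — never an error — so long time series
  with occasional bad frames survive.
* The edge threshold on an all-equal magnitude field is the common value
  itself with a strict comparison, so the mask is empty rather than full.
* Watershed ties and linking ties are broken by deterministic order
  (scan order and smallest-distance-first, respectively).
* Fraction binning searches cut points exhaustively (the number of
  fractions is tens, so the search is exact, not heuristic); ties resolve
  to the first minimiser.
* The multiquadric system falls back to a small ridge with a warning if
  numerically singular (e.g. pathological sample geometries).

## Problem sizes used in the shipped checks

The end-to-end recovery scene used by the test suite and the acceptance
script is 55 cells in a 256 × 256 px chamber imaged every 10 s for 40 min
(241 frames) with stimulus at 10 min — comfortably above the 50-cell /
40-min condition the recovery claims are stated for, while a single run of
the full pipeline stays in the low minutes on one core. Oracle and property
checks use 64–128 px frames and run in seconds.

## Known limitations

* The seed detector requires a nuclei channel or a usable FxM deficit; very
  flat cells in a noisy frame can drop below the adaptive floor.
* The greedy linker has no motion model; it is adequate at 10 µm/frame
  gates and the simulated densities but will swap identities if cells
  routinely pass within a frame-to-frame displacement of each other.
* `population_density_mode()` resolves density only to the fraction
  spacing; with 6–7 measured fractions per gradient the mode is coarse,
  which is faithful to the underlying assay.
* Absolute volumes scale linearly with the configured chamber height; an
  error there is undetectable downstream (normalised responses are immune).
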
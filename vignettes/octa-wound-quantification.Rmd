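---
title: "Quantifying wound angiogenesis from repeated-B-scan OCT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying wound angiogenesis from repeated-B-scan OCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

octawound turns repeated complex OCT B-scans of healing skin wounds into a
single longitudinal readout — the vessel area density (VAD) of the wound —
and the group statistics built on it. This vignette explains the processing
model stage by stage, the tunable parameters and why their defaults are what
they are, what the digital phantom does and does not emulate, and the
numerical choices made where the underlying methods literature leaves the
design open.

## The acquisition model

The package assumes a repetition protocol: a B-scan of $n_x$ A-lines is
acquired $N$ times at each of $n_y$ slow-axis positions, giving a complex
cube of shape $(n_z, n_x, n_y, N)$. The reference configuration
(`oct_optics()`) is a 1300 nm swept source with 70 nm bandwidth at 3 dB,
1024 depth pixels at 2.7 µm/pixel in tissue, 500 × 500 lateral positions
over a 3.0 × 3.2 mm² field (6.0 × 6.4 µm pitch), and $N = 8$ repeats —
i.e. 4000 B-scan frames along the slow axis. The 2.7 µm/pixel figure is
taken to be the in-tissue axial sampling, already incorporating the mean
tissue refractive index (1.37); no second refractive-index correction is
applied anywhere, which avoids double-counting the index.

`scale_optics()` rescales the voxel grid while preserving the physical field
of view, so every micrometre-denominated parameter below (slab offsets, ROI
diameters, window sizes) behaves identically at any grid size. All
simulation-driven analyses in this package run on the desk-scale grid
`phantom_optics()` — 256 × 128 × 128 voxels, 8 repeats — for which one full
scene (render + reconstruction + quantification) takes seconds rather than
the minutes-to-hours a 1024 × 500 × 500 cube would need. The cohort-level
checks in the test suite and the acceptance script use 9 control fish at six
post-wound timepoints plus 6 diabetic fish at three timepoints at this
scale; these problem sizes are stated here as the package's chosen reference
conditions.

## Eigen-decomposition clutter filtering (ED-OMAG)

At each slow-axis position the $N$ repeats of a pixel form a vector
$x_p \in \mathbb{C}^N$. Static tissue contributes a repeat-space component
that is identical across repeats up to a global phase; blood flow
decorrelates between repeats. The filter:

1. optionally removes global inter-repeat bulk phase (`align_bulk_phase()`):
   for each adjacent repeat pair the intensity-weighted circular mean phase
   difference $\arg\sum_p x_{p,k+1}\bar{x}_{p,k}$ is estimated and unwound
   cumulatively, with the first repeat as reference. A rigid global phase
   ramp is removed exactly;
2. estimates the repeat-space covariance $C = \frac1M \sum_p x_p x_p^H$ over
   all $M = n_z n_x$ pixels of the position (`ed_covariance()`);
3. eigendecomposes $C$ and projects every pixel vector off the $K$ leading
   eigenvectors; the flow value is the mean residual power
   $f_p = \|x_p - \sum_{i\le K}(e_i^Hx_p)e_i\|^2 / N$ (`ed_filter()`).

Two exact identities anchor the implementation and are enforced in the
tests: clutter power plus $N\times$flow power equals total power pixel by
pixel (projection theorem), and the mean flow over all pixels equals
$\sum_{i>K}\lambda_i / N$ (trace identity).

Design choices the methods literature leaves open, and how they were made:

* **Covariance support.** $C$ is estimated globally per position rather than
  in local windows: with $N = 8$ an 8×8 covariance needs many more than a
  few dozen samples to be stable, and the static-tissue subspace is global
  by nature (bulk motion, shared speckle statistics).
* **Clutter rank.** Default fixed $K = 1$ with bulk-phase alignment on.
  After alignment the static subspace is one-dimensional by construction,
  so $K = 1$ removes it exactly while costing flow signal only its
  $1/N$ projection onto the clutter axis. An adaptive mode (smallest $K$
  holding 90% of eigen-energy, clipped to $[1, N-1]$) is available; the rank
  used is recorded per position either way.
* **Flow statistic.** Mean residual power (a quadratic, energy-conserving
  statistic); amplitude and max are selectable but non-default.
* **Degenerate eigenvalues.** Any orthonormal basis of a degenerate
  eigenspace yields the same projector, so tests assert projector equality,
  never eigenvector equality.

## Surface detection, slab extraction, en face projection

The vascular slab is referenced to the skin surface. Per A-line, a moving
window (60 pixels at 2.7 µm/pixel; the physical equivalent, 162 µm, at other
grid scales) slides down from the top and the first window whose mean
intensity exceeds a threshold marks the surface region
(`detect_surface_aline()`). Because the window start systematically
overshoots the boundary, `detect_surface()` refines it to the first
supra-threshold pixel inside the qualifying window, which makes the
estimate unbiased on known-geometry phantoms (recovery within ±2 px is a
test contract). The index map is then median-filtered (5 × 5) and
undetected positions are filled from their nearest valid neighbours and
flagged — never guessed silently. If more than half the A-lines fail, the
function refuses to return a surface.

The threshold is automatic by default: mean + 4 SD of the top rows of the
cube (20 rows at full scale; the 54 µm physical equivalent otherwise),
which are assumed to be above the tissue. Because this floor scales linearly
with the data, detection is invariant to global intensity rescaling.

`extract_slab()` copies, per lateral position, the half-open depth interval
$[\mathrm{surface} + \mathrm{offset}, \mathrm{surface} + \mathrm{offset} +
\mathrm{thickness})$ into a flattened slab; defaults are 200 µm offset and
400 µm thickness — the hypodermis-plus-muscle band where wound angiogenesis
concentrates. Micrometres convert to pixels by rounding half away from zero
(200 µm → 74 px, 400 µm → 148 px at 2.7 µm/px). Rows beyond the cube bottom
are zero-filled and flagged. `mip()` takes the per-position depth maximum;
its depth-coded variant records the argmax depth for depth-colored
renderings. Depth indices are 1-based with $z = 1$ the shallowest sample.

## VAD quantification

A circular analysis mask (2 mm diameter by default) is applied to the en
face flow map in physical coordinates — a pixel belongs to the ROI iff its
center lies within the radius, with anisotropic pixel pitches honored — and
the map is binarized inside the ROI only. The scalar VAD is the plain pixel
ratio of vessel pixels to ROI pixels of the raw binary mask. The block-wise
VAD map tiles the binary image with non-overlapping 25 × 25 blocks (edge
blocks use their actual pixel counts), bilinearly resizes the block grid
back to the image size and smooths with a 3 × 3 Gaussian; it is a reporting
product and never feeds back into the scalar.

Binarization method: Otsu's threshold computed from ROI pixels, clamped
from below by a robust noise floor (median + 3 MAD of the ROI). The clamp
matters on avascular ROIs — a fresh wound at 3 h post-wounding contains
essentially no perfused vessels, and plain Otsu would bisect the noise
distribution and report a spurious VAD near 0.5; with the clamp the measured
VAD of an avascular ROI stays at the false-positive tail rate (≈1%). On
vascularized ROIs Otsu exceeds the clamp and behaves normally. The method
and threshold are recorded in every quantification record. The Gaussian σ
for the 3 × 3 kernel is 0.8 px, a standard choice for that support.

## The digital phantom

The phantom exists so that every stage above can be validated against known
ground truth; it emulates the reference study conditions, and its parameters are not
tuning knobs.

* **Tissue** (`build_tissue()`): a gently undulating surface (nominal depth
  170 µm, 25 µm undulation, a 0.55 mm-period scale-tile relief) over a
  five-layer stack — scale, pigmented layer, epidermis+dermis, hypodermis
  (200–400 µm below the surface), muscle — with fixed relative
  reflectivities and exponential single-pass attenuation (5 × 10⁻⁴/µm).
* **Vessels** (`build_vessels()`): persistent-random-walk tubes, radius
  4–15 µm, flow speed 0.5–2 mm/s, confined to 210–590 µm below the local
  surface (inside the default slab). Vessels are added — and the last one
  truncated — until the en face projected area fraction inside the target
  ROI reaches the requested value, so the generator's reported fraction is
  an exact pixel count of its own projected mask.
* **Speckle model** (`render_cube()`): per voxel, complex field =
  $\sqrt{\text{reflectivity}} \times$ unit-variance circular complex
  Gaussian speckle $\times$ attenuation, plus additive circular complex
  noise per repeat (default SNR 25 dB re unit reflectivity). Static voxels
  share one speckle draw across repeats; vessel voxels follow an AR(1)
  chain with inter-repeat correlation $\rho = \exp(-(v/v_c)^2)$,
  $v_c = 0.3$ mm/s. The mapping from flow speed to decorrelation is a free
  phantom parameter — cutaneous flow speeds in adult zebrafish are not
  established quantities — chosen so that capillary-range speeds
  decorrelate almost completely within one repeat interval. An optional
  global per-repeat phase (SD 0.2 rad in pipeline runs) emulates bulk
  motion.
* **Wound** (`apply_wound()`): a 1 mm punch centered in the field. Inside
  the disc the layers are excised to mid-muscle at early timepoints
  (crater depth interpolated from 260 µm at ≤1 dpw down to 10 µm at
  15 dpw), covered by a thin neo-epidermis from 3 h post-wounding, and
  filled with fine-grained granulation texture from day 4 — regressing to
  zero by day 15 in the control group, persisting (downsized) in the
  diabetic group. Sparse bright decorrelating voxels emulate inflammatory
  infiltrate around 1 dpw; they are cosmetic for structural images and
  excluded from ground-truth vessel masks.
* **Angiogenic response.** The vasculature of a perilesional zone of twice
  the wound diameter — i.e. the 2 mm analysis mask for a 1 mm punch — is
  replaced by an angiogenic vessel field whose projected area fraction
  follows the healing curve. The zone extends beyond the punch because
  wound angiogenesis sprouts around and into the wound, and because a fresh
  wound shows no perfused vessels in the surrounding tissue either.
* **Healing curve** (`healing_vad_curve()`): a log-normal-shaped pulse
  $A\exp(-\log^2(t/t_p)/2w^2)$ with amplitude $A = 0.30$, peak at
  $t_p = 4$ dpw, log-width $w = 0.6$, over a pre-wound baseline fraction
  $V_0 = 0.05$. The diabetic curve is the control curve scaled by
  $\delta = 0.4$ through day 10 (a 60% reduction); on days 10–15 both
  groups blend quadratically to the common recovery level $0.7\,V_0$,
  emulating the return to normoglycemia. The curves are unimodal with their
  maximum at 4 dpw on the sampled timepoint grid {0.125, 1, 4, 7, 10, 15};
  exact unimodality of the continuous diabetic curve is impossible jointly
  with day-15 convergence, since the diabetic VAD must re-rise toward the
  common level after its suppressed peak.
* **Cohort** (`simulate_cohort()`): 9 control + 9 diabetic fish, glucose
  checked at 4, 8 and 14 days post-injection (arbitrary units: normal
  60 ± 15, hyperglycemic 300 ± 15, recovery at 14 dpi; only the ordering
  and recovery pattern are meaningful), with two planned failed-induction
  low-glucose fish and one handling death among the diabetic group —
  yielding 16 included and 6 analyzed diabetic fish. The exclusion floor
  defaults to the normal mean − 2 SD. Normo- and hyperglycemic draws are
  rejection-sampled above the floor so the planned attrition is stable
  across seeds. In table-level mode the observed VAD is ground truth × a
  per-fish log-normal effect (SD 0.1) + Gaussian measurement noise
  (SD 0.015); in rendered mode every retained fish-timepoint goes through
  the full reconstruction chain.

What the phantom does **not** emulate: lateral point-spread blurring and
defocus, shadowing under scales beyond exponential attenuation, spectral
roll-off, multiple scattering, lateral bulk motion (frame-to-frame
registration is out of scope), heartbeat-locked flow pulsatility, and any
physiological coupling between glucose and vessel biology beyond the
group-level curve. Passing tests therefore demonstrate that the processing
chain is correct and self-consistent under a realistic speckle model — not
that it is robust to every artifact of in vivo data.

## Statistics

Group summaries are mean ± SEM (sample SD/√n; single-observation cells are
flagged rather than given a fake SEM). The group comparison is a two-way
ANOVA of VAD on group × timepoint with Type II sums of squares — attrition
makes the design unbalanced (9 vs 6), and Type II coincides with the
textbook decomposition when the design happens to be balanced. Per-timepoint
comparisons are Welch unequal-variance t tests with Bonferroni adjustment
$p_{\mathrm{adj}} = \min(1, m\,p)$, family size $m$ = number of timepoints
compared (configurable). Significance labels use the three-level convention
*** $p \le 0.001$, ** $p \le 0.003$, * $p \le 0.03$. Timepoint is treated
as a plain second factor, not a repeated measure; a mixed-effects
formulation is deliberately out of scope.

## Degenerate inputs and numerical edges

* All-zero repeat pairs make the bulk-phase estimate undefined; the pair is
  passed through unchanged with a warning.
* An all-zero eigen-spectrum yields clutter rank 1.
* Constant ROI intensities make Otsu undefined; `binarize()` fails with a
  pointer to the fixed-threshold mode.
* Empty ROIs are an error for the scalar VAD (a 0/0 ratio has no meaning).
* Pre-wound scenes use the sentinel timepoint −1; any other negative
  timepoint is rejected.
* Integer depth indices make surface flattening exact for integer synthetic
  surfaces — no interpolation is performed anywhere in the slab path.

## Worked example

```{r, eval = FALSE}
library(octawound)
opt <- phantom_optics(96L, 64L, 64L)        # small grid for a quick look
ms <- measure_scene("control", 4, seed = 77, optics = opt)
ms$vad              # pipeline-measured wound VAD at 4 dpw
ms$truth_fraction   # generator ground truth for the same ROI

run <- run_pipeline(seed = 1, optics = opt,
                    cohort = cohort_config(n_control = 3L, n_diabetic = 3L,
                                           timepoints = c(-1, 1, 4, 10),
                                           n_low_glucose = 0L, n_died = 0L))
print(run$report)
```

## Known limitations

* The renderer holds one full complex cube in memory; at the full
  1024 × 500 × 500 × 8 protocol that is ≈16 GB and is intended for
  out-of-core or chunked processing, not for the bundled simulations.
* Surface detection assumes the tissue is the first bright structure; media
  or mounting reflections above the skin would need masking first.
* The binarization noise-floor clamp assumes vessels occupy well under half
  of the ROI; fields denser than ~50% would bias the MAD estimate.
* VAD is the only vascular metric implemented; length density, diameter,
  tortuosity and branch-point density are deliberately out of scope.
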
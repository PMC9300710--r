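---
title: "Models and methods behind spinetrack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind spinetrack}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`spinetrack` measures dendritic spines — head volume and neck length —
across a time series of fluorescence z-stacks. This vignette explains the
models each stage rests on, the parameters that matter, the choices made
where the design was genuinely open, and what the synthetic data used for
testing does and does not establish about real microscopy.

## Registration

Lateral drift between consecutive stacks is estimated on
maximum-intensity projections by the cross-correlation peak in the
frequency domain, refined to a fraction of a pixel by evaluating the
cross-correlation on a fine grid around the coarse peak with a
matrix-multiply DFT. The cross power is deliberately left *unnormalized*:
whitening the spectrum (pure phase correlation) weights all frequencies
equally, and with PSF-band-limited images the high frequencies carry only
shot noise — under Poisson noise the phase-only variant loses more than a
pixel of accuracy while the unnormalized peak stays within a few
hundredths. Shifts between consecutive time points are accumulated and
each stack is resampled once, with a single Fourier shift, to avoid
compounding interpolation loss. Axial offsets are corrected to the
nearest whole slice by maximizing slice-wise correlation; sub-slice
accuracy is unnecessary because all downstream 2D analysis happens on
projections.

After global alignment, each spine's ROI is re-centered by an exhaustive
search over integer offsets within a Chebyshev radius (default 10 px),
scoring each candidate crop against the previous time point's ROI with
normalized mutual information, NMI = (H(A)+H(B))/H(A,B) on a 64-bin joint
histogram. NMI rather than correlation because the spine may change
brightness and shape between time points while remaining the same
structure. A constant image pair is defined to score the maximum (2); a
best score below a configurable floor flags the spine as missing at that
time point rather than silently measuring the wrong structure.

## Detection

Candidate locations are scale-space determinant-of-Hessian maxima
(bright blobs only, four scales spanning head radii of 0.15–0.6 µm).
Maxima are taken per scale rather than across the scale stack: a head
responding at two scales yields near-duplicate candidates that downstream
non-maximum suppression merges, whereas requiring a maximum across scales
was observed to drop real spines whose response is shared between
neighbouring scales. Candidates are cheap; precision comes from the
classifier.

The classifier is a small convolutional network — six blocks of 3×3
convolution, batch normalization, swish activation and 2×2 max pooling,
then three fully connected layers — trained on fixed-size patches whose
*physical* side (3.4 µm) is converted to pixels per dataset, because the
tuned quantity is physical extent, not pixel count. Patches are resampled
to a fixed 32×32 network input and standardized per patch, which makes
classification invariant to absolute intensity. Nine classes cover the
features that occur on a dendrite (head, overlapping heads, head–dendrite
junction, dendrite edge, dendrite interior, neck, head edge,
bouton/axon, background); a two-class profile pools everything non-spine,
which is the more robust choice when counting spines is the goal. The
network is implemented natively in R with im2col/BLAS matrix products and
Adam; the `small` profile (narrower blocks, 256-unit first FC layer)
trains a nine-class problem in under a minute at desk scale. Training
patches come from the simulator's ground-truth geometry; class imbalance
is handled with inverse-frequency loss weights, and the checkpoint with
the best validation accuracy (70/30 split) is kept. All of it is
deterministic given the configuration seed.

## Dendrite segmentation

The branch-plus-spines silhouette comes from a median filter (3 px at
≥0.03 µm/px sampling, else 5 px) followed by Otsu thresholding computed
on a 256-bin histogram spanning the observed intensity range — that
choice makes the threshold covariant with intensity scaling, which is
what ultimately makes segmentation insensitive to laser power. The medial
axis is traced between the two farthest foreground points (found by two
fast-marching sweeps) on a speed map proportional to the squared distance
transform, so the geodesic hugs the tube center. At each axis point a
disk of radius equal to the local distance-transform value — clamped to
the median radius ±25% — is swept along the axis; the union of disks,
intersected with the Otsu foreground, is the shaft. The clamp implements
the assumption that the dendrite diameter is locally constant: spines are
bumps whose local radius exceeds the clamp, so they are excluded. The
median shaft intensity is recorded as the IFI normalizer; a median (not a
maximum) because projected out-of-plane spines create saturated hotspots
that would make the normalizer a floating reference.

When several equally large components exist the one containing the image
center is analyzed, and an error lists the candidates otherwise. Manual
boundary correction is exposed as `adjust_boundary()`: one pixel of
morphological growth or shrinkage per iteration, gated by a fixed
intensity threshold (the Otsu level of the guiding image) so the contour
locks onto the intensity edge; where the gate stalls the full ring moves,
which keeps grow-then-shrink near-inverse on smooth shapes.

## Spine-head segmentation

Seeds are the regional maxima of the h-maxima transform (prominence
threshold h defaulting to 10% of the ROI dynamic range — unstated in the
underlying method, chosen so shot-noise texture does not seed) plus a
one-pixel seed at the detected center, which guarantees at least one
seed. Seeded region growing on the intensity relief, bounded by the Otsu
foreground of the ROI, gives the initial head region; a spine entirely
below the Otsu threshold gets a circular mock boundary of 0.6 µm radius
around its center (a typical head radius — the method needs *some*
support to segment a dim spine).

Watershed regions are systematically larger than what an expert would
call the head, so a second, graph-based stage refines them: pixels of the
region are clustered on standardized (intensity, geodesic distance to
seed) features — over-clustered by Ward agglomeration, merged to at most
ten clusters, ranked by mean geodesic distance from the seed. Clusters
are accumulated from the inside out until the mean intensity first falls
below a fraction f = 0.5 of the seed cluster's mean; how many outer
clusters to drop is thereby decided adaptively rather than by a fixed
count, which is this package's concretization of an otherwise
under-specified step. The refined mask is the connected component
containing the seed and is by construction a subset of the watershed
region; if exclusion would empty it, the innermost cluster is kept.

## Neck path

The neck is extracted in 3D. The stack is turned into a speed map by
grayscale-eroding each slice with a 1 px disk (suppressing one-pixel
bridges that create spurious shortcuts) and normalizing to [0, 1] with a
floor of 10⁻³ of the maximum, so arrival times are finite everywhere and
tracing is total. Arrival times from the head center solve
|∇T| = 1/speed with a multi-stencil fast-marching solver (axis and
in-plane diagonal stencils, second-order upwind differences where the
two-step neighbour is strictly smaller; anisotropic voxel spacing enters
through the physical direction vectors). Two numerical safeguards matter:
second-order differences near a strongly curved front systematically
undershoot, so the immediate neighbourhood of the source is initialised
analytically where the medium is locally homogeneous; and the strictness
condition on the two-step neighbour suppresses the same pathology at
plateau fronts. On a 21³ uniform grid the arrival times stay within 1.6%
of Euclidean distance.

Candidate neck paths are traced from the N = 8 dendrite-perimeter voxels
nearest (in physical distance) to the head center, by fourth-order
Runge–Kutta descent on the arrival-time gradient in 0.25-voxel steps,
with a discrete steepest-descent fallback where the interpolated gradient
stalls (narrow channels). Each candidate is scored by three terms — its
physical length L, its complexity C (sum of L1 norms of the coordinate
increments after resampling to uniform half-voxel arclength steps, so the
term is independent of the tracer's step size), and its smoothness S (the
total variation of the image intensity sampled along the resampled path).
The total-variation reading of S is deliberate: summing raw intensities
would perversely penalize bright, well-resolved necks, whereas a path
that dips through dark background accumulates variation. The selected
path minimizes L/max(L) + C/max(C) + S/max(S), a cost invariant to
rescaling any single term across candidates. Finally the portions inside
the segmented head and dendrite are removed; the longest contiguous
outside run is the neck, its recomputed L the reported length, and a head
that touches the shaft yields length zero with a flag rather than an
error. Terms are recomputed after trimming, since the selection-time
values include the intra-head segment. A nearby bright process that is
closer in Euclidean terms than the parent dendrite does not capture the
path: it is not part of the segmented dendrite (so contributes no
candidate base points), and the geodesic cannot cross the dark gap
cheaply, which is exactly the behaviour verified on phantoms with
distractor tubes.

## Volume estimation

IFI: intensities inside the head mask are summed; the background (the
minimum intensity of the spine's own field of view times the mask area)
is subtracted; the result is divided by the median dendrite intensity at
the same time point. The quotient is invariant under a common intensity
scaling of the frame — the property that makes longitudinal IFI volumes
comparable across laser-power drift. The FOV minimum is taken per ROI
rather than per frame, since frame-wide minima are dominated by empty
corners. A negative numerator (dim, noise-dominated time point) clamps to
zero with a flag so a longitudinal run is never aborted by one bad frame.

FWHM: an intensity profile is sampled by interpolation along a line
through the head center at a user-supplied orientation (the orientation
is an explicit parameter; the postsynaptic density that defines it is not
reliably visible in projections, so no automatic search is attempted),
a Gaussian with constant offset is fitted by Levenberg–Marquardt, and the
fitted FWHM is treated as the diameter of a sphere: V = 4/3·π·(FWHM/2)³.
The offset term makes the fit robust to nonzero background; fits whose
width exceeds half the profile length are rejected as unconstrained.

Trend agreement between two volume series uses the symmetric mean
absolute percentage error, sMAPE = 100/t·Σ|aᵢ−bᵢ|/|aᵢ+bᵢ|, and the
similarity score SS = 100 − sMAPE. As printed, the score formula
multiplies a percentage by 100 a second time; the subtraction form is
used because it reproduces the scale on which such scores are reported
(identical series score 100, and scores in the 70–97 range are typical
for inter-method agreement). A 0/0 term is defined as zero agreement
error; a cancelling pair of opposite signs is rejected as undefined.

## The simulator and what the tests establish

The simulator is the package's source of ground truth. Its defaults *are*
the study conditions: 512×512 frames at 72 nm/px, one smooth dendrite in
the optical plane, potential synapses placed by a Poisson process with
density 2.56 µm⁻¹, two-state Markov turnover with p_on = 10⁻³ and
p_off = 4.1·10⁻³ per step over 2000 steps, 26 rendered keyframes
(labelled in days up to 75 for reporting), dendrite pixels ~N(1000, 100),
spine pixels ~N(2000, 300), values clipped to [0, 2000], a Gaussian PSF
of 600 nm FWHM, and Poisson noise applied last (shot noise physically
follows the optics; a photon-budget multiplier γ scales its strength,
with γ = 4 used as the "low-noise" condition and γ = Inf disabling noise
for noise-free checks). Geometry the original description leaves open is
fixed once at realistic values: a low-order spline centerline with gentle
wobble, 0.8 µm dendrite width, head radii ~N(0.4, 0.1) µm floored at
0.15 µm, one-pixel necks of uniform 0.2–1.5 µm length, sides assigned at
random per synapse and fixed across time. Initial states are drawn from
the chain's stationary distribution, p_on/(p_on+p_off) ≈ 0.196. All
randomness flows from one seed; identical seeds give bit-identical
frames.

A 3D phantom (sphere head, cylinder neck of known length and tilt, tube
dendrite, optional distractor tube that is Euclidean-nearer to the head
but intensity-disconnected) extends the same intensity/PSF/noise model to
z-stacks for registration and neck-path validation; its ground-truth neck
length is exact by construction.

Synthetic data establishes internal correctness — parameter recovery,
invariances, geometric accuracy — under a known forward model. It does
not establish performance on real tissue: real dendrites branch, cross,
and leave the optical plane; real noise includes detector offsets and
motion within a stack; real spines are not discs with straight necks; and
the classifier trained on simulated patches has seen none of the texture
of real neuropil. Results on the paper-scale questions (expert agreement,
LTD/LTP cohorts) require real annotated datasets and are out of scope
here.

## Problem sizes and numerical conventions

The shipped tests run the conditions above at sizes a workstation handles
comfortably: 100 branches for density recovery, 500×2000 chains for rate
recovery, 20 rendered frames for segmentation accuracy, 10 phantoms for
neck recovery, 5 series of 26 keyframes for spine counting with the
`small` two-class classifier, and 2-timepoint 192-pixel runs for
pipeline determinism. Coordinates are 1-based (row, col, slice) in R;
physical lengths always pass through the voxel geometry; Fourier shifts
use periodic boundaries (and frames are clamped to non-negative
intensities afterwards); Otsu histograms always span the observed range;
ties in candidate selection, non-maximum suppression and base-point
ordering are broken deterministically (first candidate, lower row, then
lower column, then slice). One verification detail: a 26-neighbour
Dijkstra oracle bounds fast-marching arrival times only up to the graph
metric's own overshoot, which is 8% in 2D but up to 12.5% in 3D
(direction (3,1,1)); the tests derive that bound explicitly rather than
assuming the 2D figure.

## Known limitations

Single dendrite per field of view (the largest, most central component is
analyzed); translation-only registration (no rotation or deformation); no
neck-width estimate; FWHM orientation is manual; IFI volumes are in
arbitrary units (converting to µm³ requires a user-supplied calibration
from spines measured both ways); and the classifier shipped from
simulator training should be retrained on annotated patches from the
user's own imaging system before being trusted on real data.
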
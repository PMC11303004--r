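---
title: "Membrane tube subtraction and particle recovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Membrane tube subtraction and particle recovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Binding His-tagged proteins to Ni-NTA lipid nanotubes keeps them away from
the air/water interface and lets them adopt a full range of orientations.
The price is that every particle image is superimposed on a strong membrane
signal. `rastr` implements the computational half of that experiment: align
each boxed tube segment in plane, build the rotational (azimuthal) average
of the tube, project it back, subtract it from every segment, and then
recover the decorating particles from the membrane-free images — either
with a template or, template-free, by tiling the segments into sub-boxes
and letting 2D classification sort particle-containing boxes from membrane
residue and noise.

All stages are validated against a synthetic decorated-tube simulator that
carries exact ground truth for every tube pose and particle position.

## Conventions

* Images are matrices indexed `[x, y]`; 0-based pixel coordinates; the
  image center sits at `(n-1)/2` (between the two middle pixels of an even
  box). Shifts are the translation that moves the tube onto the center and
  are stored in the rotated (tube-vertical) frame; `shift_y` is fixed at 0
  because a straight tube is translationally invariant along its axis.
* Euler angles, in degrees: `phi` spins the tube about its own (volume z)
  axis; `theta` in {90, 270} encodes the polarity of the tube; `psi` is the
  in-plane angle, defined so that rotating the image content by `+psi`
  makes the tube vertical. Internally the rotation mapping volume to image
  coordinates is `Rz(-psi) Rx(theta) Rz(phi)`; with `theta = 90` and
  `psi = 0` the tube axis lies along the image y axis. (Realizing the
  polarity flip about the in-plane x axis rather than y is what makes the
  aligned tube vertical at `psi = 0`; the exported STAR labels are the
  conventional rlnAngleRot/Tilt/Psi names.)
* The tube axis direction in an unaligned image is `(sin psi, cos psi)`;
  particle azimuth 0&deg; faces the viewer (projects onto the tube midline)
  and 90&deg; points toward +x after the psi rotation, so the projected
  perpendicular offset of a particle is
  `(outer_radius + attachment_offset) * sin(azimuth)`.

## The synthetic decorated tube

The tube is a body of revolution whose radial density is the sum of two
Gaussian shells — the bilayer leaflets:

* `outer_radius` 137.5 Å (a 27.5 nm tube, the middle of the 25–30 nm
  range these lipid nanotubes show),
* `bilayer_separation` 37 Å (headgroup-to-headgroup),
* `shell_sigma` 8 Å, `amplitude` 1.

Its noiseless projection is computed analytically: the intensity at
perpendicular distance `x` from the axis is the Abel transform
`P(x) = 2 ∫ g(sqrt(x² + s²)) ds`, evaluated by quadrature on a quarter-pixel
lookup table. Particles are Gaussian blobs (default radius 85 Å, a ~520 kDa
globular protein) held `attachment_offset = 20` Å off the outer shell by
their linker, with peak density 1.35× the shell — the typical
protein-to-lipid density ratio. Their projections are ray sums of the blob
volume, added at the exact sub-pixel position with bilinear splatting.

Each simulated tube is rendered once as a micrograph-sized field (tube plus
particles plus white Gaussian noise), and segments are cut out as
integer-pixel windows along the axis. Overlapping windows therefore share
their pixels — exactly like overlapping boxes from a real micrograph —
which is what makes cross-correlation duplicate elimination meaningful.
The noise level is set as `sigma = sd(bare tube frame) / sqrt(SNR)`, i.e.
SNR is the variance ratio of the noiseless tube image to the noise; this is
calibrated once per dataset on a segment-sized bare-tube field so that the
stated SNR does not depend on how many particles happen to be in a window.

What the simulator does **not** model: ice-thickness gradients, beam-induced
motion, detector transfer functions, curved or crossing tubes, aberrant
"ghost"/"dark" tube morphologies, or structured backgrounds. A CTF can be
applied optionally (standard weak-phase model, 300 kV, Cs 2.7 mm), but the
validation runs are CTF-free: passing tests demonstrate the pipeline's
geometry and statistics, not robustness to every property of real
micrographs.

## In-plane alignment

`estimate_psi` follows the autocorrelation route: the linear (zero-padded)
2D autocorrelation of a tube image is elongated along the tube axis. The
autocorrelation is normalized by the zero-padding overlap envelope (the
raw pyramid envelope would bias the angle), windowed isotropically, and
scored over a 1° grid by the variance of per-column line sums after
rotation; golden-section refinement takes the optimum to 0.1°. The
reported score is the anisotropy of this objective over the grid
(`max/median − 1`): pure-noise fields score around 1–2, clear tubes above
6, and the default floor of 3 turns featureless segments into "no tube
detected" failures.

`find_tube_edges` works on the per-x profile (mean over the central half
of y) of the rotated segment, Gaussian-smoothed with σ = 2 px. Because the
two bilayer peaks per side can merge or one can drop below the prominence
threshold under noise, the edge pair is anchored by the profile's symmetry
center — the peak of its self-convolution, a matched filter of the profile
against its own mirror image — and the outermost pair of local maxima
lying symmetrically about that center (within the configured tube-width
window) becomes the edges. The centering shift is the distance from the
edge midpoint to the image center. Note that the detected edges are the
outer-tangent *maxima* of the projected shell, which sit slightly inside
the nominal outer radius (the Abel peak of a Gaussian shell of width σ at
radius r lies below r); the package treats the edges as those maxima.

`phi` is drawn uniformly from [0, 360) and `theta` from {90, 270} with
equal probability. Polarity is not estimable before subtraction and is
irrelevant to an axially averaged map, so it is randomized rather than
estimated.

### Reference-based refinement

The initial psi estimate is accurate to about 1–2° at SNR 0.2. The second
alignment pass refines each segment against a reference tube profile by a
matched filter: the reference image is *evaluated analytically* at any
candidate angle and offset from a band-limited (sinc-interpolated) 1D
profile, so the noisy segment pixels are never interpolated and the
objective has no grid-direction bias. Two further choices matter:

* the filter is evaluated over a central disk — a disk is
  reflection-symmetric about any candidate axis, which keeps the objective
  exactly even in the angle error even when the reference profile is
  imperfect (a square support would bias psi by up to a degree);
* by default the reference is the leave-one-out mean of the aligned
  per-segment profiles, so a segment's own noise cannot attract its
  refinement; a projection of the azimuthal-average volume can be supplied
  instead.

`refine_loop` iterates this until the mean parameter changes fall below
0.2° and 0.25 px (at most 5 passes; 2–3 are typical). At SNR 0.2 on a
160-px box the final accuracy is ~0.15° and ~0.2 px (the Cramér–Rao bound
for this geometry is ≈0.1–0.2°), which is what the acceptance run
demonstrates.

## The azimuthal average

`reconstruct_average` is a direct Fourier (central-slice) inversion: each
shift-corrected segment transform is inserted as a central slice at its
Euler orientation with trilinear spreading and per-voxel weight
accumulation, and the accumulated transform is divided by
`max(weight, eps · max(weight))` (`eps = 0.001`). A hard weight floor is
used rather than an additive constant because an additive Wiener term
damps the sparsely covered high radii and visibly broadens the shell
profile. Numerical accuracy choices:

* Fourier oversampling (default 2×, 3× for the high-fidelity validation
  runs): slices are inserted into a finer frequency grid, which suppresses
  the low-frequency gridding error that otherwise fills the tube interior
  with a spurious pedestal;
* roll-off correction: the volume is divided by the real-space transform
  of the trilinear kernel (sinc²);
* the object center (between pixels, at `(n-1)/2`) is handled by exact
  phase ramps.

With 360 uniformly spun noiseless views of a 64-px tube this reaches a
correlation of ≥0.99 with the analytic body of revolution, cylindricity
≥0.999, and a radial profile within 2% RMS of the inverse Abel transform
of the mean projection (the inverse Abel oracle integrates the classical
`−(1/π) ∫ P'(x)/sqrt(x²−r²) dx` formula exactly on a piecewise-linear,
sinc-upsampled profile).

`smooth_z` replaces every slice by the mean over the central 80% of slices
(`z_fraction = 0.8` excludes wrap-around edge slices), making the volume
exactly z-invariant. `cylindricity` reports
`1 − residual power after removing the rotational average / total power`,
with 0.25-voxel radial bins so the metric itself saturates only above
0.9998 on an analytic cylinder. `symmetrize_average` can additionally
enforce exact rotational symmetry.

`project_average` ray-sums the rotated volume; for a z-invariant volume it
instead renders the tube as axially unbounded from its profile (a tilted
finite cube would otherwise show tube ends inside the frame), and for a
near-cylindrical volume the profile is taken as the Abel transform of the
radial profile, which makes the projection exactly independent of `phi`.

## Subtraction

`subtract_segment` fits a single scale `alpha = argmin ‖img − α·proj‖²`
with an intercept (ice background varies per segment) over the tube mask
(`proj > 10%` of its maximum), then subtracts `α·proj` from the whole
frame. One trimmed refit (residuals beyond 3.5 MAD excluded) stops bright
particles that overlap the tube band from inflating the scale. An optional
Gaussian band-limit matching factor can be co-fitted (`match_bandlimit`),
off by default.

`subtract_stack` by default derives the per-segment tube projection from
the stack's own pooled profile: every aligned pixel is binned by its exact
analytic perpendicular distance to the axis (0.25-px bins, per-bin
median). This is the projection of the azimuthal average *estimated
directly in projection space*; it avoids both the interpolation blur of
rotating noisy images and the gridding loss of the 3D round-trip, and the
per-bin median is robust to the minority of pixels that belong to
particles. The volume route (`projection = "volume"`) is retained and is
what the residual-vs-segment-count monotonicity test exercises. On
noiseless simulated stacks the pooled-profile subtraction leaves under 1%
of the shell RMS with true alignment and a few percent with estimated
alignment; the subtracted segments correlate with the ground-truth
particle-only images at NCC > 0.9.

## Particle recovery

**Template picking.** Normalized cross-correlation (FFT-based, locally
normalized) of a particle template over each subtracted segment, maximized
over 24 in-plane template rotations; local maxima above the threshold are
accepted greedily with a minimum separation of half the template side.
The default threshold of 0.15 was calibrated once against the null
distribution of frame maxima on tube-only and pure-noise fields (null
maxima ≈0.10–0.13, true particles ≈0.2–0.4 at SNR 0.3). Accepted peaks
are localized by an intensity-weighted centroid of the correlation peak
(window 0.3 of the template side, squared weights): the blob's broad
correlation peak makes a plain argmax jitter by 1–2 px under noise while
the centroid stays within ~0.5 px.

**Picking by classification.** Subtracted segments are tiled into
overlapping sub-boxes just larger than the particle; `classify_2d` is a
multi-reference alignment classifier: random partition under the seed,
then iterations of align-to-every-reference (rotation grid × FFT shift
search) and reference re-averaging, stopping when under 1% of assignments
change. Two implementation details are required for usable picks: each
reference is seeded from a single member of its random class (an unaligned
class *mean* smears features beyond the alignment capture range and stalls
the iteration), and every reference is re-centered on its energy centroid
after each update (in-class shifts are reported relative to the reference
frame, so picks are only meaningful for centered references).
"Good" classes are ranked by coherence — the mean member-to-reference
correlation — with classes kept when they approach the best one and the
best one clearly stands out; this automatic stand-in replaces the manual
class curation an operator would do interactively, as does the final
evidence pruning (picks whose local smoothed density falls far below the
bulk of the selected class are residue boxes that slipped through).
Sub-box picks are re-centered by an intensity centroid on the subtracted
segment and re-scored by their local smoothed density so that duplicate
elimination keeps the best-centered copy.

**Duplicate elimination.** Two picks are duplicates iff they lie within
`dist_px` on the same micrograph *and* the peak normalized
cross-correlation of their boxed images over a small shift search exceeds
the threshold. Picks are processed greedily in descending score with
deterministic tie-breaks, which makes the operation order-independent and
idempotent. Because white noise decorrelates completely under shifts
larger than the search radius, duplicates are only recognizable when
their windows share underlying pixels — which overlapping segments of one
micrograph do. For template picks (centered to ~1 px) the ±2 px search
suffices; classification picks are coarser, so the pipeline uses a ±8 px
search with the distance gate at the particle diameter and a correlation
gate of 0.6 (the correlation of same-pixel crops at a few pixels'
mismatch), values chosen on simulation.

## Validation geometry and what the tests show

The test and acceptance runs use scaled-down problem sizes chosen for a
single CPU: alignment accuracy on 20 tubes in 160-px boxes at 3.44 Å/px
(outer radius 40 px); reconstruction fidelity at 64³ from 360 views at
6.875 Å/px (radius 20 px); picking on 50 segments of 160 px at 6.875 Å/px
with 200 particles at SNR 0.3, where both routes reach ≥0.95 recall and
precision against ground truth within 2 px. The end-to-end pipeline run
(overlapping segments, both pickers, duplicate elimination) reproduces
byte-identical pick lists under a fixed seed, with the pick count matching
the simulated particle count.

These are demonstrations on an idealized specimen: straight tubes of a
single known profile, identical particles, white noise, no CTF. They
validate the geometry, estimators and bookkeeping of the implementation —
not its performance on every pathology of real cryo-EM data, where
2D-classification triage of bad segments, CTF handling, and per-dataset
threshold tuning would all matter.

## Known limitations

* One tube per segment; multi-tube boxes and curved tubes are expected to
  fail alignment QC rather than be modeled.
* Subtraction operates in the recorded image domain; no CTF-aware
  weighting (the azimuthal average is built from, and subtracted from,
  images with identical optics in the validation runs).
* Residual-based automatic segment rejection is reported
  (`residual_rms`) but not applied as a filter.
* The 2D classifier searches in-plane rotations only; out-of-plane views
  are handled by multiple classes, not by a projection model.
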
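---
title: "Localized reconstruction of subunits: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localized reconstruction of subunits: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(localrec)
library(dplyr)
```

## The problem

Single-particle cryo-EM routinely exploits the point-group symmetry of
large complexes: averaging over all asymmetric units multiplies the
effective number of observations by the group order. The price is that
any component which does *not* obey the imposed symmetry — a monomeric
polymerase sitting under one threefold axis of an icosahedral capsid, a
flexibly attached vertex of a protein cage, a spike present in only
some of its binding sites — is rotationally smeared and lost.

Localized reconstruction recovers such components by demoting them to
single particles in their own right. Given (i) refined whole-complex
orientations and origins for every particle image, (ii) the point
group of the complex, and (iii) a single vector from the center of the
complex to the center of one subunit, the positions and orientations of
*all* symmetry-related subunits in every particle image follow by pure
rotation algebra. Small windows ("sub-particles") are cut out of the
particle images at those positions and thereafter treated as an
independent single-particle data set: they can be classified (for
occupancy or for the degenerate orientations on a symmetry axis),
reconstructed by direct Fourier inversion, and assessed by Fourier
shell correlation.

## Pose algebra and conventions

Orientations are ZYZ Euler triplets `(rot, tilt, psi)` in degrees,
composed intrinsically (rotate by `rot` about z, by `tilt` about the
new y, by `psi` about the new z), acting on column vectors. The pinned
observation model is: the image-plane position of a model point `p`
(Angstrom, relative to the map center) is the first two components of
`M %*% p`, and the third component is the height of the point above the
image plane along the beam. All other conventions are forced from this
one by the projection oracle in the test suite, which renders phantom
projections analytically and requires predicted sub-particle positions
to land on the rendered blobs to sub-pixel accuracy.

The sub-particle pose composition is

```
M_sub  =  M_particle %*% M_sym %*% M_vec
offset =  M_particle %*% M_sym %*% (length * direction)
```

where `M_vec` is the minimal rotation taking the reference axis
`(0,0,1)` onto the subunit vector (rotation about `(0,0,1) x v`; the
anti-parallel case is fixed, stably, as a 180-degree rotation about x).
At gimbal lock (`tilt` 0 or 180) the returned Euler triplet sets
`rot = 0` and carries all in-plane rotation in `psi`; the matrix
round-trip remains exact even though individual angles are not unique.

Point groups are generated by closure from small generator sets and
ordered deterministically. The icosahedral setting is the common "I2"
orientation with twofold axes along x, y, z, so threefold axes lie
along the body diagonals and fivefolds along `(0, 1, phi)` and its even
permutations; the octahedral setting has fourfold axes on the
coordinate axes. If metadata produced by a tool using a different
icosahedral setting must be matched numerically, the vector can be
given in that setting's frame; only the I2 setting is generated here.

Orbit decomposition is numerical: the vector is rotated by every group
element and positions that coincide within a merge tolerance (default 1
pixel) are merged into one *site*, so a vector on an n-fold axis yields
`|G|/n` sites (orbit–stabilizer). The group elements merged into a site
differ by a rotation about the subunit axis; they are ordered by that
residual angle, which defines the 0-based `degen_index` (e.g. the
0/120/240-degree orientations on a threefold). By default one of them
is drawn uniformly at random per record, seeded, so downstream
processing is not biased toward one orientation; `degenerate = "all"`
emits every orientation (a plain symmetry expansion into asymmetric
units), and `"first"` is deterministic.

## Coordinates, origins and defocus

Particle image coordinates are 0-based with the box center at
`floor(N/2)`. A record's origin is the shift that re-centers its image:
a particle whose origin is `(ox, oy)` sits at `center - origin` in the
raw image. Sub-particle positions are split into an integer extraction
coordinate (nearest pixel, halves away from zero) and a sub-pixel
origin `integer - position` with `|origin| <= 0.5`, so extracting at
the integer pixel and translating by the origin re-centers exactly
(verified to 0.05 px by interpolated re-centering in the tests).

The sub-particle height along the beam adjusts its defocus: both
defocus values shift by `-z_height * pixel_size`. Positive defocus
denotes underfocus, and a sub-particle above the particle center
(towards the electron source) is taken to be *less* underfocused. The
sign is not derivable from the inputs the method consumes, so it is
pinned and exposed (`invert_z`); at typical box sizes it affects only
sub-Angstrom-scale CTF fidelity.

Two geometric filters mitigate overlap of sub-particles with the bulk
and with each other. Side-view selection keeps records whose rotated
subunit vector lies within a maximum elevation of the image plane
(kept fraction `sin(angle)` under uniform orientations, which the test
suite checks by Monte Carlo), and can exclude top views near the beam
axis. Overlap exclusion removes, symmetrically, both members of any
same-particle pair whose boxes overlap by more than a threshold along
the center line (`box_size - distance`); removing only the
later-encountered member is available behind a flag, since the
symmetric rule discards more records than strictly necessary. Both
filters are pure predicates of the particle geometry; evaluating the
overlap rule against the full expansion (the `reference` argument)
makes them commute.

## Signal subtraction

The bulk of the complex is removed from the particle images in
projection space: a mask over one subunit (here a sphere at the vector
endpoint, optionally soft-edged) is symmetrized over the group by
voxelwise maximum of rotated copies; masked voxels of the consensus
map are flattened to the background level; the resulting
subunit-free map is projected in each particle's orientation and
origin, CTF-modulated with the particle's own defocus, and subtracted.
"Background" is the mean of unmasked voxels outside a generous
particle radius (default `0.45 N`), which flattens the masked region
without introducing a density step; the global unmasked mean is
available as an alternative. Whole-particle defocus is used for the
subtraction projection because sub-particle heights vary across one
image; the per-sub-particle adjusted defocus is used downstream.

A least-squares intensity scale between the reference projection and
the image is available (`scale = TRUE`) for experimental data whose
absolute scale is arbitrary, but it is off by default: whenever the
retained subunit signal correlates with the bulk reference — which is
generic, since both live on the same support — the fitted scale
absorbs part of the subunit signal and distorts the residual. On the
synthetic oracle the unscaled residual is ~0.2% of the subunit
projection norm, while the scaled residual fluctuates up to ~14%.

## Projection, reconstruction and gridding

The projector extracts central slices of the 3D Fourier transform
(2x zero-padded) and the reconstructor inserts CTF-premultiplied image
transforms as central slices with CTF^2 weights, divided with
Wiener-style regularization (`k * mean(weight)`, default `k = 1e-3`).
Both use Kaiser–Bessel convolution gridding with the kernel's
continuous transform divided out in real space. The extraction kernel
is width 6 (shape 13.86), which keeps worst-case projection error
below `1e-3` relative RMS against analytic and rotate-and-sum oracles
over random poses, including the lattice-aligned poses where plain
trilinear interpolation with a sinc^2 correction is several times
worse; insertion uses the cheaper width-4 kernel (shape 9.0), which is
ample for the correlation-level accuracy reconstruction requires. The
real-space rotate-and-sum projector is retained in the test suite as
the independent cross-check.

CTF evaluation follows the standard weak-phase model with astigmatic
defocus, relativistic electron wavelength, and amplitude contrast;
`CTF(0) = -amplitude_contrast`. Phase flipping multiplies by the sign
of the CTF only and preserves every Fourier amplitude.

## Quality metrics

FSC is computed in shells one Fourier voxel wide, optionally after
real-space masking; resolution is reported at the first crossing of
the threshold (0.143 for independent half-sets) with linear
interpolation between shells, Nyquist if the curve never crosses, and
the first shell if the curve starts below the threshold. The B-factor
is the Guinier slope of log spherically-averaged amplitude against
`s^2` (`B = -4 * slope`), fitted by least squares between
`max(10, 5 * pixel_size)` and 2.5x the pixel size by default (the fit
window is exposed because no universal choice exists); sharpening
multiplies amplitudes by `exp(+B/4 * s^2)`. Low-pass filtering uses a
cosine edge (3 Fourier pixels) ending at the cutoff, preserving DC
exactly. No detector MTF model is included: the estimator measures
only the map's own amplitude decay, so B-factors from detector-limited
experimental maps will exceed what it reports on synthetic data.

## The synthetic phantom and what it does (not) show

The generator emulates the scenario the method is hardest pressed by:
a large icosahedral shell carrying a small asymmetric subunit at a
sub-stoichiometric fraction of its threefold sites. Defaults define
the study conditions and are not tuned per run:

* shell: Gaussian blobs at the twelve fivefold directions, radius 130 Å,
  sigma 12 Å — a symmetric cage standing in for a capsid;
* subunit: main blob (sigma 10 Å, amplitude 1.5) centered on a
  threefold axis at radius 100 Å, the geometry of a polymerase bound
  under a capsid shell;
* satellite: a smaller off-axis blob (sigma 6 Å, amplitude 1.2, offset
  15 Å in the subunit frame), which makes the three degenerate axial
  orientations distinguishable — without it, orientation recovery
  would be unfalsifiable;
* occupancy 0.6, drawn independently per site; degenerate orientation
  drawn uniformly per occupied site;
* imaging: uniform orientations on SO(3), sub-pixel origins in ±2 px,
  defocus uniform in 1.0–3.0 µm, 300 kV, Cs 2 mm, amplitude contrast
  0.07; projections are *analytic* Gaussian line integrals (exact, and
  independent of the Fourier projector, so each can validate the
  other), CTF-applied, with white Gaussian noise scaled to a requested
  SNR defined against the recorded (post-CTF) clean image. An optional
  smooth random background field emulates unsubtractable structural
  noise such as internal genome density.

Pipeline-level tests run at 80-pixel particle images with 4.5 Å pixels
(a 360 Å field), 300 particles and 32-pixel sub-particle boxes —
sizes chosen so the full simulate–subtract–expand–extract–score–
reconstruct cycle completes in about a minute while every count,
distance and frequency in play remains at the scale of the real use
case.

What passing these tests shows: the bookkeeping (orbit sizes, record
counts, coordinate splitting, defocus heights), the pose conventions,
the subtraction identity, occupancy recovery at SNR 0.1, and the
ability of the reconstruction to recover a correctly oriented
asymmetric subunit that symmetric averaging smears. What it does not
show: performance under orientation misassignment (true poses are used
as the paper's workflow inherits refined poses), flexibility,
non-Gaussian noise, detector effects, or classification of real
heterogeneity — the classifier here is a deliberately simple
matched-filter stand-in for the 3D classification an external package
would perform.

## Occupancy scoring

Each bulk-subtracted sub-particle is scored by a matched filter: a
mean-centered Gaussian template of the subunit width, at the
sub-particle center, modulated by the record's own CTF, normalized,
and divided by the image noise level estimated outside the footprint.
Over empty sites this z-score is close to standard normal, which is
exploited directly: occupancy is estimated by EM on a two-component
mixture whose null component is anchored at zero mean. Anchoring
matters — with the populations overlapping at SNR 0.1 (separation
around 1.8 noise SDs), a free two-component fit is poorly identified
and biases the weight by ~10 percentage points, while the anchored fit
recovers the occupied fraction to within ~1 point. When the fitted
signal component is not separated from the null (below half a null SD)
the mixture is declared unidentifiable and the occupied fraction falls
back to the `z > 3` outlier rate, which keeps the all-empty case
honest. Labels are posterior > 1/2; the raw (un-normalized) matched
filter amplitude is also returned, as the z-score denominator is
meaningless on noise-free data.

On noise-free fixtures, clean separation of occupied from empty sites
additionally requires overlap filtering: without it, a neighbouring
occupied subunit can project into an empty site's box and mimic
occupancy. This is a faithful property of the data geometry, not an
artifact — it is precisely the overlap problem the filters exist for.

## Degenerate-orientation assignment in the recovery experiment

The end-to-end recovery test reconstructs occupied sub-particles with
the degenerate orientation assignment taken from the simulation
manifest. This isolates what the package claims to do (geometry,
extraction, reconstruction); resolving the 0/120/240-degree assignment
from data is the job of the external 3D classification step that this
package's scope explicitly delegates, exactly as the workflow hands
classified sub-particles back for reconstruction. The matched-filter
scorer demonstrates presence/absence classification; orientation
classification would require a template per degenerate copy and is out
of scope.

## Numerical choices

* Merge tolerance for coincident sites: 1 px. Sites of a point group
  are either identical to machine precision or separated by large
  angles, so the choice is uncritical across two orders of magnitude.
* Wiener constant: `1e-3 * mean(CTF^2 weight)`; exposed.
* Rounding: halves away from zero, so sub-pixel origins satisfy
  `|origin| <= 0.5` strictly.
* Soft edges: cosine, 3 px, on masks (optional) and low-pass filters;
  masks are binary by default as the subtraction oracle prefers exact
  support.
* Empty stacks, all-zero masks, all-covering masks, zero-length
  vectors, non-orthonormal rotations, unknown symmetry labels,
  beyond-Nyquist cutoffs and sub-minimal Guinier windows all raise
  classed errors rather than propagating nonsense.

## Known limitations

The reconstructor is a minimal, testable direct Fourier inversion; it
does not implement gold-standard masking corrections, phase
randomization, or maximum-likelihood refinement, and the package does
not re-refine sub-particle orientations. STAR output uses the legacy
single-block dialect (optics-group files are read, not written). MRC
support is mode 2 only. Helical and mirror symmetries are out of
scope.
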
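---
title: "Multi-symmetry refinement of a symmetry-mismatched decamer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-symmetry refinement of a symmetry-mismatched decamer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Molluscan hemocyanin decamers are cylinders whose wall — sixty functional
units (FUs) contributed by ten identical protomers — obeys D5 point-group
symmetry, while the inner collar of squid-type hemocyanin (ten FU-g and ten
FU-d* domains) is asymmetric. About three quarters of the particle density
is the symmetric wall. During single-particle projection matching the wall
dominates the cross-correlation, so the azimuthal assignment of each
particle is nearly degenerate across the ten wall-equivalent frames;
averaged over many particles the collar washes out into an artificial D5
arrangement with twice the number of apparent density sites (40 instead of
20). `symref` implements, at desk scale, the refinement strategy that
resolves this: between refinement iterations the reference volume is
*adjusted* — the wall region is replaced by its D5-symmetrized version and
the collar region is multiplied by a weighting factor (default 1.5) — so
that the wall contributes a clean, unbiased signal while the collar, the
only asymmetric part, is up-weighted in the match.

## The phantom

All tests run on a parametric phantom (`phantom_spec()`,
`build_decamer_truth()`, `render_map()`): Gaussian blobs (sigma 2.5 voxels)
on a 64^3 grid at 3 A/voxel. The wall is the D5 orbit of a three-blob
asymmetric unit (30 blobs at radius 22). The collar encodes the decamer's
architecture rather than metric fidelity to any deposited map:

* five FU-g dimers at azimuths 72k degrees, each with a polar and an
  equatorial FU-g, occupying the northern or southern hemisphere of the
  lumen according to the pattern N,S,N,S,N;
* a southern dimer is the *two-fold image* of a northern one — the local
  azimuth offset and z are both negated. This detail matters: it makes
  every FU class occupy half of a single D5 orbit, which is why expanding
  the 20 collar centroids over D5 and clustering them at 1-voxel tolerance
  yields exactly 40 distinct sites (the apparent site count of a
  symmetry-averaged collar);
* the ten FU-d* fill the voids on the hemisphere opposite each dimer,
  azimuthally between dimers (offsets +30 and +42 degrees, z levels 13 and
  7 voxels). The offsets were chosen so that all 40 expanded sites stay
  distinct at 1-voxel tolerance.

Because five dimers alternate on a ring of odd length, two same-hemisphere
dimers are forced to be adjacent — the symmetry break
(`min_adjacent_equal()` proves the minimum of one adjacent equal pair by
exhaustive enumeration). `assemble_decamer()` maps any valid pattern onto
the protomer conformer labelling: four conformer-1 and four conformer-2
homodimers alternating 1-2-1-2, and the conformer-3/4 heterodimer closing
the ring at the break (protomers 09 and 10).

The simulator (`simulate_particles()`) projects the phantom at orientations
uniform over SO(3) (a side-view-rich mode is available), applies uniform
in-plane shifts, optionally a phase-contrast CTF (off by default — CTF
estimation is out of scope), and adds white Gaussian noise with variance =
signal variance / SNR. What the phantom does *not* emulate: atomic detail,
ice and amplitude contrast, beam-induced motion, defocus variation,
structural heterogeneity. Passing tests therefore demonstrate the
*geometry* of the method — degeneracy, rescue, readout — not performance on
real micrographs.

## Conventions

One orientation convention is used everywhere: intrinsic ZYZ Euler angles
(`R = Rz(phi) Ry(theta) Rz(psi)`, degrees), projection along +z after
sampling the map at `R v`, so a Cn-symmetric map gives identical
projections at `phi` and `phi + 360/n`. The box centre is the voxel with
0-based index `N/2`; rotations use trilinear interpolation with zeros
outside the box; real-space projection integrates over the inscribed
sphere. The n-fold axis is z; the first two-fold axis of Dn is +x.

## The refinement loop

`refine()` is gold-standard: half-sets split by particle parity, refined
against their own references, never mixed before the final FSC. Per
iteration: exhaustive or local orientation assignment (normalized
cross-correlation over a template bank and integer shifts, evaluated in the
Fourier band `|k| <= N/4` where the blob references carry their power),
direct Fourier reconstruction (central-slice insertion with trilinear
gridding; weights regularized by 1e-3 of the maximum), and — during the
first `active_rounds` iterations — the reference adjustment.

The angular search schedule is a strictly decreasing sequence of steps
(default 30, 25, 20, 15, 12, 10 degrees). Iteration 1 is a full global
search. While the adjustment is active the local search is
*symmetry-relaxed*: candidate orientations lie within twice the current
step of any D5-equivalent of the previous assignment, because the
symmetrized wall makes those ten frames genuine competing local optima that
a particle must be allowed to revisit. After the adjustment rounds the
search is strictly local, mirroring the final local refinements of the
original protocol. The exact search schedule of the original refinement
package is not published; this coarse-to-fine grid is a documented
stand-in.

Template banks sample (phi, theta) quasi-uniformly (area-weighted phi
counts per theta ring) with uniform psi. Inside `refine()` only the
templates reachable by the current candidate sets are rendered, one exact
projection per viewing direction plus in-plane rotations for the psi
copies; `make_template_bank()` remains the exact reference implementation.

## Registration and the flip near-degeneracy

A refined map legitimately sits in any of the ten wall-equivalent frames,
so all truth comparisons and the half-map combination first register over
the D5 operators. A subtlety discovered while validating: the collar of
any valid alternating pattern shares 8 of its 10 FU-g sites with one of its
flip images, so masked-correlation registration between two blurry maps is
nearly degenerate between the identity and that flip — and picking the flip
averages the break region away even when both half-maps individually
resolve it. `combine_half_maps()` therefore registers each half by its own
*canonical collar readout* (the operator that brings its hemisphere pattern
to N,S,N,S,N — the symmetry break is the fiducial), falling back to
correlation registration when a readout is undetermined (e.g. for
symmetrized controls).

`collar_readout()` integrates density in northern vs southern windows
(radius 3 voxels) at the five dimer loci for each registration operator and
labels each locus by its dominant hemisphere; a locus with contrast
`|N - S| / (N + S)` below 0.05 is undetermined. The floor is chosen so that
a D5-symmetrized collar is undetermined at every locus by construction.

## The demonstration experiment

`run_demo()` reproduces the methodological claim end to end at the study
conditions: 2000 particles at SNR 0.1, shifts up to 2 voxels, six
iterations with the adjustment active for the first three, collar weight
1.5. The adjusted arm starts from an ab-initio-like reference — the phantom
low-passed to 25 A (`lowpass()`), the realistic resolution of a de novo
initial model: correct asymmetric topology, no detail. The control arm
starts from the collar-D5-symmetrized version of the same map (the
artificial-D5 state a symmetry-imposed reconstruction produces) and never
adjusts. The adjusted run recovers the full N,S,N,S,N hemisphere pattern
with per-locus contrast far above the floor and a higher D5-registered
collar correlation with ground truth than the control, across seeds.

```{r}
library(symref)
summary <- run_demo(demo_config(), out_dir = "demo_out")
```

Problem sizes throughout the package's test suite were chosen to keep a
full run at desk scale: 64^3 grids, up to 2000 particles, three seeds for
the stochastic end-to-end comparison.

## Numerical choices and degenerate inputs

* Trilinear interpolation (rotation, gridding) loses about 1% normalized
  RMS per pass on sigma-2.5-voxel Gaussians; symmetrization and reference
  adjustment are therefore idempotent only to ~2%, and fixed-point tests
  use that tolerance.
* Region masks form a partition of unity (collar + wall = outer exactly,
  raised-cosine radial split at the collar/wall mid-radius, binary outer
  mask), so recombination conserves density and repeated adjustment does
  not erode edges.
* FSC uses shells of one Fourier voxel; `resolution_at()` interpolates the
  crossing linearly and returns Nyquist for curves that never cross. The
  FSC null sd in shell s is ~(4 pi s^2)^(-1/2), so null-hypothesis
  assertions are made from shell 8 outward where 0.1 is a ~3-sigma bound.
* Orientation ties in assignment resolve to the lowest bank index;
  reconstruction weights are strictly positive thanks to the epsilon
  regularizer; empty masks, empty stacks, non-cubic volumes and non-squid
  ring patterns raise errors rather than propagating.
* `simulate_particles()` measures signal variance per image, so the
  realized SNR matches the request to within sampling error.

## Limitations

No CTF correction in reconstruction, no 3D classification or variability
analysis, no local-resolution estimation or filtering, no icosahedral or
helical groups, no handedness search (phantom and reference share hand by
construction). The conformer-RMSD operation (`superpose_rmsd()`) is fully
implemented and tested on synthetic models; applying it to a deposited
decamer model requires the user to supply the chain-to-protomer and
FU-residue-range mapping for that entry.
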
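---
title: "Along-tract analysis of the anterior optic pathway: methods notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Along-tract analysis of the anterior optic pathway: methods notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette documents the models, conventions and design choices behind
`opticpath`, in the spirit of a methods appendix: what each stage assumes,
which knobs matter, what the synthetic phantom does and does not emulate,
and where the design was genuinely open.

## The analysis model

The anterior optic pathway runs from the orbit through the optic chiasm to
the lateral geniculate nucleus (LGN). Roughly half of the fibres decussate
at the chiasm, so four bundles are tracked per subject: crossing and
noncrossing fibres from each LGN. Because the pregeniculate pathway runs
mainly anterior–posterior (AP), all along-tract statistics are computed
over coronal slices, i.e. planes of constant index along the grid's AP
axis. The AP axis is a property of `voxel_grid`, never a hard-coded
convention.

### Compartment fractions

Multi-shell multi-tissue spherical deconvolution yields three raw
compartment intensities per voxel: anisotropic "WM-like", restricted
isotropic "GM-like" and free-diffusion "CSF-like". Voxels with little or
no MR signal (bone, air, outside the head) would otherwise normalize
noise, so a fourth *background* component absorbs the shortfall below a
total-intensity floor τ:

* `bg_raw = max(0, τ − (WM + GM + CSF))`,
* every component is divided by `max(WM + GM + CSF, τ)`.

At or above the floor this is plain division by the total; below it the
background fills the voxel to exactly τ. The fill rule is a package
choice — the convention was selected because it is the simplest one that
makes the fractions continuous in the raw intensities and guarantees an
exact unit sum everywhere. τ defaults to 0.075 in the units of the
deconvolution output; whether that scale is raw or b0-normalized
amplitude is an assumption the configuration documents rather than
resolves. The "total absolute intensity" is computed on inputs validated
to be non-negative, so the absolute value is a defensive no-op.

### Tensor scalars and validity

Tensors are fitted by unweighted log-linear least squares: the b = 0
volumes are averaged into S₀ and log(S/S₀) is regressed on the six tensor
design coefficients. This estimator is exact at zero noise (the test
suite checks recovery of random SPD tensors to 1e-9), which is what makes
the phantom's closed-loop checks meaningful; weighted variants would add
options without changing any exact property. Non-positive signals are
clamped to 1e-10 before the log. Negative eigenvalues from noisy fits are
*not* clipped: the downstream validity mask (FA in the open interval
(0, 1), MD in (0, 0.005) mm²·s⁻¹) excludes the affected voxels from mean
computation, which matches an exclusion-based rather than
projection-based philosophy. The MD ceiling is interpreted in mm²·s⁻¹:
free water at body temperature is ≈0.003 mm²·s⁻¹, so 0.005 is a generous
physical bound. All four shells (b = 0, 300, 1000, 2000 s·mm⁻²) enter the
fit by default.

### Masking

A streamline visits a voxel at most once regardless of how often it
re-enters (binary per-streamline visitation, as in track-density
imaging); polylines are resampled at half-voxel arclength steps, and a
point on a voxel boundary belongs to the voxel with the larger index
(half-open cells). The slicewise threshold keeps voxels with at least 40 %
of the slice maximum count — ties at exactly 40 % are kept, because the
exclusion rule is "fewer than 40 %".

The background exclusion mask removes voxels with nBG ≥ t. The refinement
loop starts at t = 0.15 and steps by 0.01 until the mask has a single
26-connected component joining the LGN seed ROI to the postorbital
waypoint ROI. The loop's default direction is *decreasing*, following the
published wording, even though decreasing the nBG cutoff enlarges the
excluded set and therefore cannot reconnect a tract severed by
background; whether that wording meant "reduce the threshold" or "reduce
the excluded volume" is ambiguous, so the loop tries the opposite
direction once before failing with a message naming the subject/side.
Neither reading is asserted as the original intent. 26-connectivity was
chosen because corner-touching voxels of a thin oblique tract should
count as connected; the test suite pins the component logic against an
independent breadth-first-search oracle.

When whole-pathway tracking fails, pre- and postchiasmatic masks are
unioned; the merged landmark metadata take the seed from the
postchiasmatic piece and the waypoint from the prechiasmatic piece.

### Segments, ROIs, statistics

Ten segments tile chiasm→LGN evenly and seven tile orbit→chiasm, with
per-subject lengths (≈4 mm for a ≈68 mm pathway); slices are assigned by
centre coordinate, and the terminal segments absorb one voxel of slack
because streamline endpoints may legitimately sit within one voxel of the
landmark planes. Segment ids run 1 (at the LGN) to 17 (at the orbit).
Macroscopic ROIs: optic tract = segments 1–9 per side, chiasm = the two
juxtachiasmatic segments pooled bilaterally into a single ROI, optic
nerve = segments 12–17 per side. Pooling both juxtachiasmatic segments
was chosen so the chiasm is one bilateral ROI, matching how the five-ROI
summary family (5 variables × 5 ROIs = 25 tests) is constructed.

Segment and ROI values are means of slice means weighted by in-mask voxel
count, so they equal plain voxelwise means over the segment — this makes
them invariant to splitting a slice into pseudo-slices (a property the
suite tests). Welch's *t* with Welch–Satterthwaite degrees of freedom is
used throughout, two-sided; the Hochberg step-up procedure controls the
familywise error within each *declared* family, whose size is recorded in
the output because segment-level and ROI-level families are corrected
separately. Missing segments are dropped pairwise per test with per-test
group sizes reported.

The decussation fraction is computed from the *weighted fibre volume*,
interpreted as the voxelwise sum of visitation counts — the simplest
volume measure that weights voxels by local fibre density. Whether Dice
overlap should be computed on thresholded masks or raw density supports
is not specified by the procedure being reproduced; the package defaults
to thresholded masks and exposes the choice.

Clinical correlations use Pearson's r with uncorrected two-sided
p-values, flagged at the exploratory 0.05 threshold. Prechiasmatic ROIs
pair with the ipsilateral eye; chiasmatic and postchiasmatic ROIs pair
with eyes grouped by affected order, and their RNFL covariate can use the
mean of the two contributing lateral quadrants (right temporal + left
nasal for the right side, mirrored on the left). The ipsilateral
convention is applied to the optic-nerve ROIs as stated in the source
procedure; its anatomical tension for postchiasmatic structures is
flagged in the output mapping labels rather than silently resolved.

## The phantom: what it emulates

`make_geometry` builds four C¹ centerlines on a default 96×96×60 grid of
2 mm isotropic voxels: the tube pair of each side converges from ±14 mm
(LGN) and ±16 mm (orbit) lateral offsets to ±0.9 mm at the chiasm, and
crossing bundles blend through the midline over a ±3 mm window. The
left/right noncrossing centerlines come within one voxel of each other
only at the chiasm plane — this is the property that defines the chiasm
slice, and the offsets were chosen once to satisfy it at 2 mm resolution.
The default decussation fraction is 0.53 rather than 0.50 so that
recovery tests can tell the estimate from the idealized textbook value;
reported cohort values span roughly 49–54 %.

Streamlines add smooth low-order random jitter (default pointwise sd
1.2 mm, clamped at 2 sd) in the plane perpendicular to the local tangent,
which keeps arclength parametrization stable and endpoints within one
voxel of the landmark planes. Volumes draw one subject-level effect per
ROI and variable from the bundled published group summaries N(m, sd) and
add small per-segment wiggle (0.25 × the ROI sd), so cohort-level ROI
statistics reproduce the published means and sds while segments still
vary within subject. Segments are conditionally independent given the
subject effect: no spatial covariance model is imposed, because none is
published; this is configurable in principle but deliberately not a
default. Tensors are axially symmetric with the long axis along AP,
solving λ₁ = MD(1+2f), λ⊥ = MD(1−f) with f = FA/√(3−2FA²) so the target
FA and MD are met exactly; DWI follows S = S₀·exp(−b·gᵀDg) with Rician
noise (sd 0 supported for exact tests). Outside-tube voxels get total
tissue intensity 0.045 < τ so the background rule is always exercised.

One data caveat: the bundled summary profiles follow their source table's
column labels verbatim, although the nGM and nWM labels there appear
transposed relative to the accompanying narrative (which describes
patients as having an *elevated* GM-like and *reduced* WM-like fraction).
The package treats the labels as printed; nothing in the pipeline depends
on which of the two names is attached to which column.

Clinical covariates per subject and eye use the published cohort
summaries (visual acuity 1.69 logMAR, sd 0.34/0.36; average RNFL
76.2/74.9 µm, sd ≈22 µm; disease duration 332/315 days). A target
correlation r between optic-nerve nWM and visual acuity is planted by the
z-construction `z_va = r·z_nwm + √(1−r²)·ε` (RNFL gets −r), so |r| = 1 is
exactly linear and r is the population value otherwise.

What the phantom does **not** emulate: curved or oblique pathway
courses (centerlines stay in one axial plane), partial-volume mixing at
tube boundaries, spatially correlated noise, susceptibility or motion
artefacts, fibre dispersion or crossing-fibre microstructure within a
voxel, and any spatial covariance of the along-tract profiles. A green
test therefore establishes that the *post-processing* is correct under
the stated statistical structure — not that the upstream tractography or
deconvolution would behave on real data.

## Numerical choices

* Voxel indices are 0-based everywhere in public structures (matching the
  NIfTI convention); world↔voxel mapping goes through the grid affine.
* The slicewise threshold and Dice are exact integer/rational
  computations; unit-sum conservation of fractions is asserted to 1e-9.
* `welch_from_summary` refuses n < 2 and zero variance in both groups;
  `hochberg` breaks ties by stable original order; empty p-vectors give
  empty flags.
* Degenerate inputs fail loudly: empty masks, both-empty Dice, both-empty
  density sums (NA with a warning), landmark ROIs that are not disjoint,
  or a chiasm slice not strictly between seed and waypoint.
* All stochastic operations are pure functions of an integer seed;
  identical seeds give bitwise-identical streamlines.

## Known limitations

* The NIfTI-1 reader supports axis-aligned affines only — sufficient for
  the pipeline's own files and standard preprocessed data, not for
  oblique acquisitions.
* Tensor fitting is plain OLS; no RESTORE-style robust variants.
* The refinement loop explores a single threshold parameter; it does not
  jointly optimize the slicewise fraction.
* Correlation analyses are exploratory by construction: uncorrected
  p-values with a pragmatic 0.05 flag, as in the procedure reproduced.
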
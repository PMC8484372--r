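---
title: "Methods: landmark-driven mandibular volumetry and its simulators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: landmark-driven mandibular volumetry and its simulators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`mandivol` measures how much of a mandible's volume sits in each anatomical
unit — condyle, coronoid process, ramus, hemibody — per side, from a binary
mandible mask and a set of named cephalometric landmarks. The target
application is condylar and ramal growth deficit in juvenile idiopathic
arthritis (JIA) with temporomandibular-joint involvement, where the clinical
question is which unit carries the deficit on an affected side. This
vignette documents the model, its conventions, the two simulators that
stand in for patient data, and the choices made where the procedure is
genuinely underdetermined.

## The reference frame and the five planes

All geometry lives in LPS world millimetres (+x left, +y posterior,
+z superior; DICOM convention). The frame is anchored at Sella:

* the **mid-sagittal plane** passes through Sella, Nasion and Basion. Its
  normal is oriented toward the subject's left as the direction of
  `(N − S) × (Ba − S)`; with the normal anatomical arrangement (Nasion
  anterior, Basion posterior-inferior) this is unambiguous.
* the **horizontal plane** passes through Sella: the plane through S and N
  normal to the mid-sagittal plane, tilted 6° about the mid-sagittal normal
  so that its anterior (Nasion) end moves inferiorly. The 6° value is the
  classical correction that brings the S–N direction close to a true
  clinical horizontal; it is a parameter (`tilt_deg`) of
  `build_reference_frame()`.
* vertical (coronal) and sagittal reference planes complete a right-handed
  orthonormal triad (anterior, left, superior).

From the mandibular landmarks, `build_mandibular_planes()` constructs per
side: the **Condylion–Gonion plane** (through Co and Go, perpendicular to
the mid-sagittal plane — the 2D ramus line of lateral cephalometry swept
laterally); the **C-point plane** (through the sigmoid-notch C-point,
parallel to the horizontal plane); the shared **Gonion–Menton** and
**median** planes; and the **mandibular-angle plane**, the bisector of the
Condylion–Gonion and Gonion–Menton planes through the Gonion.

Two constructions deserve comment because the verbal definitions
underdetermine them:

* *Which reference plane the Condylion–Gonion plane is perpendicular to.*
  We use the mid-sagittal plane. This reproduces the 2D ramus line in 3D
  and keeps the plane well-defined for any ramus inclination. The
  alternative readings (horizontal or vertical reference planes) would make
  the plane degenerate for nearly-vertical rami.
* *Which bisector the mandibular-angle plane is.* Two planes bisect a pair
  of intersecting planes, and both make equal dihedral angles with the
  parents. Summing the parents' normals after orienting them to agree
  yields the *external* bisector here — a plane that would put the entire
  mandibular body on the Condylion side, so the downstream classification
  would label the body as ramus. The anatomically meaningful plane is the
  one containing the gonial-angle bisector line; `mandivol` selects it as
  the bisector that separates Condylion from Menton, oriented so Condylion
  has positive signed distance. With Condylion placed on a ray at gonial
  angle γ from the mandibular base, this plane makes exactly γ/2 with each
  parent (a property the tests assert). `bisecting_plane()` itself keeps
  the plain summed-normal default for generic use; the selection rule is
  applied by `build_mandibular_planes()` via its `separate_point`
  argument. The alternative parent pair (ramus line vs C-point plane) is
  available as `bisector_parents = "ramus_cpoint"`.

Orientation conventions are fixed once so every half-space label is
deterministic: median normal toward the left, Gonion–Menton and C-point
normals superior, Condylion–Gonion normal anterior-superior,
mandibular-angle normal with Condylion positive.

## The voxel partition

Voxels are classified at their centre points; "above" a plane means
*strictly positive* signed distance; distance-zero ties fall to the lower
label, except the median-plane tie, which goes Left. One fixed rule makes
the partition reproducible bit for bit, which is what allows the test suite
to demand *exact* agreement with an independent brute-force classifier.

The pipeline order is: intensity threshold (grayscale input only) →
internal-cavity fill → crown removal → partition → volumes.

* **Cavity fill.** Background components not 6-connected to the grid
  boundary become foreground (foreground connectivity is 26 — the standard
  dual pair). The mandibular canal opens at foramina in real data, so a
  configurable morphological closing (ellipsoidal element, default radius
  1.0 mm, spacing-aware) can seal openings first; radius 0 performs a plain
  hole fill. On the phantom the canal void is fully enclosed, so the
  phantom-based tests run with radius 0, where the fill restores the
  reference solid exactly.
* **Crown removal.** Clinical crowns are removed by clipping plane(s)
  supplied by the caller (single plane or per-side pair; the per-tooth
  tailored cutting surfaces used in clinical software are treated as this
  clipping-surface abstraction). Voxels with strictly positive signed
  distance to the applicable plane are removed; voxels exactly on the
  plane are retained.
* **Condyle vs coronoid.** Everything strictly above the C-point plane is
  a condyle candidate; 26-connected components are computed and the
  component containing (or nearest to) Condylion is the condyle, the rest
  the coronoid. If only one component exists, everything is assigned to the
  condyle — a fused condyle/coronoid is indistinguishable from an absent
  coronoid at this level, which is why the phantom maintains a sigmoid
  notch gap.
* **Hemimandible.** Defined as *all* foreground on a side of the median
  plane — condyle + coronoid + ramus + hemibody, an exact voxel-count
  identity. (The source tables are internally inconsistent about whether
  the coronoid is included; the identity definition is the only one under
  which the printed additivity can hold at all.)

## The phantom and what it does (not) emulate

`generate_phantom()` rasterises a constructive solid: a U-shaped body band,
sheared rami at the gonial angle, a condylar ellipsoid per side centred
exactly on the sigmoid-notch (C-point) plane, a coronoid block, anterior
incisal crown pegs, and an enclosed canal void. Landmarks are derived
analytically from the construction (e.g. Condylion is the ellipsoid's
superior pole; the skull-base triple is placed so the tilted horizontal
plane is a true horizontal). Ground truth is computed by an independent
per-voxel classifier written in the phantom module — inline signed-distance
arithmetic plus constructive-solid membership for the condyle/coronoid
distinction — never by the segmentation module, so accuracy tests are not
self-referential.

Deliberate design choices:

* The ellipsoid centre lies on the C-point plane, so the condyle segment is
  exactly the upper half-ellipsoid and isotropic scaling by `s_condyle`
  scales its volume by exactly `s³` — a sharp check for the
  unilateral-damage emulation. `s_ramus` scales the supra-body ramus
  height, lowering the notch on that side.
* The sigmoid notch is a slot: the ramus top sits `notch_drop` (default
  2.05 mm) *below* the C-point plane. A flat notch floor at the plane
  level would let any downward landmark jitter merge condyle and coronoid
  into one component; the slot keeps the split stable for plane errors up
  to the slot depth, mirroring the saddle shape of a real notch.
* Crown pegs protrude anteriorly from the symphyseal face and the clip
  plane is that face. A single horizontal "alveolar" plane cannot model
  crown removal on anything mandible-shaped (the rami rise above any such
  plane), so the phantom realises the clipping abstraction where a single
  plane is exact: clipping removes precisely the protruding crown voxels.
* Default spacing is 0.4 mm (typical CBCT); boundary positions are chosen
  off the voxel lattice at 0.8/0.4/0.2 mm so no voxel centre falls exactly
  on a primitive boundary, keeping voxel counts stable to floating-point
  noise. Grids are x-symmetric with even sample counts, so lattice-aligned
  mirroring is exact.

What the phantom does **not** emulate: cortical/trabecular texture, beam
hardening and scatter, fossa anatomy, curved tooth rows, or segmentation
error of real CBCT. Passing the exactness tests therefore demonstrates the
*partition* is correct given a mask and landmarks; it says nothing about
mask quality on real scans.

## The cohort simulator

`default_calibration()` transcribes the published per-group distributions
(mm³, mean ± SD) of hemimandible, condyle, ramus, hemibody and total
mandible for the three study arms — unilateral JIA (affected and unaffected
sides, n = 29), bilateral JIA (n = 48) and controls (n = 25) — plus the
demographic covariates. A `"recruited"` preset carries the alternative
40/48/45 sizes, which the source reports inconsistently with its tables.
For the bilateral and control arms the published values describe
per-subject side averages; they are applied as per-side marginals.

`simulate_cohort()` draws the two sides of each segment from a bivariate
normal with inter-side correlation ρ (default 0.8; the source reports no
correlation, and 0.8 gives paired side contrasts of realistic strength),
resampling while any component is non-positive. Two details matter:

* **Marginal calibration.** Each volumetric variable is calibrated
  independently; additivity across variables is *not* enforced, because the
  printed table itself violates it (the printed control total mandible is
  not twice the printed control hemimandible). Enforcing additivity would
  make it impossible to recover every printed cell.
* **Truncation-aware locations.** Resampling at zero inflates the mean of
  a normal by `s·φ(m/s)/Φ(m/s)` (plus a joint-positivity term for the
  correlated pair). For mean/SD ratios above 4.5 this is below 1e-4 SD and
  ignored; below that — the bilateral condyle's printed ratio is 2.6, where
  the bias reaches ~1% — the underlying location is moment-matched by
  quadrature so the truncated draw has exactly the published mean.

Averaging group means over 200 simulated cohorts at the published sizes
reproduces each printed mean within three standard errors of the
mean-of-means (the quantity `scripts/acceptance.R` recomputes). One
published pattern is *not* reproduced at that strength: the ordering
control > unilateral > bilateral of total mandibular volume holds in about
91% of independently simulated replicates, not more than 95% — at the
printed means, SDs and group sizes the ordering's per-replicate probability
is analytically ≈ 0.91 (z-scores 1.80 and 1.64 for the two inequalities),
so a >95% rate is not attainable without larger groups or artificially
coupling the arms' random draws.

## The statistical battery

All tests are two-tailed at α = 0.05 by default.

* **Normality gate.** Shapiro–Wilk per analysis group; a failure warns but
  the pipeline stays parametric, as the emulated protocol did.
* **t tests.** Pooled-variance independent t by default (Welch by flag);
  paired t for within-subject side contrasts. The source text applied
  independent t tests to side comparisons, which ignores the within-subject
  pairing; the report uses the paired form and this caveat is the one
  deliberate deviation from the verbal protocol.
* **ANOVA.** One-way, with a sufficient-statistics variant
  (`summary_anova()`) that is algebraically identical to the raw
  computation (asserted to 1e-10). The four groups per segment are
  unilateral-affected, unilateral-unaffected, bilateral (per-subject side
  average) and control (side average) — the affected/unaffected sides enter
  as separate groups despite their within-subject dependence, reproducing
  the emulated analysis rather than correcting it.
* **Post hoc.** "Tukey's test with Bonferroni's correction" is
  contradictory as written; both are implemented. Bonferroni-adjusted
  pairwise pooled-t (error MS from the full ANOVA, p × k(k−1)/2 capped at
  1) is the default, matching the published pairwise-comparison tables;
  the studentized-range (Tukey) adjustment is available by flag.
* **Percentage differences** use `100·(ref − other)/ref` with the larger
  group mean as reference. The published difference table is internally
  inconsistent about its denominator, so this convention is documented
  rather than fitted to it.
* **Reliability.** ICC from two-way ANOVA mean squares; the model is
  unspecified in the source, so the default is ICC(2,1) (two-way random,
  single rater, absolute agreement), with ICC(3,1) available; the model
  token is recorded in every report. Dahlberg error is
  `sqrt(Σd²/2n)`.
* **Sample size.** Smallest integer n per group whose two-sample
  noncentral-t power reaches the target. With the reference condylar
  values (1007.82 ± 384.27 vs 1424.69 ± 417.64, α = 0.05, power 0.95) the
  pooled-SD convention gives 26 per group, single-group SD conventions 24
  and 28; the published figure of 23 is not reproduced under any of these,
  so the convention of the original power analysis appears unrecoverable.
  All three `sd_mode`s are exposed; none is tuned to the published number.

## Problem sizes and numerical tolerances

The test suite exercises: 20 randomized phantoms at 0.8 mm spacing (exact
oracle agreement is spacing-independent, so the coarse grid keeps the
property suite fast), the default phantom at 0.4 mm and 0.2 mm for
end-to-end accuracy and resolution consistency, 30 landmark-jitter
replicates at σ = 0.5 mm for reliability realism, 1000-replicate null
simulations for type-I calibration, and 200-replicate cohort batches for
calibration recovery. Geometric tolerances are 1e-9 for unit-length and
orthogonality, 1e-6 mm for plane offsets under rigid motion, and 1e-3 mm
for anchor-on-plane preconditions (landmarks are digitised at ~0.4 mm voxel
resolution). Voxel-count comparisons are exact integer equality.

Resolution consistency (volume change < 2% when the voxel size is halved
from 0.4 to 0.2 mm) is asserted for the segments the analysis reports —
condyle, ramus, hemibody, hemimandible, total. The coronoid, which the
analysis excludes, is a small block whose worst-case lattice quantisation
can exceed that bound at coarse spacing.

## Known limitations

* The partition assumes planar cuts; curved cutting surfaces (and automatic
  landmark detection) are out of scope.
* The condyle/coronoid component split degrades to "all condyle" with a
  warning on fused anatomy.
* Real-CBCT intensity calibration (HU thresholds, artifact handling) is out
  of scope; thresholds are in the synthetic two-level convention.
* The cohort simulator reproduces the published *marginal* distributions;
  it does not model within-subject additivity, growth, or covariate-volume
  dependence, and inter-side correlation is an assumption (ρ = 0.8), not an
  estimate.
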
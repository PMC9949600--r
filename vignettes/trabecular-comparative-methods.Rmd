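---
title: "Trabecular architecture morphometry and comparative scaling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular architecture morphometry and comparative scaling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Trabecular bone — the spongy lattice inside vertebral centra and long-bone
ends — remodels under load, so its architecture carries a signal of body
size, locomotor ecology, and evolutionary history. `trabcomp` implements the
full quantitative chain needed to study that signal in a comparative sample
of vertebrae: binarized micro-CT stacks are reduced to seven microstructure
metrics plus two whole-bone measures, and those metrics are carried through
allometric, phylogenetic and discriminant analyses. Because real museum scan
sets are large and rarely redistributable, the package also ships a
synthetic-data module that generates phantoms and comparative datasets with
known ground truth; every stage of the pipeline is validated against those
truths.

The motivating study system is the extant xenarthran radiation (armadillos,
anteaters, sloths): ten species spanning roughly 85 g to 40 kg in which
locomotor ecology and phylogeny are almost perfectly confounded — all
armadillos scratch-dig, all extant sloths are suspensorial arborealists, and
all hook-and-pull diggers are anteaters (the silky anteater, an arborealist,
is the single exception). The bundled study design reproduces that structure
so the package can demonstrate, on data with known generating parameters,
how phylogenetic and non-phylogenetic methods partition variance when the
two are confounded.

# Image-analysis stage

## Containers and conventions

A `binary_volume` is a 3D logical array plus an isotropic voxel size in µm.
The third index runs cranio-caudally (one transverse slice per index); within
a slice the first index is dorso-ventral and the second medio-lateral. All
indices are 1-based R conventions. Stacks round-trip to multi-page 8-bit TIFF
(0 background / 255 bone) with a JSON sidecar carrying the voxel size, since
baseline TIFF has no reliable 3D voxel-size slot.

Binarization is threshold-inclusive (`intensity >= t` is bone), matching the
127–255 binary convention of the fabric-analysis software lineage this
package follows; Otsu's between-class-variance criterion is available when no
operator threshold exists.

## The VOI protocol

The analysis region inside a vertebra is standardized in three steps:

1. **Waist finding.** The centrum region of each slice (operator-supplied, or
   by default the smallest bone-bounded region containing the bone centroid —
   the neural arch, when closed, bounds a larger region around it) is scanned
   for the transverse slice with the lexicographically smallest
   (dorso-ventral, medio-lateral) extent. Ties go to the slice nearest the
   axial midpoint, so a constant-radius tube yields its middle slice.
2. **Inscribed square.** Within the waist slice, the trabecular interior is
   the part of the centrum deeper (by 2D Euclidean distance to the centrum
   exterior) than the cortical shell; shell depth is estimated from the
   shallowest point of the trabecular space itself. The largest axis-aligned
   square of interior pixels is found by the classic all-ones-square dynamic
   program, then extended symmetrically in both cranio-caudal directions
   while every included slice still contains it. We enforce the containment
   test on *every* extended slice, the stricter reading of the protocol.
3. **Inscribed sphere.** The largest sphere centered at the prism centroid
   (radius = half the smaller of square side and cranio-caudal extent)
   becomes the region of interest, eliminating the prism's edge and corner
   artifacts.

## Microstructure metrics

* **BV.TV** — bone voxels / all voxels with centers inside the sphere.
* **MIL fabric and DA.** For each direction of a Fibonacci-spiral hemisphere
  set (default 2049 directions; desk-scale analyses use 25–129, which is
  sufficient for a rank-2 tensor fit), a parallel grid of test lines (default
  spacing 2 voxels, sampling step 0.5 voxel) is cast through the sphere. The
  mean intercept length is total test-line length divided by half the number
  of bone/background crossings; bone chords touching the sphere boundary are
  omitted from the run bookkeeping (side-intersecting paths excluded). The
  fabric tensor is the least-squares fit of `1/MIL(w)^2 = w'Aw`; the degree
  of anisotropy is the ratio of the longest to shortest MIL-ellipsoid
  semi-axis, so DA ≥ 1 with 1 = isotropic. Directions with no crossings are
  dropped with a warning (for perfect plates, in-plane directions never cross
  an interface); eigenvalues are floored at 1e-6 of the largest, which caps
  DA near 1000 for perfectly layered structures.
* **SLD.** From 2000 (default; tests use a few hundred) seeded points sampled
  uniformly among bone voxels in the sphere, the bone intercept through the
  point is marched in both senses along each direction until leaving bone or
  the sphere. The star-length orientation tensor's extreme-eigenvalue ratio
  summarizes anisotropy. Sampling is seeded and reproducible; if fewer bone
  voxels than points exist, sampling is with replacement (warned).
* **Tb.Th.** The headline estimator is local (inscribed-sphere) thickness:
  the squared Euclidean distance transform is computed separably with
  offset-bounded envelope passes (exact, and cheap because trabecular
  structures are thin), then spheres are painted in decreasing radius order
  with the standard dominance shortcut; a bone voxel's thickness is the
  diameter of the largest sphere containing it. Radii are binned to half
  voxels for the vectorized dilation, a sub-voxel approximation. The
  plate-model estimator `2*BV/BS` (surface from exposed voxel faces) is also
  reported because different software lineages disagree systematically, and
  the offset between the two estimators is itself of interest.
* **Tb.N** — crossings/2 per mm of test line, averaged over the direction
  set; the plate-model value `(BV/TV)/Tb.Th` is reported alongside.
* **Connectivity and Conn.D.** After purification (keep the largest
  26-connected bone component, fill cavities = non-maximal 6-connected
  background components), the Euler characteristic is computed exactly by the
  vertex − edge + face − cell count of the voxel cubical complex;
  connectivity is `1 − χ` and Conn.D divides by the ROI volume in mm³.
  Negative connectivity after purification indicates topological noise and is
  clamped to zero with a flag.
* **QC.** Relative resolution = Tb.Th / voxel size (px per trabecula). A
  result passes when connectivity ≥ 40 and relative resolution ≥ 2.5, both
  boundary-inclusive; boundary sitters are flagged so a stricter reading can
  exclude them downstream.

## Whole-vertebra morphometry

Global compactness (GC) and cross-sectional area (CSA) are measured on
slices where the vertebral foramen is completely surrounded by bone. The
literal flood-fill rule (any enclosed background component) cannot
distinguish an open arch on a vertebra whose centrum encloses trabecular
cavities — which is every binarized vertebra — so by default enclosed
cavities lying wholly inside the centrum region are discounted and only a
cavity outside the centrum (the foramen) qualifies a slice. The literal rule
remains available (`discount_centrum = FALSE`) and is the right choice for
clean ring-shaped sections. Per included slice, bone area is the bone pixel
count times pixel area and total area fills all enclosed holes (bone plus
cavities, deliberately *not* the convex hull); CSA is the unweighted mean
bone area and GC the unweighted mean of per-slice ratios. The aggregation is
a documented choice — the protocol this follows does not state one — and
per-slice series are returned for users who prefer medians.

# Synthetic data

## Phantoms

* **Rod lattice**: hard cylinders of radius r along all three axes through
  the nodes of a (possibly anisotropic) cubic lattice, unioned at nodes so
  the analytic picture stays tractable. Ground truth: Tb.Th = 2r, per-axis
  Tb.N = 1/spacing, BV.TV by voxel counting, and connectivity as the cycle
  rank E − V + 1 of the node-strut graph — an independent oracle for the
  Euler-characteristic route.
* **Plate stack**: solid plates normal to one axis; BV.TV = t/(t+g),
  Tb.Th = t, plate-model Tb.N = 1/(t+g), strongly anisotropic. Fixture
  extents are whole multiples of the period so the analytic BV.TV is exact.
* **Synthetic vertebra**: a cortical tube narrowing parabolically to
  `waist_fraction` of its radius at mid-length (so the true waist plane is
  the axial midpoint), lattice trabeculae inside, and a concentric dorsal
  arch ring whose annular gap to the centrum forms an enclosed foramen;
  `arch_gap` cuts a 40° dorsal wedge, opening the foramen.

## The comparative simulator

`simulate_clade()` generates one row per specimen × position under the
bundled design (Table-1-style species, masses, specimen counts). IZL is
mass^(1/3) times lognormal noise whose sd is position-dependent and smallest
at the third position (0.04 in log10 at ps3), calibrated so the mass ~ IZL
refit attains R² ≈ 0.98 — which also makes the proxy-selection stage pick
IZL at ps3 for the right reason. Each log10 metric is
`intercept + exponent·log10(IZL) + ecology offset + Brownian species
deviation + specimen noise`, with exponents from the reference whole-dataset
fits (0.33, −0.28, 0.66, 0.14, 1.84, 0.04, −1.35) and residual variance per
metric derived from the reference R² values. Two calibration choices are the
package's own, since within-species variance components are not published:

* **Residual split.** `bm_share` sets the fraction of residual variance
  placed at the species level as a Brownian deviation on the tree. The
  default is 0: the generator's calibration property — the 95% CI of the
  row-level refit covers the generating exponent in ≥ 90 of 100 seeds —
  holds only when rows are independent, and measured coverage collapses to
  ~60–70% already at a 25% species-level share. Phylogenetically structured
  datasets are produced by raising `bm_share` (the PGLS-side property tests
  use 0.1, where species-mean PGLS coverage holds).
* **Ecology offsets** default to zero for the same reason; the pipeline and
  discriminant demonstrations switch them on (offsets of half a residual sd
  per ecology), which is enough for the confound to matter.

The bundled ten-species Newick tree mimics the topology of the extant
xenarthran radiation with invented, ultrametric branch lengths (root depth 65
time units); it is synthetic, not a published calibrated tree.

# Statistics stage

* **Log-log fits** are OLS on log10 data — the iid special case of GLS,
  which is what an unspecified-correlation GLS reduces to — with 95% t-based
  CIs (n − 2 df). The allometry call is "0" when the isometric expectation
  (0 for ratios, −1 for Tb.N, 1 for Tb.Th, 2 for CSA, −3 for Conn.D, 3 for
  mass) lies inside the CI, otherwise "+" or "−" by the side of the CI the
  expectation falls on.
* **Species means** are arithmetic means of raw-scale metrics per species ×
  position (log-then-mean available via `log_first`); logs are taken on the
  means downstream. Mean-then-log versus log-then-mean differ on skewed data
  (Jensen), which the tests demonstrate.
* **SMA common-slope test.** Each group is modelled as a centred bivariate
  normal; constraining the SMA slope (sign(r)·sd(y)/sd(x)) to a common value
  leaves correlation and scale free, and profiling them gives a closed-form
  per-group deviance (the stationary correlation is 2bSxy/(b²Sxx + Syy)).
  The common slope minimizes the summed profile deviance in one dimension,
  and the likelihood ratio is referred to χ² with (groups − 1) df. At each
  group's own SMA slope the constrained deviance equals the unconstrained
  one, so identical groups give LR = 0 exactly; null simulations reject at
  ≈ 5% at α = 0.05.
* **PGLS** computes `(X'C⁻¹X)⁻¹X'C⁻¹y` with the Brownian covariance
  C[i,j] = shared root-to-MRCA path length, t-based CIs with n − 2 df, and a
  whitened-coordinates pseudo-R². With C = I it reproduces OLS to 1e-10; on
  Brownian data it matches the standard GLS implementation to 1e-8. One row
  per species is required; per-position fits are averaged arithmetically
  with the slope range reported as "mean (low–high)".
* **Blomberg's K** uses the phylogenetically corrected mean and the
  (tr C − n/(1'C⁻¹1))/(n − 1) Brownian expectation; significance comes from
  tip-label permutations with the (r+1)/(n+1) correction so p is never 0.
  K is invariant to scaling and shifting of the trait, matches the standard
  implementation to 1e-8, and centres on 1 under Brownian simulation on the
  bundled tree.
* **FDA** is linear discriminant classification through optimal scoring:
  regress the class indicator matrix on centred predictors, eigen-decompose
  the scored cross-product, and rescale the resulting variates to unit
  pooled within-class variance so nearest-centroid-minus-log-prior equals
  the canonical LDA rule (verified prediction-for-prediction against the
  reference implementation). At most three predictors are accepted,
  mirroring the protocol's limit; accuracy is the resubstitution correct
  classification rate (the convention that makes 10-species accuracies read
  as 0.9 = one miss), with leave-one-out available as an option.
* **pFDA** whitens predictors and class indicators by C(λ)^(−1/2)
  (eigenvalue floor 1e-10), with λ estimated by maximizing the summed
  per-trait Brownian profile log-likelihood over a coarse grid plus 1D
  refinement; traits are treated as independent given the tree, a documented
  simplification. With λ = 0 on an ultrametric tree, or on a star tree, pFDA
  reduces exactly to FDA. The three conventional 3-metric subsets (most
  size-correlated: Tb.Th, CSA, Conn.D; least: BV.TV, GC, DA; most
  phylogenetically correlated: DA, Tb.Th, CSA) are configurable, since the
  ranking rule behind the third subset is conventional rather than stated.

# Problem sizes and numerical choices

Tests and the analysis scripts run phantoms at 1.2–1.5 mm extents and 10–25
µm voxels (up to 150³ voxels), direction sets of 25–129, SLD with a few
hundred points, 100-seed calibration loops, 500 Brownian replicates for the
K calibration and 2000 for the SMA null — sizes chosen so the whole suite
completes on one CPU in minutes while every estimator is still resolved well
above its noise floor. Direction counts only tighten the fabric fit beyond
~25 directions for these phantoms (the tensor has six free parameters);
line-spacing halving changes MIL by under 3%.

Degenerate inputs are rejected with informative errors throughout: empty or
overlapping lattice specs, shells thinner than a voxel, constant images under
Otsu, nonpositive values in log-log fits, zero-variance SMA groups, singular
phylogenetic covariances, and constant traits for K.

# What passing tests do and do not show

The phantoms exercise every estimator against analytic or graph-theoretic
truth, but they are idealized: hard binary interfaces (no partial-volume
gray levels), perfectly periodic geometry, no scanner noise or beam
hardening, and trabeculae that are cylinders or plates rather than remodelled
biological struts. The simulator generates exactly the power-law-plus-noise
world the estimators assume, so parameter-recovery results validate the
statistical machinery, not the biological model. Real-data caveats — operator
thresholding, centrum delineation, the foramen rule on connected arches —
are flagged at the relevant functions, and the centrum-dependent defaults
accept caller-supplied masks precisely because real anatomy will defeat
simple heuristics.
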
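---
title: "The volumetric gap fraction of tree crowns: model, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The volumetric gap fraction of tree crowns: model, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The model

Classical gap-fraction estimates describe what a viewer (a fisheye camera, a
laser beam) sees through a crown, and therefore change with the viewing
position and angle. `crowngf3d` instead treats the crown as a porous medium:
the vegetative elements are the solid matrix, the air between them the pore
space, and the **volume-based gap fraction** is the crown's void fraction,

$$GF_{vol} \;=\; 1 - \frac{\sum_{t=1}^{N} V_{leaf_t} + \sum_{u=1}^{M} V_{branch_u}}{V_{canopy}},$$

with $N$ individually segmented leaves, $M$ fitted branch cylinders, and
$V_{canopy}$ the volume of the crown envelope. All three ingredients come
from a single terrestrial-laser-scanning (TLS) point cloud, in metres.

The quantity that makes per-leaf volumes meaningful is the **equivalent
leaf thickness**: real laminae are curled, twisted and drooping, so the
extent of a leaf's points along its own normal — the distance between the
highest and lowest point in the normal direction — is centimetres rather
than the sub-millimetre anatomical blade thickness. Each leaf is enclosed
in a **hexagonal prism**: the base is the simple hexagon through the
petiole tip, the blade apex and two refined edge points per side, and the
height is the equivalent thickness. The prism volume is the base area
(lower triangle + middle trapezoid + upper triangle, equal to the shoelace
area) times the thickness.

# Pipeline stages and their parameters

## Wood-leaf classification

Each point is classified from the eigenvalues $\lambda_1 \ge \lambda_2 \ge
\lambda_3$ of its neighbourhood covariance (linearity
$(\lambda_1-\lambda_2)/\lambda_1$, planarity
$(\lambda_2-\lambda_3)/\lambda_1$, scattering $\lambda_3/\lambda_1$). A
point is wood when its linearity exceeds `linearityThreshold` (default
0.6). Two design choices matter here, both visible in the defaults:

* **Physical, entropy-optimal scales.** A fixed k-nearest-neighbour scale
  cannot work: at TLS densities, twenty neighbours of a trunk point span a
  centimetre — a locally flat patch indistinguishable from a leaf — while
  the curvature of the trunk only becomes visible at a decimetre scale, at
  which blades and twigs blur together. Features are therefore computed at
  five physical radii (`classifyScales`, 0.01–0.08 m, against a
  voxel-thinned reference cloud so density cannot shrink the effective
  radius), and each point uses the scale whose feature triple has minimal
  Shannon entropy — the standard optimal-neighbourhood rule.
* **Field smoothing.** Blade *edges* are genuinely linear at any scale
  smaller than the blade, producing salt-and-pepper wood labels across
  every lamina. The per-point linearity is averaged over the 16
  nearest neighbours for 3 rounds before thresholding.

A quadratic-discriminant ("gaussian") and an SVM classifier over the same
multi-scale features are available when a labelled training cloud exists.
Ambiguous points default to leaf: leaf volume is measured from the points
themselves, while wood volume comes from cylinder fits that tolerate a few
missing points.

## Individual leaf segmentation

A point lies at the centre of a leaf surface when its spherical
neighbourhood (radius = three quarters of the average half leaf width,
`radius`) looks like a great circle through the point:

1. the neighbours lie near the least-squares plane constrained through the
   point (mean absolute distance < `threshold1`, default `0.2 * radius`);
2. the robust normal (iteratively reweighted smallest eigenvector with
   Gaussian weights $e^{-(w_j^\top n)^2/h^2}$) agrees with the neighbours'
   normals (mean unsigned angle < `threshold2`, default 15°);
3. the neighbours, projected to the plane, cover the disc isotropically:
   the disc is split into 40 equal-area cells (8 sectors × 5 annuli with
   boundary radii $R\sqrt{d/5}$) and the index of dispersion
   $\sigma' = [\sum_d (num_d-\mu)^2/40]/\mu$ must not exceed `threshold3`
   (default 2; $\sigma' \approx 1$ for uniform random cover). $\sigma'$ is
   a variance-to-mean ratio, not a standard deviation; a square-root
   variant is switchable (`sqrtUniformity`) for users who prefer the
   literal reading.

The robust-normal objective $\sum_j (w_j^\top n)^2 e^{-(w_j^\top n)^2}$ is
not minimised literally — it vanishes as residuals grow, so its global
minimiser is degenerate; the iteratively reweighted eigen scheme preserves
its intent (down-weighting off-plane offsets) while staying well-posed.

Candidates within `suppressionRadius` of a stronger (lower $\sigma'$)
candidate are suppressed. The suppression scale must be the *leaf* scale,
not the neighbourhood scale: the test passes throughout the inner region
of a lamina where the neighbourhood disc fits inside the blade, so a
sub-centimetre suppression distance retains several centres per leaf and
triples the instance count. The default is half the average leaf length.

Instances are grown geodesically (multi-source Dijkstra over the 10-NN
graph, capped at twice the leaf length). Basins whose watershed divide is
shallower than `mergeRadius` (default a third of the cap) are merged —
this absorbs the second centre that a strongly drooped lamina (a kinked,
two-faceted surface) otherwise produces. Unreached points fall to DBSCAN
(`eps` = twice the mean point spacing, `minPts` 10); clusters of at least
`minLeafPoints` (default 40, the minimum per-leaf coverage the method
needs) become instances, smaller ones noise.

## Per-leaf geometry

Each instance is smoothed by moving least squares (local quadratic in the
tangent frame, Gaussian weights, support = a quarter of the leaf width) to
suppress wind-ghost points; the midrib endpoints are the farthest point
pair (petiole tip = lower endpoint); edge points are per-slab transverse
extremes along 21 slicing bins (`nSlices`; the slab width is one bin);
each side's edges are refined by two least-squares cubics $v(u), w(u)$
solved from the explicit normal equations in the leaf-local frame. The
cubic is fitted in the local frame rather than against the global
y-coordinate, which degenerates whenever a midrib happens to run
perpendicular to the y-axis; for a midrib along y the two are identical.
The hexagon uses the edge points at counting numbers round(k/4) and
round(3k/4) per side (round half up). Leaves below `minLeafPoints`, or
whose hexagon construction fails, fall back to the covariance-aligned
bounding-box volume; leaves with fewer than 3 points are rejected with
zero volume.

## Wood and crown volume

Wood points are decomposed into branch segments: edges of the 10-NN graph
whose endpoint principal directions disagree by more than 25° are cut,
connected components are recursively bisected until each group is at most
`segmentLength` (0.2 m) long and tube-like (transverse RMS ≤ 1.5 cm, or an
isotropic cross-section up to 5 cm). Each group gets a least-squares
cylinder: axis refined by Levenberg–Marquardt on point-to-axis distances,
radius recovered by Rician moment matching
($r^2 = m_2 - b$, $b = m_2 - \sqrt{2m_2^2 - m_4}$ from the radial-distance
moments), which removes the upward bias a plain mean distance suffers when
the branch radius is comparable to scanner noise. Three safeguards handle
ill-posed fits: the radius is capped by the observed radial spread
($\sqrt{\lambda_2+\lambda_3}$, which equals $r$ for a fully sampled tube);
groups whose fitted cylinder wraps only a narrow azimuthal arc (a curved
chain of branch segments lying on a spuriously fat cylinder —
`circumCoverage` < 0.4) are bisected and refitted; and cylinders whose rms
residual exceeds `cylinderRmsFactor` (3) times the median rms — the
scanner-noise floor — are excluded from the wood volume, since no *single*
branch can produce residuals far above the noise whatever its radius.

The crown volume is the 3D alpha shape of the vegetative points above the
crown base; `alpha = Inf` (the default, matching the convex-hull usage in
the source workflow) gives the convex hull via quickhull, finite alpha the
basic alpha complex (Delaunay tetrahedra with circumradius ≤ alpha;
non-decreasing in alpha, equal to the hull at infinity). The crown base
defaults to the lowest wood point farther than twice the estimated trunk
radius from the trunk axis and can be overridden. Wood cylinders are
clipped at the crown base so numerator and denominator of $GF_{vol}$ refer
to the same region.

## Baselines

Three conventional estimators are provided for comparison: a synthetic
hemispherical photograph (Lambert azimuthal equal-area by default — the
standard HP convention; an equidistant "equal-angle" variant is
switchable), reporting sky-pixel fractions per zenith ring with the
conventional 57.3° ring as default; a voxel-occupancy gap fraction
(0.1 m voxels by default; the occupied volume is subtracted from the crown
volume); and the Beer–Lambert transmission
$P(\theta) = \exp[-G(\theta)\,\Omega\,\mathrm{LAI}/\cos\theta]$. The full
per-emission-angle ray-traced transmission matrix is intentionally out of
scope; the closed-form law plus the voxel estimator cover the comparisons
the package makes.

# The synthetic-tree generator

Because raw TLS scans of the original study trees are not publicly
deposited, validation rests on a parametric generator whose defaults
emulate a small ornamental crown of the crepe-myrtle type, matched to
field-reported conditions:

* **Lamina**: elliptic planform (a fan-shaped, ginkgo-like sector is
  available), blade length 4–6 cm with width following length
  allometrically (aspect ≈ 0.7, the reported mean for this crown type),
  out-of-plane curl $z = c\,(2u-1)^2$ with $c$ = 0.4–1.6 cm and a distal
  droop rotation of 0.1–0.5 rad. These distortion ranges reproduce
  field-measured equivalent thicknesses of roughly 0.3–1.7 cm.
* **Architecture**: a 0.8 m trunk; three first-order branches diverging at
  the trunk top (so the crown base is well defined); recursive
  dichotomous branching to depth 7 with radius taper 0.7 (close to
  area-preserving) and length taper 0.8, steered to stay inside a
  spheroidal crown envelope. 150 leaves attach along the three deepest
  branch orders on 1–2.5 cm petioles, blades extending outward along the
  petiole, with a soft internode spacing of half a leaf length.
* **Sampling**: surfaces sampled uniformly by area at 150 000 points/m²
  (≈ 2.6 mm spacing, ≈ 200 points per leaf) with isotropic Gaussian noise
  of 1 mm — TLS-like ranging error. Occlusion is *not* simulated: the
  generator stays analytic, and sparse-data robustness is probed by
  lowering the density instead.

Ground truth is analytic where possible (wood volume from the generating
cylinders) and definitional elsewhere: per-leaf true volumes apply the
*same* hexagonal-prism construction to a dense noiseless surface grid, so
pipeline-versus-truth comparisons isolate segmentation and fitting error
rather than model mismatch, and the true crown volume is the convex hull
of a fixed-resolution noiseless surface sample, making all truth
quantities independent of the sampling density. Passing these tests shows
the chain recovers its own model from noisy samples of known geometry; it
does not certify performance under occlusion, registration error, wind
ghosting beyond i.i.d. noise, or foliage morphologies far from the
parametric family.

# Numerical choices and degenerate inputs

* Neighbour queries exclude the query point (its offset vanishes in every
  covariance the method builds); coincident neighbourhoods return the
  scattering convention $(0,0,1)$.
* Normals fix their sign by non-negative z (ties: y, then x); all
  angle comparisons use unsigned dot products.
* The farthest-pair search is exact (pairwise) up to 5000 points and uses
  the convex hull above that; ties break lexicographically.
* Hexagon vertices are projected to their best-fit plane before the area
  computation: the prism base is planar by construction and off-plane
  extent is already captured by the thickness. Self-intersecting
  projected hexagons are rejected and the leaf falls back to its bounding
  box.
* An empty uniformity disc returns $\sigma' = +\infty$; a gap fraction
  outside $[0,1]$ is reported as computed, with a warning, so
  pathological geometry stays visible.
* Delaunay tetrahedralisation normalises coordinates to the unit cube and
  uses long-double orientation/insphere predicates with a large finite
  super-tetrahedron; on random clouds the tetrahedra tile the convex hull
  to machine precision (this identity is a test).
* All randomness (generator, pipeline seed) flows through a single
  integer seed; runs are byte-reproducible.

# Problem sizes used in the validation suite

Unit tests run on purpose-built fixtures of a few hundred to a few
thousand points. End-to-end validation uses five default-specification
trees (seeds 1–5, ≈ 65 000 points each); a full pipeline run takes well
under a minute per tree on one core, and the whole suite a few minutes.
The Monte-Carlo area oracle uses 10⁶ samples; the hull convergence check
10⁵ ball points.

# Known limitations

* The threshold classifier reaches ≈ 90–93 % on default synthetic trees;
  its errors concentrate on blade edges and leafy twigs. Trained
  classifiers help only marginally with the same features (~92 %).
* Equivalent thickness is an extreme-value statistic: residual noise after
  MLS inflates it by 1–2 mm, a 15–20 % volume bias for thin leaves. The
  definition is kept as stated (max minus min projection) rather than
  robustified.
* Compound leaves are segmented as leaflets, conifer needles and deeply
  lobed laminae do not fit the hexagonal-prism family, and heavy
  occlusion (unscanned interior crowns) biases $GF_{vol}$ upward — these
  mirror the stated limits of the underlying method.
* The hemispherical baseline rasterises points with a fixed 0.15° angular
  footprint; it is a comparison device, not a calibrated HP simulator.
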
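---
title: "Methods: from axonal reconstructions to mesoscale projection statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from axonal reconstructions to mesoscale projection statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

axonmap turns complete single-neuron axonal reconstructions, registered to a
common mouse-brain coordinate space, into mesoscale connectivity statistics:
per-area projection strengths, higher-order projection motifs, a pairwise
morphological dissimilarity, a one-dimensional morphological gradient, and a
quantitative soma-to-terminal topography. This vignette explains each model
and procedure, the parameters that matter, the synthetic population the tests
rely on, and the limits of what those tests demonstrate.

## Data model and coordinate conventions

A morphology is a pair of arrays: an ordered list of 3-D points and, per
point, a structure label (soma, axon, dendrite) and the index of its parent
in the list (a tree with a single root). The canonical analysis space is PIR
— anterior-to-posterior, superior-to-inferior, left-to-right, origin at the
anterior-superior-left corner — in micrometers. MouseLight-style sources are
stored in LIP at 1 um; `to_ccf_pir()` swaps the first and third coordinate,
reflects the new third coordinate against the template left-right extent
(11,400 um for the 10-um reference template), and rescales. Storing
micrometers internally and deriving voxel indices on demand (`floor(p /
voxel_size)`, 0-based, half-open ownership) avoids any ambiguity about
rescale direction between sources digitized at different resolutions. The
swap-and-reflect map is an isometry, which the test suite checks directly.

## Topological minor

Full reconstructions carry tens of thousands of points, most of them interior
samples along unbranched stretches. `extract_topological_minor()` keeps only
the soma, the axonal branch nodes (two or more axonal children; trifurcations
count once) and the terminal branches, each backtracked from an axonal leaf
to the nearest branch node (or to the soma when the path never branches).
Terminal-branch path lengths are preserved exactly because the branch keeps
its interior points; the reduction discards dendrites and inter-node interior
points. All downstream statistics — projection profiles, CPD clouds,
morphometrics — operate on the minor.

Morphometrics reported per neuron: number of branch points; mean radial
distance (soma to terminal points — terminals, not all minor points, because
the radial measure describes where the arbor ends); mean branching width,
defined per branch node as the maximum pairwise distance among the terminal
points descending from it, averaged over branch nodes. This width definition
is rotation-invariant, unlike a projection onto a fixed axis, so all
morphometrics are invariant under rigid motion of the whole cell — a
property the tests assert.

## Projection profiles, motifs, focality

Each terminal branch is assigned to the atlas area (and cortical layer)
containing its terminal point, and the branch's full path length accrues
there; branches ending outside the configured areas accrue to `"other"`.
Assignment by terminal point (rather than per-segment splitting) reflects the
view of a terminal branch as a unit of innervation at its termination site.
Length is conserved: summed per-area lengths equal summed branch lengths.

The dominant target is the area with the greatest terminal length (ties
broken by a fixed canonical area order and flagged). A projection motif is
the list of areas receiving at least `min_terminal_branches = 5` terminal
branches, ordered by descending terminal count; motif sizes 0–4 map to
subthreshold, monofocal, bifurcating, trifurcating and quadrifurcating.
Multifocal neurons are labeled `center` when at least 4 terminal points in
the *second*-ranked area lie more than 200 um from the nearest voxel of the
dominant area, else `border`; only the secondary area is evaluated because
the center/border question is about whether the secondary arborization might
be a parcellation artifact of the primary one. Border distance is 3-D
Euclidean to the nearest voxel of the dominant area — not geodesic along the
cortical sheet — the simplest defensible reading, computed by an exact
cached nearest-voxel search.

Motif significance uses the null hypothesis that areas are targeted
independently: for each multi-area motif the null joint probability is the
product of the marginal targeting fractions, the observed count of neurons
jointly targeting all motif areas is tested with a two-sided exact binomial
test, and Bonferroni correction is applied over the motifs tested. The
marginal/joint counting is motif-membership based (a neuron "targets" an
area when the area passes the terminal threshold).

At barrel resolution the same machinery runs against an atlas whose barrel
field is subdivided into barrel columns, with a targeting threshold of 4
terminal branches, and each neuron is cross-classified monofocal/multifocal
(area level) by single-/multi-barrel (barrel level); the partition sums to
the per-barrel total by construction.

## Rotation-only Coherent Point Drift

The pairwise morphological dissimilarity registers one soma-centered axonal
point cloud (all topological-minor points, soma excluded) to another with
Coherent Point Drift restricted to pure rotation: scale fixed at 1,
translation fixed at 0. The moving cloud provides Gaussian-mixture centroids
fitted to the reference cloud by EM. The E-step computes responsibilities
with an optional uniform outlier component of weight `w` (default 0); the
M-step takes the rotation from the SVD of the uncentered posterior-weighted
cross-covariance with a determinant correction, so the estimate is always a
proper rotation; the variance follows the standard rigid update. Sigma^2 is
initialized to the mean squared cross-pair distance over 3. Iteration stops
when the absolute change in the negative log-likelihood falls below `tol =
0.001` or at `max_iter = 60`. The final dissimilarity is the mean squared
distance between each rotated moving point and its argmax-responsibility
correspondent (a responsibility-weighted variant is available behind
`soft_mse`). The EM inner loop is implemented in C++ (RcppArmadillo) because
the all-pairs matrix performs O(n^2) registrations.

Restricting the registration to rotation about the shared soma makes the
dissimilarity invariant to where the neuron sits and how its arbor is
oriented, leaving only arbor geometry. A consequence worth stating plainly:
for an arbor that is a single compact cluster, the optimal rotation can move
the cluster anywhere on its radius, so the dissimilarity is driven by the
*radial* structure of the cloud (distances from the soma) plus residual
shape, not by direction. Matrix asymmetry (registering a to b vs b to a) is
resolved by averaging, and the diagonal is zero.

## Embedding, gradient, morphotypes

The dissimilarity matrix is embedded in 2-D with exact t-SNE in
precomputed-distance mode (perplexity 30, fixed seed, 1000 iterations, early
exaggeration 12 for 250 iterations, learning rate 200). An exact O(n^2)
implementation is used because populations here number a few hundred at
most and bit-reproducibility for a fixed seed matters more than speed.
Perplexity must be below n; the pipeline caps it at n − 1 for small runs.

Each neuron receives a gradient index: the geodesic distance from a root
point, computed on a k-nearest-neighbor graph (k = 10, grown until the graph
connects) with Euclidean edge weights, normalized by the maximum so indices
span [0, 1] with the root at 0. The root is the most dorsal (smallest
superior-inferior soma coordinate) among barrel-cortex-dominant neurons,
ties broken by id; if none exists the point farthest from the embedding
centroid is used, with a warning. Normalizing by the highest index is the
default; morphotypes come from Ward agglomerative clustering of the 2-D
coordinates cut at k = 3, with labels renumbered so mean gradient increases
with the label. Gradient–morphometric associations use Spearman rank
correlation with two-sided p-values.

## Topography

Somata are fitted to the medoids of their axonal terminal points — the
medoid, unlike the centroid, is an actual location in the data even for
multi-cluster arbors — by affine least squares (translation included, the
standard least-squares reading). The 3x3 linear part is polar-decomposed
A = R S with the reflection-corrected SVD, and Euler angles are read from R.
Euler conventions are genuinely ambiguous in the field, so both the
decomposition order and intrinsic/extrinsic composition are parameters
(default: extrinsic x-y-z); the implementation supports all six Tait-Bryan
orders in both senses with exact round-trips. The fit unit defaults to 10-um
voxels, and the reported MSE is the mean squared residual distance in the
fit unit.

## The synthetic population generator

No archived data ships with the package, so every claim the tests make is
established on a synthetic population with known ground truth. The generator
emulates a first-order somatosensory relay: a toy atlas (2 x 2 x 3 mm at
10 um) holds a layered cortical slab partitioned into six areas of 500 um
along the left-right axis — comparable to real somatosensory area widths —
and a nucleus ellipsoid (radii 180 x 300 x 180 um, elongated along the
dorsoventral axis that carries the topography). Somata sample the ellipsoid
with the depth parameter d uniform in [0, 1] along the dorsoventral axis so
the population covers the whole topographic axis.

The soma-to-arbor map is c = base + R* S (s − mu), with R* the generator
rotation (default extrinsic XYZ angles (−60, 0, −120) degrees) and S =
diag(0.5, 5.35, 0.5) a stretch that spreads the rotated soma cloud across
all six areas. The primary target area is whichever area contains c, so the
primary target is determined by depth through the rotation. Because S is
symmetric positive definite, the polar decomposition of the fitted linear
map recovers R* exactly in the noiseless limit — this is the ground truth
for the topography-recovery test.

Motif order is sampled from (0.26, 0.53, 0.17, 0.015) for orders 1–4 (the
remainder goes to order 5), and secondary areas are the nearest neighbors of
the primary along the topographic axis, so the two extreme areas never
appear in one motif. The primary arbor always keeps the clear majority of
terminal branches (17–23 for low orders, scaled up so it always exceeds the
summed secondary counts of 11, 9, 7, 5), mirroring the definition of a
dominant target.

Arbors are built as a trunk, one fan cone per target: a branch node above
the cluster center with terminal branches fanning to the terminals. Three
choices make recovery properties exact rather than approximate:

* The terminal fan spans only the anteroposterior/depth plane — zero extent
  along the area axis — so in the noiseless limit every terminal lands in
  its intended area and the extracted motif equals the intended motif for
  100% of neurons.
* The fan is a central terminal plus antipodal pairs, and secondary cluster
  centers share the primary's AP/depth coordinates, so the medoid of all
  terminals is exactly the primary central terminal; the soma-to-medoid map
  is then exactly affine and the topography fit is exact when noiseless.
* The nucleus is offset laterally and posteriorly from the cortical anchor
  so that soma-to-arbor radial distance is strictly monotone in depth
  (vertex of |v(s)|^2 outside the sampled range). Since a rotation-only
  registration is blind to arbor direction, radial structure is the
  carrier the CPD dissimilarity can see; together with a fan-cone height
  (80–430 um) and fan radius (40–150 um) that grow with depth, this encodes
  the depth-to-morphology program — increasing branch length, width and
  count along the gradient — that the gradient-recovery test expects the
  pipeline to read back out.

Default terminal jitter is 10 um — about one atlas voxel of registration
error — applied as a rigid offset per terminal branch. At this level motif
recovery stays at or above 95% (errors concentrate in neurons whose primary
cluster lies within about one jitter s.d. of an area border, an honest
ambiguity that the center/border analysis exists to flag) and recovered
Euler angles stay within a few degrees.

What the generator does *not* emulate: tortuous axon paths and collaterals,
boutons, realistic branch-order statistics, curved cortical sheets and
columns, registration artifacts that are correlated across neurons, and any
coupling between motif order and depth. Passing tests therefore demonstrate
that the pipeline recovers known structure of this idealized kind; they do
not certify performance on archive reconstructions, whose noise is richer.

## Numerical choices and degenerate inputs

* CPD: sigma^2 floored at 1e-10; degenerate clouds (under 3 points, rank
  below 2) are rejected; failed pairs in the matrix are imputed at the
  matrix maximum with a warning. Convergence monitors the negative
  log-likelihood, and with `tol = 0.001` on populations of this size the
  60-iteration cap frequently binds first — by design, both bounds are part
  of the procedure.
* Ties: dominant-target ties break by canonical area order with a flag;
  motif count ties break the same way; medoid ties take the lowest index;
  nearest-neuron ties take collection order.
* Euler extraction near gimbal lock (|second angle| near 90 degrees) zeroes
  the third angle and sets a flag.
* t-SNE input probabilities are floored at 1e-12; the per-point precision
  search runs 64 bisection steps.
* Zero-length terminal segments are deduplicated before morphometrics.

## Problem sizes

The test suite and the acceptance script run populations of 8–100 neurons
for structural checks, a 60-neuron population (about 3,500 CPD pair
registrations) per seed for gradient recovery, and 400 generated neurons for
the motif-order census. These sizes give stable statistics for every
recovery property while keeping a full run in the low minutes on one CPU;
the same code paths scale to archive-sized populations (a few hundred
neurons) unchanged.

## Known limitations

* The dissimilarity is rotation-invariant by construction, so genuinely
  direction-coded differences between arbors (same radii, different target
  direction) are invisible to it; this is the price of decoupling
  morphology from topography.
* Border distance is volumetric, not geodesic along the cortical sheet;
  near strongly curved boundaries the two diverge.
* The binomial motif null treats area targeting as independent Bernoulli
  draws with motif-membership marginals; it ignores the constraint that
  counts come from the same finite arbor.
* Dense occupancy arrays at 10 um are only materialized on demand; the
  stored representation is sparse.
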
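---
title: "Cohort-level RSFC boundary mapping: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cohort-level RSFC boundary mapping: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific problem

Cortical areas are distinguished by their function, architectonics,
topography and connectivity.  Resting-state functional correlations
(RSFC) offer a non-invasive proxy for the last criterion: where the
whole-surface connectivity pattern changes abruptly as one moves along
the cortical sheet, an areal border is likely.  `arealmap` implements a
cohort-level version of this *boundary mapping* idea and everything
that surrounds it in a typical aging study: motion scrubbing and
nuisance cleaning of the vertex time series, bootstrap-averaged
similarity gradients, watershed boundary maps and parcellations,
rotation ("spin") null models for every evaluation statistic, and
parcel-graph community detection with brain system segregation.

Because the human datasets such analyses are built on are rarely
redistributable, the package is organized around a synthetic cohort
generator with *planted* areal and system structure.  Every stage of
the pipeline can therefore be verified against a known ground truth,
at desk scale, on one CPU.

# The generative model

`make_sphere_mesh()` builds an icosphere (default: 4 subdivisions,
2562 vertices, radius 50 mm) with a polar cap marked as medial wall.
A sphere rather than a brain-shaped surface is used deliberately:
every computation in the pipeline depends only on mesh topology and
geodesic distances, and exact spherical geometry makes the rotation
null exact rather than approximate.

`plant_parcellation()` plants `n_parcels` geodesic Voronoi parcels
from farthest-point-sampled seeds (bounding parcel size imbalance) and
groups them into `n_systems` spatially coherent systems; systems
farthest from the medial pole are typed "sensory-motor", the rest
"association".

`simulate_cohort()` generates, per subject,

* **vertex time series**: a sum of a *system latent*, a *parcel
  latent*, a parcel-specific *connectivity fingerprint* (fixed
  `N(0, 0.3^2)` loadings onto 8 shared latents), and white vertex
  noise (`noise_sd`, default 1).  All latents are white noise
  band-pass filtered to 0.009-0.08 Hz at TR = 2 s, so cleaning is
  near-idempotent on clean data.  The fingerprint term deserves a
  comment: with only system + parcel latents, two adjacent parcels of
  the same system would have *identical* expected whole-surface
  connectivity, so the border between them would be invisible to RSFC
  similarity by construction.  Real cortical areas are assumed to have
  individually distinct connectivity profiles -- that is the premise
  that makes boundary mapping work -- and the fingerprint encodes
  exactly that, while preserving the ordering
  within-parcel > within-system > between-system correlation.
* **border jitter**: vertices close to a planted border flip to the
  neighbouring parcel with probability decaying in the geodesic margin
  over `jitter_mm`, modulated by a smooth "vulnerability" field with a
  cohort-common component.  This makes a cohort's *effective* borders
  shift coherently away from the planted ones, which is what the
  cohort-specific-vs-young parcellation comparisons detect.
* **between-system coupling**: each system's latent absorbs a fraction
  `coupling` of its variance from the other systems' latents, with
  random per-subject pair weights.  The pairwise, heterogeneous form
  matters: a single shared global latent would be removed wholesale by
  global-signal regression in preprocessing, erasing the planted
  desegregation; heterogeneous pairwise mixing survives nuisance
  cleaning, as between-system desegregation does in practice.
* **motion**: a slow random walk plus Poisson spikes (default rate
  0.03/frame) that jump the parameters by ~0.6 mm FD *and* inject a
  transient artifact into all vertex series, so scrubbing has a
  measurable denoising effect.
* **structure maps**: per-parcel thickness baselines thinned with age
  (0.012 mm/yr association, 0.004 mm/yr sensory-motor), and a
  deformation map whose magnitude co-varies with the jitter field --
  planting the structural correlates of boundary differences that the
  vertex-wise regression is meant to recover.
* **task betas**: per-parcel condition amplitudes (4 conditions) plus
  vertex noise, aligned with the subject's effective labels.

The aging "knobs" (jitter 0 to 8 mm and coupling 0.10 to 0.40 across
five cohorts spanning 20-93 years) are this package's
parameterization: the aging literature establishes the direction of
these effects (blurrier boundary maps, lower segregation, structural
mediation) but no quantitative model, so the ladder was fixed once at
values that produce unmistakable but not caricatured effects, and all
defaults live in `default_study_config()`.

# The pipeline

**Preprocessing** (`preprocess_subject()`): framewise displacement is
the sum of absolute differentials of the six rigid-body parameters,
rotations converted at a 50 mm radius (the definition's convention;
the choice is configurable because published definitions rarely state
it).  Frames with FD > 0.3 mm are flagged with one frame of padding on
each side; nuisance regression (detrended motion parameters, global
signal, and their first differences) and 0.009-0.08 Hz band-pass
filtering run once on all frames, and are then re-run on the retained
frames only; subjects retaining fewer than 75 frames are flagged
unusable.  The band-pass is a zero-phase frequency-domain filter: the
hard band guarantees the pass/stop behaviour the tests assert, and on
censored data the kept frames are concatenated before filtering -- a
documented simplification (the bias at censoring joins is small in the
0.009-0.08 Hz band relative to TR = 2 s) in preference to spectral
interpolation, whose details published pipelines rarely specify either.

**Boundary mapping** (`cohort_bootstrap_gradient()`,
`boundary_map()`): per subject, the full vertex-by-vertex correlation
matrix over retained frames, Fisher z-transformed (r clipped at
1 - 1e-7).  Per bootstrap sample (100 samples of subjects drawn with
replacement), subject z-maps are averaged and the RSFC similarity
matrix is computed -- the correlation between connectivity rows with
the two self-entries excluded, evaluated by closed-form correction of
full-matrix cross-products so the whole computation is three dense
matrix products rather than a per-pair loop.  Each similarity column
becomes a tangent-plane gradient-magnitude map (least-squares fit of a
linear function over the 1-ring; the operator is exact on linear
fields restricted to the sphere, which the tests verify analytically)
and is smoothed with a 6 mm FWHM geodesic Gaussian.  The bootstrap
mean of these gradient matrices is the input to the watershed stage:
for every seed column, regional minima seed a Beucher-style flooding,
and the per-vertex mean of the binary ridge images is the cohort
boundary map -- the probability that a vertex is an RSFC transition.

Two numerical choices matter at desk resolution.  First, *regional*
minima (equal-valued plateaus with no lower neighbour) are used, not
per-vertex minima, so flat fields produce one seed per basin.  Second,
each gradient column passes through an h-minima transform
(morphological reconstruction) with depth 0.2 of the column's 5-95
percentile spread before flooding: a watershed depends only on the
*ordering* of values, so the nearly flat noise floor of a
bootstrap-averaged gradient map would otherwise seed basins at every
ripple.  On the default synthetic cohort this leaves parcel interiors
with boundary probability near zero while planted borders approach 1.

**Parcellation** (`parcellate()`): the threshold (default 35%) is the
fraction of *strongest* boundary values treated as boundary: the
flooding ceiling is the 65th percentile of the boundary distribution.
Among the plausible interpretations of such a threshold, this is the only one
that reproduces the reported sweep behaviour (over-segmentation at
lower thresholds, under-segmentation at higher ones), and it is
resolution-independent.  The boundary map is pre-smoothed (6 mm, the
pipeline's own kernel scale) and depth-pruned (0.2 of its spread)
before seeding; minima within 3 mm of a stronger minimum are merged;
single-vertex parcels dissolve and every parcel is a connected
component, labelled in seed-vertex order for determinism.

**Evaluation** (`dice_boundary()`, `homogeneity()`,
`silhouette_coefficient()`, `match_parcels()`, `adjusted_rand()`,
`task_sd()`, and their `_z` wrappers): every Z statistic is
`(actual - null mean) / null SD` against 100 seeded uniform rotations
of the reference payload on the sphere, with the valid-rotation
averaging rule: a unit (vertex or parcel) that a rotation pushes into
the medial wall is imputed with that unit's mean over the rotations
where it stayed valid.  A rotated parcel counts as "in the medial
wall" when it keeps less than 75% of its vertices -- a cutoff the
published pipelines do not standardize, recorded in the results and configurable.
Parcel homogeneity is the percent variance explained by the first
principal component of the member vertices' whole-surface maps, with
each map demeaned first; that convention is forced by two properties
the statistic should have (a parcel of identical-up-to-scale maps
scores 100, a half-and-half mix of two orthogonal equal-variance
patterns scores 50) together with invariance to adding a constant to
all maps.  The silhouette's "immediately adjacent parcels" are parcels
within 3 mesh edges, so the label-0 boundary ribbon a watershed leaves
between parcels does not disconnect the adjacency graph.

**Network analysis** (`build_graph()`, `map_equation_partition()`,
`bootstrap_mode_communities()`, `cross_density_consensus()`,
`system_segregation()`): node series are parcel means; edges are
positive Fisher-z correlations with node pairs closer than 20 mm
excluded; densities span 3-10% (0.1% steps to 5%, then 1% steps).
Community detection minimizes the two-level map equation with a
seeded greedy node-moving/aggregation optimizer written for this
package -- a native implementation is what makes seeded determinism
and the exhaustive-enumeration optimality test (all graphs up to 8
nodes) possible.  Bootstrap modal assignments are label-aligned to the
first bootstrap's partition by maximal-Jaccard matching before taking
the per-node mode (a mode over raw labels would be ill-defined), and
the cross-density consensus codifies the published rule set: dissolve
communities smaller than 6 nodes or present at a single density,
reassign their nodes to their community at the nearest less-sparse
density, and resolve leftovers by each node's majority assignment
across densities -- a deterministic replacement for the per-node manual
reassignment such pipelines otherwise require.  System segregation is
`(mean within-system z - mean between-system z) / mean within-system z`
over positive edges, with type-wise scopes (association,
sensory-motor, association-to-sensory) computed from per-system means.

# What the synthetic data do and do not establish

The generator reproduces the *statistical skeleton* the pipeline
assumes: block connectivity nested in systems, distinct per-parcel
connectivity fingerprints, band-limited signals, motion spikes with
signal artifact, age-graded border displacement and desegregation, and
structure maps correlated with border shifts.  It does not attempt
realistic hemodynamics, spatial autocorrelation of vertex noise,
distance-dependent connectivity, individual anatomical variability, or
scanner artifacts.  Passing the planted-recovery suite therefore shows
that the implementation is faithful and the statistics behave as
designed -- not that the pipeline would segment real cortex at any
particular accuracy.

# Desk-scale problem sizes

The reference conditions used by the tests and the acceptance script
are: 2562 vertices, 40 parcels in 5 systems, 20 subjects with 200
frames at TR = 2 s, 100 bootstraps and 100 rotations for the
single-cohort recovery suite.  The five-cohort lifespan runs use the
same mesh with 12 subjects per cohort, 16 bootstraps, 50 rotations and
a density grid scaled to the 40-node graphs (10-30%; the 3-10% grid is
calibrated for graphs with hundreds of nodes).  The repeated-seed
suites (the cohort-specific-vs-young sign tests) run on a reduced mesh
that keeps the desk vertex spacing -- 642 vertices on a 25 mm sphere --
with 12 subjects, 140 frames and 16 bootstraps.  These sizes keep a
full run on one CPU in the minutes range while leaving all planted
effects far from threshold.

# Known limitations

* Nearest-neighbour rotation resampling is label-safe but not a
  bijection: composing a rotation with its inverse restores ~90% of
  vertices (misses are 1-ring neighbours).  Statistics built on
  rotation nulls are unaffected; vertex-level round-trips are.
* The similarity stage holds a V x V dense matrix; at 32k vertices the
  per-column/block streaming the module layout anticipates would be
  required.
* Iteration-2 filtering concatenates censored series (see above).
* The h-minima depths (0.2 of spread) and the 75% rotated-parcel
  validity cutoff are desk-scale operating points, exposed as
  arguments, not claims about real data.
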
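---
title: "Connectopic mapping: models, design choices and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectopic mapping: models, design choices and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectopy)
```

## The analysis model

Connectopic mapping treats the connectivity of a cortical region not as
a parcellation into homogeneous patches but as a superposition of
smooth, overlapping *modes of connectivity change*. The input per
subject and session is a seed-vertex × target-voxel matrix of
probabilistic-tractography visitation counts; each row is a vertex's
connectivity profile.

The pipeline has five stages.

1. **Similarity.** Profiles are compared with the η² coefficient, the
   fraction of a profile pair's total variance not attributable to
   within-pair disagreement. η² is bounded in [0, 1], equals 1 for
   identical profiles, and — unlike Pearson correlation — is sensitive
   to absolute count differences, which carry signal when every vertex
   is seeded with the same number of streamlines. By default similarity
   is computed on raw counts; `log1p` and row-normalised transforms are
   available (`similarity_matrix(transform = )`) because the
   preprocessing of real visitation matrices varies between studies.

2. **Graph.** The similarity matrix becomes a weighted
   k-nearest-neighbour graph: each vertex links to its k most similar
   peers (ties broken by ascending vertex index; union symmetrisation;
   self-links and zero-weight edges excluded), with k the smallest
   value producing a single connected component. Union symmetrisation
   is the weakest rule guaranteeing minimum degree k, so the minimal-k
   search terminates at the sparsest usable graph. Connectivity is
   monotone in k, so the search is a binary scan.

3. **Embedding.** The generalised eigenproblem L v = λ D v (L = D − W)
   is reduced to an ordinary symmetric problem via D^{-1/2} L D^{-1/2}
   and solved densely; the constant eigenvector at λ = 0 is discarded
   and the next m eigenvectors, in ascending eigenvalue order, are the
   gradients. Eigenvector signs are fixed deterministically (the
   largest-magnitude entry is made positive). Each gradient is affinely
   rescaled to [1, 10].

4. **Dimensionality.** m is chosen as the *common dimension*: the floor
   of the minimum per-subject Levina–Bickel maximum-likelihood estimate
   computed on the rows of the η² matrix under Euclidean distance,
   averaged over neighbourhood sizes k = 8…20 (the common practice
   range; the estimate is scale-invariant by construction). Using 1 − η²
   directly as a distance is available as a configuration switch.

5. **Alignment and group maps.** Eigenvector sign is not identifiable,
   so maps are aligned to a reference subject — the lexicographically
   first subject ID, a deterministic choice — by reflecting a map about
   the 5.5 midpoint of the [1, 10] scale whenever its Pearson
   correlation with the reference is below 0.75. The reference itself
   is first put in a canonical orientation (its most extreme vertex
   lies above 5.5), which makes group maps invariant to the arbitrary
   sign of *every* subject's eigenvectors, the reference's included.
   Group maps are vertexwise means over aligned subjects within a
   session, re-normalised to [1, 10].

The flip rule is applied literally: a map correlating with the
reference anywhere below 0.75 is reflected, even in the band
(−0.75, 0.75) where a reflection cannot raise the correlation above the
threshold. The rule is only well-behaved when cohort maps are strongly
correlated in magnitude, which holds in the regimes the package
simulates; the ambiguity is inherited from the flip-about-midpoint
convention itself and is documented rather than patched.

Downstream stages: **projection images** populate every voxel reached
by at least `frac` (default 1%) of a vertex's streamlines with the
count-weighted mean gradient value of the top-3 vertices hitting it
(ties by ascending index; counts taken post-threshold — pre- and
post-threshold selections coincide except exactly at the boundary);
**tract projections** mask projection images with binary tract masks
and report per-tract means with 10,000-resample percentile bootstrap
95% CIs; **reliability** uses ICC(2,1) — two-way random effects,
absolute agreement, single measure — over vertices with k = 2 raters
(the two sessions of one subject, or an unordered pair of subjects
within a session), reporting the mean across subjects (or pairs) with a
percentile bootstrap CI of that mean (between-subject bootstraps
resample pairs by default; resampling subjects is an option);
**decoding** splits a group gradient into ten equal-population rank
deciles (remainder vertices go one-each to the lowest bins; ties by
vertex index), rasterises each decile, correlates it with every
term map over an explicit analysis mask (default: the whole grid), and
keeps the top three positive, non-anatomical correlations per decile,
at most one per synonym group. Synonym groups are an explicit metadata
column, not a stemming heuristic, so the collapsing is auditable.

## The synthetic cohort: what it emulates and how

No public tractography data ships with the package; instead a
generator plants known structure and the tests verify the pipeline
recovers it.

**Geometry.** The seed surface is a regular triangulated sheet, not a
folded cortex: on a sheet the planted gradients (the normalised u and v
coordinates, plus a corner-radial field orthogonalised against both)
are exactly quasi-orthogonal and trivially inspectable. The raw radial
field is strongly collinear with u + v, so its projection onto the
first two fields is removed before rescaling; all fields live in
[0, 1] with pairwise centred |cosine| < 0.05.

**Connectivity model.** Target voxels belong to one of six tracts,
named after the temporal-lobe association tracts (ILF, AF, AR, IFOF,
MdLF, UF). Tract centres are spread along latent axis 1 — so the
ordering of tracts along the dominant gradient is a testable ground
truth, the logic of tract-projection scatter plots — and each tract's
voxels fan out evenly across the full range of every higher axis, with
per-voxel jitter (N(0, (τ/2)²) along axis 1, N(0, (τ/8)²) around the
fan positions) fixed once per cohort so all subjects and sessions see
the same targets. The expected count from vertex i to voxel j is
`depth · K_ij / Σ_j K_ij` with the Gaussian tuning kernel
`K_ij = exp(−‖g_i − x_j‖² / 2τ²)`; realised counts are independent
Poisson draws. τ defaults to 0.25 latent units — wide enough that
profiles overlap smoothly along each axis, narrow enough that the six
tracts remain distinct; depth defaults to 10⁴ streamlines per vertex,
matching standard tractography practice.

**Planted resolution.** Each gradient is coarse-grained to a finite
number of resolvable levels before kernel evaluation: 16, 11 and 9
levels for axes 1–3. This is the generator's key structural choice.
Two planted axes of identical spatial scale produce near-degenerate
Laplacian eigenvalues, and on the very sparse minimal-k graphs these
data yield (k is typically 2–6), any noise then rotates the eigenpair
arbitrarily — the recovered modes are mixtures even though the
two-dimensional subspace is correct. Decreasing per-axis resolution
separates the spectrum (the axis-1 fundamental, the axis-2 fundamental
and the axis-1 second harmonic fall in the ratio ≈ 1 : 2.1 : 4), which
pins each recovered mode to one planted axis. It is also the
biologically natural statement that the dominant mode of connectivity
change is the best spatially resolved and successive modes explain
less variance — the same ordering real gradient analyses report.

**Subject and session variability** enter as additive white Gaussian
perturbations of the (coarse-grained) latent fields, the subject term
shared across that subject's sessions. Defaults σ_subject = 0.10,
σ_session = 0.05: session noise below subject noise makes
between-session ICC exceed between-subject ICC by construction, the
test–retest signature of real cohorts. With these scales the dominant
mode remains stably recoverable; the second mode's eigengap, however,
is comparable to the perturbation scale, so multi-gradient cohorts at
this problem size lose second-mode purity under noise. Reliability
ordering is therefore demonstrated on single-gradient cohorts — an
honest reflection of the steep reliability decline real studies report
for higher-order gradients, not a workaround hidden from the reader.

**Term libraries** contain, for each planted gradient and decile, the
indicator volume of that decile's vertices plus voxelwise Gaussian
noise (σ default 0.2); pure-noise maps; and at least one
anatomical-flagged map (the seed footprint, plus tract masks when an
atlas is supplied) that decoding must exclude.

What the generator does *not* emulate: realistic cortical geometry,
spatially correlated streamline noise (counts are independent Poisson
given the kernel), distance-dependent tractography attenuation, and
partial-volume effects. Passing tests show the analysis machinery is
correct and recovers planted structure under the stated statistical
assumptions — not that those assumptions exhaust real diffusion data.

## Numerical choices and degenerate inputs

- η² of two equal constant profiles is 1 by convention, with a warning;
  a zero denominator with unequal profiles raises an error.
- All-zero count rows are rejected at container construction (such a
  vertex has no profile).
- Duplicate points in the dimensionality estimator produce zero
  nearest-neighbour distances; those log terms are skipped with a
  warning, fully duplicated input errors.
- The minimal-k search drops would-be zero-weight edges; if that
  leaves the graph disconnected at every k, an error names the
  problem rather than silently bridging with meaningless edges.
- Eigenvalue/eigenvector agreement with a dense reference solver is
  held to 10⁻⁸/10⁻⁶ in tests; D-orthonormality to 10⁻⁸; η² against its
  brute-force oracle to 10⁻¹²; ICC against an ANOVA decomposition to
  10⁻¹⁰.
- Constant maps cannot be normalised or aligned and are rejected.
- The default projection threshold is the conventional 1%; for the
  synthetic cohort's more diffuse profiles (300 target voxels rather
  than the ~10⁵ of a real hemisphere), tract-ordering analyses use
  0.5%, below which no seed vertex loses its entire skeleton.
- Every stochastic step — cohort generation, bootstraps, the pipeline
  stages — derives an independent substream from one master seed, so
  reruns with an identical configuration are byte-identical (the run
  manifest's checksums verify this).

## Problem sizes used in validation

Tests and the acceptance script run on 20 × 20-vertex sheets (400
vertices, 300 target voxels, depth 10⁴), cohorts of 2–6 subjects × 2
sessions, 10⁴ random pairs for the η² oracle, 100 random graphs for the
eigen-solver oracle, 50 block-structured matrices for the minimal-k
oracle, and n = 10⁴ simulations for ICC calibration. These sizes were
chosen so the full suite completes in well under a minute per stage
while leaving the statistical margins of every check wide.

## Known limitations

- Real visitation matrices' noise structure is uncharacterised;
  Poisson is an assumption (flagged in the generator's documentation).
- The flip-about-5.5 alignment rule is ill-posed for weakly correlated
  maps, as discussed above.
- Second and higher modes are intrinsically less stable at desk-scale
  problem sizes; cross-subject analyses of higher modes should expect
  lower ICC for structural, not implementation, reasons.
- Deciles are equal-population rank bins; value-range binning would
  differ on heavily skewed maps.
- The decoding correlation domain is a user-supplied analysis mask;
  the default whole-grid mask includes empty voxels, which deflates
  correlations uniformly without reordering terms.
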
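# connectopy

Connectopic mapping for diffusion-tractography data: recover overlapping
**connectivity gradients** of a cortical region from a seed-vertex ×
target-voxel streamline visitation count matrix, and carry them through
to white-matter tract projections, test–retest reliability statistics,
and meta-analytic functional decoding.

## Who this is for

Researchers analysing probabilistic-tractography output (e.g. FSL
PROBTRACKX "matrix2" matrices) who want the full gradients workflow —
similarity, embedding, normalisation, alignment, group averaging,
projection, reliability, decoding — as tested, composable R functions,
plus a synthetic-cohort generator with planted ground truth so every
stage can be validated without imaging data.

## The method

Each seed vertex *i* has a connectivity profile: its row of visitation
counts over target voxels. Profiles are compared with the η²
coefficient — with *m* = (*a* + *b*)/2 and *M̄* its grand mean,

    η²(a, b) = 1 − [ Σᵢ (aᵢ − mᵢ)² + (bᵢ − mᵢ)² ] /
                   [ Σᵢ (aᵢ − M̄)²  + (bᵢ − M̄)²  ]

which is 1 for identical profiles and 0 when all variance lies within
pairs. The η² matrix becomes a weighted k-nearest-neighbour graph with
the smallest k giving a single connected component. Laplacian eigenmaps
then solve the generalised eigenproblem **L v = λ D v** (L = D − W);
after discarding the trivial constant eigenvector, the eigenvectors of
the smallest eigenvalues are the gradients, each affinely normalised to
[1, 10] ("connectopic maps"). The number of modes common to a cohort is
the floor of the minimum per-subject Levina–Bickel maximum-likelihood
intrinsic dimensionality estimate. Individual maps are aligned to a
reference subject — a map is reflected about the 5.5 midpoint when its
Pearson correlation with the reference falls below 0.75 — and averaged
vertexwise into group maps.

Downstream, each gradient is (a) projected into white matter: every
voxel visited by at least a threshold fraction (default 1%) of a
vertex's streamlines takes the count-weighted mean gradient value of
the top-3 vertices reaching it, and projection images are split by
binary tract masks and summarised per tract with bootstrap CIs;
(b) assessed for reliability with ICC(2,1) — two-way random effects,
absolute agreement, single measure — between sessions (same subject)
and between subjects (same session), with percentile-bootstrap CIs of
the means; (c) functionally decoded: the group map is split into ten
equal-population rank deciles, each binarised decile volume is
correlated with every map in a term library, and the top three
positively correlated non-anatomical terms (one per synonym group) are
reported per decile.

## Worked example

Simulate one noiseless subject with two planted overlapping gradients
and recover them:

```r
library(connectopy)

mesh  <- make_seed_mesh(20, 20)                  # 400-vertex seed sheet
truth <- plant_gradients(mesh, m_true = 2)       # two latent gradients
spec  <- cohort_spec(n_subjects = 1, n_sessions = 1, depth = 1e4,
                     sigma_subject = 0, sigma_session = 0, rng_seed = 7)
cm <- simulate_connectivity(truth, n_targets_per_tract = 50, spec,
                            subject = 1, session = 1, mesh = mesh)
cm
#> connectivity_matrix: 400 seed vertices x 300 target voxels (grid 20x20x8), 10000 streamlines/vertex

map <- fit_connectopic_map(cm, m = 2)            # eta^2 -> kNN -> eigenmaps
map
#> connectopic_map: 400 vertices x 2 mode(s) (subject 1, session 1)

round(abs(cor(map$values, truth$latent_fields, method = "spearman")), 3)
#>    field1 field2
#> g1  0.022  0.979
#> g2  0.994  0.037

round(map$eigenvalues, 5)
#> [1] 0.00400 0.00941

estimate_intrinsic_dimension(attr(map, "similarity"))
#> [1] 1.78828
```

The recovered modes match the planted gradients almost perfectly
(|Spearman ρ| = 0.98 and 0.99 after pairing — which planted field maps
to which mode, and its sign, are arbitrary), the eigenvalues are
strictly ordered, and the intrinsic-dimensionality estimate of the
similarity structure is ≈ 2, the number of planted gradients.

`run_pipeline(run_config(out_dir = "out"))` executes the whole chain —
simulate → gradients → project → icc → decode — writing MatrixMarket
matrices, GIFTI surface maps, NIfTI volumes, TSV tables and a JSON run
manifest. A thin command-line wrapper with the same stages lives at
`inst/cli/connectopy.R`.

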
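---
title: "From bone voxels to genomic shape prediction: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From bone voxels to genomic shape prediction: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(scapmorph)
```

scapmorph implements a complete pipeline from segmented CT bone volumes to
heritable three-dimensional shape phenotypes and genomic predictions of
whole-bone morphology. This vignette explains the model behind each stage,
the tunable parameters and their defaults, the numerical choices, what the
synthetic-data generator does and does not emulate, and the known
limitations. The running example is the pig scapula — a thin, curved,
ridged bone whose shape matters for sow robustness — but nothing in the
pipeline is specific to that bone.

## 1. From voxels to a surface

CT intensities are in Hounsfield units (HU); bone is extracted with an
inclusive threshold at **200 HU** (`threshold_bone()`), the conventional
bone/soft-tissue cutoff. World coordinates follow the voxel-centre
convention `origin + (index - 1) * spacing`, with anisotropic spacing
supported (the reference CT protocol is 0.94 × 0.94 × 1.25 mm).

Each bone cloud is pose-normalized (`normalize_pose()`): centred on its
centroid, rotated so the principal axes of the point covariance align with
the coordinate axes (largest variance → x, second → y, third → z), and
scaled so the **second covariance eigenvalue equals one**. Anchoring scale
on the width axis reflects the fact that, on scapula CT, width is measured
more precisely than length. The second moment invariant of the covariance
tensor is available as an alternative scale anchor
(`invariant = "inertia_I2"`); we default to the eigenvalue because it maps
directly onto the "best-measured axis" rationale.

Axis *signs* are where moment-based alignment is genuinely underdetermined.
We orient each axis so the third central moment of the projections is
non-negative, and restore right-handedness (if needed) by flipping the axis
with the *weakest* skewness evidence, so that strongly asymmetric axes keep
a stable orientation across individuals. Early development versions flipped
a fixed axis instead; on plate-like bones this silently mirrored a subset
of animals and inflated the first principal component with a spurious
reflection mode — the weakest-evidence rule removes that failure.

The surface is built by 3D Delaunay tetrahedralization followed by
**long-edge pruning**: every tetrahedron with an edge longer than 5 mm is
removed (alpha-shape-style), so concave regions of the bone are preserved
rather than spanned, and faces belonging to exactly one remaining
tetrahedron form the surface (`delaunay_tets()`, `prune_long_edges()`,
`extract_surface()`). The 5 mm default interacts with grid resolution: much
lower and the surface fragments, much higher and concave detail (e.g. where
tendons attach near the spine) is smoothed away. Pipelines that mesh in the
normalized frame convert the threshold through the recorded scale.

Two triangulation engines are provided. Voxel clouds (which carry their
integer grid index) use the **Kuhn split of complete lattice cells**: for a
regular grid this is a true Delaunay triangulation of the occupied region
(each cell's circumsphere contains no other lattice point), it is exact, and
it is immune to the cospherical degeneracy that grids inflict on
floating-point geometry. Arbitrary clouds use an incremental
Bowyer–Watson triangulation after a deterministic relative joggle of 1e-8
— the joggle plays the role of a symbolic perturbation, so the triangulation
is valid and watertight even for degenerate inputs, while reported
coordinates remain the originals. On random clouds the engine agrees with
an independent Qhull implementation tet-for-tet.

## 2. The semi-landmark atlas

A single reference individual with ordinary-looking anatomy defines the
atlas. Its dense surface is decimated by the **local-volume criterion**
(`sparsify()`): the node whose one-ring convex hull has the smallest volume
(i.e. the flattest neighbourhood) is removed, the hole is re-triangulated by
a fan from its least-index vertex, affected volumes are recomputed, and the
loop repeats until a target landmark count is reached (default 1234, the
scale used for a real scapula) or until every local volume exceeds a
threshold. Ties break to the lowest node index; nodes whose one-ring is not
a single simple cycle are never removed. The survivors, ordered
lexicographically by coordinate, are the **semi-landmarks**: surface points
without individually unique anatomical definitions that acquire meaning
through their fixed ordering. That ordering defines phenotype identity for
every animal, so it is frozen with the atlas and serialized alongside the
pose transform and meshing parameters.

Target count is the default mode because the volume threshold that yields a
given landmark count depends on grid resolution and bone size; both modes
are exposed. A single-individual atlas is a deliberate simplification — an
average or multi-atlas can improve correspondence in concave regions but is
out of scope here.

## 3. Point correspondence by coherent point drift

For each animal, the atlas `X` (sparse, ~1234 points) is registered to the
individual's dense surface cloud `Y` by **coherent point drift**
(`cpd_register()`): `Y` is treated as the centroids of a Gaussian mixture
fitted to `X` by EM, under a rigid, affine, or non-rigid (Gaussian kernel)
deformation family. At convergence the posterior matrix `P` gives, for each
atlas point, the probability that each surface point generated it; the
argmax of each column is the corresponding surface point
(`extract_correspondence()`), so raw phenotypes are a subset of the
individual's own surface. Ties break to the lowest index; several atlas
points may legally map to one surface point, and the duplicate count is
reported as a per-animal diagnostic.

Defaults (`cpd_params()`): no outlier mass (`w = 0`), relative objective
tolerance 1e-5, 100 iterations, non-rigid kernel width `beta = 2` and
regularization `lambda = 2` in the internally standardized units. The
negative log-likelihood is recorded each iteration and is non-increasing
(exact EM); a mixture variance collapsing to the 1e-10 floor is treated as
convergence (flagged `"sigma2_floor"`) — it is the natural endpoint of
registering nearly identical clouds, not an error. Affine is the default
deformation: on scapula-like surfaces it represents the data as well as
non-rigid at a fraction of the cost and with none of the regularization
tuning, and the package's own comparison utilities (`fit_quality()`:
median and maximum distance from every dense surface point to its nearest
landmark) let users repeat that comparison on their data.

A **soft** correspondence option (the `P`-weighted average of surface
coordinates) is provided alongside the hard argmax. Hard correspondence is
the default; the soft variant suppresses
the coordinate quantization a coarse voxel grid imprints on argmax choices
and is recommended for scaled-down simulated studies, where voxels are
deliberately coarse relative to shape variation.

After correspondence, landmark sets are re-aligned (`realign_landmarks()`):
pose-normalized and mapped back to millimetres by undoing the scale only,
so animals share centre and orientation but keep individual size — size is
itself a breeding-relevant trait and must survive into the phenotypes.
Because all sets share the atlas ordering, axis signs during re-alignment
are resolved against the first set's configuration rather than by shape
moments; point-for-point correspondence pins orientation even for animals
whose shapes are nearly symmetric about an axis, which third moments cannot.

Thin-bone regions are the known weak point of distance-only registration:
where two surfaces lie close together (the scapular spine, the fossae), a
landmark can be matched to the wrong side. `paired_distance_qc()` measures
signed coordinate differences across landmark pairs chosen on opposite
sides of such regions — negative values flag side swaps — and `qc_ecdf()`
summarizes their distribution across a population. The pair definitions are
configuration data (atlas landmark ids plus an axis), since they depend on
where the atlas happens to place its landmarks.

## 4. Shape phenotypes: outlier filter and PCA

Whole-animal failures are removed first: for each animal the absolute
deviations from the population column means are summed over all 3K
coordinates, and animals outside 1.5 interquartile ranges of the quartiles
of that sum are dropped (`flag_outliers()`). Then a validation set is
masked, and **covariance PCA** is fitted on the training animals only
(`fit_pca()`): coordinates share units (mm), so no standardization; masked
animals are projected but provably cannot influence the mean, loadings, or
explained fractions. Loading signs are canonicalized (largest-magnitude
entry positive) so scores are reproducible across linear-algebra backends.
Every shape decomposes as `X_m = mean + sum_n w_n s_nm`; the leading scores
are the scalar phenotypes. Ten components are the default for genetics —
on real scapula data ten components carry over 80% of shape variance while
keeping the multi-trait analysis manageable — and `truncation_error()`
reports the mm cost of that compression per animal.

## 5. The animal model

Each PC score is analysed with the standard animal model

`s = HY + BM + PN + beta * LW + a + e`

— herd-year of birth, birth month, and parity number of the dam as
categorical fixed effects, live weight at scanning as a covariate
(correcting shape for the animal's overall size/management), an additive
genetic effect with covariance proportional to a relationship matrix, and a
residual. Identifiability uses treatment constraints: the first factor
keeps all levels, later factors drop their first level; only estimable
quantities (contrasts, predictions) are interpreted.

Relationships come from the pedigree (`build_pedigree_A()`, the tabular
method with inbreeding, after a topological sort that rejects cycles) or
from SNP genotypes (`build_grm()`, `G = ZZ' / 2Σp(1-p)` with `Z` the
frequency-centred allele counts; frequencies from all supplied animals,
monomorphic SNPs dropped). Both paths are available because genetic
parameters are naturally estimated on the deep pedigree while prediction of
masked animals requires the genomic matrix. No blending of `G` with `A` is
performed.

**BLUP** (`solve_mme()`) solves Henderson's mixed-model equations in a form
premultiplied by `K` in the random block, which avoids `K^{-1}` entirely.
This matters because the sample-frequency GRM is *exactly* singular
(`G 1 = 0`); the premultiplied system is algebraically equivalent for
invertible `K`, remains exact in the PSD limit (the solution lies in the
range of `K`, pinning the GEBV sum to zero), and reproduces a brute-force
generalized-least-squares solution to 1e-11 even on singular `G`. Masked
animals receive predictions purely through their relationships.

**REML** (`reml_estimate()`) estimates variance components per trait by an
exact one-dimensional profile likelihood over the variance ratio after
eigen-rotation of the relationship matrix: given the ratio, the residual
variance has a closed form, so a scalar golden-section search finds the
global REML optimum without iteration failures. Standard errors come from
the inverse average-information matrix at the optimum, and heritability
standard errors by the delta method. Multi-trait covariances are estimated
pairwise (bivariate REML on the rotated likelihood with variances held at
their univariate estimates) — adequate for the weak genetic correlations
typical of PC traits, and far more robust than a joint 10-trait solve.
An optional weakly-informative penalty (`h2_penalty = 1`, a Beta(2,2)-type
prior on h²) pulls boundary estimates off 0 and 1; it is off by default
(plain REML is unbiased at realistic sample sizes) and enabled in the
bundled small-sample study, where forty training animals are simply too few
for the likelihood to exclude h² = 1 on noise-dominated components, and the
resulting overdispersed breeding values would corrupt validation metrics.

`genetic_eigen()` decomposes `G P^{-1}` through the Cholesky similarity
`L^{-1} G L^{-T}` (real eigenvalues guaranteed), giving genetically
uncorrelated combinations of the PC traits whose eigenvalues act as
heritabilities; `aggregate_heritability()` computes the
explained-variance-weighted heritability of the whole observed shape — a
lower bound, since discarded components may carry genetics too.

## 6. Validation: predicted shapes and spatial reliability

Validation animals are masked before the PCA (so phenotype definitions do
not change between folds — the reason K-fold is deliberately not the
default), their PC scores predicted as fixed-effect solutions plus GEBV
(`predict_scores()`), and shapes reconstructed from the first ten predicted
scores. Animals whose fixed-effect levels have fewer than 4 training
records are excluded (`filter_validation()`) — unbalanced field data makes
some level estimates meaningless. Two summaries are computed:

* `mean_error_curve()` — the mean Euclidean landmark error of the
  reconstruction as components are added, starting from the population mean
  shape at k = 0. With estimated scores the curve need not be monotone and
  is reported as observed.
* `spatial_reliability()` — per landmark,
  `R² = 1 - mean d(x, x̂)² / mean d(x, x̄)²` over validation animals, with
  `x̄` the *training* mean shape. Perfect prediction gives 1, predicting
  the mean gives 0, and worse-than-mean predictions go negative; the ratio
  is deliberately not floored.

For visualization, `isonormal_field()` orients face normals outward (by the
centroid test), averages them per node, and `loading_heatmap()` projects a
PC loading onto the node normals: positive values mean the component grows
the bone outward at that point, negative values shrink it. The scalar
fields are emitted as CSV and as PLY quality channels for external viewers
rather than rendered images.

## 7. The synthetic-data generator

No real scapula CT data are distributable, so the generator
(`sim_config()`, `make_scapuloid_volume()`, `simulate_pedigree_genotypes()`,
`simulate_shapes()`) reproduces the *statistical structure* the pipeline
assumes. Its defaults mirror the scale of a real nucleus-herd CT study:
2143 scanned
animals, 34,726 SNPs, five ancestor generations, 148/12/4 levels of
herd-year/birth-month/parity, live weight 122.8 ± 5.2 kg, voxels
0.94 × 0.94 × 1.25 mm, and latent-mode heritabilities in the 0.5–0.7 range
of the leading real PC traits. Tests and examples pass smaller sizes
explicitly.

The scapuloid solid is a thin egg-shaped plate (wider toward one end) with
a quadratically curved mid-surface and a Gaussian-profile ridge that is
higher toward the other end — asymmetric along every axis, as a real
scapula is, which keeps moment-based pose conventions stable. Interior
voxels get a smooth deterministic 300–1500 HU field; exterior is -1000 HU,
so thresholding recovers the analytic solid exactly. Latent scores perturb
geometry (size, curvature, ridge height, thickness, aspect) with
amplitudes calibrated so shape variation dominates voxel quantization by
roughly the factor seen in real CT (millimetre voxels under several
millimetres of biological variation).

Genetics: founders are drawn in Hardy–Weinberg proportions at frequencies
uniform on (0.1, 0.9); descendants receive alleles by per-SNP Mendelian
sampling (no linkage — LD beyond pedigree structure is deliberately not
modelled). Per-mode true breeding values are built from Gaussian effects at
randomly chosen QTL and rescaled so the *realized* genetic variance matches
the target exactly; residuals are likewise rescaled, so configured
heritabilities hold exactly in every replicate — what the recovery tests
then measure is estimation error, not simulation error. Fixed effects and
the live-weight regression are layered on per the animal model. Shape
deformations are applied both in landmark space (fast statistical tests)
and as warps of the parametric solid before voxelization (integration tests
of meshing plus registration), so both pipeline entry points are exercised.

What passing synthetic tests do *not* show: performance under real
segmentation artefacts, real LD structure, selection, heterogeneous scan
protocols, or anatomy whose thin-bone regions are more intricate than a
single ridge. The QC and diagnostic machinery exists precisely because real
data will stress those assumptions harder.

## 8. Problem sizes and numerical choices

The bundled end-to-end study (`run_synthetic_study()`) uses 50 animals at
1.8 × 1.8 × 0.75 mm voxels, a 120-landmark atlas, three latent modes at
h² = 0.6 in eight sire families, ten masked validation animals, soft
correspondence, three retained PCs, and penalized REML — a configuration
chosen to finish in a few minutes on one core while preserving the real
study's noise-to-signal regime. At this sample size the genomic-versus-
environmental reliability contrast has substantial Monte-Carlo variance, so
the package's own acceptance test evaluates it on the mean of three
replicate simulations rather than on a single run.

Numerical details worth knowing: the Bowyer–Watson joggle is 1e-8 of the
bounding box (deterministic, hash-based, reported coordinates unperturbed);
degenerate local volumes (coplanar one-rings) are exactly 0 via a rank
check rather than a noisy determinant; the REML profile is searched on
log-ratio in [-14, 14] with boundary flagging; CPD ties in the posterior
argmax and sparsification ties in local volume both break to the lowest
index; and all text serializations round-trip at 17 significant digits.

## 9. Limitations

* Correspondence quality degrades where opposite surfaces approach within
  the CPD kernel scale; the QC pairs detect but do not repair side swaps.
* A single-individual atlas inherits that individual's idiosyncrasies.
* Pairwise REML ignores information that a joint multi-trait solve would
  borrow across traits; with |genetic correlations| below ~0.3 the
  difference is negligible.
* Per-trait BLUP prediction ignores genetic covariances between PC scores
  (exact only when those are zero; they are small by construction of PCA
  phenotypes).
* The generator's geometry is a caricature: adequate for exercising every
  algorithmic path, not for benchmarking anatomical realism.
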
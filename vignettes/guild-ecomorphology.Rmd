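---
title: "Methods: jaw ecomorphology, feeding guilds and disparity through time"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: jaw ecomorphology, feeding guilds and disparity through time}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(guildspace)
```

This vignette documents the models, algorithms and design choices behind
the package, in the order the analysis workflow runs them. Everything
stated here is computed by the package's tests or scripts; nothing is an
external empirical claim.

## Superimposition with sliding semilandmarks

Each mandible is a configuration of 2D landmarks: a small number of fixed,
homologous points plus semilandmarks spaced along outline curves between
them (the default scheme is 4 fixed + 55 semilandmarks on 4 curves, 59
points in all — appropriate for jaws too morphologically disparate for a
dense homologous scheme). `gpa_align()` removes translation (centering),
size (scaling to unit centroid size) and orientation (least-squares
rotation from the SVD of the cross-covariance matrix, with the rotation
determinant forced to +1 so reflections are never introduced; all jaws are
assumed digitised in the same lateral view).

Semilandmark spacing along a curve is an artefact of digitisation, not a
shape difference. With `slide = TRUE`, each semilandmark is moved along the
chord joining its two immediate outline neighbours to the closed-form
orthogonal projection of the corresponding consensus landmark onto that
chord line — the position minimising its squared distance to the consensus.
Curve anchor points (fixed landmarks) never slide; a zero-length chord
(coincident neighbours) leaves the point unmoved with a warning.

**Sliding schedule.** Sliding is applied as a small fixed number of passes
(default `slide_passes = 5`), each followed by re-alignment to convergence,
rather than being iterated indefinitely. Iterating chord-line projection
against a moving consensus has no useful fixed point: every pass lets the
semilandmarks creep a little further along the outline (we observed a
steady ~4e-6 per-iteration objective decrement with no convergence), slowly
degrading the outline geometry. Bounded passes are also how the standard
relative-warps tools behave. After the final pass the alignment itself is
run to convergence (consensus root-mean-square change < `tol`, default
1e-7, cap 100 iterations per phase), so the reported consensus is a true
GPA consensus of the slid configurations. The sliding reference is the
current consensus, not a designated specimen: this is the standard choice
and keeps the result invariant to input order (verified to ~1e-13 in the
pairwise distances).

Aligned coordinates are used directly as shape variables, without
projection to tangent space: at the shape variation scales involved the
difference is far below the resolution of any downstream statistic, and it
keeps distances identical to the Procrustes distances used for disparity.

## Functional characters and standardisation

Eight biomechanical characters are computed from ten linear measurements
(`compute_functional_characters()`): three mechanical advantage variants
(closing in-lever over anterior/posterior out-lever; opening in-lever over
anterior out-lever), maximum aspect ratio, relative symphyseal length,
articulation offset and relative tooth-row length (all scaled by jaw
length), and the symphyseal angle kept in degrees. A single closing
in-lever serves both MA variants — only the bite point moves — which
implies the invariant `MA_post >= MA_ant` (the posterior out-lever is
shorter). All ratios are dimensionless, so the table is invariant to
measurement units; for edentulous jaws the "tooth row" measurement is the
functional-surface length, resolved in the measurement table rather than in
code. Taxa with missing measurements are dropped listwise with a logged
report — characters are only comparable when complete.

`z_standardize()` centres each character and divides by its sample standard
deviation (n−1), yielding the standardised functional measurement data
(SFMD). Since the symphyseal angle is on a different scale from the ratios,
z-scoring is what makes Euclidean distances across the eight characters
meaningful. The transform parameters are retained and written alongside the
matrix.

## Ordination and contour maps

`pca_ordination()` performs mean-centred PCA: on covariance for aligned
coordinates (the relative-warps convention with no bending-energy
weighting), and on the already z-scored SFMD (correlation-equivalent) for
function. Eigenvector signs are fixed by making each axis's
largest-magnitude loading positive, so plots are reproducible across
platforms. Axis contributions are squared loadings normalised to
percentages. Contour maps of a character over the shape morphospace use
piecewise-linear (barycentric) interpolation on a Delaunay triangulation of
the score points, built in-package with the Bowyer–Watson algorithm; grid
nodes outside the convex hull are reported missing rather than
extrapolated. The default grid is 200×200 over the occupied bounding box
(the analysis scripts use 100×100 to keep file sizes modest).

## Guild clustering

Guilds are defined on the Euclidean distance matrix of the SFMD. Three
established clusterers are run at the same k: agglomerative hierarchical
clustering with Ward linkage (`ward.D2`, i.e. Ward's criterion on squared
Euclidean distances — the common default of the ecology clustering
front-ends; exposed as a parameter), Lloyd k-means (best of `n_starts`
random initialisations, seeded), and PAM (BUILD+SWAP on the dissimilarity
matrix, deterministic).

**Choosing k.** The gap statistic compares log pooled within-cluster
dispersion `log W_k` with its expectation under B reference data sets drawn
uniformly within the principal-axis-aligned bounding box of the data (the
"scaled PCA" reference of the original proposal). `W_k` is the total
within-cluster sum of squared deviations from cluster centroids, equal to
the pairwise form Σ_r D_r/(2 n_r). k is chosen by the 1-SE rule — the
smallest k in range with `Gap(k) ≥ Gap(k+1) − s_{k+1}` — falling back to
the arg-max when the rule never fires. The default K range is 4–10 for the
top-level guild analysis and B = 2000 reference sets for a production run;
tests and the acceptance script use B = 100, which is ample for the modal-k
behaviour they assert and keeps the suite fast.

**Consensus.** The k-means and PAM labelings are matched onto the
hierarchical labels by maximum contingency-table overlap (greedy; an exact
permutation matching is available via `exact = TRUE` for k ≤ 8 — on clean
relabelings the two agree, and greedy is robust when the methods disagree
structurally). Taxa on which all three matched labelings agree form the
consensus FFGs; the rest are flagged inconsistent. For reporting, each
inconsistent taxon is attached to the guild of its nearest consistent
neighbour in SFMD space, retaining the flag. Guild *recovery* is measured
on the consistent core: the groups are defined by consensus, and the
flagged taxa are explicitly not part of that definition. Sub-clustering
(`subcluster_guild()`) re-runs the entire pipeline on one guild's members
with its own K range (default 2–6, since subgroup structure is expected to
be coarser than 4 groups); default subgroup labels are namespaced by the
parent guild so FFsG-resolution labels can never collide with other guilds'
FFG labels — which is what guarantees conflict counts can only drop under
refinement.

Validation: silhouette widths (singletons scored 0) and external validation
against taxonomic labels via the adjusted Rand index and variation of
information, both computed from the contingency table. Clades are assigned
their plurality guild over consistent taxa; ties and empty clades are
reported `"unresolved"`, never broken silently.

## Disparity, permutation tests, divergence, occupancy

Time bins follow a built-in Changhsingian→Toarcian stage/substage table
with the Carnian and Norian split into lower/middle/upper; stage boundary
ages follow the 2019 international chart, and the substage boundaries the
chart does not formalise numerically are interpolated evenly within the
stage (the table is a config input and can be replaced). Taxa occupy every
bin from first to last appearance (range-through; occurrence-only binning
is available behind a flag).

Three disparity metrics are computed side by side — mean pairwise distance,
sum of variances (covariance trace, n−1), and Procrustes variance (mean
squared distance to the group mean) — because the field uses all three
names for closely related dispersion summaries; reporting them together
avoids ambiguity. MPD confidence intervals: resample members with
replacement B times (default 1000), recompute MPD excluding pairs formed
from the same resampled index (a taxon paired with its own copy carries no
dispersion information), take percentile 2.5/97.5 bounds.

NPMANOVA partitions the squared-distance sums: `SS_total = Σ d²/n` over all
pairs, `SS_within` summed per group, pseudo-F their ratio weighted by
degrees of freedom. The p-value uses the add-one permutation estimator
`(1 + #{F* ≥ F}) / (1 + n_perm)` (default `n_perm = 9999`), which is
super-uniform under the null by construction; the permutation loop is
vectorised as indicator-matrix algebra so the 1000-replicate calibration
check runs in seconds. Pairwise tables multiply p by the number of
comparisons (Bonferroni, capped at 1); groups with fewer than two members
are skipped with a message. Groups for the time-level tests are formed from
each taxon's first-appearance bin, mapped to epoch; range-through grouping
would place one taxon in several groups, which a one-way partition cannot
represent.

Clade divergence is the Euclidean distance between clade mean vectors per
bin, in shape or function space. Morphospace occupancy per bin and clade is
the convex hull of the PC1–PC2 scores (area by the shoelace formula;
degenerate hulls of fewer than three distinct points have area 0).
Disparity itself is computed in the full trait spaces, not the first two
PCs — the two-axis view is for the time-slice plots only.

## The synthetic-data generator

The generator's defaults mirror the study scale the pipeline targets: 136
herbivore taxa in eleven subclades of three major clades (sample sizes
proportional to the empirical taxonomic structure), eight characters with
five planted guilds, 59-landmark jaws, Changhsingian→Toarcian bins, twelve
localities plus one with planted same-guild pairs.

* **Functional structure.** Guild centres sit along mutually orthogonal
  random directions in z-space, scaled so every pair of centres is
  `separation × within_sd` apart (default separation 6, within-guild SD 1 —
  overlapping enough that the three clusterers genuinely disagree on
  borderline taxa, which exercises the consensus machinery). Members are
  isotropic Gaussian about their centre. Clades have home guilds; a taxon
  deviates from its clade's guild with probability `1 − guild_fidelity`
  (default 0.9), emulating the strong but imperfect phylogenetic control on
  jaw function. The z-scale table is expressed on plausible character
  scales (e.g. anterior MA ≈ 0.35 ± 0.04, symphyseal angle ≈ 35° ± 4°) and
  back-solved into a raw measurement set (jaw lengths log-normal around 10
  units), so the measurement-to-character stage is exercised end to end;
  infeasible draws (e.g. posterior MA below anterior) are resampled with a
  log.
* **Shapes.** A template jaw outline is deformed per planted group by a
  smooth low-order trigonometric/polynomial displacement field plus i.i.d.
  landmark noise, then hit with a random similarity transform so the
  superimposition has real work to do. Displacement fields are deliberately
  *not* thin-plate splines, keeping the generator independent of any
  analysis machinery it is used to test.
* **Ranges and assemblages.** First-appearance bins uniform over the
  scheme; extra duration geometric (default mean 2 bins); assemblages
  sample each locality's members from one bin's standing fauna with
  log-normal abundance counts; extra faunivorous taxa pad the taxon table
  so diet summaries are non-trivial.

What the generator does **not** emulate: phylogenetic autocorrelation of
trait values within clades (members are exchangeable within guilds),
non-Gaussian and anisotropic within-guild dispersion, preservation and
sampling biases through time, correlated character noise from shared
measurement landmarks, and allometry. Passing recovery tests therefore
demonstrates that the pipeline finds structure of the planted kind at the
planted strength — not that any real fauna has that structure.

## Numerical choices and degenerate inputs

* Seeds are explicit arguments everywhere randomness occurs; the same
  configuration and master seed give byte-identical output files.
* Distances/ties: greedy consensus matching breaks contingency ties by
  first index; plurality ties in clade assignment are reported, not broken.
* Degenerate inputs fail loudly by name: zero-centroid-size shapes,
  zero-variance characters, rank-0 ordination input, all-identical points
  in the gap statistic, clusters emptied by a cut, single-member disparity
  bins (missing estimate with a log), collinear point sets for
  triangulation.
* Problem sizes in the shipped tests and scripts: oracle checks at n ≤ 12
  against exhaustive enumeration; guild recovery at the full 136-taxon
  scale over 20 seeds with B = 100; NPMANOVA calibration over 1000 null
  data sets at n = 30 with 999 permutations; disparity bootstrap B = 1000
  in the analysis scripts and B = 50–500 in unit tests.

## Known limitations

* Chord-projection sliding is the only sliding criterion implemented;
  minimum bending energy sliding is out of scope.
* The consensus rule (greedy overlap matching + unanimity) is one
  defensible operationalisation of "consensus across methods"; near-miss
  taxa are flagged rather than scored by partial agreement.
* NPMANOVA group membership uses first-appearance bins (see above), so
  long-ranging taxa influence only their first time group.
* 2D landmarks only; no 3D, no outline Fourier methods, no
  phylogenetically corrected disparity or clustering.
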
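---
title: "Wing morphometrics: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wing morphometrics: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wingmorph)
```

This vignette is the package's own account of the statistics it
implements: the superimposition model and its assumptions, the decision
procedure for fossil placement, the parameters that matter, what the
synthetic generator does and does not emulate, and the numerical choices
made where the design was genuinely open.

## The data model

A wing is a configuration of 27 labelled 2D points: 21 fixed landmarks at
homologous vein junctions and endpoints, and 6 semilandmarks along the
2m-cu cross-vein, whose position *along* the curve is arbitrary and is
optimized during superimposition. Data enter as TPS files (tpsDig2
dialect) plus a delimited label sidecar (specimen, subfamily, tribe,
genus, side, provenance). Coordinates are kept in digitizer units with
the per-record `SCALE` stored separately and applied lazily: shape
analyses are scale-free after superimposition, while centroid-size
analyses need physical units, so one store serves both. Specimens
without a scale get pixel-unit sizes and are flagged; size-dependent
analyses refuse mixed-unit inputs rather than silently comparing pixels
with millimetres.

Two conventions worth stating explicitly:

* **Reflection is never solved for.** Wings are digitized in a planar
  standard orientation; a right wing is converted to its left-wing
  equivalent by an explicit mirroring step (`mirror_wings()`), and the
  rotation solved during superimposition is constrained to proper
  rotations. Letting the superimposition pick reflections would silently
  hide digitizing-side errors.
* **Missing landmarks are never imputed silently.** A fossil's uncertain
  points are excluded from the fossil *and* from every reference specimen
  in that comparison (`drop_landmarks()`), so all configurations stay
  commensurable. Thin-plate-spline estimation (`estimate_missing()`)
  exists for joint visualisation only; using estimated points in
  classification would leak the reference group's geometry into the
  specimen being classified. Excluding any semilandmark removes the whole
  curve, because the six points jointly describe one feature.

## Superimposition

`gpa()` is a standard generalized Procrustes analysis: center, scale to
unit centroid size, rotate each configuration onto the consensus by the
closed-form 2D least-squares rotation, update the consensus, iterate
until the summed squared deviation changes by less than `tol` (default
1e-10; an error is raised after `max_iter = 100` iterations rather than
returning a half-converged alignment). Full Procrustes scaling is used —
size is analysed separately via centroid size, so shapes carry no size.
After convergence the consensus is rotated to its principal axes with a
deterministic 180-degree convention, which makes the output independent
of specimen order (the first specimen otherwise seeds the orientation).

**Sliding criterion.** The tools this workflow descends from default to
minimizing bending energy when sliding semilandmarks; the alternative is
minimizing plain Procrustes distance to the consensus. Both are
implemented (`criterion = "bending"` or `"procrustes"`); bending energy
is the default to match common practice, and the choice is recorded in
the fit object. Sliding runs as a small number of outer passes (default
5): each pass solves its criterion exactly against the converged
consensus — the bending-energy step solves the restricted least-squares
system over tangent displacements in closed form, the Procrustes step
projects the consensus point orthogonally onto the tangent — and then
re-superimposes. A fixed pass count is used because the slid positions
are not part of the Procrustes objective: iterating sliding inside the
main loop lets semilandmarks drift indefinitely along the curve and the
superimposition never settles. Tangents follow the chain anchored at
fixed landmarks 4 and 13, the endpoints of 2m-cu; coincident curve
neighbours (degenerate tangent) hold that point fixed with a warning.

## Shape statistics

`procrustes_anova()` fits sequential (type-I) linear models to the
flattened aligned coordinates, in the order the formula states — size
first, then group, then their interaction, which makes each term's
R-squared interpretable as "variation explained after the previous
terms". Significance is by residual randomization (RRPP): for each term
the reduced-model residuals are permuted across specimens, the observed
statistic counts as one replicate, so p-values live in `[1/n_perm, 1]`
and are reproducible under a fixed seed. The default 1000 permutations
resolve p = 0.001, which is as fine as such tables are usually reported.

`shape_size_regression()` regresses shape on raw centroid size (not its
logarithm — the size range of these wings spans less than a factor of
three, where the distinction is cosmetic and raw size matches how such
regressions are usually plotted). It uses the full flattened coordinates
rather than a truncated PC subset: a full-rank PC rotation leaves the
regression identical, so nothing is lost and nothing depends on how many
components someone retained. The pooled within-group variant centers
**both** sizes and shapes on their group means before fitting one common
slope: centering only sizes would leave group mean-shape differences in
the response and bias the slope toward the among-group axis. Per-group
mean centered size is exactly zero by construction.

`procrustes_variance()` is the mean squared deviation from the group
mean shape (disparity); `group_distance_summary()` reports means and
standard errors of pairwise full Procrustes distances within and between
groups, sorted ascending.

## Classification and fossil placement

`cva()` pre-projects shapes onto principal components with non-negligible
variance, capped at `n - g` dimensions so the pooled within-group
covariance stays invertible, then solves the symmetric whitened
eigenproblem; canonical scores have identity pooled within-group
covariance by construction. This pre-projection is the main
reproducibility risk against other implementations: with p >> n the
trailing dimensions of the estimated within-covariance are pure noise,
and how many of them an implementation keeps (and whether it regularizes
instead) perturbs axes and posteriors at the second or third decimal.
The `retain` argument exposes the choice.

`loo_crossvalidate()` refits everything per fold — PC basis, group means,
pooled covariance — so the held-out specimen influences nothing. The
posterior for a specimen is `prior x exp(-d²/2)` over Mahalanobis
distances in canonical space, normalized; priors are equal by default
(`"proportional"` is available — with group sizes as unbalanced as 16
versus 81 the prior is consequential, and equal priors match the
convention of reporting what the *shape* says rather than what the
sampling says). Ties are broken lexicographically and logged.

`place_fossil()` chains the steps with two structural guarantees checked
in code: the reference CVA never contains the fossil (the training-set
hash is part of the report), and every landmark excluded for the fossil
is excluded from every reference specimen. The thresholds — accuracy
> 80 %, Kappa > 0.7, winning posterior > 0.9, strict inequalities,
conjunctive — gate whether the between-group-PCA refinement is restricted
to the winning subfamily; when they fail, refinement runs across the
tribes of *all* candidate subfamilies and the report carries a narrative
flag. When several specimens of one species are placed (holotype and
paratypes), each is an independent placement and disagreements are
reported, not adjudicated: resolving a holotype/paratype conflict is a
taxonomic judgment, not a computation.

`bgpca()` ordinates group mean shapes (for groups too small to estimate a
within-group covariance) and tests pairwise distances between group
averages by permutation. The test statistic is the Euclidean distance
between group averages in the **full** aligned shape space, not in the
reduced bgPCA space — the reduced space depends on which other groups
happen to be present, which a test statistic should not. The default
10 000 replications resolve p = 1e-4; when the two groups are small
enough that all label splits can be enumerated (at most `n_perm`
combinations), enumeration replaces sampling and the p-value is exact.

## The synthetic generator

`simulate_wings()` draws specimen `i` of group `g` as
`template + offset_g + slope x (size_i - mean size) x v + noise`, scaled
to centroid size `size_i`, randomly rotated and translated. Defaults
describe the structure of a subfamily-level reference collection: nine
groups of 37, sizes uniform on 2.9-8.1 wing-length units, isotropic
landmark noise sd 0.01 in shape units — chosen so per-group Procrustes
variance lands near 0.005, the middle of the range observed across real
subfamilies — and group separation 0.08, comparable to between-subfamily
mean-shape distances. The template is a once-digitized idealized wing;
only its relative geometry matters. Nuisance effects (second digitizer,
second medium, fossil part/counterpart with mirrored right wings) are
fixed dataset-level shape offsets, mirroring the structure the three
data-quality assessments are designed to detect.

What the generator does **not** emulate: anisotropic and
landmark-specific digitizing error, correlated deformation of
neighbouring landmarks (taphonomic shear), phylogenetic covariance among
species within a group, and curve semilandmarks whose noise is
concentrated along the curve. Passing tests on synthetic data therefore
demonstrate correctness of the algorithms under the stated model, not
robustness of the biology to every way real fossils are distorted.

## Numerical choices and limits

* GPA convergence `1e-10` on the summed squared deviation; both `tol`
  and `max_iter` are arguments. Degenerate (all-coincident)
  configurations error at input.
* Full Procrustes distance is computed in closed form via the complex
  inner product; its floating-point floor is around 1e-8 for identical
  shapes (square root of machine epsilon), which is why identity checks
  in the tests use that scale.
* Eigen-decompositions keep components above `1e-12` of the leading
  eigenvalue; the CVA errors rather than inverting a singular
  within-covariance.
* Every stochastic operation (`procrustes_anova`, regressions, `bgpca`,
  `simulate_wings`, `place_fossil`) takes an explicit integer seed,
  default 42, and restores the caller's RNG state.
* Problem sizes in the test suite (up to ~120 specimens, 27 landmarks,
  a few hundred permutations) keep the whole suite under a minute while
  leaving Monte-Carlo margins wide enough that the asserted properties
  are structural, not tuned.

## A worked decision, end to end

```{r placement, eval = requireNamespace("wingmorph", quietly = TRUE)}
sim <- simulate_wings(n_groups = 3, n_per_group = 14, group_effect = 0.09,
                      noise_sd = 0.008, seed = 101)
md <- sim$metadata
md$subfamily <- md$group
md$tribe <- paste0(md$group, "_t", rep(1:2, length.out = nrow(md)))

fossil <- sim$wings[sim$wings$specimen == "G02_s001", ]
fossil$specimen <- "FOSSIL_A"
reference <- sim$wings[sim$wings$specimen != "G02_s001", ]
md <- md[md$specimen != "G02_s001", ]

cfg <- placement_config("FOSSIL_A", candidates = c("G01", "G02", "G03"),
                        excluded_landmarks = c(1, 18),
                        n_perm = 1000, seed = 5)
place_fossil(reference, fossil, cfg, md)
```

The report shows each gate the decision passed: the reference CVA
quality, the posterior assignment, the three thresholds, and the
refinement scope that followed from them.
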
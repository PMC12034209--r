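---
title: "Landmark-free deterministic atlas morphometrics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-free deterministic atlas morphometrics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`morphoatlas` implements two parallel routes from a population of triangle
meshes to a shape space, plus the statistics that compare the two routes and
the macroevolutionary analyses that consume either. This vignette explains
the models, the tunable parameters and their defaults, the synthetic
populations the package is validated on, and the numerical decisions taken
where the design was genuinely open.

## The deformation model

The landmark-free branch treats each specimen surface as the endpoint of a
smooth deformation of a common template. Deformations are parameterised by
`p` control points `q_i` (mm) and, per specimen, `p` momentum vectors
`mu_i` (mm). These generate an ambient velocity field

    X(x) = sum_i K(x, q_i) mu_i,     K(x, y) = exp(-|x - y|^2 / sigma^2),

with a single kernel width `sigma` (mm) controlling the spatial scale of
deformation: larger `sigma`, smoother and coarser deformations; smaller
`sigma`, more control points and finer detail. Note the convention: no
factor of two in the Gaussian's denominator.

Deforming along a geodesic of the induced metric means integrating the
Hamiltonian system

    dq/dt  = K(q, q) mu
    dmu/dt = -1/2 grad_q { K(q, q) mu' mu }

over t in [0, 1] (`geodesic_shoot()`), while mesh vertices are advected by
the same field (`flow_mesh()`). A single control point moves in an exact
straight line (`q0 + mu0`), which the tests use as a closed form; in
general the Hamiltonian `H = 1/2 mu' K(q, q) mu` and the total momentum are
conserved, and the test suite bounds their drift under the default
integrator (midpoint Runge-Kutta, 10 steps; Euler is available for
comparisons). Atlas fits in the packaged experiments use 5 integration
steps — at the kernel widths involved the trajectories are mild and the
halved cost changes the fitted momenta negligibly.

## Surface attachment: currents and varifolds

Fidelity between a deformed template and a specimen is measured without
point correspondence, through oriented face measures: per-face centres
`c_p` and area-weighted normals `n_p` (magnitude = face area). With a
second Gaussian kernel `K_W` of width `sigma_w`, the pairing between faces
is `K_W(c_p, c_q) (n_p . n_q)` for currents and
`K_W(c_p, c_q) (n_p . n_q)^2 / (|n_p||n_q|)` for varifolds; these are RKHS
inner products `<A, B>`, and the squared distance is the bilinear expansion
`<A,A> - 2<A,B> + <B,B>`. The varifold form ignores orientation sign and is
the default, as it is the robust choice for meshes of mixed provenance.
`sigma_w` defaults to `sigma / 2`; it is a genuinely free parameter that
sets the scale below which surface detail is invisible to the data term.

## Atlas estimation

`estimate_atlas()` minimises

    f(T, q, mu) = sum_i [ d^2(Phi_{q, mu_i}(T), C_i) / (2 tau^2)
                          + 1/2 mu_i' K(q, q) mu_i ]

jointly over the template vertices `T`, the control points `q` and all
per-specimen momenta. The regulariser is the kinetic energy of the initial
momenta — the standard deformation-energy penalty of this model family —
and `tau` (argument `noise_sigma`, default 10) sets the data/regularity
trade-off. Momenta start at zero; the template starts at a chosen specimen;
control points start on a regular grid of spacing `sigma` covering the
template's bounding box padded by `sigma/2` (`init_control_points()`),
so the control-point count is a deterministic function of `sigma`.

Gradients are hand-derived adjoints of the discretised forward computation:
the attachment gradient with respect to the flowed vertices is pulled back
through each Runge-Kutta step by transpose-Jacobian products. A required
test verifies agreement with central finite differences to 1e-4 relative
on a small system (it agrees to ~1e-9 in practice).

The optimiser is deterministic gradient descent with an adaptive line
search: each parameter block (template, control points, momenta) moves on
its own scale, fixed by the first non-zero gradient of that block, and each
iteration halves the step until the loss decreases, then doubles it
greedily while that keeps improving. The initial step is 0.01. A fixed
halve-on-increase / double-after-five-accepts schedule was tried first and
discarded: at this problem scale it left the fit an order of magnitude
short of convergence within a realistic iteration budget, whereas the line
search reaches a ~98% data-term reduction in 30 iterations on the recovery
experiment. Accepted losses are monotone non-increasing by construction,
and the trace is stored in the fitted object.

## The shape spaces

The fitted momenta (one `p x 3` block per specimen, flattened
control-point-major) enter kernel PCA: the Gram matrix
`G_ij = exp(-gamma |m_i - m_j|^2)` is double-centred and eigendecomposed;
scores are eigenvectors scaled by the square root of their eigenvalues, at
most `n - 1` axes, each axis signed so its largest-magnitude score is
positive. On physical momenta scales of the original application
`gamma = 2.5e-6` is the published setting and remains the default. Because
the sensible `gamma` scales with the momenta magnitude, `gamma = "auto"`
is provided; it uses `1 / (10 * median squared pairwise distance)`.
The factor 10 places the kernel in its near-linear regime: this projection
exists to *linearise* momenta space into variance-ordered axes, and on
synthetic populations with a known dominant axis the choice
`1 / median d^2` proved strongly non-linear (it halved the correlation
between PC1 and the known axis even when computed on the true momenta),
while the near-linear width recovers it almost exactly.

The landmark branch is classical: curves resampled to equal arc-length
spacing (`resample_curve()`), semilandmarks slid along reference tangents
to minimise thin-plate-spline bending energy (`slide_semilandmarks()`;
one Gauss-Seidel sweep per outer iteration, three outer iterations by
default, consensus recomputed per iteration — more iterations converge to
the per-point grid-search optimum, which the tests verify), generalised
Procrustes superimposition (`generalized_procrustes()`; partial Procrustes,
unit centroid size, no reflections), and ordinary PCA of the flattened
aligned coordinates. The GPA solution is rotated into the consensus's
principal axes with a deterministic sign rule, so the output is invariant
to the coordinate frame of the inputs — without this canonicalisation the
result is only defined up to a global rotation.

TPS uses the 3-D biharmonic kernel `U(r) = -r`, which is conditionally
positive definite of order 1, so the bending energy `sum_d w_d' K w_d` is
non-negative and vanishes exactly on affine maps; `tps_warp()` carries a
mesh through the spline for heatmap comparisons (`per_vertex_distance()`,
corresponding-vertex mode for warped pairs, closest-point mode when vertex
counts differ).

## Concordance statistics

Agreement between the two shape spaces is quantified by Euclidean distance
profiles with OLS regressions, the Mantel test (Pearson correlation of
lower-triangle distances, one-sided greater alternative, rows and columns
permuted jointly), PROTEST (both configurations centred and scaled to unit
total sum of squares, rotation by SVD, `m2 = 1 - (sum of singular
values)^2`, one-sided permutation of rows), and the R^2 between the two
percent-of-variance spectra. All permutation p-values use the
`(1 + exceedances) / (1 + n_perm)` convention and are seeded; at `n = 5`
both tests support exhaustive enumeration over all 120 relabelings, which
the tests compare against an independent enumeration. Published settings
(9999 permutations) are the defaults.

## Macroevolutionary statistics

`kmult()` is the multivariate generalisation of Blomberg's K: the ratio of
summed squared distances of tip rows to the GLS root estimate under the
Euclidean versus the phylogenetic inverse-covariance metric, divided by its
Brownian-motion expectation `(tr(C) - N/(1'C^-1 1)) / (N - 1)`. The
`N - 1` divisor is the one under which the univariate case reduces exactly
to Blomberg's K (verified against an independent implementation to 1e-10)
and a star phylogeny gives K = 1 identically for any data. Significance
permutes tip rows, 99 permutations by default.

`morphological_disparity()` is per-group Procrustes variance with
label-permutation tests. `compare_evolutionary_rates()` transforms the
deviations from the GLS root by the inverse symmetric square root of the
phylogenetic covariance, averages squared row norms per group (divided by
the trait dimension), and tests the max/min rate ratio against 100 seeded
single-rate Brownian simulations. Simulation checks: two-clade populations
with a true 4-fold rate contrast recover a median ratio in [3, 5], and
equal-rate populations reject at most 10% of the time at alpha = 0.05.

## Mesh standardisation

Mixed-provenance mesh populations (CT segmentations vs surface scans)
differ in ways that are invisible to landmarks but not to surface
attachment: CT meshes carry internal surfaces and open patches.
`close_watertight()` standardises any mesh to a closed surface by
voxelising on a padded grid, classifying voxel centres by their
generalized winding number (> 1/2 inside; exact for closed surfaces, and
the winding field of an open mesh continues the missing patch smoothly),
and extracting the boundary of the voxel solid as triangles (cuberille
extraction with pinch repair so the result is edge- and vertex-manifold).
This replaces a segmentation + screened-Poisson workflow with an operation
that has the same contract — watertight output, bounded Hausdorff
deviation, internal structure removed — while being simple enough to test
exhaustively. A nearest-vertex pseudo-normal classifier was implemented
first and discarded for this role: it leaks through large boundary
openings. The default voxel size is the bounding-box diagonal / 200; the
packaged experiments use diagonal / 40, which keeps reconstruction error
well under the deformation scales being studied.

`decimate_quadric()` is classical quadric-error edge collapse (candidate
positions: endpoints and midpoint; link-condition and normal-flip guards;
boundary vertices immobile so open meshes stay open), reaching the face
budget within 2% or stopping early with a warning. The face budget for
synthetic icospheres defaults to a few hundred faces; the published
workflow's 50,000-face budget is a property of cranium-scale scans, not of
the algorithm.

`align_mesh_to_landmarks()` maps a mesh onto a target landmark
configuration by least-squares rotation + translation (reflections
disallowed — anatomical meshes must never be mirrored silently), optionally
premultiplying by the centroid-size ratio to remove scale.

## The synthetic study populations

`build_study()` generates seeded populations with known ground truth so
that every downstream stage is testable without external data:

* **Base shape**: a subdivided icosahedron projected to a sphere
  (`generate_base_mesh()`), radius 40 mm by default — an 80 mm object,
  i.e. cranium scale. An analytic base gives exact control of topology,
  vertex count and landmark placement.
* **Deformations**: each specimen is the geodesic flow of the base under
  momenta `mu_i = alpha_i * M_stretch + BM_i + eps_i` at a true kernel
  width of 25 mm. `M_stretch` sets each control point's momentum to its
  signed x-coordinate, producing a smooth elongation — the synthetic
  analogue of the dolichocephalic-brachycephalic axis that dominates
  cranial variation. `alpha_i ~ N(0, 0.15^2)` (roughly +/-15% length),
  `BM_i` evolves on a unit-depth pure-birth phylogeny at rate 1 mm^2 per
  coordinate, and `eps_i` is iid N(0, 0.5^2) noise. These defaults make
  elongation the dominant axis while leaving clade-structured and
  idiosyncratic variation clearly present.
* **Landmarks**: a fixed, pre-registered subset of base vertices (30
  fixed + 4 curves x 6 semilandmarks by default, a scale model of dense
  cranial schemes) tracked through the same flow, so homology is exact by
  construction and the landmark branch has zero digitisation error.
* **Modality artifact**: a seeded subset of specimens
  (`floor(open_fraction * n)`) emulates CT-derived meshes: they carry a
  concentric internal shell (0.7 R) deformed by the same flow and lose a
  ventral surface cap (Euclidean radius 1.0 R) at a fixed anatomical
  location. Both features were chosen after diagnosing what a varifold
  data term at sigma = 25 mm can and cannot feel: scattered small
  perforations are below the deformation scale, and randomly located caps
  spread their momenta response over many axes instead of one. A
  consistent location and an internal target surface produce the
  documented phenomenon — the raw analysis separates modalities on its
  first axis, and watertight standardisation (which solidifies internals
  away and fills the cap) removes the separation and raises the agreement
  between the landmark and landmark-free branches. The modality experiment
  uses milder biological variation (elongation sd 0.05, BM rate 0.3, noise
  0.3): the regime it reproduces is precisely one where the technical
  artifact dominates the biology.
* **Groups and tree**: ecological-analogue labels come from the two clades
  splitting at the root (with an option for more groups); one global seed
  feeds a named sub-stream per component, so each component is
  independently reproducible and written studies are byte-identical across
  runs.

What passing tests on these populations do show: the estimator recovers
deformation structure generated by its own model family; the statistics
have their closed-form, oracle and calibration properties; the modality
artifact behaves as documented. What they do not show: robustness to
segmentation noise, non-manifold geometry, or deformations far outside the
Gaussian-kernel family — real cranial data differ in all three ways, and a
config flag (`individual_noise_sd`, plus fitting at a kernel width other
than the true one) only partially probes this.

## Problem sizes in the packaged experiments

The recovery experiment fits 20 level-3 icosphere specimens (642 vertices,
1280 faces) with 216 grid control points for 30 iterations; the modality
experiment fits 20 level-2 specimens (162 vertices) twice, before and
after standardisation. These sizes were chosen as the smallest populations
on which all the studied effects are comfortably resolved; every
experiment is seeded and reruns identically.

## Known limitations

* The voxel-based closing cannot restore genuinely missing geometry: a
  large hole is filled near the winding-number 1/2 level set, which for a
  wide opening is a membrane across the mouth, not the original surface.
* Quadric decimation is plain single-threaded R; it is comfortable at
  10^4-face scale but not at 10^6.
* The atlas optimiser is first-order; momenta for specimens far from the
  template converge more slowly than near ones, and template choice,
  while empirically mild (it is a config option), is not marginalised.
* Sliding supports curve semilandmarks only; surface-patch semilandmarks
  are out of scope.
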
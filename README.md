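# morphoatlas

Landmark-free morphometrics of triangle-mesh populations by deterministic
atlas estimation, side by side with classical landmark-based geometric
morphometrics, for researchers comparing the two families of methods or
running either end to end.

## What it does

Geometric morphometrics usually starts from homologous landmarks placed by
hand — slow, observer-dependent, and hard to scale to the mesh archives now
coming out of CT and surface scanning. The landmark-free alternative
implemented here registers every specimen mesh to a population **atlas**
under the large deformation diffeomorphic metric mapping (LDDMM) model:
deformations are generated by control points `q_i` and per-specimen momenta
`mu_i` through a Gaussian velocity field

    X(x) = sum_i K(x, q_i) mu_i,   K(x, y) = exp(-||x - y||^2 / sigma^2),

flowed along geodesics of the Hamiltonian system

    dq/dt = K(q,q) mu,   dmu/dt = -1/2 grad_q { K(q,q) mu' mu }.

Atlas estimation minimises

    f(T, q, mu) = sum_i [ d^2(Phi_{q,mu_i}(T), C_i) / (2 tau^2)
                          + 1/2 mu_i' K(q,q) mu_i ]

over the template `T`, control points and momenta, where `d` is a current
or varifold surface distance built from per-face centres and area-weighted
normals — no point correspondence needed. The fitted momenta are the shape
data: kernel PCA projects them into at most n−1 variance-ordered axes.

Around that core the package provides:

* the landmark branch: curve resampling, semilandmark sliding by bending
  energy, generalised Procrustes analysis, thin-plate-spline warps,
  ordinary PCA;
* mesh standardisation: PLY/OBJ I/O, watertight closing by voxel +
  generalized-winding-number reconstruction, quadric edge-collapse
  decimation, rigid alignment onto landmarks;
* concordance statistics between shape spaces: distance profiles and
  regressions, Mantel test, PROTEST, eigenvalue-spectrum correlation,
  per-vertex heatmap distances;
* macroevolution: multivariate phylogenetic signal (K_mult), morphological
  disparity, simulation-based evolutionary-rate comparison;
* a seeded synthetic-population generator (meshes + exactly homologous
  landmarks + phylogeny + group labels + a CT-vs-surface-scan modality
  artifact) with known ground truth, so the whole pipeline is testable
  without external data.

## A worked example

```r
library(morphoatlas)

# a seeded population of 12 deformed icospheres with known structure
spec  <- population_spec(n_specimens = 12, subdivision_level = 2, seed = 1)
study <- build_study(spec)
study
#> <synthetic_study> 12 specimens (radius 40 mm, level 2), 216 control points, 0 open

# landmark-free branch: estimate the atlas, project momenta
atlas <- estimate_atlas(study$meshes, study$meshes[[1]],
                        kernel = list(sigma = 25), max_iter = 15,
                        n_steps = 5)
atlas
#> <daa_atlas> 12 specimens, 108 control points, sigma = 25 mm, sigma_w = 12.5 mm, varifold attachment
#>   loss: 958803 -> 220170 in 15 accepted iterations
daa <- kpca(flatten_momenta(atlas$momenta, names(study$meshes)),
            gamma = "auto")
daa
#> <shape_scores:kpca> 12 specimens x 11 axes; PC1 78.4% of variance

cor(daa$scores[, 1], study$elongation)
#> [1] -0.964548

# landmark branch and concordance
lm_scores <- landmark_pca(generalized_procrustes(study$landmarks))
mantel_test(score_distance_matrix(lm_scores),
            score_distance_matrix(daa), n_perm = 999, seed = 1)
#> # A tibble: 1 × 3
#>       r p_value n_perm
#>   <dbl>   <dbl>  <dbl>
#> 1 0.986   0.001    999

# phylogenetic signal of the landmark-free shape space
kmult(daa, study$tree, n_perm = 99, seed = 1)
#> # A tibble: 1 × 3
#>       K p_value n_perm
#>   <dbl>   <dbl>  <dbl>
#> 1 0.450    0.23     99
```

The first kernel-PCA axis of the fitted momenta recovers the population's
true elongation coefficient almost exactly (|r| ≈ 0.96), and the landmark
and landmark-free distance matrices agree strongly (Mantel r ≈ 0.99,
p = 0.001): at this small demo scale the two branches measure the same
shape variation. K ≈ 0.45 with p = 0.23 says the 12-specimen shape space
shows no significant phylogenetic signal — expected, because the dominant
elongation axis and the individual noise are deliberately phylogeny-free
and only the Brownian component tracks the tree; the packaged calibration
experiments use 64-tip pure-Brownian populations, where K centres on 1.
`autoplot(daa)`, `autoplot(atlas)`, `tidy()` and `glance()` give ggplot
ordinations, loss traces and tibble summaries.

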
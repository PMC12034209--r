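test_that("curve resampling places points at equal arc length", {
  seg <- rbind(c(0, 0, 0), c(10, 0, 0))
  expect_equal(resample_curve(seg, 3), rbind(c(0, 0, 0), c(5, 0, 0),
                                             c(10, 0, 0)))
  expect_equal(resample_curve(seg, 2), seg)
  # random polyline: arc-length positions equally spaced, verified by an
  # independent cumulative-length interpolation oracle
  set.seed(9)
  poly <- matrix(cumsum(rnorm(30)), 10, 3)
  out <- resample_curve(poly, 20)
  cum <- c(0, cumsum(sqrt(rowSums(diff(poly)^2))))
  oracle <- sapply(1:3, function(d)
    stats::approx(cum, poly[, d], xout = seq(0, max(cum),
                                             length.out = 20))$y)
  expect_lt(max(abs(out - oracle)), 1e-9)
  expect_equal(out[1, ], poly[1, ])
  expect_equal(out[20, ], poly[10, ])
  expect_error(resample_curve(rbind(c(0, 0, 0), c(0, 0, 0)), 3))
})

test_that("GPA collapses similarity-transformed copies of one shape", {
  set.seed(11)
  shape <- matrix(rnorm(24), 8, 3)
  configs <- lapply(1:6, function(i) {
    R <- random_rotation(i)
    s <- runif(1, 0.5, 2)
    t_ <- rnorm(3, sd = 5)
    s * shape %*% t(R) + rep(t_, each = 8)
  })
  gp <- generalized_procrustes(configs, with_scale = TRUE)
  for (i in 2:6)
    expect_lt(max(abs(gp$aligned[[i]] - gp$aligned[[1]])), 1e-8)
  expect_lt(sqrt(sum(colMeans(gp$mean_shape)^2)), 1e-12)
  expect_equal(sqrt(sum(gp$mean_shape^2)), 1, tolerance = 1e-12)
})

test_that("GPA output is invariant to rigid motions of its inputs", {
  set.seed(12)
  configs <- lapply(1:5, function(i) matrix(rnorm(24), 8, 3))
  gp1 <- generalized_procrustes(configs)
  moved <- lapply(seq_along(configs), function(i) {
    R <- random_rotation(100 + i)
    configs[[i]] %*% t(R) + rep(rnorm(3, sd = 10), each = 8)
  })
  gp2 <- generalized_procrustes(moved)
  for (i in seq_along(configs))
    expect_lt(max(abs(gp1$aligned[[i]] - gp2$aligned[[i]])), 1e-8)
})

test_that("two identical configurations superimpose exactly", {
  cfg <- matrix(rnorm(15), 5, 3)
  gp <- generalized_procrustes(list(cfg, cfg))
  expect_lt(max(abs(gp$aligned[[1]] - gp$aligned[[2]])), 1e-12)
  expect_error(generalized_procrustes(list(matrix(1, 4, 3),
                                           matrix(1, 4, 3))),
               class = "morphoatlas_error_degenerate_landmarks")
})

test_that("mirroring reflects across the midline plane as an isometry", {
  set.seed(13)
  midline <- cbind(rnorm(5), rnorm(5), 0)      # points on z = 0
  side <- matrix(rnorm(12), 4, 3)
  cfg <- rbind(midline, side)
  out <- mirror_configuration(cfg, midline_indices = 1:5)
  pairs <- attr(out, "mirror_pairs")
  expect_equal(nrow(out), 13)
  # midline rows unchanged
  expect_equal(out[1:5, ], midline, ignore_attr = TRUE)
  # signed distance negated, magnitude preserved
  expect_equal(out[pairs[, "mirrored"], 3], -side[, 3], tolerance = 1e-12)
  expect_equal(out[pairs[, "mirrored"], 1:2], side[, 1:2],
               tolerance = 1e-12, ignore_attr = TRUE)
  # involution: mirroring the mirrored side recovers the original points
  out2 <- mirror_configuration(out[c(1:5, pairs[, "mirrored"]), ], 1:5)
  p2 <- attr(out2, "mirror_pairs")
  expect_lt(max(abs(out2[p2[, "mirrored"], ] - side)), 1e-9)
  expect_error(mirror_configuration(cfg, 1:2),
               class = "morphoatlas_error_degenerate_landmarks")
})

test_that("TPS interpolates exactly and is affine-exact with zero bending", {
  set.seed(14)
  src <- matrix(rnorm(30, sd = 2), 10, 3)
  mesh <- generate_base_mesh(2, 1)
  # identity
  w0 <- tps_warp(mesh, src, src)
  expect_lt(max(abs(w0$mesh$vertices - mesh$vertices)), 1e-8)
  expect_lt(w0$model$bending_energy, 1e-10)
  # affine target: warp equals the direct affine transform of the mesh
  A <- matrix(rnorm(9, sd = 0.3), 3) + diag(3)
  b <- c(1, -2, 0.5)
  tgt <- src %*% t(A) + rep(b, each = 10)
  wa <- tps_warp(mesh, src, tgt)
  direct <- mesh$vertices %*% t(A) + rep(b, each = nrow(mesh$vertices))
  expect_lt(max(abs(wa$mesh$vertices - direct)), 1e-8)
  expect_lt(wa$model$bending_energy, 1e-10)
  # generic target: exact interpolation at the landmarks, positive bending
  tgt2 <- tgt + matrix(rnorm(30, sd = 0.5), 10, 3)
  m2 <- tps_model(src, tgt2)
  expect_lt(max(abs(tps_apply(m2, src) - tgt2)), 1e-9)
  expect_gt(m2$bending_energy, 1e-8)
  expect_error(tps_model(src[c(1, 1, 2, 3), ], tgt[1:4, ]),
               class = "morphoatlas_error_tps_singular")
  expect_error(tps_model(cbind(rnorm(5), rnorm(5), 0) * c(1, 1, 0),
                         matrix(rnorm(15), 5, 3)),
               class = "morphoatlas_error_tps_singular")
})

test_that("sliding lowers bending energy and never moves fixed landmarks", {
  ref <- demo_config(seed = 21, jitter = 0)
  cfg <- demo_config(seed = 21, jitter = 0)
  # perturb the interior curve points off the straight reference segment
  set.seed(22)
  interior <- ref$curves[[1]][-c(1, 6)]
  cfg$points[interior, 1] <- cfg$points[interior, 1] + rnorm(4, sd = 0.8)
  e_before <- morphoatlas:::bending_energy_to_reference(cfg, ref)
  slid3 <- slide_semilandmarks(list(cfg), reference = ref, n_iter = 3)[[1]]
  expect_lt(morphoatlas:::bending_energy_to_reference(slid3, ref), e_before)
  slid <- slide_semilandmarks(list(cfg), reference = ref, n_iter = 10)[[1]]
  e_after <- morphoatlas:::bending_energy_to_reference(slid, ref)
  expect_lt(e_after, e_before)
  # fixed landmarks and curve endpoints bit-identical
  fixed <- which(ref$roles == "fixed")
  ends <- ref$curves[[1]][c(1, 6)]
  expect_identical(slid3$points[c(fixed, ends), ],
                   cfg$points[c(fixed, ends), ])
  # 1-D grid-search oracle: at the slid configuration no tangent move of
  # any single semilandmark improves the energy appreciably
  Be <- morphoatlas:::bending_energy_matrix(ref)
  for (i in interior) {
    u <- ref$points[i + 1, ] - ref$points[i - 1, ]
    u <- u / sqrt(sum(u^2))
    grid_best <- min(vapply(seq(-2, 2, length.out = 801), function(t_) {
      X <- slid$points
      X[i, ] <- X[i, ] + t_ * u
      sum(vapply(1:3, function(d) drop(crossprod(X[, d], Be %*% X[, d])), 0))
    }, 0))
    expect_lt(e_after - grid_best, 1e-8 + 0.01 * e_after)
  }
  # a configuration identical to the reference stays put
  same <- slide_semilandmarks(list(ref), reference = ref)[[1]]
  expect_lt(max(abs(same$points - ref$points)), 1e-9)
})

test_that("landmark PCA matches a covariance eigendecomposition oracle", {
  set.seed(23)
  configs <- lapply(1:10, function(i) matrix(rnorm(12), 4, 3))
  gp <- generalized_procrustes(configs)
  sc <- landmark_pca(gp)
  expect_equal(ncol(sc$scores), 9)
  flat <- t(vapply(gp$aligned, function(m) as.vector(t(m)), numeric(12)))
  ev_oracle <- sort(eigen(stats::cov(flat), symmetric = TRUE)$values,
                    decreasing = TRUE)[1:9]
  expect_lt(max(abs(sc$eigenvalues - ev_oracle)), 1e-9)
  # scores carry the full centred variation through the retained axes
  centred <- scale(flat, scale = FALSE)
  expect_equal(sum(sc$scores^2), sum(centred^2), tolerance = 1e-8)
})

test_that("landmark PCA has the documented degenerate behaviours", {
  two <- generalized_procrustes(list(matrix(rnorm(12), 4, 3),
                                     matrix(rnorm(12), 4, 3)))
  sc2 <- landmark_pca(two)
  expect_equal(ncol(sc2$scores), 1)
  expect_gt(sc2$eigenvalues[1], 0)
  # variation confined to one direction -> PC1 explains everything
  base <- matrix(rnorm(12), 4, 3)
  shifts <- seq(-0.1, 0.1, length.out = 5)
  configs <- lapply(shifts, function(s) {
    b <- base
    b[1, 1] <- b[1, 1] + s
    b
  })
  # no alignment (use configurations directly as flattened data)
  flat <- t(vapply(configs, function(m) as.vector(t(m)), numeric(12)))
  pc <- stats::prcomp(flat)
  expect_gt(pc$sdev[1]^2 / sum(pc$sdev^2), 1 - 1e-9)
})
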
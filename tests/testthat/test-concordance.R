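toy_scores <- function(mat, ids = NULL) {
  ids <- ids %||% paste0("s", seq_len(nrow(mat)))
  shape_scores(mat, rev(seq_len(ncol(mat))), axis_kind = "pca",
               specimen_ids = ids)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("distances to a reference specimen are plain Euclidean", {
  sc <- toy_scores(rbind(c(0, 0), c(3, 4), c(1, 1)))
  d <- distance_to_reference(sc, "s1")
  expect_equal(d$distance, c(0, 5, sqrt(2)))
  expect_error(distance_to_reference(sc, "nope"))
  # invariance under orthogonal rotation of the score matrix
  set.seed(51)
  S <- matrix(rnorm(30), 10, 3)
  R <- random_rotation(52)
  d1 <- distance_to_reference(toy_scores(S), "s4")$distance
  d2 <- distance_to_reference(toy_scores(S %*% R), "s4")$distance
  expect_lt(max(abs(d1 - d2)), 1e-9)
})

test_that("the score distance matrix matches a two-loop oracle", {
  set.seed(53)
  S <- matrix(rnorm(24), 6, 4)
  D <- score_distance_matrix(toy_scores(S))
  oracle <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6)
    oracle[i, j] <- sqrt(sum((S[i, ] - S[j, ])^2))
  expect_lt(max(abs(D - oracle)), 1e-12)
  expect_equal(diag(D), rep(0, 6), ignore_attr = TRUE)
  # metric property on random input
  for (i in 1:6) for (j in 1:6) for (k in 1:6)
    expect_lte(D[i, k], D[i, j] + D[j, k] + 1e-12)
  # identical rows give an all-zero matrix
  Z <- matrix(1, 4, 3)
  expect_equal(max(score_distance_matrix(toy_scores(Z))), 0)
})

test_that("the linear fit reproduces closed-form least squares", {
  f1 <- suppressWarnings(linear_fit_r2(0:10, 2 * (0:10) + 1))
  expect_equal(f1$slope, 2)
  expect_equal(f1$intercept, 1)
  expect_equal(f1$r_squared, 1)
  f2 <- linear_fit_r2(c(0, 1, 2), c(0, 1, 1))
  expect_equal(f2$slope, 0.5)
  expect_equal(f2$intercept, 1 / 6, tolerance = 1e-12)
  expect_equal(f2$r_squared, 0.75)
  f3 <- linear_fit_r2(1:5, rep(2, 5))
  expect_equal(f3$r_squared, 0)
  expect_error(linear_fit_r2(rep(1, 5), 1:5))
})

test_that("Mantel r hits its constructed extremes and matches vegan", {
  set.seed(54)
  S <- matrix(rnorm(18), 6, 3)
  d1 <- score_distance_matrix(toy_scores(S))
  expect_equal(mantel_test(d1, d1, n_perm = 19, seed = 1)$r, 1)
  anti <- (max(d1) + 1) - d1
  diag(anti) <- 0
  expect_equal(mantel_test(d1, anti, n_perm = 19, seed = 1)$r, -1)
  skip_if_not_installed("vegan")
  S2 <- matrix(rnorm(18), 6, 3)
  d2 <- score_distance_matrix(toy_scores(S2))
  r_vegan <- vegan::mantel(as.dist(d1), as.dist(d2),
                           permutations = 5)$statistic
  expect_equal(mantel_test(d1, d2, n_perm = 9, seed = 1)$r,
               unname(r_vegan), tolerance = 1e-12)
})

test_that("Mantel exhaustive p equals full enumeration at n = 5", {
  set.seed(55)
  d1 <- score_distance_matrix(toy_scores(matrix(rnorm(15), 5, 3)))
  d2 <- score_distance_matrix(toy_scores(matrix(rnorm(15), 5, 3)))
  res <- mantel_test(d1, d2, n_perm = "all")
  expect_equal(res$n_perm, 120)
  # independent enumeration via recursive permutations of 1:5
  perms <- morphoatlas:::all_permutations(5)
  lt <- lower.tri(d1)
  r_obs <- cor(d1[lt], d2[lt])
  rs <- apply(perms, 1, function(p) cor(d1[lt], d2[p, p][lt]))
  expect_equal(res$p_value, mean(rs >= r_obs - 1e-12))
  # the +1/(n+1) sampled convention approaches the same value
  res2 <- mantel_test(d1, d2, n_perm = 9999, seed = 2)
  expect_lt(abs(res2$p_value - res$p_value), 0.05)
})

test_that("PROTEST is exact on similarity-transformed configurations", {
  set.seed(56)
  X <- matrix(rnorm(30), 10, 3)
  res_same <- protest(toy_scores(X), toy_scores(X), n_perm = 19, seed = 1)
  expect_lt(res_same$ss_m2, 1e-12)
  expect_equal(res_same$correlation, 1)
  expect_equal(res_same$rmse, 0)
  R <- random_rotation(57)
  Y <- 3.7 * X %*% R
  res_rot <- protest(toy_scores(X), toy_scores(Y), n_perm = 19, seed = 1)
  expect_lt(res_rot$ss_m2, 1e-10)
})

test_that("PROTEST matches vegan and exhaustive enumeration", {
  set.seed(58)
  X <- matrix(rnorm(15), 5, 3)
  Y <- X + matrix(rnorm(15, sd = 0.4), 5, 3)
  skip_if_not_installed("vegan")
  pv <- vegan::protest(X, Y, permutations = 5)
  ours <- protest(toy_scores(X), toy_scores(Y), n_perm = "all")
  expect_equal(ours$ss_m2, unname(pv$ss), tolerance = 1e-10)
  expect_equal(ours$correlation, unname(pv$t0), tolerance = 1e-10)
  # exhaustive p equals direct enumeration
  perms <- morphoatlas:::all_permutations(5)
  norm_cfg <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    M / sqrt(sum(M^2))
  }
  Xn <- norm_cfg(X)
  m2 <- function(Yp) 1 - sum(svd(crossprod(Xn, norm_cfg(Yp)))$d)^2
  m2s <- apply(perms, 1, function(p) m2(Y[p, , drop = FALSE]))
  expect_equal(ours$p_value, mean(m2s <= m2(Y) + 1e-12))
})

test_that("eigenvalue-spectrum correlation delegates to the linear fit", {
  spec <- c(60, 25, 10, 5)
  expect_equal(suppressWarnings(eigenvalue_correlation(spec, spec))$r_squared, 1)
  expect_equal(eigenvalue_correlation(spec, rep(25, 4))$r_squared, 0)
  set.seed(59)
  a <- runif(8); b <- runif(8)
  expect_equal(eigenvalue_correlation(a, b)$r_squared,
               linear_fit_r2(a, b)$r_squared)
})

test_that("auxiliary statistics match hand-coded formulas", {
  a <- c(1, 2, 3); b <- c(2, 4, 7)
  res <- auxiliary_stats(a, b, "welch_t")
  # textbook Welch formulas, written independently
  se2 <- var(a) / 3 + var(b) / 3
  t_oracle <- (mean(a) - mean(b)) / sqrt(se2)
  df_oracle <- se2^2 / ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_lt(abs(res$statistic - t_oracle), 1e-12)
  expect_lt(abs(res$df - df_oracle), 1e-12)
  expect_equal(auxiliary_stats(a, a, "welch_t")$statistic, 0)
  rho <- auxiliary_stats(c(1, 5, 9, 12), c(0.1, 0.4, 2, 30), "spearman")
  expect_equal(rho$statistic, 1)
  expect_lte(rho$p_value, 0.05 + 1)  # permutation p is a valid probability
  expect_gte(rho$p_value, 0)
})

test_that("per-vertex distances behave in both modes", {
  m <- generate_base_mesh(5, 1)
  expect_equal(per_vertex_distance(m, m, "corresponding"),
               rep(0, nrow(m$vertices)))
  shifted <- mesh3t(m$vertices + rep(c(1, 0, 0), each = nrow(m$vertices)),
                    m$faces)
  expect_equal(per_vertex_distance(shifted, m, "corresponding"),
               rep(1, nrow(m$vertices)))
  # closest-point distance never exceeds the corresponding distance
  set.seed(60)
  warped <- mesh3t(m$vertices + matrix(rnorm(length(m$vertices), sd = 0.3),
                                       ncol = 3), m$faces)
  d_corr <- per_vertex_distance(warped, m, "corresponding")
  d_close <- per_vertex_distance(warped, m, "closest")
  expect_true(all(d_close <= d_corr + 1e-12))
  # signed distances are negative inside, positive outside
  bigger <- mesh3t(m$vertices * 1.2, m$faces)
  smaller <- mesh3t(m$vertices * 0.8, m$faces)
  expect_true(all(per_vertex_distance(bigger, m, "closest",
                                      signed = TRUE) > 0))
  expect_true(all(per_vertex_distance(smaller, m, "closest",
                                      signed = TRUE) < 0))
  expect_error(per_vertex_distance(m, random_patch_mesh(1), "corresponding"))
})
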
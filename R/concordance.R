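score_matrix <- function(x) {
  if (inherits(x, "shape_scores")) x$scores else as.matrix(x)
}

#' Euclidean distance of every specimen to a reference specimen
#'
#' Distances over all score axes from each specimen's score row to the
#' reference specimen's row (for example the atlas specimen), the per-
#' specimen distance profile compared between methods.
#'
#' @param scores A [shape_scores()] or score matrix with row names.
#' @param reference_id Row name of the reference specimen.
#' @return Tibble with `specimen_id` and `distance`.
#' @export
distance_to_reference <- function(scores, reference_id) {
  S <- score_matrix(scores)
  if (!reference_id %in% rownames(S)) stop("unknown reference: ", reference_id)
  ref <- S[reference_id, ]
  tibble::tibble(specimen_id = rownames(S),
                 distance = unname(sqrt(rowSums(sweep(S, 2, ref)^2))))
}

#' Pairwise Euclidean distance matrix of score rows
#'
#' @param scores A [shape_scores()] or score matrix.
#' @return Symmetric `n x n` matrix with zero diagonal, dimnames the
#'   specimen ids.
#' @export
score_distance_matrix <- function(scores) {
  S <- score_matrix(scores)
  d <- as.matrix(stats::dist(S))
  dimnames(d) <- list(rownames(S), rownames(S))
  d
}

#' Ordinary least-squares fit with R-squared
#'
#' Simple linear regression `y ~ x` with the coefficient of determination
#' and the two-sided slope p-value from the t distribution.
#'
#' @param x,y Numeric vectors of equal length (>= 3); `x` non-constant.
#' @return Tibble with `slope`, `intercept`, `r_squared`, `p_value`.
#' @export
linear_fit_r2 <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0) stop("x is constant")
  if (stats::sd(y) == 0)
    return(tibble::tibble(slope = 0, intercept = y[1], r_squared = 0,
                          p_value = NA_real_))
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  tibble::tibble(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 p_value = sm$coefficients[2, 4])
}

check_distance_matrix <- function(d) {
  d <- as.matrix(d)
  stopifnot(nrow(d) == ncol(d), max(abs(d - t(d))) <= 1e-12,
            all(diag(d) == 0))
  d
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Mantel test between two distance matrices
#'
#' Pearson correlation of the strictly-lower-triangle entries, with a one-
#' sided (greater) permutation test that relabels rows and columns of `d2`
#' jointly.  `n_perm = "all"` enumerates every relabelling exactly.
#'
#' @param d1,d2 Symmetric distance matrices, same dimension (>= 4).
#' @param n_perm Number of permutations (printed setting 9999) or `"all"`.
#' @param seed Integer seed for the sampled permutations.
#' @return Tibble with `r`, `p_value`, `n_perm`.
#' @export
mantel_test <- function(d1, d2, n_perm = 9999L, seed = 1L) {
  d1 <- check_distance_matrix(d1); d2 <- check_distance_matrix(d2)
  n <- nrow(d1)
  stopifnot(n == nrow(d2), n >= 4)
  lt <- lower.tri(d1)
  if (stats::sd(d1[lt]) == 0 || stats::sd(d2[lt]) == 0)
    stop("constant lower triangle")
  r_obs <- stats::cor(d1[lt], d2[lt])
  stat <- function(perm) stats::cor(d1[lt], d2[perm, perm][lt])
  if (identical(n_perm, "all")) {
    perms <- all_permutations(n)
    rs <- apply(perms, 1, stat)
    p <- mean(rs >= r_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    rs <- replicate(n_perm, stat(sample.int(n)))
    p <- (1 + sum(rs >= r_obs - 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  tibble::tibble(r = r_obs, p_value = p, n_perm = n_used)
}

protest_m2 <- function(X, Y) {
  # both column-centred and scaled to unit total sum of squares
  1 - sum(svd(crossprod(X, Y))$d)^2
}

#' Procrustean randomisation test (PROTEST)
#'
#' Symmetric Procrustes comparison of two score configurations: both
#' matrices are column-centred and scaled to unit total sum of squares, the
#' optimal rotation comes from the SVD of their cross-product, and the
#' Procrustes statistic is `m2 = 1 - (sum of singular values)^2`, with
#' correlation `sqrt(1 - m2)` and `rmse = sqrt(m2 / n)`.  Significance by
#' row permutation of `y` (one-sided: permuted fits should be worse);
#' `n_perm = "all"` enumerates exactly.
#'
#' @param scores_x,scores_y [shape_scores()] or matrices over the same
#'   specimens (>= 3); axes truncated to the common count.
#' @param n_perm Number of permutations (printed setting 9999) or `"all"`.
#' @param seed Integer seed.
#' @return Tibble with `ss_m2`, `rmse`, `correlation`, `p_value`, `n_perm`.
#' @export
protest <- function(scores_x, scores_y, n_perm = 9999L, seed = 1L) {
  X <- score_matrix(scores_x); Y <- score_matrix(scores_y)
  stopifnot(nrow(X) == nrow(Y))
  n <- nrow(X)
  if (n < 3) stop("fewer than 3 specimens")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)))
    Y <- Y[rownames(X), , drop = FALSE]
  k <- min(ncol(X), ncol(Y))
  X <- X[, seq_len(k), drop = FALSE]; Y <- Y[, seq_len(k), drop = FALSE]
  norm_cfg <- function(M) {
    M <- sweep(M, 2, colMeans(M))
    M / sqrt(sum(M^2))
  }
  X <- norm_cfg(X); Y <- norm_cfg(Y)
  m2_obs <- protest_m2(X, Y)
  if (identical(n_perm, "all")) {
    perms <- all_permutations(n)
    m2s <- apply(perms, 1, function(pp) protest_m2(X, norm_cfg(Y[pp, ,
                                                                 drop = FALSE])))
    p <- mean(m2s <= m2_obs + 1e-12)
    n_used <- nrow(perms)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                        globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    m2s <- replicate(n_perm,
                     protest_m2(X, norm_cfg(Y[sample.int(n), , drop = FALSE])))
    p <- (1 + sum(m2s <= m2_obs + 1e-12)) / (1 + n_perm)
    n_used <- n_perm
  }
  m2c <- min(max(m2_obs, 0), 1)
  tibble::tibble(ss_m2 = m2_obs, rmse = sqrt(m2c / n),
                 correlation = sqrt(1 - m2c), p_value = p, n_perm = n_used)
}

#' Correlation between two eigenvalue spectra
#'
#' [linear_fit_r2()] applied to the paired percent-of-variance spectra of
#' two shape spaces (landmark PCA vs momenta kPCA).
#'
#' @param spec_a,spec_b Percent-per-axis vectors of equal length.
#' @return Tibble with `r_squared` and `p_value`.
#' @export
eigenvalue_correlation <- function(spec_a, spec_b) {
  stopifnot(length(spec_a) == length(spec_b))
  fit <- linear_fit_r2(spec_a, spec_b)
  tibble::tibble(r_squared = fit$r_squared, p_value = fit$p_value)
}

#' Auxiliary two-sample and rank-correlation statistics
#'
#' `welch_t`: unequal-variance t statistic with Welch-Satterthwaite degrees
#' of freedom (two-sided p).  `spearman`: rank correlation with midrank tie
#' handling; for n < 10 the p-value comes from exact permutation of the
#' ranks, otherwise from the asymptotic t approximation.
#'
#' @param a,b Numeric vectors (paired for `spearman`).
#' @param kind `"welch_t"` or `"spearman"`.
#' @return Tibble with `statistic`, `df` (welch) or `n` (spearman), `p_value`.
#' @export
auxiliary_stats <- function(a, b, kind = c("welch_t", "spearman")) {
  kind <- match.arg(kind)
  if (kind == "welch_t") {
    stopifnot(length(a) >= 2, length(b) >= 2)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      if (mean(a) == mean(b))
        return(tibble::tibble(statistic = 0, df = NA_real_, p_value = 1))
      stop("zero variance in both samples")
    }
    tt <- stats::t.test(a, b, var.equal = FALSE)
    tibble::tibble(statistic = unname(tt$statistic),
                   df = unname(tt$parameter), p_value = tt$p.value)
  } else {
    stopifnot(length(a) == length(b), length(a) >= 3)
    n <- length(a)
    rho <- stats::cor(a, b, method = "spearman")
    p <- if (n < 10) {
      perms <- all_permutations(n)
      ra <- rank(a); rb <- rank(b)
      rhos <- apply(perms, 1, function(pp) stats::cor(ra, rb[pp]))
      mean(abs(rhos) >= abs(rho) - 1e-12)
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * stats::pt(-abs(tstat), n - 2)
    }
    tibble::tibble(statistic = rho, n = n, p_value = p)
  }
}

#' Per-vertex distances between two meshes for heatmap rendering
#'
#' `corresponding` mode: `|a_i - b_i|` per vertex (equal vertex counts and
#' ordering, e.g. a TPS-warped pair).  `closest` mode: distance from each
#' vertex of `a` to the nearest point on surface `b` (exact point-to-
#' triangle), the mode for specimen-vs-atlas comparisons where vertex
#' counts differ.  With `signed = TRUE` each distance is multiplied by the
#' sign of the displacement's projection on `a`'s outward vertex normal
#' (corresponding mode) or by -1 where the vertex lies inside `b` (closest
#' mode).
#'
#' @param a,b [mesh3t()] meshes.
#' @param mode `"corresponding"` or `"closest"`.
#' @param signed Return signed distances?
#' @return Numeric vector, one value per vertex of `a`.
#' @export
per_vertex_distance <- function(a, b, mode = c("corresponding", "closest"),
                                signed = FALSE) {
  mode <- match.arg(mode)
  if (mode == "corresponding") {
    if (nrow(a$vertices) != nrow(b$vertices))
      stop("corresponding mode requires equal vertex counts")
    disp <- b$vertices - a$vertices
    d <- sqrt(rowSums(disp^2))
    if (signed) {
      s <- sign(rowSums(disp * vertex_normals(a)))
      s[s == 0] <- 1
      d <- d * s
    }
    d
  } else {
    d <- cpp_point_surface_dist(a$vertices, b$vertices, b$faces)
    if (signed) {
      inside <- cpp_inside_pseudonormal(a$vertices, b$vertices,
                                        vertex_normals(b))
      d <- d * ifelse(inside, -1, 1)
    }
    d
  }
}
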
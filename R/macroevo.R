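#' Read a rooted phylogeny and its Brownian-motion covariance
#'
#' `read_newick()` wraps [ape::read.tree()] with validation (unique tips,
#' strictly positive branch lengths).  `phylo_covariance()` returns the
#' Brownian-motion tip covariance `C_ij` = shared root-to-tip path length of
#' tips i and j (diagonal = tip depths), the matrix every downstream
#' phylogenetic statistic uses.
#'
#' @param path Newick file path.
#' @param tree An `ape` `phylo` object.
#' @return `read_newick()`: a `phylo`; `phylo_covariance()`: a symmetric
#'   PSD matrix with tip-label dimnames.
#' @export
read_newick <- function(path) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("could not parse Newick file")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  if (is.null(tree$edge.length) || any(tree$edge.length <= 0))
    stop("tree must have strictly positive branch lengths")
  tree
}

#' @rdname read_newick
#' @export
phylo_covariance <- function(tree) {
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must have non-negative branch lengths")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  ape::vcv(tree)
}

# align a score matrix's rows to the tree's tips
align_to_tips <- function(Y, tree) {
  if (is.null(rownames(Y))) {
    if (nrow(Y) != length(tree$tip.label))
      stop("scores and tree tips differ in number")
    rownames(Y) <- tree$tip.label
    return(Y)
  }
  if (!setequal(rownames(Y), tree$tip.label))
    stop("score rows and tree tips must match")
  Y[tree$tip.label, , drop = FALSE]
}

kmult_stat <- function(Y, Cinv, denom_expect) {
  one <- rep(1, nrow(Y))
  a <- drop(crossprod(one, Cinv) %*% Y) / sum(Cinv)
  R <- sweep(Y, 2, a)
  num <- sum(R^2)
  den <- sum(R * (Cinv %*% R))
  (num / den) / denom_expect
}

#' Multivariate phylogenetic signal K_mult
#'
#' Multivariate generalisation of Blomberg's K: the ratio of the summed
#' squared Euclidean distances of the tip rows to the GLS root estimate over
#' the same quantity under the phylogenetic inverse-covariance metric,
#' divided by its Brownian-motion expectation
#' `(tr(C) - N / (1' Cinv 1)) / (N - 1)`.  Reduces exactly to Blomberg's K
#' for one trait, and equals 1 for any data on a star phylogeny with equal
#' tip depths.  Significance by permutation of the tip rows.
#'
#' @param scores A [shape_scores()] or matrix with specimen row names
#'   matching the tree tips.
#' @param tree Rooted `phylo` with positive branch lengths (>= 4 tips).
#' @param n_perm Permutations (printed setting 99).
#' @param seed Integer seed.
#' @return Tibble with `K`, `p_value`, `n_perm`.
#' @export
kmult <- function(scores, tree, n_perm = 99L, seed = 1L) {
  Y <- align_to_tips(score_matrix(scores), tree)
  N <- nrow(Y)
  if (N < 4) stop("need at least 4 tips")
  if (sum(scale(Y, scale = FALSE)^2) == 0) stop("zero total variance")
  C <- phylo_covariance(tree)
  ch <- tryCatch(chol(C), error = function(e)
    stop("phylogenetic covariance is (near-)singular: duplicated tips?"))
  Cinv <- chol2inv(ch)
  denom_expect <- (sum(diag(C)) - N / sum(Cinv)) / (N - 1)
  K_obs <- kmult_stat(Y, Cinv, denom_expect)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  Ks <- replicate(n_perm, kmult_stat(Y[sample.int(N), , drop = FALSE],
                                     Cinv, denom_expect))
  p <- (1 + sum(Ks >= K_obs - 1e-12)) / (1 + n_perm)
  tibble::tibble(K = K_obs, p_value = p, n_perm = n_perm)
}

#' Morphological disparity (Procrustes variance) by group
#'
#' Per-group Procrustes variance `PV_g = sum_{i in g} |y_i - ybar_g|^2 /
#' n_g` with pairwise `|PV_a - PV_b|` differences tested by permutation of
#' the group labels.
#'
#' @param scores A [shape_scores()] or matrix.
#' @param groups Named character vector (specimen -> group) or vector in row
#'   order; every group needs >= 2 specimens.
#' @param n_perm Label permutations (default 999).
#' @param seed Integer seed.
#' @return List of tibbles: `disparity` (group, n, proc_var) and `pairwise`
#'   (group_a, group_b, difference, p_value).
#' @export
morphological_disparity <- function(scores, groups, n_perm = 999L,
                                    seed = 1L) {
  Y <- score_matrix(scores)
  g <- resolve_groups(groups, Y)
  if (any(table(g) < 2)) stop("every group needs at least 2 specimens")
  pv <- function(gg) {
    vapply(split(seq_len(nrow(Y)), gg), function(idx) {
      Z <- Y[idx, , drop = FALSE]
      sum(sweep(Z, 2, colMeans(Z))^2) / length(idx)
    }, 0)
  }
  pv_obs <- pv(g)
  lev <- names(pv_obs)
  pairs <- utils::combn(lev, 2)
  diff_obs <- abs(pv_obs[pairs[1, ]] - pv_obs[pairs[2, ]])
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  exceed <- rep(0, ncol(pairs))
  for (b in seq_len(n_perm)) {
    pvp <- pv(sample(g))
    exceed <- exceed +
      (abs(pvp[pairs[1, ]] - pvp[pairs[2, ]]) >= diff_obs - 1e-12)
  }
  list(disparity = tibble::tibble(group = lev, n = as.integer(table(g)[lev]),
                                  proc_var = unname(pv_obs[lev])),
       pairwise = tibble::tibble(group_a = pairs[1, ], group_b = pairs[2, ],
                                 difference = unname(diff_obs),
                                 p_value = unname((1 + exceed) / (1 + n_perm))))
}

resolve_groups <- function(groups, Y) {
  g <- if (!is.null(names(groups)) && !is.null(rownames(Y)))
    groups[rownames(Y)] else groups
  if (length(g) != nrow(Y) || anyNA(g))
    stop("every specimen must be labelled")
  as.character(g)
}

#' Compare multivariate Brownian-motion rates between groups
#'
#' Per-group rate `sigma2_g`: the mean over the group's tips of the squared
#' Euclidean norms of the phylogenetically transformed residuals (inverse
#' symmetric square root of C applied to the deviations from the GLS root
#' state), divided by the trait dimension.  The statistic is the max/min
#' rate ratio; its null distribution comes from seeded Brownian-motion
#' simulations on the same tree under the pooled single-rate model.
#'
#' @param scores A [shape_scores()] or matrix (rows = tips).
#' @param tree Rooted `phylo`.
#' @param groups Named specimen -> group map (>= 2 groups for a test).
#' @param n_sim Null simulations (printed setting 100).
#' @param seed Integer seed.
#' @return List: `rates` tibble (group, n, sigma2), `ratio`, `p_value`.
#' @export
compare_evolutionary_rates <- function(scores, tree, groups, n_sim = 100L,
                                       seed = 1L) {
  Y <- align_to_tips(score_matrix(scores), tree)
  g <- resolve_groups(groups, Y)
  if (!setequal(names(table(g)), unique(g))) stop("group mismatch")
  N <- nrow(Y); m <- ncol(Y)
  C <- phylo_covariance(tree)
  eg <- eigen(C, symmetric = TRUE)
  if (any(eg$values <= 1e-12 * max(eg$values)))
    stop("phylogenetic covariance is (near-)singular")
  Cinv_half <- eg$vectors %*% diag(1 / sqrt(eg$values)) %*% t(eg$vectors)
  C_half <- eg$vectors %*% diag(sqrt(eg$values)) %*% t(eg$vectors)
  Cinv <- eg$vectors %*% diag(1 / eg$values) %*% t(eg$vectors)
  one <- rep(1, N)
  rate_by_group <- function(Yx, gg) {
    a <- drop(crossprod(one, Cinv) %*% Yx) / sum(Cinv)
    Z <- Cinv_half %*% sweep(Yx, 2, a)
    sq <- rowSums(Z^2) / m
    vapply(split(sq, gg), mean, 0)
  }
  sig_obs <- rate_by_group(Y, g)
  ratio_obs <- max(sig_obs) / min(sig_obs)
  lev <- names(sig_obs)
  out_rates <- tibble::tibble(group = lev, n = as.integer(table(g)[lev]),
                              sigma2 = unname(sig_obs[lev]))
  if (length(lev) < 2L)
    return(list(rates = out_rates, ratio = 1, p_value = NA_real_))
  pooled <- mean(rowSums((Cinv_half %*%
                            sweep(Y, 2, drop(crossprod(one, Cinv) %*% Y) /
                                    sum(Cinv)))^2) / m)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_sim)) {
    Ysim <- C_half %*% matrix(stats::rnorm(N * m, 0, sqrt(pooled)), N, m)
    rownames(Ysim) <- rownames(Y)
    sb <- rate_by_group(Ysim, g)
    if (max(sb) / min(sb) >= ratio_obs - 1e-12) exceed <- exceed + 1L
  }
  list(rates = out_rates, ratio = ratio_obs,
       p_value = (1 + exceed) / (1 + n_sim))
}
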
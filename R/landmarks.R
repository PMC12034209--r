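#' Landmark configuration
#'
#' An ordered set of homologous 3D points for one specimen: fixed anatomical
#' landmarks plus curve semilandmarks grouped into ordered curves.  Point
#' order must be identical across the specimens of a study.
#'
#' @param points `k x 3` numeric matrix of coordinates (mm).
#' @param curves List of integer vectors, each the ordered point indices of
#'   one semilandmark curve (each of length >= 2).  Points not in any curve
#'   are fixed landmarks.
#' @param specimen_id Optional identifier.
#' @return An object of class `landmark_config`.
#' @export
landmark_config <- function(points, curves = list(), specimen_id = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  if (ncol(points) != 3L) stop("points must have 3 columns")
  roles <- rep("fixed", nrow(points))
  for (ci in seq_along(curves)) {
    idx <- as.integer(curves[[ci]])
    if (length(idx) < 2L) stop("each curve needs at least 2 points")
    if (any(idx < 1L | idx > nrow(points))) stop("curve index out of range")
    roles[idx] <- paste0("curve:", ci)
  }
  structure(list(points = points, curves = lapply(curves, as.integer),
                 roles = roles, specimen_id = specimen_id),
            class = "landmark_config")
}

as_landmark_matrix <- function(x) {
  if (inherits(x, "landmark_config")) x$points
  else {
    m <- as.matrix(x)
    storage.mode(m) <- "double"
    m
  }
}

with_points <- function(config, points) {
  if (inherits(config, "landmark_config")) {
    config$points <- points
    config
  } else points
}

#' Resample a polyline to equally spaced points
#'
#' Places `k` points at equal arc-length spacing along a 3D polyline,
#' preserving both endpoints exactly.  Used to bring semilandmark curves to
#' a common point count across specimens.
#'
#' @param polyline `m x 3` matrix of ordered points (m >= 2).
#' @param k Number of output points (>= 2).
#' @return `k x 3` matrix.
#' @export
resample_curve <- function(polyline, k) {
  polyline <- as.matrix(polyline)
  if (nrow(polyline) < 2L) stop("polyline needs at least 2 points")
  if (k < 2L) stop("k must be >= 2")
  seg <- sqrt(rowSums(diff(polyline)^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  if (total == 0) stop("zero-length polyline")
  targets <- seq(0, total, length.out = k)
  out <- matrix(0, k, 3)
  out[1, ] <- polyline[1, ]
  out[k, ] <- polyline[nrow(polyline), ]
  for (i in seq(2, k - 1)) {
    s <- targets[i]
    j <- findInterval(s, cum, rightmost.closed = TRUE)
    w <- (s - cum[j]) / (cum[j + 1] - cum[j])
    out[i, ] <- (1 - w) * polyline[j, ] + w * polyline[j + 1, ]
  }
  out
}

# TPS pieces ----------------------------------------------------------------

tps_kernel_matrix <- function(a, b) {
  # U(r) = -r, the 3-D biharmonic convention; conditionally positive
  # definite of order 1, so w' K w >= 0 whenever P' w = 0.
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * tcrossprod(a, b)
  -sqrt(pmax(d2, 0))
}

#' Thin-plate spline model and mesh warp
#'
#' Fits the 3D thin-plate spline with kernel U(r) = -r interpolating
#' `source` landmarks onto `target` landmarks exactly, and (for
#' `tps_warp()`) maps every mesh vertex through the spline.  The bending
#' energy is the non-affine quadratic form `sum_d w_d' K w_d`; it is zero
#' exactly when the landmark map is affine.
#'
#' @param source,target Landmark matrices (k x 3, k >= 4, source
#'   non-coplanar) or [landmark_config()] objects in corresponding order.
#' @param mesh A [mesh3t()] to deform.
#' @return `tps_model()`: an object of class `tps3d` with elements `source`,
#'   `target`, `weights` (non-affine), `affine` (4 x 3, intercept first) and
#'   `bending_energy`.  `tps_apply()`: the mapped points.  `tps_warp()`: a
#'   list with the warped `mesh` and the `model`.
#' @export
tps_model <- function(source, target) {
  S <- as_landmark_matrix(source)
  T_ <- as_landmark_matrix(target)
  if (nrow(S) != nrow(T_)) stop("landmark counts differ")
  if (nrow(S) < 4L) stop("TPS needs at least 4 landmarks")
  if (anyDuplicated(S))
    stop_morpho("duplicated source landmarks make the TPS system singular",
                "tps_singular")
  k <- nrow(S)
  P <- cbind(1, S)
  if (qr(P)$rank < 4L)
    stop_morpho("coplanar source landmarks make the TPS system singular",
                "tps_singular")
  K <- tps_kernel_matrix(S, S)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(T_, matrix(0, 4, 3))
  sol <- tryCatch(solve(L, rhs),
                  error = function(e)
                    stop_morpho("singular TPS system", "tps_singular"))
  W <- sol[seq_len(k), , drop = FALSE]
  A <- sol[k + 1:4, , drop = FALSE]
  be <- sum(vapply(1:3, function(d) drop(crossprod(W[, d], K %*% W[, d])),
                   0))
  structure(list(source = S, target = T_, weights = W, affine = A,
                 bending_energy = max(be, 0)), class = "tps3d")
}

#' @rdname tps_model
#' @param model A fitted `tps3d` object.
#' @param points Points to map through the spline.
#' @export
tps_apply <- function(model, points) {
  X <- as.matrix(points)
  U <- tps_kernel_matrix(X, model$source)
  cbind(1, X) %*% model$affine + U %*% model$weights
}

#' @rdname tps_model
#' @export
tps_warp <- function(mesh, source, target) {
  model <- tps_model(source, target)
  warped <- mesh3t(tps_apply(model, mesh$vertices), mesh$faces,
                   specimen_id = mesh$specimen_id)
  list(mesh = warped, model = model)
}

# Bending-energy matrix of a reference configuration: upper-left k x k block
# of the inverse of the bordered TPS system.
bending_energy_matrix <- function(reference) {
  S <- as_landmark_matrix(reference)
  k <- nrow(S)
  P <- cbind(1, S)
  K <- tps_kernel_matrix(S, S)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  solve(L)[seq_len(k), seq_len(k), drop = FALSE]
}

bending_energy_to_reference <- function(config, reference) {
  Be <- bending_energy_matrix(reference)
  X <- as_landmark_matrix(config)
  sum(vapply(1:3, function(d) drop(crossprod(X[, d], Be %*% X[, d])), 0))
}

#' Slide semilandmarks to minimise bending energy
#'
#' Curve semilandmarks (curve interiors; endpoints and fixed landmarks are
#' immobile) are moved along their local tangent directions to minimise the
#' thin-plate-spline bending energy of the map from the reference onto each
#' specimen.  One Gauss-Seidel sweep over the slidable points is performed
#' per outer iteration; when no explicit reference is given the Procrustes
#' consensus is used and recomputed after each outer iteration.  Bending
#' energy never increases within a sweep.
#'
#' @param configs List of [landmark_config()] with identical schemes.
#' @param reference Optional reference [landmark_config()] (or matrix)
#'   defining the bending-energy metric and the curve tangents.  Default:
#'   GPA consensus of `configs`.
#' @param n_iter Outer iterations (default 3).
#' @return List of slid [landmark_config()] objects, same order.
#' @export
slide_semilandmarks <- function(configs, reference = NULL, n_iter = 3L) {
  stopifnot(length(configs) >= 1L)
  curves <- configs[[1]]$curves
  if (length(curves) == 0L) return(configs)
  pts <- lapply(configs, as_landmark_matrix)
  use_consensus <- is.null(reference)
  for (outer in seq_len(n_iter)) {
    ref <- if (use_consensus) {
      gp <- generalized_procrustes(pts, with_scale = TRUE)
      gp$mean_shape
    } else as_landmark_matrix(reference)
    Be <- bending_energy_matrix(ref)
    # slidable points and their unit tangents from the reference
    slid_idx <- integer(0); tangents <- NULL
    for (cv in curves) {
      if (length(cv) < 3L) next
      inner <- cv[-c(1L, length(cv))]
      tg <- ref[cv[-(1:2)], , drop = FALSE] -
        ref[cv[seq_len(length(cv) - 2L)], , drop = FALSE]
      len <- sqrt(rowSums(tg^2))
      if (any(len == 0))
        stop_morpho("degenerate curve tangent (coincident reference points)",
                    "degenerate_tangent")
      slid_idx <- c(slid_idx, inner)
      tangents <- rbind(tangents, tg / len)
    }
    for (s in seq_along(pts)) {
      X <- pts[[s]]
      for (m in seq_along(slid_idx)) {
        i <- slid_idx[m]
        u <- tangents[m, ]
        g <- drop(Be[i, ] %*% X)      # gradient rows: (Be X)[i, ]
        if (Be[i, i] <= 0) next
        t_star <- -sum(u * g) / Be[i, i]
        X[i, ] <- X[i, ] + t_star * u
      }
      pts[[s]] <- X
    }
  }
  purrr::map2(configs, pts, with_points)
}

#' Generalised Procrustes analysis
#'
#' Iterative superimposition of landmark configurations: each is centred,
#' scaled to unit centroid size (when `with_scale`), and rotated onto the
#' consensus, which is re-estimated until it changes by less than 1e-10.
#' Reflections are never used.  The consensus is centred at the origin with
#' centroid size 1.
#'
#' @param configs List of [landmark_config()] objects or k x 3 matrices with
#'   equal landmark counts (k >= 3).
#' @param with_scale Remove size by scaling each configuration to unit
#'   centroid size (default TRUE)?
#' @return An object of class `procrustes_gpa`: list with `aligned` (list of
#'   k x 3 matrices), `mean_shape`, `centroid_sizes`.
#' @export
generalized_procrustes <- function(configs, with_scale = TRUE) {
  pts <- lapply(configs, as_landmark_matrix)
  n <- length(pts)
  if (n < 2L) stop("need at least 2 configurations")
  k <- nrow(pts[[1]])
  if (k < 3L) stop("need at least 3 landmarks")
  cs <- vapply(pts, function(p) sqrt(sum(scale(p, scale = FALSE)^2)), 0)
  if (any(cs == 0))
    stop_morpho("all-coincident landmarks (zero centroid size)",
                "degenerate_landmarks")
  X <- lapply(seq_len(n), function(i) {
    p <- sweep(pts[[i]], 2, colMeans(pts[[i]]))
    if (with_scale) p / cs[i] else p
  })
  consensus <- X[[1]]
  consensus <- consensus / sqrt(sum(consensus^2))
  for (it in 1:200) {
    X <- lapply(X, function(p) {
      sv <- svd(crossprod(p, consensus))
      d <- sign(det(sv$v %*% t(sv$u)))
      p %*% (sv$u %*% diag(c(1, 1, d)) %*% t(sv$v))
    })
    new_con <- Reduce(`+`, X) / n
    new_con <- sweep(new_con, 2, colMeans(new_con))
    new_con <- new_con / sqrt(sum(new_con^2))
    delta <- sqrt(sum((new_con - consensus)^2))
    consensus <- new_con
    if (delta < 1e-10) break
  }
  # canonical orientation: rotate the whole solution so the consensus sits
  # on its principal axes, making the output independent of the input frame
  sv <- svd(consensus)
  V <- sv$v
  for (j in 1:3) {
    col <- consensus %*% V[, j]
    if (col[which.max(abs(col))] < 0) V[, j] <- -V[, j]
  }
  if (det(V) < 0) V[, 3] <- -V[, 3]
  consensus <- consensus %*% V
  X <- lapply(X, function(p) p %*% V)
  aligned <- purrr::map2(configs, X, with_points)
  structure(list(aligned = aligned, mean_shape = consensus,
                 centroid_sizes = cs), class = "procrustes_gpa")
}

#' Mirror a half-side landmark configuration across its midline plane
#'
#' Fits the least-squares plane through the midline landmarks and appends a
#' reflected copy of every non-midline point, turning a one-sided scheme
#' into a bilaterally complete one.  Midline points are not duplicated.
#'
#' @param config A [landmark_config()] or k x 3 matrix.
#' @param midline_indices Indices (>= 3, non-collinear) of points on the
#'   midsagittal plane.
#' @return Matrix with the reflected copies appended; attribute
#'   `mirror_pairs` is a two-column matrix pairing each original one-sided
#'   index with its mirrored row.
#' @export
mirror_configuration <- function(config, midline_indices) {
  X <- as_landmark_matrix(config)
  if (length(midline_indices) < 3L)
    stop_morpho("need >= 3 midline points to define the plane",
                "degenerate_landmarks")
  M <- X[midline_indices, , drop = FALSE]
  ctr <- colMeans(M)
  sv <- svd(sweep(M, 2, ctr))
  normal <- sv$v[, 3]
  side <- setdiff(seq_len(nrow(X)), midline_indices)
  d <- drop(sweep(X[side, , drop = FALSE], 2, ctr) %*% normal)
  reflected <- X[side, , drop = FALSE] - 2 * outer(d, normal)
  out <- rbind(X, reflected)
  attr(out, "mirror_pairs") <- cbind(original = side,
                                     mirrored = nrow(X) + seq_along(side))
  out
}

#' Principal component analysis of Procrustes-aligned landmarks
#'
#' Ordinary PCA (singular-value route) of the centred, flattened aligned
#' coordinates: at most n-1 axes with non-negative eigenvalues sorted
#' descending.  Sign convention: each axis is oriented so that its
#' largest-magnitude loading is positive.
#'
#' @param proc A `procrustes_gpa` result.
#' @param specimen_ids Optional ids; defaults to ids stored in the configs.
#' @return A [shape_scores()] object with `axis_kind = "pca"`.
#' @export
landmark_pca <- function(proc, specimen_ids = NULL) {
  mats <- lapply(proc$aligned, as_landmark_matrix)
  n <- length(mats)
  flat <- t(vapply(mats, function(m) as.vector(t(m)), numeric(3 * nrow(mats[[1]]))))
  ids <- specimen_ids %||%
    vapply(seq_len(n), function(i) {
      cfg <- proc$aligned[[i]]
      id <- if (inherits(cfg, "landmark_config")) cfg$specimen_id else NULL
      id %||% paste0("spec_", i)
    }, "")
  pc <- stats::prcomp(flat, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(n - 1L, ncol(pc$rotation)))
  scores <- pc$x[, keep, drop = FALSE]
  rot <- pc$rotation[, keep, drop = FALSE]
  # orient each axis so its largest-magnitude loading is positive
  for (j in seq_along(keep)) {
    l <- rot[, j]
    if (l[which.max(abs(l))] < 0) {
      rot[, j] <- -l
      scores[, j] <- -scores[, j]
    }
  }
  ev <- pc$sdev[keep]^2
  shape_scores(scores, ev, axis_kind = "pca", specimen_ids = ids)
}
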
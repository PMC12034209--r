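#' Standardise a mesh to a watertight surface
#'
#' Voxelises the mesh on a padded axis-aligned grid, classifies voxel
#' centres as inside/outside by their generalized winding number (> 1/2 is
#' inside), and extracts the boundary of the voxel solid as a consistently
#' oriented triangle surface (cuberille extraction with pinch repair).  The
#' winding-number field of an open mesh continues the missing patch
#' smoothly, so the reconstruction closes holes near the natural surface;
#' the output is watertight regardless of whether the input was open or
#' closed, with two-sided Hausdorff distance to a closed input bounded by
#' `2 * voxel_size * sqrt(3)`.  This standardisation removes the
#' open-vs-closed modality artifact of mixed CT/surface-scan populations.
#'
#' @param mesh A [mesh3t()]; may be open (boundary edges allowed).
#' @param voxel_size Edge length of the cubic voxels, mm.  Must be positive
#'   and at most a tenth of the bounding-box diagonal.
#' @return A watertight [mesh3t()].
#' @export
close_watertight <- function(mesh, voxel_size) {
  if (nrow(mesh$faces) == 0L) stop("empty mesh")
  bb <- mesh_bbox(mesh)
  diag_len <- sqrt(sum((bb["hi", ] - bb["lo", ])^2))
  if (voxel_size <= 0 || voxel_size > diag_len / 10)
    stop("voxel_size must be in (0, bounding-box diagonal / 10]")
  h <- voxel_size
  pad <- 2L
  origin <- bb["lo", ] - pad * h
  n <- ceiling((bb["hi", ] - origin) / h) + pad
  nx <- n[1]; ny <- n[2]; nz <- n[3]

  cx <- origin[1] + (seq_len(nx) - 0.5) * h
  cy <- origin[2] + (seq_len(ny) - 0.5) * h
  cz <- origin[3] + (seq_len(nz) - 0.5) * h
  centres <- cbind(rep(cx, times = ny * nz),
                   rep(rep(cy, each = nx), times = nz),
                   rep(cz, each = nx * ny))
  occ <- array(cpp_winding_number(centres, mesh$vertices,
                                  mesh$faces) > 0.5,
               dim = c(nx, ny, nz))
  if (!any(occ))
    stop_morpho("voxel grid too coarse: no interior voxels", "voxel_too_coarse")
  occ <- repair_pinches(occ)
  out <- cuberille_surface(occ, origin, h)
  out$specimen_id <- mesh$specimen_id
  out
}

# Make the voxel solid edge- and vertex-manifold by filling voxels at
# diagonal pinches; iterated to a fixpoint.
repair_pinches <- function(occ) {
  d <- dim(occ)
  shift2 <- function(a, off) {
    # a restricted to the overlap window offset by off (each in 0:1)
    a[(1 + off[1]):(d[1] - 1 + off[1]),
      (1 + off[2]):(d[2] - 1 + off[2]),
      (1 + off[3]):(d[3] - 1 + off[3]), drop = FALSE]
  }
  for (iter in 1:50) {
    changed <- FALSE
    # edge pinches: in each axis-aligned 2x2 cross-section, both diagonal
    # voxels solid and both anti-diagonal voxels empty
    for (ax in 1:3) {
      u <- c(0L, 0L, 0L); v <- c(0L, 0L, 0L)
      other <- setdiff(1:3, ax)
      u[other[1]] <- 1L; v[other[2]] <- 1L
      a00 <- shift2(occ, c(0L, 0L, 0L)); a11 <- shift2(occ, u + v)
      a10 <- shift2(occ, u); a01 <- shift2(occ, v)
      bad <- (a00 & a11 & !a10 & !a01) | (a10 & a01 & !a00 & !a11)
      if (any(bad)) {
        idx <- which(bad, arr.ind = TRUE)
        # fill the +u cell of each bad cross-section
        sel <- cbind(idx[, 1] + u[1], idx[, 2] + u[2], idx[, 3] + u[3])
        occ[sel] <- TRUE
        changed <- TRUE
      }
    }
    # vertex pinches: a 2x2x2 block whose solid set is exactly a main
    # diagonal pair
    corners <- as.matrix(expand.grid(0:1, 0:1, 0:1))
    blocks <- lapply(seq_len(8), function(i) shift2(occ, corners[i, ]))
    cnt <- Reduce(`+`, blocks)
    for (i in 1:4) {
      j <- 9 - i  # opposite corner
      bad <- blocks[[i]] & blocks[[j]] & (cnt == 2L)
      if (any(bad)) {
        idx <- which(bad, arr.ind = TRUE)
        off <- corners[i, ]; off[1] <- 1L - off[1]  # a face neighbour of corner i
        sel <- cbind(idx[, 1] + off[1], idx[, 2] + off[2], idx[, 3] + off[3])
        occ[sel] <- TRUE
        changed <- TRUE
        cnt <- Reduce(`+`, lapply(seq_len(8), function(k) shift2(occ, corners[k, ])))
        blocks <- lapply(seq_len(8), function(k) shift2(occ, corners[k, ]))
      }
    }
    if (!changed) break
  }
  occ
}

# Boundary quadrangulation of a voxel solid, split into triangles with
# outward orientation.  Voxel (i,j,k) spans corners (i-1..i, j-1..j, k-1..k).
cuberille_surface <- function(occ, origin, h) {
  d <- dim(occ)
  padded <- array(FALSE, d + 2L)
  padded[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- occ
  # corner offsets (relative to voxel corner i-1,j-1,k-1) per face, wound
  # so the normal points along the outward direction
  face_specs <- list(
    list(dir = c(1, 0, 0),  quad = rbind(c(1, 0, 0), c(1, 1, 0), c(1, 1, 1), c(1, 0, 1))),
    list(dir = c(-1, 0, 0), quad = rbind(c(0, 0, 0), c(0, 0, 1), c(0, 1, 1), c(0, 1, 0))),
    list(dir = c(0, 1, 0),  quad = rbind(c(0, 1, 0), c(0, 1, 1), c(1, 1, 1), c(1, 1, 0))),
    list(dir = c(0, -1, 0), quad = rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1))),
    list(dir = c(0, 0, 1),  quad = rbind(c(0, 0, 1), c(1, 0, 1), c(1, 1, 1), c(0, 1, 1))),
    list(dir = c(0, 0, -1), quad = rbind(c(0, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, 0, 0))))
  nxc <- d[1] + 1L; nyc <- d[2] + 1L  # corner-lattice dims for keying
  corner_key <- function(ijk) ijk[, 1] + nxc * (ijk[, 2] + nyc * ijk[, 3])
  tri_keys <- list()
  for (fs in face_specs) {
    nb <- padded[2:(d[1] + 1) + fs$dir[1], 2:(d[2] + 1) + fs$dir[2],
                 2:(d[3] + 1) + fs$dir[3], drop = FALSE]
    dim(nb) <- d
    expose <- occ & !nb
    if (!any(expose)) next
    vox <- which(expose, arr.ind = TRUE) - 1L  # corner base (i-1,j-1,k-1)
    q <- fs$quad
    ck <- lapply(1:4, function(m)
      corner_key(cbind(vox[, 1] + q[m, 1], vox[, 2] + q[m, 2],
                       vox[, 3] + q[m, 3])))
    tri_keys[[length(tri_keys) + 1L]] <- cbind(ck[[1]], ck[[2]], ck[[3]])
    tri_keys[[length(tri_keys) + 1L]] <- cbind(ck[[1]], ck[[3]], ck[[4]])
  }
  tk <- do.call(rbind, tri_keys)
  if (is.null(tk) || nrow(tk) == 0L)
    stop_morpho("voxel solid has no boundary surface", "voxel_too_coarse")
  keys <- sort(unique(as.vector(tk)))
  faces <- matrix(match(as.vector(tk), keys), ncol = 3)
  kz <- keys %/% (nxc * nyc)
  ky <- (keys %% (nxc * nyc)) %/% nxc
  kx <- keys %% nxc
  verts <- cbind(origin[1] + kx * h, origin[2] + ky * h, origin[3] + kz * h)
  mesh3t(verts, faces)
}

#' Quadric edge-collapse decimation
#'
#' Iterative edge collapse driven by the quadric error metric, reducing the
#' mesh to approximately `target_faces` faces.  Boundary edges of open meshes
#' are preserved exactly (edges touching a boundary vertex are never
#' collapsed); collapses that would break the edge manifold (link condition)
#' or flip a face normal are skipped.  If the target cannot be reached
#' without destroying manifoldness, decimation stops early and returns the
#' achieved count.
#'
#' @param mesh A [mesh3t()].
#' @param target_faces Desired face count, at least 4.
#' @return A [mesh3t()] with face count within 2 percent of
#'   `min(target_faces, input faces)` (or the achieved count on early stop).
#' @export
decimate_quadric <- function(mesh, target_faces) {
  if (target_faces < 4) stop("target_faces must be >= 4")
  if (nrow(mesh$faces) <= target_faces) return(mesh)
  V <- mesh$vertices
  F <- mesh$faces
  nv <- nrow(V); nf <- nrow(F)

  # per-vertex quadrics (area-weighted fundamental error quadrics)
  quad <- matrix(0, nv, 10)  # symmetric 4x4: a11 a12 a13 a14 a22 a23 a24 a33 a34 a44
  ofs <- oriented_face_set(mesh)
  area <- sqrt(rowSums(ofs$normals^2))
  nrm <- ofs$normals / pmax(area, 1e-300)
  dpl <- -rowSums(nrm * V[F[, 1], , drop = FALSE])
  kq <- cbind(nrm[, 1]^2, nrm[, 1] * nrm[, 2], nrm[, 1] * nrm[, 3],
              nrm[, 1] * dpl, nrm[, 2]^2, nrm[, 2] * nrm[, 3], nrm[, 2] * dpl,
              nrm[, 3]^2, nrm[, 3] * dpl, dpl^2) * area
  for (k in 1:3) {
    agg <- rowsum(kq, F[, k])
    quad[as.integer(rownames(agg)), ] <-
      quad[as.integer(rownames(agg)), ] + agg
  }
  quad_eval <- function(q, p) {
    q[, 1] * p[, 1]^2 + q[, 5] * p[, 2]^2 + q[, 8] * p[, 3]^2 +
      2 * (q[, 2] * p[, 1] * p[, 2] + q[, 3] * p[, 1] * p[, 3] +
             q[, 6] * p[, 2] * p[, 3] + q[, 4] * p[, 1] +
             q[, 7] * p[, 2] + q[, 9] * p[, 3]) + q[, 10]
  }

  eraw <- rbind(F[, 1:2], F[, 2:3], F[, c(3, 1)])
  ekey <- paste(pmin(eraw[, 1], eraw[, 2]), pmax(eraw[, 1], eraw[, 2]))
  emult <- table(ekey)
  boundary_v <- rep(FALSE, nv)
  bkeys <- names(emult)[emult == 1L]
  if (length(bkeys)) {
    bv <- as.integer(unlist(strsplit(bkeys, " ")))
    boundary_v[bv] <- TRUE
  }
  uek <- unique(ekey)
  E <- do.call(rbind, strsplit(uek, " "))
  E <- cbind(as.integer(E[, 1]), as.integer(E[, 2]))
  ne <- nrow(E)

  vfaces <- vector("list", nv)
  fl <- rep(seq_len(nf), 3)
  vl <- as.vector(F)
  sp <- split(fl, vl)
  vfaces[as.integer(names(sp))] <- sp
  vedges <- vector("list", nv)
  spe <- split(rep(seq_len(ne), 2), as.vector(E))
  vedges[as.integer(names(spe))] <- spe

  face_alive <- rep(TRUE, nf)
  edge_alive <- rep(TRUE, ne)
  vert_alive <- rep(TRUE, nv)

  edge_cost <- function(idx) {
    a <- E[idx, 1]; b <- E[idx, 2]
    qs <- quad[a, , drop = FALSE] + quad[b, , drop = FALSE]
    cand1 <- V[a, , drop = FALSE]; cand2 <- V[b, , drop = FALSE]
    cand3 <- (cand1 + cand2) / 2
    c1 <- quad_eval(qs, cand1); c2 <- quad_eval(qs, cand2)
    c3 <- quad_eval(qs, cand3)
    best <- pmin(c1, c2, c3)
    which_best <- max.col(-cbind(c1, c2, c3), ties.method = "first")
    list(cost = best, which = which_best)
  }
  cc <- edge_cost(seq_len(ne))
  cost <- cc$cost
  opt <- cc$which
  cost[boundary_v[E[, 1]] | boundary_v[E[, 2]]] <- Inf

  faces_left <- nf
  while (faces_left > target_faces) {
    cost[!edge_alive] <- Inf
    i <- which.min(cost)
    if (!is.finite(cost[i])) break
    a <- E[i, 1]; b <- E[i, 2]
    shared_f <- intersect(vfaces[[a]], vfaces[[b]])
    shared_f <- shared_f[face_alive[shared_f]]
    # link condition: common vertex neighbours must be exactly the opposite
    # vertices of the shared faces
    na_ <- setdiff(unique(as.vector(F[vfaces[[a]][face_alive[vfaces[[a]]]], ])), a)
    nb_ <- setdiff(unique(as.vector(F[vfaces[[b]][face_alive[vfaces[[b]]]], ])), b)
    common <- intersect(na_, nb_)
    opp <- setdiff(unique(as.vector(F[shared_f, , drop = FALSE])), c(a, b))
    if (length(shared_f) != 2L || length(common) != length(opp) ||
          faces_left - 2L < 4L) {
      cost[i] <- Inf
      next
    }
    newp <- switch(opt[i], V[a, ], V[b, ], (V[a, ] + V[b, ]) / 2)
    # normal-flip guard on surviving faces around a and b
    ring <- setdiff(union(vfaces[[a]], vfaces[[b]]), shared_f)
    ring <- ring[face_alive[ring]]
    flip <- FALSE
    for (fi in ring) {
      tri <- F[fi, ]
      p_old <- V[tri, , drop = FALSE]
      p_new <- p_old
      p_new[tri == a | tri == b, ] <- matrix(newp, sum(tri == a | tri == b),
                                             3, byrow = TRUE)
      n_old <- cross3(p_old[2, ] - p_old[1, ], p_old[3, ] - p_old[1, ])
      n_new <- cross3(p_new[2, ] - p_new[1, ], p_new[3, ] - p_new[1, ])
      if (sum(n_old * n_new) <= 0) { flip <- TRUE; break }
    }
    if (flip) { cost[i] <- Inf; next }

    # perform the collapse: b merges into a at newp
    V[a, ] <- newp
    quad[a, ] <- quad[a, ] + quad[b, ]
    vert_alive[b] <- FALSE
    face_alive[shared_f] <- FALSE
    faces_left <- faces_left - length(shared_f)
    for (fi in setdiff(vfaces[[b]], shared_f)) F[fi, ][F[fi, ] == b] <- a
    vfaces[[a]] <- setdiff(union(vfaces[[a]], vfaces[[b]]), shared_f)
    vfaces[[b]] <- integer(0)
    edge_alive[i] <- FALSE
    # re-point b's edges to a, dropping duplicates
    eb <- vedges[[b]][edge_alive[vedges[[b]]]]
    for (ei in eb) E[ei, ][E[ei, ] == b] <- a
    ea <- unique(c(vedges[[a]][edge_alive[vedges[[a]]]], eb))
    keyz <- paste(pmin(E[ea, 1], E[ea, 2]), pmax(E[ea, 1], E[ea, 2]))
    dup <- duplicated(keyz) | E[ea, 1] == E[ea, 2]
    edge_alive[ea[dup]] <- FALSE
    ea <- ea[!dup]
    vedges[[a]] <- ea
    vedges[[b]] <- integer(0)
    if (length(ea)) {
      cc <- edge_cost(ea)
      cost[ea] <- cc$cost
      opt[ea] <- cc$which
      cost[ea[boundary_v[E[ea, 1]] | boundary_v[E[ea, 2]]]] <- Inf
    }
  }

  keep_f <- which(face_alive)
  keep_v <- sort(unique(as.vector(F[keep_f, ])))
  remap <- integer(nv)
  remap[keep_v] <- seq_along(keep_v)
  out <- mesh3t(V[keep_v, , drop = FALSE],
                matrix(remap[as.vector(F[keep_f, ])], ncol = 3),
                specimen_id = mesh$specimen_id)
  if (faces_left > target_faces * 1.02)
    rlang::warn(sprintf("decimation stopped early at %d faces (target %d)",
                        faces_left, target_faces),
                class = "morphoatlas_warning_decimation_early_stop")
  out
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rigidly align a mesh onto a target landmark configuration
#'
#' Fits the least-squares rigid-body transform (rotation + translation,
#' reflections disallowed) mapping `source_lm` onto `target_lm` and applies
#' it to every mesh vertex.  With `with_scale = TRUE` the mesh is first
#' scaled by the ratio of target to source centroid sizes, removing
#' size-related effects before shape comparison.
#'
#' @param mesh A [mesh3t()] on which `source_lm` was digitised.
#' @param source_lm,target_lm Landmark matrices (k x 3, k >= 3,
#'   non-collinear) in corresponding order, or [landmark_config()] objects.
#' @param with_scale Apply the centroid-size ratio before the rigid fit?
#' @return The transformed [mesh3t()]; topology (faces) is untouched.
#' @export
align_mesh_to_landmarks <- function(mesh, source_lm, target_lm,
                                    with_scale = FALSE) {
  S <- as_landmark_matrix(source_lm)
  T_ <- as_landmark_matrix(target_lm)
  if (nrow(S) != nrow(T_)) stop("landmark counts differ")
  if (nrow(S) < 3)
    stop_morpho("at least 3 landmarks are required", "degenerate_landmarks")
  cs <- colMeans(S); ct <- colMeans(T_)
  S0 <- sweep(S, 2, cs); T0 <- sweep(T_, 2, ct)
  if (qr(S0)$rank < 2)
    stop_morpho("collinear landmark configuration", "degenerate_landmarks")
  scale <- 1
  if (with_scale) {
    scale <- sqrt(sum(T0^2)) / sqrt(sum(S0^2))
    S0 <- S0 * scale
  }
  sv <- svd(crossprod(S0, T0))
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  Vm <- sweep(mesh$vertices, 2, cs)
  Vm <- (Vm * scale) %*% t(R)
  Vm <- sweep(Vm, 2, ct, `+`)
  mesh3t(Vm, mesh$faces, specimen_id = mesh$specimen_id)
}
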
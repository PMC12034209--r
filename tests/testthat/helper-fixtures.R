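# small fixtures built in code

# a random small closed-ish triangle soup (two triangles on four vertices)
random_patch_mesh <- function(seed, n_extra = 0) {
  set.seed(seed)
  v <- matrix(rnorm(12 + 3 * n_extra), ncol = 3)
  f <- rbind(c(1, 2, 3), c(1, 3, 4))
  if (n_extra > 0)
    for (k in seq_len(n_extra)) f <- rbind(f, c(1, 3 + k, 4 + k))
  mesh3t(v, f)
}

# brute-force double-loop attachment oracle, written independently of the
# vectorised implementation
oracle_attachment <- function(a, b, sigma_w, varifold) {
  ip <- function(X, Y) {
    s <- 0
    for (p in seq_len(nrow(X$centres))) {
      np <- X$normals[p, ]
      if (varifold && sqrt(sum(np^2)) == 0) next
      for (q in seq_len(nrow(Y$centres))) {
        nq <- Y$normals[q, ]
        if (varifold && sqrt(sum(nq^2)) == 0) next
        K <- exp(-sum((X$centres[p, ] - Y$centres[q, ])^2) / sigma_w^2)
        nn <- sum(np * nq)
        s <- s + if (varifold) K * nn^2 / (sqrt(sum(np^2)) * sqrt(sum(nq^2)))
                 else K * nn
      }
    }
    s
  }
  A <- suppressWarnings(oriented_face_set(a))
  B <- suppressWarnings(oriented_face_set(b))
  ip(A, A) - 2 * ip(A, B) + ip(B, B)
}

# random rotation matrix (uniform via QR)
random_rotation <- function(seed) {
  set.seed(seed)
  qr_ <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# landmark configuration with one curve, for sliding/TPS tests
demo_config <- function(seed = 1, jitter = 0) {
  set.seed(seed)
  fixed <- matrix(rnorm(15, sd = 3), 5, 3)
  curve <- cbind(seq(0, 10, length.out = 6), 0, 0) +
    matrix(rnorm(18, sd = jitter), 6, 3)
  landmark_config(rbind(fixed, curve), curves = list(5 + 1:6))
}

boundary_edge_key <- function(mesh) {
  e <- morphoatlas:::edge_multiplicity(mesh)
  names(e)[e == 1L]
}

# coordinates (as strings) of the vertices on the boundary loop
boundary_vertex_coords <- function(mesh) {
  keys <- boundary_edge_key(mesh)
  idx <- unique(as.integer(unlist(strsplit(keys, " "))))
  apply(round(mesh$vertices[idx, , drop = FALSE], 9), 1, paste,
        collapse = ",")
}
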